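# ImageJ .roi record codec, a store-only RoiSet.zip writer, the plain-text
# polygon dialect, and tabular measurement output.

IJ_TYPE_POLYGON <- 0L
IJ_TYPE_FREELINE <- 4L
IJ_TYPE_POLYLINE <- 5L
IJ_TYPE_FREEHAND <- 7L
IJ_TYPE_TRACED <- 8L

#' Write an ImageJ .roi record
#'
#' Encodes a polygon or polyline as a version-227 ImageJ ROI record with
#' 16-bit integer coordinates. Internal pixel-center coordinates are shifted
#' by +0.5 into ImageJ's pixel-corner convention and rounded.
#'
#' @param roi a [polygon_roi()] or [polyline_roi()].
#' @param path output path (conventionally `*.roi`).
#' @return `path`, invisibly.
#' @export
write_imagej_roi <- function(roi, path) {
  v <- roi$vertices + 0.5
  xi <- as.integer(round(v[, 1]))
  yi <- as.integer(round(v[, 2]))
  left <- min(xi); top <- min(yi)
  type <- if (inherits(roi, "polygon_roi")) IJ_TYPE_POLYGON else IJ_TYPE_POLYLINE
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("Iout"), con)
  writeBin(c(227L, 0L), con, size = 2, endian = "big")  # version, type byte pair
  # rewrite type byte: bytes 6-7 are (type, 0)
  seek(con, 6)
  writeBin(as.raw(c(type, 0L)), con)
  writeBin(as.integer(c(top, left, max(yi), max(xi), length(xi))), con,
           size = 2, endian = "big")
  writeBin(raw(64 - 18), con)  # unused header fields through byte 63
  writeBin(xi - left, con, size = 2, endian = "big")
  writeBin(yi - top, con, size = 2, endian = "big")
  invisible(path)
}

read_imagej_roi <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 64 || rawToChar(raw[1:4]) != "Iout") {
    stop("not an ImageJ ROI record: ", path)
  }
  type <- as.integer(raw[7])
  be_short <- function(off, n = 1L) {
    readBin(raw[(off + 1L):(off + 2L * n)], "integer", n = n, size = 2,
            endian = "big")
  }
  top <- be_short(8); left <- be_short(10)
  n <- be_short(16)
  if (n < 1L) stop("corrupt ROI record (no coordinates): ", path)
  if (length(raw) < 64 + 4L * n) stop("corrupt ROI record (truncated): ", path)
  xs <- be_short(64, n) + left
  ys <- be_short(64 + 2L * n, n) + top
  v <- cbind(x = xs, y = ys) - 0.5  # ImageJ corner -> internal center coords
  label <- sub("\\.roi$", "", basename(path), ignore.case = TRUE)
  if (type %in% c(IJ_TYPE_POLYGON, IJ_TYPE_FREEHAND, IJ_TYPE_TRACED)) {
    polygon_roi(v, label = label)
  } else if (type %in% c(IJ_TYPE_POLYLINE, IJ_TYPE_FREELINE)) {
    polyline_roi(v, label = label)
  } else {
    stop("unsupported ImageJ ROI type ", type, " in ", path)
  }
}

#' Write a RoiSet.zip archive
#'
#' Packs ImageJ .roi records into a ZIP archive using stored (uncompressed)
#' entries, readable by ImageJ and by [read_rois()].
#'
#' @param rois list of [polygon_roi()] / [polyline_roi()] objects; entry
#'   names come from each ROI's label.
#' @param path output `.zip` path.
#' @return `path`, invisibly.
#' @export
write_roi_zip <- function(rois, path) {
  entries <- lapply(seq_along(rois), function(i) {
    tmp <- tempfile(fileext = ".roi")
    write_imagej_roi(rois[[i]], tmp)
    dat <- readBin(tmp, "raw", n = file.size(tmp))
    unlink(tmp)
    list(name = paste0(rois[[i]]$label, ".roi"), data = dat)
  })
  zip_write_stored(entries, path)
  invisible(path)
}

# Minimal ZIP container with stored entries only (no compression).
zip_write_stored <- function(entries, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  le <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  offsets <- integer(length(entries))
  pos <- 0L
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    nm <- charToRaw(e$name)
    crc <- crc32(e$data)
    offsets[i] <- pos
    le(0x04034b50, 4); le(20, 2); le(0, 2); le(0, 2); le(0, 2); le(0, 2)
    writeBin(crc, con)
    le(length(e$data), 4); le(length(e$data), 4)
    le(length(nm), 2); le(0, 2)
    writeBin(nm, con); writeBin(e$data, con)
    pos <- pos + 30L + length(nm) + length(e$data)
  }
  cd_start <- pos
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    nm <- charToRaw(e$name)
    crc <- crc32(e$data)
    le(0x02014b50, 4); le(20, 2); le(20, 2); le(0, 2); le(0, 2)
    le(0, 2); le(0, 2)
    writeBin(crc, con)
    le(length(e$data), 4); le(length(e$data), 4)
    le(length(nm), 2); le(0, 2); le(0, 2); le(0, 2); le(0, 2); le(0, 4)
    le(offsets[i], 4)
    writeBin(nm, con)
    pos <- pos + 46L + length(nm)
  }
  le(0x06054b50, 4); le(0, 2); le(0, 2)
  le(length(entries), 2); le(length(entries), 2)
  le(pos - cd_start, 4); le(cd_start, 4); le(0, 2)
}

# CRC-32 (IEEE 802.3) of a raw vector, returned as 4 little-endian raw bytes.
# Implemented over a 256-entry table using byte-wise arithmetic on the four
# octets so no 32-bit signed overflow can occur.
crc32 <- function(data) {
  tab <- crc32_table()
  crc <- c(255L, 255L, 255L, 255L)  # bytes, LSB first (complemented)
  for (b in as.integer(data)) {
    idx <- bitwXor(crc[1], b) + 1L
    te <- tab[idx, ]
    crc <- c(bitwXor(crc[2], te[1]), bitwXor(crc[3], te[2]),
             bitwXor(crc[4], te[3]), te[4])
  }
  as.raw(bitwXor(crc, c(255L, 255L, 255L, 255L)))
}

crc32_table <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    poly <- c(0x20L, 0x83L, 0xb8L, 0xedL)  # 0xEDB88320, LSB first
    t <- matrix(0L, 256, 4)
    for (n in 0:255) {
      c4 <- c(n, 0L, 0L, 0L)
      for (k in 1:8) {
        lsb <- c4[1] %% 2L
        c4 <- c(c4[1] %/% 2L + (c4[2] %% 2L) * 128L,
                c4[2] %/% 2L + (c4[3] %% 2L) * 128L,
                c4[3] %/% 2L + (c4[4] %% 2L) * 128L,
                c4[4] %/% 2L)
        if (lsb == 1L) c4 <- bitwXor(c4, poly)
      }
      t[n + 1L, ] <- c4
    }
    tab <<- t
    tab
  }
})

# Plain-text dialect: one ROI per line,
#   [polygon|polyline] [label] x,y x,y x,y ...
read_text_rois <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    toks <- strsplit(lines[i], "[[:space:]]+")[[1]]
    kind <- "polygon"
    if (toks[1] %in% c("polygon", "polyline")) {
      kind <- toks[1]; toks <- toks[-1]
    }
    label <- sprintf("%s_%d", kind, i)
    if (!grepl(",", toks[1], fixed = TRUE)) {
      label <- toks[1]; toks <- toks[-1]
    }
    xy <- do.call(rbind, lapply(toks, function(t) {
      p <- suppressWarnings(as.numeric(strsplit(t, ",", fixed = TRUE)[[1]]))
      if (length(p) != 2L || anyNA(p)) stop("bad coordinate token '", t,
                                            "' in ", path)
      p
    }))
    out[[i]] <- if (kind == "polygon") polygon_roi(xy, label = label) else
      polyline_roi(xy, label = label)
  }
  out
}

#' Write measurement rows to delimited text
#'
#' Values survive a write/read round-trip to at least 10 significant digits
#' (doubles are serialized at R's full 15-digit precision).
#'
#' @param rows a data.frame of measurement records sharing one schema.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(rows, path) {
  if (!is.data.frame(rows)) rows <- as.data.frame(rows)
  write.csv(rows, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read measurement rows written by [write_measurements()]
#' @param path CSV path.
#' @return data.frame.
#' @export
read_measurements <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
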