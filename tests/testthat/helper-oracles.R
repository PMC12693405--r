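# Independent oracles used across test files. These deliberately use naive
# per-element loops or closed forms, not the package's vectorized paths.

# Even-odd point-in-polygon test for a single point (ray cast along +x).
pip_oracle <- function(px, py, verts) {
  n <- nrow(verts)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- verts[i, 1]; yi <- verts[i, 2]
    xj <- verts[j, 1]; yj <- verts[j, 2]
    if ((yi <= py) != (yj <= py)) {
      xint <- xi + (py - yi) * (xj - xi) / (yj - yi)
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

rasterize_oracle <- function(verts, h, w) {
  m <- matrix(FALSE, h, w)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      m[r, c] <- pip_oracle(c - 1, r - 1, verts)
    }
  }
  m
}

# Yen's criterion evaluated by direct summation at one candidate split.
yen_criterion_oracle <- function(counts, t) {
  p <- counts / sum(counts)
  i <- seq_along(p) - 1L
  p1 <- sum(p[i <= t]); p2 <- 1 - p1
  s1 <- sum(p[i <= t]^2); s2 <- sum(p[i > t]^2)
  (if (s1 * s2 > 0) -log(s1 * s2) else 0) +
    (if (p1 * p2 > 0) 2 * log(p1 * p2) else 0)
}

yen_oracle <- function(counts) {
  nz <- which(counts > 0)
  cand <- (min(nz) - 1L):(max(nz) - 2L)  # zero-based, both classes nonempty
  crit <- vapply(cand, function(t) yen_criterion_oracle(counts, t), 0)
  cand[which.max(crit)]
}

# AUC by exhaustive pair counting (Mann-Whitney with half-ties), oriented so
# that positives are expected to score LOWER.
auc_pairs_oracle <- function(scores, labels, direction = "lower") {
  s <- if (direction == "lower") -scores else scores
  pos <- s[labels]; neg <- s[!labels]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + (if (a > b) 1 else if (a == b) 0.5 else 0)
  }
  tot / (length(pos) * length(neg))
}

# A small textured test pattern at the cohort scale.
cohort_scale_pattern <- function(frac = 30, size = 400L, seed = 7L,
                                 phase = 0.3, noise_sd = 0.03, ...) {
  make_pattern(pattern_spec(size = c(size, size), scale = 0.01,
                            fp_period = 0.15 / (frac / 100),
                            noise_sd = noise_sd, seed = seed, phase = phase,
                            ...))
}

roi_truth_fraction <- function(pat, roi) {
  m <- rasterize_roi(roi, dim(pat$image$pixels))
  100 * sum(pat$truth$slit_mask & m) / sum(m)
}
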