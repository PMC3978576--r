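# Independent brute-force oracles used across the suite.

# direct 2-D convolution with edge replication (no separability tricks)
conv2d_brute <- function(m, kern) {
  r <- (nrow(kern) - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  padded <- m[pmin(pmax(seq_len(nr + 2 * r) - r, 1L), nr),
              pmin(pmax(seq_len(nc + 2 * r) - r, 1L), nc)]
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    out[i, j] <- sum(padded[i:(i + 2 * r), j:(j + 2 * r)] * kern)
  }
  out
}

# the full 2-D LoG kernel from the package's sampled 1-D factors
log_kernel_2d <- function(sigma_px) {
  k <- enthesomorph:::log_kernels(sigma_px)
  outer(k$g2, k$g) + outer(k$g, k$g2)
}

# pixel-count bone fraction by explicit loop
ba_oracle <- function(bits) {
  n_bone <- 0L
  for (i in seq_len(nrow(bits))) for (j in seq_len(ncol(bits)))
    if (bits[i, j]) n_bone <- n_bone + 1L
  n_bone / (nrow(bits) * ncol(bits))
}

# exhaustive run-length scan of one phase along rows and columns,
# dropping runs that touch the line ends
runs_oracle <- function(bits, phase_val) {
  scan_line <- function(line) {
    runs <- integer(0)
    len <- 0L
    start <- NA_integer_
    for (p in seq_along(line)) {
      if (line[p] == phase_val) {
        if (len == 0L) start <- p
        len <- len + 1L
      } else if (len > 0L) {
        if (start > 1L) runs <- c(runs, len)  # start==1 touches the border
        len <- 0L
      }
    }
    # a run still open at the line end is censored
    runs
  }
  out <- integer(0)
  for (i in seq_len(nrow(bits))) out <- c(out, scan_line(bits[i, ]))
  for (j in seq_len(ncol(bits))) out <- c(out, scan_line(bits[, j]))
  out
}

# exact two-sided signed-rank p by enumerating all 2^n sign assignments
wilcoxon_enum_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% rk)
  p_ge <- mean(v_all >= v_obs)
  p_le <- mean(v_all <= v_obs)
  min(1, 2 * min(p_ge, p_le))
}

digest_file <- function(path) unname(tools::md5sum(path))

# small deterministic random mask
random_mask <- function(n, p = 0.5, seed = 1, pixel_size_mm = 0.05) {
  set.seed(seed)
  binary_mask(matrix(runif(n * n) < p, n, n), pixel_size_mm)
}
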