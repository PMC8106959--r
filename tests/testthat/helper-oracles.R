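# Independent oracles and fixture builders used across the suite.

# Brute-force 8-connected component labelling by explicit flood fill
# (queue-based; independent of the package's graph-based labelling).
flood_fill_sizes <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  sizes <- integer(0)
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!mask[r0, c0] || seen[r0, c0]) next
    queue <- list(c(r0, c0)); seen[r0, c0] <- TRUE; size <- 0L
    while (length(queue)) {
      p <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
      size <- size + 1L
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; c <- p[2] + dc
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            mask[r, c] && !seen[r, c]) {
          seen[r, c] <- TRUE
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
    sizes <- c(sizes, size)
  }
  sizes
}

# Monte-Carlo power of the two-sided two-sample t-test (vectorised)
mc_power_ttest <- function(n1, n2, d, alpha = 0.05, reps = 50000) {
  x <- matrix(stats::rnorm(reps * n1), reps)
  y <- matrix(stats::rnorm(reps * n2, mean = d), reps)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  tt <- (m2 - m1) / (sp * sqrt(1 / n1 + 1 / n2))
  mean(abs(tt) > stats::qt(1 - alpha / 2, n1 + n2 - 2))
}

# Minimal single-axon image: a bare pixel chain of intensity 1 on zeros.
line_image <- function(shape, chain) {
  img <- matrix(0, shape[1], shape[2])
  img[chain] <- 1
  img
}

# Small geometry for hand-built line fixtures
line_geometry <- function(shape = c(80L, 60L), exit_row = 5L, hm_row = 30L) {
  embryo_geometry(shape = shape, exit_row = exit_row, hm_row = hm_row,
                  ventral_extent_row = shape[1] - 5L,
                  exit_cols = seq(10L, by = 6L, length.out = 8L))
}

vertical_chain <- function(r0, c0, len) cbind(r0:(r0 + len), rep(c0, len + 1))
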