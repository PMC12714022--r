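# Independent reference implementations used to cross-check the package.

# Double-loop net-flow reference: mean of nonzero off-diagonal row entries
# minus mean of nonzero off-diagonal column entries, per cell.
net_flow_oracle <- function(m) {
  m <- as.matrix(m)
  diag(m) <- 0
  n <- nrow(m)
  raw <- numeric(n)
  for (i in seq_len(n)) {
    ro <- m[i, ][m[i, ] != 0]
    co <- m[, i][m[, i] != 0]
    raw[i] <- (if (length(ro) > 0) mean(ro) else 0) -
      (if (length(co) > 0) mean(co) else 0)
  }
  raw
}

minmax_oracle <- function(x) {
  if (max(x) == min(x)) return(rep(0, length(x)))
  (x - min(x)) / (max(x) - min(x))
}

# Linear-interpolation percentile between order statistics.
percentile_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  vapply(p, function(pp) {
    h <- (n - 1) * pp + 1
    lo <- floor(h)
    hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }, numeric(1))
}

# Small spot tables on a regular grid, for QC tests.
grid_spots <- function(nx, ny, spacing = 20, counts = 1000L) {
  g <- expand.grid(x = seq_len(nx) * spacing, y = seq_len(ny) * spacing)
  tibble::tibble(
    spot_id = sprintf("g%04d", seq_len(nrow(g))),
    x = g$x, y = g$y,
    total_counts = as.integer(counts)
  )
}

# Shared medium-sized annulus simulation (computed once per test run).
annulus_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- sim_spots(tissue_annulus(r_inner = 300, r_outer = 600),
                          smear_fraction = 0.1, seed = 42)
    }
    cache
  }
})
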