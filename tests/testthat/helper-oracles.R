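# Independent oracles used across the suite. These deliberately take the
# dumbest correct route (rasterisation, definitional sums of squares,
# exhaustive enumeration) so they share no code with the implementation.

# Union length of a set of intervals by rasterising at `res` mm.
rasterize_union_length <- function(starts, ends, lo, hi, res = 0.01) {
  centers <- seq(lo + res / 2, hi - res / 2, by = res)
  covered <- rep(FALSE, length(centers))
  for (i in seq_along(starts)) {
    covered <- covered | (centers >= starts[i] & centers < ends[i])
  }
  sum(covered) * res
}

# Brute-force sagittal MIP: explicit loop over the slab columns.
brute_force_mip <- function(volume, center_x, thickness) {
  dx <- volume$spacing[1]
  nx <- dim(volume$data)[1]
  i_lo <- max(floor((center_x - thickness / 2) / dx), 0) + 1
  i_hi <- min(ceiling((center_x + thickness / 2) / dx), nx)
  d <- dim(volume$data)
  out <- matrix(-Inf, d[3], d[2])
  for (k in seq_len(d[3])) {
    for (j in seq_len(d[2])) {
      for (i in i_lo:i_hi) out[k, j] <- max(out[k, j], volume$data[i, j, k])
    }
  }
  out
}

# Two-way ANOVA mean squares from their definitional sums of squares,
# written as explicit loops over cells.
oracle_mean_squares <- function(x) {
  n <- nrow(x); k <- ncol(x)
  grand <- mean(x)
  ssr <- 0
  for (i in seq_len(n)) ssr <- ssr + k * (mean(x[i, ]) - grand)^2
  ssc <- 0
  for (j in seq_len(k)) ssc <- ssc + n * (mean(x[, j]) - grand)^2
  sse <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) {
    sse <- sse + (x[i, j] - mean(x[i, ]) - mean(x[, j]) + grand)^2
  }
  list(msr = ssr / (n - 1), msc = ssc / (k - 1), mse = sse / ((n - 1) * (k - 1)))
}

# ICC point estimates straight from the oracle mean squares.
oracle_icc <- function(x, model) {
  ms <- oracle_mean_squares(x)
  n <- nrow(x); k <- ncol(x)
  with(ms, switch(model,
    two_way_random_absolute_single =
      (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n),
    two_way_random_absolute_average =
      (msr - mse) / (msr + (msc - mse) / n),
    two_way_consistency_single =
      (msr - mse) / (msr + (k - 1) * mse)))
}

# Recursive permutation generator (independent of the package's
# iterative one).
oracle_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  smaller <- oracle_permutations(n - 1)
  out <- NULL
  for (pos in seq_len(n)) {
    block <- cbind(smaller[, seq_len(pos - 1), drop = FALSE], n,
                   if (pos <= n - 1) smaller[, pos:(n - 1), drop = FALSE])
    out <- rbind(out, block)
  }
  out
}

# Exhaustive-permutation Spearman: rho of average ranks and the exact
# two-sided p-value, by recomputing rho for every permutation of y.
oracle_spearman <- function(x, y) {
  rho_of <- function(a, b) stats::cor(rank(a), rank(b))
  obs <- rho_of(x, y)
  perms <- oracle_permutations(length(y))
  rhos <- apply(perms, 1, function(p) rho_of(x, y[p]))
  list(rho = obs, p = mean(abs(rhos) >= abs(obs) - 1e-12))
}
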