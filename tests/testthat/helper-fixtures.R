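# Shared fixtures and independent oracles.

write_temp_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# closed-form MI of a bivariate Gaussian with correlation rho, in bits
gaussian_mi_bits <- function(rho) -0.5 * log2(1 - rho^2)

# closed-form MI between the time variable and both scores of the
# gaussian_pair construction (scores = rho * T + noise, conditionally
# independent given T): I = 0.5 * log2((1 + rho^2) / (1 - rho^2))
gaussian_pair_mi_bits <- function(rho) 0.5 * log2((1 + rho^2) / (1 - rho^2))

# plugin (maximum-likelihood) entropy in bits
plugin_entropy_bits <- function(counts) {
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

# Independent NSB oracle: plain scalar-loop quadrature over a fixed fine
# grid in log(alpha), explicit sums over the full alphabet (no
# counts-of-counts grouping). Only usable for small alphabets.
nsb_oracle_bits <- function(counts, K, n_grid = 4000) {
  n <- sum(counts)
  tgrid <- seq(log(1e-8), log(1e7), length.out = n_grid)
  logw <- EH <- numeric(n_grid)
  full <- c(counts, rep(0, K - length(counts)))
  for (i in seq_len(n_grid)) {
    a <- exp(tgrid[i])
    b <- full + a
    A <- n + K * a
    logL <- lgamma(K * a) - lgamma(A) + sum(lgamma(b)) - K * lgamma(a)
    prior <- K * trigamma(K * a + 1) - trigamma(a + 1)
    logw[i] <- logL + log(max(prior, 1e-300)) + tgrid[i]
    EH[i] <- digamma(A + 1) - sum(b * digamma(b + 1)) / A
  }
  w <- exp(logw - max(logw))
  sum(w * EH) / sum(w) / log(2)
}

# small curve fixture builders
sigmoid_curve <- function(center_ms = 2, n_levels = 60, i0 = 1.5, s0 = 0.05) {
  grid <- noise_grid_default(n_levels)
  x <- log10(grid[-1L])
  mi <- i0 / (1 + exp((x - log10(center_ms)) / 0.15))
  as_noise_curve(grid, c(i0, mi), zero_noise_std = s0)
}
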