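# Independent oracles and small fixture builders used across the suite.

# SIMPLS (de Jong 1993) for univariate y: an algorithm independent of the
# package's NIPALS implementation, used to cross-check PLS predictions.
simpls_predict <- function(X, y, n_components, newdata = X) {
  X <- as.matrix(X)
  mx <- colMeans(X); my <- mean(y)
  Xc <- sweep(X, 2, mx)
  S <- crossprod(Xc, y - my)
  p <- ncol(X); n <- nrow(X)
  R <- matrix(0, p, n_components); V <- matrix(0, p, n_components)
  q <- numeric(n_components)
  for (a in seq_len(n_components)) {
    r <- S
    t_ <- Xc %*% r
    nt <- sqrt(sum(t_^2))
    t_ <- t_ / nt; r <- r / nt
    pa <- crossprod(Xc, t_)
    q[a] <- sum(y * t_)
    v <- pa
    if (a > 1) v <- v - V[, 1:(a - 1), drop = FALSE] %*%
        crossprod(V[, 1:(a - 1), drop = FALSE], pa)
    v <- v / sqrt(sum(v^2))
    V[, a] <- v
    S <- S - v %*% crossprod(v, S)
    R[, a] <- r
  }
  B <- R %*% q
  drop(my + sweep(as.matrix(newdata), 2, mx) %*% B)
}

# trapezoidal total integral (textbook formula), independent of the
# package's piecewise integrator
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# flat spectrum covering the full analyzed region
flat_spectrum <- function(value = 1, lo = 0.45, hi = 4.75, by = 0.001)
  nmr_spectrum(seq(lo, hi, by = by), rep(value, length(seq(lo, hi, by = by))))

# small tabular cohort (no spectra) for stratified-integration tests
quant_cohort <- function(n = 400, seed = 1, null_genotype = NULL,
                         maf = 0.5) {
  specs <- data.frame(snp_id = "rs1", chromosome = 1, maf = maf, effect = 0)
  cfg <- sim_config(n_subjects = n, snp_specs = specs,
                    null_genotype = null_genotype, seed = seed)
  generate_cohort(cfg, spectra = FALSE)
}
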