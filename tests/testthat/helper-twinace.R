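# Shared fixtures and independent oracles for the test suite.

# Published trivariate AE solution used as generating truth throughout:
# standardized a, e per trait and etiological correlations.
truth_a <- c(0.34, 0.42, 0.57)
truth_e <- 1 - truth_a
truth_rA <- matrix(c(1, 0.22, 0.36,
                     0.22, 1, 0.80,
                     0.36, 0.80, 1), 3, 3)
truth_rE <- matrix(c(1, 0.15, 0.14,
                     0.15, 1, 0.47,
                     0.14, 0.47, 1), 3, 3)

study_params <- function(seed = 1, nMZ = 429, nDZ = 707, ...) {
  generating_params(a = truth_a, e = truth_e, rA = truth_rA, rE = truth_rE,
                    nMZ = nMZ, nDZ = nDZ, seed = seed, ...)
}

# Independent FIML oracle: naive per-pair loop over marginal multivariate
# normal densities (no sufficient-statistic pooling).
naive_m2ll <- function(comp, table) {
  traits <- attr(table, "traits")
  Y <- as.matrix(table[, c(paste0(traits, "_1"), paste0(traits, "_2"))])
  mu <- rep(comp$means, 2L)
  total <- 0
  for (i in seq_len(nrow(Y))) {
    o <- which(!is.na(Y[i, ]))
    if (!length(o)) next
    S <- expected_covariance(comp, as.character(table$zygosity[i]))
    S <- S[o, o, drop = FALSE]
    d <- Y[i, o] - mu[o]
    total <- total + length(o) * log(2 * pi) +
      as.numeric(determinant(S)$modulus) +
      drop(t(d) %*% solve(S) %*% d)
  }
  total
}

# Closed-form complete-data two-group MVN -2LL from group sample moments.
moment_m2ll <- function(comp, table) {
  traits <- attr(table, "traits")
  Y <- as.matrix(table[, c(paste0(traits, "_1"), paste0(traits, "_2"))])
  stopifnot(!anyNA(Y))
  mu <- rep(comp$means, 2L)
  total <- 0
  for (z in c("MZ", "DZ")) {
    Yz <- Y[table$zygosity == z, , drop = FALSE]
    n <- nrow(Yz)
    if (!n) next
    S <- expected_covariance(comp, z)
    Sml <- stats::cov(Yz) * (n - 1) / n
    dbar <- colMeans(Yz) - mu
    Sinv <- solve(S)
    total <- total + n * (ncol(Y) * log(2 * pi) +
                            as.numeric(determinant(S)$modulus) +
                            sum(Sinv * Sml) +
                            drop(t(dbar) %*% Sinv %*% dbar))
  }
  total
}

# random PSD component matrix (for algebraic identity checks)
random_psd <- function(p) {
  M <- matrix(stats::rnorm(p * p), p, p)
  crossprod(M) / p + diag(p) * 0.1
}

make_table <- function(df, traits) twin_pair_table(df, traits)

# tiny hand-built table: 3 pairs, 1 trait
toy_table <- function() {
  twin_pair_table(data.frame(
    family_id = c("f1", "f2", "f3"),
    zygosity = c("MZ", "MZ", "DZ"),
    sex1 = "female", sex2 = "female",
    y_1 = c(0.0, 1.0, -0.5),
    y_2 = c(0.0, 0.5, 0.25)), "y")
}
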