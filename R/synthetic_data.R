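#' Generating parameters for simulated twin data
#'
#' Bundles the standardized variance shares and etiological correlation
#' matrices of a correlated-factors ACE structure together with sample
#' sizes, trait means, a sex mean shift, and a missingness rate, for use
#' by \code{\link{simulate_twins}}.  All shares are on the standardized
#' scale: every latent factor has unit variance and
#' \code{a + c + e = 1} per trait, so simulated traits have population
#' variance 1 before any mean structure.
#'
#' @param a,c,e numeric vectors of per-trait standardized variance
#'   shares for the additive-genetic, shared-environmental and
#'   nonshared-environmental components; each in \code{[0, 1]} and
#'   summing to 1 per trait.  \code{e} must be strictly positive (it
#'   absorbs measurement error) unless \code{allow_degenerate = TRUE}.
#' @param rA,rC,rE symmetric positive-semidefinite correlation matrices
#'   (unit diagonal) among the same-type latent factors.  Defaults to
#'   identity.
#' @param means per-trait means (default 0).
#' @param sex_effect per-trait additive mean shift applied to males
#'   (default 0).
#' @param missing_rate probability each individual trait value is
#'   masked, independently and completely at random (default 0).
#' @param nMZ,nDZ pair counts.
#' @param seed optional integer seed; if supplied,
#'   \code{\link{simulate_twins}} is deterministic.
#' @param dz_mix length-3 probabilities of a DZ pair being male-male,
#'   female-female or opposite-sex.  The default is the observed mix of
#'   a large UK adolescent twin register (138/227/342 of 707).
#' @param mz_male_prob probability an MZ pair is male (default 145/429,
#'   same source).
#' @param allow_degenerate permit \code{e = 0} (useful for textbook
#'   perfect-heritability checks; the fitted models require e > 0).
#' @return list of class \code{"generating_params"}.
#' @export
generating_params <- function(a, c = rep(0, length(a)), e = 1 - a - c,
                              rA = diag(length(a)), rC = diag(length(a)),
                              rE = diag(length(a)), means = rep(0, length(a)),
                              sex_effect = rep(0, length(a)),
                              missing_rate = 0, nMZ = 429L, nDZ = 707L,
                              seed = NULL,
                              dz_mix = c(138, 227, 342) / 707,
                              mz_male_prob = 145 / 429,
                              allow_degenerate = FALSE) {
  p <- length(a)
  stopifnot(length(c) == p, length(e) == p, length(means) == p)
  sex_effect <- rep_len(sex_effect, p)
  if (any(a < 0 | c < 0 | e < 0) || any(a > 1 | c > 1 | e > 1))
    stop("a, c, e must lie in [0, 1]")
  if (any(abs(a + c + e - 1) > 1e-8))
    stop("a + c + e must equal 1 for every trait (standardized scale)")
  if (!allow_degenerate && any(e <= 0))
    stop("e must be > 0 for every trait (E absorbs measurement error)")
  for (nm in c("rA", "rC", "rE")) {
    m <- get(nm)
    if (!is.matrix(m) || any(dim(m) != p))
      stop(nm, " must be a ", p, "x", p, " matrix")
    if (max(abs(m - t(m))) > 1e-10) stop(nm, " must be symmetric")
    if (max(abs(diag(m) - 1)) > 1e-10) stop(nm, " must have unit diagonal")
    if (min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      stop(nm, " is not positive semidefinite")
  }
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  if (abs(sum(dz_mix) - 1) > 1e-8 || any(dz_mix < 0))
    stop("dz_mix must be nonnegative and sum to 1")
  structure(list(p = p, a = a, c = c, e = e, rA = rA, rC = rC, rE = rE,
                 means = means, sex_effect = sex_effect,
                 missing_rate = missing_rate,
                 nMZ = as.integer(nMZ), nDZ = as.integer(nDZ),
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 dz_mix = dz_mix, mz_male_prob = mz_male_prob),
            class = "generating_params")
}

# draw n rows from N(0, R) via the (pivoted-safe) Cholesky root of R
rmvn <- function(n, R) {
  p <- ncol(R)
  ev <- eigen(R, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), p)
  matrix(stats::rnorm(n * p), n, p) %*% t(L)
}

#' Simulate twin-pair phenotype data
#'
#' Generates a \code{\link{twin_pair_table}} under the correlated-factors
#' ACE structure of \code{params}: per pair, additive-genetic factor
#' scores for the two twins are jointly multivariate normal with
#' within-twin correlation \code{rA} and cross-twin block \code{rA}
#' (MZ) or \code{0.5 rA} (DZ); shared-environment scores are drawn once
#' per pair with correlation \code{rC}; nonshared-environment scores are
#' drawn independently per twin with correlation \code{rE}.  The
#' phenotype of twin t on trait j is
#' \code{mean_j + sex_shift + sqrt(a_j) gA + sqrt(c_j) gC + sqrt(e_j) gE}.
#' Values are then masked independently at \code{missing_rate}.
#'
#' @param params a \code{\link{generating_params}} object.
#' @param traits trait names (default \code{trait1..traitp}).
#' @return a \code{\link{twin_pair_table}} with \code{nMZ + nDZ} pairs.
#' @export
simulate_twins <- function(params, traits = paste0("trait", seq_len(params$p))) {
  stopifnot(inherits(params, "generating_params"))
  p <- params$p
  if (length(traits) != p) stop("need ", p, " trait names")
  if (!is.null(params$seed)) set.seed(params$seed)

  n <- params$nMZ + params$nDZ
  zyg <- rep(c("MZ", "DZ"), c(params$nMZ, params$nDZ))

  # joint 2p x 2p correlation of the A scores for a DZ pair
  rA2_dz <- rbind(cbind(params$rA, 0.5 * params$rA),
                  cbind(0.5 * params$rA, params$rA))

  gA <- matrix(0, n, 2 * p)
  if (params$nMZ) {
    g <- rmvn(params$nMZ, params$rA)          # identical genotypes
    gA[zyg == "MZ", ] <- cbind(g, g)
  }
  if (params$nDZ) gA[zyg == "DZ", ] <- rmvn(params$nDZ, rA2_dz)
  gC <- rmvn(n, params$rC)                    # one draw per pair
  gE1 <- rmvn(n, params$rE)
  gE2 <- rmvn(n, params$rE)

  sa <- sqrt(params$a); sc <- sqrt(params$c); se <- sqrt(params$e)
  y1 <- sweep(gA[, 1:p, drop = FALSE], 2, sa, `*`) +
        sweep(gC, 2, sc, `*`) + sweep(gE1, 2, se, `*`)
  y2 <- sweep(gA[, p + 1:p, drop = FALSE], 2, sa, `*`) +
        sweep(gC, 2, sc, `*`) + sweep(gE2, 2, se, `*`)

  # sex: MZ same-sex; DZ same- or opposite-sex with the preset mix
  sex1 <- sex2 <- character(n)
  if (params$nMZ) {
    s <- ifelse(stats::runif(params$nMZ) < params$mz_male_prob,
                "male", "female")
    sex1[zyg == "MZ"] <- s; sex2[zyg == "MZ"] <- s
  }
  if (params$nDZ) {
    kind <- sample(c("mm", "ff", "os"), params$nDZ, replace = TRUE,
                   prob = params$dz_mix)
    s1 <- ifelse(kind == "ff", "female", "male")
    s2 <- ifelse(kind == "mm", "male", "female")
    sex1[zyg == "DZ"] <- s1; sex2[zyg == "DZ"] <- s2
  }
  shift1 <- (sex1 == "male") %o% params$sex_effect
  shift2 <- (sex2 == "male") %o% params$sex_effect
  y1 <- y1 + rep(params$means, each = n) + shift1
  y2 <- y2 + rep(params$means, each = n) + shift2

  if (params$missing_rate > 0) {
    y1[matrix(stats::runif(n * p) < params$missing_rate, n, p)] <- NA
    y2[matrix(stats::runif(n * p) < params$missing_rate, n, p)] <- NA
  }

  df <- data.frame(family_id = sprintf("fam%05d", seq_len(n)),
                   zygosity = zyg, sex1 = sex1, sex2 = sex2,
                   stringsAsFactors = FALSE)
  for (j in seq_len(p)) {
    df[[paste0(traits[j], "_1")]] <- y1[, j]
    df[[paste0(traits[j], "_2")]] <- y2[, j]
  }
  twin_pair_table(df, traits)
}

#' Closed-form correlations implied by generating parameters
#'
#' Analytic twin-design correlations under a correlated-factors ACE
#' structure: per-trait twin correlations \code{rMZ = a + c},
#' \code{rDZ = a/2 + c}; phenotypic correlations
#' \code{rph_jk = rA_jk sqrt(a_j a_k) + rC_jk sqrt(c_j c_k) +
#' rE_jk sqrt(e_j e_k)}; and cross-twin cross-trait (CTCT) correlations
#' with the E term dropped (MZ) or the A term halved as well (DZ).
#' These serve as oracles for the saturated-model estimates.
#'
#' @param params a \code{\link{generating_params}} object.
#' @return list of class \code{"correlation_report"} with elements
#'   \code{rph}, \code{rMZ}, \code{rDZ}, \code{ctct_MZ}, \code{ctct_DZ}.
#' @export
expected_correlations <- function(params) {
  stopifnot(inherits(params, "generating_params"))
  a <- params$a; c <- params$c; e <- params$e
  cross <- function(w) params$rA * (w * sqrt(outer(a, a))) +
    params$rC * sqrt(outer(c, c))
  rph <- params$rA * sqrt(outer(a, a)) + params$rC * sqrt(outer(c, c)) +
    params$rE * sqrt(outer(e, e))
  ctct_MZ <- cross(1); ctct_DZ <- cross(0.5)
  rMZ <- diag(ctct_MZ); rDZ <- diag(ctct_DZ)
  diag(ctct_MZ) <- NA_real_; diag(ctct_DZ) <- NA_real_
  diag(rph) <- 1
  structure(list(rph = rph, rMZ = rMZ, rDZ = rDZ,
                 ctct_MZ = ctct_MZ, ctct_DZ = ctct_DZ,
                 ci = NULL, n_used = NULL, source = "analytic"),
            class = "correlation_report")
}
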