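#' Standardized correlated-factors solution
#'
#' Container for per-trait standardized variance shares and etiological
#' correlation matrices, either produced from fitted component matrices
#' by \code{\link{standardize_components}} or entered directly (e.g.
#' from a published table).  Per-trait shares are expected to sum to 1;
#' entries quoted at 2 decimals are accepted with rounding slack.
#'
#' @param std_a,std_c,std_e numeric vectors of standardized shares.
#' @param rA,rC,rE etiological correlation matrices; \code{NA} where the
#'   corresponding component variance is zero or negative.
#' @param tol allowed deviation of each per-trait share sum from 1.
#' @return list of class \code{"std_solution"}.
#' @export
std_solution <- function(std_a, std_c = rep(0, length(std_a)), std_e,
                         rA = diag(length(std_a)),
                         rC = diag(length(std_a)),
                         rE = diag(length(std_a)), tol = 0.02) {
  p <- length(std_a)
  stopifnot(length(std_c) == p, length(std_e) == p)
  s <- std_a + std_c + std_e
  if (any(abs(s - 1) > tol))
    stop("standardized shares must sum to 1 per trait (got ",
         paste(round(s, 3), collapse = ", "), ")")
  for (nm in c("rA", "rC", "rE")) {
    m <- get(nm)
    if (!is.matrix(m) || any(dim(m) != p)) stop(nm, " must be ", p, "x", p)
    if (any(abs(m[!is.na(m)]) > 1 + 1e-8))
      stop(nm, " entries must lie in [-1, 1]")
  }
  structure(list(std_a = std_a, std_c = std_c, std_e = std_e,
                 rA = rA, rC = rC, rE = rE, p = p),
            class = "std_solution")
}

#' Standardize fitted component matrices
#'
#' Converts phenotype-scale component matrices to the standardized
#' solution: \code{std_x_j = X_jj / (A_jj + C_jj + E_jj)} and
#' etiological correlations \code{rX_jk = X_jk / sqrt(X_jj X_kk)}.  A
#' correlation is undefined (\code{NA}, with the trait flagged) where a
#' component's variance is zero or negative, which direct variance
#' estimation permits; shares are reported signed, never truncated.
#'
#' @param comp a \code{\link{component_matrices}} object.
#' @return a \code{\link{std_solution}} with a \code{flags} field naming
#'   traits whose correlations are undefined per component.
#' @export
standardize_components <- function(comp) {
  stopifnot(inherits(comp, "component_matrices"))
  tot <- diag(comp$A + comp$C + comp$E)
  if (any(tot <= 0)) stop("degenerate: non-positive total variance")
  corr_or_na <- function(M) {
    d <- diag(M)
    ok <- d > 0
    R <- matrix(NA_real_, comp$p, comp$p)
    R[ok, ok] <- M[ok, ok] / sqrt(outer(d[ok], d[ok]))
    R
  }
  out <- std_solution(diag(comp$A) / tot, diag(comp$C) / tot,
                      diag(comp$E) / tot,
                      corr_or_na(comp$A), corr_or_na(comp$C),
                      corr_or_na(comp$E), tol = 1e-8)
  out$flags <- lapply(list(A = comp$A, C = comp$C, E = comp$E),
                      function(M) which(diag(M) <= 0))
  out
}

# rX_jk * sqrt(x_j x_k) with the convention that a zero weight kills the
# term even when rX is undefined (NA)
comp_term <- function(r, x) {
  w <- sqrt(outer(pmax(x, 0), pmax(x, 0)))
  t <- r * w
  t[w == 0] <- 0
  t
}

#' Model-implied phenotypic correlations
#'
#' Path algebra of the correlated-factors model: the phenotypic
#' correlation implied between traits j and k is
#' \code{rA_jk sqrt(a_j a_k) + rC_jk sqrt(c_j c_k) + rE_jk sqrt(e_j e_k)}
#' on the standardized scale; the diagonal is 1.
#'
#' @param std a \code{\link{std_solution}}.
#' @return p x p matrix.
#' @export
implied_rph <- function(std) {
  stopifnot(inherits(std, "std_solution"))
  R <- comp_term(std$rA, std$std_a) + comp_term(std$rC, std$std_c) +
    comp_term(std$rE, std$std_e)
  diag(R) <- 1
  R
}

#' Proportions of phenotypic correlation by component
#'
#' Splits each implied phenotypic correlation into the fractions carried
#' by the A, C and E components:
#' \code{share_X_jk = rX_jk sqrt(x_j x_k) / rph_jk} with the
#' model-implied \code{rph} as denominator, so defined shares sum to 1
#' exactly.  Cells with \code{|rph| < 1e-6} are flagged undefined rather
#' than raising an error.  Negative component estimates propagate to
#' signed shares.
#'
#' @param std a \code{\link{std_solution}}.
#' @return list of class \code{"rph_shares"}: \code{share_A},
#'   \code{share_C}, \code{share_E}, \code{implied_rph}, and a logical
#'   \code{defined} matrix.
#' @export
proportion_rph <- function(std) {
  stopifnot(inherits(std, "std_solution"))
  tA <- comp_term(std$rA, std$std_a)
  tC <- comp_term(std$rC, std$std_c)
  tE <- comp_term(std$rE, std$std_e)
  rph <- tA + tC + tE
  diag(rph) <- 1
  defined <- abs(rph) >= 1e-6
  share <- function(t) {
    s <- t / rph
    s[!defined] <- NA_real_
    diag(s) <- NA_real_
    s
  }
  structure(list(share_A = share(tA), share_C = share(tC),
                 share_E = share(tE), implied_rph = rph,
                 defined = defined), class = "rph_shares")
}

#' Decompose a fitted ACE model
#'
#' One-call wrapper producing the full etiological decomposition of an
#' \code{\link{fit_ace}} result: standardized variance shares,
#' etiological correlations, model-implied phenotypic correlations, and
#' per-component shares of each phenotypic correlation.  Shares are also
#' reported against an observed (saturated-model) phenotypic correlation
#' if one is supplied; the implied-denominator shares are canonical
#' since they sum to 1 by construction.
#'
#' @param fit an \code{"ace_fit"}.
#' @param observed_rph optional p x p phenotypic correlation matrix from
#'   a saturated model, used for the alternative share denominator.
#' @param ci \code{"profile"} for profile-likelihood intervals on the
#'   standardized shares and etiological correlations, \code{"none"}
#'   (default) to skip.
#' @param level confidence level for \code{ci = "profile"}.
#' @return list of class \code{"decomposition_report"}.
#' @export
decompose <- function(fit, observed_rph = NULL, ci = c("none", "profile"),
                      level = 0.95) {
  stopifnot(inherits(fit, "ace_fit"))
  ci <- match.arg(ci)
  std <- standardize_components(fit$estimates)
  sh <- proportion_rph(std)
  p <- std$p

  obs_shares <- NULL
  if (!is.null(observed_rph)) {
    obs_shares <- list(share_A = comp_term(std$rA, std$std_a) / observed_rph,
                       share_C = comp_term(std$rC, std$std_c) / observed_rph,
                       share_E = comp_term(std$rE, std$std_e) / observed_rph)
    for (nm in names(obs_shares)) diag(obs_shares[[nm]]) <- NA_real_
  }

  ci_out <- NULL
  if (ci == "profile") {
    free <- fit$spec$components_free
    ci_std <- lapply(free, function(cc) t(vapply(seq_len(p), function(j)
      profile_ci(fit, list(type = "std", comp = cc, trait = j), level),
      numeric(2L))))
    names(ci_std) <- paste0("std_", tolower(free))
    ci_r <- lapply(free, function(cc) {
      lowM <- upM <- matrix(NA_real_, p, p)
      for (j in seq_len(p)) for (l in seq_len(j - 1L)) {
        b <- profile_ci(fit, list(type = "rcomp", comp = cc,
                                  traits = c(j, l)), level)
        lowM[j, l] <- lowM[l, j] <- b[1L]
        upM[j, l] <- upM[l, j] <- b[2L]
      }
      list(lower = lowM, upper = upM)
    })
    names(ci_r) <- paste0("r", free)
    ci_out <- list(std = ci_std, r = ci_r, level = level)
  }

  dimn <- list(fit$traits, fit$traits)
  for (nm in c("rA", "rC", "rE")) dimnames(std[[nm]]) <- dimn
  for (nm in c("implied_rph", "share_A", "share_C", "share_E"))
    dimnames(sh[[nm]]) <- dimn
  structure(list(std_a = stats::setNames(std$std_a, fit$traits),
                 std_c = stats::setNames(std$std_c, fit$traits),
                 std_e = stats::setNames(std$std_e, fit$traits),
                 rA = std$rA, rC = std$rC, rE = std$rE,
                 implied_rph = sh$implied_rph,
                 share_A = sh$share_A, share_C = sh$share_C,
                 share_E = sh$share_E, defined = sh$defined,
                 observed_denominator_shares = obs_shares,
                 ci = ci_out, model = fit$model, traits = fit$traits),
            class = "decomposition_report")
}

#' @export
print.decomposition_report <- function(x, digits = 2, ...) {
  cat(sprintf("Etiological decomposition (%s model)\n", x$model))
  tab <- rbind(std_a = x$std_a, std_c = x$std_c, std_e = x$std_e)
  print(round(tab, digits))
  cat("Genetic correlations (rA):\n"); print(round(x$rA, digits))
  cat("Nonshared-environment correlations (rE):\n")
  print(round(x$rE, digits))
  cat("Implied phenotypic correlations:\n")
  print(round(x$implied_rph, digits))
  cat("Share of rph due to A:\n"); print(round(x$share_A, digits))
  invisible(x)
}
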