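# Constrained saturated parameterization:
#   theta = [means (p), variances (p),
#            within-twin cross-trait covs MZ (p(p-1)/2),
#            within-twin cross-trait covs DZ (p(p-1)/2),
#            vech(X_MZ) (p(p+1)/2), vech(X_DZ) (p(p+1)/2)]
# Means and variances are shared across twin order and zygosity; all
# covariances are zygosity-specific; cross-twin blocks are symmetric
# (twin order exchangeable).  The ACE correlated-factors model is a
# strict submodel (it forces the within-twin block equal across
# zygosity and ties the cross blocks to A, C).

sat_dims <- function(p) {
  m <- p * (p - 1L) / 2L
  q <- p * (p + 1L) / 2L
  list(m = m, q = q,
       off = c(means = 0L, v = p, wMZ = 2L * p, wDZ = 2L * p + m,
               XMZ = 2L * p + 2L * m, XDZ = 2L * p + 2L * m + q),
       n_par = as.integer(2L * p + 2L * m + 2L * q))
}

# strict-lower-triangle packing for the within-twin covariances
unvech0 <- function(v, diag_vals, p) {
  M <- diag(diag_vals, p)
  M[lower.tri(M)] <- v
  M[upper.tri(M)] <- t(M)[upper.tri(M)]
  M
}

sat_unpack <- function(theta, p) {
  d <- sat_dims(p)
  means <- theta[seq_len(p)]
  v <- theta[d$off["v"] + seq_len(p)]
  grab <- function(nm, n) theta[d$off[nm] + seq_len(n)]
  list(means = means, v = v,
       W_MZ = unvech0(grab("wMZ", d$m), v, p),
       W_DZ = unvech0(grab("wDZ", d$m), v, p),
       X_MZ = unvech(grab("XMZ", d$q), p),
       X_DZ = unvech(grab("XDZ", d$q), p))
}

sat_sigma <- function(W, X) rbind(cbind(W, X), cbind(X, W))

sat_obj_factory <- function(fd) {
  p <- fd$p
  function(theta) {
    if (anyNA(theta)) return(1e10)
    pr <- sat_unpack(theta, p)
    fiml_eval(fd, rep(pr$means, 2L),
              sat_sigma(pr$W_MZ, pr$X_MZ), sat_sigma(pr$W_DZ, pr$X_DZ))
  }
}

#' Fit the constrained saturated model
#'
#' Baseline model for twin analyses: the stacked pair vector is
#' multivariate normal with, per trait, one mean and one variance shared
#' across twin order and zygosity, while all covariances are free per
#' zygosity group -- the within-twin cross-trait covariances and the
#' symmetric cross-twin blocks (twin order exchangeable).  The
#' correlated-factors ACE model is strictly nested in this baseline, so
#' the likelihood-ratio test of the genetic model's overall fit is well
#' defined.  Maximized by FIML.
#'
#' @param table a \code{\link{twin_pair_table}} with at least 2 MZ and 2
#'   DZ pairs.
#' @param control passed to \code{\link[stats]{nlminb}}.
#' @return object of class \code{"saturated_fit"} with elements
#'   \code{means}, \code{v} (shared variances), \code{W_MZ},
#'   \code{W_DZ} (within-twin blocks), \code{X_MZ}, \code{X_DZ}
#'   (cross-twin blocks), \code{minus2ll}, \code{df},
#'   \code{n_free_params}, \code{converged}, plus data digests used by
#'   \code{\link{correlation_report}} and \code{\link{lrt}}.
#' @export
fit_constrained_saturated <- function(table, control = list()) {
  fd <- fiml_data(table)
  p <- fd$p
  if (fd$nMZ < 2L || fd$nDZ < 2L)
    stop("need at least 2 MZ and 2 DZ pairs with observed values")
  obj <- sat_obj_factory(fd)

  # per-zygosity moment starts with shared variances
  traits <- attr(table, "traits")
  Y1 <- as.matrix(table[, trait_cols(traits, 1), drop = FALSE])
  Y2 <- as.matrix(table[, trait_cols(traits, 2), drop = FALSE])
  safe_cov <- function(A, B) {
    M <- suppressWarnings(stats::cov(A, B, use = "pairwise.complete.obs"))
    M[!is.finite(M)] <- 0
    M
  }
  Wz <- Xz <- list()
  for (z in c("MZ", "DZ")) {
    i <- table$zygosity == z
    Wz[[z]] <- (safe_cov(Y1[i, , drop = FALSE], Y1[i, , drop = FALSE]) +
                safe_cov(Y2[i, , drop = FALSE], Y2[i, , drop = FALSE])) / 2
    B <- safe_cov(Y1[i, , drop = FALSE], Y2[i, , drop = FALSE])
    Xz[[z]] <- (B + t(B)) / 2
  }
  v0 <- (fd$nMZ * diag(Wz$MZ) + fd$nDZ * diag(Wz$DZ)) / fd$n_pairs
  v0 <- pmax(v0, 0.05 * max(mean(v0), 1e-3))
  mu0 <- colMeans(rbind(Y1, Y2), na.rm = TRUE)
  mu0[!is.finite(mu0)] <- 0
  # clamp covariances just inside the correlation bound (so starts near a
  # singular boundary stay close to it), then shrink as a fallback
  fix_z <- function(z) {
    sdv <- sqrt(outer(v0, v0))
    clamp <- function(M) sign(M) * pmin(abs(M), 0.999 * sdv)
    W <- unvech0(clamp(Wz[[z]])[lower.tri(Wz[[z]])], v0, p)
    X <- clamp(Xz[[z]])
    for (i in 0:40) {
      if (is_pd(sat_sigma(W, X))) break
      X <- 0.9 * X
      W <- unvech0(0.9 * W[lower.tri(W)], v0, p)
    }
    if (!is_pd(sat_sigma(W, X))) X <- matrix(0, p, p)
    list(W = W, X = X)
  }
  sMZ <- fix_z("MZ"); sDZ <- fix_z("DZ")
  th0 <- c(mu0, v0, sMZ$W[lower.tri(sMZ$W)], sDZ$W[lower.tri(sDZ$W)],
           vech(sMZ$X), vech(sDZ$X))

  ctrl <- utils::modifyList(list(rel.tol = 1e-10, iter.max = 1000L,
                                 eval.max = 5000L), control)
  run <- nlminb_polish(th0, obj, ctrl)
  if (!is.finite(run$objective) || run$objective >= 1e9)
    stop("saturated model did not converge: ", run$message,
         " (last -2LL = ", format(run$objective), ")")
  pr <- sat_unpack(run$par, p)
  n_free <- sat_dims(p)$n_par
  structure(c(pr, list(minus2ll = run$objective,
                       df = as.integer(fd$n_obs_values - n_free),
                       n_free_params = n_free,
                       converged = run$convergence == 0L,
                       status = run$message, theta = run$par,
                       model = "saturated",
                       constraints = paste(
                         "means and variances equated across twin order",
                         "and zygosity; within-twin cross-trait and",
                         "cross-twin covariances free per zygosity,",
                         "cross blocks symmetric"),
                       traits = fd$traits, n_pairs = fd$n_pairs,
                       nMZ = fd$nMZ, nDZ = fd$nDZ,
                       checksum = fd$checksum, fd = fd,
                       table = table, control = ctrl)),
            class = "saturated_fit")
}

#' @export
print.saturated_fit <- function(x, ...) {
  cat(sprintf("Constrained saturated model (FIML): -2LL = %.4f, df = %d, %s\n",
              x$minus2ll, x$df,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

# report statistics; the single rph matrix pools the zygosity-specific
# within-twin correlation blocks with pair-count weights
sat_stats <- function(fit) {
  v <- fit$v
  sdv <- sqrt(outer(v, v))
  rph_MZ <- fit$W_MZ / sdv
  rph_DZ <- fit$W_DZ / sdv
  rph <- (fit$nMZ * rph_MZ + fit$nDZ * rph_DZ) / (fit$nMZ + fit$nDZ)
  diag(rph) <- diag(rph_MZ) <- diag(rph_DZ) <- 1
  list(rph = rph, rph_MZ = rph_MZ, rph_DZ = rph_DZ,
       rMZ = diag(fit$X_MZ) / v, rDZ = diag(fit$X_DZ) / v,
       ctct_MZ = fit$X_MZ / sdv, ctct_DZ = fit$X_DZ / sdv)
}

#' @export
profile_ci.saturated_fit <- function(fit, target, level = 0.95, ...) {
  p <- fit$fd$p
  d <- sat_dims(p)
  IX <- matrix(0L, p, p); IX[lower.tri(IX, diag = TRUE)] <- seq_len(d$q)
  IX[upper.tri(IX)] <- t(IX)[upper.tri(IX)]
  IXo <- matrix(0L, p, p); IXo[lower.tri(IXo)] <- seq_len(d$m)
  IXo[upper.tri(IXo)] <- t(IXo)[upper.tri(IXo)]

  obj <- sat_obj_factory(fit$fd)
  th <- fit$theta
  ctrl <- utils::modifyList(fit$control, list(iter.max = 300L))
  st <- sat_stats(fit)
  vat <- function(j) d$off["v"] + j
  blk <- function(zyg) if (zyg == "MZ") "XMZ" else "XDZ"

  if (target$type == "rph") {
    # pooled within-twin correlation; eliminate the MZ covariance entry
    j <- target$traits[1]; l <- target$traits[2]
    k <- d$off["wMZ"] + IXo[j, l]
    kDZ <- d$off["wDZ"] + IXo[j, l]
    est <- st$rph[j, l]
    nM <- fit$nMZ; nD <- fit$nDZ
    fix <- function(red, t) {
      full <- th; full[-k] <- red
      prod <- full[vat(j)] * full[vat(l)]
      full[k] <- if (prod > 0)
        ((nM + nD) * t * sqrt(prod) - nD * full[kDZ]) / nM else NA_real_
      full
    }
  } else if (target$type == "rtwin") {
    j <- target$trait
    k <- d$off[blk(target$zyg)] + IX[j, j]
    est <- if (target$zyg == "MZ") st$rMZ[j] else st$rDZ[j]
    fix <- function(red, t) {
      full <- th; full[-k] <- red
      full[k] <- t * full[vat(j)]
      full
    }
  } else if (target$type == "ctct") {
    j <- target$traits[1]; l <- target$traits[2]
    k <- d$off[blk(target$zyg)] + IX[j, l]
    est <- (if (target$zyg == "MZ") st$ctct_MZ else st$ctct_DZ)[j, l]
    fix <- function(red, t) {
      full <- th; full[-k] <- red
      prod <- full[vat(j)] * full[vat(l)]
      full[k] <- if (prod > 0) t * sqrt(prod) else NA_real_
      full
    }
  } else stop("unknown profile target type: ", target$type)

  profile_engine(obj, th, setdiff(seq_along(th), k), fix, est,
                 fit$minus2ll, level, ctrl, caps = c(-1 + 1e-9, 1 - 1e-9))
}

# pairs contributing to each statistic (complete observations only)
sat_n_used <- function(table) {
  traits <- attr(table, "traits")
  Y1 <- as.matrix(table[, trait_cols(traits, 1), drop = FALSE])
  Y2 <- as.matrix(table[, trait_cols(traits, 2), drop = FALSE])
  mz <- table$zygosity == "MZ"
  rph <- crossprod(!is.na(rbind(Y1, Y2)))     # individuals with both traits
  cnt <- function(A, B) crossprod(!is.na(A), !is.na(B))
  list(rph = rph,
       rMZ = diag(cnt(Y1[mz, , drop = FALSE], Y2[mz, , drop = FALSE])),
       rDZ = diag(cnt(Y1[!mz, , drop = FALSE], Y2[!mz, , drop = FALSE])),
       ctct_MZ = cnt(Y1[mz, , drop = FALSE], Y2[mz, , drop = FALSE]),
       ctct_DZ = cnt(Y1[!mz, , drop = FALSE], Y2[!mz, , drop = FALSE]))
}

#' Correlation report from a saturated fit
#'
#' Converts the fitted covariance structure into the familiar twin-table
#' shape: phenotypic correlations (within-twin block, pooled over
#' zygosity with pair-count weights; the per-zygosity blocks are also
#' returned), per-trait MZ/DZ twin correlations (cross-twin diagonal)
#' and cross-twin cross-trait (CTCT) correlation matrices, with 95\%
#' confidence intervals by likelihood profiling (default) or a seeded
#' pair-resampling bootstrap.
#'
#' @param fit a \code{"saturated_fit"}.
#' @param ci \code{"profile"}, \code{"bootstrap"} or \code{"none"}.
#' @param level confidence level.
#' @param B bootstrap draws (pair-level resampling within zygosity).
#' @param seed bootstrap seed.
#' @return list of class \code{"correlation_report"}: \code{rph},
#'   \code{rph_MZ}, \code{rph_DZ}, \code{rMZ}, \code{rDZ},
#'   \code{ctct_MZ}, \code{ctct_DZ}, matching \code{ci} lower/upper
#'   arrays, and \code{n_used} counts.
#' @export
correlation_report <- function(fit, ci = c("profile", "bootstrap", "none"),
                               level = 0.95, B = 1000L, seed = 1L) {
  stopifnot(inherits(fit, "saturated_fit"))
  ci <- match.arg(ci)
  if (!fit$converged) stop("saturated fit did not converge")
  if (any(fit$v <= 0))
    stop("degenerate fit: non-positive fitted variance")
  p <- fit$fd$p
  st <- sat_stats(fit)
  diag(st$ctct_MZ) <- NA_real_; diag(st$ctct_DZ) <- NA_real_

  ci_out <- NULL
  if (ci == "profile") {
    blank <- list(rph = diag(p), rMZ = numeric(p), rDZ = numeric(p),
                  ctct_MZ = matrix(NA_real_, p, p),
                  ctct_DZ = matrix(NA_real_, p, p))
    lower <- upper <- blank
    set_sym <- function(slot, j, l, b) {
      lower[[slot]][j, l] <<- lower[[slot]][l, j] <<- b[1L]
      upper[[slot]][j, l] <<- upper[[slot]][l, j] <<- b[2L]
    }
    for (j in seq_len(p)) {
      b <- profile_ci(fit, list(type = "rtwin", zyg = "MZ", trait = j), level)
      lower$rMZ[j] <- b[1L]; upper$rMZ[j] <- b[2L]
      b <- profile_ci(fit, list(type = "rtwin", zyg = "DZ", trait = j), level)
      lower$rDZ[j] <- b[1L]; upper$rDZ[j] <- b[2L]
      for (l in seq_len(j - 1L)) {
        set_sym("rph", j, l,
                profile_ci(fit, list(type = "rph", traits = c(j, l)), level))
        set_sym("ctct_MZ", j, l,
                profile_ci(fit, list(type = "ctct", zyg = "MZ",
                                     traits = c(j, l)), level))
        set_sym("ctct_DZ", j, l,
                profile_ci(fit, list(type = "ctct", zyg = "DZ",
                                     traits = c(j, l)), level))
      }
    }
    ci_out <- list(lower = lower, upper = upper)
  } else if (ci == "bootstrap") {
    set.seed(seed)
    draws <- array(NA_real_, c(B, 5L, p, p))
    tab <- fit$table
    mzi <- which(tab$zygosity == "MZ"); dzi <- which(tab$zygosity == "DZ")
    for (b in seq_len(B)) {
      idx <- c(sample(mzi, replace = TRUE), sample(dzi, replace = TRUE))
      bt <- twin_pair_table(as.data.frame(tab)[idx, , drop = FALSE],
                            attr(tab, "traits"))
      bf <- try(fit_constrained_saturated(bt, control = fit$control),
                silent = TRUE)
      if (inherits(bf, "try-error")) next
      s <- sat_stats(bf)
      draws[b, 1, , ] <- s$rph
      draws[b, 2, , ] <- diag(s$rMZ, p); draws[b, 3, , ] <- diag(s$rDZ, p)
      draws[b, 4, , ] <- s$ctct_MZ; draws[b, 5, , ] <- s$ctct_DZ
    }
    qs <- apply(draws, c(2, 3, 4), stats::quantile,
                probs = c((1 - level) / 2, 1 - (1 - level) / 2), na.rm = TRUE)
    pick <- function(side, slot, diag_only = FALSE) {
      M <- qs[side, slot, , ]
      if (diag_only) diag(as.matrix(M)) else as.matrix(M)
    }
    ci_out <- list(
      lower = list(rph = pick(1, 1), rMZ = pick(1, 2, TRUE),
                   rDZ = pick(1, 3, TRUE), ctct_MZ = pick(1, 4),
                   ctct_DZ = pick(1, 5)),
      upper = list(rph = pick(2, 1), rMZ = pick(2, 2, TRUE),
                   rDZ = pick(2, 3, TRUE), ctct_MZ = pick(2, 4),
                   ctct_DZ = pick(2, 5)))
  }

  dimn <- list(fit$traits, fit$traits)
  for (nm in c("rph", "rph_MZ", "rph_DZ", "ctct_MZ", "ctct_DZ"))
    dimnames(st[[nm]]) <- dimn
  structure(c(st, list(ci = ci_out, ci_method = ci, level = level,
                       n_used = sat_n_used(fit$table),
                       traits = fit$traits, source = "saturated_fit")),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, digits = 2, ...) {
  cat("Phenotypic correlations (rph):\n")
  print(round(x$rph, digits))
  tw <- rbind(MZ = x$rMZ, DZ = x$rDZ)
  colnames(tw) <- x$traits %||% colnames(x$rph)
  cat("Twin correlations:\n"); print(round(tw, digits))
  cat("CTCT correlations, MZ:\n"); print(round(x$ctct_MZ, digits))
  cat("CTCT correlations, DZ:\n"); print(round(x$ctct_DZ, digits))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
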