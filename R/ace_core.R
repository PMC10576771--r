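# ---- symmetric-matrix plumbing -------------------------------------------

# half-vectorization (lower triangle, diagonal included)
vech <- function(M) M[lower.tri(M, diag = TRUE)]

unvech <- function(v, p) {
  M <- matrix(0, p, p)
  M[lower.tri(M, diag = TRUE)] <- v
  M[upper.tri(M)] <- t(M)[upper.tri(M)]
  M
}

is_pd <- function(M, tol = 1e-10) {
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  min(ev) > tol * max(abs(ev), 1)
}

#' Component matrices of a correlated-factors ACE model
#'
#' Phenotype-scale covariance contributed by the additive-genetic (A),
#' shared-environmental (C) and nonshared-environmental (E) latent
#' factors, plus per-trait means.  Under direct variance estimation the
#' A and C matrices may carry negative diagonal entries at a solution;
#' only the total covariance \code{A + C + E} must be positive definite.
#'
#' @param A,C,E symmetric p x p matrices.
#' @param means per-trait mean vector (default 0).
#' @return list of class \code{"component_matrices"}.
#' @export
component_matrices <- function(A, C, E, means = rep(0, nrow(E))) {
  E <- as.matrix(E)
  p <- nrow(E)
  if (missing(A) || is.null(A)) A <- matrix(0, p, p)
  if (missing(C) || is.null(C)) C <- matrix(0, p, p)
  A <- as.matrix(A); C <- as.matrix(C)
  for (nm in c("A", "C", "E")) {
    M <- get(nm)
    if (any(dim(M) != p)) stop("dimension mismatch in ", nm)
    if (max(abs(M - t(M))) > 1e-8) stop(nm, " must be symmetric")
  }
  if (length(means) != p) stop("means must have length ", p)
  structure(list(A = A, C = C, E = E, means = as.numeric(means), p = p),
            class = "component_matrices")
}

#' Expected twin-pair covariance under the ACE model
#'
#' The 2p x 2p covariance of the stacked phenotype vector
#' (twin 1 traits, twin 2 traits) is \code{[[W, X], [X, W]]} with
#' \code{W = A + C + E} and cross-twin block \code{X = A + C} for MZ
#' pairs (identical genotypes) or \code{X = 0.5 A + C} for DZ pairs
#' (half the segregating additive-genetic variance shared).
#'
#' @param comp a \code{\link{component_matrices}} object.
#' @param zygosity \code{"MZ"} or \code{"DZ"}.
#' @return a 2p x 2p matrix.
#' @export
expected_covariance <- function(comp, zygosity = c("MZ", "DZ")) {
  stopifnot(inherits(comp, "component_matrices"))
  zygosity <- match.arg(zygosity)
  W <- comp$A + comp$C + comp$E
  X <- if (zygosity == "MZ") comp$A + comp$C else 0.5 * comp$A + comp$C
  rbind(cbind(W, X), cbind(X, W))
}

# ---- FIML machinery ------------------------------------------------------

# Pre-digest a table for repeated likelihood evaluation: rows are grouped
# by (zygosity, missingness pattern) and reduced to per-group sufficient
# statistics (count, sum vector, crossproduct matrix over observed
# coordinates).  The -2LL is then a sum over patterns, not over pairs.
fiml_data <- function(table) {
  stopifnot(inherits(table, "twin_pair_table"))
  traits <- attr(table, "traits")
  p <- length(traits)
  Y <- as.matrix(table[, c(trait_cols(traits, 1), trait_cols(traits, 2)),
                       drop = FALSE])
  storage.mode(Y) <- "double"
  zyg <- as.character(table$zygosity)
  obs <- !is.na(Y)
  key <- paste(zyg, apply(obs, 1L, function(m) paste(as.integer(m),
                                                     collapse = "")))
  groups <- split(seq_len(nrow(Y)), key)
  pats <- lapply(groups, function(idx) {
    o <- which(obs[idx[1L], ])
    if (!length(o)) return(NULL)
    Yo <- Y[idx, o, drop = FALSE]
    list(zyg = zyg[idx[1L]], o = o, n = length(idx),
         s = colSums(Yo), CP = crossprod(Yo))
  })
  pats <- pats[!vapply(pats, is.null, logical(1L))]
  list(p = p, traits = traits, patterns = pats,
       n_pairs = nrow(Y), nMZ = sum(zyg == "MZ"), nDZ = sum(zyg == "DZ"),
       n_obs_values = sum(obs),
       checksum = c(nrow(Y), sum(obs), sum(Y[obs])))
}

# -2 log likelihood for given mean vector (length 2p) and per-zygosity
# covariances; returns `penalty` if any needed submatrix is not PD.
fiml_eval <- function(fd, mu, SigmaMZ, SigmaDZ, penalty = 1e10) {
  total <- 0
  for (pt in fd$patterns) {
    S <- if (pt$zyg == "MZ") SigmaMZ else SigmaDZ
    So <- S[pt$o, pt$o, drop = FALSE]
    R <- tryCatch(chol(So), error = function(e) NULL)
    if (is.null(R)) return(penalty)
    mo <- mu[pt$o]
    k <- length(pt$o)
    # sum_i (y_i - mu)' So^-1 (y_i - mu) via sufficient statistics
    M <- pt$CP - tcrossprod(pt$s, mo) - tcrossprod(mo, pt$s) +
      pt$n * tcrossprod(mo)
    Sinv <- chol2inv(R)
    total <- total + pt$n * (k * log(2 * pi) + 2 * sum(log(diag(R)))) +
      sum(Sinv * M)
  }
  total
}

#' Full-information maximum-likelihood -2 log likelihood
#'
#' Each pair contributes a multivariate-normal density over its observed
#' (non-missing) phenotype coordinates only, with mean and covariance
#' given by the zygosity-appropriate expected structure; pairs with all
#' values missing contribute nothing.  A covariance submatrix that is
#' not positive definite makes the value a large finite penalty rather
#' than an error, so optimizers can back off.
#'
#' @param comp a \code{\link{component_matrices}} object.
#' @param table a \code{\link{twin_pair_table}} (or a pre-digested
#'   structure from the internal \code{fiml_data}).
#' @return scalar -2 log likelihood.
#' @export
fiml_minus2ll <- function(comp, table) {
  stopifnot(inherits(comp, "component_matrices"))
  fd <- if (inherits(table, "twin_pair_table")) fiml_data(table) else table
  if (fd$p != comp$p) stop("trait count mismatch")
  fiml_eval(fd, rep(comp$means, 2L),
            expected_covariance(comp, "MZ"),
            expected_covariance(comp, "DZ"))
}

# ---- model specification and parameter packing ---------------------------

#' Model specification for ACE submodels
#'
#' @param model one of \code{"ACE"}, \code{"AE"}, \code{"CE"},
#'   \code{"E"}; the named components are freely estimated (E always
#'   is), the rest fixed to zero.
#' @return list of class \code{"model_spec"}.
#' @export
model_spec <- function(model = c("ACE", "AE", "CE", "E")) {
  model <- match.arg(model)
  comps <- switch(model, ACE = c("A", "C", "E"), AE = c("A", "E"),
                  CE = c("C", "E"), E = "E")
  structure(list(label = model, components_free = comps),
            class = "model_spec")
}

# theta = [means (p), vech(A) if free, vech(C) if free, vech(E)]
theta_to_comp <- function(theta, spec, p) {
  q <- p * (p + 1L) / 2L
  means <- theta[seq_len(p)]
  at <- p
  A <- C <- matrix(0, p, p)
  if ("A" %in% spec$components_free) {
    A <- unvech(theta[at + seq_len(q)], p); at <- at + q
  }
  if ("C" %in% spec$components_free) {
    C <- unvech(theta[at + seq_len(q)], p); at <- at + q
  }
  E <- unvech(theta[at + seq_len(q)], p)
  component_matrices(A, C, E, means)
}

# validation-free objective for optimization hot paths
ace_obj_factory <- function(fd, spec) {
  p <- fd$p
  q <- p * (p + 1L) / 2L
  hasA <- "A" %in% spec$components_free
  hasC <- "C" %in% spec$components_free
  function(theta) {
    if (anyNA(theta)) return(1e10)
    at <- p
    A <- C <- matrix(0, p, p)
    if (hasA) { A <- unvech(theta[at + seq_len(q)], p); at <- at + q }
    if (hasC) { C <- unvech(theta[at + seq_len(q)], p); at <- at + q }
    E <- unvech(theta[at + seq_len(q)], p)
    W <- A + C + E
    XMZ <- A + C
    XDZ <- 0.5 * A + C
    fiml_eval(fd, rep(theta[seq_len(p)], 2L),
              rbind(cbind(W, XMZ), cbind(XMZ, W)),
              rbind(cbind(W, XDZ), cbind(XDZ, W)))
  }
}

comp_to_theta <- function(comp, spec) {
  th <- comp$means
  if ("A" %in% spec$components_free) th <- c(th, vech(comp$A))
  if ("C" %in% spec$components_free) th <- c(th, vech(comp$C))
  c(th, vech(comp$E))
}

# moment-based blocks: pooled within-twin covariance W, symmetrized
# cross-twin covariance per zygosity, grand means
moment_blocks <- function(table) {
  traits <- attr(table, "traits")
  p <- length(traits)
  Y1 <- as.matrix(table[, trait_cols(traits, 1), drop = FALSE])
  Y2 <- as.matrix(table[, trait_cols(traits, 2), drop = FALSE])
  safe_cov <- function(A, B) {
    M <- suppressWarnings(stats::cov(A, B, use = "pairwise.complete.obs"))
    M[!is.finite(M)] <- 0
    M
  }
  W <- (safe_cov(Y1, Y1) + safe_cov(Y2, Y2)) / 2
  X <- lapply(c(MZ = "MZ", DZ = "DZ"), function(z) {
    i <- table$zygosity == z
    if (sum(i) < 3L) return(matrix(0, p, p))
    B <- safe_cov(Y1[i, , drop = FALSE], Y2[i, , drop = FALSE])
    (B + t(B)) / 2
  })
  mu <- colMeans(rbind(Y1, Y2), na.rm = TRUE)
  mu[!is.finite(mu)] <- 0
  list(W = W, X_MZ = X$MZ, X_DZ = X$DZ, means = mu)
}

# floor eigenvalues so E-type starting matrices are safely PD
pd_floor <- function(M, floor) {
  ev <- eigen(M, symmetric = TRUE)
  ev$vectors %*% diag(pmax(ev$values, floor), nrow(M)) %*% t(ev$vectors)
}

moment_start <- function(mb, spec) {
  p <- nrow(mb$W)
  floor <- 0.05 * mean(diag(mb$W))
  if (!is.finite(floor) || floor <= 0) floor <- 0.05
  A <- C <- matrix(0, p, p)
  if (identical(spec$label, "ACE")) {
    A <- 2 * (mb$X_MZ - mb$X_DZ); C <- 2 * mb$X_DZ - mb$X_MZ
  } else if (identical(spec$label, "AE")) {
    A <- (mb$X_MZ + 0.5 * mb$X_DZ) / 1.25        # least-squares in X blocks
  } else if (identical(spec$label, "CE")) {
    C <- (mb$X_MZ + mb$X_DZ) / 2
  }
  E <- pd_floor(mb$W - A - C, floor)
  component_matrices(A, C, E, mb$means)
}

perturb_comp <- function(comp, scale = 0.15) {
  p <- comp$p
  jitter <- function(M) {
    s <- sqrt(mean(diag(comp$E)))
    D <- matrix(stats::rnorm(p * p, 0, scale * s^2 / 2), p, p)
    M + (D + t(D)) / 2
  }
  component_matrices(jitter(comp$A), jitter(comp$C),
                     pd_floor(jitter(comp$E), 0.02 * mean(diag(comp$E))),
                     comp$means + stats::rnorm(p, 0, scale / 2))
}

# ---- fitting -------------------------------------------------------------

# nlminb with a polish restart: with numerically approximated gradients a
# large-n objective can stall with status "false convergence" at the
# optimum; rerunning from the solution either cleans the status or shows
# no further improvement, which we accept as converged.
nlminb_polish <- function(start, obj, ctrl) {
  run <- stats::nlminb(start, obj, control = ctrl)
  if (run$convergence != 0L && is.finite(run$objective)) {
    run2 <- stats::nlminb(run$par, obj, control = ctrl)
    improved <- run$objective - run2$objective
    if (run2$objective <= run$objective) run <- run2
    if (run$convergence != 0L && improved < 1e-6) {
      run$convergence <- 0L
      run$message <- paste0(run$message, "; accepted after stationary restart")
    }
  }
  run
}

#' Fit a correlated-factors ACE model by FIML
#'
#' Minimizes the full-information -2 log likelihood over the free means
#' and the free components' symmetric matrix entries.  Components are
#' parameterized directly by their p(p+1)/2 entries (direct variance
#' estimation): diagonals are not squared or Cholesky-constrained, so
#' variance components may go negative and likelihood-ratio tests of
#' them remain unbiased.  Optimization uses quasi-Newton iterations
#' (\code{\link[stats]{nlminb}}) from a moment-based start plus
#' seeded perturbed restarts; the best converged solution is returned.
#'
#' @param table a \code{\link{twin_pair_table}}.
#' @param model \code{"ACE"}, \code{"AE"}, \code{"CE"} or \code{"E"}
#'   (or a \code{\link{model_spec}}).
#' @param starts number of optimization starts (first is the moment
#'   start, the rest perturbations of it).
#' @param seed integer seed for the perturbed starts.
#' @param control passed to \code{\link[stats]{nlminb}}; defaults set
#'   \code{rel.tol = 1e-10} and generous evaluation limits.
#' @return object of class \code{"ace_fit"}: \code{estimates}
#'   (component matrices), \code{minus2ll}, \code{df} (observed
#'   non-missing values minus free parameters), \code{n_free_params},
#'   \code{converged}, optimizer diagnostics per start, and the data
#'   digest needed for profiling and model comparison.
#' @export
fit_ace <- function(table, model = "ACE", starts = 5L, seed = 1L,
                    control = list()) {
  spec <- if (inherits(model, "model_spec")) model else model_spec(model)
  fd <- fiml_data(table)
  p <- fd$p
  if (any(c("A", "C") %in% spec$components_free) &&
      (fd$nMZ == 0L || fd$nDZ == 0L))
    stop("model ", spec$label, " needs both MZ and DZ pairs: A and C are ",
         "identified only by the MZ/DZ contrast")
  if (fd$nMZ < p + 1L || fd$nDZ < p + 1L)
    warning("fewer than p+1 pairs in a zygosity group; fit may be unstable")

  obj <- ace_obj_factory(fd, spec)

  ctrl <- utils::modifyList(list(rel.tol = 1e-10, iter.max = 1000L,
                                 eval.max = 5000L), control)
  mb <- moment_blocks(table)
  base <- moment_start(mb, spec)
  runs <- vector("list", starts)
  set.seed(seed)
  for (s in seq_len(starts)) {
    st <- if (s == 1L) base else perturb_comp(base)
    runs[[s]] <- nlminb_polish(comp_to_theta(st, spec), obj, ctrl)
  }
  vals <- vapply(runs, function(f) f$objective, numeric(1L))
  conv <- vapply(runs, function(f) f$convergence == 0L, logical(1L))
  if (!any(is.finite(vals) & vals < 1e9))
    stop("no optimization start converged to a feasible solution; ",
         "statuses: ", paste(vapply(runs, function(f) f$message, ""),
                             collapse = " | "))
  best <- which.min(ifelse(is.finite(vals), vals, Inf))
  est <- theta_to_comp(runs[[best]]$par, spec, p)

  n_free <- as.integer(p + length(spec$components_free) * p * (p + 1L) / 2L)
  Sigma_ok <- is_pd(est$A + est$C + est$E)
  if (!Sigma_ok) warning("total covariance A+C+E not positive definite ",
                         "at the solution; fit flagged invalid")
  structure(list(estimates = est, minus2ll = runs[[best]]$objective,
                 df = as.integer(fd$n_obs_values - n_free),
                 n_free_params = n_free,
                 converged = conv[best], sigma_pd = Sigma_ok,
                 status = runs[[best]]$message,
                 start_values = vals, start_converged = conv,
                 model = spec$label, spec = spec, traits = fd$traits,
                 n_pairs = fd$n_pairs, nMZ = fd$nMZ, nDZ = fd$nDZ,
                 checksum = fd$checksum, fd = fd,
                 theta = runs[[best]]$par, control = ctrl),
            class = "ace_fit")
}

#' @export
print.ace_fit <- function(x, ...) {
  cat(sprintf("Correlated-factors %s model (FIML): -2LL = %.4f, df = %d, %s\n",
              x$model, x$minus2ll, x$df,
              if (x$converged) "converged" else "NOT converged"))
  std <- standardize_components(x$estimates)
  tab <- rbind(std_a = std$std_a, std_c = std$std_c, std_e = std$std_e)
  colnames(tab) <- x$traits
  print(round(tab, 3))
  invisible(x)
}

# ---- profile-likelihood confidence intervals -----------------------------

# Generic bound finder: pfn(t) is the profiled -2LL as a function of the
# target value t.  A one-point curvature probe predicts where the
# likelihood crosses min + crit (exact if the profile were quadratic);
# the bracket is then expanded if needed and the crossing root-found.
profile_bounds <- function(pfn, est, min_val, crit, lower_cap = -Inf,
                           upper_cap = Inf, tol = 5e-5) {
  target <- min_val + crit
  one_side <- function(dir) {
    cap <- if (dir < 0) lower_cap else upper_cap
    h <- max(abs(est) * 0.1, 0.02)
    t1 <- est + dir * h
    if (dir * (t1 - cap) >= 0) t1 <- (est + cap) / 2
    v1 <- pfn(t1)
    if (is.finite(v1) && v1 > target) {      # bound closer than the probe
      r <- stats::uniroot(function(t) pfn(t) - target,
                          sort(c(est, t1)), f.lower = if (dir < 0) v1 -
                            target else min_val - target,
                          f.upper = if (dir < 0) min_val - target else
                            v1 - target, tol = tol)
      return(r$root)
    }
    curv <- max((v1 - min_val) / (t1 - est)^2, 1e-8)
    t_in <- t1; v_in <- v1
    t_out <- est + dir * sqrt(crit / curv)
    for (i in 1:60) {
      capped <- FALSE
      if (dir * (t_out - cap) >= 0) { t_out <- cap - dir * 1e-9
                                      capped <- TRUE }
      v <- pfn(t_out)
      if (is.finite(v) && v > target) {
        lo <- min(t_in, t_out); hi <- max(t_in, t_out)
        r <- stats::uniroot(function(t) pfn(t) - target, c(lo, hi),
                            f.lower = (if (lo == t_in) v_in else v) - target,
                            f.upper = (if (hi == t_out) v else v_in) - target,
                            tol = tol)
        return(r$root)
      }
      if (capped || !is.finite(v)) return(NA_real_)   # one-sided
      t_in <- t_out; v_in <- v
      t_out <- est + dir * (abs(t_out - est) * 1.7)
    }
    NA_real_
  }
  lo <- one_side(-1); hi <- one_side(+1)
  if (anyNA(c(lo, hi)))
    warning("profile bound not bracketable within the parameter domain; ",
            "interval is one-sided")
  c(lower = lo, upper = hi)
}

#' Profile-likelihood confidence interval
#'
#' Finds the values of a parameter or derived quantity at which the
#' -2 log likelihood, re-minimized over all other parameters, rises by
#' the chi-square(1) quantile (3.84 at 95\%) above its minimum.  Derived
#' targets (standardized shares, etiological correlations) are profiled
#' by constrained reparameterization: the target is fixed at a trial
#' value, one matrix entry is solved for it, and the rest re-optimized.
#'
#' @param fit an \code{"ace_fit"} or \code{"saturated_fit"} object.
#' @param target a list naming the quantity: for ACE fits
#'   \code{list(type = "std", comp = "A", trait = j)},
#'   \code{list(type = "rcomp", comp = "A", traits = c(j, k))},
#'   \code{list(type = "component", comp = "A", i = , j = )} or
#'   \code{list(type = "mean", trait = j)}; for saturated fits
#'   \code{list(type = "rph", traits = c(j, k))},
#'   \code{list(type = "rtwin", zyg = "MZ", trait = j)} or
#'   \code{list(type = "ctct", zyg = "MZ", traits = c(j, k))}.
#' @param level confidence level (default 0.95).
#' @param ... unused.
#' @return named numeric \code{c(lower, upper)}; an unbracketable side
#'   is \code{NA} with a warning (one-sided interval).
#' @export
profile_ci <- function(fit, target, level = 0.95, ...) UseMethod("profile_ci")

# Shared engine: `fix_fn(theta_red, t)` -> full theta; `free_idx` are the
# coordinates of theta kept free; est_val the fitted target value.
profile_engine <- function(obj, theta_hat, free_idx, fix_fn, est_val,
                           minus2ll, level, ctrl, caps = c(-Inf, Inf)) {
  warm <- theta_hat[free_idx]
  pfn <- function(t) {
    r <- stats::nlminb(warm, function(th) obj(fix_fn(th, t)), control = ctrl)
    if (r$convergence == 0L || is.finite(r$objective)) warm <<- r$par
    r$objective
  }
  crit <- stats::qchisq(level, 1L)
  profile_bounds(pfn, est_val, minus2ll, crit,
                 lower_cap = caps[1], upper_cap = caps[2], tol = 1e-5)
}

#' @export
profile_ci.ace_fit <- function(fit, target, level = 0.95, ...) {
  spec <- fit$spec; p <- fit$fd$p
  q <- p * (p + 1L) / 2L
  comp_off <- function(comp) {
    if (!comp %in% spec$components_free)
      stop("component ", comp, " is not free in the ", fit$model, " model")
    at <- p
    for (cc in c("A", "C")) {
      if (cc == comp) return(at)
      if (cc %in% spec$components_free) at <- at + q
    }
    at
  }
  # index of entry (i,j) within vech()
  IX <- matrix(0L, p, p); IX[lower.tri(IX, diag = TRUE)] <- seq_len(q)
  IX[upper.tri(IX)] <- t(IX)[upper.tri(IX)]

  obj <- ace_obj_factory(fit$fd, spec)
  th <- fit$theta
  ctrl <- utils::modifyList(fit$control, list(iter.max = 300L))
  comp_hat <- fit$estimates
  tot <- comp_hat$A + comp_hat$C + comp_hat$E

  if (target$type == "mean") {
    k <- target$trait
    fix <- function(red, t) { full <- th; full[-k] <- red; full[k] <- t; full }
    return(profile_engine(obj, th, setdiff(seq_along(th), k), fix,
                          comp_hat$means[k], fit$minus2ll, level, ctrl))
  }
  if (target$type == "component") {
    k <- comp_off(target$comp) + IX[target$i, target$j]
    est <- comp_hat[[target$comp]][target$i, target$j]
    fix <- function(red, t) { full <- th; full[-k] <- red; full[k] <- t; full }
    return(profile_engine(obj, th, setdiff(seq_along(th), k), fix,
                          est, fit$minus2ll, level, ctrl))
  }
  if (target$type == "std") {
    j <- target$trait
    k <- comp_off(target$comp) + IX[j, j]       # eliminate X_jj
    others <- setdiff(spec$components_free, target$comp)
    oth_idx <- vapply(others, function(cc) comp_off(cc) + IX[j, j],
                      numeric(1L))
    est <- comp_hat[[target$comp]][j, j] / tot[j, j]
    fix <- function(red, t) {
      full <- th; full[-k] <- red
      osum <- sum(full[oth_idx])                # X_jj = t/(1-t) * sum(others)
      full[k] <- if (t < 1 && osum > 0) t / (1 - t) * osum else NA_real_
      full
    }
    return(profile_engine(obj, th, setdiff(seq_along(th), k), fix,
                          est, fit$minus2ll, level, ctrl,
                          caps = c(-Inf, 0.999999)))
  }
  if (target$type == "rcomp") {
    j <- target$traits[1]; l <- target$traits[2]
    off <- comp_off(target$comp)
    k <- off + IX[j, l]                         # eliminate X_jl
    djj <- off + IX[j, j]; dll <- off + IX[l, l]
    M <- comp_hat[[target$comp]]
    est <- M[j, l] / sqrt(M[j, j] * M[l, l])
    fix <- function(red, t) {
      full <- th; full[-k] <- red
      prod <- full[djj] * full[dll]
      full[k] <- if (prod > 0) t * sqrt(prod) else NA_real_
      full
    }
    return(profile_engine(obj, th, setdiff(seq_along(th), k), fix,
                          est, fit$minus2ll, level, ctrl))
  }
  stop("unknown profile target type: ", target$type)
}
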