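#' Lightweight fit summary
#'
#' Minimal stand-in for a fitted model in comparison operations: a
#' label, -2 log likelihood and degrees of freedom (plus optionally the
#' free-parameter count).  Useful for reproducing a published fit table
#' whose raw data are not available.
#'
#' @param minus2ll -2 log likelihood.
#' @param df degrees of freedom (observed data values minus free
#'   parameters).
#' @param label model name.
#' @param n_free_params optional free-parameter count.
#' @param n_pairs optional pair count (for BIC).
#' @return list of class \code{"fit_summary"}.
#' @export
fit_summary <- function(minus2ll, df, label = "model",
                        n_free_params = NULL, n_pairs = NULL) {
  structure(list(minus2ll = minus2ll, df = as.integer(df), model = label,
                 n_free_params = n_free_params, n_pairs = n_pairs,
                 checksum = NULL),
            class = "fit_summary")
}

fit_fields <- function(fit) {
  stopifnot(is.list(fit), !is.null(fit$minus2ll), !is.null(fit$df))
  fit
}

#' Likelihood-ratio test of nested twin models
#'
#' The difference in -2 log likelihood between a nested submodel and its
#' reference is asymptotically chi-square with the difference in degrees
#' of freedom.  A slightly negative difference (optimizer noise, within
#' 1e-4) is clamped to zero for the p-value with a warning; larger
#' negative values are flagged as a dominance violation.
#'
#' @param reference the richer model's fit (\code{ace_fit},
#'   \code{saturated_fit} or \code{\link{fit_summary}}).
#' @param nested the submodel's fit.
#' @return one-row data.frame of class \code{"comparison_row"}: label,
#'   minus2ll, df, chi2, delta_df, p_value, reference.
#' @export
lrt <- function(reference, nested) {
  reference <- fit_fields(reference); nested <- fit_fields(nested)
  if (!is.null(reference$checksum) && !is.null(nested$checksum) &&
      !isTRUE(all.equal(reference$checksum, nested$checksum)))
    stop("fits are not on the same data (checksum mismatch)")
  if (!is.null(reference$n_free_params) && !is.null(nested$n_free_params) &&
      nested$n_free_params > reference$n_free_params)
    stop("'nested' has more free parameters than 'reference'; not nested")
  chi2 <- nested$minus2ll - reference$minus2ll
  delta_df <- nested$df - reference$df
  if (delta_df < 0) stop("'nested' has fewer degrees of freedom than ",
                         "'reference'; models are not nested")
  flagged <- chi2 < -1e-4
  if (flagged)
    warning("nested model fits better than reference by ",
            format(-chi2), "; likelihood dominance violated")
  else if (chi2 < 0)
    warning("slightly negative chi-square (optimizer noise) clamped to 0")
  p <- if (chi2 <= 0 || delta_df == 0L) 1 else
    stats::pchisq(chi2, delta_df, lower.tail = FALSE)
  out <- data.frame(label = nested$model %||% "nested",
                    minus2ll = nested$minus2ll, df = nested$df,
                    chi2 = chi2, delta_df = delta_df, p_value = p,
                    reference = reference$model %||% "reference",
                    dominance_flag = flagged,
                    stringsAsFactors = FALSE)
  class(out) <- c("comparison_row", "data.frame")
  out
}

#' Information criteria for a fitted twin model
#'
#' Two conventions are reported.  The behavior-genetics fit-table
#' convention treats -2LL relative to the data degrees of freedom:
#' \code{AIC = -2LL - 2 df} and \code{BIC = -2LL - df log(n)} with n the
#' number of twin pairs.  The standard penalized-likelihood convention
#' uses the free-parameter count k: \code{AIC = -2LL + 2k},
#' \code{BIC = -2LL + k log(n)}.  Model ranking by AIC difference is
#' identical under both whenever models are fitted to the same data.
#'
#' @param fit a fit object or \code{\link{fit_summary}}.
#' @param n_pairs number of twin pairs (taken from the fit if present).
#' @return named list: \code{aic}, \code{bic} (fit-table convention),
#'   \code{aic_standard}, \code{bic_standard} (NULL without k or n).
#' @export
information_criteria <- function(fit, n_pairs = fit$n_pairs) {
  fit <- fit_fields(fit)
  k <- fit$n_free_params
  list(aic = fit$minus2ll - 2 * fit$df,
       bic = if (is.null(n_pairs)) NULL else
         fit$minus2ll - fit$df * log(n_pairs),
       aic_standard = if (is.null(k)) NULL else fit$minus2ll + 2 * k,
       bic_standard = if (is.null(k) || is.null(n_pairs)) NULL else
         fit$minus2ll + k * log(n_pairs))
}

#' Compare the saturated, full and reduced twin models
#'
#' Builds the standard twin-study fit table: the full correlated-factors
#' ACE model is tested against the constrained saturated baseline, and
#' each submodel against the full ACE model, with likelihood-ratio
#' statistics and both AIC conventions.
#'
#' @param saturated a \code{saturated_fit} (or \code{fit_summary}).
#' @param ace the full ACE \code{ace_fit}.
#' @param ... further nested fits (AE, CE, E), each compared to
#'   \code{ace}.
#' @return data.frame of class \code{"model_comparison"}; one row per
#'   model with minus2ll, df, chi2, delta_df, p_value, aic, bic,
#'   reference.
#' @export
compare_models <- function(saturated, ace, ...) {
  subs <- list(...)
  rows <- list(lrt(saturated, ace))
  for (f in subs) rows <- c(rows, list(lrt(ace, f)))
  tab <- do.call(rbind, rows)
  fits <- c(list(ace), subs)
  ics <- lapply(fits, information_criteria)
  tab$aic <- vapply(ics, function(x) x$aic, numeric(1L))
  tab$bic <- vapply(ics, function(x) x$bic %||% NA_real_, numeric(1L))
  tab$n_free_params <- vapply(fits, function(f)
    f$n_free_params %||% NA_integer_, numeric(1L))
  sat <- fit_fields(saturated)
  satic <- information_criteria(sat)
  satrow <- data.frame(label = sat$model %||% "saturated",
                       minus2ll = sat$minus2ll, df = sat$df,
                       chi2 = NA_real_, delta_df = NA_integer_,
                       p_value = NA_real_, reference = NA_character_,
                       dominance_flag = FALSE, aic = satic$aic,
                       bic = satic$bic %||% NA_real_,
                       n_free_params = sat$n_free_params %||% NA_integer_,
                       stringsAsFactors = FALSE)
  out <- rbind(satrow, tab)
  rownames(out) <- NULL
  class(out) <- c("model_comparison", "data.frame")
  out
}

#' Select the preferred model from a comparison table
#'
#' Applies the parsimony rule used in twin-model fit tables: among
#' models whose AIC lies within \code{aic_window} of the minimum AIC and
#' whose likelihood-ratio test against the full model is nonsignificant
#' at \code{alpha}, the most parsimonious (fewest free parameters,
#' i.e. largest df) is selected.  Ties on df are broken by the
#' documented label ordering ACE < AE < CE < E and flagged.
#'
#' @param rows a \code{model_comparison} (or data.frame with columns
#'   label, df, aic, p_value); the saturated baseline row, if present,
#'   is not a candidate.
#' @param aic_window AIC tolerance for parsimony (default 10).
#' @param alpha LRT significance level (default 0.05).
#' @return list of class \code{"model_selection"}: \code{label},
#'   \code{tie} flag, and a \code{trace} character vector quoting each
#'   criterion applied.
#' @export
select_model <- function(rows, aic_window = 10, alpha = 0.05) {
  if (is.null(rows) || !nrow(rows)) stop("empty comparison table")
  cand <- rows[!(rows$label %in% "saturated"), , drop = FALSE]
  if (!nrow(cand)) stop("no candidate models (only a saturated row)")
  trace <- character(0)
  note <- function(...) trace <<- c(trace, sprintf(...))
  if (nrow(cand) == 1L) {
    note("single model '%s': selected by default", cand$label[1L])
    return(structure(list(label = cand$label[1L], tie = FALSE,
                          trace = trace), class = "model_selection"))
  }
  aic_min <- min(cand$aic)
  note("minimum AIC %.2f ('%s')", aic_min, cand$label[which.min(cand$aic)])
  ok_aic <- cand$aic - aic_min < aic_window
  note("AIC within %g of minimum: %s", aic_window,
       paste(cand$label[ok_aic], collapse = ", "))
  pv <- ifelse(is.na(cand$p_value), 1, cand$p_value)  # full model vs itself
  ok_lrt <- pv >= alpha
  note("LRT vs full model nonsignificant at %.2f: %s", alpha,
       paste(cand$label[ok_lrt], collapse = ", "))
  ok <- ok_aic & ok_lrt
  if (!any(ok)) {
    note("no model passes both rules; falling back to minimum AIC")
    ok <- cand$aic == aic_min
  }
  pool <- cand[ok, , drop = FALSE]
  most <- pool[pool$df == max(pool$df), , drop = FALSE]
  tie <- nrow(most) > 1L
  ord <- c("ACE", "AE", "CE", "E")
  pick <- most$label[order(match(most$label, ord))][1L]
  if (tie) note("tie on parsimony between %s; '%s' chosen by label order",
                paste(most$label, collapse = ", "), pick)
  note("selected '%s' as the most parsimonious adequate model", pick)
  structure(list(label = pick, tie = tie, trace = trace),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("Selected model:", x$label, "\n")
  cat(paste0("  - ", x$trace, collapse = "\n"), "\n")
  invisible(x)
}
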