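# ---- configuration -------------------------------------------------------

#' Read a pipeline run configuration
#'
#' YAML key-value file naming either an input CSV (\code{data}) or a
#' \code{simulate:} block mirroring \code{\link{generating_params}},
#' plus \code{traits}, \code{covariates}, \code{models}, \code{ci}
#' method, optimizer settings (\code{starts}), \code{seed} and
#' \code{out_dir}.  Round-trips losslessly through
#' \code{yaml::write_yaml}.
#'
#' @param path YAML file path.
#' @return list of class \code{"run_config"}.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  as_run_config(yaml::read_yaml(path))
}

as_run_config <- function(cfg) {
  stopifnot(is.list(cfg))
  defaults <- list(covariates = "sex", models = c("ACE", "AE", "CE", "E"),
                   ci = "none", starts = 5L, seed = 1L, out_dir = ".")
  cfg <- utils::modifyList(defaults, cfg)
  if (is.null(cfg$traits) && is.null(cfg$simulate))
    stop("config must name 'traits' (and 'data') or a 'simulate' block")
  bad <- setdiff(cfg$models, c("ACE", "AE", "CE", "E"))
  if (length(bad)) stop("unknown model label(s): ", paste(bad, collapse = ", "))
  if (!cfg$ci %in% c("none", "profile", "bootstrap"))
    stop("ci must be one of none, profile, bootstrap")
  structure(cfg, class = c("run_config", "list"))
}

config_to_params <- function(sim, seed) {
  m <- function(x) if (is.null(x)) NULL else
    matrix(unlist(x), nrow = length(x), byrow = TRUE)
  p <- length(sim$a)
  generating_params(a = as.numeric(sim$a),
                    c = as.numeric(sim$c %||% rep(0, p)),
                    e = as.numeric(sim$e %||% (1 - as.numeric(sim$a) -
                                    as.numeric(sim$c %||% rep(0, p)))),
                    rA = m(sim$rA) %||% diag(p), rC = m(sim$rC) %||% diag(p),
                    rE = m(sim$rE) %||% diag(p),
                    means = as.numeric(sim$means %||% rep(0, p)),
                    sex_effect = as.numeric(sim$sex_effect %||% rep(0, p)),
                    missing_rate = sim$missing_rate %||% 0,
                    nMZ = sim$nMZ %||% 429L, nDZ = sim$nDZ %||% 707L,
                    seed = sim$seed %||% seed)
}

# ---- JSON rendering ------------------------------------------------------

json_ready <- function(x) {
  if (is.matrix(x)) return(apply(x, 1L, as.numeric, simplify = FALSE))
  if (is.list(x)) return(lapply(x, json_ready))
  x
}

write_report_json <- function(x, path) {
  jsonlite::write_json(json_ready(x), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE, force = TRUE)
}

fit_to_list <- function(fit) {
  keep <- intersect(names(fit),
                    c("model", "minus2ll", "df", "n_free_params",
                      "converged", "status", "sigma_pd", "constraints",
                      "n_pairs", "nMZ", "nDZ"))
  out <- fit[keep]
  if (!is.null(fit$estimates)) {
    out$A <- fit$estimates$A; out$C <- fit$estimates$C
    out$E <- fit$estimates$E; out$means <- fit$estimates$means
  }
  if (is.null(fit$estimates) && !is.null(fit$X_MZ)) {
    out$means <- fit$means; out$v <- fit$v
    out$W_MZ <- fit$W_MZ; out$W_DZ <- fit$W_DZ
    out$X_MZ <- fit$X_MZ; out$X_DZ <- fit$X_DZ
  }
  out
}

# ---- pipeline ------------------------------------------------------------

#' Run the full twin-analysis pipeline
#'
#' Orchestrates the analysis end to end: load (or simulate) a twin-pair
#' table, residualize traits on sex, fit the constrained saturated model
#' and produce the correlation report, fit the requested ACE submodels,
#' compare them, select the preferred model by the parsimony rule, and
#' decompose it into genetic and environmental shares.  All stage
#' outputs are written as JSON under \code{out_dir} together with a run
#' log (seeds, package version, convergence diagnostics) and a MANIFEST;
#' on a stage failure the partial outputs are retained and the MANIFEST
#' marks the run incomplete.
#'
#' @param config a \code{run_config}, plain list, or YAML file path (see
#'   \code{\link{read_run_config}}).
#' @return invisibly, a list with the table, fits, reports and the
#'   selected model label.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- as_run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  logi <- function(stage, ...) {
    line <- sprintf("[%s] %s", stage, sprintf(...))
    log_lines <<- c(log_lines, line)
    message(line)
  }
  manifest <- list(complete = FALSE, seed = cfg$seed,
                   version = as.character(utils::packageVersion("twinace")),
                   artifacts = character(0))
  emit <- function(name, obj) {
    path <- file.path(cfg$out_dir, name)
    write_report_json(obj, path)
    manifest$artifacts <<- c(manifest$artifacts, name)
  }
  finish <- function() {
    writeLines(log_lines, file.path(cfg$out_dir, "run_log.txt"))
    write_report_json(manifest, file.path(cfg$out_dir, "MANIFEST.json"))
  }

  stage <- "config"
  result <- tryCatch({
    stage <- "data"
    if (!is.null(cfg$simulate)) {
      params <- config_to_params(cfg$simulate, cfg$seed)
      traits <- cfg$traits %||% paste0("trait", seq_len(params$p))
      table <- simulate_twins(params, traits = traits)
      logi(stage, "simulated %d MZ + %d DZ pairs, seed %d",
           params$nMZ, params$nDZ, params$seed)
    } else {
      table <- read_twin_csv(cfg$data, cfg$traits)
      logi(stage, "loaded %d pairs from %s", nrow(table), cfg$data)
    }

    stage <- "residualize"
    if (length(cfg$covariates)) {
      table <- residualize(table, cfg$covariates)
      logi(stage, "residualized on %s", paste(cfg$covariates, collapse = "+"))
    }

    stage <- "saturated"
    sat <- fit_constrained_saturated(table)
    logi(stage, "-2LL %.4f, df %d, converged %s", sat$minus2ll, sat$df,
         sat$converged)
    rep2 <- correlation_report(sat, ci = cfg$ci, seed = cfg$seed)
    emit("correlations.json",
         c(rep2[c("rph", "rMZ", "rDZ", "ctct_MZ", "ctct_DZ", "ci_method")],
           list(ci = rep2$ci, fit = fit_to_list(sat), seed = cfg$seed)))

    stage <- "fit"
    fits <- list()
    for (m in cfg$models) {
      fits[[m]] <- fit_ace(table, m, starts = cfg$starts, seed = cfg$seed)
      logi(stage, "%s: -2LL %.4f, df %d, converged %s", m,
           fits[[m]]$minus2ll, fits[[m]]$df, fits[[m]]$converged)
      emit(paste0("fit_", m, ".json"),
           c(fit_to_list(fits[[m]]), list(seed = cfg$seed)))
    }

    stage <- "compare"
    full <- fits[["ACE"]] %||% fits[[cfg$models[1L]]]
    subs <- fits[setdiff(names(fits), full$model)]
    comp <- do.call(compare_models, c(list(sat, full), unname(subs)))
    sel <- select_model(comp)
    logi(stage, "selected %s", sel$label)
    emit("model_comparison.json",
         list(table = comp, selected = sel$label, trace = sel$trace,
              seed = cfg$seed))

    stage <- "decompose"
    dec <- decompose(fits[[sel$label]], observed_rph = rep2$rph,
                     ci = if (cfg$ci == "profile") "profile" else "none")
    emit("decomposition.json",
         c(dec[c("std_a", "std_c", "std_e", "rA", "rC", "rE",
                 "implied_rph", "share_A", "share_C", "share_E", "model")],
           list(seed = cfg$seed)))

    manifest$complete <- TRUE
    list(table = table, saturated = sat, correlations = rep2, fits = fits,
         comparison = comp, selected = sel, decomposition = dec)
  }, error = function(e) {
    logi(stage, "FAILED: %s", conditionMessage(e))
    finish()
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  finish()
  invisible(result)
}
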