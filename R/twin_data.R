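#' Trait specification
#'
#' Fixes the ordered set of phenotype names used throughout an analysis.
#' The ordering determines row/column indices of every matrix a fit
#' returns (component matrices, correlation reports, decomposition
#' tables).
#'
#' @param names character vector of trait labels; must be unique and
#'   non-empty.
#' @return character vector of class \code{"trait_spec"}.
#' @export
trait_spec <- function(names) {
  names <- as.character(names)
  if (length(names) < 1L) stop("at least one trait name is required")
  if (anyNA(names) || any(!nzchar(names))) stop("trait names must be non-empty")
  if (anyDuplicated(names)) stop("trait names must be unique")
  structure(names, class = "trait_spec")
}

# column names for a trait vector: "<trait>_1", "<trait>_2"
trait_cols <- function(traits, twin) paste0(traits, "_", twin)

#' Twin-pair phenotype table
#'
#' Wide table with one row per twin pair: a pair identifier, zygosity
#' (\code{"MZ"} or \code{"DZ"}), the sex of each twin, and for each of
#' the \code{p} traits two value columns \code{<trait>_1} /
#' \code{<trait>_2}.  Missing phenotype or sex values are allowed and
#' handled downstream by full-information maximum likelihood; pairs with
#' every trait value missing carry no likelihood information and are
#' dropped with a warning.
#'
#' @param df data.frame holding the columns described above.
#' @param traits character vector (or \code{\link{trait_spec}}) of trait
#'   names.
#' @param drop_empty drop pairs with all \code{2p} trait values missing
#'   (default \code{TRUE}).
#' @return a \code{data.frame} of class \code{"twin_pair_table"} with a
#'   \code{"traits"} attribute.
#' @export
twin_pair_table <- function(df, traits, drop_empty = TRUE) {
  traits <- as.character(traits)
  req <- c("family_id", "zygosity", "sex1", "sex2",
           as.vector(rbind(trait_cols(traits, 1), trait_cols(traits, 2))))
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))

  df <- df[, req, drop = FALSE]
  zyg <- toupper(trimws(as.character(df$zygosity)))
  bad <- !(zyg %in% c("MZ", "DZ"))
  if (any(bad)) {
    warning(sum(bad), " row(s) rejected: zygosity not in {MZ, DZ}")
    df <- df[!bad, , drop = FALSE]
    zyg <- zyg[!bad]
  }
  df$zygosity <- factor(zyg, levels = c("MZ", "DZ"))

  for (s in c("sex1", "sex2")) {
    v <- tolower(trimws(as.character(df[[s]])))
    v[v %in% c("", "na")] <- NA
    if (!all(v %in% c("male", "female", NA)))
      stop("column ", s, " must contain 'male', 'female' or missing")
    df[[s]] <- factor(v, levels = c("female", "male"))
  }

  vcols <- c(trait_cols(traits, 1), trait_cols(traits, 2))
  for (v in vcols) df[[v]] <- as.numeric(df[[v]])

  if (drop_empty && nrow(df)) {
    empty <- rowSums(!is.na(as.matrix(df[, vcols, drop = FALSE]))) == 0L
    if (any(empty)) {
      warning(sum(empty), " pair(s) dropped: all trait values missing")
      df <- df[!empty, , drop = FALSE]
    }
  }
  rownames(df) <- NULL
  structure(df, traits = traits,
            class = c("twin_pair_table", "data.frame"))
}

#' @export
print.twin_pair_table <- function(x, ...) {
  traits <- attr(x, "traits")
  cat(sprintf("Twin-pair table: %d pairs (%d MZ, %d DZ), %d trait(s): %s\n",
              nrow(x), sum(x$zygosity == "MZ"), sum(x$zygosity == "DZ"),
              length(traits), paste(traits, collapse = ", ")))
  invisible(x)
}

#' Number of traits in a twin-pair table
#' @param table a \code{twin_pair_table}.
#' @return integer trait count.
#' @export
n_traits <- function(table) length(attr(table, "traits"))

#' Read a twin-pair table from CSV
#'
#' Expects a comma-delimited UTF-8 file with a header row containing
#' \code{family_id}, \code{zygosity}, \code{sex1}, \code{sex2} and, for
#' each trait, \code{<trait>_1} and \code{<trait>_2}.  Empty cells and
#' the token \code{"NA"} are read as missing.  Rows with unknown
#' zygosity, and pairs with all trait values missing, are rejected with
#' a warning naming the reason.
#'
#' @param path file path.
#' @param traits character vector or \code{\link{trait_spec}}.
#' @param missing_tokens strings treated as missing values.
#' @return a \code{\link{twin_pair_table}}.
#' @export
read_twin_csv <- function(path, traits, missing_tokens = c("", "NA")) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character",
                        na.strings = missing_tokens,
                        check.names = FALSE, fileEncoding = "UTF-8")
  twin_pair_table(df, traits)
}

#' Write a twin-pair table to CSV
#'
#' Emits the same wide dialect \code{\link{read_twin_csv}} accepts, with
#' missing values as empty cells.  Numeric values are written with full
#' double precision so a read/write round trip is lossless.
#'
#' @param table a \code{twin_pair_table}.
#' @param path output file path.
#' @export
write_twin_csv <- function(table, path) {
  traits <- attr(table, "traits")
  out <- as.data.frame(table)
  vcols <- c(trait_cols(traits, 1), trait_cols(traits, 2))
  for (v in vcols) {
    x <- formatC(out[[v]], digits = 17, format = "g")
    x[is.na(out[[v]])] <- ""
    out[[v]] <- x
  }
  for (s in c("sex1", "sex2", "zygosity")) {
    x <- as.character(out[[s]])
    x[is.na(x)] <- ""
    out[[s]] <- x
  }
  ok <- try(utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                             na = "", fileEncoding = "UTF-8"), silent = TRUE)
  if (inherits(ok, "try-error")) stop("cannot write to ", path)
  invisible(NULL)
}

#' Residualize traits on covariates
#'
#' Replaces each trait by the residuals of an ordinary least-squares
#' regression of that trait on the covariate(s), pooling all individuals
#' (both twins, both zygosity groups) into one long sample per trait.
#' Individuals with a non-missing trait value but missing covariate have
#' the trait value set missing (with a warning) rather than having the
#' covariate imputed.  Residuals have zero sample correlation with the
#' covariate, and the operation is idempotent.
#'
#' @param table a \code{\link{twin_pair_table}}.
#' @param covariates character vector; currently only \code{"sex"} is
#'   supported.
#' @return a \code{twin_pair_table} with residualized trait values.
#' @export
residualize <- function(table, covariates = "sex") {
  if (!inherits(table, "twin_pair_table")) stop("not a twin_pair_table")
  if (!length(covariates)) return(table)
  if (!all(covariates %in% "sex"))
    stop("unsupported covariate(s): ",
         paste(setdiff(covariates, "sex"), collapse = ", "))
  traits <- attr(table, "traits")
  sex <- cbind(as.integer(table$sex1) - 1L, as.integer(table$sex2) - 1L)
  if (all(is.na(sex))) stop("sex is missing for every individual")
  if (stats::var(as.vector(sex), na.rm = TRUE) == 0)
    stop("degenerate design: sex is constant across all individuals")

  n_masked <- 0L
  for (j in seq_along(traits)) {
    cols <- trait_cols(traits[j], 1:2)
    y <- cbind(table[[cols[1]]], table[[cols[2]]])
    mask <- !is.na(y) & is.na(sex)
    n_masked <- n_masked + sum(mask)
    y[mask] <- NA
    keep <- !is.na(y) & !is.na(sex)
    fit <- stats::lm.fit(cbind(1, as.vector(sex)[as.vector(keep)]),
                         as.vector(y)[as.vector(keep)])
    y[keep] <- fit$residuals
    table[[cols[1]]] <- y[, 1]
    table[[cols[2]]] <- y[, 2]
  }
  if (n_masked)
    warning(n_masked,
            " trait value(s) set missing: covariate missing for individual")
  table
}
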