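# CSV I/O, run manifests.  Responses round-trip as a CSV with an item-ID
# header, one row per person, cells in {0, 1, NA} ("NA" or empty cell =
# missing, the booklet-design convention).

#' Read a dichotomous response matrix from CSV
#'
#' @param path CSV file: header row of item IDs, one row per person,
#'   cells in `{0, 1, NA}` (empty cells also count as missing).
#' @return A validated [response_matrix()].
#' @export
read_responses <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        na.strings = c("NA", ""))
  y <- as.matrix(df)
  if (!is.numeric(y)) {
    bad <- which(!is.na(y) & is.na(suppressWarnings(
      matrix(as.numeric(y), nrow(y)))), arr.ind = TRUE)
    if (nrow(bad) > 0L) {
      stop(sprintf("non-numeric response '%s' at row %d, column %d of %s",
                   y[bad[1, 1], bad[1, 2]], bad[1, 1], bad[1, 2], path),
           call. = FALSE)
    }
    storage.mode(y) <- "numeric"
  }
  bad <- which(!is.na(y) & y != 0 & y != 1, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-binary response %g at row %d, column %d of %s",
                 y[bad[1, 1], bad[1, 2]], bad[1, 1], bad[1, 2], path),
         call. = FALSE)
  }
  response_matrix(y)
}

#' Write a response matrix to CSV
#'
#' @param responses matrix of 0/1/`NA` responses.
#' @param path output path.
#' @export
write_responses <- function(responses, path) {
  y <- as.matrix(responses)
  if (is.null(colnames(y))) colnames(y) <- paste0("item", seq_len(ncol(y)))
  utils::write.csv(as.data.frame(y), path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a person-level covariate table from CSV
#'
#' @param path numeric CSV with a header of variable names, one row per
#'   person, aligned with the response file.
#' @param fit_intercept prepend an all-ones `(Intercept)` column.
#' @param n_expected optional person count to validate against.
#' @return Numeric matrix with column names.
#' @export
read_covariates <- function(path, fit_intercept = FALSE,
                            n_expected = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  X <- as.matrix(df)
  if (!is.numeric(X)) {
    stop(sprintf("non-numeric covariate cell in %s", path), call. = FALSE)
  }
  if (!is.null(n_expected) && nrow(X) != n_expected) {
    stop(sprintf("covariate file has %d rows but %d persons expected",
                 nrow(X), n_expected), call. = FALSE)
  }
  if (fit_intercept) X <- cbind("(Intercept)" = 1, X)
  X
}

#' Write a run manifest
#'
#' A JSON snapshot of the configuration, seeds, package version and
#' wall-clock timestamps; re-running a fit from the manifest's
#' configuration and seed reproduces the outputs bit for bit.
#'
#' @param path output path (`manifest.json`).
#' @param config a [chain_config()].
#' @param extra named list of additional fields (model, tau, files,
#'   per-replication seeds, ...).
#' @param started,finished POSIXct timestamps.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, config, extra = list(),
                           started = Sys.time(), finished = Sys.time()) {
  man <- c(list(
    package = "qmlirt",
    version = as.character(utils::packageVersion("qmlirt")),
    config = unclass(config),
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(finished, "%Y-%m-%dT%H:%M:%S%z")), extra)
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(man)
}

#' Read a run manifest
#'
#' @param path path to a `manifest.json` written by [write_manifest()].
#' @return Named list.
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write the post-burn-in draw archive of a fit as CSV
#'
#' Columnar text format: one row per stored draw, a `chain` column, and
#' one column per scalar parameter (structural coefficients, the
#' structural scale, and all item parameters).  Together with the run
#' manifest this is sufficient to recompute posterior summaries and the
#' deviance-based diagnostics.
#'
#' @param fit a fitted [qmlirt()] or [mmlirt()] object.
#' @param path output path.
#' @export
write_draws <- function(fit, path) {
  scale_name <- if (fit$model == "qmlirt") "omega" else "alpha2"
  tabs <- lapply(seq_along(fit$chains), function(j) {
    ch <- fit$chains[[j]]
    d <- data.frame(chain = j, ch$beta, ch[[scale_name]], ch$a, ch$b,
                    deviance = ch$deviance)
    names(d) <- c("chain", paste0("beta.", colnames(fit$X)), scale_name,
                  paste0("a.", seq_len(fit$K)),
                  paste0("b.", seq_len(fit$K)), "deviance")
    d
  })
  utils::write.csv(do.call(rbind, tabs), path, row.names = FALSE)
  invisible(path)
}

#' Write the posterior summary of a fit as CSV
#'
#' Flat table: parameter, mean, sd (and psrf for multi-chain fits).
#'
#' @param fit a fitted model object.
#' @param path output path.
#' @export
write_summary <- function(fit, path) {
  utils::write.csv(fit$posterior, path, row.names = FALSE)
  invisible(path)
}
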