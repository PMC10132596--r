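#' Read fingerprints from CSV
#'
#' Expects a header with `sample_id`, one absorbance column per wavelength
#' named `a<wavelength-in-nm>` (e.g. `a240`), and optional `substance` and
#' `truth` columns. The wavelength grid is inferred from the headers and
#' sorted ascending, so fingerprints for other medications on other grids
#' parse unchanged. Truth values are matched case-insensitively;
#' `"A"`/`"authentic"` and `"LQ/C"`/`"LQC"`/`"lqc"` are accepted.
#'
#' @param path Path to a CSV file.
#' @param strict If `TRUE` (default), absorbances outside \[0, 2\] are an
#'   error naming the offending row and column; if `FALSE` they are clipped
#'   with a warning.
#' @return List of [fingerprint()] objects. Any extra columns are attached
#'   to each fingerprint as attribute `extra` (named character vector).
#' @export
read_fingerprints_csv <- function(path, strict = TRUE) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L)
    stop(sprintf("no fingerprint rows in '%s'", path), call. = FALSE)
  if (!"sample_id" %in% names(tab))
    stop("missing required column 'sample_id'", call. = FALSE)
  acols <- grep("^a[0-9]+(\\.[0-9]+)?$", names(tab), value = TRUE)
  if (length(acols) == 0L)
    stop("no absorbance columns found (expected names like 'a240')",
         call. = FALSE)
  wl <- as.numeric(sub("^a", "", acols))
  ord <- order(wl)
  acols <- acols[ord]; wl <- wl[ord]
  for (col in acols) {
    vals <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(vals) & !is.na(tab[[col]]) | is.na(tab[[col]]))
    if (length(bad))
      stop(sprintf("non-numeric absorbance in column '%s', row %d",
                   col, bad[1L]), call. = FALSE)
    if (strict) {
      oob <- which(vals < 0 | vals > 2)
      if (length(oob))
        stop(sprintf("absorbance out of [0, 2] in column '%s', row %d (%g)",
                     col, oob[1L], vals[oob[1L]]), call. = FALSE)
    }
    tab[[col]] <- vals
  }
  truth <- if ("truth" %in% names(tab)) normalise_truth(tab$truth)
           else rep("unknown", nrow(tab))
  substance <- if ("substance" %in% names(tab)) as.character(tab$substance)
               else rep(NA_character_, nrow(tab))
  extra_cols <- setdiff(names(tab), c("sample_id", acols, "substance", "truth"))
  lapply(seq_len(nrow(tab)), function(i) {
    fp <- fingerprint(tab$sample_id[i], wl,
                      unlist(tab[i, acols], use.names = FALSE),
                      substance = substance[i], truth_label = truth[i],
                      strict = strict)
    if (length(extra_cols))
      attr(fp, "extra") <- vapply(extra_cols, function(cc)
        as.character(tab[[cc]][i]), character(1))
    fp
  })
}

# Accepts the published table aliases for the two truth classes.
normalise_truth <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- ifelse(x %in% c("authentic", "a"), "authentic",
         ifelse(x %in% c("lqc", "lq/c", "lq-c", "counterfeit"), "lqc",
         ifelse(x %in% c("", "unknown", NA), "unknown", NA)))
  out[is.na(x)] <- "unknown"
  if (anyNA(out))
    stop(sprintf("unrecognised truth label '%s'", x[which(is.na(out))[1L]]),
         call. = FALSE)
  out
}

#' Write fingerprints to CSV
#'
#' Inverse of [read_fingerprints_csv()]: columns `sample_id`, `a<nm>` per
#' wavelength, `substance`, `truth`. Round-trips exactly.
#'
#' @param fingerprints List of [fingerprint()] objects on a shared grid.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fingerprints_csv <- function(fingerprints, path) {
  if (length(fingerprints) == 0L)
    stop("nothing to write", call. = FALSE)
  grid <- fingerprints[[1L]]$wavelengths
  for (fp in fingerprints) check_grid(fp$wavelengths, grid)
  tab <- data.frame(sample_id = vapply(fingerprints, `[[`, character(1),
                                       "sample_id"),
                    stringsAsFactors = FALSE)
  for (j in seq_along(grid))
    tab[[paste0("a", format(grid[j], trim = TRUE))]] <-
      vapply(fingerprints, function(fp) fp$absorbances[j], numeric(1))
  tab$substance <- vapply(fingerprints, `[[`, character(1), "substance")
  tab$truth <- vapply(fingerprints, `[[`, character(1), "truth_label")
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write classification results to CSV or JSON
#'
#' The CSV layout mirrors the published validation table: sample id, the
#' absorbance columns when the classified fingerprints are supplied, sorted
#' category, verdict and reason. The JSON report additionally carries the
#' per-boundary credibility indices, the full parameter set, the seed and
#' the package version. Output bytes are deterministic for fixed inputs.
#'
#' @param results List of `bsf_classification` objects.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @param counts Optional [confusion()] object (JSON only).
#' @param thresholds Optional [threshold_set()] recorded in the JSON report.
#' @param samples Optional list of the classified [fingerprint()] objects;
#'   when given, absorbance columns are included in the CSV.
#' @param seed Optional seed recorded in the JSON report.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, format = c("csv", "json"),
                          counts = NULL, thresholds = NULL, samples = NULL,
                          seed = NULL) {
  format <- match.arg(format)
  if (length(results) == 0L)
    stop("no results to write", call. = FALSE)
  tab <- results_table(results)
  tab$sorted_category <- ifelse(tab$verdict == "Authentic", "A", "LQ/C")
  if (!is.null(samples)) {
    grid <- samples[[1L]]$wavelengths
    amat <- do.call(rbind, lapply(samples, `[[`, "absorbances"))
    colnames(amat) <- paste0("a", format(grid, trim = TRUE))
    tab <- cbind(tab[, "sample_id", drop = FALSE], amat,
                 tab[, setdiff(names(tab), "sample_id")])
  }
  if (format == "csv") {
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  } else {
    report <- list(
      package = "bsfs",
      version = as.character(utils::packageVersion("bsfs")),
      parameters = if (!is.null(thresholds))
        list(q = thresholds$q, p = thresholds$p, v = thresholds$v,
             lambda = thresholds$lambda,
             weights = if (is.null(thresholds$weights)) "equal"
                       else thresholds$weights),
      seed = seed,
      confusion = if (!is.null(counts))
        list(tp = counts$tp, tn = counts$tn, fp = counts$fp, fn = counts$fn,
             n_total = counts$n_total),
      results = tab)
    report <- report[!vapply(report, is.null, logical(1))]
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(path)
}
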