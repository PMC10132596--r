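#' Candidate grid for threshold calibration
#'
#' Defines the candidate preference and veto thresholds searched during
#' calibration. Only admissible pairs with `v > p >= q_fixed` are evaluated.
#' The default grid brackets plausible uncertainty widths on the 0–2
#' absorbance scale at the resolution of typical instrument readouts.
#'
#' @param p_values Ascending candidate preference thresholds (AU).
#' @param v_values Ascending candidate veto thresholds (AU).
#' @param q_fixed Indifference threshold held fixed during the search (AU).
#' @return An object of class `calibration_grid`.
#' @export
calibration_grid <- function(p_values = seq(0, 0.20, by = 0.01),
                             v_values = seq(0.01, 0.30, by = 0.01),
                             q_fixed = 0) {
  p_values <- sort(as.numeric(p_values))
  v_values <- sort(as.numeric(v_values))
  if (length(p_values) < 1L || length(v_values) < 1L)
    stop("the calibration grid must contain candidate values", call. = FALSE)
  if (any(p_values < 0) || any(v_values < 0) || q_fixed < 0)
    stop("all candidate thresholds must be non-negative", call. = FALSE)
  structure(list(p_values = p_values, v_values = v_values, q_fixed = q_fixed),
            class = "calibration_grid")
}

#' Calibrate preference and veto thresholds on a labelled set
#'
#' Exhaustive grid search: every admissible `(p, v)` pair is evaluated by
#' classifying the labelled calibration fingerprints and counting
#' misclassifications. The pair minimising the (optionally weighted) total
#' of false positives and false negatives is returned, ties broken towards
#' the smaller veto threshold and then the smaller preference threshold —
#' the strictest admissible system. The credibility cut `lambda` is a
#' user-set operating point, not a calibrated parameter; explore it with
#' [lambda_sweep()] instead.
#'
#' @param labeled List of [fingerprint()] objects carrying truth labels;
#'   both classes must be present.
#' @param system A [category_system()].
#' @param grid A [calibration_grid()].
#' @param lambda Credibility cut level used throughout the search.
#' @param fp_weight Relative cost of a false positive (default 1, the
#'   unweighted objective fp + fn).
#' @return A list with `thresholds` (the winning [threshold_set()]),
#'   `counts` (the achieved [confusion()] optimum) and `search` (a
#'   data.frame of every admissible pair with its fp, fn and objective).
#' @examples
#' \donttest{
#' cal <- praziquantel_data("calibration_set")
#' sys <- praziquantel_data("boundaries")
#' fit <- calibrate_thresholds(cal, sys, calibration_grid(), lambda = 0.85)
#' fit$counts   # fp + fn = 0 on the calibration set
#' }
#' @export
calibrate_thresholds <- function(labeled, system, grid = calibration_grid(),
                                 lambda = 0.85, fp_weight = 1) {
  truths <- vapply(labeled, `[[`, character(1), "truth_label")
  if (!all(c("authentic", "lqc") %in% truths))
    stop("calibration requires both authentic and lqc labelled samples",
         call. = FALSE)
  pairs <- expand.grid(p = grid$p_values, v = grid$v_values,
                       KEEP.OUT.ATTRS = FALSE)
  pairs <- pairs[pairs$v > pairs$p & pairs$p >= grid$q_fixed, , drop = FALSE]
  if (nrow(pairs) == 0L)
    stop("no admissible (p, v) pair in the grid (need v > p >= q)",
         call. = FALSE)

  evaluate <- function(p, v) {
    ts <- threshold_set(q = grid$q_fixed, p = p, v = v, lambda = lambda)
    confusion(classify_batch(labeled, system, ts))
  }
  rows <- mapply(function(p, v) {
    cc <- evaluate(p, v)
    c(p = p, v = v, fp = cc$fp, fn = cc$fn,
      objective = fp_weight * cc$fp + cc$fn)
  }, pairs$p, pairs$v)
  search <- as.data.frame(t(rows))
  # tie-break: minimal objective, then smaller v, then smaller p
  ord <- order(search$objective, search$v, search$p)
  best <- search[ord[1L], ]
  thresholds <- threshold_set(q = grid$q_fixed, p = best$p, v = best$v,
                              lambda = lambda)
  list(thresholds = thresholds,
       counts = evaluate(best$p, best$v),
       search = search)
}

#' Sensitivity sweep over the credibility cut level
#'
#' Re-classifies a labelled batch at each value of `lambda` in an ascending
#' grid, holding all other parameters fixed, and reports the false positive
#' and false negative counts per value. This maps the operating bands of the
#' cut level — e.g. the low-lambda band in which borderline authentic
#' samples become indifferent to the lower boundary and flip to LQ/C.
#'
#' @param labeled List of labelled [fingerprint()] objects.
#' @param system A [category_system()].
#' @param thresholds A [threshold_set()]; its `lambda` is overridden by each
#'   grid value in turn.
#' @param lam_grid Ascending vector of cut levels in \[0, 1\]
#'   (default 0 to 1 in steps of 0.01).
#' @return A data.frame with columns `lam`, `fp`, `fn`.
#' @export
lambda_sweep <- function(labeled, system, thresholds,
                         lam_grid = seq(0, 1, by = 0.01)) {
  if (length(lam_grid) < 1L)
    stop("lam_grid must be non-empty", call. = FALSE)
  if (is.unsorted(lam_grid, strictly = TRUE))
    stop("lam_grid must be strictly ascending", call. = FALSE)
  if (any(lam_grid < 0) || any(lam_grid > 1))
    stop("lam_grid values must lie in [0, 1]", call. = FALSE)
  rows <- lapply(lam_grid, function(lam) {
    ts <- thresholds
    ts$lambda <- lam
    cc <- suppressWarnings(confusion(classify_batch(labeled, system, ts)))
    data.frame(lam = lam, fp = cc$fp, fn = cc$fn)
  })
  do.call(rbind, rows)
}

#' Group a lambda sweep into constant-error bands
#'
#' Summarises a [lambda_sweep()] table into maximal runs of consecutive grid
#' values sharing the same (fp, fn), reported as closed intervals of the
#' evaluated grid.
#'
#' @param rows A data.frame with ascending `lam` and integer `fp`, `fn`
#'   (as returned by [lambda_sweep()]).
#' @return A data.frame with columns `lam_from`, `lam_to`, `fp`, `fn`, one
#'   row per band.
#' @export
find_breakpoints <- function(rows) {
  if (is.null(rows) || nrow(rows) == 0L)
    stop("empty sweep table", call. = FALSE)
  key <- paste(rows$fp, rows$fn)
  run <- cumsum(c(TRUE, key[-1L] != key[-length(key)]))
  out <- lapply(split(seq_len(nrow(rows)), run), function(i) {
    data.frame(lam_from = rows$lam[i[1L]],
               lam_to = rows$lam[i[length(i)]],
               fp = rows$fp[i[1L]],
               fn = rows$fn[i[1L]])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
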