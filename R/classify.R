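#' Learn CAT-A boundaries from replicate authentic fingerprints
#'
#' The authentic band is defined empirically: the lower boundary at each
#' wavelength is the minimum absorbance observed over the replicate
#' preparations, and the upper boundary the maximum. Replication is meant to
#' capture the preparation variability of field samples, not to be a
#' statistically significant sample, so raw minima and maxima are used with
#' no trimming. An optional widening fraction applies the intrinsic-range
#' rule: lower boundary a fraction below the observed minimum, upper a
#' fraction above the observed maximum (capped at the saturation value 2).
#'
#' @param replicates List of [fingerprint()] objects on a shared wavelength
#'   grid; at least 2 are required for non-degenerate boundaries (fewer than
#'   5 triggers a warning).
#' @param widen_fraction Non-negative fraction by which to widen the band
#'   (e.g. 0.10 for the 10\% intrinsic-range rule). Default 0.
#' @return A [category_system()].
#' @examples
#' reps <- list(fingerprint("r1", c(240, 250), c(1.0, 0.6)),
#'              fingerprint("r2", c(240, 250), c(0.9, 0.7)),
#'              fingerprint("r3", c(240, 250), c(1.1, 0.65)))
#' build_category_system(reps)                       # band [0.9,1.1] x [0.6,0.7]
#' build_category_system(reps, widen_fraction = 0.1)
#' @export
build_category_system <- function(replicates, widen_fraction = 0) {
  if (length(replicates) < 1L)
    stop("at least one replicate fingerprint is required", call. = FALSE)
  if (!all(vapply(replicates, inherits, logical(1), "spectral_fingerprint")))
    stop("replicates must be spectral_fingerprint objects", call. = FALSE)
  if (widen_fraction < 0)
    stop("widen_fraction must be non-negative", call. = FALSE)
  grid <- replicates[[1L]]$wavelengths
  for (r in replicates) check_grid(r$wavelengths, grid, "replicate")
  if (length(replicates) < 5L)
    warning(sprintf(
      "only %d replicate(s): boundaries may understate preparation variability",
      length(replicates)), call. = FALSE)
  mat <- do.call(rbind, lapply(replicates, `[[`, "absorbances"))
  lower <- apply(mat, 2L, min)
  upper <- apply(mat, 2L, max)
  lower <- lower * (1 - widen_fraction)
  upper <- pmin(upper * (1 + widen_fraction), 2)
  if (any(lower >= upper))
    stop(paste("degenerate boundaries: lower >= upper at some wavelength;",
               "supply more variable replicates or a positive widen_fraction"),
         call. = FALSE)
  category_system(grid, lower, upper)
}

# Assignment procedures from precomputed credibility pairs; the exported
# assign_* wrappers in outranking.R recompute the pairs themselves.
assign_pessimistic_sigma <- function(s_lower, s_upper, lambda) {
  if (s_upper[["sigma_ab"]] >= lambda) "CAT-C"
  else if (s_lower[["sigma_ab"]] >= lambda) "CAT-A"
  else "CAT-B"
}

assign_optimistic_sigma <- function(s_lower, s_upper, lambda) {
  strict <- function(s) s[["sigma_ba"]] >= lambda && s[["sigma_ab"]] < lambda
  if (strict(s_lower)) "CAT-B"
  else if (strict(s_upper)) "CAT-A"
  else "CAT-C"
}

#' Classify a fingerprint as Authentic or LQ/C
#'
#' Runs the full two-procedure sorting against both CAT-A boundaries and
#' maps the outcome to a verdict. A sample is `Authentic` only when both the
#' pessimistic and the optimistic procedure place it in CAT-A and it is not
#' indifferent to either boundary; every other outcome — assignment to
#' CAT-B or CAT-C, disagreement between the procedures (incomparability),
#' or indifference to a boundary — is `LQC`. The reason field records which
#' of these applied, with incomparability reported whenever the procedures
#' disagree and indifference taking precedence over a clean CAT-A.
#'
#' @param sample A [fingerprint()] object.
#' @param system A [category_system()].
#' @param thresholds A [threshold_set()].
#' @return An object of class `bsf_classification`: a list with
#'   `sample_id`, `pessimistic`, `optimistic`, `relation_lower`,
#'   `relation_upper`, `sigma` (named vector of the four credibility
#'   indices), `verdict` (`"Authentic"` or `"LQC"`) and `reason` (one of
#'   `"in_cat_a"`, `"cat_b"`, `"cat_c"`, `"indifferent_boundary"`,
#'   `"incomparable"`).
#' @examples
#' sys <- praziquantel_data("boundaries")
#' ts  <- praziquantel_data("thresholds")
#' classify(fingerprint("s3", sys$wavelengths, c(0.907, 0.584, 0.56, 0.478)),
#'          sys, ts)
#' @export
classify <- function(sample, system, thresholds) {
  check_grid(sample$wavelengths, system$wavelengths)
  lam <- thresholds$lambda
  s_lo <- credibility_pair(sample, system$lower_boundary, thresholds)
  s_up <- credibility_pair(sample, system$upper_boundary, thresholds)
  rel_lo <- outranking_relation(s_lo[["sigma_ab"]], s_lo[["sigma_ba"]], lam)
  rel_up <- outranking_relation(s_up[["sigma_ab"]], s_up[["sigma_ba"]], lam)
  pess <- assign_pessimistic_sigma(s_lo, s_up, lam)
  opti <- assign_optimistic_sigma(s_lo, s_up, lam)

  indifferent <- rel_lo == "indifferent" || rel_up == "indifferent"
  if (pess != opti) {
    verdict <- "LQC"; reason <- "incomparable"
  } else if (pess == "CAT-A") {
    if (indifferent) { verdict <- "LQC"; reason <- "indifferent_boundary" }
    else             { verdict <- "Authentic"; reason <- "in_cat_a" }
  } else if (indifferent) {
    verdict <- "LQC"; reason <- "indifferent_boundary"
  } else {
    verdict <- "LQC"; reason <- if (pess == "CAT-B") "cat_b" else "cat_c"
  }

  structure(
    list(sample_id = sample$sample_id,
         substance = sample$substance,
         truth_label = sample$truth_label,
         pessimistic = pess,
         optimistic = opti,
         relation_lower = rel_lo,
         relation_upper = rel_up,
         sigma = c(sigma_ab_lower = s_lo[["sigma_ab"]],
                   sigma_ba_lower = s_lo[["sigma_ba"]],
                   sigma_ab_upper = s_up[["sigma_ab"]],
                   sigma_ba_upper = s_up[["sigma_ba"]]),
         verdict = verdict,
         reason = reason),
    class = "bsf_classification")
}

#' @export
print.bsf_classification <- function(x, ...) {
  cat(sprintf("<bsf_classification> %s: %s (%s)\n",
              x$sample_id, x$verdict, x$reason))
  cat(sprintf("  pessimistic %s | optimistic %s | lower %s | upper %s\n",
              x$pessimistic, x$optimistic, x$relation_lower, x$relation_upper))
  invisible(x)
}

#' Classify a batch of fingerprints
#'
#' Order-preserving, deterministic application of [classify()] to every
#' fingerprint in the batch.
#'
#' @param samples Non-empty list of [fingerprint()] objects on a shared grid.
#' @inheritParams classify
#' @return A list of `bsf_classification` objects, one per sample, in input
#'   order. Convert to a table with [results_table()].
#' @export
classify_batch <- function(samples, system, thresholds) {
  if (length(samples) < 1L)
    stop("classify_batch requires at least one sample", call. = FALSE)
  lapply(samples, function(s) {
    tryCatch(classify(s, system, thresholds),
             error = function(e) stop(sprintf("sample '%s': %s",
                                              s$sample_id, conditionMessage(e)),
                                      call. = FALSE))
  })
}

#' Tabulate classification results
#'
#' @param results List of `bsf_classification` objects.
#' @return A data.frame with one row per sample: id, substance, truth label,
#'   both category assignments, boundary relations, the four credibility
#'   indices, verdict and reason.
#' @export
results_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(sample_id = r$sample_id,
               substance = r$substance,
               truth = r$truth_label,
               pessimistic = r$pessimistic,
               optimistic = r$optimistic,
               relation_lower = r$relation_lower,
               relation_upper = r$relation_upper,
               sigma_ab_lower = r$sigma[["sigma_ab_lower"]],
               sigma_ba_lower = r$sigma[["sigma_ba_lower"]],
               sigma_ab_upper = r$sigma[["sigma_ab_upper"]],
               sigma_ba_upper = r$sigma[["sigma_ba_upper"]],
               verdict = r$verdict,
               reason = r$reason,
               stringsAsFactors = FALSE)
  }))
}

#' Confusion counts for a labelled batch
#'
#' Tallies the verdicts of classified fingerprints against ground truth.
#' `Authentic` is the positive class: a false positive is a factually LQ/C
#' sample given an Authentic verdict; a false negative a factually authentic
#' sample given an LQC verdict. Samples with unknown truth are excluded.
#'
#' @param results List of `bsf_classification` objects.
#' @param truth Optional character vector of truth labels (`"authentic"` /
#'   `"lqc"`), either unnamed and aligned with `results` or named by
#'   sample id; defaults to the truth labels carried by the fingerprints.
#' @return An object of class `confusion_counts` with fields `tp`, `tn`,
#'   `fp`, `fn` and `n_total`.
#' @export
confusion <- function(results, truth = NULL) {
  verdicts <- vapply(results, `[[`, character(1), "verdict")
  ids <- vapply(results, `[[`, character(1), "sample_id")
  if (is.null(truth)) {
    truth <- vapply(results, `[[`, character(1), "truth_label")
  } else {
    truth <- as.character(truth)
    if (!is.null(names(truth))) {
      if (!all(ids %in% names(truth)))
        stop("truth labels missing for some sample ids", call. = FALSE)
      truth <- unname(truth[ids])
    } else if (length(truth) != length(results)) {
      stop("truth must align with results (same length or named by id)",
           call. = FALSE)
    }
  }
  keep <- truth %in% c("authentic", "lqc")
  verdicts <- verdicts[keep]; truth <- truth[keep]
  structure(
    list(tp = sum(truth == "authentic" & verdicts == "Authentic"),
         tn = sum(truth == "lqc" & verdicts == "LQC"),
         fp = sum(truth == "lqc" & verdicts == "Authentic"),
         fn = sum(truth == "authentic" & verdicts == "LQC"),
         n_total = sum(keep)),
    class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> n = %d: TP %d, TN %d, FP %d, FN %d\n",
              x$n_total, x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}
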