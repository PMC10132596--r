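#' Construct a spectral fingerprint
#'
#' A spectral fingerprint is one sample's UV absorbance vector over an ordered
#' wavelength grid: the numeric signature against which authenticity is
#' judged. Absorbance is dimensionless optical density on the saturating
#' instrument scale from 0 (transparent solution) to 2 (opaque solution).
#'
#' @param sample_id Character scalar identifying the sample.
#' @param wavelengths Strictly increasing numeric vector of wavelengths (nm).
#' @param absorbances Numeric vector of absorbance values (AU), one per
#'   wavelength, each in \[0, 2\].
#' @param substance Optional character scalar naming the (claimed or factual)
#'   substance.
#' @param truth_label Optional ground-truth class, one of `"authentic"`,
#'   `"lqc"` or `"unknown"` (default).
#' @param strict If `TRUE` (default) absorbances outside \[0, 2\] are an
#'   error; if `FALSE` they are clipped to the scale with a warning, which
#'   mirrors instrument saturation.
#'
#' @return An object of class `spectral_fingerprint`.
#' @examples
#' fingerprint("A", c(240, 250, 260, 270), c(1.0, 0.8, 0.6, 0.4))
#' @export
fingerprint <- function(sample_id, wavelengths, absorbances,
                        substance = NA_character_,
                        truth_label = c("unknown", "authentic", "lqc"),
                        strict = TRUE) {
  truth_label <- match.arg(truth_label)
  wavelengths <- as.numeric(wavelengths)
  absorbances <- as.numeric(absorbances)
  if (length(wavelengths) < 1L)
    stop("a fingerprint needs at least one wavelength", call. = FALSE)
  if (length(wavelengths) != length(absorbances))
    stop("wavelengths and absorbances must have equal length", call. = FALSE)
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  if (anyNA(absorbances))
    stop("absorbances must not contain NA", call. = FALSE)
  out_of_range <- absorbances < 0 | absorbances > 2
  if (any(out_of_range)) {
    if (strict) {
      stop(sprintf(
        "absorbance out of [0, 2] for sample '%s' at %s nm",
        sample_id, paste(wavelengths[out_of_range], collapse = ", ")),
        call. = FALSE)
    }
    warning(sprintf("clipping %d out-of-range absorbance value(s) for sample '%s'",
                    sum(out_of_range), sample_id), call. = FALSE)
    absorbances <- pmin(pmax(absorbances, 0), 2)
  }
  structure(
    list(sample_id = as.character(sample_id),
         wavelengths = wavelengths,
         absorbances = absorbances,
         substance = as.character(substance),
         truth_label = truth_label),
    class = "spectral_fingerprint")
}

#' @export
print.spectral_fingerprint <- function(x, ...) {
  cat(sprintf("<spectral_fingerprint> %s", x$sample_id))
  if (!is.na(x$substance)) cat(sprintf(" (%s)", x$substance))
  if (x$truth_label != "unknown") cat(sprintf(" [truth: %s]", x$truth_label))
  cat("\n")
  print(stats::setNames(x$absorbances, paste0(x$wavelengths, " nm")))
  invisible(x)
}

#' Construct a category system
#'
#' Two boundary profiles over a shared wavelength grid delimit three ordered
#' categories on the absorbance axis: CAT-B (below the authentic band),
#' CAT-A (the authentic band) and CAT-C (above it). The lower profile is the
#' boundary between CAT-B and CAT-A; the upper profile between CAT-A and
#' CAT-C.
#'
#' @param wavelengths Strictly increasing numeric vector (nm).
#' @param lower_boundary,upper_boundary Numeric absorbance vectors (AU), one
#'   value per wavelength, each in \[0, 2\], with
#'   `lower_boundary < upper_boundary` elementwise.
#'
#' @return An object of class `category_system`.
#' @examples
#' category_system(c(240, 250, 260, 270),
#'                 lower_boundary = c(0.71, 0.44, 0.46, 0.40),
#'                 upper_boundary = c(1.22, 0.79, 0.80, 0.68))
#' @seealso [build_category_system()] to learn the boundaries from replicates.
#' @export
category_system <- function(wavelengths, lower_boundary, upper_boundary) {
  wavelengths <- as.numeric(wavelengths)
  lower_boundary <- as.numeric(lower_boundary)
  upper_boundary <- as.numeric(upper_boundary)
  k <- length(wavelengths)
  if (k < 1L || any(diff(wavelengths) <= 0))
    stop("wavelengths must be a strictly increasing vector", call. = FALSE)
  if (length(lower_boundary) != k || length(upper_boundary) != k)
    stop("boundary vectors must match the wavelength grid", call. = FALSE)
  if (any(lower_boundary < 0) || any(upper_boundary > 2))
    stop("boundaries must lie within the [0, 2] absorbance scale", call. = FALSE)
  if (any(lower_boundary >= upper_boundary))
    stop("lower_boundary must be strictly below upper_boundary at every wavelength",
         call. = FALSE)
  structure(
    list(wavelengths = wavelengths,
         lower_boundary = lower_boundary,
         upper_boundary = upper_boundary),
    class = "category_system")
}

#' @export
print.category_system <- function(x, ...) {
  cat("<category_system> CAT-B < CAT-A < CAT-C\n")
  print(data.frame(wavelength_nm = x$wavelengths,
                   lower = x$lower_boundary,
                   upper = x$upper_boundary))
  invisible(x)
}

#' Construct an outranking threshold set
#'
#' Uncertainty parameters of the ELECTRE TRI-B comparison, applied as scalars
#' to every criterion (wavelength) and both boundary profiles: the
#' indifference threshold `q` (deficits up to `q` do not count against a
#' sample), the preference threshold `p` (deficits beyond `p` give zero
#' per-criterion support) and the veto threshold `v` (a single deficit of
#' `v` or more annihilates the credibility of an outranking claim). `lambda`
#' is the credibility cut level: the outranking relation holds when the
#' credibility index reaches it.
#'
#' @param q Indifference threshold (AU), `0 <= q <= p`. Default 0.
#' @param p Preference threshold (AU), `p < v`. Default 0.05.
#' @param v Veto threshold (AU), `v > p`. Default 0.10.
#' @param lambda Credibility cut level in \[0, 1\]. Values at or below 0.5
#'   are accepted with a warning, since outranking is only meaningful above a
#'   majority of the weighted evidence. Default 0.85.
#' @param weights Optional positive per-criterion weights summing to 1; if
#'   `NULL` (default), equal weights `1/k` are used for a grid of `k`
#'   wavelengths.
#'
#' @return An object of class `threshold_set`.
#' @examples
#' threshold_set()                      # q = 0, p = 0.05, v = 0.10, lambda = 0.85
#' threshold_set(p = 0.02, v = 0.2, lambda = 0.9)
#' @export
threshold_set <- function(q = 0, p = 0.05, v = 0.10, lambda = 0.85,
                          weights = NULL) {
  if (!is.numeric(q) || !is.numeric(p) || !is.numeric(v) ||
      length(q) != 1L || length(p) != 1L || length(v) != 1L)
    stop("q, p and v must be numeric scalars", call. = FALSE)
  if (q < 0 || p < q)
    stop("thresholds must satisfy 0 <= q <= p", call. = FALSE)
  if (v <= p)
    stop("veto threshold v must exceed the preference threshold p", call. = FALSE)
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0 || lambda > 1)
    stop("lambda must be a single value in [0, 1]", call. = FALSE)
  if (lambda <= 0.5)
    warning("lambda <= 0.5: outranking is only meaningful above 0.5",
            call. = FALSE)
  if (!is.null(weights)) {
    weights <- as.numeric(weights)
    if (any(weights <= 0))
      stop("weights must be positive", call. = FALSE)
    if (abs(sum(weights) - 1) > 1e-8)
      stop("weights must sum to 1", call. = FALSE)
  }
  structure(
    list(q = q, p = p, v = v, lambda = lambda, weights = weights),
    class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("<threshold_set> q = %g, p = %g, v = %g, lambda = %g\n",
              x$q, x$p, x$v, x$lambda))
  if (is.null(x$weights)) cat("  weights: equal (1/k)\n")
  else cat("  weights:", paste(signif(x$weights, 4), collapse = " "), "\n")
  invisible(x)
}

# Resolve the weights of a threshold set against a grid of k criteria.
resolve_weights <- function(thresholds, k) {
  w <- thresholds$weights
  if (is.null(w)) return(rep(1 / k, k))
  if (length(w) != k)
    stop(sprintf("threshold set has %d weights but the grid has %d wavelengths",
                 length(w), k), call. = FALSE)
  w
}

# Shared grid check for sample-vs-system operations.
check_grid <- function(wavelengths, reference_wavelengths, what = "sample") {
  if (length(wavelengths) != length(reference_wavelengths) ||
      any(wavelengths != reference_wavelengths))
    stop(sprintf("%s wavelength grid does not match the category system grid",
                 what), call. = FALSE)
  invisible(TRUE)
}
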