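#' Published Praziquantel reference data
#'
#' Returns the shipped Praziquantel reference tables as typed objects:
#' the CAT-A boundary profiles learned from 15 replicate authentic
#' preparations, the calibrated uncertainty thresholds, the 25-sample
#' labelled calibration set (4 authentic Praziquantel, 21 proxy low-quality
#' or counterfeit substances) and the 50-sample blinded validation set
#' (4 authentic, 46 LQ/C). Values are exactly as published; mixtures of
#' Praziquantel with another medication carry the truth label `lqc`.
#'
#' @param name One of `"boundaries"`, `"thresholds"`, `"calibration_set"`,
#'   `"validation_set"`.
#' @return `boundaries`: a [category_system()] on the 240/250/260/270 nm
#'   grid (the published mean profile is attached as attribute `mean`).
#'   `thresholds`: a [threshold_set()] with q = 0, p = 0.05, v = 0.10,
#'   lambda = 0.85 and equal weights. `calibration_set` /
#'   `validation_set`: lists of labelled [fingerprint()] objects (the
#'   validation set carries the published sorted category as attribute
#'   `sorted_category` on each fingerprint).
#' @examples
#' praziquantel_data("boundaries")
#' praziquantel_data("thresholds")
#' length(praziquantel_data("validation_set"))  # 50
#' @export
praziquantel_data <- function(name = c("boundaries", "thresholds",
                                       "calibration_set", "validation_set")) {
  name <- match.arg(name)
  extfile <- function(f) system.file("extdata", f, package = "bsfs",
                                     mustWork = TRUE)
  switch(name,
    boundaries = {
      tab <- utils::read.csv(extfile("praziquantel_boundaries.csv"))
      sys <- category_system(tab$wavelength, tab$lower, tab$upper)
      attr(sys, "mean") <- tab$mean
      sys
    },
    thresholds = threshold_set(q = 0, p = 0.05, v = 0.10, lambda = 0.85),
    calibration_set = read_fingerprints_csv(
      extfile("praziquantel_calibration.csv")),
    validation_set = read_fingerprints_csv(
      extfile("praziquantel_validation.csv"))
  )
}

#' Specification of a synthetic authentic-fingerprint generator
#'
#' Describes the stochastic model used to emulate replicate authentic
#' preparations: preparation variability perturbs a mean absorbance profile
#' wavelength-by-wavelength, either uniformly within a half-range or with
#' truncated Gaussian noise, and all draws are clipped to the saturating
#' \[0, 2\] instrument scale.
#'
#' @param wavelengths Strictly increasing grid (nm).
#' @param mean_profile Mean absorbance profile (AU), within \[0, 2\].
#' @param spread Per-wavelength half-range (uniform model) or standard
#'   deviation (truncated-normal model), in AU; recycled if scalar.
#' @param noise_model `"uniform_range"` or `"truncated_normal"`.
#' @param seed Integer seed; generation is a pure function of
#'   (spec, n, seed).
#' @return An object of class `synthetic_spec`.
#' @examples
#' synthetic_spec(c(240, 250, 260, 270), c(0.97, 0.62, 0.63, 0.54),
#'                spread = c(0.26, 0.18, 0.17, 0.14))
#' @export
synthetic_spec <- function(wavelengths, mean_profile, spread,
                           noise_model = c("uniform_range", "truncated_normal"),
                           seed = 1L) {
  noise_model <- match.arg(noise_model)
  wavelengths <- as.numeric(wavelengths)
  mean_profile <- as.numeric(mean_profile)
  spread <- rep_len(as.numeric(spread), length(wavelengths))
  if (length(mean_profile) != length(wavelengths))
    stop("mean_profile must match the wavelength grid", call. = FALSE)
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  if (any(mean_profile < 0) || any(mean_profile > 2))
    stop("mean_profile must lie within [0, 2]", call. = FALSE)
  if (any(spread < 0))
    stop("spread must be non-negative", call. = FALSE)
  structure(list(wavelengths = wavelengths, mean_profile = mean_profile,
                 spread = spread, noise_model = noise_model,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Run code under a given seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Generate synthetic replicate authentic fingerprints
#'
#' Draws `n` fingerprints around the spec's mean profile under its noise
#' model, emulating the spread of absorbance readings produced by simplified
#' field preparation (crush, dissolve, gauze-filter, dilute). All values are
#' clipped to \[0, 2\] and the fingerprints are labelled `authentic`.
#'
#' @param spec A [synthetic_spec()].
#' @param n Number of fingerprints, `n >= 1`.
#' @return List of `n` [fingerprint()] objects.
#' @examples
#' sp <- synthetic_spec(c(240, 250), c(1.0, 0.6), spread = 0.1, seed = 7)
#' reps <- generate_authentic(sp, 15)
#' @export
generate_authentic <- function(spec, n) {
  if (!inherits(spec, "synthetic_spec"))
    stop("spec must be a synthetic_spec", call. = FALSE)
  if (n < 1L) stop("n must be at least 1", call. = FALSE)
  k <- length(spec$wavelengths)
  draws <- with_seed(spec$seed, {
    switch(spec$noise_model,
      uniform_range = matrix(
        stats::runif(n * k,
                     rep(spec$mean_profile - spec$spread, each = n),
                     rep(spec$mean_profile + spec$spread, each = n)),
        nrow = n),
      truncated_normal = {
        m <- matrix(stats::rnorm(n * k,
                                 rep(spec$mean_profile, each = n),
                                 rep(spec$spread, each = n)),
                    nrow = n)
        # resample outside mean +/- 3 sd to keep draws near the profile
        lo <- rep(spec$mean_profile - 3 * spec$spread, each = n)
        hi <- rep(spec$mean_profile + 3 * spec$spread, each = n)
        bad <- m < lo | m > hi
        while (any(bad)) {
          m[bad] <- stats::rnorm(sum(bad),
                                 rep(spec$mean_profile, each = n)[bad],
                                 rep(spec$spread, each = n)[bad])
          bad <- m < lo | m > hi
        }
        m
      })
  })
  draws <- pmin(pmax(draws, 0), 2)
  lapply(seq_len(n), function(i)
    fingerprint(sprintf("synthetic_authentic_%03d", i),
                spec$wavelengths, draws[i, ],
                substance = "synthetic authentic",
                truth_label = "authentic"))
}

#' Generate synthetic contaminant fingerprints
#'
#' Draws smooth random absorbance curves standing in for the UV signatures
#' of substances other than the medication of interest: random mixtures of
#' monotone exponential decays (salt-like, sugar-like profiles), saturating
#' near-opaque curves, and single Gaussian peaks placed on the grid. Curves
#' are clipped to \[0, 2\] and labelled `lqc`. The family is synthetic — it
#' spans the qualitative shapes of common adulterants, not the physics of
#' any particular chromophore.
#'
#' @param wavelengths Strictly increasing grid (nm).
#' @param n Number of fingerprints, `n >= 1`.
#' @param seed Integer seed.
#' @return List of `n` [fingerprint()] objects labelled `lqc`.
#' @examples
#' generate_contaminant(c(240, 250, 260, 270), n = 3, seed = 11)
#' @export
generate_contaminant <- function(wavelengths, n, seed = 1L) {
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) < 1L || any(diff(wavelengths) <= 0))
    stop("wavelengths must be a strictly increasing vector", call. = FALSE)
  if (n < 1L) stop("n must be at least 1", call. = FALSE)
  span <- max(diff(range(wavelengths)), 1)
  x <- (wavelengths - min(wavelengths)) / span
  curves <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      kind <- sample(c("decay", "peak", "flat_low", "saturating", "mix"), 1L)
      decay <- function()
        stats::runif(1, 0.2, 2) * exp(-stats::runif(1, 0.5, 6) * x)
      peak <- function() {
        centre <- stats::runif(1, -0.2, 1.2)
        width <- stats::runif(1, 0.1, 0.6)
        stats::runif(1, 0.05, 0.3) +
          stats::runif(1, 0.4, 2) * exp(-((x - centre) / width)^2 / 2)
      }
      y <- switch(kind,
        decay = decay(),
        peak = peak(),
        flat_low = stats::runif(1, 0.05, 0.45) * (1 - 0.3 * x),
        saturating = pmin(stats::runif(1, 1.6, 2.4) * (1 + 0.2 * x), 2.4),
        mix = {
          a <- stats::runif(1)
          a * decay() + (1 - a) * peak()
        })
      pmin(pmax(y, 0), 2)
    })
  })
  lapply(seq_len(n), function(i)
    fingerprint(sprintf("synthetic_contaminant_%03d", i),
                wavelengths, curves[[i]],
                substance = "synthetic contaminant",
                truth_label = "lqc"))
}

#' Mix an authentic fingerprint with a contaminant
#'
#' Elementwise convex combination of two fingerprints on a shared grid,
#' emulating a low-quality product adulterated with another substance (a
#' proxy-LQ sample). Any positive contaminant fraction yields the truth
#' label `lqc`.
#'
#' @param base,contaminant [fingerprint()] objects on the same grid.
#' @param fraction Contaminant fraction in \[0, 1\].
#' @return A [fingerprint()] object.
#' @export
generate_mixture <- function(base, contaminant, fraction) {
  check_grid(base$wavelengths, contaminant$wavelengths, "mixture component")
  if (fraction < 0 || fraction > 1)
    stop("fraction must lie in [0, 1]", call. = FALSE)
  fingerprint(sprintf("%s+%s@%.2f", base$sample_id, contaminant$sample_id,
                      fraction),
              base$wavelengths,
              (1 - fraction) * base$absorbances +
                fraction * contaminant$absorbances,
              substance = sprintf("%s / %s mixture", base$substance,
                                  contaminant$substance),
              truth_label = if (fraction > 0) "lqc" else base$truth_label)
}
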