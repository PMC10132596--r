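#' Per-criterion concordance with an outranking claim
#'
#' Degree, between 0 and 1, to which an alternative with performance `value`
#' is at least as good as a reference with performance `reference` on one
#' maximising criterion. Full support (1) when the deficit is at most the
#' indifference threshold `q`; no support (0) when it reaches the preference
#' threshold `p`; linear in between. With `p == q` the score degenerates to a
#' step function (1 iff `value >= reference - q`), the limit of the
#' interpolation.
#'
#' @param value Performance of the alternative (absorbance, AU). Vectorised.
#' @param reference Performance of the reference profile (AU). Vectorised.
#' @param q Indifference threshold (AU), `0 <= q <= p`.
#' @param p Preference threshold (AU).
#' @return Concordance score(s) in \[0, 1\], nondecreasing in `value`.
#' @examples
#' partial_concordance(0.714, 0.71, q = 0, p = 0.05)  # 1
#' partial_concordance(0.71, 0.714, q = 0, p = 0.05)  # 0.92
#' @export
partial_concordance <- function(value, reference, q, p) {
  if (q < 0 || p < q)
    stop("thresholds must satisfy 0 <= q <= p", call. = FALSE)
  deficit <- reference - value
  out <- ifelse(deficit <= q, 1,
         ifelse(deficit >= p, 0, (p - deficit) / (p - q)))
  # p == q: the ifelse chain already yields the step function (deficit <= q
  # wins ties at the boundary), so no special case is needed.
  out
}

#' Per-criterion discordance against an outranking claim
#'
#' Degree, between 0 and 1, of opposition to the claim that the alternative
#' is at least as good as the reference: zero while the deficit is within the
#' preference threshold `p`, one (a veto) once it reaches the veto threshold
#' `v`, linear in between. A full veto on any single criterion annihilates
#' the credibility of the claim regardless of the other criteria.
#'
#' @inheritParams partial_concordance
#' @param v Veto threshold (AU), `v > p`.
#' @return Discordance score(s) in \[0, 1\], nonincreasing in `value`.
#' @examples
#' partial_discordance(0.324, 0.44, p = 0.05, v = 0.10)  # 1 (veto)
#' partial_discordance(0.38, 0.44, p = 0.05, v = 0.10)   # 0.2
#' @export
partial_discordance <- function(value, reference, p, v) {
  if (v <= p)
    stop("veto threshold v must exceed the preference threshold p", call. = FALSE)
  deficit <- reference - value
  ifelse(deficit <= p, 0,
  ifelse(deficit >= v, 1, (deficit - p) / (v - p)))
}

#' Global concordance
#'
#' Weighted aggregate of the per-criterion concordance scores.
#'
#' @param partials Numeric vector of per-criterion concordances in \[0, 1\].
#' @param weights Positive weights summing to 1, one per criterion.
#' @return A single concordance score in \[0, 1\].
#' @export
global_concordance <- function(partials, weights) {
  if (length(partials) != length(weights))
    stop("partials and weights must have equal length", call. = FALSE)
  if (any(weights <= 0) || abs(sum(weights) - 1) > 1e-8)
    stop("weights must be positive and sum to 1", call. = FALSE)
  # clamp: normalised weights can sum to 1 +/- a few ulp
  min(max(sum(partials * weights), 0), 1)
}

#' Credibility of an outranking claim
#'
#' The global concordance discounted by strong discordances: each criterion
#' whose discordance exceeds the global concordance contributes a factor
#' `(1 - d_j) / (1 - C)`. A discordance of exactly 1 on any criterion (a
#' veto) forces the credibility to 0; when no discordance exceeds the global
#' concordance the credibility equals it. The credibility never exceeds the
#' global concordance.
#'
#' @param global_c Global concordance in \[0, 1\].
#' @param discordances Numeric vector of per-criterion discordances in \[0, 1\].
#' @return Credibility index in \[0, 1\].
#' @examples
#' credibility(0.8, c(0, 0, 0, 0))        # 0.8
#' credibility(0.75, c(1, 0, 0, 0))       # 0 (veto)
#' credibility(0.5, c(0.32, 0.84, 0, 0))  # 0.5 * (0.68/0.5) * (0.16/0.5)
#' @export
credibility <- function(global_c, discordances) {
  if (any(discordances >= 1)) return(0)
  strong <- discordances > global_c
  if (!any(strong)) return(min(max(global_c, 0), 1))
  min(max(global_c * prod((1 - discordances[strong]) / (1 - global_c)), 0), 1)
}

#' Credibility indices for a sample/boundary pair
#'
#' Computes the credibility that the sample outranks the boundary profile
#' (`sigma_ab`) and that the boundary outranks the sample (`sigma_ba`), each
#' via per-criterion concordance and discordance, weighted aggregation, and
#' discordance discounting. The two directions correspond to the "is the
#' sample at least as good as the boundary?" and "is the boundary at least
#' as good as the sample?" questions of the two-sweep sorting procedure.
#'
#' @param sample A [fingerprint()] object, or a bare numeric absorbance
#'   vector on the boundary's grid.
#' @param boundary Numeric absorbance vector of the boundary profile (AU).
#' @param thresholds A [threshold_set()].
#' @param wavelengths Optional grid to check `sample` against when it is a
#'   fingerprint object.
#' @return Named numeric vector `c(sigma_ab = ..., sigma_ba = ...)`.
#' @examples
#' ts <- threshold_set()
#' credibility_pair(c(0.714, 0.45, 0.474, 0.412),
#'                  c(0.71, 0.44, 0.46, 0.40), ts)
#' @export
credibility_pair <- function(sample, boundary, thresholds, wavelengths = NULL) {
  if (inherits(sample, "spectral_fingerprint")) {
    if (!is.null(wavelengths))
      check_grid(sample$wavelengths, wavelengths)
    values <- sample$absorbances
  } else {
    values <- as.numeric(sample)
  }
  if (length(values) != length(boundary))
    stop("sample and boundary are not on the same wavelength grid", call. = FALSE)
  w <- resolve_weights(thresholds, length(boundary))
  q <- thresholds$q; p <- thresholds$p; v <- thresholds$v

  sigma_one <- function(a, b) {
    C <- global_concordance(partial_concordance(a, b, q, p), w)
    credibility(C, partial_discordance(a, b, p, v))
  }
  c(sigma_ab = sigma_one(values, boundary),
    sigma_ba = sigma_one(boundary, values))
}

#' Outranking relation between a sample and a boundary
#'
#' Maps the two credibility indices to the four-way relation at cut level
#' `lambda`: the sample outranks the boundary iff `sigma_ab >= lambda`
#' (non-strict), and symmetrically for the boundary. Both directions holding
#' is indifference; neither is incomparability.
#'
#' @param sigma_ab Credibility that the sample outranks the boundary.
#' @param sigma_ba Credibility that the boundary outranks the sample.
#' @param lambda Credibility cut level in \[0, 1\].
#' @return One of `"sample_preferred"`, `"boundary_preferred"`,
#'   `"indifferent"`, `"incomparable"`.
#' @examples
#' outranking_relation(1.0, 0.80, lambda = 0.85)  # sample_preferred
#' outranking_relation(1.0, 0.80, lambda = 0.75)  # indifferent
#' @export
outranking_relation <- function(sigma_ab, sigma_ba, lambda) {
  ab <- sigma_ab >= lambda
  ba <- sigma_ba >= lambda
  if (ab && ba) "indifferent"
  else if (ab) "sample_preferred"
  else if (ba) "boundary_preferred"
  else "incomparable"
}

#' Pessimistic category assignment
#'
#' The descending (pessimistic, conjunctive) assignment procedure of
#' ELECTRE TRI-B specialised to two boundary profiles: the sample is placed
#' in the highest category whose lower boundary it outranks — CAT-C if it
#' outranks the upper boundary, else CAT-A if it outranks the lower boundary,
#' else CAT-B.
#'
#' @param sample A [fingerprint()] object.
#' @param system A [category_system()].
#' @param thresholds A [threshold_set()].
#' @return `"CAT-B"`, `"CAT-A"` or `"CAT-C"`.
#' @seealso [assign_optimistic()], [classify()]
#' @export
assign_pessimistic <- function(sample, system, thresholds) {
  check_grid(sample$wavelengths, system$wavelengths)
  lam <- thresholds$lambda
  s_up <- credibility_pair(sample, system$upper_boundary, thresholds)
  if (s_up[["sigma_ab"]] >= lam) return("CAT-C")
  s_lo <- credibility_pair(sample, system$lower_boundary, thresholds)
  if (s_lo[["sigma_ab"]] >= lam) return("CAT-A")
  "CAT-B"
}

#' Optimistic category assignment
#'
#' The ascending (optimistic, disjunctive) assignment procedure: the sample
#' is placed just below the first boundary that strictly outranks it —
#' CAT-B if the lower boundary strictly outranks the sample, else CAT-A if
#' the upper boundary does, else CAT-C. A boundary strictly outranks the
#' sample when it outranks it and is not outranked in return.
#'
#' @inheritParams assign_pessimistic
#' @return `"CAT-B"`, `"CAT-A"` or `"CAT-C"`.
#' @seealso [assign_pessimistic()], [classify()]
#' @export
assign_optimistic <- function(sample, system, thresholds) {
  check_grid(sample$wavelengths, system$wavelengths)
  lam <- thresholds$lambda
  strictly_outranks <- function(sig)
    sig[["sigma_ba"]] >= lam && sig[["sigma_ab"]] < lam
  s_lo <- credibility_pair(sample, system$lower_boundary, thresholds)
  if (strictly_outranks(s_lo)) return("CAT-B")
  s_up <- credibility_pair(sample, system$upper_boundary, thresholds)
  if (strictly_outranks(s_up)) return("CAT-A")
  "CAT-C"
}
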