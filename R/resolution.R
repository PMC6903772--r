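#' Experimental precision of an isotope ratio (2sd)
#'
#' Twice the sample standard deviation of the ratio across independent
#' treatment replicates — the conservative precision against which isotope
#' enrichment is compared when counting distinguishable ratios.
#'
#' @param replicate_ratios Numeric vector of per-replicate 67:66 ratios,
#'   length >= 2.
#' @return 2 * sd, numeric scalar.
#' @export
experimental_precision <- function(replicate_ratios) {
  x <- as.numeric(replicate_ratios)
  if (length(x) < 2L)
    stop("insufficient replication: need n >= 2 replicates")
  stopifnot(all(is.finite(x)))
  2 * stats::sd(x)
}

#' Isotope enrichment between a labeled and an unlabeled source
#'
#' The difference of 67:66 ratios, labeled minus unlabeled.
#'
#' @param labeled,unlabeled 67:66 ratios (numeric scalars).
#' @return labeled - unlabeled.
#' @export
enrichment <- function(labeled, unlabeled) {
  stopifnot(is.numeric(labeled), is.numeric(unlabeled))
  labeled - unlabeled
}

## floor with a 1e-9 absolute guard: quotients that are whole numbers in
## decimal arithmetic (e.g. 0.0702/0.0027 = 26) must not lose a unit to
## binary rounding.
floor_guard <- function(x) floor(x + 1e-9)

#' Number of statistically distinguishable isotope ratios
#'
#' How many ratio values, spaced by the experimental precision, fit between
#' the two sources: floor(enrichment / precision), floored at zero for
#' negative enrichment.
#'
#' @param enrichment Labeled-minus-unlabeled 67:66 difference.
#' @param precision Experimental precision (the 2sd value itself).
#' @return Non-negative integer count.
#' @export
distinguishable_ratios <- function(enrichment, precision) {
  stopifnot(is.numeric(enrichment), is.numeric(precision))
  if (any(precision <= 0)) stop("precision must be > 0")
  pmax(0, floor_guard(enrichment / precision))
}

#' Smallest detectable source contribution
#'
#' With n distinguishable ratios between the two sources, contributions of
#' about 100/n percent of plant Zn can be resolved.
#'
#' @param n Positive integer count of distinguishable ratios.
#' @return Percentage, rounded to 2 decimals.
#' @export
detectable_contribution <- function(n) {
  stopifnot(is.numeric(n))
  if (any(n < 1)) stop("need n >= 1 distinguishable ratios")
  round(100 / n, 2)
}

#' Distinguishable ratios within a sub-range of fertilizer fractions
#'
#' When the plausible fertilizer-derived fractions span only part of the
#' full 0-100% mixing range (e.g. organic fertilizers rarely exceed 50%),
#' the resolvable count shrinks proportionally:
#' floor(range_fraction * enrichment / precision). `range_fraction = 1`
#' reduces to [distinguishable_ratios()].
#'
#' @param enrichment,precision As in [distinguishable_ratios()].
#' @param range_fraction Fraction of the mixing range considered, in (0, 1].
#' @return Non-negative integer count.
#' @export
resolution_within_range <- function(enrichment, precision, range_fraction) {
  stopifnot(is.numeric(range_fraction),
            all(range_fraction > 0), all(range_fraction <= 1))
  if (any(precision <= 0)) stop("precision must be > 0")
  pmax(0, floor_guard(range_fraction * enrichment / precision))
}

#' Zn input to soil from an amendment
#'
#' @param content_mg_per_kg Zn content of the amendment (mg Zn per kg
#'   amendment).
#' @param rate_g_per_kg Application rate (g amendment per kg soil).
#' @return Zn input in mg Zn per kg soil: content * rate / 1000.
#' @export
zn_input <- function(content_mg_per_kg, rate_g_per_kg) {
  stopifnot(all(content_mg_per_kg >= 0), all(rate_g_per_kg >= 0))
  content_mg_per_kg * rate_g_per_kg / 1000
}

#' Field-scale application rate equivalent of a pot dose
#'
#' Converts g amendment per kg soil to t per hectare, assuming the amendment
#' is mixed into the plough layer: soil mass per ha = 10,000 m2 x depth x
#' density.
#'
#' @param rate_g_per_kg Application rate (g amendment per kg soil).
#' @param depth_m Ploughing depth in m (default 0.2).
#' @param density_t_per_m3 Soil bulk density in t/m3 (default 1.3).
#' @return t amendment per ha.
#' @export
field_rate <- function(rate_g_per_kg, depth_m = 0.2, density_t_per_m3 = 1.3) {
  stopifnot(all(rate_g_per_kg > 0), depth_m > 0, density_t_per_m3 > 0)
  ## g/kg soil == kg/t soil; soil mass (t/ha) = 10000 * depth * density
  rate_g_per_kg * 10000 * depth_m * density_t_per_m3 / 1000
}

#' Source-resolution report for one labeling system
#'
#' The one-row summary of how well a labeled/unlabeled source pair can be
#' resolved at a given experimental precision: enrichment, distinguishable
#' ratio count, smallest detectable contribution, and (optionally) the
#' count within a restricted fertilizer-fraction range.
#'
#' @param labeled_ratio,unlabeled_ratio 67:66 ratios of the labeled and the
#'   unlabeled source.
#' @param precision Experimental precision (2sd units of the 67:66 ratio).
#' @param range_fraction Optional fraction of the mixing range for the
#'   within-range count (NA to omit).
#' @param label Optional row label.
#' @return Object of class `resolution_report` (one-row data.frame).
#' @export
resolution_report <- function(labeled_ratio, unlabeled_ratio, precision,
                              range_fraction = NA, label = NA_character_) {
  e <- enrichment(labeled_ratio, unlabeled_ratio)
  n <- distinguishable_ratios(e, precision)
  out <- data.frame(
    label = label,
    labeled_ratio = labeled_ratio,
    unlabeled_ratio = unlabeled_ratio,
    enrichment = e,
    experimental_precision = precision,
    n_distinguishable = n,
    detectable_contribution_pct = if (n >= 1) detectable_contribution(n) else NA_real_,
    range_fraction = range_fraction,
    n_within_range = if (is.na(range_fraction)) NA_integer_
                     else resolution_within_range(e, precision, range_fraction),
    stringsAsFactors = FALSE)
  class(out) <- c("resolution_report", "data.frame")
  out
}
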