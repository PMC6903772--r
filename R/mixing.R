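#' Pair of Zn sources entering the two-source mixing model
#'
#' The mixing model partitions plant Zn between exactly two sources: the
#' soil-available Zn pool (its composition read from plants grown on
#' unfertilized reference pots) and the fertilizer. The model is resolvable
#' only if the two sources' 67:66 ratios are separated by more than
#' `min_separation`; by convention that floor is set to 10 times the
#' experimental precision (2sd units of the 67:66 ratio) when one is known.
#'
#' @param soil,fertilizer [abundance_vector()]s of the two sources.
#' @param min_separation Minimum |67:66(fert) - 67:66(soil)| for the pair to
#'   be declared resolvable. Default 0 (any strict difference). Pass
#'   `10 * precision` to apply the conventional floor.
#' @return Object of class `source_pair`.
#' @export
source_pair <- function(soil, fertilizer, min_separation = 0) {
  stopifnot(inherits(soil, "abundance_vector"),
            inherits(fertilizer, "abundance_vector"),
            min_separation >= 0)
  sep <- abs(ratio_67_66(fertilizer) - ratio_67_66(soil))
  if (sep <= min_separation)
    stop(sprintf(paste0("sources are unresolvable: |67:66 separation| = %.3g",
                        " <= minimum %.3g"), sep, min_separation))
  structure(list(soil = soil, fertilizer = fertilizer,
                 min_separation = min_separation),
            class = "source_pair")
}

#' @export
print.source_pair <- function(x, ...) {
  cat("Two-source Zn mixing system\n")
  cat(sprintf("  soil       67:66 = %.4f\n", ratio_67_66(x$soil)))
  cat(sprintf("  fertilizer 67:66 = %.4f\n", ratio_67_66(x$fertilizer)))
  invisible(x)
}

#' Forward mixing model: plant 67:66 ratio from a fertilizer fraction
#'
#' The plant's 67:66 ratio implied by the two-source mass balance when a
#' mole fraction `zndf_fert` of plant Zn comes from the fertilizer and the
#' remainder from the soil-available pool:
#' \deqn{R = \frac{f\,{}^{67}Zn_{fert} + (1-f)\,{}^{67}Zn_{soil}}
#'            {f\,{}^{66}Zn_{fert} + (1-f)\,{}^{66}Zn_{soil}}}
#' with abundances in mole-fraction percent. Strictly monotonic in `f`
#' whenever the source ratios differ.
#'
#' @param zndf_fert Fraction of plant Zn from the fertilizer, in \[0, 1\].
#' @param sources A [source_pair()].
#' @return The plant 67:66 ratio (numeric scalar).
#' @seealso [zndf_fertilizer()] for the inverse.
#' @export
plant_ratio <- function(zndf_fert, sources) {
  stopifnot(inherits(sources, "source_pair"),
            is.numeric(zndf_fert), length(zndf_fert) == 1L,
            is.finite(zndf_fert), zndf_fert >= 0, zndf_fert <= 1)
  s <- unclass(sources$soil); f <- unclass(sources$fertilizer)
  num <- zndf_fert * f["67"] + (1 - zndf_fert) * s["67"]
  den <- zndf_fert * f["66"] + (1 - zndf_fert) * s["66"]
  if (den <= 0) stop("degenerate sources: mixed 66Zn abundance is <= 0")
  unname(num / den)
}

#' Inverse mixing model: fraction of plant Zn derived from the fertilizer
#'
#' Solves the two-source mass balance for the fertilizer-derived fraction,
#' given the measured plant 67:66 ratio R and the 66/67 abundances of the
#' two sources:
#' \deqn{Zndf_{fert}\% = 100\cdot\frac{{}^{66}Zn_{soil} R - {}^{67}Zn_{soil}}
#'   {({}^{67}Zn_{fert} - {}^{67}Zn_{soil}) - R({}^{66}Zn_{fert} - {}^{66}Zn_{soil})}}
#'
#' Measurement noise on plants that took (nearly) all their Zn from one
#' source can push the estimate slightly past 0 or 100; such values are
#' returned with attribute `out_of_range = TRUE` (and a warning) rather than
#' rejected. A ratio exactly equal (in floating point) to a source's own
#' 67:66 ratio returns exactly 0 or 100.
#'
#' @param plant_ratio_67_66 Measured (mass-bias corrected) plant 67:66 ratio.
#' @param sources A [source_pair()].
#' @param admissible Interval (in %) outside which the estimate is flagged;
#'   default c(-10, 110).
#' @return Percentage of plant Zn from the fertilizer, with attribute
#'   `out_of_range`.
#' @export
zndf_fertilizer <- function(plant_ratio_67_66, sources,
                            admissible = c(-10, 110)) {
  stopifnot(inherits(sources, "source_pair"),
            is.numeric(plant_ratio_67_66), length(plant_ratio_67_66) == 1L,
            is.finite(plant_ratio_67_66), plant_ratio_67_66 > 0,
            length(admissible) == 2L, admissible[1] < admissible[2])
  s <- unclass(sources$soil); f <- unclass(sources$fertilizer)
  R <- plant_ratio_67_66
  ## exact-endpoint tie-break: R equal to a source's own ratio in FP
  if (R == unname(s["67"] / s["66"]))
    return(structure(0, out_of_range = FALSE))
  if (R == unname(f["67"] / f["66"]))
    return(structure(100, out_of_range = FALSE))
  den <- (f["67"] - s["67"]) - R * (f["66"] - s["66"])
  if (abs(den) < .Machine$double.eps * max(abs(f["67"]), abs(s["67"]), 1))
    stop("unresolvable mixture: mass-balance denominator is numerically 0")
  zndf <- unname(100 * (s["66"] * R - s["67"]) / den)
  oor <- zndf < admissible[1] || zndf > admissible[2]
  if (oor)
    warning(sprintf("Zndf estimate %.2f%% outside admissible [%g, %g]%%",
                    zndf, admissible[1], admissible[2]))
  structure(zndf, out_of_range = oor)
}

#' Summarize fertilizer-derived fractions across treatment replicates
#'
#' Mean, sample standard deviation and 95% confidence interval (Student t,
#' n-1 degrees of freedom) of per-replicate Zndf estimates from independent
#' treatment replicates.
#'
#' @param per_replicate_zndf Numeric vector of per-replicate Zndf values (%),
#'   length >= 2.
#' @param conf Confidence level, default 0.95.
#' @return Object of class `mixing_result`: list with `per_replicate`,
#'   `n`, `mean`, `sd`, `ci` (length-2), `conf`. The complementary
#'   soil-derived fraction is `100 - mean` exactly.
#' @export
summarize_treatment <- function(per_replicate_zndf, conf = 0.95) {
  x <- as.numeric(per_replicate_zndf)
  if (length(x) < 2L)
    stop("insufficient replication: need n >= 2 treatment replicates")
  stopifnot(all(is.finite(x)), conf > 0, conf < 1)
  n <- length(x)
  m <- mean(x)
  s <- stats::sd(x)
  half <- stats::qt(1 - (1 - conf) / 2, df = n - 1) * s / sqrt(n)
  structure(list(per_replicate = x, n = n, mean = m, sd = s,
                 ci = c(m - half, m + half), conf = conf,
                 zndf_fertilizer_pct = m, zndf_soil_pct = 100 - m),
            class = "mixing_result")
}

#' @export
print.mixing_result <- function(x, ...) {
  cat(sprintf("Zndf(fertilizer) = %.2f%% (sd %.2f, %d%% CI [%.2f, %.2f], n = %d)\n",
              x$mean, x$sd, round(100 * x$conf), x$ci[1], x$ci[2], x$n))
  cat(sprintf("Zndf(soil)       = %.2f%%\n", x$zndf_soil_pct))
  invisible(x)
}

#' Read source compositions from a CSV table
#'
#' Expected columns: `source_id`, `role` ("soil" or "fertilizer"), and
#' `A64, A66, A67, A68, A70` (mole-fraction percent). Printed tables round
#' abundances to a few decimals, so the closure check is applied at a
#' tolerance of 1e-4 relative and the vectors are renormalized on read.
#'
#' @param path CSV file path.
#' @return Named list of [abundance_vector()]s with attribute `roles`.
#' @export
read_sources <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("source_id", "role", "A64", "A66", "A67", "A68", "A70")
  if (!all(need %in% names(d)))
    stop("source CSV must have columns ", paste(need, collapse = ", "))
  if (!all(d$role %in% c("soil", "fertilizer")))
    stop("role must be 'soil' or 'fertilizer'")
  out <- lapply(seq_len(nrow(d)), function(i)
    abundance_vector(c(`64` = d$A64[i], `66` = d$A66[i], `67` = d$A67[i],
                       `68` = d$A68[i], `70` = d$A70[i]), tol = 1e-4))
  names(out) <- d$source_id
  attr(out, "roles") <- stats::setNames(d$role, d$source_id)
  out
}

#' Write source compositions to a CSV table
#'
#' @param sources Named list of [abundance_vector()]s.
#' @param roles Character vector ("soil"/"fertilizer"), one per source.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sources <- function(sources, roles, path) {
  stopifnot(length(sources) == length(roles))
  d <- do.call(rbind, lapply(sources, function(a) as.data.frame(t(unclass(a)))))
  names(d) <- paste0("A", zn_masses())
  d <- cbind(source_id = names(sources), role = roles, d)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
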