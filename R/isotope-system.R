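#' The stable zinc isotope system
#'
#' Zinc has five stable isotopes (mass numbers 64, 66, 67, 68, 70). This
#' object fixes the frame in which all abundance/ratio conversions, mass-bias
#' corrections and molar mixing calculations are done: the atomic mass of
#' each isotope, the IUPAC natural abundances (mole fraction in percent:
#' 49.17, 27.73, 4.04, 18.45, 0.61) and the reference isotope used as the
#' numerator of all reported ratios.
#'
#' @param reference Mass number of the reference (numerator) isotope.
#'   Defaults to 67, the tracer isotope: all reported ratios are
#'   \eqn{^{67}Zn{:}^{xx}Zn}.
#' @return An object of class `isotope_system` with elements `masses`
#'   (named numeric, atomic mass units), `natural` (an
#'   [abundance_vector()]) and `reference`.
#' @examples
#' sys <- zn_isotope_system()
#' sys$natural
#' @export
zn_isotope_system <- function(reference = 67L) {
  masses <- c(`64` = 63.9291420, `66` = 65.9260338, `67` = 66.9271277,
              `68` = 67.9248446, `70` = 69.9253192)
  stopifnot(all(diff(masses) > 0))
  reference <- as.integer(reference)
  if (!reference %in% c(64L, 66L, 67L, 68L, 70L))
    stop("reference must be one of the stable Zn mass numbers 64/66/67/68/70")
  structure(
    list(masses = masses,
         natural = abundance_vector(c(`64` = 49.17, `66` = 27.73, `67` = 4.04,
                                      `68` = 18.45, `70` = 0.61)),
         reference = reference),
    class = "isotope_system")
}

zn_masses <- function() c(64L, 66L, 67L, 68L, 70L)

#' @export
print.isotope_system <- function(x, ...) {
  cat("Stable Zn isotope system (reference isotope:", x$reference, ")\n")
  m <- rbind(`atomic mass (u)` = x$masses,
             `natural abundance (%)` = unclass(x$natural))
  print(round(m, 4))
  invisible(x)
}

#' Isotopic composition as mole-fraction percentages
#'
#' An abundance vector stores the isotopic composition of a Zn pool as mole
#' fractions in percent over the five stable isotopes, the unit in which
#' source compositions are tabulated. Entries must be non-negative and sum
#' to 100 within `tol`; on construction the vector is renormalized so the
#' sum is exactly 100.
#'
#' @param x Named numeric vector; names must be the mass numbers
#'   "64","66","67","68","70" (any order).
#' @param tol Relative tolerance on the pre-normalization sum (default 1e-6).
#' @return Object of class `abundance_vector` (named numeric, percent).
#' @seealso [ratios_from_abundances()], [abundances_from_ratios()]
#' @examples
#' natural <- abundance_vector(c(`64` = 49.17, `66` = 27.73, `67` = 4.04,
#'                               `68` = 18.45, `70` = 0.61))
#' @export
abundance_vector <- function(x, tol = 1e-6) {
  want <- as.character(zn_masses())
  if (is.null(names(x)) || !setequal(names(x), want))
    stop("abundance vector needs entries named ", paste(want, collapse = ", "))
  x <- as.numeric(x[want])
  names(x) <- want
  if (any(!is.finite(x)) || any(x < 0))
    stop("abundances must be finite and >= 0")
  s <- sum(x)
  if (abs(s - 100) > tol * 100)
    stop(sprintf("abundances sum to %.8g, not 100 (tol %g relative)", s, tol))
  structure(100 * x / s, class = "abundance_vector")
}

#' @export
print.abundance_vector <- function(x, ...) {
  cat("Zn isotope abundances (mole fraction, %)\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Isotope ratios relative to a reference isotope
#'
#' Stores a sample's composition as molar ratios reference:denominator for
#' the four non-reference isotopes, e.g. 67:64, 67:66, 67:68, 67:70. This is
#' the form in which ICP-MS measurements are taken; it is interconvertible
#' with [abundance_vector()] (the round trip is the identity to machine
#' precision).
#'
#' @param ratios Named numeric vector of positive ratios; names are the
#'   denominator mass numbers (all four non-reference isotopes).
#' @param reference Reference (numerator) mass number, default 67.
#' @return Object of class `ratio_set`: named numeric with attribute
#'   `reference`.
#' @examples
#' rs <- ratio_set(c(`64` = 4.04 / 49.17, `66` = 4.04 / 27.73,
#'                   `68` = 4.04 / 18.45, `70` = 4.04 / 0.61))
#' @export
ratio_set <- function(ratios, reference = 67L) {
  reference <- as.integer(reference)
  want <- as.character(setdiff(zn_masses(), reference))
  if (is.null(names(ratios)) || !setequal(names(ratios), want))
    stop("ratio set for reference ", reference, " needs denominators ",
         paste(want, collapse = ", "),
         " (missing or extra denominator isotope)")
  r <- as.numeric(ratios[want])
  names(r) <- want
  if (any(!is.finite(r)) || any(r <= 0))
    stop("all isotope ratios must be finite and > 0")
  structure(r, reference = reference, class = "ratio_set")
}

#' @export
print.ratio_set <- function(x, ...) {
  ref <- attr(x, "reference")
  v <- unclass(x)
  names(v) <- paste0(ref, ":", names(v))
  cat("Zn isotope ratios (mol/mol)\n")
  print(signif(v, 6))
  invisible(x)
}

#' Convert a full ratio set to isotope abundances
#'
#' Given all four ratios R_x = A_ref / A_x, the reference abundance follows
#' from closure of the mole fractions:
#' A_ref = 100 / (1 + sum_x 1/R_x), and A_x = A_ref / R_x.
#'
#' @param rs A [ratio_set()] with all four non-reference denominators.
#' @return An [abundance_vector()].
#' @examples
#' iupac <- zn_isotope_system()$natural
#' abundances_from_ratios(ratios_from_abundances(iupac))
#' @export
abundances_from_ratios <- function(rs) {
  stopifnot(inherits(rs, "ratio_set"))
  ref <- as.character(attr(rs, "reference"))
  a_ref <- 100 / (1 + sum(1 / unclass(rs)))
  out <- a_ref / unclass(rs)
  out[ref] <- a_ref
  abundance_vector(out, tol = 1e-9)
}

#' Convert isotope abundances to a ratio set
#'
#' The inverse of [abundances_from_ratios()]: R_x = A_ref / A_x for each
#' non-reference isotope x.
#'
#' @param av An [abundance_vector()].
#' @param reference Reference mass number (numerator), default 67.
#' @return A [ratio_set()].
#' @export
ratios_from_abundances <- function(av, reference = 67L) {
  stopifnot(inherits(av, "abundance_vector"))
  reference <- as.integer(reference)
  ref <- as.character(reference)
  if (unclass(av)[ref] <= 0)
    stop("reference isotope abundance must be > 0")
  den <- as.character(setdiff(zn_masses(), reference))
  if (any(unclass(av)[den] <= 0))
    stop("zero abundance in a denominator isotope; ratios undefined")
  ratio_set(unclass(av)[ref] / unclass(av)[den], reference = reference)
}

#' The 67:66 reporting ratio of a composition
#'
#' Convenience accessor for the ratio in which enrichments and mixing results
#' are reported.
#'
#' @param av An [abundance_vector()].
#' @return Numeric scalar, A67/A66.
#' @export
ratio_67_66 <- function(av) {
  stopifnot(inherits(av, "abundance_vector"))
  unname(unclass(av)["67"] / unclass(av)["66"])
}
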