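#' Standard-sample-standard bracketing sequence
#'
#' An ordered measurement sequence interleaving a bracketing standard of
#' known composition with samples. Every sample event must have at least one
#' standard event before and one after it (the "envelope"); time indices
#' must be strictly increasing.
#'
#' @param events data.frame with columns `time` (numeric, strictly
#'   increasing), `kind` ("standard" or "sample"), `sample_id` (character;
#'   NA allowed for standards) and `R64, R66, R68, R70` (raw 67:xx ratios).
#'   One row per measurement event; replicate measurements of a sample
#'   occupy consecutive time indices inside one envelope.
#' @param standard_true [abundance_vector()] assumed for the bracketing
#'   standard (conventionally the IUPAC natural composition).
#' @return Object of class `bracketing_sequence`.
#' @export
bracketing_sequence <- function(events, standard_true) {
  stopifnot(is.data.frame(events), inherits(standard_true, "abundance_vector"))
  need <- c("time", "kind", "sample_id", "R64", "R66", "R68", "R70")
  if (!all(need %in% names(events)))
    stop("events needs columns ", paste(need, collapse = ", "))
  if (nrow(events) < 1L) stop("empty sequence")
  if (any(diff(events$time) <= 0))
    stop("time indices must be strictly increasing")
  if (!all(events$kind %in% c("standard", "sample")))
    stop("kind must be 'standard' or 'sample'")
  st <- events$time[events$kind == "standard"]
  sa <- events$time[events$kind == "sample"]
  if (length(sa) && (!length(st) || any(sa < min(st)) || any(sa > max(st))))
    stop("unbracketed sample: every sample needs a standard before and after")
  structure(list(events = events, standard_true = standard_true),
            class = "bracketing_sequence")
}

#' Read a bracketing sequence from CSV
#'
#' Columns: `time`, `kind`, `sample_id`, `R64`, `R66`, `R68`, `R70`.
#'
#' @param path CSV path.
#' @param standard_true [abundance_vector()] of the bracketing standard.
#' @return A [bracketing_sequence()].
#' @export
read_sequence <- function(path, standard_true) {
  bracketing_sequence(utils::read.csv(path, stringsAsFactors = FALSE),
                      standard_true)
}

#' Write a bracketing sequence's events to CSV
#'
#' @param seq A [bracketing_sequence()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sequence <- function(seq, path) {
  stopifnot(inherits(seq, "bracketing_sequence"))
  utils::write.csv(seq$events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fit a power-law mass-bias correction model from bracketing standards
#'
#' Instrumental mass discrimination is modeled by a per-atomic-mass-unit
#' factor b(t): a measured ratio relates to the true ratio as
#' R_meas = R_true * b(t)^dm, with dm the (signed) atomic-mass difference
#' between reference and denominator isotope. At each standard event the
#' factor is estimated from the 67:66 ratio, b = (R_meas/R_true)^(1/dm),
#' and between standards it is interpolated linearly in time, so a slow
#' linear drift of the instrument bias is inverted exactly.
#'
#' @param seq A [bracketing_sequence()].
#' @param system An [isotope_system()][zn_isotope_system] (atomic masses).
#' @param joint If TRUE, estimate b at each standard as the geometric mean
#'   of the per-ratio estimates over all four ratios instead of 67:66 alone.
#' @return Object of class `correction_model`: per-standard times and bias
#'   factors plus an interpolator.
#' @export
fit_bracketing <- function(seq, system = zn_isotope_system(), joint = FALSE) {
  stopifnot(inherits(seq, "bracketing_sequence"),
            inherits(system, "isotope_system"))
  ev <- seq$events
  std <- ev[ev$kind == "standard", , drop = FALSE]
  if (nrow(std) < 1L) stop("no standard events to fit")
  m <- system$masses
  true_rs <- ratios_from_abundances(seq$standard_true, reference = 67L)
  dm <- m["67"] - m[c("64", "66", "68", "70")]
  b <- vapply(seq_len(nrow(std)), function(i) {
    if (joint) {
      meas <- c(std$R64[i], std$R66[i], std$R68[i], std$R70[i])
      f <- (meas / unclass(true_rs))^(1 / dm)
      exp(mean(log(f)))
    } else {
      (std$R66[i] / unclass(true_rs)["66"])^(1 / dm["66"])
    }
  }, numeric(1))
  if (any(!is.finite(b)) || any(b <= 0))
    stop("fitted per-amu factor must be finite and > 0")
  structure(list(times = std$time, bias = b,
                 t_range = range(std$time), joint = joint),
            class = "correction_model")
}

#' Evaluate the fitted per-amu bias factor at a time index
#'
#' Piecewise-linear in time between bracketing standards; only defined
#' inside the standard envelope.
#'
#' @param model A [fit_bracketing()] model.
#' @param t Time index (vectorized).
#' @return Per-amu bias factor(s).
#' @export
bias_factor <- function(model, t) {
  stopifnot(inherits(model, "correction_model"))
  if (any(t < model$t_range[1] | t > model$t_range[2]))
    stop("time outside the standard envelope; sample is unbracketed")
  if (length(model$times) == 1L) return(rep(model$bias, length(t)))
  stats::approx(model$times, model$bias, xout = t, method = "linear")$y
}

#' Apply a mass-bias correction to a raw ratio set
#'
#' Each raw ratio is divided by b(t)^dm, where dm is the signed atomic-mass
#' difference between the reference isotope and the denominator isotope.
#' Correcting a measurement of the bracketing standard itself returns the
#' standard's true ratios.
#'
#' @param raw A [ratio_set()] of raw (measured) 67:xx ratios.
#' @param model A [fit_bracketing()] model.
#' @param t Time index of the measurement (inside the envelope).
#' @param system An isotope system (atomic masses).
#' @return Corrected [ratio_set()].
#' @export
correct_ratios <- function(raw, model, t, system = zn_isotope_system()) {
  stopifnot(inherits(raw, "ratio_set"))
  b <- bias_factor(model, t)
  m <- system$masses
  den <- names(unclass(raw))
  dm <- m["67"] - m[den]
  ratio_set(unclass(raw) / b^dm, reference = attr(raw, "reference"))
}

#' Correct every sample event of a bracketing sequence
#'
#' Fits the correction model on the sequence's own standards and applies it
#' to each sample event.
#'
#' @param seq A [bracketing_sequence()].
#' @param system An isotope system.
#' @param joint Passed to [fit_bracketing()].
#' @return data.frame like the sample rows of `seq$events` but with
#'   mass-bias-corrected ratios.
#' @export
correct_sequence <- function(seq, system = zn_isotope_system(), joint = FALSE) {
  model <- fit_bracketing(seq, system, joint = joint)
  ev <- seq$events
  sam <- ev[ev$kind == "sample", , drop = FALSE]
  for (i in seq_len(nrow(sam))) {
    rs <- ratio_set(c(`64` = sam$R64[i], `66` = sam$R66[i],
                      `68` = sam$R68[i], `70` = sam$R70[i]))
    cr <- unclass(correct_ratios(rs, model, sam$time[i], system))
    sam$R64[i] <- cr["64"]; sam$R66[i] <- cr["66"]
    sam$R68[i] <- cr["68"]; sam$R70[i] <- cr["70"]
  }
  sam
}
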