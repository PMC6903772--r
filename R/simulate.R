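#' Instrument noise and replicate-scheme profile
#'
#' Describes how an ICP-MS instrument turns a true composition into raw
#' replicate ratio measurements. Two built-in profiles match the study
#' conditions: a single-collector quadrupole instrument ("Q": per-ratio
#' relative standard deviation 1.3%, except 2.7% for 67:70 whose denominator
#' isotope is only 0.61% abundant; 12 repeats per sample) and a
#' multicollector instrument ("MC": 0.05% RSD for all ratios; 3 blocks of
#' 20 cycles, block means retained). Mass bias is a per-amu factor drifting
#' slowly and linearly in time.
#'
#' @param name "Q" or "MC".
#' @param ratio_rsd Named numeric (per denominator "64","66","68","70"):
#'   relative standard deviation of each ratio per single measurement.
#' @param repeats Number of raw repeats per sample (Q scheme).
#' @param blocks,cycles MC scheme: blocks x cycles raw measurements; the
#'   run retains block means.
#' @param bias0 Per-amu mass-bias factor at time 0 (1 = unbiased).
#' @param drift Linear change of the per-amu factor per time unit.
#' @return Object of class `instrument_profile`.
#' @export
instrument_profile <- function(name = c("Q", "MC"),
                               ratio_rsd = NULL,
                               repeats = NULL, blocks = NULL, cycles = NULL,
                               bias0 = 1.03, drift = -2e-5) {
  name <- match.arg(name)
  if (is.null(ratio_rsd))
    ratio_rsd <- if (name == "Q")
      c(`64` = 0.013, `66` = 0.013, `68` = 0.013, `70` = 0.027)
    else
      c(`64` = 5e-4, `66` = 5e-4, `68` = 5e-4, `70` = 5e-4)
  want <- c("64", "66", "68", "70")
  stopifnot(setequal(names(ratio_rsd), want))
  ratio_rsd <- ratio_rsd[want]
  if (any(ratio_rsd <= 0)) stop("all RSDs must be > 0")
  if (name == "Q") {
    if (is.null(repeats)) repeats <- 12L
    if (repeats < 1L) stop("repeats must be >= 1")
  } else {
    if (is.null(blocks)) blocks <- 3L
    if (is.null(cycles)) cycles <- 20L
    if (blocks < 1L || cycles < 1L) stop("blocks and cycles must be >= 1")
  }
  stopifnot(is.finite(bias0), bias0 > 0, is.finite(drift))
  structure(list(name = name, ratio_rsd = ratio_rsd, repeats = repeats,
                 blocks = blocks, cycles = cycles,
                 bias0 = bias0, drift = drift),
            class = "instrument_profile")
}

profile_bias <- function(profile, t) profile$bias0 + profile$drift * t

#' Simulate raw replicate ratio measurements of one sample
#'
#' Each true ratio is multiplied by the instrument's per-amu mass-bias
#' factor raised to the signed atomic-mass difference, and by (1 + eps)
#' with eps drawn independently per ratio and per raw measurement from a
#' normal law with the profile's RSD. For an MC profile the raw cycles are
#' aggregated to block means; for a Q profile each repeat is retained.
#'
#' @param true_av True [abundance_vector()] of the sample.
#' @param profile An [instrument_profile()].
#' @param t Time index (drives the mass-bias drift): a scalar, or one value
#'   per retained row (Q: per repeat; MC: per block — the drift is treated
#'   as negligible within a block of cycles).
#' @param seed Optional integer; if given, the simulation is a deterministic
#'   function of it (the caller's RNG state is left untouched).
#' @param system Isotope system (atomic masses for the bias law).
#' @return A `measurement_run`: data.frame with columns `replicate`, `R64`,
#'   `R66`, `R68`, `R70`, with attributes `instrument` and `time`.
#' @export
simulate_measurement <- function(true_av, profile, t = 0,
                                 seed = NULL, system = zn_isotope_system()) {
  stopifnot(inherits(true_av, "abundance_vector"),
            inherits(profile, "instrument_profile"))
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  true_rs <- unclass(ratios_from_abundances(true_av, reference = 67L))
  m <- system$masses
  dm <- m["67"] - m[c("64", "66", "68", "70")]
  n_rows <- if (profile$name == "Q") profile$repeats else profile$blocks
  if (length(t) == 1L) t <- rep(t, n_rows)
  if (length(t) != n_rows)
    stop("t must be scalar or one value per retained row (", n_rows, ")")
  n_raw <- if (profile$name == "Q") profile$repeats
           else profile$blocks * profile$cycles
  b <- profile_bias(profile, t)           # one per retained row
  b_raw <- if (profile$name == "Q") b else rep(b, each = profile$cycles)
  biased <- outer(b_raw, dm, `^`) * rep(true_rs, each = n_raw)
  eps <- matrix(stats::rnorm(n_raw * 4L, 0, rep(profile$ratio_rsd, each = n_raw)),
                nrow = n_raw)
  raw <- biased * (1 + eps)
  colnames(raw) <- c("R64", "R66", "R68", "R70")
  if (profile$name == "MC") {
    blk <- rep(seq_len(profile$blocks), each = profile$cycles)
    raw <- apply(raw, 2L, function(col) tapply(col, blk, mean))
    if (profile$blocks == 1L) raw <- matrix(raw, nrow = 1L,
                                            dimnames = list(NULL, c("R64", "R66", "R68", "R70")))
  }
  out <- data.frame(replicate = seq_len(nrow(raw)), raw, row.names = NULL)
  attr(out, "instrument") <- profile$name
  attr(out, "time") <- t
  class(out) <- c("measurement_run", "data.frame")
  out
}

#' Matrix-interference profile
#'
#' Additive spectral interference (argides, oxides formed in the plasma
#' from the sample matrix) modeled per isotope channel as a fraction of the
#' total Zn signal, scaled by a per-sample matrix level. A zero profile is
#' the purified (ion-exchange separated) case.
#'
#' @param fractions Named numeric over "64","66","67","68","70": interfering
#'   signal at each mass as a fraction of the total Zn-channel signal, at
#'   matrix level 1. Default all zero.
#' @return Object of class `interference_profile`.
#' @export
interference_profile <- function(fractions = c(`64` = 0, `66` = 0, `67` = 0,
                                               `68` = 0, `70` = 0)) {
  want <- as.character(zn_masses())
  stopifnot(setequal(names(fractions), want))
  fractions <- as.numeric(fractions[want]); names(fractions) <- want
  if (any(fractions < 0)) stop("interference fractions must be >= 0")
  structure(list(fractions = fractions,
                 purified = all(fractions == 0)),
            class = "interference_profile")
}

#' Superimpose matrix interference on a measurement run
#'
#' For each raw measurement the implied per-isotope signals are recovered
#' from the ratios (signal at mass x proportional to the implied abundance),
#' each channel is augmented by `matrix_level * fraction_x * (total signal)`,
#' and ratios are re-formed. A zero profile or zero matrix level returns the
#' run unchanged (identical object).
#'
#' @param run A `measurement_run` from [simulate_measurement()].
#' @param ip An [interference_profile()].
#' @param matrix_level Non-negative scalar scaling the interference.
#' @return A `measurement_run` with perturbed ratios.
#' @export
apply_interference <- function(run, ip, matrix_level = 1) {
  stopifnot(inherits(run, "measurement_run"),
            inherits(ip, "interference_profile"),
            is.numeric(matrix_level), length(matrix_level) == 1L,
            matrix_level >= 0)
  if (matrix_level == 0 || ip$purified) return(run)
  fr <- ip$fractions
  for (i in seq_len(nrow(run))) {
    rs <- ratio_set(c(`64` = run$R64[i], `66` = run$R66[i],
                      `68` = run$R68[i], `70` = run$R70[i]))
    S <- unclass(abundances_from_ratios(rs))   # signals, total = 100
    S2 <- S + matrix_level * fr * sum(S)
    run$R64[i] <- S2["67"] / S2["64"]; run$R66[i] <- S2["67"] / S2["66"]
    run$R68[i] <- S2["67"] / S2["68"]; run$R70[i] <- S2["67"] / S2["70"]
  }
  run
}

#' Define a virtual source-tracing experiment
#'
#' The design of an in-silico growth trial: the source compositions, the
#' treatments (each with a true fertilizer-derived fraction), the replicate
#' count, purification flags and instrument assignments. The default is the
#' study design scaled to its essentials: a directly labeled wheat-straw
#' compost (67Zn at 31.08%) on a soil at natural composition, four
#' treatment replicates, measured on both instruments.
#'
#' @param sources Named list of [abundance_vector()]s.
#' @param treatments data.frame with columns `name`, `soil` (source name),
#'   `fertilizer` (source name or NA for a reference treatment), `zndf`
#'   (true fertilizer fraction in \[0,1\]; 0 for references), `n_reps`,
#'   `purified` (logical).
#' @param instruments Character subset of c("Q", "MC").
#' @return Object of class `virtual_experiment`.
#' @export
virtual_experiment <- function(sources, treatments,
                               instruments = c("Q", "MC")) {
  stopifnot(is.list(sources), length(sources) >= 1L,
            all(vapply(sources, inherits, TRUE, "abundance_vector")),
            is.data.frame(treatments))
  need <- c("name", "soil", "fertilizer", "zndf", "n_reps", "purified")
  if (!all(need %in% names(treatments)))
    stop("treatments needs columns ", paste(need, collapse = ", "))
  refs <- c(treatments$soil, treatments$fertilizer)
  refs <- refs[!is.na(refs)]
  bad <- setdiff(refs, names(sources))
  if (length(bad)) stop("undefined source reference: ", paste(bad, collapse = ", "))
  if (any(treatments$n_reps < 2L)) stop("each treatment needs >= 2 replicates")
  if (any(treatments$zndf < 0 | treatments$zndf > 1))
    stop("true zndf must lie in [0, 1]")
  if (any(is.na(treatments$fertilizer) & treatments$zndf != 0))
    stop("reference treatments (no fertilizer) must have zndf = 0")
  stopifnot(all(instruments %in% c("Q", "MC")))
  structure(list(sources = sources, treatments = treatments,
                 instruments = instruments),
            class = "virtual_experiment")
}

#' Built-in study-like direct-labeling design
#'
#' Labeled compost at 31.08% 67Zn (remaining mole fraction on 64/66/68/70
#' in natural proportion), soil-available Zn at the IUPAC natural
#' composition, one reference treatment and one fertilized treatment per
#' true fraction, four replicates each.
#'
#' @param zndf_true Numeric vector of true fertilizer fractions in \[0,1\].
#' @param n_reps Treatment replicates (default 4).
#' @param instruments Instruments to assign.
#' @return A [virtual_experiment()].
#' @export
direct_labeling_experiment <- function(zndf_true = c(0.05, 0.10, 0.30),
                                       n_reps = 4L,
                                       instruments = c("Q", "MC")) {
  nat <- unclass(zn_isotope_system()$natural)
  rest <- nat[c("64", "66", "68", "70")]
  fert <- c(rest / sum(rest) * (100 - 31.08), `67` = 31.08)
  sources <- list(
    soil_natural = zn_isotope_system()$natural,
    compost_67 = abundance_vector(fert))
  tr <- data.frame(
    name = c("reference", paste0("direct_", round(100 * zndf_true), "pct")),
    soil = "soil_natural",
    fertilizer = c(NA, rep("compost_67", length(zndf_true))),
    zndf = c(0, zndf_true),
    n_reps = as.integer(n_reps),
    purified = TRUE,
    stringsAsFactors = FALSE)
  virtual_experiment(sources, tr, instruments)
}

## deterministic per-unit seed derivation, kept < 2^31
derive_seed <- function(base, i, j, k) {
  (base + 1000003L * i + 997L * j + k) %% 2147483587L + 1L
}

#' Simulate a full virtual experiment to bracketed raw sequences
#'
#' For every treatment x replicate x instrument, emits a
#' standard-sample-standard bracketed sequence whose underlying truth is the
#' two-source mixture of the treatment's sources at its true zndf (the
#' replicate's raw repeats sit between two standard blocks). Also simulates
#' `n_proc` processing replicates of every fertilizer source. Deterministic
#' function of `seed` and the design.
#'
#' @param ve A [virtual_experiment()].
#' @param profiles Named list of [instrument_profile()]s keyed "Q"/"MC";
#'   defaults to the built-in profiles.
#' @param ip Optional [interference_profile()] applied to non-purified
#'   samples at `matrix_level`.
#' @param matrix_level Matrix level for non-purified samples (default 1).
#' @param seed Integer base seed.
#' @param standard_true Bracketing standard composition (default IUPAC
#'   natural).
#' @param n_proc Processing replicates simulated per fertilizer source.
#' @return Object of class `icpms_dataset`: list with `sequences` (named
#'   list of [bracketing_sequence()]), `index` (data.frame keying sequences
#'   by treatment/replicate/instrument), `source_runs` (fertilizer
#'   processing replicates), `truth`, `ve`.
#' @export
simulate_experiment <- function(ve, profiles = NULL, ip = NULL,
                                matrix_level = 1, seed = 1L,
                                standard_true = zn_isotope_system()$natural,
                                n_proc = 4L) {
  stopifnot(inherits(ve, "virtual_experiment"))
  if (is.null(profiles))
    profiles <- list(Q = instrument_profile("Q"), MC = instrument_profile("MC"))
  sequences <- list(); idx <- NULL
  tr <- ve$treatments
  for (ii in seq_len(nrow(tr))) {
    soil <- ve$sources[[tr$soil[ii]]]
    true_av <- if (is.na(tr$fertilizer[ii])) soil else {
      fert <- ve$sources[[tr$fertilizer[ii]]]
      f <- tr$zndf[ii]
      abundance_vector(f * unclass(fert) + (1 - f) * unclass(soil))
    }
    for (jj in seq_len(tr$n_reps[ii])) {
      for (kk in seq_along(ve$instruments)) {
        ins <- ve$instruments[kk]
        pr <- profiles[[ins]]
        s_unit <- derive_seed(seed, ii, jj, kk)
        n_rows <- if (pr$name == "Q") pr$repeats else pr$blocks
        t_sam <- seq_len(n_rows) / (n_rows + 1) * 2
        run <- simulate_measurement(true_av, pr, t = t_sam, seed = s_unit)
        if (!is.null(ip) && !tr$purified[ii])
          run <- apply_interference(run, ip, matrix_level)
        std0 <- simulate_measurement(standard_true, pr, t = 0,
                                     seed = s_unit + 1L)
        std1 <- simulate_measurement(standard_true, pr, t = 2,
                                     seed = s_unit + 2L)
        ## collapse standard blocks to their mean raw ratios
        mean_row <- function(r, t) data.frame(
          time = t, kind = "standard", sample_id = NA_character_,
          R64 = mean(r$R64), R66 = mean(r$R66),
          R68 = mean(r$R68), R70 = mean(r$R70))
        sid <- sprintf("%s_rep%d", tr$name[ii], jj)
        ev <- rbind(
          mean_row(std0, 0),
          data.frame(time = t_sam, kind = "sample",
                     sample_id = sid, R64 = run$R64, R66 = run$R66,
                     R68 = run$R68, R70 = run$R70),
          mean_row(std1, 2))
        key <- sprintf("%s_rep%d_%s", tr$name[ii], jj, ins)
        sequences[[key]] <- bracketing_sequence(ev, standard_true)
        idx <- rbind(idx, data.frame(
          key = key, treatment = tr$name[ii], replicate = jj,
          instrument = ins, purified = tr$purified[ii],
          true_zndf = tr$zndf[ii], stringsAsFactors = FALSE))
      }
    }
  }
  ## processing replicates of each fertilizer source, per instrument
  fert_names <- unique(stats::na.omit(tr$fertilizer))
  source_runs <- list()
  for (fn in fert_names) {
    for (kk in seq_along(ve$instruments)) {
      ins <- ve$instruments[kk]
      for (pp in seq_len(n_proc)) {
        s_unit <- derive_seed(seed + 500000L, match(fn, names(ve$sources)),
                              pp, kk)
        pr <- profiles[[ins]]
        n_rows <- if (pr$name == "Q") pr$repeats else pr$blocks
        t_sam <- seq_len(n_rows) / (n_rows + 1) * 2
        run <- simulate_measurement(ve$sources[[fn]], pr,
                                    t = t_sam, seed = s_unit)
        std0 <- simulate_measurement(standard_true, pr, t = 0,
                                     seed = s_unit + 1L)
        std1 <- simulate_measurement(standard_true, pr, t = 2,
                                     seed = s_unit + 2L)
        mean_row <- function(r, t) data.frame(
          time = t, kind = "standard", sample_id = NA_character_,
          R64 = mean(r$R64), R66 = mean(r$R66),
          R68 = mean(r$R68), R70 = mean(r$R70))
        ev <- rbind(
          mean_row(std0, 0),
          data.frame(time = t_sam, kind = "sample",
                     sample_id = sprintf("%s_proc%d", fn, pp),
                     R64 = run$R64, R66 = run$R66,
                     R68 = run$R68, R70 = run$R70),
          mean_row(std1, 2))
        source_runs[[sprintf("%s_proc%d_%s", fn, pp, ins)]] <-
          bracketing_sequence(ev, standard_true)
      }
    }
  }
  structure(list(sequences = sequences, index = idx,
                 source_runs = source_runs,
                 truth = tr[, c("name", "zndf")], ve = ve,
                 standard_true = standard_true, seed = seed),
            class = "icpms_dataset")
}
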