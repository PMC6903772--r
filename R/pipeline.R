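#' Load or validate a run configuration
#'
#' A run configuration fully describes a virtual experiment: the seed, the
#' instruments, the source compositions, the treatment table and (optional)
#' interference settings. Everything is plain scalars/lists, so a config
#' echoed to YAML reproduces the run.
#'
#' @param config A list, or a path to a YAML file.
#' @return Validated config list of class `run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  need <- c("seed", "sources", "treatments")
  missing <- setdiff(need, names(config))
  if (length(missing))
    stop("config schema error; missing keys: ", paste(missing, collapse = ", "))
  if (is.null(config$instruments)) config$instruments <- c("Q", "MC")
  if (is.null(config$range_fraction)) config$range_fraction <- 0.5
  structure(config, class = c("run_config", "list"))
}

#' Default study-like run configuration
#'
#' Direct labeling: compost at 31.08% 67Zn on a natural-composition soil,
#' reference plus three fertilized treatments (5/10/30% true fertilizer
#' fraction), four replicates, both instruments.
#'
#' @param seed Base seed.
#' @return A [run_config()] list.
#' @export
default_run_config <- function(seed = 1L) {
  ve <- direct_labeling_experiment()
  src <- lapply(ve$sources, function(a) as.list(unclass(a)))
  src <- lapply(src, function(s) stats::setNames(s, paste0("A", names(s))))
  tr <- ve$treatments
  run_config(list(
    seed = as.integer(seed),
    instruments = c("Q", "MC"),
    sources = src,
    treatments = lapply(seq_len(nrow(tr)), function(i) list(
      name = tr$name[i], soil = tr$soil[i],
      fertilizer = if (is.na(tr$fertilizer[i])) NULL else tr$fertilizer[i],
      zndf = tr$zndf[i], n_reps = tr$n_reps[i], purified = tr$purified[i])),
    range_fraction = 0.5))
}

config_to_experiment <- function(config) {
  sources <- lapply(config$sources, function(s) {
    v <- unlist(s)
    names(v) <- sub("^A", "", names(v))
    abundance_vector(v)
  })
  tr <- do.call(rbind, lapply(config$treatments, function(t) data.frame(
    name = t$name, soil = t$soil,
    fertilizer = if (is.null(t$fertilizer)) NA_character_ else t$fertilizer,
    zndf = t$zndf, n_reps = as.integer(t$n_reps),
    purified = isTRUE(t$purified), stringsAsFactors = FALSE)))
  virtual_experiment(sources, tr, instruments = config$instruments)
}

## corrected per-sample mean ratios for every sequence in a dataset list
collapse_sequences <- function(seqs, system = zn_isotope_system()) {
  rows <- lapply(names(seqs), function(key) {
    sam <- correct_sequence(seqs[[key]], system)
    data.frame(key = key, sample_id = sam$sample_id[1],
               R64 = mean(sam$R64), R66 = mean(sam$R66),
               R68 = mean(sam$R68), R70 = mean(sam$R70),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

ratios_row_to_av <- function(row) {
  abundances_from_ratios(ratio_set(c(`64` = row$R64, `66` = row$R66,
                                     `68` = row$R68, `70` = row$R70)))
}

#' Analyze a simulated (or imported) ICP-MS dataset end-to-end
#'
#' Runs the full workflow on an `icpms_dataset`: mass-bias correction of
#' every bracketed sequence, per-sample mean ratios, estimation of each
#' source's composition (fertilizers from processing replicates, the
#' soil-available pool from the reference treatment's plants), per-replicate
#' fertilizer-derived fractions through the two-source mass balance,
#' treatment summaries with 95% confidence intervals, a source-resolution
#' report and a Bland-Altman comparison between instruments.
#'
#' @param ds An `icpms_dataset` from [simulate_experiment()].
#' @param range_fraction Fraction of the mixing range for the within-range
#'   resolution count (default 0.5).
#' @param system Isotope system.
#' @return List of class `trace_report`: `source_summary`, `zndf_table`,
#'   `resolution`, `bland_altman` (NULL with < 2 instruments),
#'   `per_replicate`.
#' @export
analyze_experiment <- function(ds, range_fraction = 0.5,
                               system = zn_isotope_system()) {
  stopifnot(inherits(ds, "icpms_dataset"))
  idx <- ds$index
  plant <- merge(idx, collapse_sequences(ds$sequences, system), by = "key")
  tr <- ds$ve$treatments
  instruments <- ds$ve$instruments

  ## source compositions per instrument
  ref_names <- tr$name[is.na(tr$fertilizer)]
  fert_names <- unique(stats::na.omit(tr$fertilizer))
  proc <- collapse_sequences(ds$source_runs, system)
  src_rows <- list(); est <- list()
  for (ins in instruments) {
    ## soil from reference-treatment plants (treatment replicates)
    for (rn in ref_names) {
      sub <- plant[plant$treatment == rn & plant$instrument == ins, ]
      avs <- lapply(seq_len(nrow(sub)), function(i) unclass(ratios_row_to_av(sub[i, ])))
      av <- abundance_vector(Reduce(`+`, avs) / length(avs))
      soil_name <- tr$soil[tr$name == rn][1]
      est[[paste(soil_name, ins, sep = ".")]] <- av
      a67 <- vapply(avs, `[`, numeric(1), "67")
      src_rows[[length(src_rows) + 1L]] <- data.frame(
        source = soil_name, role = "soil", instrument = ins,
        A67_mean = mean(a67),
        A67_ci95 = stats::qt(0.975, length(a67) - 1) * stats::sd(a67) / sqrt(length(a67)),
        ratio_67_66 = ratio_67_66(av), n = length(a67))
    }
    ## fertilizers from processing replicates
    for (fn in fert_names) {
      keys <- grepl(paste0("^", fn, "_proc\\d+_", ins, "$"), proc$key)
      sub <- proc[keys, ]
      avs <- lapply(seq_len(nrow(sub)), function(i) unclass(ratios_row_to_av(sub[i, ])))
      av <- abundance_vector(Reduce(`+`, avs) / length(avs))
      est[[paste(fn, ins, sep = ".")]] <- av
      a67 <- vapply(avs, `[`, numeric(1), "67")
      src_rows[[length(src_rows) + 1L]] <- data.frame(
        source = fn, role = "fertilizer", instrument = ins,
        A67_mean = mean(a67),
        A67_ci95 = stats::qt(0.975, length(a67) - 1) * stats::sd(a67) / sqrt(length(a67)),
        ratio_67_66 = ratio_67_66(av), n = length(a67))
    }
  }
  source_summary <- do.call(rbind, src_rows)

  ## per-replicate Zndf through the mass balance, per instrument
  zrows <- list(); per_rep <- list()
  for (ins in instruments) {
    for (tn in tr$name[!is.na(tr$fertilizer)]) {
      soil_name <- tr$soil[tr$name == tn][1]
      fert_name <- tr$fertilizer[tr$name == tn][1]
      sp <- source_pair(est[[paste(soil_name, ins, sep = ".")]],
                        est[[paste(fert_name, ins, sep = ".")]])
      sub <- plant[plant$treatment == tn & plant$instrument == ins, ]
      sub <- sub[order(sub$replicate), ]
      z <- vapply(sub$R66, function(r) as.numeric(zndf_fertilizer(r, sp)),
                  numeric(1))
      sm <- summarize_treatment(z)
      zrows[[length(zrows) + 1L]] <- data.frame(
        treatment = tn, instrument = ins, true_zndf_pct = 100 * tr$zndf[tr$name == tn][1],
        zndf_mean_pct = sm$mean, zndf_sd = sm$sd,
        ci_lower = sm$ci[1], ci_upper = sm$ci[2], n = sm$n)
      per_rep[[length(per_rep) + 1L]] <- data.frame(
        treatment = tn, instrument = ins, replicate = sub$replicate,
        ratio_67_66 = sub$R66, zndf_pct = z)
    }
  }
  zndf_table <- do.call(rbind, zrows)
  per_replicate <- do.call(rbind, per_rep)

  ## resolution: labeled (fertilizer) vs unlabeled (soil) per instrument,
  ## at the experimental precision of the reference treatment's plants
  res_rows <- list()
  for (ins in instruments) {
    for (rn in ref_names) {
      soil_name <- tr$soil[tr$name == rn][1]
      sub <- plant[plant$treatment == rn & plant$instrument == ins, ]
      prec <- experimental_precision(sub$R66)
      for (fn in fert_names) {
        rr <- resolution_report(
          labeled_ratio = ratio_67_66(est[[paste(fn, ins, sep = ".")]]),
          unlabeled_ratio = ratio_67_66(est[[paste(soil_name, ins, sep = ".")]]),
          precision = prec, range_fraction = range_fraction,
          label = sprintf("%s_vs_%s_%s", fn, soil_name, ins))
        res_rows[[length(res_rows) + 1L]] <- as.data.frame(rr)
      }
    }
  }
  resolution <- do.call(rbind, res_rows)

  ## instrument agreement on per-replicate plant ratios
  ba <- NULL
  if (all(c("Q", "MC") %in% instruments) && !is.null(per_replicate)) {
    wq <- per_replicate[per_replicate$instrument == "Q", ]
    wm <- per_replicate[per_replicate$instrument == "MC", ]
    key <- function(d) paste(d$treatment, d$replicate)
    wm <- wm[match(key(wq), key(wm)), ]
    ba <- bland_altman(wq$ratio_67_66, wm$ratio_67_66)
  }

  structure(list(source_summary = source_summary, zndf_table = zndf_table,
                 resolution = resolution, bland_altman = ba,
                 per_replicate = per_replicate),
            class = "trace_report")
}

#' @export
print.trace_report <- function(x, ...) {
  cat("== Source compositions (measured) ==\n")
  print(x$source_summary, digits = 5, row.names = FALSE)
  cat("\n== Fertilizer-derived Zn fractions ==\n")
  print(x$zndf_table, digits = 4, row.names = FALSE)
  cat("\n== Source resolution ==\n")
  print(x$resolution, digits = 4, row.names = FALSE)
  if (!is.null(x$bland_altman)) {
    cat("\n== Instrument agreement (Q vs MC, plant 67:66) ==\n")
    print(x$bland_altman)
  }
  invisible(x)
}

#' Run the virtual-experiment pipeline from a configuration
#'
#' Simulate, calibrate, unmix, resolve and compare in one call:
#' a deterministic function of the configuration (including its seed).
#' Optionally writes each report table as CSV under `out_dir`.
#'
#' @param config A [run_config()], a list, or a YAML file path.
#' @param out_dir Optional output directory for CSV reports.
#' @return The [analyze_experiment()] report (class `trace_report`), with
#'   the simulated dataset attached as attribute `dataset`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL) {
  config <- run_config(config)
  ve <- config_to_experiment(config)
  ip <- NULL; lvl <- 1
  if (!is.null(config$interference)) {
    fr <- unlist(config$interference$fractions)
    names(fr) <- sub("^A", "", names(fr))
    ip <- interference_profile(fr)
    if (!is.null(config$interference$level)) lvl <- config$interference$level
  }
  ds <- simulate_experiment(ve, ip = ip, matrix_level = lvl,
                            seed = as.integer(config$seed))
  rep <- analyze_experiment(ds, range_fraction = config$range_fraction)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(rep$source_summary,
                     file.path(out_dir, "source_summary.csv"), row.names = FALSE)
    utils::write.csv(rep$zndf_table,
                     file.path(out_dir, "zndf_table.csv"), row.names = FALSE)
    utils::write.csv(rep$resolution,
                     file.path(out_dir, "resolution.csv"), row.names = FALSE)
    if (!is.null(rep$bland_altman))
      utils::write.csv(
        data.frame(bias = rep$bland_altman$bias, sd = rep$bland_altman$sd,
                   loa_lower = rep$bland_altman$loa[1],
                   loa_upper = rep$bland_altman$loa[2],
                   n = rep$bland_altman$n),
        file.path(out_dir, "bland_altman.csv"), row.names = FALSE)
  }
  attr(rep, "dataset") <- ds
  rep
}

#' Summary statistics of literature fertilizer-derived fractions
#'
#' Mean, median, count and the share of values above 50% for a collection
#' of fertilizer-derived Zn fractions, e.g. compiled from published source
#' tracing studies.
#'
#' @param zndf_values Numeric vector of Zndf values in percent (0-100).
#' @return List with `mean`, `median`, `n`, `share_above_50_pct`.
#' @export
summarize_literature <- function(zndf_values) {
  x <- as.numeric(zndf_values)
  stopifnot(length(x) >= 1L, all(is.finite(x)), all(x >= 0), all(x <= 100))
  list(mean = mean(x), median = stats::median(x), n = length(x),
       share_above_50_pct = 100 * mean(x > 50))
}
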