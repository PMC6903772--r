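# shared fixtures: a worked source pair and small builders

# soil/fertilizer pair whose 66/67 abundances give plant_ratio(0.3) = 14.9/23.3
fix_sources <- function() {
  source_pair(
    soil = abundance_vector(c(`64` = 49.17, `66` = 27.5, `67` = 8.0,
                              `68` = 14.72, `70` = 0.61)),
    fertilizer = abundance_vector(c(`64` = 40.0, `66` = 13.5, `67` = 31.0,
                                    `68` = 14.89, `70` = 0.61)))
}

# random valid abundance vector (all entries strictly positive)
rand_av <- function() {
  x <- stats::runif(5, 0.1, 50)
  names(x) <- c("64", "66", "67", "68", "70")
  abundance_vector(100 * x / sum(x))
}

# random resolvable source pair
rand_pair <- function(min_sep = 0.02) {
  repeat {
    s <- rand_av(); f <- rand_av()
    if (abs(ratio_67_66(f) - ratio_67_66(s)) > min_sep)
      return(source_pair(s, f))
  }
}

# a noise-free instrument profile (RSDs cannot be exactly zero by contract,
# so use a negligible value) with optional bias/drift
quiet_profile <- function(name = "Q", bias0 = 1, drift = 0) {
  rsd <- c(`64` = 1e-14, `66` = 1e-14, `68` = 1e-14, `70` = 1e-14)
  instrument_profile(name, ratio_rsd = rsd, bias0 = bias0, drift = drift)
}

# bracketed sequence around one sample run, standards collapsed to means
bracketed_events <- function(run, std0, std1, t_sam, sample_id = "s") {
  mean_row <- function(r, t) data.frame(
    time = t, kind = "standard", sample_id = NA_character_,
    R64 = mean(r$R64), R66 = mean(r$R66),
    R68 = mean(r$R68), R70 = mean(r$R70))
  rbind(mean_row(std0, 0),
        data.frame(time = t_sam, kind = "sample", sample_id = sample_id,
                   R64 = run$R64, R66 = run$R66,
                   R68 = run$R68, R70 = run$R70),
        mean_row(std1, 2))
}
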