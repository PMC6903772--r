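sys <- zn_isotope_system()

test_that("sequence construction enforces bracketing and time ordering", {
  std <- data.frame(time = c(0, 2), kind = "standard", sample_id = NA,
                    R64 = 0.08, R66 = 0.15, R68 = 0.22, R70 = 6.6)
  sam <- data.frame(time = 1, kind = "sample", sample_id = "s",
                    R64 = 0.08, R66 = 0.15, R68 = 0.22, R70 = 6.6)
  expect_s3_class(bracketing_sequence(rbind(std[1, ], sam, std[2, ]),
                                      sys$natural),
                  "bracketing_sequence")
  # sample after the last standard
  late <- sam; late$time <- 3
  expect_error(bracketing_sequence(rbind(std[1, ], std[2, ], late),
                                   sys$natural), "unbracketed")
  # non-increasing times
  dup <- rbind(std[1, ], sam, sam, std[2, ])
  expect_error(bracketing_sequence(dup, sys$natural), "strictly increasing")
})

test_that("standard measured at its true ratios fits a unit bias factor", {
  true_rs <- unclass(ratios_from_abundances(sys$natural))
  ev <- data.frame(time = c(0, 1, 2),
                   kind = c("standard", "sample", "standard"),
                   sample_id = c(NA, "s", NA),
                   R64 = unname(true_rs["64"]), R66 = unname(true_rs["66"]),
                   R68 = unname(true_rs["68"]), R70 = unname(true_rs["70"]))
  model <- fit_bracketing(bracketing_sequence(ev, sys$natural), sys)
  expect_equal(bias_factor(model, c(0, 0.5, 2)), rep(1, 3), tolerance = 1e-14)
  # correcting the standard itself returns its true ratios (self-consistency)
  raw <- ratio_set(true_rs)
  expect_equal(unclass(correct_ratios(raw, model, 1, sys)), true_rs,
               tolerance = 1e-14)
})

test_that("per-amu factor follows the closed form and corrects a raw ratio", {
  # standard's 67:66 measured 0.150000 against true 0.145691: the per-amu
  # bias obeys b^dm = 0.150/0.145691, and any raw 67:66 is corrected by
  # division with b^dm, e.g. 0.300000 -> 0.291382
  true66 <- 4.04 / 27.73
  fake <- true66 / 0.145691 * 0.150000  # measured value scaled to true base
  dm <- sys$masses["67"] - sys$masses["66"]
  ev <- data.frame(time = c(0, 1, 2),
                   kind = c("standard", "sample", "standard"),
                   sample_id = c(NA, "s", NA),
                   R64 = 0.09, R66 = fake, R68 = 0.24, R70 = 7)
  model <- fit_bracketing(bracketing_sequence(ev, sys$natural), sys)
  b <- bias_factor(model, 1)
  expect_equal(unname(b), unname((fake / true66)^(1 / dm)), tolerance = 1e-12)
  expect_equal(unname(b^dm), 0.150000 / 0.145691, tolerance = 1e-5)
  raw <- ratio_set(c(`64` = 0.09, `66` = 0.300000, `68` = 0.24, `70` = 7))
  corr <- correct_ratios(raw, model, 1, sys)
  expect_equal(unname(unclass(corr)["66"]), 0.291382, tolerance = 1e-4)
})

test_that("bias factor interpolates linearly between bracketing standards", {
  true_rs <- unclass(ratios_from_abundances(sys$natural))
  dm <- unname(sys$masses["67"] - sys$masses["66"])
  mk <- function(b) true_rs * b^c(sys$masses["67"] - sys$masses[c("64", "66", "68", "70")])
  r0 <- mk(1.02); r1 <- mk(1.04)
  ev <- data.frame(time = c(0, 1, 2),
                   kind = c("standard", "sample", "standard"),
                   sample_id = c(NA, "s", NA),
                   R64 = c(r0["64"], 0.09, r1["64"]),
                   R66 = c(r0["66"], 0.15, r1["66"]),
                   R68 = c(r0["68"], 0.22, r1["68"]),
                   R70 = c(r0["70"], 7.0, r1["70"]))
  model <- fit_bracketing(bracketing_sequence(ev, sys$natural), sys)
  expect_equal(bias_factor(model, 0), 1.02, tolerance = 1e-12)
  expect_equal(bias_factor(model, 2), 1.04, tolerance = 1e-12)
  expect_equal(bias_factor(model, 1), 1.03, tolerance = 1e-12)   # midpoint
  expect_error(bias_factor(model, 2.5), "envelope")
})

test_that("correction inverts a linearly drifting bias exactly (zero noise)", {
  sp <- fix_sources()
  true_av <- abundance_vector(0.3 * unclass(sp$fertilizer) +
                              0.7 * unclass(sp$soil))
  true_rs <- unclass(ratios_from_abundances(true_av))
  for (nm in c("Q", "MC")) {
    pr <- quiet_profile(nm, bias0 = 1.03, drift = 5e-3)
    n_rows <- if (nm == "Q") pr$repeats else pr$blocks
    t_sam <- seq_len(n_rows) / (n_rows + 1) * 2
    run <- simulate_measurement(true_av, pr, t = t_sam, seed = 1)
    std0 <- simulate_measurement(sys$natural, pr, t = 0, seed = 2)
    std1 <- simulate_measurement(sys$natural, pr, t = 2, seed = 3)
    seq <- bracketing_sequence(bracketed_events(run, std0, std1, t_sam),
                               sys$natural)
    sam <- correct_sequence(seq, sys)
    got <- cbind(sam$R64, sam$R66, sam$R68, sam$R70)
    expect_lt(max(abs(got / rep(true_rs, each = n_rows) - 1)), 1e-10)
  }
})

test_that("correction commutes with dropping a ratio from the set", {
  true_rs <- unclass(ratios_from_abundances(sys$natural))
  mk <- function(b) true_rs * b^c(sys$masses["67"] - sys$masses[c("64", "66", "68", "70")])
  r0 <- mk(1.03)
  ev <- data.frame(time = c(0, 1, 2),
                   kind = c("standard", "sample", "standard"),
                   sample_id = c(NA, "s", NA),
                   R64 = unname(r0["64"]), R66 = unname(r0["66"]),
                   R68 = unname(r0["68"]), R70 = unname(r0["70"]))
  model <- fit_bracketing(bracketing_sequence(ev, sys$natural), sys)
  raw <- ratio_set(c(`64` = 0.09, `66` = 0.16, `68` = 0.23, `70` = 7))
  full <- unclass(correct_ratios(raw, model, 1, sys))
  # correcting is per-ratio: each corrected entry is independent of the others
  for (d in c("64", "66", "68", "70")) {
    dm <- sys$masses["67"] - sys$masses[d]
    expect_equal(unname(full[d]),
                 unname(unclass(raw)[d] / bias_factor(model, 1)^dm),
                 tolerance = 1e-14)
  }
})

test_that("joint (all-ratio) bias estimation agrees when bias is per-amu", {
  true_rs <- unclass(ratios_from_abundances(sys$natural))
  mk <- function(b) true_rs * b^c(sys$masses["67"] - sys$masses[c("64", "66", "68", "70")])
  r0 <- mk(1.025)
  ev <- data.frame(time = c(0, 1, 2),
                   kind = c("standard", "sample", "standard"),
                   sample_id = c(NA, "s", NA),
                   R64 = unname(r0["64"]), R66 = unname(r0["66"]),
                   R68 = unname(r0["68"]), R70 = unname(r0["70"]))
  seqb <- bracketing_sequence(ev, sys$natural)
  m1 <- fit_bracketing(seqb, sys, joint = FALSE)
  m2 <- fit_bracketing(seqb, sys, joint = TRUE)
  expect_equal(bias_factor(m1, 1), bias_factor(m2, 1), tolerance = 1e-10)
})

test_that("sequence CSV round-trips", {
  true_rs <- unclass(ratios_from_abundances(sys$natural))
  ev <- data.frame(time = c(0, 1, 2),
                   kind = c("standard", "sample", "standard"),
                   sample_id = c(NA, "s", NA),
                   R64 = unname(true_rs["64"]), R66 = unname(true_rs["66"]),
                   R68 = unname(true_rs["68"]), R70 = unname(true_rs["70"]))
  seqb <- bracketing_sequence(ev, sys$natural)
  path <- withr::local_tempfile(fileext = ".csv")
  write_sequence(seqb, path)
  back <- read_sequence(path, sys$natural)
  expect_equal(back$events$R66, seqb$events$R66, tolerance = 1e-12)
  expect_equal(back$events$kind, seqb$events$kind)
})
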