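test_that("isotope system carries IUPAC abundances that close to 100%", {
  sys <- zn_isotope_system()
  expect_equal(sum(unclass(sys$natural)), 100, tolerance = 1e-12)
  expect_equal(unname(unclass(sys$natural)["67"]), 4.04)
  expect_true(all(diff(sys$masses) > 0))
  expect_error(zn_isotope_system(reference = 65), "mass numbers")
})

test_that("abundance vector validates, normalizes and rejects bad input", {
  a <- abundance_vector(c(`64` = 20, `66` = 20, `67` = 20, `68` = 20, `70` = 20))
  expect_s3_class(a, "abundance_vector")
  expect_identical(sum(unclass(a)), 100)
  expect_error(abundance_vector(c(`64` = 50, `66` = 50)), "named")
  expect_error(abundance_vector(c(`64` = 99, `66` = 1, `67` = -1,
                                  `68` = 0.5, `70` = 0.5)), ">= 0")
  expect_error(abundance_vector(c(`64` = 50, `66` = 30, `67` = 4,
                                  `68` = 18, `70` = 1)), "sum")
})

test_that("ratios from IUPAC abundances and back reproduce the printed values", {
  sys <- zn_isotope_system()
  rs <- ratios_from_abundances(sys$natural)
  expect_equal(unname(unclass(rs)["66"]), 4.04 / 27.73)   # 0.145691...
  av <- abundances_from_ratios(rs)
  expect_equal(unclass(av), unclass(sys$natural), tolerance = 1e-12)
  expect_equal(unname(unclass(av)["67"]), 4.04, tolerance = 1e-12)
})

test_that("all-ones ratio set maps to the uniform composition and back", {
  rs <- ratio_set(c(`64` = 1, `66` = 1, `68` = 1, `70` = 1))
  av <- abundances_from_ratios(rs)
  expect_equal(unname(unclass(av)), rep(20, 5))
  expect_equal(as.numeric(unclass(ratios_from_abundances(av))), rep(1, 4))
})

test_that("abundance<->ratio round trip is the identity on random vectors", {
  set.seed(11)
  for (i in 1:100) {
    av <- rand_av()
    back <- abundances_from_ratios(ratios_from_abundances(av))
    expect_equal(unclass(back), unclass(av), tolerance = 1e-12)
  }
})

test_that("ratio set construction rejects incomplete or nonpositive input", {
  expect_error(ratio_set(c(`64` = 1, `66` = 1, `68` = 1)), "denominator")
  expect_error(ratio_set(c(`64` = 1, `66` = -0.1, `68` = 1, `70` = 1)), "> 0")
  bad <- abundance_vector(c(`64` = 50, `66` = 30, `67` = 0, `68` = 19, `70` = 1))
  expect_error(ratios_from_abundances(bad), "reference isotope abundance")
})

test_that("forward mixing model matches hand arithmetic and endpoints", {
  sp <- fix_sources()
  expect_equal(plant_ratio(0.30, sp), 14.9 / 23.3)          # 0.639485
  expect_equal(plant_ratio(0, sp), 8.0 / 27.5)
  expect_equal(plant_ratio(1, sp), 31.0 / 13.5)
  expect_error(plant_ratio(1.2, sp))
})

test_that("plant ratio is strictly monotonic between the source ratios", {
  set.seed(21)
  for (i in 1:20) {
    sp <- rand_pair()
    f <- seq(0, 1, length.out = 41)
    r <- vapply(f, plant_ratio, numeric(1), sources = sp)
    dir <- sign(ratio_67_66(sp$fertilizer) - ratio_67_66(sp$soil))
    expect_true(all(dir * diff(r) > 0))
  }
})

test_that("mass-balance inversion recovers the mixing fraction", {
  sp <- fix_sources()
  expect_equal(as.numeric(zndf_fertilizer(0.639485, sp)), 30, tolerance = 1e-4)
  # forward-inverse identity over a grid and random pairs
  set.seed(31)
  for (i in 1:20) {
    spr <- rand_pair()
    for (f in seq(0, 1, length.out = 21)) {
      z <- zndf_fertilizer(plant_ratio(f, spr), spr)
      expect_equal(as.numeric(z), 100 * f, tolerance = 1e-10)
    }
  }
})

test_that("endpoint ratios give exactly 0 and 100 percent", {
  set.seed(41)
  for (i in 1:20) {
    sp <- rand_pair()
    expect_identical(as.numeric(zndf_fertilizer(plant_ratio(0, sp), sp)), 0)
    expect_identical(as.numeric(zndf_fertilizer(plant_ratio(1, sp), sp)), 100)
  }
})

test_that("fertilizer and soil fractions always close the mass balance", {
  sp <- fix_sources()
  sm <- summarize_treatment(c(20.5, 21.5, 19.5, 22.5))
  expect_identical(sm$zndf_fertilizer_pct + sm$zndf_soil_pct, 100)
})

test_that("out-of-range estimates are flagged, not rejected", {
  sp <- fix_sources()
  r_beyond <- plant_ratio(1, sp) * 1.5   # beyond the fertilizer endpoint
  expect_warning(z <- zndf_fertilizer(r_beyond, sp), "outside admissible")
  expect_true(attr(z, "out_of_range"))
  z_ok <- zndf_fertilizer(plant_ratio(0.5, sp), sp)
  expect_false(attr(z_ok, "out_of_range"))
})

test_that("unresolvable source pairs are rejected at construction", {
  a <- abundance_vector(c(`64` = 49.17, `66` = 27.73, `67` = 4.04,
                          `68` = 18.45, `70` = 0.61))
  expect_error(source_pair(a, a), "unresolvable")
  b <- abundance_vector(c(`64` = 49.0, `66` = 27.73, `67` = 4.1,
                          `68` = 18.56, `70` = 0.61))
  # separation ~0.002 in 67:66; a 10x-precision floor of 0.05 rejects it
  expect_error(source_pair(a, b, min_separation = 0.05), "unresolvable")
  expect_s3_class(source_pair(a, b), "source_pair")
})

test_that("treatment summary gives t-based CI and rejects single replicates", {
  sm <- summarize_treatment(c(10, 12, 11, 13))
  expect_equal(sm$mean, 11.5)
  expect_equal(sm$sd, 1.29099, tolerance = 1e-5)
  expect_equal(sm$ci, 11.5 + c(-1, 1) * qt(0.975, 3) * sm$sd / 2,
               tolerance = 1e-12)
  sm0 <- summarize_treatment(c(20, 20, 20, 20))
  expect_equal(sm0$mean, 20)
  expect_equal(diff(sm0$ci), 0)
  expect_error(summarize_treatment(42), "insufficient replication")
})

test_that("source CSV round-trips through read/write", {
  sp <- fix_sources()
  path <- withr::local_tempfile(fileext = ".csv")
  write_sources(list(soil1 = sp$soil, fert1 = sp$fertilizer),
                c("soil", "fertilizer"), path)
  back <- read_sources(path)
  expect_equal(unclass(back$soil1), unclass(sp$soil), tolerance = 1e-12)
  expect_equal(unclass(back$fert1), unclass(sp$fertilizer), tolerance = 1e-12)
  expect_equal(unname(attr(back, "roles")), c("soil", "fertilizer"))
})
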