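## abundance-weighted atomic mass (g/mol) of a Zn pool
atomic_mass <- function(av, system = zn_isotope_system()) {
  stopifnot(inherits(av, "abundance_vector"))
  sum(unclass(av) * system$masses) / 100
}

#' Mix two Zn pools in molar isotope space
#'
#' Each component is converted to moles through its abundance-weighted
#' atomic mass (enriched spikes have materially different atomic weights
#' than natural Zn), per-isotope mole amounts add, and the result is
#' renormalized to mole-fraction percent. Conserves the total moles of each
#' isotope exactly.
#'
#' @param mass_a,mass_b Masses of the two components (same mass unit, e.g.
#'   mg); non-negative, not both zero.
#' @param av_a,av_b [abundance_vector()]s of the two components.
#' @param system Isotope system (atomic masses).
#' @return [abundance_vector()] of the mixture.
#' @export
mix_abundances <- function(mass_a, av_a, mass_b, av_b,
                           system = zn_isotope_system()) {
  stopifnot(mass_a >= 0, mass_b >= 0)
  if (mass_a == 0 && mass_b == 0)
    stop("both component masses are zero; mixture undefined")
  na <- mass_a / atomic_mass(av_a, system)
  nb <- mass_b / atomic_mass(av_b, system)
  iso <- na * unclass(av_a) / 100 + nb * unclass(av_b) / 100
  abundance_vector(100 * iso / sum(iso))
}

#' Spike mass needed to drive a soil pool to a target 67:66 ratio
#'
#' For indirect labeling, solves the one-unknown molar mixing equation for
#' the mass of an enriched spike that brings the soil-available Zn pool's
#' 67:66 ratio to a target value. With pool moles n_p and spike abundances
#' A67s/A66s, the spike moles are
#' n_s = n_p (T A66p - A67p) / (A67s - T A66s); the target must lie
#' strictly between the pool's and the spike's own ratios (reaching the
#' spike's ratio would take an infinite addition). The plan records the
#' resulting relative increase of the pool and is flagged infeasible when
#' that exceeds `max_increase_pct` — adding so much Zn that the available
#' pool itself is altered defeats the labeling.
#'
#' @param pool_zn Size of the soil-available Zn pool (mg Zn per kg soil).
#' @param pool_av,spike_av [abundance_vector()]s of pool and spike.
#' @param target_ratio_67_66 Desired 67:66 ratio of the labeled pool.
#' @param system Isotope system.
#' @param max_increase_pct Largest acceptable pool increase in % (default
#'   Inf; no community-endorsed threshold exists, so it is a user choice).
#' @return Object of class `spike_plan`: pool/spike definitions, computed
#'   `spike_mass` (mg per kg soil), `pool_increase_pct`, `achieved_av`,
#'   `feasible`.
#' @export
spike_mass_for_target <- function(pool_zn, pool_av, spike_av,
                                  target_ratio_67_66,
                                  system = zn_isotope_system(),
                                  max_increase_pct = Inf) {
  stopifnot(pool_zn > 0, inherits(pool_av, "abundance_vector"),
            inherits(spike_av, "abundance_vector"),
            is.numeric(target_ratio_67_66), target_ratio_67_66 > 0)
  r_pool <- ratio_67_66(pool_av)
  r_spike <- ratio_67_66(spike_av)
  T <- target_ratio_67_66
  ## target must lie in [pool, spike), moving from pool towards spike
  inside <- (T >= min(r_pool, r_spike)) && (T <= max(r_pool, r_spike)) &&
    (T != r_spike || T == r_pool)
  if (!inside)
    stop(sprintf(paste0("infeasible target: 67:66 = %.4g is not inside ",
                        "[pool %.4g, spike %.4g)"), T, r_pool, r_spike))
  p <- unclass(pool_av); s <- unclass(spike_av)
  n_p <- pool_zn / atomic_mass(pool_av, system)
  n_s <- n_p * (T * p["66"] - p["67"]) / (s["67"] - T * s["66"])
  n_s <- unname(n_s)
  if (n_s < 0) stop("infeasible target: negative spike amount")
  spike_mass <- n_s * atomic_mass(spike_av, system)
  achieved <- if (spike_mass == 0) pool_av else
    mix_abundances(pool_zn, pool_av, spike_mass, spike_av, system)
  increase <- 100 * spike_mass / pool_zn
  structure(list(pool_zn = pool_zn, pool_av = pool_av, spike_av = spike_av,
                 target_ratio_67_66 = T, spike_mass = spike_mass,
                 pool_increase_pct = increase, achieved_av = achieved,
                 max_increase_pct = max_increase_pct,
                 feasible = increase <= max_increase_pct),
            class = "spike_plan")
}

#' @export
print.spike_plan <- function(x, ...) {
  cat(sprintf("Spike plan: reach 67:66 = %.4f from %.4f (spike at %.4f)\n",
              x$target_ratio_67_66, ratio_67_66(x$pool_av),
              ratio_67_66(x$spike_av)))
  cat(sprintf("  spike mass         %.4g mg per kg soil\n", x$spike_mass))
  cat(sprintf("  pool increase      %.3g%% of %.3g mg/kg (max %.3g%%) -> %s\n",
              x$pool_increase_pct, x$pool_zn, x$max_increase_pct,
              if (x$feasible) "feasible" else "INFEASIBLE"))
  invisible(x)
}

#' Tabulate spike plans against an experimental precision
#'
#' For each plan: the enrichment its target creates over the natural 67:66
#' ratio, the number of statistically distinguishable ratios at the given
#' precision, the smallest detectable contribution, the pool increase and
#' the feasibility flag.
#'
#' @param plans List of [spike_mass_for_target()] plans (may be empty).
#' @param precision Experimental precision (2sd of the 67:66 ratio).
#' @param reference_ratio Unlabeled reference ratio (default: IUPAC natural
#'   67:66).
#' @return data.frame, one row per plan.
#' @export
design_report <- function(plans, precision,
                          reference_ratio = ratio_67_66(zn_isotope_system()$natural)) {
  if (length(plans) == 0L)
    return(data.frame(target_ratio = numeric(), enrichment = numeric(),
                      n_distinguishable = integer(),
                      detectable_contribution_pct = numeric(),
                      spike_mass = numeric(), pool_increase_pct = numeric(),
                      feasible = logical()))
  stopifnot(all(vapply(plans, inherits, TRUE, "spike_plan")))
  rows <- lapply(plans, function(pl) {
    e <- enrichment(pl$target_ratio_67_66, reference_ratio)
    n <- distinguishable_ratios(e, precision)
    data.frame(target_ratio = pl$target_ratio_67_66, enrichment = e,
               n_distinguishable = n,
               detectable_contribution_pct =
                 if (n >= 1) detectable_contribution(n) else NA_real_,
               spike_mass = pl$spike_mass,
               pool_increase_pct = pl$pool_increase_pct,
               feasible = pl$feasible)
  })
  do.call(rbind, rows)
}
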