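#' Transition-state-theory conversions
#'
#' `eyring_rate()` converts an activation free energy into a first-order
#' rate constant, `k = (k_B T / h) exp(-dG / RT)` with unit transmission
#' coefficient; `eyring_barrier()` inverts it. At 310.15 K the prefactor
#' `k_B T / h` is 6.462e12 s^-1.
#'
#' @param dg_kcal Activation free energy, kcal mol^-1.
#' @param temperature Temperature, K.
#' @return Rate constant in s^-1 (or barrier in kcal mol^-1).
#' @examples
#' eyring_rate(17.0)              # ~6.8 s^-1
#' eyring_barrier(7.85)           # ~16.9 kcal/mol
#' @export
eyring_rate <- function(dg_kcal, temperature = spla2_constants$temperature_K) {
  if (temperature <= 0) stop("validation error: temperature must be > 0",
                             call. = FALSE)
  prefactor(temperature) * exp(-dg_kcal / rt_kcal(temperature))
}

#' @rdname eyring_rate
#' @param k Rate constant, s^-1.
#' @export
eyring_barrier <- function(k, temperature = spla2_constants$temperature_K) {
  if (any(k <= 0)) stop("validation error: rate must be > 0", call. = FALSE)
  if (temperature <= 0) stop("validation error: temperature must be > 0",
                             call. = FALSE)
  rt_kcal(temperature) * log(prefactor(temperature) / k)
}

prefactor <- function(temperature) {
  spla2_constants$kB_J * temperature / spla2_constants$h_J
}

#' Catalytic rate constant from a specific activity
#'
#' Converts an interfacial-assay specific activity (umol of substrate per
#' minute per mg of enzyme) into a per-enzyme turnover number,
#' `k_cat = sa * M / 60` with `M` the enzyme molar mass in kg mol^-1.
#'
#' @param sa_umol_min_mg Specific activity, umol min^-1 mg^-1.
#' @param molar_mass_kg_mol Enzyme molar mass, kg mol^-1 (13.9 for mature
#'   human group IIA sPLA2).
#' @return k_cat in s^-1.
#' @examples
#' kcat_from_specific_activity(33.9, 13.9)   # ~7.85 s^-1
#' @export
kcat_from_specific_activity <- function(sa_umol_min_mg,
                                        molar_mass_kg_mol = 13.9) {
  if (sa_umol_min_mg <= 0 || molar_mass_kg_mol <= 0) {
    stop("validation error: inputs must be > 0", call. = FALSE)
  }
  # umol/min/mg -> mol/s/g (1e-6 / 60 * 1e3), times g/mol (M_kg * 1e3)
  sa_umol_min_mg * molar_mass_kg_mol / 60
}

#' One pathway's population, barrier and rate
#'
#' @param name Pathway label.
#' @param population Fraction of the reactant ensemble in this pathway's
#'   productive conformation, in `[0, 1]`.
#' @param barrier Activation free energy, kcal mol^-1.
#' @param temperature Temperature, K.
#' @return One-row tibble with the Eyring `rate` (s^-1) and the
#'   population-weighted `effective_rate`.
#' @export
pathway_kinetics <- function(name, population, barrier,
                             temperature = spla2_constants$temperature_K) {
  stopifnot(population >= 0, population <= 1)
  rate <- eyring_rate(barrier, temperature)
  tibble::tibble(name = name, population = population, barrier = barrier,
                 temperature = temperature, rate = rate,
                 effective_rate = population * rate)
}

#' Population-weighted comparison of two reaction pathways
#'
#' Each pathway's effective rate is `p_i * (k_B T / h) exp(-dG_i / RT)`;
#' the comparison reports the fast/slow rate ratio, the corresponding
#' effective barrier difference `ddG = RT ln(ratio)`, and its exact
#' decomposition into a population factor `RT ln(p_fast / p_slow)` and a
#' barrier factor `dG_slow - dG_fast`.
#'
#' @param paths Tibble of two [pathway_kinetics()] rows (rbind them), or a
#'   list of two such tibbles.
#' @return Object of class `pathway_comparison`: list with `fast`, `slow`
#'   (names), `ratio`, `ratio_1sf` (one significant figure, how such
#'   ratios are usually quoted), `ddg`, `population_term`, `barrier_term`,
#'   `temperature`, `infinite` (flag when a population is zero).
#' @examples
#' paths <- rbind(pathway_kinetics("single_water", 0.75, 17.0),
#'                pathway_kinetics("assisting_water", 0.04, 19.0))
#' compare_pathways(paths)
#' @export
compare_pathways <- function(paths) {
  if (is.list(paths) && !is.data.frame(paths)) {
    paths <- dplyr::bind_rows(paths)
  }
  if (nrow(paths) != 2) {
    stop("compare_pathways expects exactly 2 pathways", call. = FALSE)
  }
  if (length(unique(paths$temperature)) != 1) {
    stop("pathways must share one temperature", call. = FALSE)
  }
  temperature <- paths$temperature[1]
  rt <- rt_kcal(temperature)
  infinite <- any(paths$population == 0)
  i_fast <- which.max(paths$effective_rate)
  i_slow <- setdiff(1:2, i_fast)
  ratio <- paths$effective_rate[i_fast] / paths$effective_rate[i_slow]
  pop_term <- rt * log(paths$population[i_fast] / paths$population[i_slow])
  bar_term <- paths$barrier[i_slow] - paths$barrier[i_fast]
  structure(list(
    fast = paths$name[i_fast], slow = paths$name[i_slow],
    ratio = ratio,
    ratio_1sf = signif(ratio, 1),
    ddg = if (infinite) Inf else rt * log(ratio),
    population_term = pop_term,
    barrier_term = bar_term,
    temperature = temperature,
    infinite = infinite,
    paths = paths
  ), class = "pathway_comparison")
}

#' @export
print.pathway_comparison <- function(x, ...) {
  cat("Pathway comparison at", x$temperature, "K\n")
  cat(sprintf("  %s is %.3g-fold (~%g) faster than %s\n",
              x$fast, x$ratio, x$ratio_1sf, x$slow))
  cat(sprintf("  effective ddG  = %+.2f kcal/mol\n", x$ddg))
  cat(sprintf("    population term %+.2f, barrier term %+.2f kcal/mol\n",
              x$population_term, x$barrier_term))
  invisible(x)
}
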