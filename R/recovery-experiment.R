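#' Correction-factor recovery experiment
#'
#' The package's standard validation of the quantitation pipeline: a fully
#' synthetic calibration set with known truth is built and the genetic
#' algorithm is asked to recover the factors. Fifteen bee genera (the five
#' with published correction factors — Hylaeus 1x, Hoplitis 14.9x,
#' Lasioglossum 30.0x, Megachile 124.5x, Bombus 1,248x — plus ten more with
#' plausible factors) and a two-leg beetle calibrator are simulated over
#' `n_samples` concordant samples with observed read proportions set exactly
#' to the forward model, so the normalized truth is recoverable up to the
#' optimizer's precision.
#'
#' @param n_samples Number of concordant calibration samples.
#' @param population_size,iterations,mutation_genes Passed to [ga_run()].
#' @param seed Integer seed driving both the simulation (`seed`) and the
#'   optimizer (`seed + 1`).
#' @return A list: `fit` (the [ga_run()] result), `truth` (true factors),
#'   `truth_normalized`, `recovered` (normalized estimates), and `comparison`
#'   (tibble with per-taxon relative error).
#' @export
factor_recovery_experiment <- function(n_samples = 15, population_size = 1000,
                                       iterations = 1e5, mutation_genes = 1,
                                       seed = 1) {
  profiles <- bee_taxon_profiles(15)
  sim <- simulate_concordant_calibration(profiles, n_samples = n_samples,
                                         dispersion = 2,
                                         calibrator_factor = 50, seed = seed)
  fit <- ga_run(sim$calibration, population_size = population_size,
                iterations = iterations, mutation_genes = mutation_genes,
                seed = seed + 1)
  truth_norm <- normalize_factors(sim$truth)
  comparison <- tibble::tibble(
    taxon = fit$taxa,
    truth = unname(truth_norm[fit$taxa]),
    recovered = unname(fit$best_normalized),
    relative_error = abs(recovered - truth) / truth
  )
  list(fit = fit, truth = sim$truth, truth_normalized = truth_norm,
       recovered = fit$best_normalized, comparison = comparison)
}
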