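#' Build a table of taxon simulation profiles
#'
#' A profile row drives the simulator for one taxon: its true copy-number
#' correction factor (the per-specimen read-mass multiplier combining rRNA
#' copies per haploid genome, genomes per cell and cells per leg), its mean
#' per-trap abundance, the negative-binomial dispersion (`size`; variance
#' `m + m^2/size`), and optional per-location abundance multipliers.
#'
#' @param taxon_id Character vector of taxon labels.
#' @param true_factor Positive true correction factors (fold units), recycled.
#' @param mean_abundance Non-negative mean specimens per trap, recycled.
#' @param dispersion Positive negative-binomial size parameter, recycled.
#' @param location_effects Optional list (recycled) of named numeric vectors of
#'   per-location abundance multipliers; locations absent from a vector get 1.
#' @return A tibble with one row per taxon.
#' @export
taxon_profiles <- function(taxon_id, true_factor = 1, mean_abundance = 3,
                           dispersion = 1, location_effects = NULL) {
  stopifnot(length(taxon_id) >= 1, !anyDuplicated(taxon_id))
  n <- length(taxon_id)
  tf <- rep_len(true_factor, n)
  ma <- rep_len(mean_abundance, n)
  dp <- rep_len(dispersion, n)
  if (any(tf <= 0)) abort("true_factor must be positive")
  if (any(ma < 0)) abort("mean_abundance must be non-negative")
  if (any(dp <= 0)) abort("dispersion must be positive")
  le <- if (is.null(location_effects)) {
    rep_len(list(NULL), n)
  } else if (is.list(location_effects) && !is.numeric(location_effects[[1]]) ||
             is.list(location_effects) && all(vapply(location_effects, is.numeric, logical(1)))) {
    rep_len(location_effects, n)
  } else {
    rep_len(list(location_effects), n)
  }
  tibble::tibble(
    taxon_id = as.character(taxon_id),
    true_factor = tf,
    mean_abundance = ma,
    dispersion = dp,
    location_effects = le
  )
}

#' Default bee community profiles
#'
#' A ready-made community of bee genera for simulation. The first fifteen taxa
#' are common prairie bee genera; correction factors span roughly 1- to
#' 1,250-fold, with the four most frequently trapped genera (Agapostemon,
#' Bombus, Hylaeus, Lasioglossum) given the highest mean abundances, matching
#' the frequency structure typical of grassland vane-trap catches. Taxa beyond
#' the named genera are filled in with generic labels, moderate factors and
#' low abundances (the long tail of rarely caught taxa).
#'
#' @param n_taxa Number of taxa (>= 1). The default 56 emulates a full
#'   season's morphotaxon catalogue.
#' @param seed Integer seed for the generated long-tail factors/abundances.
#' @return A profile tibble (see [taxon_profiles()]).
#' @export
bee_taxon_profiles <- function(n_taxa = 56, seed = 101) {
  named <- tibble::tibble(
    taxon_id = c("Hylaeus", "Hoplitis", "Lasioglossum", "Megachile", "Bombus",
                 "Agapostemon", "Andrena", "Ceratina", "Melissodes", "Osmia",
                 "Augochlorella", "Halictus", "Eucera", "Svastra", "Nomada"),
    true_factor = c(1, 14.9, 30, 124.5, 1248, 6, 12, 45, 80, 200, 350, 2.5, 60, 500, 8),
    mean_abundance = c(15, 4, 15, 3, 8, 12, 3, 2, 2, 1.5, 1.5, 3, 1.5, 1, 2)
  )
  named <- named[seq_len(min(n_taxa, nrow(named))), ]
  extra <- n_taxa - nrow(named)
  if (extra > 0) {
    tail_tbl <- withr::with_seed(seed, tibble::tibble(
      taxon_id = sprintf("Taxon%02d", nrow(named) + seq_len(extra)),
      true_factor = round(exp(stats::runif(extra, log(1.5), log(600))), 1),
      mean_abundance = round(exp(stats::runif(extra, log(0.3), log(2))), 2)
    ))
    named <- dplyr::bind_rows(named, tail_tbl)
  }
  taxon_profiles(named$taxon_id, named$true_factor, named$mean_abundance,
                 dispersion = 1)
}

#' Calibrator spike-in profile
#'
#' The inter-sample control: a beetle taxon whose legs are added to every
#' pool in a fixed, known number (two by default), providing an internal
#' abundance anchor for correction-factor estimation.
#'
#' @param true_factor Correction factor assigned to the calibrator tissue.
#' @return A one-row profile tibble with `taxon_id = "Tenebrio"`.
#' @export
calibrator_profile <- function(true_factor = 50) {
  taxon_profiles("Tenebrio", true_factor = true_factor, mean_abundance = 0,
                 dispersion = 1)
}
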