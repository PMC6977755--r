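#' Describe a pooled-trap sampling design
#'
#' A study design records how specimen pools ("community tubes") arise in the
#' field: every combination of management type, location and sampling date
#' yields one pooled sample, with the vane traps at a site pooled within a
#' date. The default mirrors a two-management, four-location, 28-date season
#' (224 community pools).
#'
#' @param management_types Character vector of management regime labels.
#' @param locations Character vector of location labels.
#' @param n_dates Number of sampling dates per location-management combination.
#' @param traps_per_site Number of traps pooled into each sample.
#' @return An object of class `bq_design`.
#' @examples
#' d <- study_design()
#' n_samples(d)  # 224
#' @export
study_design <- function(management_types = c("CRP", "NPAM"),
                         locations = c("Arrowwood", "Kulm", "SullysHill", "Tewaukon"),
                         n_dates = 28,
                         traps_per_site = 2) {
  stopifnot(length(management_types) >= 1, length(locations) >= 1,
            n_dates >= 1, traps_per_site >= 1)
  if (anyDuplicated(management_types) || anyDuplicated(locations)) {
    abort("management and location labels must be unique")
  }
  structure(
    list(management_types = as.character(management_types),
         locations = as.character(locations),
         n_dates = as.integer(n_dates),
         traps_per_site = as.integer(traps_per_site)),
    class = "bq_design"
  )
}

#' @rdname study_design
#' @param design A `bq_design` object.
#' @export
n_samples <- function(design) {
  length(design$management_types) * length(design$locations) * design$n_dates
}

#' Sample metadata implied by a study design
#'
#' Expands a design into one row per community pool, with the sample
#' identifier used throughout the package (`<management>_<location>_d<date>`).
#'
#' @param design A `bq_design` object.
#' @return A tibble with columns `sample_id`, `management`, `location`, `date`.
#' @export
design_metadata <- function(design) {
  md <- tidyr::expand_grid(
    management = design$management_types,
    location = design$locations,
    date = seq_len(design$n_dates)
  )
  md$sample_id <- sprintf("%s_%s_d%02d", md$management, md$location, md$date)
  dplyr::select(md, "sample_id", "management", "location", "date")
}

#' @export
print.bq_design <- function(x, ...) {
  cat("Pooled-trap study design\n")
  cat("  management types:", paste(x$management_types, collapse = ", "), "\n")
  cat("  locations:       ", paste(x$locations, collapse = ", "), "\n")
  cat("  sampling dates:  ", x$n_dates, "\n")
  cat("  traps per site:  ", x$traps_per_site, "\n")
  cat("  community pools: ", n_samples(x), "\n")
  invisible(x)
}
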