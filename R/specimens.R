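#' Simulate a specimen count table from a study design
#'
#' Draws per-trap specimen counts for every taxon from a negative-binomial
#' distribution (mean = `mean_abundance` x the taxon's location multiplier,
#' size = `dispersion`; variance `m + m^2/size`) and sums the traps within
#' each management x location x date pool, yielding one row per community
#' pool.
#'
#' @param design A [study_design()] object.
#' @param profiles A [taxon_profiles()] tibble.
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A tibble with `sample_id` followed by one count column per taxon.
#' @export
generate_specimen_table <- function(design, profiles, seed = NULL) {
  stopifnot(inherits(design, "bq_design"), nrow(profiles) >= 1)
  md <- design_metadata(design)
  gen <- function() {
    cols <- lapply(seq_len(nrow(profiles)), function(i) {
      le <- profiles$location_effects[[i]]
      eff <- if (is.null(le)) rep(1, nrow(md)) else {
        e <- le[md$location]
        e[is.na(e)] <- 1
        unname(e)
      }
      mu <- profiles$mean_abundance[i] * eff
      # per-trap draws summed over the traps pooled into each sample
      counts <- integer(nrow(md))
      for (trap in seq_len(design$traps_per_site)) {
        counts <- counts + rnbinom(nrow(md), size = profiles$dispersion[i], mu = mu)
      }
      counts
    })
    names(cols) <- profiles$taxon_id
    tibble::tibble(sample_id = md$sample_id, !!!cols)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Pool specimens by morphotaxon ("taxa tubes")
#'
#' Mirrors the bench practice of pooling one leg from every specimen of a
#' morphologically identified taxon into a single tube used to validate that
#' taxon's reference sequence. One pool is emitted per taxon observed at
#' least once.
#'
#' @param specimens A specimen count table.
#' @return A tibble with one row per observed taxon: `sample_id`
#'   (`pool_<taxon>`) and that taxon's column holding its total count.
#' @export
generate_taxa_pools <- function(specimens) {
  taxa <- taxon_names(specimens)
  totals <- colSums(count_matrix(specimens, taxa))
  keep <- taxa[totals > 0]
  m <- matrix(0L, length(keep), length(taxa), dimnames = list(NULL, taxa))
  m[cbind(seq_along(keep), match(keep, taxa))] <- as.integer(totals[keep])
  tibble::tibble(sample_id = paste0("pool_", keep),
                 !!!as.data.frame(m))
}

#' Read and write specimen tables as TSV
#'
#' First column `sample_id`, remaining columns taxon counts.
#'
#' @param table A specimen count tibble.
#' @param path File path.
#' @return `write_specimen_tsv()` returns `path` invisibly;
#'   `read_specimen_tsv()` returns a tibble.
#' @export
write_specimen_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_specimen_tsv
#' @export
read_specimen_tsv <- function(path) {
  tibble::as_tibble(utils::read.delim(path, check.names = FALSE,
                                      colClasses = c(sample_id = "character")))
}
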