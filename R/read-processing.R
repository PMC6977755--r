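#' Expected number of errors of a read
#'
#' The expected-error statistic used for quality filtering: the sum over
#' bases of the error probability implied by each Phred+33 quality character,
#' `E = sum 10^(-Q/10)`.
#'
#' @param quality Character vector of Phred+33 quality strings.
#' @return Numeric vector of expected error counts (0 for empty strings).
#' @examples
#' expected_errors(strrep("5", 100))  # 100 bases at Q20 -> 1.0
#' @export
expected_errors <- function(quality) {
  vapply(quality, function(q) {
    if (is.na(q)) abort("quality must not be NA")
    if (nchar(q) == 0) return(0)
    ph <- utf8ToInt(q) - 33L
    if (any(ph < 0L) || any(ph > 93L)) {
      abort("invalid Phred+33 quality character")
    }
    sum(10^(-ph / 10))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Quality-filter and dereplicate reads
#'
#' Discards every read with at least `max_expected_errors` predicted errors
#' (the boundary itself is discarded: a read with `E >= 1` has at least one
#' predicted error), then collapses identical full-length sequences within a
#' sample into uniques with replicate counts, and drops uniques below
#' `min_replicates`. The conventional thresholds are `min_replicates = 10`
#' when validating per-taxon reference pools and `min_replicates = 2` for
#' community samples.
#'
#' @param reads Read tibble with `sample_id`, `sequence`, `quality`.
#' @param max_expected_errors Reads with `E >=` this are discarded.
#' @param min_replicates Minimum replicate count for a unique to survive.
#' @return A tibble of uniques: `sample_id`, `sequence`, `replicate_count`.
#' @export
filter_and_dereplicate <- function(reads, max_expected_errors = 1, min_replicates = 2) {
  stopifnot(min_replicates >= 1)
  keep <- reads[expected_errors(reads$quality) < max_expected_errors, ]
  keep |>
    dplyr::count(.data$sample_id, .data$sequence, name = "replicate_count") |>
    dplyr::filter(.data$replicate_count >= min_replicates) |>
    dplyr::arrange(.data$sample_id, dplyr::desc(.data$replicate_count))
}

#' Assign uniques to reference taxa and tabulate read counts
#'
#' Globally (end-to-end) aligns every unique sequence against every reference
#' and computes identity as matching columns over total alignment columns
#' (gaps count against identity). A unique is assigned to the single best
#' reference at identity `>= min_identity`; ties at the best identity are
#' tallied as `ambiguous` (assigned to no taxon); best identity below the
#' threshold is `unassigned`; hits to the calibrator taxon are tallied in
#' `calibrator_reads` and excluded from the taxon matrix. Per sample,
#' mapped + unassigned + ambiguous + calibrator equals the total replicate
#' count passed in.
#'
#' @param uniques Uniques tibble from [filter_and_dereplicate()].
#' @param refdb Reference database tibble.
#' @param min_identity Minimum alignment identity (fraction) for assignment.
#' @param calibrator_taxon Calibrator label in `refdb`, or `NULL` if none.
#' @param samples Optional character vector fixing the output rows (samples
#'   with no uniques get all-zero rows).
#' @return A read-count tibble: `sample_id`, one column per non-calibrator
#'   reference taxon, then `unassigned`, `ambiguous`, `calibrator_reads`.
#' @export
map_and_tabulate <- function(uniques, refdb, min_identity = 0.99,
                             calibrator_taxon = NULL, samples = NULL) {
  stopifnot(nrow(refdb) >= 1)
  taxa <- setdiff(refdb$taxon_id, calibrator_taxon)
  samples <- samples %||% unique(uniques$sample_id)

  useq <- unique(uniques$sequence)
  assignment <- if (length(useq)) {
    ids <- identity_matrix(useq, refdb$sequence)  # uniques x references
    best <- apply(ids, 1, max)
    vapply(seq_along(useq), function(i) {
      hits <- which(ids[i, ] >= best[i] - 1e-9)
      if (best[i] < min_identity) ".unassigned"
      else if (length(hits) > 1) ".ambiguous"
      else refdb$taxon_id[hits]
    }, character(1))
  } else character(0)

  lut <- stats::setNames(assignment, useq)
  tallied <- uniques
  tallied$target <- unname(lut[tallied$sequence])

  m <- matrix(0L, length(samples), length(taxa), dimnames = list(samples, taxa))
  extra <- matrix(0L, length(samples), 3,
                  dimnames = list(samples, c("unassigned", "ambiguous", "calibrator_reads")))
  for (k in seq_len(nrow(tallied))) {
    s <- tallied$sample_id[k]; tg <- tallied$target[k]; n <- tallied$replicate_count[k]
    if (!s %in% samples) next
    if (tg == ".unassigned") extra[s, "unassigned"] <- extra[s, "unassigned"] + n
    else if (tg == ".ambiguous") extra[s, "ambiguous"] <- extra[s, "ambiguous"] + n
    else if (!is.null(calibrator_taxon) && tg == calibrator_taxon) {
      extra[s, "calibrator_reads"] <- extra[s, "calibrator_reads"] + n
    } else m[s, tg] <- m[s, tg] + n
  }
  tibble::tibble(sample_id = samples,
                 !!!as.data.frame(m, check.names = FALSE),
                 !!!as.data.frame(extra))
}

## identity of each query vs each reference: matching columns / alignment columns
identity_matrix <- function(queries, references) {
  q <- Biostrings::DNAStringSet(queries)
  out <- matrix(NA_real_, length(queries), length(references))
  for (j in seq_along(references)) {
    aln <- Biostrings::pairwiseAlignment(q, Biostrings::DNAString(references[j]),
                                         type = "global")
    cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
    out[, j] <- Biostrings::nmatch(aln) / cols
  }
  out
}

#' Process per-sample FASTQ reads into a read-count table
#'
#' Convenience pipeline: [filter_and_dereplicate()] then [map_and_tabulate()].
#' `mode = "taxa"` applies the reference-validation replicate threshold (10);
#' `mode = "community"` applies the community threshold (2).
#'
#' @inheritParams filter_and_dereplicate
#' @inheritParams map_and_tabulate
#' @param mode `"community"` or `"taxa"`.
#' @return A read-count tibble (see [map_and_tabulate()]).
#' @export
process_reads <- function(reads, refdb, mode = c("community", "taxa"),
                          max_expected_errors = 1, min_identity = 0.99,
                          calibrator_taxon = NULL, samples = NULL) {
  mode <- match.arg(mode)
  min_rep <- if (mode == "taxa") 10L else 2L
  uniq <- filter_and_dereplicate(reads, max_expected_errors, min_rep)
  map_and_tabulate(uniq, refdb, min_identity, calibrator_taxon,
                   samples = samples %||% unique(reads$sample_id))
}

#' Write a read-count table as TSV files
#'
#' Writes the taxon matrix to `path` and the unassigned/ambiguous/calibrator
#' tallies to `tally_path` (default `<path base>_tallies.tsv`).
#'
#' @param table Read-count tibble.
#' @param path Output TSV for the sample x taxon matrix.
#' @param tally_path Output TSV for the per-sample tallies.
#' @return `path`, invisibly.
#' @export
write_read_counts_tsv <- function(table, path, tally_path = NULL) {
  tally_path <- tally_path %||% sub("(\\.tsv)?$", "_tallies.tsv", path)
  taxa <- taxon_names(table)
  utils::write.table(table[, c("sample_id", taxa)], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tcols <- intersect(c("sample_id", "unassigned", "ambiguous", "calibrator_reads"),
                     names(table))
  utils::write.table(table[, tcols], tally_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
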