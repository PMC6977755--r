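#' Simulate merged amplicon reads from a specimen table
#'
#' Implements the forward model of quantitative metabarcoding: the expected
#' share of reads for a taxon is proportional to the number of contributing
#' specimens times its copy-number correction factor,
#' `p_i = n_i c_i / sum_j n_j c_j`. Per sample, each specimen independently
#' survives tissue-degradation dropout with probability `1 - dropout_prob`;
#' a fixed number of calibrator legs is spiked in; `reads_per_sample` reads
#' are then drawn from a multinomial over taxa with probabilities
#' proportional to surviving specimens x factor. Each read copies its taxon's
#' reference sequence with i.i.d. substitution errors at `per_base_error` and
#' carries a constant-quality Phred+33 string consistent with that error rate
#' (Q = round(-10 log10(p)), capped to [2, 40]).
#'
#' A sample whose surviving specimen mass is zero yields an empty (or, with a
#' calibrator spike-in, all-calibrator) batch rather than an error, mirroring
#' pools whose tissue fails entirely.
#'
#' @param table Specimen count tibble (`sample_id` + taxon columns).
#' @param profiles Profile tibble supplying `true_factor` for every taxon in
#'   `table` (and the calibrator, if spiked in).
#' @param refdb Reference database tibble with a sequence for every taxon.
#' @param reads_per_sample Multinomial read depth per sample.
#' @param per_base_error Per-base substitution error probability.
#' @param dropout_prob Probability an individual specimen contributes no DNA.
#' @param calibrator_count Number of calibrator legs spiked into every sample.
#' @param calibrator_taxon Calibrator taxon label.
#' @param seed Integer seed.
#' @return A tibble of reads: `sample_id`, `read_id`, `true_taxon` (the
#'   simulator's ground-truth assignment record), `sequence`, `quality`.
#' @export
simulate_reads <- function(table, profiles, refdb, reads_per_sample = 10000,
                           per_base_error = 0.001, dropout_prob = 0,
                           calibrator_count = 0, calibrator_taxon = "Tenebrio",
                           seed = NULL) {
  stopifnot(reads_per_sample >= 1, per_base_error >= 0, per_base_error < 1,
            dropout_prob >= 0, dropout_prob <= 1, calibrator_count >= 0)
  taxa <- taxon_names(table)
  need <- taxa
  if (calibrator_count > 0) need <- union(need, calibrator_taxon)
  missing_ref <- setdiff(need, refdb$taxon_id)
  if (length(missing_ref)) {
    abort(paste("no reference sequence for:", paste(missing_ref, collapse = ", ")))
  }
  missing_prof <- setdiff(need, profiles$taxon_id)
  if (length(missing_prof)) {
    abort(paste("no profile (correction factor) for:", paste(missing_prof, collapse = ", ")))
  }
  factors <- stats::setNames(profiles$true_factor, profiles$taxon_id)
  refs <- stats::setNames(refdb$sequence, refdb$taxon_id)

  q <- if (per_base_error > 0) max(2L, min(40L, as.integer(round(-10 * log10(per_base_error))))) else 40L
  qchar <- intToUtf8(q + 33L)

  counts <- count_matrix(table, taxa)
  gen <- function() {
    out <- vector("list", nrow(counts))
    for (s in seq_len(nrow(counts))) {
      n <- counts[s, ]
      surv <- rbinom(length(n), n, 1 - dropout_prob)
      names(surv) <- taxa
      if (calibrator_count > 0) surv[calibrator_taxon] <- calibrator_count
      mass <- surv * factors[names(surv)]
      if (sum(mass) <= 0) {
        out[[s]] <- tibble::tibble(sample_id = character(), read_id = character(),
                                   true_taxon = character(), sequence = character(),
                                   quality = character())
        next
      }
      nread <- as.vector(rmultinom(1, reads_per_sample, mass / sum(mass)))
      read_taxon <- rep(names(surv), nread)
      seqs <- mutate_reads(refs[read_taxon], per_base_error)
      out[[s]] <- tibble::tibble(
        sample_id = rownames(counts)[s],
        read_id = sprintf("%s_read%06d", rownames(counts)[s], seq_along(read_taxon)),
        true_taxon = read_taxon,
        sequence = seqs,
        quality = strrep(qchar, nchar(seqs))
      )
    }
    dplyr::bind_rows(out)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

## apply i.i.d. substitution errors to a character vector of template reads
mutate_reads <- function(templates, per_base_error) {
  if (per_base_error == 0 || length(templates) == 0) return(unname(templates))
  lens <- nchar(templates)
  nerr <- rbinom(length(templates), lens, per_base_error)
  hit <- which(nerr > 0)
  out <- unname(templates)
  base_int <- utf8ToInt(paste(BASES, collapse = ""))
  for (i in hit) {
    v <- utf8ToInt(out[i])
    pos <- sample.int(lens[i], nerr[i])
    cur <- match(v[pos], base_int)
    v[pos] <- base_int[((cur - 1L + sample.int(3L, nerr[i], replace = TRUE)) %% 4L) + 1L]
    out[i] <- intToUtf8(v)
  }
  out
}

#' Write simulated reads as per-sample FASTQ files
#'
#' Standard 4-line Phred+33 FASTQ, one file per sample named
#' `<sample_id>.fastq`. The ground-truth `true_taxon` column is not written.
#'
#' @param reads A read tibble from [simulate_reads()].
#' @param dir Output directory (created if needed).
#' @return Invisible character vector of the files written.
#' @export
write_read_fastq <- function(reads, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (sid in unique(reads$sample_id)) {
    b <- reads[reads$sample_id == sid, ]
    x <- Biostrings::DNAStringSet(b$sequence)
    names(x) <- b$read_id
    f <- file.path(dir, paste0(sid, ".fastq"))
    suppressWarnings(  # qualities are passed separately, not as metadata
      Biostrings::writeXStringSet(x, f, format = "fastq",
                                  qualities = Biostrings::BStringSet(b$quality)))
    files <- c(files, f)
  }
  invisible(files)
}

#' Read per-sample FASTQ files into a read tibble
#'
#' @param dir Directory of `<sample_id>.fastq` files (or a character vector of
#'   FASTQ paths).
#' @return A tibble with `sample_id`, `read_id`, `sequence`, `quality`.
#' @export
read_read_fastq <- function(dir) {
  files <- if (length(dir) == 1 && dir.exists(dir)) {
    list.files(dir, pattern = "\\.fastq$", full.names = TRUE)
  } else dir
  out <- lapply(files, function(f) {
    # the metadata-column note from the internal XStringSet conversion is harmless
    x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(f))
    tibble::tibble(
      sample_id = sub("\\.fastq$", "", basename(f)),
      read_id = names(x),
      sequence = unname(as.character(x)),
      quality = unname(as.character(Biostrings::quality(x)))
    )
  })
  dplyr::bind_rows(out)
}
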