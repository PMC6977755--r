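BASES <- c("A", "C", "G", "T")

#' Generate a reference database of marker-like sequences
#'
#' Simulates a set of taxon-labelled marker sequences (one per taxon) whose
#' pairwise divergence mimics a chosen locus. Sequences are grown from a
#' random founder: each new sequence copies a randomly chosen existing one and
#' substitutes `min_divergence` plus a small Poisson jitter of positions, so
#' nearest-neighbour divergence sits close to `min_divergence`. Candidates
#' violating the pairwise minimum are rejection-sampled. A high-divergence
#' setting (e.g. 9 nt over 507 bp) emulates a locus that discriminates taxa
#' well at a 99% identity threshold; `min_divergence <= 1` emulates a locus
#' whose taxa collapse at that threshold.
#'
#' @param num_taxa Number of taxa (sequences) to generate.
#' @param length Sequence length in nucleotides.
#' @param min_divergence Minimum pairwise Hamming distance (substitutions)
#'   enforced between every pair of sequences.
#' @param seed Integer seed; the result is deterministic given the seed.
#' @param taxon_ids Optional character vector of taxon labels (default
#'   `Taxon01`, `Taxon02`, ...).
#' @param locus Locus label stored with every record.
#' @param max_tries Rejection-sampling attempts allowed per sequence before
#'   the configuration is declared infeasible.
#' @return A tibble with columns `taxon_id`, `locus`, `sequence`.
#' @examples
#' db <- generate_reference_db(4, length = 60, min_divergence = 5, seed = 1)
#' @export
generate_reference_db <- function(num_taxa, length = 507, min_divergence = 9,
                                  seed = NULL, taxon_ids = NULL, locus = "28S",
                                  max_tries = 1000) {
  stopifnot(num_taxa >= 1, length >= 1)
  if (min_divergence >= length) {
    abort("`min_divergence` must be smaller than the sequence length")
  }
  taxon_ids <- taxon_ids %||% sprintf("Taxon%02d", seq_len(num_taxa))
  stopifnot(length(taxon_ids) == num_taxa, !anyDuplicated(taxon_ids))

  gen <- function() {
    seqs <- vector("list", num_taxa)
    seqs[[1]] <- sample.int(4L, length, replace = TRUE)
    for (i in seq_len(num_taxa)[-1]) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        parent <- seqs[[sample.int(i - 1L, 1L)]]
        d <- min(min_divergence + rpois(1L, 1), length)
        cand <- parent
        if (d > 0) {
          pos <- sample.int(length, d)
          # substitute to a uniformly chosen *different* base
          cand[pos] <- ((cand[pos] - 1L + sample.int(3L, d, replace = TRUE)) %% 4L) + 1L
        }
        dists <- vapply(seqs[seq_len(i - 1L)], function(s) sum(s != cand), integer(1))
        if (all(dists >= min_divergence)) {
          seqs[[i]] <- cand
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        abort(sprintf(
          "could not place sequence %d at min_divergence %d within %d attempts; configuration infeasible",
          i, min_divergence, max_tries))
      }
    }
    vapply(seqs, function(s) paste(BASES[s], collapse = ""), character(1))
  }

  seqs <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  tibble::tibble(taxon_id = taxon_ids, locus = locus, sequence = seqs)
}

#' Read and write reference databases as FASTA
#'
#' FASTA headers follow the convention `taxon_id|locus`.
#'
#' @param db A reference database tibble (`taxon_id`, `locus`, `sequence`).
#' @param path File path.
#' @return `write_reference_fasta()` returns `path` invisibly;
#'   `read_reference_fasta()` returns a reference database tibble.
#' @export
write_reference_fasta <- function(db, path) {
  x <- Biostrings::DNAStringSet(db$sequence)
  names(x) <- paste(db$taxon_id, db$locus, sep = "|")
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_reference_fasta
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(x), "|", fixed = TRUE)
  tibble::tibble(
    taxon_id = vapply(parts, `[`, character(1), 1L),
    locus = vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_, character(1)),
    sequence = unname(as.character(x))
  )
}

## pairwise Hamming distances of equal-length sequences (used by tests too)
#' Pairwise Hamming distance matrix of equal-length sequences
#'
#' @param sequences Character vector of equal-length sequences.
#' @return Symmetric integer matrix of substitution counts.
#' @export
hamming_matrix <- function(sequences) {
  n <- length(sequences)
  stopifnot(n >= 1, length(unique(nchar(sequences))) == 1)
  chars <- do.call(rbind, strsplit(sequences, "", fixed = TRUE))
  d <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d[i, j] <- d[j, i] <- sum(chars[i, ] != chars[j, ])
    }
  }
  d
}
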