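# small in-code fixtures shared across tests

tiny_design <- function() {
  study_design(management_types = c("A", "B"), locations = c("L1", "L2"),
               n_dates = 3, traps_per_site = 2)
}

# two-taxon community with well-separated references
tiny_profiles <- function(factors = c(1, 1), means = c(2, 2)) {
  taxon_profiles(c("TaxA", "TaxB"), true_factor = factors, mean_abundance = means)
}

tiny_refdb <- function(n = 2, length = 60, min_divergence = 10, seed = 7,
                       ids = NULL) {
  generate_reference_db(n, length = length, min_divergence = min_divergence,
                        seed = seed, taxon_ids = ids)
}

# perfect-quality read tibble from explicit sequences
reads_from_seqs <- function(seqs, sample_id = "s1", q = "I") {
  tibble::tibble(
    sample_id = sample_id,
    read_id = sprintf("%s_r%03d", sample_id, seq_along(seqs)),
    sequence = seqs,
    quality = strrep(q, nchar(seqs))
  )
}

# substitute k positions of a sequence with a different base
substitute_bases <- function(seq, k, seed = 1) {
  withr::with_seed(seed, {
    v <- strsplit(seq, "")[[1]]
    pos <- sample(length(v), k)
    for (p in pos) v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
    paste(v, collapse = "")
  })
}
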