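#' Expected read proportions under the forward model
#'
#' The forward model of quantitative metabarcoding: the expected share of
#' reads for taxon i is `p_i = n_i c_i / sum_j n_j c_j`, the product of
#' specimen count and copy-number correction factor, renormalized.
#'
#' @param counts Non-negative per-taxon specimen counts `n`.
#' @param factors Positive per-taxon correction factors `c`.
#' @return Probability vector summing to 1.
#' @examples
#' expected_proportions(c(1, 1), c(30, 14.9))  # ~2:1 read share
#' @export
expected_proportions <- function(counts, factors) {
  stopifnot(length(counts) == length(factors))
  if (any(counts < 0)) abort("counts must be non-negative")
  if (any(factors <= 0)) abort("factors must be positive")
  mass <- counts * factors
  tot <- sum(mass)
  if (tot <= 0) abort("degenerate sample: all specimen mass is zero")
  mass / tot
}

#' Select samples concordant between morphology and sequencing
#'
#' A sample is concordant when the set of genera detected morphologically
#' (specimen count > 0) is exactly the set detected by sequencing (read count
#' > 0). Concordant samples form the training set for correction-factor
#' estimation.
#'
#' @param specimens Specimen count tibble.
#' @param reads Read-count tibble (tally columns ignored).
#' @param rank_map Optional mapping from taxon to genus: a named character
#'   vector or a tibble with columns `taxon_id`, `genus`. Defaults to the
#'   identity (taxa already at genus rank).
#' @return Character vector of concordant sample labels (possibly empty).
#' @export
select_concordant_samples <- function(specimens, reads, rank_map = NULL) {
  shared <- intersect(specimens$sample_id, reads$sample_id)
  if (!length(shared)) abort("no shared sample labels between the two tables")
  to_genus <- function(taxa) {
    if (is.null(rank_map)) return(taxa)
    if (is.data.frame(rank_map)) {
      unname(stats::setNames(rank_map$genus, rank_map$taxon_id)[taxa])
    } else unname(rank_map[taxa])
  }
  sm <- count_matrix(specimens)
  rm_ <- count_matrix(reads)
  keep <- vapply(shared, function(s) {
    gm <- unique(to_genus(colnames(sm)[sm[s, ] > 0]))
    gr <- unique(to_genus(colnames(rm_)[rm_[s, ] > 0]))
    setequal(gm, gr)
  }, logical(1))
  shared[keep]
}

#' Assemble a calibration set for correction-factor estimation
#'
#' Restricts the specimen and read-count tables to the chosen concordant
#' samples, appends the calibrator as a pseudo-taxon with a fixed specimen
#' count per sample (two legs by default), and converts read counts to
#' observed per-sample proportions over the shared taxon set including the
#' calibrator. Unassigned and ambiguous reads are excluded from the
#' denominator.
#'
#' @param specimens Specimen count tibble.
#' @param reads Read-count tibble with a `calibrator_reads` column.
#' @param samples Sample labels to use (e.g. from
#'   [select_concordant_samples()]).
#' @param calibrator_taxon Label under which the calibrator is carried.
#' @param calibrator_count Calibrator specimens (legs) per sample.
#' @return An object of class `bq_calibration`: taxa (calibrator last),
#'   samples, specimen count matrix `counts`, observed proportion matrix
#'   `observed`.
#' @export
prepare_calibration <- function(specimens, reads, samples,
                                calibrator_taxon = "Tenebrio",
                                calibrator_count = 2) {
  stopifnot(length(samples) >= 1, calibrator_count > 0)
  if (!all(samples %in% specimens$sample_id) || !all(samples %in% reads$sample_id)) {
    abort("all calibration samples must appear in both tables")
  }
  sm <- count_matrix(specimens)[samples, , drop = FALSE]
  taxa <- colnames(sm)[colSums(sm) > 0]
  rmat <- count_matrix(reads)
  missing <- setdiff(taxa, colnames(rmat))
  if (length(missing)) {
    abort(paste("taxon set mismatch between tables:", paste(missing, collapse = ", ")))
  }
  if (!"calibrator_reads" %in% names(reads)) {
    abort("reads table has no calibrator_reads column")
  }
  N <- cbind(sm[, taxa, drop = FALSE],
             matrix(calibrator_count, length(samples), 1,
                    dimnames = list(NULL, calibrator_taxon)))
  robs <- cbind(rmat[samples, taxa, drop = FALSE],
                matrix(reads$calibrator_reads[match(samples, reads$sample_id)],
                       length(samples), 1, dimnames = list(NULL, calibrator_taxon)))
  tot <- rowSums(robs)
  if (any(tot <= 0)) {
    abort(paste("sample(s) with zero mapped+calibrator reads:",
                paste(samples[tot <= 0], collapse = ", ")))
  }
  structure(
    list(taxa = c(taxa, calibrator_taxon), samples = samples,
         counts = N, observed = robs / tot,
         calibrator_taxon = calibrator_taxon),
    class = "bq_calibration"
  )
}

#' Simulate a noiseless concordant calibration set
#'
#' Builds the calibration experiment used to validate correction-factor
#' recovery: specimen counts for each taxon are drawn per sample from a
#' negative binomial (taxa absent from all samples are given one specimen in
#' a random sample so every factor is identifiable), a calibrator pseudo-taxon
#' is fixed at `calibrator_count` in every sample, and the observed read
#' proportions are set *exactly* to the forward model
#' `n_i c_i / sum_j n_j c_j` — so the true factors are recoverable up to
#' scale, by construction.
#'
#' @param profiles Profile tibble with `taxon_id`, `true_factor` and
#'   `mean_abundance` for the bee taxa (calibrator excluded).
#' @param n_samples Number of concordant samples.
#' @param dispersion Negative-binomial size for the specimen draws.
#' @param calibrator_taxon,calibrator_count Calibrator label and legs/sample.
#' @param calibrator_factor True correction factor of the calibrator tissue.
#' @param seed Integer seed.
#' @return A list: `calibration` (a `bq_calibration`) and `truth` (named
#'   vector of true factors, calibrator last).
#' @export
simulate_concordant_calibration <- function(profiles, n_samples = 15,
                                            dispersion = 2,
                                            calibrator_taxon = "Tenebrio",
                                            calibrator_count = 2,
                                            calibrator_factor = 50,
                                            seed = NULL) {
  gen <- function() {
    S <- n_samples
    taxa <- profiles$taxon_id
    N <- vapply(seq_along(taxa), function(j) {
      rnbinom(S, size = dispersion, mu = profiles$mean_abundance[j])
    }, numeric(S))
    colnames(N) <- taxa
    for (j in seq_along(taxa)) {
      if (all(N[, j] == 0)) N[sample.int(S, 1), j] <- 1
    }
    N <- cbind(N, matrix(calibrator_count, S, 1,
                         dimnames = list(NULL, calibrator_taxon)))
    truth <- c(stats::setNames(profiles$true_factor, taxa),
               stats::setNames(calibrator_factor, calibrator_taxon))
    E <- sweep(N, 2, truth, `*`)
    O <- E / rowSums(E)
    samples <- sprintf("cal%02d", seq_len(S))
    rownames(N) <- rownames(O) <- NULL
    cal <- structure(
      list(taxa = colnames(N), samples = samples, counts = N, observed = O,
           calibrator_taxon = calibrator_taxon),
      class = "bq_calibration"
    )
    list(calibration = cal, truth = truth)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Sum of squared errors between expected and observed proportions
#'
#' The genetic algorithm's fitness: summed over samples and taxa, the squared
#' difference between the forward-model proportions implied by a factor
#' vector and the observed read proportions. Scale-invariant: `sse(c)` equals
#' `sse(a*c)` for any `a > 0`.
#'
#' @param factors Positive factor vector in the calibration's taxon order.
#' @param calibration A `bq_calibration` object.
#' @return Non-negative scalar.
#' @export
sse_objective <- function(factors, calibration) {
  stopifnot(inherits(calibration, "bq_calibration"),
            length(factors) == length(calibration$taxa))
  if (any(factors <= 0)) abort("factors must be positive")
  E <- sweep(calibration$counts, 2, factors, `*`)
  P <- E / rowSums(E)
  val <- sum((P - calibration$observed)^2)
  if (!is.finite(val)) abort("non-finite fitness")
  val
}

## batch SSE for a population matrix C (genomes x taxa); algebraically
## identical to sse_objective applied row-wise, but three matrix products
sse_batch <- function(C, N, O, N2 = N^2, NO = N * O, oss = sum(O^2)) {
  denom <- C %*% t(N)
  rowSums((C^2 %*% t(N2)) / denom^2) - 2 * rowSums((C %*% t(NO)) / denom) + oss
}

#' Estimate correction factors with a genetic algorithm
#'
#' Evolves a population of candidate factor vectors ("genomes") against the
#' squared-error fitness of [sse_objective()]. All genomes start at
#' `init_value`. Each iteration the population is ranked; the worst third is
#' culled and replaced by mutated duplicates of the best third (the originals
#' are kept unmutated, so the best fitness never increases). A duplicate
#' mutates by adding `N(0, mutation_sd^2)` to `mutation_genes` randomly
#' chosen factor coordinates (one by default), clamped below at 0.01 to keep
#' factors positive. Because the fitness is scale-invariant, the raw result
#' is only meaningful after [normalize_factors()].
#'
#' The default desk budget of 1e5 iterations converges on noiseless
#' calibration sets within minutes; `iterations = 1e7` reproduces a
#' full-scale run.
#'
#' @param calibration A `bq_calibration` object.
#' @param population_size Number of genomes (>= 3).
#' @param iterations Number of selection-mutation iterations.
#' @param init_value Initial factor value for every taxon.
#' @param mutation_sd Standard deviation of the additive mutation.
#' @param mutation_genes Number of factor coordinates perturbed per duplicate.
#' @param cull_fraction Fraction (< 1/2) culled and duplicated per iteration.
#' @param seed Integer seed.
#' @param checkpoints Iterations at which the best fitness is recorded;
#'   default eight logarithmically spaced points up to `iterations`.
#' @return An object of class `bq_ga_fit` with elements `best_raw`,
#'   `best_normalized` (minimum 1), `best_sse`, `trajectory` (tibble of
#'   checkpointed best SSE), `taxa`, and `config`.
#' @export
ga_run <- function(calibration, population_size = 1000, iterations = 1e5,
                   init_value = 10, mutation_sd = 5, mutation_genes = 1,
                   cull_fraction = 1 / 3, seed = NULL, checkpoints = NULL) {
  stopifnot(inherits(calibration, "bq_calibration"),
            population_size >= 3, iterations >= 1,
            init_value > 0, mutation_sd > 0)
  if (cull_fraction >= 0.5) abort("cull_fraction must be below 1/2")
  Tt <- length(calibration$taxa)
  mutation_genes <- min(max(1L, as.integer(mutation_genes)), Tt)
  k <- floor(cull_fraction * population_size)
  if (k < 1) abort("population too small for the cull fraction")
  checkpoints <- checkpoints %||%
    unique(round(10^seq(0, log10(iterations), length.out = 8)))

  N <- calibration$counts
  O <- calibration$observed
  N2 <- N^2; NO <- N * O; oss <- sum(O^2)

  run <- function() {
    C <- matrix(init_value, population_size, Tt)
    f <- sse_batch(C, N, O, N2, NO, oss)
    best <- C[1, ]; bestf <- f[1]
    traj_it <- integer(0); traj_sse <- numeric(0)
    for (it in seq_len(iterations)) {
      ord <- order(f)
      bot <- ord[seq(population_size - k + 1, population_size)]
      mut <- C[ord[seq_len(k)], , drop = FALSE]
      if (mutation_genes == 1) {
        idx <- cbind(seq_len(k), sample.int(Tt, k, replace = TRUE))
        mut[idx] <- pmax(mut[idx] + rnorm(k, 0, mutation_sd), 0.01)
      } else {
        for (g in seq_len(mutation_genes)) {
          idx <- cbind(seq_len(k), sample.int(Tt, k, replace = TRUE))
          mut[idx] <- pmax(mut[idx] + rnorm(k, 0, mutation_sd), 0.01)
        }
      }
      C[bot, ] <- mut
      f[bot] <- sse_batch(mut, N, O, N2, NO, oss)
      if (any(!is.finite(f[bot]))) abort("non-finite fitness in population")
      i <- which.min(f)
      if (f[i] < bestf) { bestf <- f[i]; best <- C[i, ] }
      if (it %in% checkpoints) {
        traj_it <- c(traj_it, it); traj_sse <- c(traj_sse, bestf)
      }
    }
    list(best = best, bestf = bestf,
         traj = tibble::tibble(iteration = traj_it, sse = traj_sse))
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())

  best_raw <- stats::setNames(res$best, calibration$taxa)
  structure(
    list(best_raw = best_raw,
         best_normalized = normalize_factors(best_raw),
         best_sse = res$bestf,
         trajectory = res$traj,
         taxa = calibration$taxa,
         config = list(population_size = population_size, iterations = iterations,
                       init_value = init_value, mutation_sd = mutation_sd,
                       mutation_genes = mutation_genes,
                       cull_fraction = cull_fraction, seed = seed)),
    class = "bq_ga_fit"
  )
}

#' Normalize correction factors to a minimum of 1
#'
#' Correction factors are identified only up to scale; dividing by the
#' minimum expresses them in fold units relative to the lowest-copy taxon.
#'
#' @param raw Positive numeric vector.
#' @return Vector with minimum exactly 1.
#' @export
normalize_factors <- function(raw) {
  if (any(raw <= 0) || !length(raw)) abort("factors must be positive")
  raw / min(raw)
}

#' Estimate specimen abundance from read counts
#'
#' Retro-actively applies correction factors to read counts: the predicted
#' specimen proportion of taxon i is `(r_i / c_i) / sum_j (r_j / c_j)` —
#' the algebraic inverse of the forward model. With `total_specimens`,
#' proportions are scaled to predicted counts.
#'
#' @param reads_row Non-negative per-taxon read counts.
#' @param factors Positive per-taxon correction factors.
#' @param total_specimens Optional total specimens in the sample.
#' @return Predicted proportions (or counts if `total_specimens` is given).
#' @export
estimate_abundance <- function(reads_row, factors, total_specimens = NULL) {
  stopifnot(length(reads_row) == length(factors))
  if (any(factors <= 0)) abort("factors must be positive")
  if (any(reads_row < 0)) abort("read counts must be non-negative")
  w <- reads_row / factors
  tot <- sum(w)
  if (tot <= 0) abort("degenerate sample: no reads")
  q <- w / tot
  if (is.null(total_specimens)) q else q * total_specimens
}

#' Predicted abundance for every sample of a read-count table
#'
#' Maps [estimate_abundance()] over the rows of a read-count table, scaling
#' each sample by its total specimen count when a specimen table is supplied.
#'
#' @param reads Read-count tibble.
#' @param factors Named factor vector covering the table's taxa.
#' @param specimens Optional specimen tibble providing per-sample totals (and
#'   actual counts in the output).
#' @return Long tibble: `sample_id`, `taxon`, `reads`, `predicted` (and
#'   `actual` when `specimens` is given). Samples with zero reads are skipped.
#' @export
estimate_abundance_tbl <- function(reads, factors, specimens = NULL) {
  taxa <- intersect(taxon_names(reads), names(factors))
  rmat <- count_matrix(reads, taxa)
  smat <- if (!is.null(specimens)) count_matrix(specimens, taxa) else NULL
  rows <- lapply(rownames(rmat), function(s) {
    r <- rmat[s, ]
    if (sum(r) == 0) return(NULL)
    total <- if (!is.null(smat)) sum(smat[s, ]) else NULL
    pred <- estimate_abundance(r, factors[taxa], total)
    out <- tibble::tibble(sample_id = s, taxon = taxa, reads = unname(r),
                          predicted = unname(pred))
    if (!is.null(smat)) out$actual <- unname(smat[s, ])
    out
  })
  dplyr::bind_rows(rows)
}

#' @export
print.bq_ga_fit <- function(x, ...) {
  cat("Correction-factor genetic algorithm fit\n")
  cat(sprintf("  %d taxa, population %d, %g iterations\n",
              length(x$taxa), x$config$population_size, x$config$iterations))
  cat(sprintf("  best SSE: %.4g\n", x$best_sse))
  print(tidy(x), n = length(x$taxa))
  invisible(x)
}

#' Tidy a genetic-algorithm fit
#'
#' @param x A `bq_ga_fit`.
#' @param ... Unused.
#' @return A tibble with `taxon`, `raw`, `normalized`.
#' @export
tidy.bq_ga_fit <- function(x, ...) {
  tibble::tibble(taxon = x$taxa,
                 raw = unname(x$best_raw),
                 normalized = unname(x$best_normalized))
}

#' One-row summary of a genetic-algorithm fit
#'
#' @param x A `bq_ga_fit`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.bq_ga_fit <- function(x, ...) {
  tibble::tibble(n_taxa = length(x$taxa),
                 population_size = x$config$population_size,
                 iterations = x$config$iterations,
                 best_sse = x$best_sse,
                 max_factor = max(x$best_normalized))
}

#' Plot the fitness trajectory of a genetic-algorithm fit
#'
#' Best (lowest) SSE at each checkpoint against iteration, log-log.
#'
#' @param object A `bq_ga_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bq_ga_fit <- function(object, ...) {
  ggplot2::ggplot(object$trajectory, ggplot2::aes(.data$iteration, .data$sse)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "best sum of squared errors",
                  title = "Genetic algorithm convergence") +
    ggplot2::theme_minimal()
}
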