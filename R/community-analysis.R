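#' Per-sample taxon richness
#'
#' Counts, for every sample, the taxa with a positive count. Tally columns
#' (unassigned, ambiguous, calibrator) are excluded, so the same function
#' serves specimen tables (morphological richness) and read-count tables
#' (molecular richness).
#'
#' @param table Specimen or read-count tibble.
#' @return A tibble with `sample_id` and `richness`.
#' @export
sample_richness <- function(table) {
  m <- count_matrix(table)
  tibble::tibble(sample_id = table$sample_id,
                 richness = as.integer(rowSums(m > 0)))
}

#' Correlation between morphological and molecular richness
#'
#' Pearson product-moment correlation between two per-sample richness
#' vectors.
#'
#' @param morph_richness,mol_richness Numeric vectors of equal length >= 3.
#' @return Pearson r in \[-1, 1\].
#' @export
richness_correlation <- function(morph_richness, mol_richness) {
  if (length(morph_richness) != length(mol_richness) || length(morph_richness) < 3) {
    abort("need two vectors of equal length >= 3")
  }
  if (sd(morph_richness) == 0 || sd(mol_richness) == 0) {
    abort("correlation undefined for a constant richness vector")
  }
  cor(morph_richness, mol_richness)
}

#' Incidence (presence-absence) summary of a count table
#'
#' Reduces counts to presences and computes the quantities that drive
#' sample-based rarefaction: the number of sampling units `T`, each taxon's
#' incidence frequency `T_i` (units in which it occurs), the counts of
#' taxa occurring in exactly one (`Q1`) and exactly two (`Q2`) units, and the
#' observed richness `S_obs`.
#'
#' @param table Specimen or read-count tibble; each row is a sampling unit.
#' @return An object of class `bq_incidence`.
#' @export
incidence_matrix <- function(table) {
  pres <- count_matrix(table) > 0
  Ti <- colSums(pres)
  structure(
    list(presence = pres, samples = table$sample_id, taxa = colnames(pres),
         T = nrow(pres), Ti = Ti,
         Q1 = sum(Ti == 1), Q2 = sum(Ti == 2), S_obs = sum(Ti > 0)),
    class = "bq_incidence"
  )
}

#' @export
print.bq_incidence <- function(x, ...) {
  cat(sprintf("Incidence summary: %d sampling units, S_obs = %d (Q1 = %d, Q2 = %d)\n",
              x$T, x$S_obs, x$Q1, x$Q2))
  invisible(x)
}

#' Sample-based rarefaction and extrapolation
#'
#' Expected taxon richness for `t` sampling units. Interpolation (`t <= T`)
#' uses the hypergeometric formula
#' `S(t) = S_obs - sum_i C(T - T_i, t) / C(T, t)`, the exact mean richness
#' over all subsets of `t` units. Extrapolation (`t > T`) uses the Chao2
#' estimate of undetected richness,
#' `Q0 = ((T-1)/T) * Q1^2 / (2 Q2)` (with the standard substitution
#' `Q1 (Q1 - 1) / 2` when `Q2 = 0`), and
#' `S(T + t*) = S_obs + Q0 * (1 - (1 - Q1 / (T Q0 + Q1))^t*)`.
#'
#' @param inc A [incidence_matrix()] object.
#' @param t_values Positive integers; defaults to `1:(2T)`.
#' @return A tibble of class `bq_rarefaction`: `t`, `richness`, `method`
#'   (`"interpolated"` or `"extrapolated"`).
#' @export
rarefaction_curve <- function(inc, t_values = seq_len(2 * inc$T)) {
  stopifnot(inherits(inc, "bq_incidence"))
  if (any(t_values <= 0) || any(t_values != round(t_values))) {
    abort("t values must be positive integers")
  }
  Tt <- inc$T
  Ti <- inc$Ti[inc$Ti > 0]
  chao2_q0 <- function() {
    if (inc$Q1 == 0) return(0)
    (Tt - 1) / Tt *
      if (inc$Q2 > 0) inc$Q1^2 / (2 * inc$Q2) else inc$Q1 * (inc$Q1 - 1) / 2
  }
  rich <- vapply(t_values, function(t) {
    if (t <= Tt) {
      absent <- ifelse(Tt - Ti >= t, exp(lchoose(Tt - Ti, t) - lchoose(Tt, t)), 0)
      inc$S_obs - sum(absent)
    } else {
      q0 <- chao2_q0()
      if (q0 == 0) return(as.numeric(inc$S_obs))
      inc$S_obs + q0 * (1 - (1 - inc$Q1 / (Tt * q0 + inc$Q1))^(t - Tt))
    }
  }, numeric(1))
  out <- tibble::tibble(
    t = as.integer(t_values), richness = rich,
    method = ifelse(t_values <= Tt, "interpolated", "extrapolated")
  )
  class(out) <- c("bq_rarefaction", class(out))
  attr(out, "S_obs") <- inc$S_obs
  attr(out, "T") <- Tt
  out
}

#' Plot a rarefaction curve
#'
#' @param object A `bq_rarefaction` tibble.
#' @param ... Unused.
#' @return A ggplot object; the interpolated range is drawn solid, the
#'   extrapolated range dashed, with the observed endpoint marked.
#' @export
autoplot.bq_rarefaction <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$t, .data$richness,
                                       linetype = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::annotate("point", x = attr(object, "T"), y = attr(object, "S_obs")) +
    ggplot2::scale_linetype_manual(
      values = c(interpolated = "solid", extrapolated = "dashed")) +
    ggplot2::labs(x = "sampling units", y = "expected taxon richness",
                  linetype = NULL) +
    ggplot2::theme_minimal()
}

#' PCA ordination of community composition
#'
#' Principal components analysis of per-sample relative abundances
#' (row-normalized counts; columns centered, not scaled), with the minimum
#' convex polygon of each group's scores on the first two components.
#'
#' @param table Specimen or read-count tibble.
#' @param groups Optional grouping: a named character vector (names =
#'   sample ids) or a tibble with `sample_id` and a grouping column.
#' @param relative Row-normalize counts to proportions before centering
#'   (all-zero samples are dropped with a warning). Set `FALSE` to ordinate
#'   raw counts.
#' @return An object of class `bq_pca`: `scores` (tibble), `explained_variance`
#'   (per component, non-increasing), `hulls` (tibble of hull vertices).
#' @export
pca_ordination <- function(table, groups = NULL, relative = TRUE) {
  m <- count_matrix(table)
  if (nrow(m) < 2 || ncol(m) < 2) abort("need at least 2 samples and 2 taxa")
  if (relative) {
    tot <- rowSums(m)
    if (any(tot == 0)) {
      warning(sprintf("dropping %d all-zero sample(s)", sum(tot == 0)))
      m <- m[tot > 0, , drop = FALSE]
      tot <- tot[tot > 0]
    }
    m <- m / tot
  }
  pr <- prcomp(m, center = TRUE, scale. = FALSE)
  grp <- if (is.null(groups)) {
    rep(NA_character_, nrow(m))
  } else if (is.data.frame(groups)) {
    gcol <- setdiff(names(groups), "sample_id")[1]
    unname(stats::setNames(as.character(groups[[gcol]]), groups$sample_id)[rownames(m)])
  } else unname(groups[rownames(m)])
  scores <- tibble::tibble(sample_id = rownames(m), group = grp,
                           tibble::as_tibble(unclass(pr$x)))
  hulls <- if (!all(is.na(grp))) {
    dplyr::bind_rows(lapply(split(seq_len(nrow(m)), grp), function(idx) {
      v <- idx[grDevices::chull(pr$x[idx, 1], pr$x[idx, 2])]
      tibble::tibble(group = grp[v[1]], sample_id = rownames(m)[v],
                     PC1 = pr$x[v, 1], PC2 = pr$x[v, 2])
    }))
  } else tibble::tibble(group = character(), sample_id = character(),
                        PC1 = numeric(), PC2 = numeric())
  structure(
    list(scores = scores, explained_variance = pr$sdev^2,
         loadings = pr$rotation, hulls = hulls),
    class = "bq_pca"
  )
}

#' @export
print.bq_pca <- function(x, ...) {
  pct <- 100 * x$explained_variance / sum(x$explained_variance)
  cat(sprintf("PCA ordination: %d samples, PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$scores), pct[1], pct[2]))
  invisible(x)
}

#' Tidy PCA scores
#'
#' @param x A `bq_pca`.
#' @param ... Unused.
#' @return The score tibble (`sample_id`, `group`, `PC1`, `PC2`, ...).
#' @export
tidy.bq_pca <- function(x, ...) x$scores

#' Plot a PCA ordination with group convex polygons
#'
#' @param object A `bq_pca`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bq_pca <- function(object, ...) {
  pct <- 100 * object$explained_variance / sum(object$explained_variance)
  p <- ggplot2::ggplot(object$scores,
                       ggplot2::aes(.data$PC1, .data$PC2, colour = .data$group))
  if (nrow(object$hulls)) {
    p <- p + ggplot2::geom_polygon(
      data = object$hulls,
      ggplot2::aes(fill = .data$group), alpha = 0.2, colour = NA)
  }
  p + ggplot2::geom_point() +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", pct[1]),
                  y = sprintf("PC2 (%.1f%%)", pct[2]),
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Descriptive summaries by location and management
#'
#' Mean, standard deviation and a normal-approximation 95% confidence
#' interval of a per-sample quantity (abundance, richness, ...) for every
#' location x management combination.
#'
#' @param values Tibble with `sample_id` and the value column.
#' @param metadata Tibble from [design_metadata()] (or with `sample_id`,
#'   `management`, `location`).
#' @param value Name of the value column in `values` (default `"richness"`).
#' @return A tibble with one row per location x management.
#' @export
community_summary <- function(values, metadata, value = "richness") {
  df <- dplyr::inner_join(values, metadata, by = "sample_id")
  z <- qnorm(0.975)
  df |>
    dplyr::group_by(.data$location, .data$management) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data[[value]]),
      sd = sd(.data[[value]]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      ci_low = .data$mean - z * .data$sd / sqrt(.data$n),
      ci_high = .data$mean + z * .data$sd / sqrt(.data$n)
    )
}
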