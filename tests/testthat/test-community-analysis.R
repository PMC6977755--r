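test_that("per-sample richness counts positive taxa only", {
  tab <- tibble::tibble(sample_id = c("s1", "s2"), A = c(3L, 1L), B = c(0L, 2L))
  expect_equal(sample_richness(tab)$richness, c(1L, 2L))
  # an all-zero sample has richness zero (a failed pool, not an error)
  tab0 <- tibble::tibble(sample_id = c("s1", "s2"), A = c(0L, 5L), B = c(0L, 5L))
  expect_equal(sample_richness(tab0)$richness, c(0L, 2L))
  # presence-based: invariant to scaling all counts
  tab10 <- dplyr::mutate(tab, A = A * 10L, B = B * 10L)
  expect_equal(sample_richness(tab10)$richness, sample_richness(tab)$richness)
  # tally columns of a read-count table are not taxa
  rc <- tibble::tibble(sample_id = "s1", A = 1L, unassigned = 9L,
                       ambiguous = 9L, calibrator_reads = 9L)
  expect_equal(sample_richness(rc)$richness, 1L)
})

test_that("richness correlation matches a direct covariance computation", {
  x <- c(3, 7, 2, 9, 5); y <- c(4, 8, 1, 10, 6)
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(richness_correlation(x, y), hand)
  expect_equal(richness_correlation(x, x), 1)
  expect_equal(richness_correlation(1:5, 5:1), -1)
  expect_error(richness_correlation(c(1, 2), c(1, 2)), "length")
  expect_error(richness_correlation(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("incidence summaries count frequencies, singletons and doubletons", {
  tab <- tibble::tibble(sample_id = paste0("s", 1:4),
                        A = c(1L, 2L, 3L, 4L),  # T_i = 4
                        B = c(5L, 0L, 1L, 0L),  # T_i = 2
                        C = c(0L, 0L, 7L, 0L),  # T_i = 1
                        D = c(0L, 0L, 0L, 0L))  # absent
  inc <- incidence_matrix(tab)
  expect_equal(inc$T, 4)
  expect_equal(unname(inc$Ti), c(4, 2, 1, 0))
  expect_equal(inc$Q1, 1); expect_equal(inc$Q2, 1)
  expect_equal(inc$S_obs, 3)
})

test_that("rarefaction interpolation equals the exhaustive subset oracle", {
  withr::with_seed(14, {
    for (rep in 1:3) {
      m <- matrix(rbinom(5 * 6, 1, 0.5), 5, 6)
      tab <- tibble::tibble(sample_id = paste0("u", 1:5),
                            !!!as.data.frame(m) |> stats::setNames(paste0("t", 1:6)))
      inc <- incidence_matrix(tab)
      curve <- rarefaction_curve(inc, t_values = 1:5)
      # brute force: mean richness over all C(5, t) subsets of sampling units
      for (t in 1:5) {
        subsets <- utils::combn(5, t)
        oracle <- mean(apply(subsets, 2, function(idx) {
          sum(colSums(m[idx, , drop = FALSE]) > 0)
        }))
        expect_equal(curve$richness[curve$t == t], oracle)
      }
      # t = T hits S_obs exactly; t = 1 is the mean per-unit richness
      expect_equal(curve$richness[curve$t == 5], inc$S_obs)
      expect_equal(curve$richness[curve$t == 1], mean(rowSums(m > 0)))
    }
  })
})

test_that("rarefaction agrees with vegan's exact accumulation curve", {
  tab <- generate_specimen_table(tiny_design(), bee_taxon_profiles(12), seed = 6)
  inc <- incidence_matrix(tab)
  ours <- rarefaction_curve(inc, t_values = seq_len(inc$T))
  ref <- vegan::specaccum(as.matrix(tab[, taxon_names(tab)]), method = "exact")
  expect_equal(ours$richness, unname(ref$richness), tolerance = 1e-10)
})

test_that("rarefaction extrapolates with Chao2 and stays monotone", {
  tab <- tibble::tibble(sample_id = paste0("u", 1:6),
                        A = c(1L, 1L, 1L, 1L, 0L, 0L),
                        B = c(1L, 0L, 0L, 0L, 0L, 0L),   # Q1
                        C = c(0L, 1L, 0L, 0L, 0L, 0L),   # Q1
                        D = c(1L, 1L, 0L, 0L, 0L, 0L))   # Q2
  inc <- incidence_matrix(tab)
  curve <- rarefaction_curve(inc, t_values = 1:12)
  q0 <- (5 / 6) * inc$Q1^2 / (2 * inc$Q2)
  expect_equal(curve$richness[curve$t == 8],
               inc$S_obs + q0 * (1 - (1 - inc$Q1 / (6 * q0 + inc$Q1))^2))
  expect_true(all(diff(curve$richness) >= -1e-12))
  expect_equal(curve$method, ifelse(1:12 <= 6, "interpolated", "extrapolated"))

  # Q2 = 0 branch uses the Q1(Q1-1)/2 substitution
  tab2 <- dplyr::select(tab, -"D")
  inc2 <- incidence_matrix(tab2)
  q0b <- (5 / 6) * inc2$Q1 * (inc2$Q1 - 1) / 2
  c2 <- rarefaction_curve(inc2, t_values = 12L)
  expect_equal(c2$richness,
               inc2$S_obs + q0b * (1 - (1 - inc2$Q1 / (6 * q0b + inc2$Q1))^6))

  # no singletons: the curve flattens at S_obs
  tab3 <- tibble::tibble(sample_id = paste0("u", 1:3),
                         A = c(1L, 1L, 0L), B = c(1L, 0L, 1L))
  c3 <- rarefaction_curve(incidence_matrix(tab3), t_values = c(3L, 9L))
  expect_equal(c3$richness, c(2, 2))

  expect_error(rarefaction_curve(inc, t_values = 0), "positive")
  expect_s3_class(autoplot(curve), "ggplot")
})

test_that("PCA conserves variance, yields orthogonal scores, matches closed form", {
  m <- tibble::tibble(sample_id = paste0("s", 1:8),
                      A = c(5L, 9L, 2L, 7L, 1L, 8L, 3L, 6L),
                      B = c(1L, 4L, 6L, 2L, 9L, 3L, 7L, 5L),
                      C = c(2L, 2L, 8L, 1L, 5L, 4L, 9L, 3L))
  ord <- pca_ordination(m, relative = FALSE)
  X <- as.matrix(m[, c("A", "B", "C")])
  expect_equal(sum(ord$explained_variance), sum(apply(X, 2, stats::var)))
  expect_true(all(diff(ord$explained_variance) <= 1e-12))
  sc <- as.matrix(ord$scores[, c("PC1", "PC2", "PC3")])
  expect_lt(abs(crossprod(sc[, 1], sc[, 2])), 1e-10)

  # 3 x 2 toy matrix against the closed-form 2x2 covariance eigenproblem
  toy <- tibble::tibble(sample_id = c("a", "b", "c"),
                        X = c(0L, 2L, 4L), Y = c(0L, 2L, 8L))
  tord <- pca_ordination(toy, relative = FALSE)
  S <- stats::cov(cbind(c(0, 2, 4), c(0, 2, 8)))
  tr <- sum(diag(S)); det_ <- S[1, 1] * S[2, 2] - S[1, 2]^2
  lam <- c((tr + sqrt(tr^2 - 4 * det_)) / 2, (tr - sqrt(tr^2 - 4 * det_)) / 2)
  expect_equal(tord$explained_variance, lam)
  expect_error(pca_ordination(toy[1, ]), "2 samples")
})

test_that("group hulls are convex subsets of each group's scores", {
  tab <- generate_specimen_table(tiny_design(), bee_taxon_profiles(10), seed = 12)
  md <- design_metadata(tiny_design())
  ord <- pca_ordination(tab, groups = md[, c("sample_id", "management")])
  expect_true(all(ord$hulls$sample_id %in% ord$scores$sample_id))
  for (g in unique(ord$hulls$group)) {
    h <- ord$hulls[ord$hulls$group == g, ]
    pts <- ord$scores[ord$scores$group == g, ]
    # hull vertices are that group's own points and re-hulling them is stable
    expect_true(all(h$sample_id %in% pts$sample_id))
    expect_equal(sort(grDevices::chull(h$PC1, h$PC2)), seq_len(nrow(h)))
  }
  expect_s3_class(autoplot(ord), "ggplot")
  expect_equal(tidy(ord), ord$scores)
})

test_that("locations separate more than managements in ordination space", {
  # shared taxon pools within a location, distinct pools across locations
  des <- study_design(management_types = c("A", "B"),
                      locations = c("L1", "L2"), n_dates = 10)
  profiles <- taxon_profiles(
    paste0("t", 1:8), true_factor = 1, mean_abundance = 4,
    location_effects = lapply(1:8, function(i) {
      if (i <= 4) c(L1 = 1, L2 = 0.02) else c(L1 = 0.02, L2 = 1)
    }))
  tab <- generate_specimen_table(des, profiles, seed = 77)
  md <- design_metadata(des)
  ord <- pca_ordination(tab)
  sc <- dplyr::inner_join(ord$scores, md, by = "sample_id")
  cent <- sc |>
    dplyr::group_by(.data$location, .data$management) |>
    dplyr::summarise(PC1 = mean(PC1), PC2 = mean(PC2), .groups = "drop")
  d2 <- function(a, b) sqrt(sum((a - b)^2))
  pt <- function(l, m) unlist(cent[cent$location == l & cent$management == m,
                                   c("PC1", "PC2")])
  within_loc <- mean(c(d2(pt("L1", "A"), pt("L1", "B")),
                       d2(pt("L2", "A"), pt("L2", "B"))))
  across_loc <- d2((pt("L1", "A") + pt("L1", "B")) / 2,
                   (pt("L2", "A") + pt("L2", "B")) / 2)
  expect_gt(across_loc, within_loc)
})

test_that("noiseless end-to-end richness agrees perfectly across methods", {
  # simulate -> process -> compare richness: with no error and no dropout the
  # molecular richness equals the morphological richness, so r = 1
  des <- study_design(management_types = "A", locations = c("L1", "L2"),
                      n_dates = 6)
  profiles <- taxon_profiles(paste0("t", 1:5), true_factor = c(1, 3, 10, 30, 90),
                             mean_abundance = c(3, 2, 1, 0.8, 0.5))
  db <- generate_reference_db(5, length = 300, min_divergence = 10, seed = 50,
                              taxon_ids = profiles$taxon_id)
  tab <- generate_specimen_table(des, profiles, seed = 51)
  reads <- simulate_reads(tab, profiles, db, reads_per_sample = 20000,
                          per_base_error = 0, dropout_prob = 0, seed = 52)
  uni <- filter_and_dereplicate(reads, min_replicates = 1)
  rc <- map_and_tabulate(uni, db, samples = tab$sample_id)
  morph <- sample_richness(tab)$richness
  mol <- sample_richness(rc)$richness
  expect_equal(mol, morph)
  expect_equal(richness_correlation(morph, mol), 1)
})

test_that("community_summary reports group means with normal CIs", {
  md <- design_metadata(tiny_design())
  vals <- tibble::tibble(sample_id = md$sample_id,
                         richness = rep(c(2, 4, 6), length.out = nrow(md)))
  out <- community_summary(vals, md)
  expect_equal(nrow(out), 4)  # 2 locations x 2 managements
  expect_true(all(out$ci_low <= out$mean & out$mean <= out$ci_high))
  expect_equal(out$n, rep(3L, 4))
})
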