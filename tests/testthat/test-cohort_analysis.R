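# Cohort-level analyses: SDAw matrices, PCA, marker correlation,
# differential testing and pre-ranked enrichment.

random_sda_profiles <- function(n, sd = 0.3, ids = sprintf("s%02d", seq_len(n))) {
  lapply(seq_len(n), function(i) {
    structure(stats::setNames(exp(stats::rnorm(61, 0, sd)), SENSE_CODONS),
              sample_id = ids[i], class = "sda_profile")
  })
}

test_that("sda_matrix reconciles codons across samples and keeps conditions", {
  set.seed(41)
  profs <- random_sda_profiles(4)
  profs[[2]] <- profs[[2]][names(profs[[2]]) != "GGG"]
  class(profs[[2]]) <- "sda_profile"; attr(profs[[2]], "sample_id") <- "s02"
  expect_warning(m <- sda_matrix(profs, condition = c(s01 = "A", s02 = "A",
                                                      s03 = "B", s04 = "B")),
                 "dropped")
  expect_equal(dim(m), c(4L, 60L))
  expect_false("GGG" %in% colnames(m))
  expect_equal(unname(attr(m, "condition")["s03"]), "B")
})

test_that("PCA recovers a planted one-factor structure in the loadings", {
  set.seed(42)
  n <- 12
  planted <- c("AGA", "AGG", "CGA", "CGC", "CGG", "CGT")
  z <- stats::rnorm(n)
  profs <- lapply(seq_len(n), function(i) {
    v <- exp(stats::rnorm(61, 0, 0.05))
    names(v) <- SENSE_CODONS
    v[planted] <- v[planted] * 2^(1.5 * z[i])
    structure(v, sample_id = sprintf("s%02d", i), class = "sda_profile")
  })
  m <- sda_matrix(profs)
  fit <- pca_sda(m)
  expect_false(fit$degenerate)
  expect_gt(fit$explained_variance[1], 0.5)
  expect_true(all(diff(fit$explained_variance) <= 1e-12))
  expect_lte(sum(fit$explained_variance), 1 + 1e-9)
  top6 <- names(sort(abs(fit$loadings[, 1]), decreasing = TRUE))[1:6]
  expect_setequal(top6, planted)
  # deterministic sign convention: the largest loading is positive
  expect_gt(fit$loadings[which.max(abs(fit$loadings[, 1])), 1], 0)
})

test_that("PCA is invariant to sample duplication and exactly reconstructs the data", {
  set.seed(43)
  profs <- random_sda_profiles(6)
  m <- sda_matrix(profs)
  fit <- pca_sda(m)
  dup <- sda_matrix(c(profs, lapply(profs, function(p) {
    attr(p, "sample_id") <- paste0(attr(p, "sample_id"), "_dup"); p
  })))
  fit_dup <- pca_sda(dup)
  k <- min(ncol(fit$loadings), ncol(fit_dup$loadings))
  for (j in seq_len(k)) {
    expect_equal(abs(fit_dup$loadings[, j]), abs(fit$loadings[, j]),
                 tolerance = 1e-8)
  }
  # full-rank reconstruction of the centered log2 matrix
  x <- log2(unclass(m))
  xc <- scale(x, center = TRUE, scale = FALSE)
  recon <- fit$scores %*% t(fit$loadings)
  expect_lt(max(abs(recon - xc)), 1e-8)
})

test_that("degenerate all-constant matrices are flagged, not an error", {
  profs <- lapply(1:4, function(i) {
    structure(stats::setNames(rep(2, 61), SENSE_CODONS),
              sample_id = paste0("s", i), class = "sda_profile")
  })
  fit <- pca_sda(sda_matrix(profs))
  expect_true(fit$degenerate)
  expect_equal(unname(fit$explained_variance), rep(0, length(fit$explained_variance)))
  expect_error(pca_sda(sda_matrix(profs[1:2])), "at least 3 samples")
})

test_that("component-marker correlation has the right fixed points and flags constants", {
  set.seed(44)
  s <- stats::setNames(stats::rnorm(10), paste0("s", 1:10))
  expect_equal(correlate_component(s, s)$estimate, 1)
  expect_equal(correlate_component(s, -s)$estimate, -1)
  p <- correlate_component(s, s, method = "pearson")
  expect_equal(p$estimate, 1, tolerance = 1e-12)
  flat <- correlate_component(s, stats::setNames(rep(1, 10), names(s)))
  expect_true(flat$constant_input)
  expect_true(is.na(flat$estimate))
  expect_error(correlate_component(s[1:2], s[1:2]), "at least 3")
})

test_that("marker-correlation sign is recovered across seeds on planted factors", {
  hits <- 0L
  for (seed in 1:20) {
    cfg <- sim_config(seed = seed, n_genes = 60, mean_cds_codons = 60,
                      n_samples_per_condition = 5,
                      factor_codons = c("AGA", "CCA", "GGC"),
                      factor_strength = 0.5, marker_effect = 1)
    co <- generate_cohort(cfg)
    m <- cohort_sda(co)
    fit <- pca_sda(m)
    res <- correlate_component(fit$scores[, 1], marker_expression(co))
    z_cor <- stats::cor(fit$scores[rownames(m), 1], co$truth$factor_z[rownames(m)],
                        method = "spearman")
    if (sign(res$estimate) == sign(z_cor)) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("differential test finds a planted supply shift with the right direction", {
  cfg <- sim_config(seed = 7, n_samples_per_condition = 10,
                    planted_effects = list(list(codon = "AGA", fold_change = 2,
                                                side = "SUPPLY")))
  m <- cohort_sda(generate_cohort(cfg))
  res <- differential_codon_test(m, "A", "B")
  expect_equal(res$codon[1], "AGA")
  expect_equal(res$direction[1], "FAVORED_IN_B")
  expect_gt(res$effect[1], 0)
  expect_true(all(res$q >= res$p))
  # BH adjustment is monotone in the rank of p
  ord <- order(res$p)
  expect_true(all(diff(res$q[ord]) >= -1e-12))
  # swapping the arms flips the direction
  res_swap <- differential_codon_test(m, "B", "A")
  expect_equal(res_swap$direction[res_swap$codon == "AGA"], "FAVORED_IN_A")
  expect_error(differential_codon_test(m, "A", "Z"), "absent")
})

test_that("t-test mode on log SDAw agrees with a direct computation", {
  cfg <- sim_config(seed = 8, n_samples_per_condition = 5)
  m <- cohort_sda(generate_cohort(cfg))
  res <- differential_codon_test(m, "A", "B", method = "t")
  cond <- attr(m, "condition")
  direct <- stats::t.test(log(m[cond == "B", "AGA"]),
                          log(m[cond == "A", "AGA"]))$p.value
  expect_equal(res$p[res$codon == "AGA"], direct, tolerance = 1e-12)
})

test_that("enrichment score matches an independent implementation and is sign-symmetric", {
  skip_if_not_installed("fgsea")
  set.seed(45)
  for (rep in 1:10) {
    scores <- stats::setNames(stats::rnorm(150), sprintf("g%03d", 1:150))
    gene_set <- sample(names(scores), 20)
    res <- preranked_enrichment(scores, gene_set, n_perm = 9, seed = 1)
    sorted <- sort(scores, decreasing = TRUE)
    es_ref <- fgsea::calcGseaStat(unname(sorted),
                                  which(names(sorted) %in% gene_set),
                                  gseaParam = 1)
    expect_equal(res$es, es_ref, tolerance = 1e-9)
    flipped <- preranked_enrichment(-scores, gene_set, n_perm = 9, seed = 1)
    expect_equal(flipped$es, -res$es, tolerance = 1e-9)
  }
})

test_that("a top-decile gene set attains the extreme permutation p-value", {
  set.seed(46)
  scores <- stats::setNames(sort(stats::rnorm(200), decreasing = TRUE),
                            sprintf("g%03d", 1:200))
  res <- preranked_enrichment(scores, names(scores)[1:20], n_perm = 999, seed = 3)
  expect_gt(res$es, 0)
  expect_equal(res$p, 1 / 1000)
  expect_lte(abs(res$es), 1)
  expect_gte(res$p, 1 / (res$n_perm + 1))
})

test_that("enrichment validates its inputs and records seed and n_perm", {
  scores <- stats::setNames(1:10, letters[1:10])
  expect_error(preranked_enrichment(scores, "a", n_perm = 9, seed = 1),
               "fewer than 2")
  expect_error(preranked_enrichment(scores, letters[1:10], n_perm = 9, seed = 1),
               "whole ranking")
  expect_error(preranked_enrichment(scores, c("a", "b"), n_perm = 9),
               "seed is required")
  res <- preranked_enrichment(scores, c("a", "b"), n_perm = 99, seed = 17,
                              set_id = "ab")
  expect_equal(res$seed, 17L)
  expect_equal(res$n_perm, 99L)
  expect_equal(res$set_id, "ab")
})

test_that("consistency counts reproduce X-out-of-Y summaries over cohorts", {
  results <- lapply(1:5, function(seed) {
    cfg <- sim_config(seed = seed, n_genes = 100, mean_cds_codons = 80,
                      n_samples_per_condition = 10,
                      planted_effects = list(list(codon = "AGA",
                                                  fold_change = 2,
                                                  side = "SUPPLY")))
    differential_codon_test(cohort_sda(generate_cohort(cfg)), "A", "B")
  })
  names(results) <- paste0("cohort", 1:5)
  cc <- count_consistent_changes(results, "AGA", alpha = 0.05)
  expect_equal(cc$n_signif_direction_a, 0L)
  expect_equal(cc$n_signif_direction_b, 5L)
  expect_equal(cc$n_cohorts_tested, 5L)
  # single-cohort degenerate case reads that cohort's result
  one <- count_consistent_changes(results[1], "AGA")
  expect_equal(one$n_cohorts_tested, 1L)
  expect_equal(one$n_signif_direction_b,
               as.integer(results[[1]]$q[results[[1]]$codon == "AGA"] < 0.05))
  # a codon missing from one cohort is excluded from the denominator
  results$cohort5 <- results$cohort5[results$cohort5$codon != "AGA", ]
  expect_warning(cc2 <- count_consistent_changes(results, "AGA"), "absent")
  expect_equal(cc2$n_cohorts_tested, 4L)
})
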