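test_that("standardized values evaluate occurrences x carbons / length", {
  expect_equal(stvalue("GG", "G"), 2 * 2 / 2)
  expect_equal(stvalue("GG", "A"), 0)
  expect_equal(stvalue("ACDK", "K"), 1 * 6 / 4)
  expect_error(stvalue("ACDK", "X"), "invalid residue")
})

test_that("summed standardized values conserve the peptide carbon total", {
  set.seed(3)
  peptides <- vapply(sample(7:30, 25, replace = TRUE),
                     random_tryptic_peptide, character(1))
  st <- stvalue_matrix(peptides)
  totals <- rowSums(st) * nchar(peptides)
  expect_equal(unname(totals),
               vapply(peptides, function(p) as.numeric(carbon_count(p)),
                      numeric(1), USE.NAMES = FALSE))
})

test_that("design rows carry one kept peptide each with median RIA", {
  summaries <- tibble::tibble(
    peptide = c("GGGGGGK", "AAAAAAK", "AAAAAAK", "SSSSSSK"),
    species = "A", condition = "gal_labelled",
    n_detected = 3, cv = 0.1,
    median_ria = c(0.1, 0.2, 0.2, 0.3),
    filter_flag = c("kept", "kept", "kept", "removed_cv"))
  design <- build_design(summaries)
  expect_equal(nrow(design), 2)  # duplicate collapsed, removed dropped
  expect_equal(design$ria, c(0.1, 0.2))
  expect_equal(design$st_G[design$peptide == "GGGGGGK"],
               stvalue("GGGGGGK", "G"))
  expect_error(build_design(summaries[4, ]), "no kept")
})

test_that("regression recovers a single labelled amino acid", {
  set.seed(21)
  peptides <- unique(vapply(sample(7:25, 120, replace = TRUE),
                            random_tryptic_peptide, character(1)))
  f <- setNames(rep(NATURAL_C13, 20), AA_ORDER)
  f["A"] <- 0.8
  summaries <- tibble::tibble(
    peptide = peptides, species = "A", condition = "gal_labelled",
    n_detected = 3, cv = 0, filter_flag = "kept",
    median_ria = true_ria(peptides, f) + rnorm(length(peptides), 0, 0.005))
  fit <- fit_aa_contributions(build_design(summaries), "A", "gal_labelled")
  expect_equal(names(which.max(fit$coefficients)), "A")
  expect_equal(fit$n, length(peptides))
  expect_true(fit$r2 > 0.5)
})

test_that("degenerate designs follow the stated rules", {
  peptides <- c("GGGGGGK", "GGAGGAK", "AAAGAAK", "AGAGAGK")
  summaries <- tibble::tibble(
    peptide = peptides, species = "A", condition = "x",
    n_detected = 3, cv = 0, filter_flag = "kept", median_ria = 0)
  fit <- fit_aa_contributions(build_design(summaries))
  expect_true(all(fit$coefficients == 0))
  expect_equal(fit$intercept, 0)
  # residues absent from every peptide are zeroed and flagged
  expect_true(fit$absent[["W"]])
  expect_equal(fit$coefficients[["W"]], 0)
  expect_false(fit$absent[["G"]])
  expect_error(fit_aa_contributions(build_design(summaries)[0, ]), "2")
})

test_that("coefficients scale linearly with the response", {
  set.seed(22)
  peptides <- unique(vapply(sample(7:25, 60, replace = TRUE),
                            random_tryptic_peptide, character(1)))
  summaries <- tibble::tibble(
    peptide = peptides, species = "A", condition = "x",
    n_detected = 3, cv = 0, filter_flag = "kept",
    median_ria = runif(length(peptides), 0.01, 0.4))
  f1 <- fit_aa_contributions(build_design(summaries))
  summaries$median_ria <- summaries$median_ria * 3
  f3 <- fit_aa_contributions(build_design(summaries))
  expect_equal(f3$coefficients, 3 * f1$coefficients, tolerance = 1e-8)
  expect_equal(f3$intercept, 3 * f1$intercept, tolerance = 1e-8)
})

test_that("PCA separates a distant profile and respects conventions", {
  mk <- function(label, coefs) {
    structure(list(species = label, condition = "c",
                   coefficients = setNames(coefs, AA_ORDER),
                   intercept = 0, absent = setNames(rep(FALSE, 20), AA_ORDER),
                   r2 = 1, n = 10), class = "aa_profile")
  }
  set.seed(9)
  base <- runif(20, 0, 0.05)
  near <- lapply(1:3, function(i) mk(paste0("n", i),
                                     base + rnorm(20, 0, 0.003)))
  far <- mk("far", base + 0.5)
  pca <- pca_coefficient_profiles(c(near, list(far)))
  expect_equal(pca$scores$label[which.max(abs(pca$scores$pc1))], "far_c")
  expect_false(pca$degenerate)
  expect_true(pca$explained_variance[1] > 0.9)

  # input order does not change |scores|; sign convention is deterministic
  pca2 <- pca_coefficient_profiles(c(list(far), rev(near)))
  s1 <- pca$scores[order(pca$scores$label), ]
  s2 <- pca2$scores[order(pca2$scores$label), ]
  expect_equal(abs(s1$pc1), abs(s2$pc1), tolerance = 1e-10)
  expect_equal(s1$pc1, s2$pc1, tolerance = 1e-10)

  # two clusters of two: PC1 separates the clusters
  c1 <- lapply(1:2, function(i) mk(paste0("a", i),
                                   base + rnorm(20, 0, 0.002)))
  c2 <- lapply(1:2, function(i) mk(paste0("b", i),
                                   base + 0.3 + rnorm(20, 0, 0.002)))
  pc <- pca_coefficient_profiles(c(c1, c2))
  signs <- sign(pc$scores$pc1)
  expect_equal(signs[1], signs[2])
  expect_equal(signs[3], signs[4])
  expect_true(signs[1] != signs[3])

  # identical profiles are reported degenerate, not decomposed
  same <- lapply(1:4, function(i) mk(paste0("s", i), base))
  pcd <- pca_coefficient_profiles(same)
  expect_true(pcd$degenerate)
  expect_true(all(pcd$scores$pc1 == 0))
  expect_error(pca_coefficient_profiles(same[1:2]), "3 profiles")
})
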