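test_that("RIA estimation inverts the forward envelope model", {
  comp <- peptide_composition("SAMPLER")
  expect_equal(estimate_ria(isotopic_distribution(comp, 0.30), comp), 0.30,
               tolerance = 1e-3)
  expect_lt(abs(estimate_ria(isotopic_distribution(comp, NATURAL_C13), comp) -
                  NATURAL_C13), 1e-3)
  # fully labelled limit: single peak at the carbon count
  nC <- carbon_count(comp)
  peak <- c(numeric(nC), 1)
  expect_gte(estimate_ria(peak, comp), 0.999)
  expect_error(estimate_ria(numeric(0), comp), "empty envelope")
  expect_error(estimate_ria(c(0.5, 0.5), c(H = 2, O = 1)), "no carbon")
})

test_that("RIA recovery holds across enrichments and random peptides", {
  set.seed(101)
  rs <- c(0.05, 0.30, 0.60, 0.95)
  for (i in 1:5) {
    pep <- random_tryptic_peptide(sample(7:30, 1))
    comp <- peptide_composition(pep)
    for (r in rs) {
      env <- isotopic_distribution(comp, r)
      expect_lt(abs(estimate_ria(env, comp) - r), 0.005)
      noisy <- env * exp(rnorm(length(env), 0, 0.05))
      expect_lt(abs(estimate_ria(noisy, comp) - r), 0.05)
    }
  }
})

test_that("replicate CV is sd over mean with its preconditions", {
  expect_equal(replicate_cv(c(0.2, 0.2, 0.2)), 0)
  expect_equal(replicate_cv(c(0.1, 0.3)), sd(c(0.1, 0.3)) / 0.2)
  expect_error(replicate_cv(0.2), "at least two")
  expect_error(replicate_cv(c(-0.1, 0.1)), "mean")
})

test_that("replicate filtering applies the 2-of-3 CV rule literally", {
  obs <- tibble::tibble(
    peptide = c("P1", "P1", "P2", "P2", "P2", "P3"),
    species = "A", condition = "gal_labelled",
    replicate = c(1, 2, 1, 2, 3, 1),
    ria = c(0.10, 0.30, 0.20, 0.22, 0.30, 0.20))
  out <- filter_and_summarize(obs)
  out <- out[match(c("P1", "P2", "P3"), out$peptide), ]
  # P1: 2 of 3 replicates, CV ~ 0.707 > 0.40 -> removed
  expect_equal(out$filter_flag, c("removed_cv", "kept", "removed_support"))
  expect_equal(out$median_ria[2], 0.22)
  # a 3-of-3 peptide with high CV is kept under the literal rule
  obs3 <- tibble::tibble(peptide = "P4", species = "A",
                         condition = "gal_labelled", replicate = 1:3,
                         ria = c(0.05, 0.30, 0.60))
  expect_equal(filter_and_summarize(obs3)$filter_flag, "kept")
  # a 2-of-3 peptide with low CV is kept
  obs2 <- tibble::tibble(peptide = "P5", species = "A",
                         condition = "gal_labelled", replicate = 1:2,
                         ria = c(0.20, 0.21))
  expect_equal(filter_and_summarize(obs2)$filter_flag, "kept")
})

test_that("filter verdicts partition groups and ignore replicate labels", {
  set.seed(5)
  obs <- tidyr::expand_grid(peptide = sprintf("P%02d", 1:20),
                            species = "A", condition = "glc_labelled",
                            replicate = 1:3)
  obs$ria <- runif(nrow(obs), 0.01, 0.5)
  obs <- obs[runif(nrow(obs)) < 0.7, ]  # random dropout
  out <- filter_and_summarize(obs)
  expect_equal(nrow(out), length(unique(obs$peptide)))
  expect_true(all(out$filter_flag %in%
                    c("kept", "removed_cv", "removed_support")))
  # permuting replicate labels changes neither medians nor verdicts
  perm <- obs
  perm$replicate <- c(3, 1, 2)[perm$replicate]
  out_perm <- filter_and_summarize(perm)
  expect_equal(out[order(out$peptide), c("median_ria", "filter_flag")],
               out_perm[order(out_perm$peptide),
                        c("median_ria", "filter_flag")])
})

test_that("RIA distributions summarize kept peptides by group", {
  summaries <- tibble::tibble(
    peptide = sprintf("P%d", 1:4),
    species = "A", condition = "gal_labelled",
    n_detected = 3, cv = 0.1,
    median_ria = c(0.1, 0.2, 0.3, 0.4),
    filter_flag = c("kept", "kept", "kept", "removed_support"))
  d <- ria_distribution(summaries)
  expect_equal(d$n, 3)
  expect_equal(d$median, 0.2)
  expect_equal(d$q1, 0.15)
  expect_error(ria_distribution(summaries[summaries$filter_flag == "x", ]),
               "no kept")
})

test_that("long-format envelope tables estimate one RIA per observation", {
  comp <- peptide_composition("GGGGGGK")
  env1 <- isotopic_distribution(comp, 0.20)
  env2 <- isotopic_distribution(comp, 0.50)
  tbl <- dplyr::bind_rows(
    tibble::tibble(peptide = "GGGGGGK", species = "A",
                   condition = "gal_labelled", replicate = 1L,
                   offset = seq_along(env1) - 1L, intensity = env1),
    tibble::tibble(peptide = "GGGGGGK", species = "A",
                   condition = "gal_labelled", replicate = 2L,
                   offset = seq_along(env2) - 1L, intensity = env2))
  out <- estimate_ria_table(tbl)
  expect_equal(nrow(out), 2)
  expect_equal(sort(out$ria), c(0.20, 0.50), tolerance = 1e-3)
})
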