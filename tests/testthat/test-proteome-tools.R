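test_that("FASTA round trip preserves order, case and strips stops", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1 some description", "MGGGGGGK", ">p2", "aaawwwk*"), path)
  recs <- read_fasta(path)
  expect_equal(recs$id, c("p1", "p2"))
  expect_equal(recs$sequence, c("MGGGGGGK", "AAAWWWK"))

  path2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1", "MGGK", ">empty", ">p3", "MAAK"), path2)
  expect_error(read_fasta(path2), "empty sequence")
  expect_error(read_fasta("/nonexistent/file.fasta"), "no such file")

  out <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, out)
  expect_equal(read_fasta(out), recs)
})

test_that("tryptic digestion follows the K/R-not-before-P rule", {
  expect_setequal(tryptic_digest("AAAAAAKCCCCCCC"),
                  c("AAAAAAK", "CCCCCCC", "AAAAAAKCCCCCCC"))
  expect_setequal(tryptic_digest("AAAKPAAAA", max_missed = 0), "AAAKPAAAA")
  expect_length(tryptic_digest("AAAAAA"), 0)
  expect_error(tryptic_digest("AAAB"), "invalid residue")
})

test_that("digestion matches brute-force enumeration over cleavage sites", {
  set.seed(11)
  for (i in 1:15) {
    protein <- paste(sample(AA_ORDER, sample(20:60, 1), replace = TRUE,
                            prob = c(rep(1, 20))), collapse = "")
    for (mm in 0:2) {
      expect_setequal(tryptic_digest(protein, mm, min_length = 5),
                      oracle_digest(protein, mm, min_length = 5))
    }
  }
})

test_that("index construction maps digest peptides to parent proteins", {
  idx <- build_index(list(list(
    species = "A", provenance = "target",
    records = tibble::tibble(id = "prot1", sequence = "AAAAAAKCCCCCCC"))))
  expect_length(idx, 1)
  expect_setequal(idx[[1]]$peptides$peptide,
                  c("AAAAAAK", "CCCCCCC", "AAAAAAKCCCCCCC"))
  expect_true(all(idx[[1]]$peptides$protein_id == "prot1"))
  expect_error(build_index(list()), "empty")
  expect_error(build_index(list(
    list(species = "A", provenance = "target",
         records = tibble::tibble(id = "p", sequence = "AAAAAAK")),
    list(species = "A", provenance = "target",
         records = tibble::tibble(id = "q", sequence = "CCCCCCK")))),
    "duplicate")

  # same peptide in two proteins of one species maps to both
  idx2 <- build_index(list(list(
    species = "A", provenance = "target",
    records = tibble::tibble(id = c("p", "q"),
                             sequence = c("AAAAAAK", "AAAAAAKGGGGGGR")))))
  hits <- idx2[[1]]$peptides
  expect_setequal(hits$protein_id[hits$peptide == "AAAAAAK"], c("p", "q"))

  # ambiguous residues keep whole proteins out of the index
  idx3 <- build_index(list(list(
    species = "A", provenance = "target",
    records = tibble::tibble(id = c("ok", "amb"),
                             sequence = c("AAAAAAK", "CCCCCXCK")))))
  expect_false(any(grepl("X", idx3[[1]]$peptides$peptide)))
  expect_false("amb" %in% idx3[[1]]$peptides$protein_id)
})

test_that("species assignment partitions verdicts with decoy dominance", {
  indices <- build_index(fixture_proteomes())
  res <- assign_species(
    c("MGGGGGGK", "DDDDDDDK", "AAAAAAK", "CCCCCCK", "YYYYYYY"), indices)
  expect_equal(res$verdict,
               c("species", "species", "shared", "decoy", "unmapped"))
  expect_equal(res$species, c("A", "B", NA, NA, NA))
  # exactly one verdict per peptide, decoy whenever a decoy index matches
  expect_equal(nrow(res), 5)
  decoy_peps <- indices[[3]]$peptides$peptide
  hit <- res$peptide %in% decoy_peps
  expect_true(all(res$verdict[hit] == "decoy"))
})

test_that("adding a decoy proteome never decreases decoy verdicts", {
  prot <- fixture_proteomes()
  peps <- c("MGGGGGGK", "DDDDDDDK", "AAAAAAK", "CCCCCCK", "FFFFFFFK")
  base_idx <- build_index(prot[1:2])
  n0 <- sum(assign_species(peps, base_idx)$verdict == "decoy")
  with_decoy <- build_index(prot)
  n1 <- sum(assign_species(peps, with_decoy)$verdict == "decoy")
  more <- c(prot, list(list(
    species = "D2", provenance = "decoy",
    records = tibble::tibble(id = "d2", sequence = "MGGGGGGK"))))
  n2 <- sum(assign_species(peps, build_index(more))$verdict == "decoy")
  expect_true(n0 <= n1 && n1 <= n2)
})

test_that("protein inference requires two unique peptides", {
  assignments <- tibble::tibble(
    peptide = c("p1", "p2", "p3", "s1", "s2"),
    verdict = c("species", "species", "species", "shared", "shared"),
    species = c("A", "A", "A", NA, NA),
    protein_ids = c("protX", "protX", "protY", "protZ", "protZ"))
  inferred <- infer_proteins(assignments)
  expect_equal(inferred$A, "protX")   # two unique peptides
  expect_false("protY" %in% inferred$A)  # one unique peptide
  expect_false("protZ" %in% unlist(inferred))  # only shared peptides
})

test_that("iFPR is the decoy fraction of identified peptides", {
  expect_equal(compute_ifpr(0, 100), 0)
  expect_equal(compute_ifpr(100, 100), 1)
  expect_equal(compute_ifpr(279, 49365), 279 / 49365)
  expect_error(compute_ifpr(1, 0))
})
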