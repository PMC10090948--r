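# Independent oracles used to freeze expected values: these re-derive
# results by brute force and never call the code paths they check.

# Naive polynomial-expansion oracle for isotope envelopes: multiplies in the
# single-atom isotope pattern one atom at a time.
oracle_envelope <- function(comp, c13_fraction) {
  patterns <- list(
    C  = c(1 - c13_fraction, c13_fraction),
    H  = c(1 - 0.000115, 0.000115),
    N  = c(1 - 0.00364, 0.00364),
    O  = c(0.99757, 0.00038, 0.00205),
    S  = c(0.9499, 0.0075, 0.0425, 0, 0.0001),
    Si = c(0.92223, 0.04685, 0.03092))
  poly_mult <- function(a, b) {
    out <- numeric(length(a) + length(b) - 1)
    for (i in seq_along(a)) {
      for (j in seq_along(b)) {
        out[i + j - 1] <- out[i + j - 1] + a[i] * b[j]
      }
    }
    out
  }
  env <- 1
  for (elem in names(comp)) {
    for (k in seq_len(comp[[elem]])) env <- poly_mult(env, patterns[[elem]])
  }
  env / sum(env)
}

# Brute-force tryptic digestion: enumerate every substring, keep those whose
# boundaries are valid cleavage sites (or termini) and whose internal
# missed-cleavage count is within bounds.
oracle_digest <- function(protein, max_missed, min_length) {
  res <- strsplit(protein, "")[[1]]
  n <- length(res)
  is_site <- function(i) {  # cleavable boundary after position i
    i == 0 || i == n || (res[i] %in% c("K", "R") && res[i + 1] != "P")
  }
  out <- character(0)
  for (a in 1:n) {
    for (b in a:n) {
      if (!is_site(a - 1) || !is_site(b)) next
      internal <- if (b > a) sum(vapply(a:(b - 1), is_site, logical(1))) else 0
      if (internal <= max_missed && (b - a + 1) >= min_length) {
        out <- c(out, substr(protein, a, b))
      }
    }
  }
  unique(out)
}

# Random peptide without internal cleavage sites, ending in K or R.
random_tryptic_peptide <- function(len) {
  body <- sample(setdiff(crossfeedSIP::AA_ORDER, c("K", "R")), len - 1,
                 replace = TRUE)
  paste(c(body, sample(c("K", "R"), 1)), collapse = "")
}

# Tiny two-species-plus-decoy proteome fixture with known peptide overlap.
fixture_proteomes <- function() {
  list(
    list(species = "A", provenance = "target", records = tibble::tibble(
      id = c("A1", "A2"),
      sequence = c("MGGGGGGKAAAAAAKCCCCCCK", "WWWWWWWKAAAAAAK"))),
    list(species = "B", provenance = "target", records = tibble::tibble(
      id = "B1",
      sequence = "DDDDDDDKAAAAAAKEEEEEEK")),
    list(species = "D", provenance = "decoy", records = tibble::tibble(
      id = "D1",
      sequence = "CCCCCCKFFFFFFFK")))
}
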