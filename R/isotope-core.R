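# Elemental compositions and aggregated (nominal-mass) isotopologue arithmetic.
#
# An elemental composition is a named integer vector (e.g. c(C = 3, H = 4,
# O = 3)); an isotope envelope is a numeric vector of relative intensities
# indexed by extra-neutron count, element 1 being the monoisotopic (M+0) peak.
# All heavy-isotope species contributing the same nominal mass shift are
# pooled; fine structure and mass defects are out of scope.

# Per-element natural isotope patterns, indexed by extra neutrons (offset 0
# first). IUPAC representative values; 13C at 0.0107. Sulfur has no +3
# isotope, hence the explicit 0.
.NATURAL_ISOTOPES <- list(
  C  = c(0.9893, 0.0107),
  H  = c(1 - 0.000115, 0.000115),
  N  = c(1 - 0.00364, 0.00364),
  O  = c(1 - 0.00038 - 0.00205, 0.00038, 0.00205),
  S  = c(1 - 0.0075 - 0.0425 - 0.0001, 0.0075, 0.0425, 0, 0.0001),
  Si = c(0.92223, 0.04685, 0.03092)
)

.KNOWN_ELEMENTS <- names(.NATURAL_ISOTOPES)

#' Natural abundance of carbon-13
#'
#' The probability that a carbon atom at natural abundance is 13C. Unlabelled
#' material fit with [estimate_ria()] converges to this baseline.
#' @export
NATURAL_C13 <- 0.0107

.pkg_cache <- new.env(parent = emptyenv())

# ---- compositions -----------------------------------------------------------

.validate_composition <- function(comp) {
  if (is.null(names(comp)) || any(!nzchar(names(comp)))) {
    stop("elemental composition must be a named vector", call. = FALSE)
  }
  unknown <- setdiff(names(comp), .KNOWN_ELEMENTS)
  if (length(unknown) > 0) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (any(comp < 0) || any(comp != floor(comp))) {
    stop("atom counts must be non-negative integers", call. = FALSE)
  }
  storage.mode(comp) <- "double"
  comp
}

#' Parse a chemical formula
#'
#' Parses a Hill-style formula string such as `"C3H4O3"` into a named count
#' vector. Elements are restricted to C, H, N, O, S and Si (the latter for
#' silylated GC-MS fragments); an omitted count means one atom.
#'
#' @param text Formula string, e.g. `"C3H4O3"` or `"CH4"`.
#' @return Named numeric vector of atom counts.
#' @examples
#' parse_formula("C3H4O3")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  if (!nzchar(text)) stop("empty formula", call. = FALSE)
  m <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text)) {
    stop("malformed formula: ", text, call. = FALSE)
  }
  counts <- numeric(0)
  for (tok in tokens) {
    elem <- sub("[0-9]*$", "", tok)
    nstr <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(nstr)) as.numeric(nstr) else 1
    counts[elem] <- (if (elem %in% names(counts)) counts[[elem]] else 0) + n
  }
  .validate_composition(counts)
}

#' Element-wise sum of elemental compositions
#' @param ... Elemental compositions (named count vectors).
#' @return Combined composition.
#' @export
add_compositions <- function(...) {
  comps <- list(...)
  all_elems <- unique(unlist(lapply(comps, names)))
  out <- stats::setNames(numeric(length(all_elems)), all_elems)
  for (comp in comps) out[names(comp)] <- out[names(comp)] + comp
  .validate_composition(out)
}

#' Residue elemental composition table
#'
#' The 20 standard amino-acid residue compositions (residue = amino acid minus
#' water), read from the package's versioned TSV resource and cached.
#'
#' @return Named list mapping one-letter residue codes to compositions.
#' @export
aa_residue_table <- function() {
  if (!is.null(.pkg_cache$residues)) return(.pkg_cache$residues)
  path <- system.file("extdata", "residue_compositions.tsv",
                      package = "crossfeedSIP", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  res <- stats::setNames(lapply(tab$formula, parse_formula), tab$residue)
  .pkg_cache$residues <- res
  res
}

#' Residue order used for coefficient vectors
#'
#' Fixed alphabetical one-letter ordering of the 20 standard residues, used
#' for all serialized amino-acid coefficient profiles.
#' @export
AA_ORDER <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Elemental composition of a peptide
#'
#' Sum of residue compositions plus one water. Ambiguous residue codes
#' (B, Z, X) have no unique elemental formula and are rejected.
#'
#' @param sequence Peptide string in one-letter code.
#' @return Named numeric vector of atom counts.
#' @examples
#' peptide_composition("SAMPLER")
#' @export
peptide_composition <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (!nzchar(sequence)) stop("empty peptide sequence", call. = FALSE)
  residues <- aa_residue_table()
  letters1 <- strsplit(sequence, "")[[1]]
  bad <- setdiff(letters1, names(residues))
  if (length(bad) > 0) {
    stop("non-standard residue(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  counts <- c(C = 0, H = 2, N = 0, O = 1, S = 0)
  for (res in letters1) {
    comp <- residues[[res]]
    counts[names(comp)] <- counts[names(comp)] + comp
  }
  .validate_composition(counts[counts > 0 | names(counts) %in% c("C", "H", "O")])
}

#' Count carbon atoms
#'
#' @param x Peptide string or elemental composition.
#' @return Integer carbon count; for a single residue letter this is the
#'   per-residue carbon count used throughout the amino-acid regression.
#' @examples
#' carbon_count("GG")
#' @export
carbon_count <- function(x) {
  comp <- if (is.character(x)) peptide_composition(x) else .validate_composition(x)
  n <- if ("C" %in% names(comp)) comp[["C"]] else 0
  as.integer(n)
}

# ---- envelopes --------------------------------------------------------------

# Direct linear convolution; sizes here are small enough that FFT overhead
# would dominate.
.conv <- function(a, b) {
  if (length(a) < length(b)) { tmp <- a; a <- b; b <- tmp }
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(b)) {
    idx <- i:(i + length(a) - 1L)
    out[idx] <- out[idx] + b[[i]] * a
  }
  out
}

# Distribution of extra neutrons contributed by n atoms of one element.
# Two-isotope elements use the binomial closed form; multi-isotope elements
# use convolution-by-squaring of the per-atom pattern.
.element_dist <- function(pattern, n) {
  if (n == 0) return(1)
  if (length(pattern) == 2) {
    return(stats::dbinom(0:n, n, pattern[[2]]))
  }
  out <- 1
  base <- pattern
  m <- n
  while (m > 0) {
    if (m %% 2 == 1) out <- .conv(out, base)
    m <- m %/% 2
    if (m > 0) base <- .conv(base, base)
  }
  out
}

.truncate_envelope <- function(env, threshold) {
  env <- env / sum(env)
  keep <- which(env >= threshold)
  if (length(keep) == 0) keep <- which.max(env)
  env <- env[1:max(keep)]
  env / sum(env)
}

# Envelope of everything in `comp` except carbon, at natural abundance.
# Internal fast path shared by isotopic_distribution() and the RIA estimator.
.rest_envelope <- function(comp, threshold = 1e-12) {
  comp <- .validate_composition(comp)
  env <- 1
  for (elem in setdiff(names(comp), "C")) {
    if (comp[[elem]] > 0) {
      env <- .conv(env, .element_dist(.NATURAL_ISOTOPES[[elem]], comp[[elem]]))
    }
  }
  .truncate_envelope(env, threshold)
}

#' Theoretical isotope envelope of a composition
#'
#' Convolves per-element isotope patterns into the aggregated nominal-mass
#' envelope. Carbon atoms carry 13C with probability `c13_fraction` (which
#' includes the natural baseline — pass `NATURAL_C13` for unlabelled
#' material); all other elements stay at natural abundance.
#'
#' @param comp Elemental composition.
#' @param c13_fraction Per-carbon 13C probability in \[0, 1\].
#' @param threshold Relative-intensity truncation threshold in (0, 0.01\];
#'   trailing entries below it are dropped before renormalization.
#' @return Numeric vector of relative intensities summing to 1, element 1
#'   being the M+0 peak.
#' @examples
#' isotopic_distribution(c(C = 2), 0.5)
#' @export
isotopic_distribution <- function(comp, c13_fraction = NATURAL_C13,
                                  threshold = 1e-6) {
  comp <- .validate_composition(comp)
  if (c13_fraction < 0 || c13_fraction > 1) {
    stop("c13_fraction must be in [0, 1]", call. = FALSE)
  }
  if (threshold <= 0 || threshold > 0.01) {
    stop("threshold must be in (0, 0.01]", call. = FALSE)
  }
  nC <- if ("C" %in% names(comp)) comp[["C"]] else 0
  env <- .element_dist(c(1 - c13_fraction, c13_fraction), nC)
  rest <- .rest_envelope(comp)
  if (length(rest) > 1) env <- .conv(env, rest)
  .truncate_envelope(env, threshold)
}

#' Mix isotope envelopes
#'
#' Weighted sum of envelopes renormalized to 1, modelling coexisting peptide
#' populations (e.g. unlabelled and labelled isoforms).
#'
#' @param envelopes List of numeric envelope vectors.
#' @param weights Non-negative weights, at least one positive.
#' @return Normalized envelope of length `max(lengths(envelopes))`.
#' @export
mix_envelopes <- function(envelopes, weights) {
  stopifnot(is.list(envelopes), length(envelopes) == length(weights))
  if (any(weights < 0) || all(weights == 0)) {
    stop("weights must be non-negative with at least one positive",
         call. = FALSE)
  }
  out <- numeric(max(lengths(envelopes)))
  for (i in seq_along(envelopes)) {
    e <- envelopes[[i]]
    out[seq_along(e)] <- out[seq_along(e)] + weights[[i]] * e
  }
  out / sum(out)
}
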