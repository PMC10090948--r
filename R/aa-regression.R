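# Multiple linear regression attributing peptide labelling (RIA) to
# individual amino acids, and PCA over the resulting coefficient profiles.
#
# The predictor for amino acid A in peptide P is the standardized value
#   stvalue(P, A) = o_AP * c_A / len_P
# where o_AP counts occurrences of A in P, c_A is the residue carbon count
# and len_P the peptide length. Summed over A and multiplied by len_P this
# recovers the total carbon count of P.

.residue_carbons <- function() {
  vapply(aa_residue_table()[AA_ORDER], function(c) c[["C"]], numeric(1))
}

#' Standardized amino-acid value of a peptide
#'
#' @param peptide Peptide string.
#' @param amino_acid One of the 20 standard one-letter residue codes.
#' @return `o_AP * c_A / len_P`.
#' @examples
#' stvalue("ACDK", "K")  # 1 * 6 / 4
#' @export
stvalue <- function(peptide, amino_acid) {
  if (!amino_acid %in% AA_ORDER) {
    stop("invalid residue symbol: ", amino_acid, call. = FALSE)
  }
  stvalue_matrix(peptide)[1, amino_acid]
}

#' Standardized-value design matrix for a set of peptides
#'
#' @param peptides Character vector of peptide strings.
#' @return Numeric matrix, one row per peptide, 20 columns in `AA_ORDER`.
#' @export
stvalue_matrix <- function(peptides) {
  carbons <- .residue_carbons()
  counts <- t(vapply(strsplit(peptides, ""), function(res) {
    bad <- setdiff(res, AA_ORDER)
    if (length(bad) > 0) {
      stop("non-standard residue(s): ", paste(unique(bad), collapse = ", "),
           call. = FALSE)
    }
    tabulate(factor(res, levels = AA_ORDER), nbins = length(AA_ORDER))
  }, numeric(length(AA_ORDER))))
  m <- sweep(counts, 2, carbons, `*`) / nchar(peptides)
  dimnames(m) <- list(peptides, AA_ORDER)
  m
}

#' Build the regression design from kept peptide summaries
#'
#' One row per distinct kept peptide; the response is the median RIA.
#'
#' @param summaries Tibble from [filter_and_summarize()] for one species x
#'   condition group (rows with `filter_flag != "kept"` are dropped).
#' @return Tibble with columns `peptide`, `len`, the 20 `st_*` predictors
#'   and `ria`.
#' @export
build_design <- function(summaries) {
  kept <- summaries[summaries$filter_flag == "kept", , drop = FALSE]
  kept <- kept[!duplicated(kept$peptide), , drop = FALSE]
  if (nrow(kept) == 0) stop("no kept peptides to build a design from",
                            call. = FALSE)
  st <- stvalue_matrix(kept$peptide)
  colnames(st) <- paste0("st_", AA_ORDER)
  dplyr::bind_cols(
    tibble::tibble(peptide = kept$peptide, len = nchar(kept$peptide)),
    tibble::as_tibble(st),
    tibble::tibble(ria = kept$median_ria))
}

#' Fit per-amino-acid labelling contributions
#'
#' Ordinary least squares of RIA on the 20 standardized values, with
#' intercept. Residues absent from every peptide yield rank-deficient
#' columns; their coefficients are reported as 0 and flagged.
#'
#' @param design Tibble from [build_design()] (at least 2 rows).
#' @param species,condition Labels stored on the profile.
#' @return An `aa_profile` object: list with `species`, `condition`,
#'   `coefficients` (length 20, `AA_ORDER`), `intercept`, `absent` (logical,
#'   length 20), `r2`, `n`.
#' @export
fit_aa_contributions <- function(design, species = NA_character_,
                                 condition = NA_character_) {
  if (nrow(design) < 2) stop("need at least 2 design rows", call. = FALSE)
  predictors <- paste0("st_", AA_ORDER)
  fit <- stats::lm(stats::reformulate(predictors, response = "ria"),
                   data = design)
  est <- stats::coef(fit)
  coefs <- est[predictors]
  # absent = residue occurs in no peptide; other aliased (collinear)
  # coefficients are zeroed too but not flagged absent
  absent <- colSums(as.matrix(design[, predictors])) == 0
  coefs[is.na(coefs)] <- 0
  names(coefs) <- AA_ORDER
  names(absent) <- AA_ORDER
  r2 <- summary(fit)$r.squared
  structure(list(species = species, condition = condition,
                 coefficients = coefs,
                 intercept = unname(est[["(Intercept)"]]),
                 absent = absent, r2 = r2, n = nrow(design)),
            class = "aa_profile")
}

#' @export
print.aa_profile <- function(x, ...) {
  cat("Amino-acid contribution profile:", x$species, "/", x$condition, "\n")
  cat(sprintf("  n = %d peptides, R^2 = %.3f, intercept = %.4f\n",
              x$n, x$r2, x$intercept))
  top <- sort(x$coefficients, decreasing = TRUE)[1:5]
  cat("  top coefficients:",
      paste(sprintf("%s=%.4f", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a list of coefficient profiles
#'
#' @param profiles List of `aa_profile` objects.
#' @return Long tibble: `species`, `condition`, `residue`, `coefficient`,
#'   `intercept`, `r2`, `n`.
#' @export
tidy_profiles <- function(profiles) {
  dplyr::bind_rows(lapply(profiles, function(p) {
    tibble::tibble(species = p$species, condition = p$condition,
                   residue = AA_ORDER,
                   coefficient = unname(p$coefficients),
                   intercept = p$intercept, r2 = p$r2, n = p$n)
  }))
}

#' PCA over amino-acid coefficient profiles
#'
#' Column-centered, unscaled PCA of the 20-dimensional coefficient vectors.
#' Sign convention: within each component the largest-magnitude loading is
#' made positive, so scores are reproducible across runs and input orders.
#'
#' @param profiles List of at least 3 `aa_profile` objects.
#' @return List with `scores` (tibble `label`, `pc1`, `pc2`), `loadings`
#'   (20 x 2 matrix), `explained_variance` (length-2 fractions), and
#'   `degenerate` (TRUE when all profiles are identical).
#' @export
pca_coefficient_profiles <- function(profiles) {
  if (length(profiles) < 3) stop("need at least 3 profiles", call. = FALSE)
  mat <- t(vapply(profiles, function(p) p$coefficients,
                  numeric(length(AA_ORDER))))
  labels <- vapply(profiles, function(p)
    paste(p$species, p$condition, sep = "_"), character(1))
  rownames(mat) <- labels
  centered <- scale(mat, center = TRUE, scale = FALSE)
  if (all(abs(centered) < 1e-12)) {
    return(list(
      scores = tibble::tibble(label = labels, pc1 = 0, pc2 = 0),
      loadings = matrix(0, ncol(mat), 2,
                        dimnames = list(AA_ORDER, c("PC1", "PC2"))),
      explained_variance = c(NA_real_, NA_real_),
      degenerate = TRUE))
  }
  pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  k <- min(2, ncol(pc$rotation))
  rot <- pc$rotation[, 1:k, drop = FALSE]
  scr <- pc$x[, 1:k, drop = FALSE]
  for (j in seq_len(k)) {
    if (rot[which.max(abs(rot[, j])), j] < 0) {
      rot[, j] <- -rot[, j]
      scr[, j] <- -scr[, j]
    }
  }
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(
    scores = tibble::tibble(label = labels, pc1 = unname(scr[, 1]),
                            pc2 = if (k >= 2) unname(scr[, 2]) else 0),
    loadings = rot,
    explained_variance = c(ev[1], if (k >= 2) ev[2] else NA_real_),
    degenerate = FALSE)
}
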