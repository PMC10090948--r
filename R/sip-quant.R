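# Per-peptide relative isotope abundance (RIA) estimation from observed MS1
# envelopes, replicate-consistency filtering and median summarization.
#
# RIA is the fraction of a peptide's carbon atoms that are 13C, natural
# baseline included: unlabelled material fits to ~0.0107, not 0.

# Fit machinery. The model envelope at enrichment r factorizes as
# binom(nC, r) convolved with the fixed natural envelope of the non-carbon
# atoms, so the expensive part (the rest envelope and the coarse grid of
# model envelopes) is computed once per composition and reused across
# observations of the same peptide.

.RIA_GRID <- seq(0, 1, by = 0.01)

.model_bank <- function(comp, grid = .RIA_GRID) {
  nC <- carbon_count(comp)
  if (nC < 1) stop("composition has no carbon", call. = FALSE)
  rest <- .rest_envelope(comp)
  len <- nC + length(rest)
  # shift matrix: row k (carbon offset k-1) spreads over the rest envelope
  shift <- matrix(0, nrow = nC + 1L, ncol = len)
  for (k in seq_len(nC + 1L)) {
    shift[k, k:(k + length(rest) - 1L)] <- rest
  }
  carbon <- t(vapply(grid, function(r) stats::dbinom(0:nC, nC, r),
                     numeric(nC + 1L)))
  list(nC = nC, rest = rest, grid = grid, envelopes = carbon %*% shift)
}

.model_envelope <- function(bank, r) {
  env <- stats::dbinom(0:bank$nC, bank$nC, r)
  if (length(bank$rest) > 1) env <- .conv(env, bank$rest)
  env
}

.pad_to <- function(x, len) {
  if (length(x) >= len) x[seq_len(len)] else c(x, numeric(len - length(x)))
}

.sse_at <- function(bank, r, obs) {
  model <- .pad_to(.model_envelope(bank, r), length(obs))
  sum((model - obs)^2)
}

# Golden-section minimization of the envelope SSE on [lo, hi], deterministic
# tie-break toward the smaller r via strict improvement comparison.
.golden_refine <- function(bank, obs, lo, hi, tol = 1e-4) {
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
  f1 <- .sse_at(bank, x1, obs); f2 <- .sse_at(bank, x2, obs)
  while ((b - a) > tol) {
    if (f1 <= f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - phi * (b - a); f1 <- .sse_at(bank, x1, obs)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + phi * (b - a); f2 <- .sse_at(bank, x2, obs)
    }
  }
  (a + b) / 2
}

.estimate_ria_batch <- function(envelopes, comp, bank = NULL) {
  if (is.null(bank)) bank <- .model_bank(comp)
  vapply(envelopes, function(obs) {
    if (length(obs) == 0 || sum(obs) <= 0) stop("empty envelope", call. = FALSE)
    obs <- obs / sum(obs)
    width <- max(length(obs), ncol(bank$envelopes))
    obs_p <- .pad_to(obs, width)
    grid_env <- cbind(bank$envelopes,
                      matrix(0, nrow(bank$envelopes),
                             width - ncol(bank$envelopes)))
    sse <- rowSums(sweep(grid_env, 2, obs_p)^2)
    best <- which.min(sse)  # which.min takes the first (smaller r) on ties
    lo <- max(0, bank$grid[best] - 0.01)
    hi <- min(1, bank$grid[best] + 0.01)
    .golden_refine(bank, obs_p, lo, hi)
  }, numeric(1))
}

#' Estimate the relative isotope abundance of a peptide observation
#'
#' Finds the per-carbon 13C fraction `r` whose theoretical envelope (see
#' [isotopic_distribution()]) is closest in unweighted least squares to the
#' observed envelope: a coarse grid search (step 0.01) followed by
#' golden-section refinement to an interval below `1e-4`. The returned value
#' includes the natural 13C baseline, so unlabelled material estimates to
#' about 0.0107.
#'
#' @param envelope Observed intensity vector by mass offset (will be
#'   normalized).
#' @param comp Elemental composition of the peptide (must contain carbon).
#' @return Estimated RIA in \[0, 1\].
#' @examples
#' comp <- peptide_composition("SAMPLER")
#' estimate_ria(isotopic_distribution(comp, 0.30), comp)
#' @export
estimate_ria <- function(envelope, comp) {
  .estimate_ria_batch(list(envelope), comp)[[1]]
}

#' Coefficient of variation across replicates
#'
#' Sample standard deviation divided by the mean; defined only for at least
#' two values with positive mean.
#'
#' @param values Numeric vector of per-replicate RIA values.
#' @return CV as a fraction.
#' @export
replicate_cv <- function(values) {
  if (length(values) < 2) stop("need at least two replicate values",
                               call. = FALSE)
  m <- mean(values)
  if (m <= 0) stop("mean must be positive", call. = FALSE)
  stats::sd(values) / m
}

#' Filter replicate RIA values and summarize per peptide
#'
#' Applies the replicate-consistency rules: peptides detected in a single
#' replicate are dropped (`removed_cv` requires a CV, `removed_support`);
#' peptides detected in exactly two of three replicates with CV above
#' `cv_threshold` are dropped (`removed_cv`); everything else is kept with
#' the median RIA over the available replicates. Peptides detected in all
#' replicates are kept regardless of CV.
#'
#' @param observations Tibble with columns `peptide`, `species`, `condition`,
#'   `replicate`, `ria`.
#' @param n_replicates Number of replicates in the design (default 3).
#' @param cv_threshold CV cutoff as a fraction (default 0.40).
#' @return Tibble with one row per peptide x species x condition: columns
#'   `peptide`, `species`, `condition`, `n_detected`, `cv`, `median_ria`,
#'   `filter_flag` in `{"kept", "removed_cv", "removed_support"}`.
#' @export
filter_and_summarize <- function(observations, n_replicates = 3,
                                 cv_threshold = 0.40) {
  stopifnot(n_replicates >= 2)
  observations |>
    dplyr::group_by(.data$peptide, .data$species, .data$condition) |>
    dplyr::summarise(
      n_detected = dplyr::n_distinct(.data$replicate),
      cv = if (dplyr::n() >= 2 && mean(.data$ria) > 0)
        replicate_cv(.data$ria) else NA_real_,
      median_ria = stats::median(.data$ria),
      .groups = "drop") |>
    dplyr::mutate(
      filter_flag = dplyr::case_when(
        .data$n_detected < 2 ~ "removed_support",
        .data$n_detected == 2 & n_replicates >= 3 &
          !is.na(.data$cv) & .data$cv > cv_threshold ~ "removed_cv",
        TRUE ~ "kept"),
      median_ria = dplyr::if_else(.data$filter_flag == "kept",
                                  .data$median_ria, NA_real_))
}

#' Summarize kept RIA values per species and condition
#'
#' @param summaries Output of [filter_and_summarize()].
#' @return Tibble per species x condition with `n`, `median`, `q1`, `q3`
#'   (quartiles by linear interpolation).
#' @export
ria_distribution <- function(summaries) {
  kept <- summaries[summaries$filter_flag == "kept", , drop = FALSE]
  if (nrow(kept) == 0) stop("no kept peptides", call. = FALSE)
  kept |>
    dplyr::group_by(.data$species, .data$condition) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = stats::median(.data$median_ria),
      q1 = unname(stats::quantile(.data$median_ria, 0.25, type = 7)),
      q3 = unname(stats::quantile(.data$median_ria, 0.75, type = 7)),
      .groups = "drop")
}

#' Estimate RIA for a long-format envelope table
#'
#' Groups a long envelope table (one row per peak) by observation, shares
#' the per-peptide model bank across replicates and conditions, and returns
#' one RIA per observation.
#'
#' @param envelope_table Tibble with columns `peptide`, `species`,
#'   `condition`, `replicate`, `offset`, `intensity`.
#' @return Tibble with columns `peptide`, `species`, `condition`,
#'   `replicate`, `ria`.
#' @export
estimate_ria_table <- function(envelope_table) {
  needed <- c("peptide", "species", "condition", "replicate",
              "offset", "intensity")
  stopifnot(all(needed %in% names(envelope_table)))
  by_pep <- split(envelope_table, envelope_table$peptide)
  res <- purrr::map(by_pep, function(tbl) {
    bank <- .model_bank(peptide_composition(tbl$peptide[[1]]))
    obs <- tbl |>
      dplyr::group_by(.data$species, .data$condition, .data$replicate) |>
      dplyr::arrange(.data$offset, .by_group = TRUE) |>
      dplyr::summarise(envelope = list({
        e <- numeric(max(.data$offset) + 1L)
        e[.data$offset + 1L] <- .data$intensity
        e
      }), .groups = "drop")
    obs$ria <- .estimate_ria_batch(obs$envelope, comp = NULL, bank = bank)
    obs$peptide <- tbl$peptide[[1]]
    obs[, c("peptide", "species", "condition", "replicate", "ria")]
  })
  dplyr::bind_rows(res)
}
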