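# Natural-isotope-abundance correction of GC-MS mass-isotopologue
# distributions (MIDs) and labelled-fraction summaries.
#
# A fragment is modelled with a designated number of tracer carbons (the
# metabolite backbone carbons retained in the fragment); derivatization
# atoms, including Si from TBDMS groups, are part of the fragment formula
# and always at natural abundance.

#' Construct a mass-isotopologue distribution vector
#'
#' @param metabolite Metabolite name.
#' @param fragment Fragment elemental composition or formula string.
#' @param n_tracer Number of tracer (backbone) carbons, at most the fragment
#'   carbon count.
#' @param intensities Non-negative intensities, `M0` first.
#' @param state `"raw"` or `"corrected"`.
#' @return A `mid_vector` object.
#' @export
mid_vector <- function(metabolite, fragment, n_tracer, intensities,
                       state = c("raw", "corrected")) {
  state <- match.arg(state)
  if (is.character(fragment)) fragment <- parse_formula(fragment)
  if (n_tracer > carbon_count(fragment)) {
    stop("n_tracer exceeds fragment carbon count", call. = FALSE)
  }
  if (any(intensities < 0)) stop("negative intensities", call. = FALSE)
  structure(list(metabolite = metabolite, fragment = fragment,
                 n_tracer = as.integer(n_tracer),
                 intensities = as.numeric(intensities), state = state),
            class = "mid_vector")
}

#' Natural-abundance correction matrix for a fragment
#'
#' Column `j` (0-based) is the theoretical envelope of the fragment with `j`
#' tracer carbons fixed as 13C and every remaining atom at natural
#' abundance; measured raw MIDs are this matrix applied to the tracer-only
#' isotopologue fractions.
#'
#' @param fragment Elemental composition or formula string.
#' @param n_tracer Number of tracer carbons.
#' @param n_rows Number of observed mass offsets to keep (default: full
#'   envelope length).
#' @return Matrix of dimension `n_rows x (n_tracer + 1)`.
#' @export
correction_matrix <- function(fragment, n_tracer, n_rows = NULL) {
  if (is.character(fragment)) fragment <- parse_formula(fragment)
  fragment <- .validate_composition(fragment)
  nC <- carbon_count(fragment)
  if (n_tracer > nC) stop("n_tracer exceeds fragment carbon count",
                          call. = FALSE)
  cols <- lapply(0:n_tracer, function(j) {
    rest <- fragment
    rest[["C"]] <- nC - j
    env <- isotopic_distribution(rest, NATURAL_C13, threshold = 1e-9)
    c(numeric(j), env)  # j fixed 13C shift the whole envelope by +j
  })
  full <- max(lengths(cols))
  if (is.null(n_rows)) n_rows <- full
  mat <- matrix(unlist(lapply(cols, .pad_to, len = n_rows)),
                nrow = n_rows, ncol = n_tracer + 1L,
                dimnames = list(paste0("M", 0:(n_rows - 1)),
                                paste0("x", 0:n_tracer)))
  mat
}

#' Correct a raw MID for natural isotope abundance
#'
#' Solves `correction_matrix %*% x = raw` by non-negative least squares
#' (via [pracma::lsqnonneg()]) and renormalizes, exposing the tracer-derived
#' isotopologue fractions `M0..Mn`.
#'
#' @param raw A `mid_vector` in raw state with a non-zero intensity vector.
#' @return A corrected `mid_vector` of length `n_tracer + 1` summing to 1.
#' @export
correct_mid <- function(raw) {
  stopifnot(inherits(raw, "mid_vector"))
  if (raw$state != "raw") stop("input must be in raw state", call. = FALSE)
  if (sum(raw$intensities) <= 0) stop("all-zero MID", call. = FALSE)
  mat <- correction_matrix(raw$fragment, raw$n_tracer,
                           n_rows = length(raw$intensities))
  x <- pracma::lsqnonneg(mat, raw$intensities)$x
  if (sum(x) <= 0) stop("degenerate correction (all-zero solution)",
                        call. = FALSE)
  mid_vector(raw$metabolite, raw$fragment, raw$n_tracer,
             x / sum(x), state = "corrected")
}

#' Labelled fractions of a corrected MID
#'
#' @param corrected A corrected `mid_vector`.
#' @return List with `fractions` (named `M0..Mn`), `total_labelled`
#'   (`1 - M0`) and `fully_labelled` (`Mn`, all tracer carbons heavy).
#' @export
labelled_fraction <- function(corrected) {
  stopifnot(inherits(corrected, "mid_vector"))
  if (corrected$state != "corrected") {
    stop("input must be in corrected state", call. = FALSE)
  }
  f <- corrected$intensities
  names(f) <- paste0("M", seq_along(f) - 1L)
  list(fractions = f,
       total_labelled = 1 - f[["M0"]],
       fully_labelled = f[[length(f)]])
}

#' Correct a long-format MID table
#'
#' @param mid_table Tibble with columns `metabolite`, `fragment_formula`,
#'   `n_tracer_carbons`, `condition`, `replicate`, `m_offset`, `intensity`.
#' @return Tibble with one row per metabolite x condition x replicate:
#'   corrected fractions as a list column `fractions` plus `total_labelled`
#'   and `fully_labelled`.
#' @export
correct_mid_table <- function(mid_table) {
  needed <- c("metabolite", "fragment_formula", "n_tracer_carbons",
              "condition", "replicate", "m_offset", "intensity")
  stopifnot(all(needed %in% names(mid_table)))
  mid_table |>
    dplyr::group_by(.data$metabolite, .data$fragment_formula,
                    .data$n_tracer_carbons, .data$condition,
                    .data$replicate) |>
    dplyr::arrange(.data$m_offset, .by_group = TRUE) |>
    dplyr::summarise(fractions = list({
      raw <- mid_vector(.data$metabolite[[1]], .data$fragment_formula[[1]],
                        .data$n_tracer_carbons[[1]], .data$intensity,
                        state = "raw")
      correct_mid(raw)$intensities
    }), .groups = "drop") |>
    dplyr::mutate(
      total_labelled = vapply(.data$fractions, function(f) 1 - f[[1]],
                              numeric(1)),
      fully_labelled = vapply(.data$fractions, function(f) f[[length(f)]],
                              numeric(1)))
}
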