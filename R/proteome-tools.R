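# FASTA handling, in-silico tryptic digestion, species-unique peptide
# assignment against target and decoy proteomes, protein inference and the
# incorporation false positive rate (iFPR).

#' Read a protein FASTA file
#'
#' Wraps [Biostrings::readAAStringSet()]. Sequences are upper-cased, a
#' terminal stop `*` is stripped, and the identifier is the first whitespace
#' token of the header.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `sequence`, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*$", "", seqs)
  if (any(!nzchar(seqs))) {
    stop("FASTA record with empty sequence in ", path, call. = FALSE)
  }
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1)
  tibble::tibble(id = unname(ids), sequence = unname(seqs))
}

#' Write proteins to FASTA
#'
#' @param records Tibble with columns `id`, `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::AAStringSet(stats::setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, path, width = 60)
  invisible(path)
}

#' In-silico tryptic digestion
#'
#' Cleaves after K or R except when the next residue is P (the MSGF+ trypsin
#' dialect) and returns every product with at most `max_missed` internal
#' missed cleavages and length at least `min_length`, as a unique set in
#' order of first occurrence.
#'
#' @param protein Protein sequence (one-letter code).
#' @param max_missed Maximum internal missed cleavages (default 2).
#' @param min_length Minimum peptide length (default 7).
#' @return Character vector of peptides.
#' @examples
#' tryptic_digest("AAAAAAKCCCCCCC")
#' @export
tryptic_digest <- function(protein, max_missed = 2, min_length = 7) {
  stopifnot(is.character(protein), length(protein) == 1,
            max_missed >= 0, min_length >= 1)
  residues <- strsplit(protein, "")[[1]]
  if (any(!residues %in% c(AA_ORDER))) {
    bad <- setdiff(residues, AA_ORDER)
    stop("invalid residue letter(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  n <- length(residues)
  cut_after <- which(residues %in% c("K", "R"))
  cut_after <- cut_after[cut_after == n | residues[pmin(cut_after + 1, n)] != "P"]
  bounds <- c(0L, cut_after, if (!n %in% cut_after) n)  # fragment end positions
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1]
  n_frag <- length(starts)
  peptides <- character(0)
  for (i in seq_len(n_frag)) {
    for (j in i:min(n_frag, i + max_missed)) {
      if (ends[j] - starts[i] + 1L >= min_length) {
        peptides <- c(peptides, substr(protein, starts[i], ends[j]))
      }
    }
  }
  unique(peptides)
}

#' Build peptide indices for a set of proteomes
#'
#' Digests every protein and maps each peptide to its parent proteins.
#' Proteins containing ambiguous residues (B, Z, X) are excluded from
#' indexing, as they have no unique elemental composition downstream.
#'
#' @param proteomes List of entries, each a list with elements `species`
#'   (label), `records` (tibble `id`/`sequence`) and `provenance`
#'   (`"target"` or `"decoy"`).
#' @param max_missed,min_length Digestion parameters (defaults 2 and 7).
#' @return List of `proteome_index` objects: `species`, `provenance`,
#'   `peptides` (tibble `peptide`/`protein_id`).
#' @export
build_index <- function(proteomes, max_missed = 2, min_length = 7) {
  if (length(proteomes) == 0) stop("empty proteome list", call. = FALSE)
  labels <- vapply(proteomes, `[[`, character(1), "species")
  if (anyDuplicated(labels)) stop("duplicate species labels", call. = FALSE)
  lapply(proteomes, function(p) {
    stopifnot(p$provenance %in% c("target", "decoy"))
    recs <- p$records
    keep <- !grepl("[BZX]", recs$sequence)
    recs <- recs[keep, , drop = FALSE]
    maps <- purrr::map2(recs$sequence, recs$id, function(seq, id) {
      peps <- tryptic_digest(seq, max_missed = max_missed,
                             min_length = min_length)
      if (length(peps) == 0) return(NULL)
      tibble::tibble(peptide = peps, protein_id = id)
    })
    peptides <- dplyr::distinct(dplyr::bind_rows(maps))
    structure(list(species = p$species, provenance = p$provenance,
                   peptides = peptides),
              class = "proteome_index")
  })
}

#' Assign peptides to species against target and decoy indices
#'
#' A peptide matching any decoy proteome is flagged `decoy` (a false-positive
#' candidate) regardless of target matches; a peptide matching two or more
#' target species is `shared`; one matching exactly one target species gets
#' that species label; anything else is `unmapped`.
#'
#' @param peptides Character vector of peptide sequences.
#' @param indices List of `proteome_index` objects from [build_index()].
#' @return Tibble with columns `peptide`, `verdict` (`"species"`, `"shared"`,
#'   `"decoy"`, `"unmapped"`), `species` (label or `NA`), `protein_ids`
#'   (semicolon-joined).
#' @export
assign_species <- function(peptides, indices) {
  stopifnot(length(peptides) > 0, all(nzchar(peptides)))
  peptides <- unique(peptides)
  hits <- dplyr::bind_rows(lapply(indices, function(ix) {
    h <- ix$peptides[ix$peptides$peptide %in% peptides, , drop = FALSE]
    if (nrow(h) == 0) return(NULL)
    tibble::tibble(peptide = h$peptide, species = ix$species,
                   provenance = ix$provenance, protein_id = h$protein_id)
  }))
  out <- tibble::tibble(peptide = peptides, verdict = "unmapped",
                        species = NA_character_, protein_ids = NA_character_)
  if (nrow(hits) == 0) return(out)
  per_pep <- hits |>
    dplyr::group_by(.data$peptide) |>
    dplyr::summarise(
      any_decoy = any(.data$provenance == "decoy"),
      n_target_species = dplyr::n_distinct(
        .data$species[.data$provenance == "target"]),
      target_species = paste(
        sort(unique(.data$species[.data$provenance == "target"])),
        collapse = ";"),
      protein_ids = paste(sort(unique(.data$protein_id)), collapse = ";"),
      .groups = "drop")
  per_pep$verdict <- ifelse(
    per_pep$any_decoy, "decoy",
    ifelse(per_pep$n_target_species >= 2, "shared",
           ifelse(per_pep$n_target_species == 1, "species", "unmapped")))
  per_pep$species <- ifelse(per_pep$verdict == "species",
                            per_pep$target_species, NA_character_)
  out <- dplyr::rows_update(
    out, per_pep[, c("peptide", "verdict", "species", "protein_ids")],
    by = "peptide")
  out[match(peptides, out$peptide), ]
}

#' Infer proteins from species-unique peptides
#'
#' A protein is reported only if at least two distinct species-unique
#' peptides map to it; shared, decoy and unmapped peptides never contribute.
#'
#' @param assignments Tibble from [assign_species()].
#' @return Named list: species label -> character vector of protein ids.
#' @export
infer_proteins <- function(assignments) {
  uniq <- assignments[assignments$verdict == "species", , drop = FALSE]
  if (nrow(uniq) == 0) return(list())
  long <- uniq |>
    dplyr::mutate(protein_id = strsplit(.data$protein_ids, ";")) |>
    tidyr::unnest("protein_id") |>
    dplyr::distinct(.data$species, .data$protein_id, .data$peptide)
  counts <- long |>
    dplyr::group_by(.data$species, .data$protein_id) |>
    dplyr::summarise(n_unique = dplyr::n_distinct(.data$peptide),
                     .groups = "drop") |>
    dplyr::filter(.data$n_unique >= 2)
  split(counts$protein_id, counts$species)
}

#' Incorporation false positive rate
#'
#' Fraction of identified peptides whose labelled isoforms matched a decoy
#' (foreign-organism) database.
#'
#' @param n_decoy_labelled Number of decoy-flagged labelled peptides.
#' @param n_total Total identified peptides (> 0).
#' @return `n_decoy_labelled / n_total`.
#' @examples
#' compute_ifpr(279, 49365)
#' @export
compute_ifpr <- function(n_decoy_labelled, n_total) {
  stopifnot(n_total > 0, n_decoy_labelled >= 0, n_decoy_labelled <= n_total)
  n_decoy_labelled / n_total
}
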