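# Orchestration: one call runs generate -> assign -> estimate -> filter ->
# regress -> PCA -> MID-correct -> report, writing diff-able TSV/JSON stage
# outputs and vector-graphics figures.

#' Build a run configuration
#'
#' Either a synthetic scenario (via `scenario`) or real input paths
#' (`fasta_paths`, `envelope_path`, `mid_path`) must be supplied, not
#' neither.
#'
#' @param out_dir Output directory (created if needed).
#' @param scenario A `labelling_scenario`, or `NULL` for real inputs.
#' @param fasta_paths Named character vector of FASTA paths; names are
#'   species labels, a path named `decoy` is indexed as the decoy proteome.
#' @param envelope_path Long-format envelope TSV (see
#'   [estimate_ria_table()]).
#' @param mid_path Long-format MID TSV (see [correct_mid_table()]), or
#'   `NULL` to skip the metabolite section.
#' @param seed Integer seed; all stage randomness derives from it.
#' @param n_proteins Proteins per synthetic proteome.
#' @param max_missed,min_peptide_length Digestion parameters.
#' @param cv_threshold Replicate CV cutoff (default 0.40).
#' @param n_replicates Replicates in the design (default 3).
#' @return A `run_config` object.
#' @export
run_config <- function(out_dir, scenario = NULL, fasta_paths = NULL,
                       envelope_path = NULL, mid_path = NULL, seed = 1L,
                       n_proteins = 25, max_missed = 2,
                       min_peptide_length = 7, cv_threshold = 0.40,
                       n_replicates = 3) {
  if (is.null(scenario) && (is.null(fasta_paths) || is.null(envelope_path))) {
    stop("supply either a scenario or fasta_paths + envelope_path",
         call. = FALSE)
  }
  stopifnot(cv_threshold > 0, cv_threshold < 1,
            max_missed >= 0, min_peptide_length >= 1)
  structure(list(out_dir = out_dir, scenario = scenario,
                 fasta_paths = fasta_paths, envelope_path = envelope_path,
                 mid_path = mid_path, seed = as.integer(seed),
                 n_proteins = n_proteins, max_missed = max_missed,
                 min_peptide_length = min_peptide_length,
                 cv_threshold = cv_threshold, n_replicates = n_replicates),
            class = "run_config")
}

.write_tsv <- function(x, dir, name) {
  readr::write_tsv(x, file.path(dir, name))
}

#' Run the full cross-feeding inference pipeline
#'
#' Stages: (1) generate or load inputs; (2) index proteomes and assign
#' peptides to species against targets and decoy; (3) estimate per-
#' observation RIA; (4) replicate filtering and median summarization;
#' (5) RIA distributions per species x condition; (6) amino-acid
#' contribution regression per species x labelled condition; (7) PCA over
#' coefficient profiles; (8) natural-abundance correction of metabolite
#' MIDs; (9) report with figures. All stage outputs are written under
#' `config$out_dir`; ground truth (when synthetic) goes to a separate file
#' no stage reads.
#'
#' @param config A `run_config`.
#' @return A `run_report` object (invisibly also serialized to
#'   `report.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  # stage 1: inputs
  if (!is.null(config$scenario)) {
    proteomes <- generate_proteomes(config$seed,
                                    n_proteins = config$n_proteins)
    synth <- synthesize_observations(proteomes, config$scenario)
    envelopes <- synth$envelopes
    mids <- synth$mids
    for (p in proteomes) {
      write_fasta(p$records,
                  file.path(config$out_dir, paste0(p$species, ".fasta")))
    }
    .write_tsv(envelopes, config$out_dir, "envelopes.tsv")
    .write_tsv(mids, config$out_dir, "mids.tsv")
    jsonlite::write_json(
      list(peptides = synth$truth$peptides,
           metabolites = synth$truth$metabolites),
      file.path(config$out_dir, "ground_truth.json"),
      auto_unbox = TRUE, digits = NA)
  } else {
    if (!file.exists(config$envelope_path)) {
      stop("missing envelope file: ", config$envelope_path, call. = FALSE)
    }
    proteomes <- purrr::imap(config$fasta_paths, function(path, label) {
      list(species = label,
           provenance = if (label == "decoy") "decoy" else "target",
           records = read_fasta(path))
    })
    proteomes <- unname(proteomes)
    envelopes <- readr::read_tsv(config$envelope_path,
                                 show_col_types = FALSE)
    mids <- if (!is.null(config$mid_path)) {
      readr::read_tsv(config$mid_path, show_col_types = FALSE)
    }
  }

  # stage 2: assignment against targets + decoy
  indices <- build_index(proteomes, max_missed = config$max_missed,
                         min_length = config$min_peptide_length)
  all_peptides <- unique(envelopes$peptide)
  assignments <- assign_species(all_peptides, indices)
  .write_tsv(assignments, config$out_dir, "assignments.tsv")
  counts <- table(factor(assignments$verdict,
                         levels = c("species", "shared", "decoy", "unmapped")))
  ifpr <- compute_ifpr(unname(counts[["decoy"]]), length(all_peptides))

  # stage 3: per-observation RIA (species-unique peptides only; shared,
  # decoy and unmapped peptides carry no species identity downstream)
  unique_assign <- assignments[assignments$verdict == "species", , drop = FALSE]
  env_unique <- envelopes[envelopes$peptide %in% unique_assign$peptide, ,
                          drop = FALSE]
  env_unique$species <- unique_assign$species[
    match(env_unique$peptide, unique_assign$peptide)]
  ria_obs <- estimate_ria_table(env_unique)
  .write_tsv(ria_obs, config$out_dir, "ria_observations.tsv")

  # stage 4: filtering + medians
  summaries <- filter_and_summarize(ria_obs,
                                    n_replicates = config$n_replicates,
                                    cv_threshold = config$cv_threshold)
  .write_tsv(summaries, config$out_dir, "peptide_summaries.tsv")

  # stage 5: distributions
  ria_summary <- ria_distribution(summaries)
  .write_tsv(ria_summary, config$out_dir, "ria_distributions.tsv")

  # protein inference on species-unique peptides
  proteins <- infer_proteins(assignments)

  # stage 6: regression per species x condition; the unlabelled condition
  # acts as a flat negative-control profile in the comparison
  kept <- summaries[summaries$filter_flag == "kept", , drop = FALSE]
  groups <- unique(kept[, c("species", "condition")])
  profiles <- purrr::pmap(groups, function(species, condition) {
    design <- build_design(kept[kept$species == species &
                                  kept$condition == condition, ])
    fit_aa_contributions(design, species = species, condition = condition)
  })
  profile_tbl <- tidy_profiles(profiles)
  .write_tsv(profile_tbl, config$out_dir, "aa_profiles.tsv")

  # stage 7: PCA (needs >= 3 profiles)
  pca <- if (length(profiles) >= 3) {
    pca_coefficient_profiles(profiles)
  } else {
    message("PCA skipped: fewer than 3 coefficient profiles")
    NULL
  }
  if (!is.null(pca)) {
    .write_tsv(dplyr::mutate(pca$scores,
                             explained_variance_1 = pca$explained_variance[1],
                             explained_variance_2 = pca$explained_variance[2]),
               config$out_dir, "pca_scores.tsv")
  }

  # stage 8: MID correction
  mid_corrected <- if (!is.null(mids) && nrow(mids) > 0) {
    out <- correct_mid_table(mids)
    flat <- out |>
      dplyr::mutate(fractions = vapply(
        .data$fractions, function(f) paste(signif(f, 8), collapse = ";"),
        character(1)))
    .write_tsv(flat, config$out_dir, "mid_corrected.tsv")
    out
  } else {
    message("MID table absent: metabolite section omitted")
    NULL
  }

  report <- make_report(
    list(assignments = assignments, counts = counts, ifpr = ifpr,
         summaries = summaries, ria_summary = ria_summary,
         proteins = proteins, profiles = profiles,
         profile_tbl = profile_tbl, pca = pca,
         mid_corrected = mid_corrected, seed = config$seed),
    config$out_dir)
  invisible(report)
}

#' Assemble the run report and figures
#'
#' Writes `report.json` plus vector figures: RIA box plots per species and
#' condition, amino-acid coefficient profiles, the PCA score plot and
#' corrected-MID bar charts.
#'
#' @param stages Named list of stage outputs (see [run_pipeline()]).
#' @param out_dir Output directory.
#' @return A `run_report` object.
#' @export
make_report <- function(stages, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- stages$counts
  flag_counts <- table(factor(
    stages$summaries$filter_flag,
    levels = c("kept", "removed_cv", "removed_support")))
  report <- list(
    seed = stages$seed,
    peptide_counts = list(
      total = sum(counts),
      per_species = as.list(table(stages$assignments$species[
        stages$assignments$verdict == "species"])),
      shared = unname(counts[["shared"]]),
      decoy = unname(counts[["decoy"]]),
      unmapped = unname(counts[["unmapped"]])),
    ifpr = stages$ifpr,
    proteins_inferred = lapply(stages$proteins, length),
    filter_counts = as.list(flag_counts),
    ria_distributions = stages$ria_summary,
    coefficient_profiles = stages$profile_tbl,
    pca_scores = if (!is.null(stages$pca)) stages$pca$scores,
    pca_explained_variance = if (!is.null(stages$pca))
      stages$pca$explained_variance,
    mid_summary = if (!is.null(stages$mid_corrected))
      stages$mid_corrected[, c("metabolite", "condition", "replicate",
                               "total_labelled", "fully_labelled")])
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")

  kept <- stages$summaries[stages$summaries$filter_flag == "kept", ]
  p_box <- ggplot2::ggplot(kept, ggplot2::aes(
    x = .data$condition, y = .data$median_ria, fill = .data$condition)) +
    ggplot2::geom_boxplot(outlier.size = 0.3) +
    ggplot2::facet_wrap(~species) +
    ggplot2::labs(y = "median RIA (13C fraction)", x = NULL,
                  title = "Peptide RIA distributions") +
    ggplot2::theme_bw() + ggplot2::theme(legend.position = "none")
  ggplot2::ggsave(file.path(out_dir, "ria_boxplots.pdf"), p_box,
                  width = 7, height = 4)

  if (nrow(stages$profile_tbl) > 0) {
    p_coef <- ggplot2::ggplot(stages$profile_tbl, ggplot2::aes(
      x = .data$residue, y = .data$coefficient)) +
      ggplot2::geom_col() +
      ggplot2::facet_grid(species ~ condition) +
      ggplot2::labs(title = "Amino-acid labelling contributions") +
      ggplot2::theme_bw()
    ggplot2::ggsave(file.path(out_dir, "aa_coefficients.pdf"), p_coef,
                    width = 8, height = 5)
  }

  if (!is.null(stages$pca)) {
    p_pca <- ggplot2::ggplot(stages$pca$scores, ggplot2::aes(
      x = .data$pc1, y = .data$pc2, label = .data$label)) +
      ggplot2::geom_point(size = 2) +
      ggplot2::geom_text(vjust = -0.8, size = 3) +
      ggplot2::labs(
        x = sprintf("PC1 (%.0f%%)", 100 * stages$pca$explained_variance[1]),
        y = sprintf("PC2 (%.0f%%)", 100 * stages$pca$explained_variance[2]),
        title = "PCA of coefficient profiles") +
      ggplot2::theme_bw()
    ggplot2::ggsave(file.path(out_dir, "pca_scores.pdf"), p_pca,
                    width = 5, height = 4)
  }

  if (!is.null(stages$mid_corrected)) {
    mid_long <- stages$mid_corrected |>
      dplyr::mutate(id = seq_len(dplyr::n())) |>
      tidyr::unnest_longer("fractions", values_to = "fraction") |>
      dplyr::group_by(.data$id) |>
      dplyr::mutate(isotopologue = paste0("M", dplyr::row_number() - 1L)) |>
      dplyr::ungroup()
    p_mid <- ggplot2::ggplot(mid_long, ggplot2::aes(
      x = .data$isotopologue, y = .data$fraction)) +
      ggplot2::stat_summary(fun = mean, geom = "col") +
      ggplot2::facet_grid(metabolite ~ condition) +
      ggplot2::labs(title = "Corrected mass-isotopologue distributions") +
      ggplot2::theme_bw()
    ggplot2::ggsave(file.path(out_dir, "mid_fractions.pdf"), p_mid,
                    width = 7, height = 4.5)
  }

  structure(report, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("crossfeedSIP run report (seed", x$seed, ")\n")
  cat("  peptides:", x$peptide_counts$total,
      "| shared:", x$peptide_counts$shared,
      "| decoy:", x$peptide_counts$decoy,
      "| unmapped:", x$peptide_counts$unmapped, "\n")
  cat("  iFPR:", signif(x$ifpr, 3), "\n")
  cat("  filter:", paste(names(x$filter_counts),
                         unlist(x$filter_counts), sep = "=",
                         collapse = ", "), "\n")
  print(x$ria_distributions)
  invisible(x)
}
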