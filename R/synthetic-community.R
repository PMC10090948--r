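# Seeded generator of a two-species labelled co-culture dataset: random
# proteomes (two target species plus a decoy), peptide-level MS1 envelopes
# across three labelling regimes and three replicates, and supernatant
# metabolite MIDs -- with full ground truth for recovery testing.
#
# The emulated design: lactose co-culture of a yeast-like species (speciesA)
# and a bacterium-like species (speciesB) under three labelling regimes
# (unlabelled lactose, lactose with the galactose moiety 13C-labelled,
# lactose with the glucose moiety 13C-labelled), three biological
# replicates, Bernoulli peptide detection producing 2-of-3 cases, and
# multiplicative log-normal peak noise.

CONDITIONS <- c("unlabelled", "gal_labelled", "glc_labelled")

# Average proteome residue frequencies (Swiss-Prot-like background), used
# both to draw random protein sequences and to calibrate labelling targets.
.AA_BACKGROUND <- c(
  A = 0.0825, C = 0.0138, D = 0.0545, E = 0.0675, F = 0.0386,
  G = 0.0707, H = 0.0227, I = 0.0596, K = 0.0584, L = 0.0966,
  M = 0.0242, N = 0.0406, P = 0.0470, Q = 0.0393, R = 0.0553,
  S = 0.0656, T = 0.0534, V = 0.0687, W = 0.0108, Y = 0.0292)

#' Background residue frequencies of the generator
#' @return Named numeric vector over the 20 residues (sums to 1).
#' @export
aa_background_frequencies <- function() {
  .AA_BACKGROUND[AA_ORDER] / sum(.AA_BACKGROUND)
}

#' Generate random proteomes for two target species and a decoy
#'
#' Sequences are drawn residue-wise from the background frequency table;
#' the decoy plays the role of foreign-organism sequences used to flag
#' incorrect species assignments. Identical seeds give identical FASTA
#' records; with realistic lengths the inter-species overlap of tryptic
#' peptides is essentially zero (checked to be below 5%).
#'
#' @param seed Integer seed.
#' @param n_proteins Proteins per species (default 25).
#' @param length_range Protein length range, uniform draw (default
#'   `c(120, 450)`, minimum 50).
#' @return List of three proteome entries (`speciesA`, `speciesB`, `decoy`)
#'   in the shape [build_index()] consumes.
#' @export
generate_proteomes <- function(seed, n_proteins = 25,
                               length_range = c(120, 450)) {
  stopifnot(n_proteins >= 1)
  if (length(length_range) != 2 || any(length_range < 50) ||
      length_range[1] > length_range[2]) {
    stop("invalid length distribution (lengths must be >= 50)", call. = FALSE)
  }
  freqs <- aa_background_frequencies()
  make_one <- function(label, provenance, sub_seed) {
    set.seed(sub_seed)
    lens <- sample(length_range[1]:length_range[2], n_proteins, replace = TRUE)
    seqs <- vapply(lens, function(L) {
      paste(sample(AA_ORDER, L, replace = TRUE, prob = freqs), collapse = "")
    }, character(1))
    list(species = label, provenance = provenance,
         records = tibble::tibble(
           id = sprintf("%s_prot%03d", label, seq_len(n_proteins)),
           sequence = seqs))
  }
  proteomes <- list(
    make_one("speciesA", "target", seed),
    make_one("speciesB", "target", seed + 1000003L),
    make_one("decoy", "decoy", seed + 2000003L))
  digests <- lapply(proteomes[1:2], function(p) {
    unique(unlist(lapply(p$records$sequence, tryptic_digest)))
  })
  shared <- length(intersect(digests[[1]], digests[[2]]))
  if (shared / max(1, min(lengths(digests))) >= 0.05) {
    stop("generated proteomes share >= 5% of tryptic peptides", call. = FALSE)
  }
  proteomes
}

# Solve the scaling s so that the expected carbon-weighted 13C fraction over
# the residue background equals the target median RIA:
#   target = natural + s * sum(freq*c*rho) / sum(freq*c)
.calibrate_f <- function(target, rho) {
  freqs <- aa_background_frequencies()
  carbons <- .residue_carbons()
  w_tot <- sum(freqs * carbons)
  w_rho <- sum(freqs * carbons * rho)
  s <- (target - NATURAL_C13) * w_tot / w_rho
  f <- NATURAL_C13 + s * rho
  if (any(f > 1 | f < 0)) stop("labelling target infeasible", call. = FALSE)
  stats::setNames(f, AA_ORDER)
}

#' Default labelling scenario
#'
#' Per-species, per-condition, per-amino-acid 13C fractions calibrated so
#' the expected (carbon-weighted) peptide RIA matches the condition medians
#' the generator emulates: speciesA 0.30 under gal-label and 0.05 under
#' glc-label; speciesB 0.19 under glc-label and 0.15 under gal-label.
#' Medium-supplied amino acids stay at natural abundance in every
#' condition; only the biosynthesized set (G, A, E, Q, S, T, D and C) is
#' elevated, with A, G and C weighted highest under gal-label. Metabolite
#' ground truth: pyruvate and lactate 70% fully labelled under glc-label
#' and 40% under gal-label.
#'
#' @param seed Integer seed stored on the scenario and used for all
#'   stochastic draws in [synthesize_observations()].
#' @param detection_prob Bernoulli detection probability per peptide x
#'   condition x replicate (default 0.85).
#' @param noise_sd Log-scale sd of multiplicative peak noise (default 0.05).
#' @param mid_noise Relative sd of MID intensity noise (default 0.02).
#' @return A `labelling_scenario` object: `f` tibble (species, condition,
#'   residue, f13), `ria_targets`, `metabolites` tibble with true MIDs,
#'   `n_replicates`, `detection_prob`, `noise_sd`, `mid_noise`, `seed`.
#' @export
default_scenario <- function(seed = 1L, detection_prob = 0.85,
                             noise_sd = 0.05, mid_noise = 0.02) {
  biosynth <- c("G", "A", "E", "Q", "S", "T", "D", "C")
  rho_gal <- stats::setNames(numeric(20), AA_ORDER)
  rho_gal[biosynth] <- 0.92
  rho_gal[c("A", "G", "C")] <- 1.00
  rho_glc <- stats::setNames(numeric(20), AA_ORDER)
  rho_glc[biosynth] <- 1.00
  targets <- tibble::tibble(
    species = c("speciesA", "speciesA", "speciesB", "speciesB"),
    condition = c("gal_labelled", "glc_labelled",
                  "gal_labelled", "glc_labelled"),
    target_ria = c(0.30, 0.05, 0.15, 0.19))
  f_rows <- list(tibble::tibble(
    species = rep(c("speciesA", "speciesB"), each = 20),
    condition = "unlabelled", residue = rep(AA_ORDER, 2),
    f13 = NATURAL_C13))
  for (i in seq_len(nrow(targets))) {
    rho <- if (targets$condition[i] == "gal_labelled") rho_gal else rho_glc
    f <- .calibrate_f(targets$target_ria[i], rho)
    f_rows[[i + 1]] <- tibble::tibble(
      species = targets$species[i], condition = targets$condition[i],
      residue = AA_ORDER, f13 = unname(f))
  }
  metabolites <- tibble::tibble(
    metabolite = rep(c("pyruvate", "lactate"), each = 3),
    fragment_formula = rep(c("C9H18NO3Si", "C11H25O3Si2"), each = 3),
    n_tracer_carbons = 3L,
    condition = rep(CONDITIONS, 2),
    true_mid = list(
      c(1, 0, 0, 0), c(0.57, 0.01, 0.02, 0.40), c(0.28, 0.01, 0.01, 0.70),
      c(1, 0, 0, 0), c(0.58, 0.01, 0.01, 0.40), c(0.27, 0.01, 0.02, 0.70)))
  structure(list(f = dplyr::bind_rows(f_rows), ria_targets = targets,
                 metabolites = metabolites, n_replicates = 3L,
                 detection_prob = detection_prob, noise_sd = noise_sd,
                 mid_noise = mid_noise, seed = as.integer(seed)),
            class = "labelling_scenario")
}

#' True RIA of peptides under per-residue labelling fractions
#'
#' Carbon-weighted mean of residue 13C fractions:
#' `sum(o_AP * c_A * f_A) / sum(o_AP * c_A)`.
#'
#' @param peptides Character vector.
#' @param f13 Named numeric vector of per-residue 13C fractions over
#'   `AA_ORDER`.
#' @return Numeric vector of true RIA values in \[0, 1\].
#' @export
true_ria <- function(peptides, f13) {
  st <- stvalue_matrix(peptides) * nchar(peptides)  # o_AP * c_A
  as.numeric((st %*% f13[AA_ORDER]) / rowSums(st))
}

#' Synthesize peptide envelopes and metabolite MIDs for a scenario
#'
#' For every tryptic peptide of the two target proteomes (2 missed
#' cleavages, minimum length 7), every condition and replicate: a Bernoulli
#' detection draw, then the theoretical envelope at the peptide's true RIA
#' with multiplicative log-normal peak noise. Metabolite raw MIDs are the
#' natural-abundance correction matrix applied to the true MID plus
#' proportional noise. All draws flow from `scenario$seed`.
#'
#' @param proteomes Output of [generate_proteomes()].
#' @param scenario A `labelling_scenario`.
#' @return List with `envelopes` (long tibble: peptide, species, condition,
#'   replicate, offset, intensity), `mids` (long tibble: metabolite,
#'   fragment_formula, n_tracer_carbons, condition, replicate, m_offset,
#'   intensity) and `truth` (list with per-peptide true RIA table and the
#'   scenario's true MIDs), kept separate from the pipeline inputs.
#' @export
synthesize_observations <- function(proteomes, scenario) {
  stopifnot(inherits(scenario, "labelling_scenario"))
  targets <- proteomes[vapply(proteomes, `[[`, character(1), "provenance") ==
                         "target"]
  set.seed(scenario$seed + 10007L)
  truth_rows <- list()
  env_rows <- list()
  nrep <- scenario$n_replicates
  for (p in targets) {
    peptides <- unique(unlist(lapply(p$records$sequence, tryptic_digest)))
    comps <- lapply(peptides, peptide_composition)
    f_tbl <- scenario$f[scenario$f$species == p$species, , drop = FALSE]
    for (cond in CONDITIONS) {
      f_cond <- f_tbl[f_tbl$condition == cond, , drop = FALSE]
      f13 <- stats::setNames(
        f_cond$f13[match(AA_ORDER, f_cond$residue)], AA_ORDER)
      ria <- true_ria(peptides, f13)
      truth_rows[[paste(p$species, cond)]] <- tibble::tibble(
        peptide = peptides, species = p$species, condition = cond,
        true_ria = ria)
      envs <- lapply(seq_along(peptides), function(i) {
        isotopic_distribution(comps[[i]], ria[i], threshold = 1e-6)
      })
      lens <- lengths(envs)
      detected <- which(matrix(
        stats::runif(length(peptides) * nrep) <= scenario$detection_prob,
        length(peptides), nrep), arr.ind = TRUE)
      pep_i <- detected[, 1]
      rep_i <- detected[, 2]
      n_peaks <- lens[pep_i]
      intensity <- unlist(envs[pep_i], use.names = FALSE) *
        exp(stats::rnorm(sum(n_peaks), 0, scenario$noise_sd))
      env_rows[[paste(p$species, cond)]] <- tibble::tibble(
        peptide = rep(peptides[pep_i], n_peaks),
        species = p$species, condition = cond,
        replicate = rep(rep_i, n_peaks),
        offset = unlist(lapply(n_peaks, seq_len), use.names = FALSE) - 1L,
        intensity = intensity)
    }
  }
  mid_rows <- list()
  met <- scenario$metabolites
  for (i in seq_len(nrow(met))) {
    mat <- correction_matrix(met$fragment_formula[i], met$n_tracer_carbons[i])
    raw <- as.numeric(mat %*% met$true_mid[[i]])
    for (rep_i in seq_len(scenario$n_replicates)) {
      noisy <- raw + stats::rnorm(length(raw), 0, scenario$mid_noise * raw)
      mid_rows[[length(mid_rows) + 1L]] <- tibble::tibble(
        metabolite = met$metabolite[i],
        fragment_formula = met$fragment_formula[i],
        n_tracer_carbons = met$n_tracer_carbons[i],
        condition = met$condition[i], replicate = rep_i,
        m_offset = seq_along(raw) - 1L, intensity = pmax(noisy, 0))
    }
  }
  list(envelopes = dplyr::bind_rows(env_rows),
       mids = dplyr::bind_rows(mid_rows),
       truth = list(peptides = dplyr::bind_rows(truth_rows),
                    metabolites = met))
}
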