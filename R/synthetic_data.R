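# Synthetic cohorts with known planted structure: CDS sets with
# family-wise Dirichlet codon-usage bias, log-normal tRNA and mRNA
# abundances, two-condition designs with planted per-codon supply/demand
# imbalances, an optional latent "proliferation" factor coupled to a marker
# gene, and full determinism under a fixed seed.

#' Simulation configuration
#'
#' All knobs of the synthetic-cohort generator, with defaults chosen as
#' desk-scale study conditions (see the package vignette for rationale).
#' A fixed seed makes every generated object byte-identical across runs.
#'
#' @param seed Integer RNG seed.
#' @param n_genes Number of coding genes (>= 2).
#' @param mean_cds_codons Mean CDS length in codons (Poisson; min 3,
#'   including start and stop).
#' @param codon_usage_concentration Dirichlet concentration for per-gene
#'   codon preferences within each synonymous family (large values ->
#'   near-uniform usage; small -> strong per-gene bias).
#' @param expression_log_mean,expression_log_sd Log-normal parameters of
#'   baseline gene expression (TPM-like).
#' @param trna_log_mean,trna_log_sd Log-normal parameters of baseline
#'   anticodon abundance.
#' @param noise_log_sd Per-sample multiplicative log-normal noise (sdlog)
#'   applied to both tRNA and expression values.
#' @param n_samples_per_condition Samples per condition (two conditions,
#'   labels from `conditions`).
#' @param planted_effects List of planted imbalances, each a list with
#'   `codon`, `fold_change` (> 0) and `side` (`"SUPPLY"` or `"DEMAND"`),
#'   applied to the second condition only.
#' @param factor_codons Optional codon subset driven by a latent per-sample
#'   factor (one-factor covariation structure across both conditions).
#' @param factor_strength Log2 supply effect per unit of the latent factor
#'   on `factor_codons`' decoders (0 disables).
#' @param marker_effect Log2 coupling of the marker gene's expression to the
#'   latent factor (0 disables).
#' @param marker_gene Id of the marker record; expression-only (never in the
#'   CDS set), so the marker cannot perturb codon demand.
#' @param conditions Two condition labels.
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1, planted_effects = list(
#'   list(codon = "AGA", fold_change = 2, side = "SUPPLY")))
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 200L,
                       mean_cds_codons = 150,
                       codon_usage_concentration = 1,
                       expression_log_mean = 3,
                       expression_log_sd = 1,
                       trna_log_mean = 5,
                       trna_log_sd = 1,
                       noise_log_sd = 0.1,
                       n_samples_per_condition = 10L,
                       planted_effects = list(),
                       factor_codons = NULL,
                       factor_strength = 0,
                       marker_effect = 0,
                       marker_gene = "MKI67",
                       conditions = c("A", "B")) {
  stopifnot(length(seed) == 1L, is.finite(seed),
            n_genes >= 2L, mean_cds_codons >= 3,
            codon_usage_concentration > 0,
            expression_log_sd >= 0, trna_log_sd >= 0, noise_log_sd >= 0,
            n_samples_per_condition >= 2L,
            length(conditions) == 2L, !anyDuplicated(conditions))
  for (eff in planted_effects) {
    stopifnot(is.list(eff), all(c("codon", "fold_change", "side") %in% names(eff)),
              eff$fold_change > 0, eff$side %in% c("SUPPLY", "DEMAND"))
    assert_sense_codon(eff$codon)
  }
  if (!is.null(factor_codons)) assert_sense_codon(factor_codons)
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 mean_cds_codons = mean_cds_codons,
                 codon_usage_concentration = codon_usage_concentration,
                 expression_log_mean = expression_log_mean,
                 expression_log_sd = expression_log_sd,
                 trna_log_mean = trna_log_mean, trna_log_sd = trna_log_sd,
                 noise_log_sd = noise_log_sd,
                 n_samples_per_condition = as.integer(n_samples_per_condition),
                 planted_effects = planted_effects,
                 factor_codons = factor_codons,
                 factor_strength = factor_strength,
                 marker_effect = marker_effect,
                 marker_gene = marker_gene,
                 conditions = conditions),
            class = "sim_config")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- rep(1, length(alpha))
  g / sum(g)
}

# synonymous families over sense codons (single-member families included)
codon_families <- function() {
  split(SENSE_CODONS, codon_aa(SENSE_CODONS))
}

#' Generate a synthetic CDS set
#'
#' Each gene starts with ATG, ends with one stop codon and contains no
#' internal stops. Gene lengths are Poisson around `mean_cds_codons` (min 3
#' codons). Interior amino acids are drawn uniformly over the 20 standard
#' residues; within each synonymous family, codons follow a gene-specific
#' multinomial whose probabilities are Dirichlet-distributed with the
#' configured concentration, giving controllable per-gene codon-usage bias.
#'
#' @param config A [sim_config()].
#' @return A [cds_set()] with gene ids `G0001`, `G0002`, ...
#' @export
generate_cds <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  fams <- codon_families()
  fams <- fams[names(fams) != "*"]
  aas <- names(fams)
  ids <- sprintf("G%04d", seq_len(config$n_genes))
  lens <- pmax(3L, stats::rpois(config$n_genes, config$mean_cds_codons))
  seqs <- character(config$n_genes)
  conc <- config$codon_usage_concentration
  for (i in seq_len(config$n_genes)) {
    n_interior <- lens[i] - 2L
    aa_seq <- sample(aas, n_interior, replace = TRUE)
    cods <- character(n_interior)
    for (aa in unique(aa_seq)) {
      fam <- fams[[aa]]
      idx <- which(aa_seq == aa)
      if (length(fam) == 1L) {
        cods[idx] <- fam
      } else {
        p <- rdirichlet1(rep(conc, length(fam)))
        cods[idx] <- sample(fam, length(idx), replace = TRUE, prob = p)
      }
    }
    stop_cod <- sample(STOP_CODONS, 1L)
    seqs[i] <- paste0("ATG", paste0(cods, collapse = ""), stop_cod)
  }
  names(seqs) <- ids
  cds_set(seqs)
}

#' Generate a two-condition synthetic cohort
#'
#' Builds one shared CDS set, then per-sample tRNA and expression profiles:
#' baseline anticodon abundances and gene expression are log-normal (drawn
#' once per cohort), each sample adds multiplicative log-normal noise.
#' Planted `SUPPLY` effects multiply the abundance of the planted codon's
#' primary decoder (its Watson-Crick anticodon, or the most efficient wobble
#' decoder when no Watson-Crick tRNA exists under the rules) by
#' `fold_change` in the second condition — codon-specific by construction,
#' with only the partial wobble spillover real tRNA repertoires show; planted
#' `DEMAND` effects tilt the second condition's expression toward genes rich
#' in the planted codon (`tpm * fold_change^(f_g / mean(f))`, `f_g` the
#' gene's frequency of the codon). A latent per-sample factor, when enabled,
#' scales the decoders of `factor_codons` by `2^(factor_strength * z_s)` in
#' every sample and couples the expression-only marker gene by
#' `2^(marker_effect * z_s)`.
#'
#' The anticodon universe is the decoder side of the pairing-rule table, so
#' every planted supply effect has a carrier; a planted codon with no
#' decoder under the supplied rules is an error.
#'
#' @param config A [sim_config()].
#' @param rules Pairing rules (default [build_pairing_rules()]).
#' @return A list of class `synthetic_cohort`: `cds`, `trna` (named list of
#'   [trna_profile()]), `expression` (named list of [expression_profile()],
#'   marker record included), `conditions` (sample -> label), and `truth`
#'   (the config plus the drawn latent factor).
#' @export
generate_cohort <- function(config, rules = build_pairing_rules()) {
  stopifnot(inherits(config, "sim_config"))
  assert_pairing_rules(rules)
  cds <- generate_cds(config)  # seeds the stream with config$seed

  anticodon_universe <- sort(unique(rules$anticodon))
  # planted/factor supply effects act on the codon's primary decoder: the
  # Watson-Crick anticodon, falling back to the most efficient wobble
  # decoder.  Scaling every decoder would perturb box neighbors through
  # shared anticodons more than the target codon itself.
  primary_decoder <- function(codon) {
    hit <- rules[rules$codon == codon, , drop = FALSE]
    if (nrow(hit) == 0L) {
      stop(sprintf("planted codon %s has no decoder under these rules", codon),
           call. = FALSE)
    }
    wc <- hit$anticodon[hit$pair_class == "WATSON_CRICK"]
    if (length(wc) > 0L) wc[1L] else hit$anticodon[which.max(hit$efficiency)]
  }
  for (eff in config$planted_effects) {
    if (eff$side == "SUPPLY") primary_decoder(eff$codon)
  }

  n_per <- config$n_samples_per_condition
  cond_labels <- rep(config$conditions, each = n_per)
  sample_ids <- sprintf("%s_%02d", cond_labels, rep(seq_len(n_per), 2L))
  names(cond_labels) <- sample_ids
  n_samples <- length(sample_ids)

  base_trna <- stats::setNames(
    stats::rlnorm(length(anticodon_universe), config$trna_log_mean,
                  config$trna_log_sd),
    anticodon_universe)
  base_tpm <- stats::setNames(
    stats::rlnorm(config$n_genes, config$expression_log_mean,
                  config$expression_log_sd),
    names(cds))
  factor_z <- stats::setNames(stats::rnorm(n_samples), sample_ids)

  counts <- codon_count_matrix(cds)
  freq <- counts / rowSums(counts)

  trna <- vector("list", n_samples)
  expression <- vector("list", n_samples)
  for (k in seq_len(n_samples)) {
    sid <- sample_ids[k]
    in_b <- cond_labels[k] == config$conditions[2L]

    ab <- base_trna * exp(stats::rnorm(length(base_trna), 0, config$noise_log_sd))
    if (!is.null(config$factor_codons) && config$factor_strength != 0) {
      targets <- unique(vapply(config$factor_codons, primary_decoder, ""))
      ab[targets] <- ab[targets] * 2^(config$factor_strength * factor_z[k])
    }
    tpm <- base_tpm * exp(stats::rnorm(length(base_tpm), 0, config$noise_log_sd))
    if (in_b) {
      for (eff in config$planted_effects) {
        if (eff$side == "SUPPLY") {
          ab[primary_decoder(eff$codon)] <-
            ab[primary_decoder(eff$codon)] * eff$fold_change
        } else {
          f <- freq[names(tpm), eff$codon]
          tpm <- tpm * eff$fold_change^(f / mean(f))
        }
      }
    }
    marker <- stats::setNames(
      exp(config$expression_log_mean) * 2^(config$marker_effect * factor_z[k]) *
        exp(stats::rnorm(1L, 0, config$noise_log_sd)),
      config$marker_gene)
    trna[[k]] <- trna_profile(ab, sid)
    expression[[k]] <- expression_profile(c(tpm, marker), sid)
  }
  names(trna) <- sample_ids
  names(expression) <- sample_ids

  structure(list(cds = cds, trna = trna, expression = expression,
                 conditions = cond_labels,
                 truth = list(config = config, factor_z = factor_z)),
            class = "synthetic_cohort")
}

#' Compute the per-sample SDAw matrix of a cohort
#'
#' Runs the full supply/demand pipeline on every sample of a cohort
#' (synthetic or assembled from files): tAI-style supply from the sample's
#' tRNA profile, expression-weighted demand from its expression profile and
#' the shared CDS set, then SDAw, assembled into an [sda_matrix()] carrying
#' the cohort's condition labels.
#'
#' @param cohort A `synthetic_cohort`, or any list with elements `cds`,
#'   `trna`, `expression` and `conditions` of the same shape.
#' @param rules Pairing rules (default [build_pairing_rules()]).
#' @param impute Zero-supply imputation mode, see [supply_weights()].
#' @return An [sda_matrix()].
#' @export
cohort_sda <- function(cohort, rules = build_pairing_rules(),
                       impute = "geomean") {
  stopifnot(all(c("cds", "trna", "expression", "conditions") %in% names(cohort)))
  profiles <- lapply(names(cohort$trna), function(sid) {
    s <- supply_weights(cohort$trna[[sid]], rules, impute = impute)
    e <- cohort$expression[[sid]]
    e <- e[names(e) %in% names(cohort$cds)]  # expression-only records (marker) carry no demand
    d <- demand_weights(e, cohort$cds)
    sda_weights(s, d, sample_id = sid)
  })
  names(profiles) <- names(cohort$trna)
  sda_matrix(profiles, condition = cohort$conditions)
}

#' Extract the marker-gene expression vector of a cohort
#'
#' @param cohort A `synthetic_cohort`.
#' @return Named numeric vector sample -> marker expression.
#' @export
marker_expression <- function(cohort) {
  gene <- cohort$truth$config$marker_gene
  vapply(cohort$expression, function(e) unname(e[gene]), numeric(1L))
}
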