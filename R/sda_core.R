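# Supply-to-demand adaptation: per-codon SDAw, gene-level SDA (geometric
# mean), differential SDA between conditions, and codon classification.
#
# SDAw(c) = supply fraction of c / demand fraction of c, both SUM1-normalized
# over the sense-codon universe, so supply == demand gives SDAw = 1 for every
# codon (the balance point).

#' Per-codon supply-to-demand adaptation weights (SDAw)
#'
#' Elementwise ratio of the SUM1-normalized supply fraction to the
#' SUM1-normalized demand fraction. A codon with zero demand (possible in
#' tiny CDS sets) has no defined SDAw and is dropped from the profile with a
#' warning — never reported as infinite.
#'
#' @param supply,demand `codon_weights` from [supply_weights()] /
#'   [demand_weights()], SUM1-normalized over the same codon universe.
#' @param sample_id Sample identifier attached to the result.
#' @return A named positive numeric vector of class `sda_profile`.
#' @examples
#' w <- rep(1 / 61, 61); names(w) <- SENSE_CODONS
#' s <- structure(w, side = "SUPPLY", normalization = "SUM1",
#'                class = "codon_weights")
#' all(sda_weights(s, s) == 1)
#' @export
sda_weights <- function(supply, demand, sample_id = NULL) {
  for (w in list(supply, demand)) {
    if (!inherits(w, "codon_weights") ||
        !identical(attr(w, "normalization"), "SUM1")) {
      stop("supply and demand must be SUM1-normalized codon_weights",
           call. = FALSE)
    }
  }
  if (!identical(names(supply), names(demand))) {
    stop("supply and demand are defined over different codon universes",
         call. = FALSE)
  }
  zero_demand <- as.numeric(demand) == 0
  if (any(zero_demand)) {
    warning(sprintf("dropping %d codon(s) with zero demand: %s",
                    sum(zero_demand),
                    paste(names(demand)[zero_demand], collapse = ", ")),
            call. = FALSE)
  }
  zero_supply <- !zero_demand & as.numeric(supply) == 0
  if (any(zero_supply)) {
    warning(sprintf("dropping %d codon(s) with zero (unimputed) supply",
                    sum(zero_supply)), call. = FALSE)
  }
  keep <- !zero_demand & !zero_supply
  sdaw <- as.numeric(supply)[keep] / as.numeric(demand)[keep]
  names(sdaw) <- names(supply)[keep]
  if (is.null(sample_id)) sample_id <- attr(supply, "sample_id") %||% "sample"
  structure(sdaw, sample_id = sample_id, class = "sda_profile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify codons as favored, balanced or disfavored
#'
#' SDAw above the favored threshold (default 2) marks excess decoding supply;
#' below the disfavored threshold (default 0.5) marks limiting supply;
#' everything in between — including the boundary values themselves and the
#' balance point 1 — is balanced.
#'
#' @param sdaw Positive numeric vector of SDAw values.
#' @param favored,disfavored Thresholds (defaults 2 and 0.5).
#' @return Factor with levels `DISFAVORED`, `BALANCED`, `FAVORED`.
#' @examples
#' classify_codon(c(2.5, 1, 0.4, 2, 0.5))
#' @export
classify_codon <- function(sdaw, favored = 2, disfavored = 0.5) {
  if (!is.numeric(sdaw) || anyNA(sdaw) || any(sdaw <= 0)) {
    stop("SDAw values must be positive numbers", call. = FALSE)
  }
  stopifnot(disfavored < favored)
  out <- ifelse(sdaw > favored, "FAVORED",
                ifelse(sdaw < disfavored, "DISFAVORED", "BALANCED"))
  factor(out, levels = c("DISFAVORED", "BALANCED", "FAVORED"))
}

#' Gene-level SDA score
#'
#' The geometric mean of SDAw over the gene's sense-codon multiset (each
#' codon occurrence counted), computed in log space:
#' `exp(mean(log sdaw))`. Stop codons never contribute; codons missing from
#' the profile (dropped upstream for zero demand) are excluded from the
#' multiset with a warning.
#'
#' @param cds A [cds_set()].
#' @param profile An [sda_weights()] profile.
#' @param genes Gene ids to score (default: all genes in `cds`).
#' @return A `data.frame` with columns `gene_id`, `score`, `kind =
#'   "GENE_SDA"`, one row per gene, in `genes` order.
#' @export
gene_sda <- function(cds, profile, genes = names(cds)) {
  if (!inherits(cds, "cds_set")) cds <- cds_set(cds)
  if (!inherits(profile, "sda_profile")) {
    stop("profile must be an sda_profile (see sda_weights)", call. = FALSE)
  }
  missing_genes <- setdiff(genes, names(cds))
  if (length(missing_genes) > 0L) {
    stop(sprintf("gene(s) not in CDS set: %s",
                 paste(missing_genes, collapse = ", ")), call. = FALSE)
  }
  counts <- codon_count_matrix(cds[genes])
  if (any(rowSums(counts) == 0L)) {
    stop(sprintf("gene(s) with zero sense codons: %s",
                 paste(genes[rowSums(counts) == 0L], collapse = ", ")),
         call. = FALSE)
  }
  covered <- colnames(counts) %in% names(profile)
  lost <- sum(counts[, !covered, drop = FALSE])
  if (lost > 0L) {
    warning(sprintf(
      "%d codon occurrence(s) fall on codons absent from the SDAw profile and are excluded",
      lost), call. = FALSE)
  }
  counts <- counts[, covered, drop = FALSE]
  n <- rowSums(counts)
  if (any(n == 0L)) {
    stop("gene(s) left with no scoreable codons after profile reconciliation",
         call. = FALSE)
  }
  logw <- log(as.numeric(profile[colnames(counts)]))
  score <- exp(as.numeric(counts %*% logw) / n)
  data.frame(gene_id = genes, score = score, kind = "GENE_SDA",
             stringsAsFactors = FALSE)
}

# arithmetic mean of per-sample SDAw per codon over the codons every sample
# reports; accepts a single profile unchanged
average_sda_profile <- function(profiles, label = "condition") {
  if (inherits(profiles, "sda_profile")) return(profiles)
  stopifnot(is.list(profiles), length(profiles) > 0L)
  common <- Reduce(intersect, lapply(profiles, names))
  if (length(common) == 0L) {
    stop("no codon shared by all profiles in the condition", call. = FALSE)
  }
  m <- vapply(profiles, function(p) as.numeric(p[common]),
              numeric(length(common)))
  avg <- rowMeans(matrix(m, nrow = length(common)))
  structure(stats::setNames(avg, common), sample_id = label,
            class = "sda_profile")
}

#' Differential gene SDA between two conditions
#'
#' Per gene, `deltaSDA = gene SDA under condition A - gene SDA under
#' condition B`. Each condition may be a single SDAw profile or a list of
#' per-sample profiles; cohorts are aggregated by the arithmetic mean of the
#' per-sample SDAw of each codon before gene scoring. The result is sorted
#' by decreasing score with a stable gene-id tiebreak, ready for pre-ranked
#' enrichment.
#'
#' @param profile_a,profile_b An `sda_profile` or a list of them.
#' @param cds A [cds_set()] shared by the two conditions.
#' @param genes Gene ids to score (default: all).
#' @return A `data.frame` `gene_id`, `score`, `kind = "DELTA_SDA"`.
#' @export
delta_sda <- function(profile_a, profile_b, cds, genes = names(cds)) {
  pa <- average_sda_profile(profile_a, "A")
  pb <- average_sda_profile(profile_b, "B")
  common <- intersect(names(pa), names(pb))
  if (length(common) == 0L) stop("no shared codon universe", call. = FALSE)
  pa <- structure(stats::setNames(as.numeric(pa[common]), common),
                  class = "sda_profile", sample_id = "A")
  pb <- structure(stats::setNames(as.numeric(pb[common]), common),
                  class = "sda_profile", sample_id = "B")
  sa <- gene_sda(cds, pa, genes)
  sb <- gene_sda(cds, pb, genes)
  out <- data.frame(gene_id = sa$gene_id, score = sa$score - sb$score,
                    kind = "DELTA_SDA", stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
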