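# Per-codon tRNA supply (tAI-style) and expression-weighted codon demand,
# both returned as labeled relative frequencies over the 61 sense codons.

#' Construct a tRNA abundance profile
#'
#' A named non-negative numeric vector keyed by anticodon (DNA alphabet,
#' written 5'->3'), in any consistent unit (read counts, gene copy numbers,
#' normalized abundance). Anticodons absent from a profile are treated as
#' abundance 0 downstream.
#'
#' @param abundance Named numeric vector, names = anticodon strings.
#' @param sample_id Sample identifier.
#' @return A named numeric vector of class `trna_profile` with attribute
#'   `sample_id`.
#' @examples
#' trna_profile(c(AAA = 10, GAA = 4), "s1")
#' @export
trna_profile <- function(abundance, sample_id = "sample") {
  if (is.null(names(abundance)) || any(names(abundance) == "")) {
    stop("abundance must be named by anticodon", call. = FALSE)
  }
  bad <- nchar(names(abundance)) != 3L | grepl("[^ACGT]", names(abundance))
  if (any(bad)) {
    stop(sprintf("unknown anticodon key(s): %s",
                 paste(unique(names(abundance)[bad]), collapse = ", ")),
         call. = FALSE)
  }
  if (anyDuplicated(names(abundance))) {
    stop("duplicate anticodon keys in profile", call. = FALSE)
  }
  if (!is.numeric(abundance) || anyNA(abundance) || any(abundance < 0)) {
    stop("abundances must be non-negative numbers", call. = FALSE)
  }
  if (all(abundance == 0)) stop("all-zero tRNA profile", call. = FALSE)
  structure(abundance, sample_id = sample_id, class = "trna_profile")
}

#' Construct an mRNA expression profile
#'
#' A named non-negative numeric vector keyed by gene id, in TPM-like units
#' (any non-negative per-gene weight is accepted; demand is scale-invariant).
#'
#' @param tpm Named numeric vector, names = gene ids (unique, non-empty).
#' @param sample_id Sample identifier.
#' @return A named numeric vector of class `expression_profile`.
#' @export
expression_profile <- function(tpm, sample_id = "sample") {
  if (is.null(names(tpm)) || any(names(tpm) == "")) {
    stop("tpm must be named by gene id", call. = FALSE)
  }
  if (anyDuplicated(names(tpm))) {
    stop(sprintf("duplicate gene id(s): %s",
                 paste(unique(names(tpm)[duplicated(names(tpm))]), collapse = ", ")),
         call. = FALSE)
  }
  if (!is.numeric(tpm) || anyNA(tpm) || any(tpm < 0)) {
    stop("expression values must be non-negative numbers", call. = FALSE)
  }
  structure(tpm, sample_id = sample_id, class = "expression_profile")
}

#' Construct and validate a coding-sequence set
#'
#' Named character vector of CDS strings (uppercase DNA), each of length
#' divisible by 3 and at least one codon. Reading frame starts at position 1.
#' In `"lenient"` mode internal stop codons raise a warning; in `"strict"`
#' mode they are an error. A trailing stop codon is always permitted.
#'
#' @param sequences Named character vector of DNA strings, or a
#'   `Biostrings::DNAStringSet`.
#' @param mode Validation mode for internal stop codons.
#' @return A named character vector of class `cds_set`.
#' @examples
#' cds_set(c(g1 = "ATGAAATGA"))
#' @export
cds_set <- function(sequences, mode = c("lenient", "strict")) {
  mode <- match.arg(mode)
  if (methods::is(sequences, "DNAStringSet")) {
    sequences <- as.character(sequences)
  }
  if (is.null(names(sequences)) || any(names(sequences) == "")) {
    stop("CDS sequences must be named by gene id", call. = FALSE)
  }
  if (anyDuplicated(names(sequences))) {
    stop(sprintf("duplicate gene id(s): %s",
                 paste(unique(names(sequences)[duplicated(names(sequences))]),
                       collapse = ", ")), call. = FALSE)
  }
  sequences <- toupper(sequences)
  bad_alpha <- grepl("[^ACGT]", sequences)
  if (any(bad_alpha)) {
    stop(sprintf("non-ACGT characters in gene(s): %s",
                 paste(names(sequences)[bad_alpha], collapse = ", ")),
         call. = FALSE)
  }
  bad_len <- nchar(sequences) %% 3L != 0L | nchar(sequences) < 3L
  if (any(bad_len)) {
    stop(sprintf("CDS length not a positive multiple of 3 for gene(s): %s",
                 paste(names(sequences)[bad_len], collapse = ", ")),
         call. = FALSE)
  }
  has_internal_stop <- vapply(sequences, function(s) {
    cods <- codon_vector(s)
    any(cods[-length(cods)] %in% STOP_CODONS)
  }, logical(1L))
  if (any(has_internal_stop)) {
    msg <- sprintf("internal stop codon(s) in gene(s): %s",
                   paste(names(sequences)[has_internal_stop], collapse = ", "))
    if (mode == "strict") stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  structure(sequences, class = "cds_set")
}

# split a CDS into its frame-0 codon triplets
codon_vector <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

assert_gene_present <- function(cds, gene_id) {
  if (!gene_id %in% names(cds)) {
    stop(sprintf("gene '%s' not found in CDS set", gene_id), call. = FALSE)
  }
  invisible(cds)
}

#' Count codons in coding sequences
#'
#' `codon_counts()` returns the sense-codon counts of one gene (non-
#' overlapping triplets read from position 1), with the number of stop-codon
#' triplets kept separately in attribute `n_stop`. `codon_count_matrix()`
#' returns the gene x sense-codon count matrix for a whole CDS set (stop
#' triplets excluded), computed with `Biostrings::trinucleotideFrequency`.
#'
#' @param cds A [cds_set()].
#' @param gene_id A gene id present in `cds`.
#' @return A named integer vector over codons observed (sense only), with
#'   attribute `n_stop`; or an integer matrix genes x 61 sense codons.
#' @examples
#' codon_counts(cds_set(c(g = "ATGAAATGA")), "g")
#' @export
codon_counts <- function(cds, gene_id) {
  assert_gene_present(cds, gene_id)
  cods <- codon_vector(cds[[gene_id]])
  n_stop <- sum(cods %in% STOP_CODONS)
  tab <- table(cods[!(cods %in% STOP_CODONS)])
  out <- stats::setNames(as.integer(tab), names(tab))
  attr(out, "n_stop") <- n_stop
  out
}

#' @rdname codon_counts
#' @export
codon_count_matrix <- function(cds) {
  if (!inherits(cds, "cds_set")) cds <- cds_set(cds)
  dss <- Biostrings::DNAStringSet(unclass(cds))
  m <- Biostrings::trinucleotideFrequency(dss, step = 3L)
  rownames(m) <- names(cds)
  m[, SENSE_CODONS, drop = FALSE]
}

impute_geomean <- function(w) {
  zero <- w == 0
  if (any(zero) && any(!zero)) {
    w[zero] <- exp(mean(log(w[!zero])))
  }
  w
}

codon_weights <- function(values, side, normalization = "SUM1") {
  structure(values, side = side, normalization = normalization,
            class = "codon_weights")
}

#' Per-codon tRNA decoding supply
#'
#' tAI-style supply: for each sense codon `c`, the raw weight is the sum over
#' pairing rules `(c, a)` of `efficiency x abundance(a)`; anticodons absent
#' from the profile contribute 0. Codons left with zero weight (no decoding
#' tRNA observed) are, by default, imputed with the geometric mean of the
#' non-zero weights before normalization (the tAI convention, so downstream
#' geometric means are not annihilated); `impute = "zero"` leaves them at 0.
#' The result is normalized to sum to 1 over the 61 sense codons.
#'
#' @param trna A [trna_profile()] (or named abundance vector).
#' @param rules Pairing rules from [build_pairing_rules()].
#' @param impute `"geomean"` (default) or `"zero"`.
#' @return A named numeric vector of class `codon_weights` over the 61 sense
#'   codons, attributes `side = "SUPPLY"`, `normalization = "SUM1"`.
#' @examples
#' supply_weights(trna_profile(c(AAA = 1)), impute = "zero")["TTT"]
#' @export
supply_weights <- function(trna, rules = build_pairing_rules(),
                           impute = c("geomean", "zero")) {
  impute <- match.arg(impute)
  if (!inherits(trna, "trna_profile")) trna <- trna_profile(trna)
  assert_pairing_rules(rules)
  ab <- as.numeric(trna)[match(rules$anticodon, names(trna))]
  ab[is.na(ab)] <- 0
  raw <- tapply(rules$efficiency * ab, rules$codon, sum)
  w <- stats::setNames(numeric(length(SENSE_CODONS)), SENSE_CODONS)
  w[names(raw)] <- raw
  if (all(w == 0)) {
    stop("tRNA profile yields zero supply for every codon", call. = FALSE)
  }
  if (impute == "geomean") w <- impute_geomean(w)
  codon_weights(w / sum(w), side = "SUPPLY")
}

#' Expression-weighted codon demand
#'
#' For each sense codon `c`, raw demand is the sum over genes shared between
#' the expression profile and the CDS set of `tpm(g) x count_c(g)`;
#' returned normalized to sum to 1 over the 61 sense codons. With uniform
#' expression this reduces to the pooled codon frequency of the CDS set.
#'
#' @param expr An [expression_profile()] (or named numeric vector).
#' @param cds A [cds_set()].
#' @return A `codon_weights` vector, `side = "DEMAND"`, SUM1-normalized.
#' @export
demand_weights <- function(expr, cds) {
  if (!inherits(expr, "expression_profile")) expr <- expression_profile(expr)
  if (!inherits(cds, "cds_set")) cds <- cds_set(cds)
  shared <- intersect(names(expr), names(cds))
  if (length(shared) == 0L) {
    stop("no gene ids shared between expression profile and CDS set",
         call. = FALSE)
  }
  n_only <- length(names(expr)) - length(shared)
  if (n_only > 0L) {
    warning(sprintf("%d expression record(s) have no CDS and were ignored",
                    n_only), call. = FALSE)
  }
  counts <- codon_count_matrix(cds[shared])
  u <- as.numeric(expr[shared] %*% counts)
  names(u) <- colnames(counts)
  if (sum(u) == 0) stop("total demand is zero (all shared genes at 0 expression?)",
                        call. = FALSE)
  codon_weights(u / sum(u), side = "DEMAND")
}

#' Relative codon usage (RCU) of a codon within a gene
#'
#' The count of `codon` in the gene divided by the summed counts of its
#' synonymous family in that gene. When the family is entirely absent from
#' the gene the value is undefined and returned as `NA` (never 0).
#' `rcu_ranking()` computes the RCU of one codon for every gene in a CDS set,
#' as a gene-score table usable as a pre-ranked enrichment input.
#'
#' @param cds A [cds_set()].
#' @param gene_id Gene id present in `cds`.
#' @param codon A single sense codon.
#' @return `rcu()`: a single value in `[0, 1]` or `NA`. `rcu_ranking()`: a
#'   gene-score `data.frame` (`gene_id`, `score`, `kind = "RCU"`), genes with
#'   undefined RCU dropped.
#' @examples
#' rcu(cds_set(c(g = "AGAAGACGG")), "g", "AGA")  # 2/3 of the Arg family
#' @export
rcu <- function(cds, gene_id, codon) {
  stopifnot(length(codon) == 1L)
  assert_sense_codon(codon)
  if (!inherits(cds, "cds_set")) cds <- cds_set(cds)
  assert_gene_present(cds, gene_id)
  counts <- codon_counts(cds, gene_id)
  family <- SENSE_CODONS[codon_aa(SENSE_CODONS) == codon_aa(codon)]
  fam_total <- sum(counts[intersect(names(counts), family)])
  if (fam_total == 0L) return(NA_real_)
  n <- if (codon %in% names(counts)) counts[[codon]] else 0L
  n / fam_total
}

#' @rdname rcu
#' @export
rcu_ranking <- function(cds, codon) {
  stopifnot(length(codon) == 1L)
  assert_sense_codon(codon)
  if (!inherits(cds, "cds_set")) cds <- cds_set(cds)
  counts <- codon_count_matrix(cds)
  family <- SENSE_CODONS[codon_aa(SENSE_CODONS) == codon_aa(codon)]
  fam_total <- rowSums(counts[, family, drop = FALSE])
  score <- ifelse(fam_total > 0, counts[, codon] / fam_total, NA_real_)
  out <- data.frame(gene_id = rownames(counts), score = unname(score),
                    kind = "RCU", stringsAsFactors = FALSE)
  out <- out[!is.na(out$score), , drop = FALSE]
  out <- out[order(-out$score, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
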