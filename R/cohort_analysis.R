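# Multi-sample analyses over SDAw matrices: PCA with marker correlation,
# per-codon two-condition differential testing with BH control, a pre-ranked
# weighted-KS enrichment statistic, and cross-cohort consistency counts.

#' Assemble per-sample SDAw profiles into a sample x codon matrix
#'
#' Profiles are reconciled to the codons present in every sample (codons
#' dropped upstream in any sample are dropped for all, with a warning), so
#' the matrix has no missing cells.
#'
#' @param profiles Named list of [sda_weights()] profiles (names = sample
#'   ids; unnamed lists use each profile's `sample_id`).
#' @param condition Optional character vector mapping sample -> condition
#'   label (recycled names from `profiles` if unnamed).
#' @return A numeric matrix (samples x codons) of class `sda_matrix` with
#'   attribute `condition`.
#' @export
sda_matrix <- function(profiles, condition = NULL) {
  stopifnot(is.list(profiles), length(profiles) > 0L)
  ids <- names(profiles)
  if (is.null(ids)) {
    ids <- vapply(profiles, function(p) attr(p, "sample_id") %||% "", "")
  }
  if (any(ids == "") || anyDuplicated(ids)) {
    stop("profiles must carry unique sample ids", call. = FALSE)
  }
  common <- Reduce(intersect, lapply(profiles, names))
  n_union <- length(Reduce(union, lapply(profiles, names)))
  if (length(common) == 0L) stop("no codon shared by all samples", call. = FALSE)
  if (length(common) < n_union) {
    warning(sprintf("%d codon(s) absent from some samples were dropped",
                    n_union - length(common)), call. = FALSE)
  }
  common <- sort(common)
  m <- t(vapply(profiles, function(p) as.numeric(p[common]),
                numeric(length(common))))
  dimnames(m) <- list(ids, common)
  if (!is.null(condition)) {
    if (is.null(names(condition))) names(condition) <- ids
    condition <- condition[ids]
    if (anyNA(condition)) stop("condition labels missing for some samples",
                               call. = FALSE)
  }
  structure(m, condition = condition, class = c("sda_matrix", "matrix"))
}

#' PCA of a sample x codon SDAw matrix
#'
#' SDAw values are log2-transformed and each codon is centered (no
#' unit-variance scaling, so high-variance codons drive the components);
#' principal components are then extracted with [stats::prcomp()]. Each
#' component's sign is fixed by making its largest-magnitude loading
#' positive. An all-constant matrix yields a defined degenerate result with
#' all explained variances 0 and `degenerate = TRUE`.
#'
#' @param mat An [sda_matrix()] (or plain samples x codons matrix of
#'   positive values); at least 3 samples and 2 codons.
#' @param n_components Number of components to return (default: all).
#' @param log_transform Apply `log2` first? Default `TRUE`.
#' @return A list with `scores` (samples x components), `loadings`
#'   (codons x components), `explained_variance` (fractions, non-increasing,
#'   summing to at most 1), and `degenerate`.
#' @export
pca_sda <- function(mat, n_components = NULL, log_transform = TRUE) {
  m <- unclass(mat)
  if (nrow(m) < 3L) stop("PCA needs at least 3 samples", call. = FALSE)
  if (ncol(m) < 2L) stop("PCA needs at least 2 codons", call. = FALSE)
  if (log_transform) m <- log2(m)
  max_comp <- min(nrow(m) - 1L, ncol(m))
  if (is.null(n_components)) n_components <- max_comp
  if (n_components > max_comp) {
    stop(sprintf("cannot extract %d components from %d samples x %d codons",
                 n_components, nrow(m), ncol(m)), call. = FALSE)
  }
  total_var <- sum(apply(m, 2L, stats::var))
  if (total_var == 0) {
    k <- n_components
    return(list(
      scores = matrix(0, nrow(m), k, dimnames = list(rownames(m), paste0("PC", seq_len(k)))),
      loadings = matrix(0, ncol(m), k, dimnames = list(colnames(m), paste0("PC", seq_len(k)))),
      explained_variance = stats::setNames(rep(0, k), paste0("PC", seq_len(k))),
      degenerate = TRUE))
  }
  fit <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  k <- n_components
  scores <- fit$x[, seq_len(k), drop = FALSE]
  loadings <- fit$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- fit$sdev^2 / sum(fit$sdev^2)
  list(scores = scores, loadings = loadings,
       explained_variance = stats::setNames(ev[seq_len(k)], colnames(scores)),
       degenerate = FALSE)
}

#' Correlate a principal-component score with a sample marker
#'
#' Spearman by default (robust on the log-ratio scale of SDAw); Pearson
#' optional. Constant input is flagged as undefined (`NA` coefficient)
#' rather than an error.
#'
#' @param scores Named numeric vector of per-sample component scores.
#' @param marker Named numeric vector of per-sample marker values (e.g.
#'   expression of a proliferation marker such as MKI67/Ki-67).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return List with `estimate`, `p.value`, `n`, `method`.
#' @export
correlate_component <- function(scores, marker,
                                method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (!is.null(names(scores)) && !is.null(names(marker))) {
    shared <- intersect(names(scores), names(marker))
    scores <- scores[shared]
    marker <- marker[shared]
  }
  if (length(scores) != length(marker) || length(scores) < 3L) {
    stop("need at least 3 paired observations", call. = FALSE)
  }
  if (stats::sd(scores) == 0 || stats::sd(marker) == 0) {
    return(list(estimate = NA_real_, p.value = NA_real_,
                n = length(scores), method = method, constant_input = TRUE))
  }
  ct <- suppressWarnings(stats::cor.test(scores, marker, method = method))
  list(estimate = unname(ct$estimate), p.value = ct$p.value,
       n = length(scores), method = method, constant_input = FALSE)
}

#' Per-codon differential SDAw test between two conditions
#'
#' For each codon, a two-sided Wilcoxon rank-sum test (default; Welch t-test
#' on log SDAw available) compares the per-sample SDAw between the two
#' conditions. P-values are Benjamini-Hochberg adjusted across the tested
#' codons. The effect is `median SDAw(condition B) - median SDAw(condition
#' A)`; `direction` is `FAVORED_IN_B` for a positive effect, `FAVORED_IN_A`
#' otherwise. Results are sorted by `q`, then decreasing `|effect|`.
#'
#' @param mat An [sda_matrix()] with condition labels (or pass `condition`).
#' @param cond_a,cond_b Condition labels; each must have >= 2 samples.
#' @param condition Optional condition vector overriding the matrix attribute.
#' @param method `"wilcoxon"` (default) or `"t"` (Welch on log SDAw).
#' @return A `data.frame` with columns `codon`, `effect`, `direction`, `p`,
#'   `q`.
#' @export
differential_codon_test <- function(mat, cond_a, cond_b, condition = NULL,
                                    method = c("wilcoxon", "t")) {
  method <- match.arg(method)
  cond <- condition %||% attr(mat, "condition")
  if (is.null(cond)) stop("no condition labels available", call. = FALSE)
  m <- unclass(mat)
  cond <- cond[rownames(m)]
  for (lab in c(cond_a, cond_b)) {
    if (sum(cond == lab, na.rm = TRUE) < 2L) {
      stop(sprintf("condition '%s' absent or has fewer than 2 samples", lab),
           call. = FALSE)
    }
  }
  a <- m[which(cond == cond_a), , drop = FALSE]
  b <- m[which(cond == cond_b), , drop = FALSE]
  p <- vapply(seq_len(ncol(m)), function(j) {
    if (method == "wilcoxon") {
      suppressWarnings(stats::wilcox.test(b[, j], a[, j])$p.value)
    } else {
      stats::t.test(log(b[, j]), log(a[, j]))$p.value
    }
  }, numeric(1L))
  effect <- apply(b, 2L, stats::median) - apply(a, 2L, stats::median)
  out <- data.frame(
    codon = colnames(m),
    effect = unname(effect),
    direction = ifelse(effect > 0, "FAVORED_IN_B", "FAVORED_IN_A"),
    p = p,
    q = stats::p.adjust(p, method = "BH"),
    stringsAsFactors = FALSE)
  out <- out[order(out$q, -abs(out$effect), out$codon), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# weighted Kolmogorov-Smirnov running-sum enrichment score on a descending
# ranking: hits step up proportionally to |score|^exponent, misses step down
# uniformly; ES is the extreme deviation (signed).
ks_enrichment_score <- function(score_sorted, hit, weight_exponent) {
  n <- length(score_sorted)
  n_hit <- sum(hit)
  w <- abs(score_sorted)^weight_exponent
  w_hit <- w * hit
  tot <- sum(w_hit)
  inc <- if (tot > 0) w_hit / tot else hit / n_hit
  dec <- (!hit) / (n - n_hit)
  run <- cumsum(inc - dec)
  run[which.max(abs(run))]
}

#' Pre-ranked gene-set enrichment with permutation p-values
#'
#' Weighted Kolmogorov-Smirnov running-sum statistic on the descending gene
#' ranking (classic pre-ranked GSEA form): at genes in the set the running
#' sum rises in proportion to `|score|^weight_exponent`, elsewhere it falls
#' uniformly; the enrichment score (ES) is the signed extreme of the running
#' sum, in `[-1, 1]`. Significance is assessed by permuting gene labels
#' `n_perm` times under the stated `seed`:
#' `p = (1 + #\{|ES_perm| >= |ES_obs|\}) / (n_perm + 1)`.
#'
#' @param scores Gene-score `data.frame` (`gene_id`, `score`; e.g. from
#'   [delta_sda()] or [rcu_ranking()]) or a named numeric vector. Ranked
#'   descending with a stable gene-id tiebreak.
#' @param gene_set Character vector of gene ids; its intersection with the
#'   scored genes must have >= 2 members and leave >= 1 non-member.
#' @param n_perm Number of label permutations (default 999).
#' @param seed Integer seed recorded in the result (mandatory for
#'   reproducibility).
#' @param weight_exponent Exponent on `|score|` for hit increments
#'   (default 1, the classic weighted statistic; 0 gives the unweighted KS).
#' @param set_id Label for the result row.
#' @return A one-row `data.frame`: `set_id`, `es`, `p`, `n_perm`, `seed`.
#' @export
preranked_enrichment <- function(scores, gene_set, n_perm = 999L, seed,
                                 weight_exponent = 1, set_id = "gene_set") {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (is.data.frame(scores)) {
    v <- stats::setNames(scores$score, scores$gene_id)
  } else {
    v <- scores
  }
  if (is.null(names(v)) || anyDuplicated(names(v))) {
    stop("scores must be uniquely named by gene id", call. = FALSE)
  }
  ord <- order(-v, names(v))
  v <- v[ord]
  hit <- names(v) %in% gene_set
  if (sum(hit) < 2L) {
    stop("gene set shares fewer than 2 genes with the ranking", call. = FALSE)
  }
  if (all(hit)) stop("gene set covers the whole ranking", call. = FALSE)
  es <- ks_enrichment_score(as.numeric(v), hit, weight_exponent)
  n <- length(v)
  n_hit <- sum(hit)
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  perm_es <- vapply(seq_len(n_perm), function(i) {
    ph <- logical(n)
    ph[sample.int(n, n_hit)] <- TRUE
    ks_enrichment_score(as.numeric(v), ph, weight_exponent)
  }, numeric(1L))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  p <- (1 + sum(abs(perm_es) >= abs(es))) / (n_perm + 1)
  data.frame(set_id = set_id, es = es, p = p, n_perm = as.integer(n_perm),
             seed = as.integer(seed), stringsAsFactors = FALSE)
}

#' Count consistent differential-codon changes across cohorts
#'
#' Summarizes how many cohorts call one codon significant in each direction
#' (the "X out of Y cancer types" style of summary): for each cohort's
#' [differential_codon_test()] result, the codon counts toward a direction
#' when its `q` is below `alpha`. Cohorts whose results do not include the
#' codon are flagged and excluded from the denominator.
#'
#' @param results_by_cohort Named list of differential-result data.frames.
#' @param codon A single sense codon.
#' @param alpha Significance level on `q` (default 0.05).
#' @return A list: `n_signif_direction_a`, `n_signif_direction_b`,
#'   `n_cohorts_tested`, `skipped_cohorts`.
#' @export
count_consistent_changes <- function(results_by_cohort, codon, alpha = 0.05) {
  stopifnot(is.list(results_by_cohort), length(results_by_cohort) >= 1L)
  assert_sense_codon(codon)
  n_a <- 0L; n_b <- 0L; tested <- 0L; skipped <- character(0)
  for (nm in seq_along(results_by_cohort)) {
    res <- results_by_cohort[[nm]]
    row <- res[res$codon == codon, , drop = FALSE]
    if (nrow(row) == 0L) {
      skipped <- c(skipped, names(results_by_cohort)[nm] %||% as.character(nm))
      next
    }
    tested <- tested + 1L
    if (row$q[1L] < alpha) {
      if (row$direction[1L] == "FAVORED_IN_A") n_a <- n_a + 1L else n_b <- n_b + 1L
    }
  }
  if (length(skipped) > 0L) {
    warning(sprintf("codon %s absent from cohort(s): %s", codon,
                    paste(skipped, collapse = ", ")), call. = FALSE)
  }
  list(n_signif_direction_a = n_a, n_signif_direction_b = n_b,
       n_cohorts_tested = tested, skipped_cohorts = skipped)
}
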