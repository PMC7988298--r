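# Codon/anticodon algebra and the wobble pairing-rule table.
#
# Every codon-indexed quantity in this package is keyed by codon string.
# Positional 64-vectors exist only inside explicit I/O adapters (see
# read_positional_vector), so misplacing stop codons in an ordered input
# list cannot silently corrupt the pairing rules.

DNA_BASES <- c("A", "C", "G", "T")
DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' The 64 codons of the standard genetic code
#'
#' Character vectors of codon strings (DNA alphabet, uppercase), sorted
#' lexicographically. `STOP_CODONS` is `c("TAA","TAG","TGA")`; `SENSE_CODONS`
#' is the remaining 61.
#'
#' @format Character vectors.
#' @export
ALL_CODONS <- sort(apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES,
                                     stringsAsFactors = FALSE),
                         1L, paste0, collapse = ""))

#' @rdname ALL_CODONS
#' @export
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' @rdname ALL_CODONS
#' @export
SENSE_CODONS <- setdiff(ALL_CODONS, STOP_CODONS)

WOBBLE_CLASSES <- c("GU_34", "IC_34", "IA_34", "UG_34", "CA_34")
PAIR_CLASSES <- c("WATSON_CRICK", WOBBLE_CLASSES)

assert_triplet <- function(x, what = "codon") {
  if (!is.character(x) || length(x) == 0L || anyNA(x)) {
    stop(sprintf("%s must be a non-NA character vector", what), call. = FALSE)
  }
  bad <- nchar(x) != 3L | grepl("[^ACGT]", x)
  if (any(bad)) {
    stop(sprintf("invalid %s string(s): %s", what,
                 paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

assert_codon <- function(x) {
  assert_triplet(x, "codon")
  invisible(x)
}

assert_sense_codon <- function(x) {
  assert_codon(x)
  if (any(x %in% STOP_CODONS)) {
    stop(sprintf("stop codon(s) not allowed here: %s",
                 paste(intersect(x, STOP_CODONS), collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

#' Codon predicates and translation
#'
#' `is_stop_codon()` and `is_sense_codon()` classify codon strings;
#' `codon_aa()` returns the one-letter amino acid (`"*"` for stops) under the
#' standard genetic code.
#'
#' @param codon Character vector of codon strings (uppercase DNA triplets).
#' @return Logical vector, or character vector of amino-acid letters.
#' @examples
#' is_stop_codon(c("TAA", "ATG"))
#' codon_aa(c("AGA", "CGG"))
#' @export
is_stop_codon <- function(codon) {
  assert_codon(codon)
  codon %in% STOP_CODONS
}

#' @rdname is_stop_codon
#' @export
is_sense_codon <- function(codon) {
  assert_codon(codon)
  !(codon %in% STOP_CODONS)
}

#' @rdname is_stop_codon
#' @export
codon_aa <- function(codon) {
  assert_codon(codon)
  unname(Biostrings::GENETIC_CODE[codon])
}

revcomp3 <- function(x) {
  comp <- chartr("ACGT", "TGCA", x)
  paste0(substr(comp, 3L, 3L), substr(comp, 2L, 2L), substr(comp, 1L, 1L))
}

#' Convert between codons and anticodons
#'
#' Anticodons are written 5'->3' in the DNA alphabet, so the anticodon of a
#' codon is its reverse complement: anticodon position 34 (first character)
#' pairs with codon position 3. The map is a bijection on the 64 codons and
#' `anticodon_to_codon(codon_to_anticodon(x)) == x`.
#'
#' @param codon,anticodon Character vector of DNA triplets.
#' @return Character vector of the paired triplets.
#' @examples
#' codon_to_anticodon("TTT")  # "AAA"
#' anticodon_to_codon("CAT")  # "ATG"
#' @export
codon_to_anticodon <- function(codon) {
  assert_codon(codon)
  revcomp3(codon)
}

#' @rdname codon_to_anticodon
#' @export
anticodon_to_codon <- function(anticodon) {
  assert_triplet(anticodon, "anticodon")
  revcomp3(anticodon)
}

#' Selective-constraint penalties for wobble pairing
#'
#' Holds the wobble penalties `s` (one per wobble class, each in `[0, 1]`;
#' decoding efficiency of a rule is `1 - s`) used to build the pairing-rule
#' table, following the tAI convention. Watson-Crick pairs always have
#' `s = 0` and are not configurable.
#'
#' Defaults are the classic tAI selective constraints: G34:U3 = 0.41,
#' I34:C3 = 0.28, I34:A3 = 0.9999, U34:G3 = 0.68, C34:A3 = 0.89 (the last a
#' prokaryote-only lysidine pairing, off by default for eukaryotic data).
#'
#' @param s_GU,s_IC,s_IA,s_UG,s_CA Penalties in `[0, 1]` for the G34:U3,
#'   I34:C3, I34:A3, U34:G3 and C34:A3 wobble classes.
#' @param include_prokaryotic_CA Admit the prokaryote-only C34:A3 (lysidine)
#'   rules? Default `FALSE`.
#' @param strict_family Suppress non-inosine wobble rules whose donor
#'   anticodon natively decodes a different amino acid (or a stop)? Under the
#'   standard code this removes exactly the U34:G3 rules of ATG and TGG, so
#'   Met and Trp keep only their Watson-Crick decoder. Default `TRUE`.
#' @return An object of class `s_params`.
#' @examples
#' s_params()
#' s_params(s_UG = 0.5, strict_family = FALSE)
#' @export
s_params <- function(s_GU = 0.41, s_IC = 0.28, s_IA = 0.9999,
                     s_UG = 0.68, s_CA = 0.89,
                     include_prokaryotic_CA = FALSE,
                     strict_family = TRUE) {
  s <- c(GU_34 = s_GU, IC_34 = s_IC, IA_34 = s_IA, UG_34 = s_UG, CA_34 = s_CA)
  if (!is.numeric(s) || anyNA(s) || any(s < 0) || any(s > 1)) {
    stop("all wobble penalties must be numbers in [0, 1]", call. = FALSE)
  }
  stopifnot(is.logical(include_prokaryotic_CA), length(include_prokaryotic_CA) == 1L,
            is.logical(strict_family), length(strict_family) == 1L)
  structure(list(s = s,
                 include_prokaryotic_CA = include_prokaryotic_CA,
                 strict_family = strict_family),
            class = "s_params")
}

#' @export
print.s_params <- function(x, ...) {
  cat("Wobble selective constraints (efficiency = 1 - s):\n")
  for (cl in names(x$s)) cat(sprintf("  %-6s s = %.4f\n", cl, x$s[[cl]]))
  cat(sprintf("  include_prokaryotic_CA: %s\n", x$include_prokaryotic_CA))
  cat(sprintf("  strict_family:          %s\n", x$strict_family))
  invisible(x)
}

# Wobble donor at anticodon position 34, by the codon's third base:
#   3rd = T -> G34 (G:U), 3rd = C -> A34 read as inosine (I:C),
#   3rd = A -> A34 read as inosine (I:A), 3rd = G -> T34 (U:G).
WOBBLE34_BY_THIRD <- c(T = "G", C = "A", A = "A", G = "T")
WOBBLE_CLASS_BY_THIRD <- c(T = "GU_34", C = "IC_34", A = "IA_34", G = "UG_34")

#' Build the codon-anticodon pairing-rule table
#'
#' For every sense codon, emits exactly one Watson-Crick rule (the reverse
#' complement anticodon, `s = 0`) plus at most one wobble rule determined by
#' the codon's third base, and optionally the prokaryote-only C34:A3 rule for
#' codons ending in A. Stop codons never appear on the codon side. The result
#' is keyed by `(codon, anticodon)` strings; row order (codon, then
#' anticodon, lexicographic) is cosmetic and carries no meaning.
#'
#' With `strict_family = TRUE` (default), Watson-Crick-class wobble donors
#' (G34:U3, U34:G3) are admitted only when the donor anticodon's own
#' Watson-Crick codon is a synonym of the target codon; inosine rules
#' (I34:C3, I34:A3) may cross within their codon box, matching tAI behavior.
#'
#' @param params An [s_params()] object.
#' @return A `data.frame` of class `pairing_rules` with columns `codon`,
#'   `anticodon`, `pair_class`, `s`, `efficiency` (`= 1 - s`).
#' @examples
#' rules <- build_pairing_rules()
#' subset(rules, codon == "TTC")
#' @export
build_pairing_rules <- function(params = s_params()) {
  if (!inherits(params, "s_params")) {
    stop("params must be an s_params object", call. = FALSE)
  }
  sense <- SENSE_CODONS
  wc_anti <- codon_to_anticodon(sense)
  wc <- data.frame(codon = sense, anticodon = wc_anti,
                   pair_class = "WATSON_CRICK", s = 0,
                   stringsAsFactors = FALSE)

  third <- substr(sense, 3L, 3L)
  w_class <- unname(WOBBLE_CLASS_BY_THIRD[third])
  w_anti <- paste0(WOBBLE34_BY_THIRD[third], substr(wc_anti, 2L, 3L))
  wob <- data.frame(codon = sense, anticodon = w_anti,
                    pair_class = w_class, s = unname(params$s[w_class]),
                    stringsAsFactors = FALSE)
  if (params$strict_family) {
    donor_aa <- codon_aa(anticodon_to_codon(wob$anticodon))
    non_inosine <- wob$pair_class %in% c("GU_34", "UG_34")
    cross <- non_inosine & donor_aa != codon_aa(wob$codon)
    wob <- wob[!cross, , drop = FALSE]
  }

  if (params$include_prokaryotic_CA) {
    nna <- sense[third == "A"]
    ca <- data.frame(codon = nna,
                     anticodon = paste0("C", substr(codon_to_anticodon(nna), 2L, 3L)),
                     pair_class = "CA_34", s = unname(params$s[["CA_34"]]),
                     stringsAsFactors = FALSE)
    wob <- rbind(wob, ca)
  }

  rules <- rbind(wc, wob)
  rules$efficiency <- 1 - rules$s
  rules <- rules[order(rules$codon, rules$anticodon), , drop = FALSE]
  rownames(rules) <- NULL
  class(rules) <- c("pairing_rules", "data.frame")
  attr(rules, "params") <- params
  rules
}

assert_pairing_rules <- function(rules) {
  if (!is.data.frame(rules) ||
      !all(c("codon", "anticodon", "pair_class", "s", "efficiency") %in% names(rules))) {
    stop("rules must be a pairing_rules data.frame (see build_pairing_rules)",
         call. = FALSE)
  }
  invisible(rules)
}

#' List the decoders of a codon
#'
#' Returns every pairing rule for one sense codon: the Watson-Crick decoder
#' first, then wobble decoders ordered by pair-class name. Deterministic
#' order; stop codons are a domain error.
#'
#' @param codon A single sense codon string.
#' @param rules A pairing-rule table from [build_pairing_rules()].
#' @return A `data.frame` with columns `anticodon`, `pair_class`, `efficiency`.
#' @examples
#' decoders_of("TTT", build_pairing_rules())
#' @export
decoders_of <- function(codon, rules = build_pairing_rules()) {
  stopifnot(length(codon) == 1L)
  assert_sense_codon(codon)
  assert_pairing_rules(rules)
  hit <- rules[rules$codon == codon, c("anticodon", "pair_class", "efficiency"),
               drop = FALSE]
  ord <- order(hit$pair_class != "WATSON_CRICK", hit$pair_class)
  hit <- hit[ord, , drop = FALSE]
  rownames(hit) <- NULL
  hit
}

#' Read and write pairing-rule tables as TSV
#'
#' Rule tables are exchanged as TSV with header
#' `codon  anticodon  pair_class  s`, one rule per row, sorted by codon then
#' anticodon. `read_rules_tsv()` validates every field and recomputes
#' `efficiency = 1 - s`.
#'
#' @param rules A `pairing_rules` data.frame.
#' @param path File path.
#' @return `write_rules_tsv()` returns `path` invisibly; `read_rules_tsv()`
#'   returns a `pairing_rules` data.frame.
#' @export
write_rules_tsv <- function(rules, path) {
  assert_pairing_rules(rules)
  out <- rules[order(rules$codon, rules$anticodon),
               c("codon", "anticodon", "pair_class", "s"), drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rules_tsv
#' @export
read_rules_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("codon", "anticodon", "pair_class", "s")
  if (!all(need %in% names(tab))) {
    stop(sprintf("rule table %s must have columns: %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  assert_sense_codon(tab$codon)
  assert_triplet(tab$anticodon, "anticodon")
  if (!all(tab$pair_class %in% PAIR_CLASSES)) {
    stop("unknown pair_class in rule table", call. = FALSE)
  }
  if (any(tab$s < 0 | tab$s > 1)) stop("s values must lie in [0, 1]", call. = FALSE)
  tab <- tab[order(tab$codon, tab$anticodon), need, drop = FALSE]
  tab$efficiency <- 1 - tab$s
  rownames(tab) <- NULL
  class(tab) <- c("pairing_rules", "data.frame")
  tab
}
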