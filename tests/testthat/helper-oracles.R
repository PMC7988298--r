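# Independent oracles and small fixture builders. These deliberately avoid
# the package's own string machinery: complementation and reversal are done
# with an explicit base-by-base loop so the oracle cannot inherit a bug from
# the implementation it checks.

oracle_revcomp <- function(x) {
  comp_table <- list(A = "T", C = "G", G = "C", T = "A")
  vapply(x, function(s) {
    chars <- strsplit(s, "")[[1]]
    paste(unlist(comp_table[rev(chars)]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

oracle_stops <- c("TAA", "TAG", "TGA")

oracle_translate <- function(codon) {
  # independent lookup built from seqinr's genetic-code utilities
  aa <- seqinr::translate(strsplit(codon, "")[[1]])
  aa
}

# Enumerates all 64 x 64 codon/anticodon combinations and keeps those
# admissible under the textual wobble rules:
#   - Watson-Crick: anticodon is the exact reverse complement (s = 0)
#   - positions 35,36 must always reverse-complement codon positions 2,1;
#     position 34 may wobble by the codon's third base:
#       3rd T + G34 -> GU_34;  3rd C + A34 -> IC_34 (inosine);
#       3rd A + A34 -> IA_34 (inosine);  3rd G + T34 -> UG_34;
#       3rd A + C34 -> CA_34 (prokaryote-only, behind the flag)
#   - no stop codon on the codon side
#   - strict family mode: non-inosine wobble donors (GU_34, UG_34) must
#     natively decode a synonym of the target codon
oracle_pairing_rules <- function(s = c(GU_34 = 0.41, IC_34 = 0.28,
                                       IA_34 = 0.9999, UG_34 = 0.68,
                                       CA_34 = 0.89),
                                 include_CA = FALSE, strict = TRUE) {
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  rows <- list()
  for (codon in codons) {
    if (codon %in% oracle_stops) next
    for (anticodon in codons) {
      wc <- oracle_revcomp(codon)
      if (substr(anticodon, 2, 3) != substr(wc, 2, 3)) next
      third <- substr(codon, 3, 3)
      a34 <- substr(anticodon, 1, 1)
      cls <- NULL
      if (anticodon == wc) {
        cls <- "WATSON_CRICK"
      } else if (third == "T" && a34 == "G") {
        cls <- "GU_34"
      } else if (third == "C" && a34 == "A") {
        cls <- "IC_34"
      } else if (third == "A" && a34 == "A") {
        cls <- "IA_34"
      } else if (third == "G" && a34 == "T") {
        cls <- "UG_34"
      } else if (third == "A" && a34 == "C" && include_CA) {
        cls <- "CA_34"
      }
      if (is.null(cls)) next
      if (strict && cls %in% c("GU_34", "UG_34")) {
        donor <- oracle_revcomp(anticodon)
        donor_aa <- if (donor %in% oracle_stops) "*" else oracle_translate(donor)
        if (donor_aa != oracle_translate(codon)) next
      }
      s_val <- if (cls == "WATSON_CRICK") 0 else unname(s[cls])
      rows[[length(rows) + 1]] <- data.frame(
        codon = codon, anticodon = anticodon, pair_class = cls, s = s_val,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$codon, out$anticodon), ]
}

rule_key <- function(rules) {
  paste(rules$codon, rules$anticodon, rules$pair_class,
        sprintf("%.6f", rules$s))
}

# SUM1 codon_weights from a raw named vector (tests construct supply/demand
# directly where the distribution itself is the fixture)
make_weights <- function(values, side = "SUPPLY") {
  stopifnot(!is.null(names(values)))
  structure(values / sum(values), side = side, normalization = "SUM1",
            class = "codon_weights")
}

random_weights <- function(side = "SUPPLY", codons = SENSE_CODONS) {
  make_weights(stats::setNames(stats::rgamma(length(codons), 2, 1) + 1e-6,
                               codons), side)
}

tiny_cds <- function() {
  cds_set(c(g1 = "ATGAAATGA", g2 = "AGAAGACGG", g3 = "ATGCATCACTTTTAA"))
}
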