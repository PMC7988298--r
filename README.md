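# codonSDA

Codon-level translational efficiency from tRNA and mRNA abundances, as the
**supply-to-demand adaptation** (SDA) ratio, for transcriptomics researchers
who want to ask which codons a tissue, tumor or cell population decodes in
excess or short supply — and which genes that imbalance helps or hurts.

## The model

For each of the 61 sense codons *c*:

- **supply** — tAI-style decoding capacity,
  `S_raw(c) = Σ_(c,a) (1 − s_ca) · t_a`, summing the abundance `t_a` of every
  tRNA anticodon `a` that can read `c` under explicit codon–anticodon wobble
  pairing rules, discounted by the pairing's selective-constraint penalty
  `s_ca` (Watson–Crick pairs: `s = 0`; defaults for G34:U3, I34:C3, I34:A3,
  U34:G3 and the prokaryote-only C34:A3 follow the classic tAI values and
  are configurable);
- **demand** — expression-weighted codon usage,
  `D_raw(c) = Σ_g e_g · n_c(g)`, over a CDS set with per-gene expression;
- **SDAw(c) = S(c) / D(c)** with both sides normalized to relative
  frequencies: 1 means balanced, > 2 favored, < 0.5 disfavored;
- **gene SDA** = geometric mean of SDAw over the gene's codons; **ΔSDA** =
  difference of gene SDA between conditions; **RCU** = a codon's share of
  its synonymous family within one gene.

Cohort tools: PCA of sample × codon SDAw matrices with marker correlation,
per-codon Wilcoxon differential testing with Benjamini–Hochberg control,
"X out of Y cohorts" consistency counts, and a pre-ranked weighted
Kolmogorov–Smirnov enrichment statistic with permutation p-values. A
synthetic cohort generator with planted supply/demand effects makes the
whole pipeline testable offline. Every codon-indexed quantity is keyed by
codon string — positional 64-vector conventions (a classic source of
misplaced-stop-codon bugs) are quarantined behind one explicit adapter.

See `vignette("supply-demand-adaptation")` for the full model, assumptions
and design decisions.

## Worked example

```r
library(codonSDA)

rules <- build_pairing_rules()
decoders_of("AGA", rules)
#>   anticodon   pair_class efficiency
#> 1       TCT WATSON_CRICK      1e+00
#> 2       ACT        IA_34      1e-04

trna <- trna_profile(c(TCT = 120, ACG = 40, CAT = 60, AAA = 80, GAA = 30), "liver")
expr <- expression_profile(c(g1 = 50, g2 = 10), "liver")
cds  <- cds_set(c(g1 = "ATGAGAAGATTTTAA", g2 = "ATGCGTTTCTAA"))

supply <- supply_weights(trna, rules)     # SUM1 over 61 codons, geomean-imputed
demand <- demand_weights(expr, cds)       # SUM1 expression-weighted usage
sdaw   <- sda_weights(supply, demand, sample_id = "liver")
#> (codons absent from this toy CDS have zero demand and are dropped with a warning)

round(sdaw[c("AGA", "CGT", "TTT", "TTC", "ATG")], 3)
#>   AGA   CGT   TTT   TTC   ATG
#> 0.318 1.059 0.517 2.318 0.265

classify_codon(sdaw[c("AGA", "CGT", "TTT", "TTC", "ATG")])
#>        AGA        CGT        TTT        TTC        ATG
#> DISFAVORED   BALANCED   BALANCED    FAVORED   DISFAVORED

gene_sda(cds, sdaw)
#>   gene_id     score     kind
#> 1      g1 0.3427663 GENE_SDA
#> 2      g2 0.8660263 GENE_SDA
```

Reading the output: this toy tRNA pool overserves TTC (SDAw 2.3, favored —
its GAA decoder plus the inosine wobble of the abundant AAA anticodon
exceed the single TTC occurrence's demand share) and underserves the
AGA-rich gene g1, whose gene SDA of 0.34 flags it as translationally
disfavored relative to g2.

Cohort-scale work follows the same shapes: `generate_cohort()` →
`cohort_sda()` → `differential_codon_test()` / `pca_sda()` /
`delta_sda()` + `preranked_enrichment()`. A command-line wrapper with
subcommands (`rules`, `supply`, `demand`, `sda`, `gene-sda`, `diff`, `pca`,
`enrich`, `simulate`) is installed at
`system.file("scripts", "sda-cli", package = "codonSDA")`.

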