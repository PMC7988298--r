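---
title: "Supply-to-demand adaptation of translational efficiency: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supply-to-demand adaptation of translational efficiency: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonSDA)
```

## The model

Translation elongation speed at a codon depends on how much decoding
capacity the cell provides (the abundance of tRNAs able to read the codon,
discounted by the efficiency of their base-pairing geometry) and on how much
of that capacity the transcriptome requests (how often the codon must be
translated, weighted by mRNA abundance). `codonSDA` quantifies this balance
per codon as the **supply-to-demand adaptation weight**

$$\mathrm{SDAw}(c) \;=\; \frac{S(c)}{D(c)},$$

where both $S$ and $D$ are relative frequencies over the 61 sense codons.

**Supply** follows the tRNA adaptation index (tAI) construction. For codon
$c$ with admissible decoders $a$,

$$S_{\mathrm{raw}}(c) \;=\; \sum_{(c,a)} (1 - s_{ca})\, t_a,$$

with $t_a$ the abundance of the tRNA carrying anticodon $a$ and $s_{ca} \in
[0,1]$ the selective-constraint penalty of the pairing geometry
(Watson–Crick pairs have $s = 0$). $S$ is $S_{\mathrm{raw}}$ normalized to
sum to 1.

**Demand** is expression-weighted codon usage: with $n_c(g)$ the count of
codon $c$ in the coding sequence of gene $g$ and $e_g$ its mRNA abundance
(TPM-like; any non-negative per-gene weight works, because $D$ is
normalized),

$$D_{\mathrm{raw}}(c) \;=\; \sum_g e_g\, n_c(g), \qquad D = D_{\mathrm{raw}} / \textstyle\sum_c D_{\mathrm{raw}}(c).$$

When supply matches demand exactly, $\mathrm{SDAw}(c) = 1$ for every codon
(the balance point). Codons with $\mathrm{SDAw} > 2$ are classified
**favored** (decoding capacity in excess), codons with $\mathrm{SDAw} <
0.5$ **disfavored** (capacity limiting); the boundary values themselves
count as balanced. Both thresholds are arguments of `classify_codon()`.

The SUM1-fraction-ratio form of SDAw used here is a reconstruction: it
reproduces the balance point at 1 and works with the favored/disfavored
thresholds above, but other normalizations of the same ratio idea exist.
All downstream statistics (differences, ranks, tests) operate on this
definition consistently.

**Gene-level SDA** is the geometric mean of SDAw over the gene's sense-codon
multiset (each occurrence counted), computed in log space as
`exp(mean(log sdaw))` for numerical stability. Stop codons never
contribute. **ΔSDA** between two conditions is the difference of gene SDA
scores; when conditions are multi-sample cohorts, the per-codon SDAw is
first averaged arithmetically across each condition's samples. **Relative
codon usage** (RCU) of codon $c$ in gene $g$ is $n_c(g)$ divided by the
summed counts of $c$'s synonymous family in $g$; it is undefined (`NA`,
never 0) when the family is absent.

## Wobble pairing rules

Anticodons are written 5'→3' in the DNA alphabet, so the Watson–Crick
anticodon of a codon is its reverse complement and anticodon position 34
(the first character) pairs with codon position 3. Every quantity in the
package is keyed by codon or anticodon *string*; ordered 64-vectors appear
only in one explicit I/O adapter (`read_positional_vector()`) that demands a
codon-order file. This removes an entire class of bugs in which a
positional input convention silently misplaces the stop codons and
scrambles the pairing rules.

`build_pairing_rules()` emits, for each sense codon, the Watson–Crick rule
plus at most one wobble rule determined by the third base:

| codon 3rd base | wobble anticodon 34 | class  | default $s$ |
|----------------|---------------------|--------|-------------|
| T              | G                   | G34:U3 | 0.41        |
| C              | A (read as inosine) | I34:C3 | 0.28        |
| A              | A (read as inosine) | I34:A3 | 0.9999      |
| G              | T                   | U34:G3 | 0.68        |
| A (prokaryote) | C (lysidine)        | C34:A3 | 0.89        |

The defaults are the classic tAI selective constraints; they are
configuration (`s_params()`), not hard-coded truth, and any of them can be
overridden. The C34:A3 lysidine rule is off by default because the intended
organism is human.

With `strict_family = TRUE` (default) a non-inosine wobble rule is admitted
only when the donor anticodon's own Watson–Crick codon is a synonym of the
target codon. Under the standard genetic code this removes exactly two
rules: the U34:G3 wobble of ATG (its donor natively decodes isoleucine ATA)
and of TGG (its donor corresponds to the TGA stop), so methionine and
tryptophan keep only their Watson–Crick decoder. The inosine classes are
exempt — inosine genuinely reads C, U and A within a codon box, which is
why I34:A3 may cross a family boundary in split boxes (at a near-null
efficiency of $1 - 0.9999$). The lysidine rule is likewise exempt when
enabled, because cross-family decoding is its biological point.

## Numerical choices

* **Zero-supply imputation.** A codon no observed tRNA can decode would get
  $S_{\mathrm{raw}} = 0$, which annihilates every downstream geometric mean.
  Following the tAI convention, such codons receive the geometric mean of
  the non-zero raw weights before normalization (`impute = "geomean"`,
  default); `impute = "zero"` leaves them at zero, in which case they are
  dropped from SDAw profiles with a warning.
* **Zero demand.** Possible in tiny CDS sets; the codon's SDAw is undefined
  and the codon is dropped from the profile with a warning — never reported
  as infinite.
* **Missing anticodons** in a tRNA profile contribute zero supply (real
  tRNA quantifications rarely cover all anticodons); malformed anticodon
  keys are an error naming the keys.
* **CDS validation.** Frame starts at position 1; a trailing stop is
  excluded from counts; internal stops warn in `"lenient"` mode and error
  in `"strict"` mode.
* **Sorting and tie-breaks.** Gene rankings sort by descending score with a
  stable gene-id tie-break; differential results sort by adjusted p-value,
  then decreasing absolute effect, then codon.

## Cohort analyses

**PCA** (`pca_sda()`) log2-transforms SDAw and centers each codon without
unit-variance scaling, so high-variance codons drive the components — the
behavior wanted when the question is *which codons* separate samples. Each
component's sign is fixed by making its largest-magnitude loading positive.
An all-constant matrix yields a flagged degenerate result rather than an
error. `correlate_component()` relates a component to a per-sample marker
(e.g. expression of the proliferation marker MKI67/Ki-67), Spearman by
default as the robust choice on a log-ratio scale; Pearson is available.

**Differential codon testing** (`differential_codon_test()`) compares the
per-sample SDAw of each codon between two conditions with a two-sided
Wilcoxon rank-sum test — robust on ratio-scale data — with a Welch t-test
on log SDAw as an option, and controls the FDR across the tested codons by
Benjamini–Hochberg. The effect is the difference of condition medians and
the direction label follows its sign. Samples are treated as unpaired; a
paired mode is deliberately not offered until there is a use case that
defines the pairing. `count_consistent_changes()` turns per-cohort results
into "significant in the same direction in X out of Y cohorts" summaries.

**Pre-ranked enrichment** (`preranked_enrichment()`) is the weighted
Kolmogorov–Smirnov running-sum statistic on a descending gene ranking: at
set members the running sum rises proportionally to
$|\mathrm{score}|^{w}$ (default $w = 1$), elsewhere it falls uniformly; the
enrichment score is the signed extreme, bounded in $[-1, 1]$. Significance
comes from permuting gene labels, with
$p = (1 + \#\{|ES_{\mathrm{perm}}| \ge |ES_{\mathrm{obs}}|\}) / (n_{\mathrm{perm}} + 1)$,
so $p \ge 1/(n_{\mathrm{perm}}+1)$ by construction. The seed is a required
argument and is stored in the result. Typical rankings are ΔSDA
(`delta_sda()`) or the RCU of one codon (`rcu_ranking()`), with gene sets
from GMT files.

## The synthetic-data generator

`generate_cohort()` provides cohorts with known planted structure so every
pipeline stage is testable without external data. What it emulates:

* **CDS sets** whose genes start with ATG, end with a stop and contain no
  internal stops; interior amino acids uniform over the 20 residues; within
  each synonymous family, codon choice follows a gene-specific multinomial
  with Dirichlet-distributed probabilities (concentration
  `codon_usage_concentration`), so per-gene codon-usage bias is tunable from
  extreme (≪ 1) to uniform (≫ 1).
* **Abundances.** Baseline anticodon abundances and gene expression are
  log-normal, drawn once per cohort; every sample adds multiplicative
  log-normal noise (`noise_log_sd`). Log-normality is the simplest
  heavy-tailed positive model — a stand-in, not an estimate of any real
  tissue distribution.
* **Planted supply effects** multiply the target codon's *primary* decoder
  (its Watson–Crick anticodon, or the most efficient wobble decoder if no
  Watson–Crick tRNA exists under the rules) in the second condition. Scaling
  every decoder instead would perturb box neighbors through shared
  anticodons more than the target itself; with the primary-decoder design
  the planted codon carries the full fold change while neighbors see only
  the partial wobble spillover real repertoires show.
* **Planted demand effects** tilt the second condition's expression toward
  genes rich in the codon, `tpm * fold_change^(f_g / mean(f))` with $f_g$
  the gene's codon frequency — a one-parameter tilt that raises the codon's
  demand share by roughly the fold change.
* **A latent one-factor structure**: a per-sample standard-normal factor
  $z_s$ scales the decoders of `factor_codons` by
  $2^{\mathrm{strength}\, z_s}$ in all samples and couples the marker
  gene's expression as $2^{\mathrm{effect}\, z_s}$. The marker is an
  expression-only record (never in the CDS set), so marker coupling cannot
  leak into codon demand.

Defaults — 200 genes of mean length 150 codons, expression
$\mathrm{lognormal}(3, 1)$, tRNA baseline $\mathrm{lognormal}(5, 1)$, noise
sdlog 0.1, 10 samples per condition, Dirichlet concentration 1 — were
chosen once as a desk-scale caricature of a bulk two-condition cohort:
hundreds of genes rather than tens of thousands keeps a full cohort
analysis around half a second while leaving every codon family well
populated, and sdlog 0.1 puts between-sample variability at roughly ±10%,
small against the planted two-fold effects the tests must recover.

The anticodon universe is the decoder side of the pairing-rule table (61
anticodons under the eukaryotic defaults), so a planted supply effect always
has a carrier; real human repertoires express closer to ~48 anticodon
families, a difference that matters only in that real profiles exercise the
zero-supply imputation path more often. What the generator does **not**
emulate: isodecoder structure, tRNA modification chemistry beyond the
penalty model, read-level quantification artifacts, gene-length and GC
covariation, and correlated expression programs. Passing tests therefore
demonstrate correctness of the computations and calibration of the
statistics under a clean generative model — not biological validity on any
particular tissue panel.

## Validation suite and problem sizes

The test suite checks, among others: rule-for-rule agreement of the pairing
table with a brute-force enumeration of all 64 × 64 codon–anticodon
combinations under random penalty settings; the balance identity
(SDAw ≡ 1, gene SDA ≡ 1) on random distributions; exact threshold
semantics including boundaries; recovery of a planted two-fold AGA supply
shift (20 samples/arm, 50 seeds) in both magnitude and top-hit rank; null
calibration of the differential test (100 null cohorts) and uniformity of
permutation p-values (200 random gene sets); ΔSDA antisymmetry to 1e-9
(20 cohorts); RCU family closure on 1000 genes; and byte-identical outputs
under a fixed seed. For the one-factor PCA check, the planted variance
share is estimated per cohort by regressing each codon's log2 SDAw on the
drawn factor, and PC1 must capture at least that share — PC1 is the
best single axis, so it can only fall below the factor's share through
sampling noise, allowed for in 1 of 20 seeds. These problem sizes keep the
whole suite to a few minutes; the statistical conclusions they support are
stated at those sizes, not beyond.

## Limitations

* The SDAw normalization is a reconstruction (see above); absolute SDAw
  values depend on it, though classifications and all rank-based downstream
  analyses are insensitive to a global rescaling of supply or demand.
* The penalty defaults are organism-generic; tissue-specific modification
  states (e.g. variable inosine levels) are not modeled.
* Demand weights assume the provided CDS is the translated isoform;
  isoform-resolved demand requires isoform-level expression input.
* The enrichment permutation scheme permutes gene labels, which tests the
  null of exchangeable scores; correlated gene scores (e.g. shared codon
  content) make it anti-conservative, as for any pre-ranked GSEA.
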