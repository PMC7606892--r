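---
title: "Scoring incomplete programmed DNA elimination and its cross-generational dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring incomplete programmed DNA elimination and its cross-generational dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iesretention)
```

## The biological problem

During sexual reproduction, *Paramecium* rebuilds its somatic macronucleus
from a germline template. That rebuild involves programmed DNA elimination
(PDE): tens of thousands of short, TA-bounded Internal Eliminated Sequences
(IESs) are excised from the developing somatic genome. Excision is imperfect.
A given locus may keep its IES in some fraction of the polyploid somatic DNA
copies, and that fraction — the IES Retention Score,

$$\mathrm{IRS} = \frac{k_{\mathrm{IES}}}{k_{\mathrm{IES}} + k_{\mathrm{MAC}}}$$

with $k_{\mathrm{IES}}$ the junction-spanning reads supporting the retained
form and $k_{\mathrm{MAC}}$ those supporting the excised form — quantifies
how completely a locus was processed (0 = complete excision, 1 = full
retention). When an exonic IES is retained it is transcribed with its host
gene, and under the ciliate nuclear genetic code (TGA is the only stop;
TAA/TAG encode glutamine) the retained segment frequently introduces a
premature termination codon (PTC), disrupting that copy of the gene. The
package implements the full analysis chain for asking whether IES retention
responds to the environment across sexual generations: scoring, transition
testing, PTC annotation, and stratified statistics.

## Sequence conventions

An IES is stored with both flanking TAs: the somatic (MAC) sequence around a
locus is `left + TA + right`, the germline/retained form is
`left + IES + right` where the IES itself begins and ends with `TA`. The
eliminated segment is the IES minus its final TA, so excision retains exactly
one TA and is reversible by string surgery — a property the tests exercise
exhaustively. The reported IES *length* is the eliminated-segment length,
`nchar(sequence) - 2`. Whether published IES lengths count one, both, or
neither flanking TA is ambiguous in the literature; fixing the
one-TA-retained convention here makes every size threshold in the package
well defined (the study-wide minimum is length ≥ 26, "larger than 25 nt").
Coordinates are 0-based half-open internally and converted to 1-based
inclusive exactly once, at the GFF3 boundary.

## Junction classification

Reads are classified per locus by exact matching against three junction
strings, each carrying `min_flank` (default 10) bases on both sides of its
breakpoint: the MAC junction, and the left and right boundaries of the
retained form. A read (or its reverse complement) containing an IES+ boundary
is `IES_PLUS`; one containing the MAC junction is `MAC`; a read matching both
— possible for tiny flanks — or matching junctions of two different loci is
`AMBIGUOUS` and never counted as evidence, so no read is double-counted. With
the default flank, junction strings are 20-mers and spurious matches in a
30%-GC genome are vanishingly rare. No mismatches are tolerated; the
classifier is deliberately transparent rather than alignment-based, which is
sufficient for simulated reads and keeps every decision testable against a
read-name oracle.

## Transition testing between generations

To ask whether a locus's retention changed between a parental (F0) and filial
(F1) generation, the package follows a reference-bound binomial procedure:

1. a two-sided confidence interval (default level 0.75) is constructed on
   the F0 retention proportion from its counts $(k_0, n_0)$;
2. the upper bound $p_U$ is the null for an upward transition and the lower
   bound $p_L$ for a downward one;
3. one-sided exact binomial tails are computed for the F1 counts:
   $P_{\mathrm{up}} = P(X \ge k_1 \mid n_1, p_U)$ and
   $P_{\mathrm{down}} = P(X \le k_1 \mid n_1, p_L)$;
4. a direction is called only if the corresponding (optionally adjusted)
   P-value passes `alpha` *and* the F1 score strictly exceeds the bound —
   ties at a bound are never called.

The interval method is Clopper–Pearson (exact), chosen because it is
well-defined at the boundary counts $k_0 \in \{0, n_0\}$ that dominate
retention data; a Wilson interval is available. Because the reference null is
an interval bound rather than the point estimate, the test is conservative:
on null data the realised false-positive fraction sits far below the nominal
alpha (the acceptance checks measure it on 10,000 simulated null loci).
Benjamini–Hochberg adjustment is the package default; `adjust = "none"`
reproduces the plain per-locus procedure, and all raw P-values are always
reported. Loci failing the study-wide filters — fewer than 20 supporting
reads in either generation, or length < 26 — are excluded from testing and
retained in an audit table with their reasons.

## PTC annotation

For an exonic IES, the retained transcript is built by splicing the full
TA-bounded sequence into the host CDS at its insertion point (replacing the
single retained TA), in coding orientation. Translation is codon-by-codon
under the ciliate nuclear code (NCBI table 6 via Biostrings), the correct
table for *Paramecium* — calling stops with the standard table would
misclassify every TAA/TAG codon. The native stop's codon index in the
retained transcript is located by coordinate arithmetic, never by sequence
search. Three-way classification:

* `PTC_INDUCING` — translation terminates strictly before the native stop;
* `ORF_INTACT` — eliminated-segment length divisible by 3 and no stop inside
  the retained frame;
* `FRAMESHIFT_NO_STOP` — shifted frame but no premature stop.

The binary contrast used in enrichment statistics is `PTC_INDUCING` versus
everything else. Stop positions are reported as 1-based codon indices, the R
convention. Enrichment of PTC-inducing loci in an observed set over a
background stratum uses a permutation null (draws of equal size from the
stratum) with the add-one-corrected empirical P-value,
$(1 + \#\{\hat f_{\mathrm{perm}} \ge \hat f_{\mathrm{obs}}\})/(B + 1)$.

## Stratified statistics

Loci are stratified by: host-gene expression quartile (HEG = top, WEG =
bottom quartile of the log2 distribution over positively expressed genes;
linear-interpolation quantiles, boundary ties resolved to `mid`, zeros
labelled `unexpressed` and excluded from quartiles); the most frequent IES
size classes (26–30, 44–45, 46–50, 54–60, 64–70, 74–80, 84–90, 94–100 bp,
inclusive, gaps `unbinned`); a small/large split; genomic location; and
epigenetic-control class (DCL2/3-dependent scnRNA pathway, DCL5-dependent
iesRNA pathway, or neither).

The contingency and rank machinery delegates to the standard R tests — the
two-proportion test is the chi-squared equality-of-proportions test with
Yates continuity correction (the variant that reproduces the published
contingency P-values from their printed counts), Fisher's one-tailed exact
test always states which cell is tested for enrichment, Kendall's tau is the
tie-corrected tau-b, and the rank-sum test uses the normal approximation with
continuity correction. Size-class count ratios and median-IRS profiles count
only incompletely excised loci (IRS > 0.1 by default; 0.05 is available where
more power is wanted) and drop size classes with fewer than 3 such loci in
either condition before pooling. The small/large boundary is a parameter
(`small_max_length`, default 32 = the end of the first printed size class)
because no published definition of the cutoff exists; every stratified result
should be read with that caveat.

Terminal cis-signals are scored with a position-frequency profile over the
first and last `w` (default 8) bases of a training set of IES sequences: the
score of a sequence is the mean over both termini and positions of the
observed base's frequency normalised by the position's maximum frequency, so
a sequence matching the consensus everywhere scores exactly 1.

## The synthetic-data generator

`simulate_truth()` builds the complete ground truth the analysis assumes: an
AT-rich (default 70% AT) multi-scaffold MAC genome; single-CDS gene models
(ATG start, single terminal TGA, no internal in-frame TGA); IESs placed at
genuine TA dinucleotides, exonic ones strictly inside a CDS; IES lengths
drawn from the printed size classes with a peaked weight profile plus a small
uniform background; log-normal expression with a zero-expressed fraction;
epigenetic-class labels; and per-condition true retention probabilities.
Baseline retention is a mixture — a point mass at zero (default 90%) and a
Beta(0.5, 20) tail — which yields roughly half a percent of loci above the
somatic threshold IRS > 0.1, the order of magnitude reported for standard
culture conditions. Condition-specific effects multiply the baseline within a
stratum (e.g. small × exonic up at the shifted temperatures, DCL5 × large ×
exonic down), are clamped to [0, 1] with a counted warning, and are recorded
so downstream recovery is checkable. A configurable fraction of IESs carries
a TGA placed in the host's reading frame, so PTC status varies by
construction on both strands.

Counts are Poisson–Binomial: per locus, total junction coverage
$n \sim \mathrm{Poisson}(\lambda)$ and IES-supporting reads
$k \sim \mathrm{Binomial}(n, p)$; a beta-binomial option
(`overdispersion` = rho) exists and is off by default. Simulated reads carry
their locus and origin in the read name, giving every classifier test an
exact oracle. The generator does *not* emulate sequencing error, mapping
ambiguity against a real repetitive genome, paired ends, chimeric reads, or
copy-number heterogeneity across the polyploid macronucleus — so passing
tests demonstrate correctness of the statistical machinery on the stated
model, not robustness to raw-data artefacts.

## Numerical and design choices

* **Substream seeding.** One mandatory seed governs every stochastic stage
  through independent derived substreams (a small string hash of the stage
  label into a 31-bit seed), so adding a stage never perturbs the streams of
  earlier ones; two runs with the same configuration are byte-identical,
  including the JSON report (no timestamps; the configuration hash excludes
  the output path).
* **Undefined scores.** A locus with zero classified reads gets an NA score
  and an `undefined` flag; reports serialise NaN as `null` with a warning,
  never as NaN.
* **Degenerate bounds.** At $k_0 = 0$ the lower reference bound is exactly 0
  and $P_{\mathrm{down}} = 1$; at $k_0 = n_0$ the upper bound is exactly 1
  and $P_{\mathrm{up}} = 1$ — degenerate nulls can never be rejected.
* **Power-study conditions.** The planted-effect recovery checks use a
  baseline retention of Beta(2, 60) with no zero mass for affected loci,
  because a multiplicative shift of an exactly-zero baseline is undetectable
  in principle; they evaluate the unadjusted per-locus procedure (raw alpha
  0.05), the variant the reference-bound method was designed around, while
  BH remains the package default for real analyses. The planted decrease is
  0.25×, the mirror of the 4× increase.
* **Scaled-down sizes.** Test and acceptance simulations use 150–2000 loci
  and coverages of 60–1000 rather than genome scale; for count-ratio
  profiles at 2000 loci the zero-retention mass is halved (to 50%) so that
  size classes keep at least 3 incompletely excised loci per condition,
  preserving the planted small-versus-large structure under test.

## Worked example

```{r example, eval = FALSE}
library(iesretention)

truth <- simulate_truth(sim_config(n_genes = 100, n_ies = 400), seed = 7)
f0 <- simulate_counts(truth, "F0_25C", mean_coverage = 100, seed = 7) |>
  compute_irs() |>
  apply_filters(truth$ies_loci)
f1 <- simulate_counts(truth, "F1_32C", mean_coverage = 100, seed = 7) |>
  compute_irs() |>
  apply_filters(truth$ies_loci)

fit <- call_transitions(f0, f1)
glance(fit)      # loci tested, up/down counts
tidy(fit)        # per-locus calls
autoplot(fit)    # F0 vs F1 retention scatter

ptc <- annotate_ptc(truth$ies_loci, truth$genes, truth$mac_genome)
table(ptc$consequence)
```

## Known limitations

The classifier requires exact junction matches and is not a substitute for a
full aligner on real sequencing data. Gene models are single-CDS chains;
intron-aware isoform handling is out of scope, as are NMD-targeting rules for
deciding which PTC-bearing transcripts are actually degraded. The transition
test treats the two generations as independent binomial samples and does not
model replicate structure or more than two generations jointly. The
small/large IES boundary, the confidence-interval method, and the
multiple-testing policy are documented package choices, not claims about any
particular published analysis.
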