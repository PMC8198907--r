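---
title: "Inferring lncRNA-miRNA-mRNA sponge networks from knockdown data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring lncRNA-miRNA-mRNA sponge networks from knockdown data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The question the package answers

A cytoplasmic long non-coding RNA (lncRNA) can act as a competing
endogenous RNA (ceRNA): its miRNA binding sites titrate miRNAs away from
their mRNA targets. Knocking the lncRNA down with antisense reagents then
has two signatures. MiRNAs that were sequestered ("sponged") become more
abundant in the free pool, and their targets drop; miRNAs that depend on
the lncRNA through indirect mechanisms ("induced") fall, and their targets
rise. `spongenet` takes the two expression matrices such an experiment
produces (a gene-level array and a miRNA array, each with a negative
control arm and two knockdown arms), the transcript sequences, and turns
them into a classified candidate-miRNA table, a tripartite
lncRNA-miRNA-mRNA network, and one summary statistic: the fraction of
knockdown-regulated protein-coding genes that are predicted targets of at
least one candidate miRNA (the "explained fraction"); its complement is
the miRNA-independent share of the lncRNA's transcriptional footprint.

## The analysis model, stage by stage

**Differential expression.** Fold changes are computed on the linear
intensity scale as ratios of group means (with a pseudocount, default 1,
guarding background-subtracted zeros) and reported in the signed
microarray convention: values below 1 become negative reciprocals, so the
gates read symmetrically. The mRNA gate is strict — `|signed FC| > 1.6`
and `p < 0.05` in at least one knockdown arm — while the miRNA gate uses
the inclusive `|signed FC| >= 1.3`. The union-over-arms rule ("regulated
by at least one reagent") is deliberate: the two reagents differ in
efficiency and only partially overlap. Direction is `up`/`down` when all
passing arms agree and `mixed` otherwise; mixed features are retained and
flagged. No multiple-testing correction is applied in the default gate —
it mirrors the raw-p convention of array console software — and the
p-value comes from a pooled-variance Student t-test on `log2(x + 1)`. We
chose the pooled test over the Welch variant after measuring both on null
data at the design's replicate number (3 vs 3): the pooled test is exactly
calibrated there, while Welch's Satterthwaite approximation is noticeably
conservative (empirical type-I near 0.035 at a nominal 0.05), which would
make the gate's p-threshold mean something other than what it says.
`group_test(..., method = "welch")` remains available.

**Target prediction.** TargetScan-class site prediction is reduced to its
canonical core: the seed is nucleotides 2-8 of the mature miRNA, and a
site on the target strand is an exact Watson-Crick match to the reverse
complement of (part of) the seed — `6mer` (miRNA nt 2-7), `7mer-A1` (6mer
plus an A opposite miRNA position 1), `7mer-m8` (match extended to nt 8),
`8mer` (both). No G:U wobble, no context features, no conservation. Each
occurrence of the 6-nt core is typed once, by its flanks, as the strongest
site it supports. The lncRNA-binding surrogate combines sites by a
noisy-OR, `score = 1 - prod(1 - w)`, with weights 0.80 / 0.55 / 0.40 /
0.15 for 8mer / 7mer-m8 / 7mer-A1 / 6mer; a miRNA is "predicted to bind"
at score >= 0.7. The weights are a documented calibration — a single 8mer
clears the threshold, weak sites alone never do — not an empirical fit;
they are config-exposed, and the unit of meaning is the threshold
behavior, not the decimal values.

**Candidate ranking and classification.** For every differentially
expressed miRNA the pipeline counts its predicted targets among the
regulated coding genes. Candidates at or above the nearest-rank 75th
percentile of these counts (computed among candidates with at least one
common target, inclusive comparison) form the reportable shortlist; the
implied minimum count is reported alongside. We read "top 75th percentile"
as the top quartile, since the published gloss equates it with a high
minimum common-gene count; the percentile is a config knob. Every
DE-selected miRNA is classified regardless of the count filter —
`sponged` (up on knockdown and binding score >= threshold), `induced`
(down on knockdown), `unclassified` (up without binding, or mixed) — so a
sponged call never depends on the shortlist ranking; the filter only
determines what is carried into the network. The miRNA:lncRNA abundance
ratio in control arms (after per-array median scaling when the two
matrices come from different chips) is reported with an inclusive
0.25-1 band flag as descriptive stoichiometry evidence; it never gates.

**Network and explained fraction.** The network connects the lncRNA to
sponged miRNAs (`binds`) and induced miRNAs (`induces`), and each
candidate miRNA to every regulated coding gene among its predicted
targets (`targets`). Up/down pairing between miRNA and gene is
deliberately not enforced. The explained fraction is the share of
regulated coding genes with at least one incident `targets` edge; the
complement is reported as the miRNA-independent fraction, and the two sum
to one by construction. Exports are SIF (edge list for network viewers)
and attribute-complete GraphML/JSON that round-trip exactly.

**Supporting quantification.** Two small calculations accompany the
pipeline. The relative concentration index of a transcript is
`RCI = log2(cytoplasmic / nuclear)`; non-detection in a compartment is an
explicit N/D state, not a zero. Efficiency-corrected qPCR relative
expression uses per-primer amplification bases `E` in (1, 2.2] and
normalizes the target's shift by the geometric mean of at least two
reference genes; with all `E = 2` it reduces exactly to the classical
2^-ddCt formula. Technical-replicate Cts are averaged before the ratio —
the aggregation is not standardized across instruments, and the geometric
mean across references is the conventional multi-reference choice.

## The synthetic-data generator

No public fixture reproduces a full lncRNA-knockdown study at package
scale, so the generator is a first-class module that embodies the
mechanism the analysis assumes, with every constant exposed in
`simulation_config()`.

**Titration model.** Free miRNA and mRNA levels solve the coupled
mass-action system

    F_m = M_m / (1 + sum_t n_mt * T_t / K)
    T_t = T0_t / prod_m (1 + rho * n_mt * F_m / K)

where `n_mt` are planted site counts, `K` (default 100, abundance units)
sets the binding scale, `rho` (default 1) the repression strength, and
the lncRNA enters as an exogenous transcript at `L = L0 * (1 - e)` for
knockdown efficiency `e` (defaults 0.6 and 0.5 for the two reagents).
This is deliberately the simplest mass-action form that exhibits
sponging, abundance-ratio dependence, and indirect induction. The
fixed-point iteration from `T = T0` is componentwise monotone, so it
converges monotonically; we iterate to a 1e-10 maximum relative change
(cap 1000 iterations, non-convergence is an error). Measured miRNA signal
is the free pool `F_m` — the site-bound pool is assumed undetectable,
which is what makes sponged miRNAs *rise* on knockdown — except for
induced miRNAs, whose totals follow the lncRNA as
`M_m * (L / L0)^gamma`; the same scaled total drives their targets, so
induction has a transcriptome footprint. Features with a direct,
miRNA-independent lncRNA response scale as `(L / L0)^(+/-1.2)`; they are
the planted miRNA-independent complement of the explained fraction.

**Planted structure.** Three arms x 3 replicates; 500 mRNA-level features
(80% coding; the lncRNA itself and inert non-coding features — lncRNA,
snRNA, snoRNA, pseudogene, misc RNA — make up the rest, so the biotype
partition is exercised); 60 miRNAs of which 6 are sponged (1-3 exact
8mers planted on the 2500-nt lncRNA) and 4 induced (no lncRNA sites).
Sponged and induced miRNAs each repress a dedicated pool of 18 coding
genes; genes are dealt to miRNAs with load balancing (3 sponged or 2
induced miRNAs per gene, 2-3 sites per pair), so every pool gene is hit
hard enough to clear the 1.6 gate and every planted candidate has a
comparable common-target count — the structure the percentile filter
expects. Null miRNAs repress a disjoint 60-gene pool; because that
subsystem shares nothing with the lncRNA, their free levels are exactly
arm-invariant (no-site neutrality holds to machine precision, not just
statistically). Base abundances are log-normal with log2 means 9 / 9 /
7.5 (lncRNA / miRNA / mRNA) — chosen once so equilibrium intensities sit
in an array-like dynamic range comfortably above the pseudocount and the
planted fold changes clear the printed gates with margin. Measurement
noise is multiplicative, `2^N(0, sigma)` with `sigma = 0.15` log2 units
per feature and replicate.

**Sequence construction.** Backgrounds are uniform random RNA, but every
chance occurrence of any panel miRNA's seed core is mutated away, and the
panel itself is drawn with orthogonal seeds (no core occurs inside
another miRNA's site pattern). Planted sites are placed at
non-overlapping positions with controlled flanking bases, so scanning a
generated sequence returns exactly the planted site map — type, position
and count. This is a benchmark property, not realism: real UTRs carry
chance seed matches and real target prediction has false positives. What
passing recovery tests show is therefore that the pipeline's logic is
correct under its own assumptions; they say nothing about prediction
accuracy against biological site databases, which the package does not
attempt to reproduce.

**What the generator does not emulate.** Probe-level effects, batch
structure, cross-platform scale differences (both matrices are emitted on
a common scale; the per-array median scaling option is tested against
that), correlated noise, secondary structure occluding sites, and
translational repression without transcript decay. A simulated dataset
corresponds to one cell line; a two-cell-line study is two runs with
different seeds, which reproduces partial overlap of responses only
through the random target assignment.

## Numerical and interface choices

- Strict vs inclusive inequalities follow the printed gates exactly
  (`> 1.6` for mRNA, `>= 1.3` for miRNA, `< 0.05` for p, `>= 0.7` for
  binding, inclusive abundance band and percentile cutoff).
- Zero-variance groups define `p = 1` (equal means) or `p = 0` (unequal);
  an all-zero control with a zero pseudocount is an error.
- Expression values are stored linear-scale and logged on demand; feature
  identity is the probe/transcript id string, never the gene symbol, so
  many-to-one symbol mappings cannot silently collapse features.
- U and T are unified as U on input; site coordinates are 0-based
  half-open on the given transcript strand, with no genome mapping.
- Multiple lncRNA isoforms are accepted; the per-miRNA binding score is
  the maximum over isoforms.
- Regulated genes without a UTR sequence are excluded from target maps
  and counted in the report (`n_missing_utr`), never silently dropped.
- Ties in the percentile filter are kept (inclusive nearest-rank), so a
  fully tied count distribution keeps every candidate.
- Scientific outputs (candidate table, network exports, report) carry no
  timestamps; identical configuration and seed give byte-identical files.

## Problem sizes used by the test suite

Unit tests run on reduced simulations (60 mRNA-level features, 12
miRNAs); the end-to-end recovery checks use the default configuration
(500 features, 60 miRNAs, 3x3 design) across ten seeds, which keeps the
whole suite within a few minutes on one CPU while still exercising the
full-scale titration system. The same sizes are used by
`scripts/acceptance.R`, which regenerates all headline numbers from
scratch for any seed.

## Known limitations

The binding score is a surrogate with invented weights; absolute scores
are not comparable to database affinity scores, only the thresholded
behavior is meaningful. The explained fraction inherits every upstream
choice (gates, site types, percentile) and should be read as a
pipeline-conditional statistic. The titration model is a single-`K`
mass-action approximation without Ago loading, cooperative binding, or
kinetics; it supports benchmarking, not parameter inference on real
cells. And because generated sequences are scrubbed of chance seed
matches, simulated recovery rates are upper bounds on what noisy,
database-driven predictions would achieve on real arrays.
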