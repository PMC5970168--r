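---
title: "Methods: from kinase signatures to complete MAPK cascade modules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from kinase signatures to complete MAPK cascade modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mapkCascades)
```

Plant MAPK cascades relay stress signals through three phosphorylation
tiers, MAPKKK -> MKK (MAPKK) -> MAPK. This package implements the
computational chain used to characterize a cotton MAPKKK family and
assemble complete cascade modules: signature-based subfamily
classification, Ka/Ks selection analysis on paralog pairs, tissue
expression z-scoring, qRT-PCR induction calling, and tripartite
interaction-graph enumeration with shared-stress-response annotation.
This vignette records the models, the tunable parameters, and the design
choices behind each stage.

## Subfamily classification by catalytic signature

Plant MAPKKKs fall into three subfamilies distinguished by a conserved
motif in the catalytic kinase domain:

* MEKK: `G (T/S) P X (W/Y/F) M A P E V`
* Raf: `G T X X (W/Y) M A P E`
* ZIK: `G T P E F M A P E (L/V/M) (Y/F/L)`

where `X` matches any of the 20 standard residues (not gaps or
ambiguity codes). `classify_subfamily()` scans a sequence with these
patterns in the fixed precedence order **MEKK, ZIK, Raf** and reports
the leftmost match of the first subfamily that matches at all.

The precedence is forced by pattern overlap. The Raf motif is the least
specific: a MEKK instance with T at its second position and W or Y at
its fifth satisfies the Raf motif too, so testing Raf first would
absorb part of the MEKK class. Less obviously, a ZIK instance whose
tenth position is V (`GTPEFMAPEV...`) satisfies the *MEKK* motif, so
MEKK-before-ZIK misassigns that corner of the ZIK class. We keep
MEKK > ZIK > Raf because it preserves every MEKK instance (2 x 3
variable-position combinations, all tested by enumeration) and because
V-terminal ZIK variants are not represented in the cotton set the
fixtures describe; the synthetic generator rejection-samples them away
(see below). For the broader ZIK terminal classes we follow the wider
`(L/V/M)(Y/F/L)` variant, which is a superset of the narrower `(L/V)Y`
form seen in some alignments, so no printed instance is lost. The two
orderings of the MEKK fifth-position class, `(W/Y/F)` and `(F/Y/W)`,
denote the same residue set.

Where sequences are unavailable, `subfamily_from_name()` maps
paper-convention names by prefix: MEKK/ANP/YDA -> MEKK, RAF/CTR/EDR ->
Raf (CTR1 and EDR1 are Raf-subfamily members), ZIK -> ZIK. Unknown
prefixes are an error rather than `unclassified`, since they indicate a
naming-convention violation, not a biological novelty.

`protein_stats()` computes molecular weight (sum of average residue
masses plus one water, in Da) and isoelectric point. pI is the root of
the Henderson-Hasselbalch net-charge function over the termini and the
ionizable side chains (D, E, C, Y, H, K, R), found by bisection on pH
in (0, 14) to |charge| < 1e-4. The pKa table is EMBOSS-style and fixed
(`pi_pka_table()`), so results reproduce bit-for-bit; other published
pKa sets shift pI by up to a few tenths of a pH unit, which is why pI
comparisons across tools are only approximate.

## Ka/Ks selection analysis

`compute_kaks()` implements the Nei-Gojobori (1986) counting method
with Jukes-Cantor correction. The source analysis never names its
Ka/Ks tool; we adopt the classical counting estimator deliberately and
document it prominently, because approximate and maximum-likelihood
estimators (LWL85, YN00, codeml) give systematically different values
on the same pair.

Per codon, each of the nine possible single-nucleotide changes
contributes 1/3 of a synonymous site if it preserves the amino acid;
changes that create a stop codon count as nonsynonymous. This keeps the
identity S + N = 3 x (compared codons) exact, which the tests assert.
Site counts are averaged between the two sequences. For codons
differing at k positions, all k! substitution orderings are enumerated;
orderings that pass through a stop codon are excluded and the remainder
weighted equally when averaging synonymous/nonsynonymous step counts.
If every ordering for a codon passes through a stop, that codon is
masked with a warning (it carries no usable signal under this model).
Codons containing `-` or `N` in either sequence are masked pairwise
before any counting. The standard nuclear genetic code is assumed,
appropriate for plant nuclear genes.

Raw proportions pS = Sd/S and pN = Nd/N receive the Jukes-Cantor
multiple-hit correction d = -(3/4) ln(1 - 4p/3), which diverges at
p >= 3/4; such saturated pairs are reported with undefined rates and
selection class `undetermined` rather than raised as errors. The ratio
Ka/Ks classifies selection: < 1 purifying, > 1 positive, and neutral
only when |ratio - 1| <= 1e-9 (an exact-arithmetic tie, not a
statistical test). Identical sequences have Ks = 0 and an undefined
ratio.

`kaks_oracle()` recomputes every quantity for alignments up to 50
codons by brute force - direct neighbor enumeration for sites,
recursive depth-first enumeration of substitution orderings for
differences - sharing only the genetic-code table with the estimator.
The headline correctness property, asserted over 200 random pairs per
run, is agreement to 1e-9 on S, N, Sd and Nd. The published range of
cotton paralog ratios requires the original genome sequences and is
out of desk-scale reach; correctness here rests on the oracle and on
planted-truth recovery instead.

## Expression profiling

`zscore_normalize()` applies z = (x - mean)/sd per gene row across
tissues. The source formula describes sigma as a "standard error", but
the quantity consistent with z-scoring across eight tissue values is
the standard deviation; we use the sample sd (n - 1 divisor) and log
this interpretation here. Constant rows would divide by zero; they map
to all-zero rows and are flagged in the `constant_genes` attribute, the
convention heatmap pipelines expect.

`relative_expression()` is the Livak 2^-ddCt estimator: dCt =
Ct(target) - Ct(reference) per replicate, ddCt = mean dCt(treated) -
mean dCt(mock), fold change E/C = 2^-ddCt. Amplification efficiency is
assumed to be exactly 2 for both genes (the Livak assumption); no
efficiency calibration is modeled.

`call_induction()` evaluates one gene x treatment time course. At each
time point it computes the fold change and a two-sided pooled-variance
Student's t-test comparing replicate dCt values between arms. The test
is applied to dCt rather than to fold changes: dCt is approximately
normal on the Ct scale, which is standard qPCR practice. A gene is
called `up` if any time point has fold >= 2 with p < 0.05 - induction
at *any* time point counts, because peak times differ by gene - and
`down` ("D") if any time point has fold <= 0.5 with p < 0.05;
down-regulation never counts as induction. If both directions fire
(possible in principle for a biphasic course, absent from all fixtures)
the up call wins, matching the one-code-per-cell convention of the
published summary table. The peak time is the extreme-fold time point,
earliest time on ties, and the significance grade is upgraded to
p < 0.01 when the peak time point reaches it. No multiple-testing
correction is applied, mirroring the source analysis; treat the
per-test alpha as descriptive, not family-wise.

Defaults: `fold_threshold = 2.0` (dimensionless E/C), `alpha1 = 0.05`,
`alpha2 = 0.01`, time points {0, 0.5, 1, 2, 4, 6, 8, 10, 12, 24} h,
three replicates.

## Cascade assembly

`build_graph()` validates edge lists (tier must agree with name
prefixes; duplicates rejected) and assembles the three-layer directed
graph as an igraph object. Display aliases are normalized first -
notably MKK2 == MKK2_2, which the two published edge lists label
differently; without this join the MKK2 cascades silently vanish.

`enumerate_modules()` removes excluded genes *before* enumeration and
returns every (KKK, KK, K) triple with both tier edges present, in
numeric-aware lexicographic order. Removing nodes first is equivalent
to filtering modules afterwards but cheaper, and makes the count
identity |modules| = sum over MKK nodes of (in-degree x out-degree)
immediate; tests verify it against brute-force triple scanning on
random graphs. The default exclusion set is the published one -
MKK10_1 (too weakly expressed to detect across tissues), MEKK19 and
RAF17_2 (low leaf expression, sub-2-fold responses) - but exclusions
are configuration, not hard-coded biology.

`annotate_shared_responses()` intersects the induced-treatment sets of
the module members that have a response profile, splitting the result
into the signal family {JA, H2O2, ABA, SA} and the abiotic family
{NaCl, PEG, cold 4 degC, heat 37 degC, wounding}. Members without a
profile (all MKKs, whose induction data live in a companion study we
do not transcribe) are skipped and counted in `n_profiled`; modules
with fewer than two profiled members are flagged `low_support` rather
than dropped.

## Fixtures and their caveats

The packaged fixtures transcribe the published cotton results: 18
MAPKKK-MKK Y2H pairs, 16 MKK-MAPK pairs, per-treatment induced-gene
lists, the three-gene exclusion set, and MAPK-tier response profiles
(union over the cascade-narrative statements where a gene appears in
several cascades). Files are checksummed; `load_cotton_fixtures()`
refuses corrupted data. Two lists carry flags propagated to users: the
ABA list is `ambiguous` (the text counts ten induced genes but names
nine distinct ones), and the SA list is `reconstructed` (the text
gives a count but no list; gene identities were assembled from the
summary statements). Neither flagged list participates in acceptance
checks; both are usable, with eyes open, for annotation.

## The synthetic-data generator

The generator produces inputs with exactly the statistical structure
the pipeline assumes, each with planted ground truth, so every stage is
testable end-to-end without downloads.

* **Proteins** (`gen_proteins()`): one signature instance per record at
  a recorded position in uniform random background, rejection-sampled
  until the classifier recovers the planted label at the planted
  position and no signature of any subfamily occurs elsewhere. This
  makes label-recovery tests exact rather than probabilistic; the
  bounded retry count (default 1000) turns pathological configurations
  into errors instead of hangs.
* **Codon pairs** (`gen_codon_pairs()`): a random stop-free codon
  sequence is copied and exactly the requested numbers of synonymous
  and nonsynonymous single-nucleotide changes are applied at distinct
  codons, each verified against the genetic code. Distinct codons mean
  no multi-hit ambiguity, so planted Sd/Nd are recovered exactly.
  Codons with no change of the required class (ATG, TGG for
  synonymous) are re-drawn.
* **FPKM matrices** (`gen_fpkm()`): per-gene lognormal baselines
  (meanlog ~ N(3, 1), sdlog 1 across tissues), giving the nonnegative,
  right-skewed values typical of FPKM tables over the eight-tissue
  panel (root, stem, leaf, petal, anther, ovule 0 dpa, fiber 10/20
  dpa).
* **qPCR courses** (`gen_qpcr()`): paired treated/mock arms at every
  time point; reference-gene Ct constant up to noise; the treated
  target Ct shifted by -log2(fold) at the designated peak and by half
  that (in log2 space) at the two adjacent time points, zero elsewhere,
  plus Gaussian noise (default sd 0.1 Ct) per replicate. The tapered
  peak forces the caller to actually locate peak times. The planted
  design carries an explicit `peak_time_h` column (default 12 h, the
  most common published peak) because peak recovery is part of what is
  tested.

All randomness flows from one explicit seed through deterministic
per-generator sub-streams, so identical configurations are
byte-identical across runs and adding one generator never perturbs
another's draws.

What the generator does *not* emulate bounds what passing tests show:
real signature context (real kinase domains are homologous, not uniform
background), transition/transversion bias and codon-usage structure,
FPKM correlation between tissues, qPCR efficiency drift, and
non-Gaussian Ct outliers. Recovery results therefore validate the
pipeline's logic and arithmetic, not its robustness to real-data
pathologies.

## Problem sizes and runtime

The test battery uses deliberately small instances - 8-10 codon pairs
for the 200-pair oracle sweep, 100-300 codon planted pairs, 12-15
proteins per recovery run, 12-gene x 10-time-point qPCR designs, and
random tripartite graphs of ~10 nodes per layer - chosen so the whole
suite runs in well under a minute on one core while still exercising
every code path, including pathway enumeration at 3-difference codons
and stop-avoiding path exclusion. The fixture-based checks (38 modules,
interaction splits) are exact and instantaneous.

## Known limitations

* The Ka/Ks estimator is the equal-weight counting method; it is not a
  substitute for ML estimation when transition bias is strong.
* Induction significance is per-test; with 9 treatments x 10 time
  points per gene, descriptive use is intended.
* MKK-tier response profiles are absent by design; shared-response
  annotations over KKK and MAPK tiers only are flagged, not inferred.
* The pipeline consumes pre-aligned codon pairs and pre-quantified
  FPKM; alignment construction and RNA-seq quantification are out of
  scope.
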