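---
title: "Methods: a genotype-phenotype-expression screen for catabolic gene clusters"
author: "rhizoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a genotype-phenotype-expression screen for catabolic gene clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Legume roots secrete isoflavones such as daidzein — antibacterial flavonoids
that adapted rhizosphere bacteria can instead use as a carbon source. Strains
that catabolise the compound ("degraders") are expected to carry a dedicated
catabolic gene cluster that strains without the phenotype lack. `rhizoscreen`
implements the computational screen that finds such a cluster in a panel of
sequenced isolates, together with the downstream quantifications that
characterise it: trait enrichment of cluster presence, dose-response growth
inhibition, and exact-mass annotation of catabolic intermediates.

## The screen

A gene of the reference (degrader) strain is a **candidate** when it
satisfies three criteria simultaneously:

1. **Induced** under the substrate: log2 fold change of mean CPM
   (treated vs control, pseudocount 1 CPM) at least `log2fc_threshold`
   (default 1).
2. **Conserved in degraders**: in at least `conserved_fraction_degraders`
   (default all) of the degrader strains, the best protein hit has percent
   identity ≥ 50 and reference coverage ≥ 50.
3. **Less conserved in non-degraders**: in at least
   `nonconserved_fraction_nondegraders` (default all) of the non-degraders,
   the best hit is absent or has identity < `nonconserved_identity_max`
   (default 45, see below).

Candidates are then grouped into **hotspots**: maximal runs, in
coordinate-rank order along a replicon, containing at least `min_run`
(default 4) candidates with at most `max_gap` (default 2) consecutive
non-candidates between them. Ranks, not base pairs, define adjacency,
because the phenomenon of interest is a run of adjacent loci. Finally,
per-strain cluster presence (≥ half of the top hotspot's genes conserved at
the criterion-2 thresholds) is tested for association with a strain trait
such as legume isolation source by a two-sided Fisher's exact test.

### Expression criterion

Counts are normalised to counts per million (each sample column scaled to
sum to 10^6) and fold change is the log2 ratio of arithmetic mean CPM with a
1-CPM pseudocount, computed as a difference of logs so that swapping the
condition labels negates it exactly. No dispersion modelling or hypothesis
testing is applied at this stage: the criterion is a threshold on effect
size, not an inference, and the two further criteria provide the
specificity. Note that CPM is composition-sensitive: when strongly induced
genes carry a material fraction of all reads, background genes shift
slightly negative and induced genes read below their true fold change. At
the default panel scale (8 induced genes of 200, 8-fold induction) this bias
is about −0.36 log2 units — harmless for a threshold of 1, but a reason the
threshold should not be pushed toward 2.5 with these defaults.

### Conservation scoring

Every scored reference protein is aligned against every protein of every
panel strain with a global Needleman–Wunsch/Gotoh alignment (BLOSUM62, gap
open 10, gap extend 1, end gaps penalised; `Biostrings::pairwiseAlignment`
does the dynamic programming, and the test suite verifies its scores against
an independent brute-force DP). Percent identity is counted over columns
where both sequences are non-gap; coverage is the fraction of the reference
sequence in such columns. `X` never counts as identical, a conservative
choice for masked residues. The best hit in a strain is the protein
maximising identity among hits with coverage ≥ `min_coverage` (default 50%),
ties broken by lexicographically smallest locus ID; if no hit qualifies the
gene is recorded absent in that strain.

Two consequences of this design are worth stating plainly:

* **The reference column is filled with 100/100 by construction** rather
  than by self-alignment. A reference protein containing `X` would otherwise
  score below 100 against itself under the conservative `X` rule.
* **"Absent" is rare under global alignment.** Two unrelated proteins of
  comparable length still produce a global alignment with coverage above
  50%, so a lost gene usually shows up not as an absent cell but as a
  low-identity best hit. Maximising identity over a whole proteome inflates
  that low mode: empirically, the best of ~200 unrelated proteins reaches
  30–40% identity under this identity definition. This is why the
  non-conserved ceiling defaults to 45% rather than a BLAST-intuition value
  like 30%: the ceiling must sit *above* the spurious-best-hit mode and
  *below* the conserved floor (50). Both thresholds are configuration, and
  the invariant `nonconserved_identity_max < conserved_identity_min` is
  enforced.
* Within a single alignment at equal score the traceback is delegated to
  the aligner and is deterministic, though its preference order among
  equal-scoring paths is the library's own; only scores, identity and
  coverage feed the screen.

By default the pipeline computes conservation only for genes that already
pass the expression criterion (`restrict_to_upregulated = TRUE`). Because a
candidate must be upregulated, the candidate set is provably identical to
the full computation; the flag only controls whether the conservation table
covers the whole genome (useful for heatmaps) or the induced subset.

### Fisher's exact test

`fisher_exact_2x2()` computes the two-sided p-value by summing hypergeometric
point probabilities (fixed margins) of all tables no more probable than the
observed one, with a 1e-7 relative tolerance on the comparison — the
convention of mainstream implementations, against which the test suite
checks it to machine precision. The odds ratio is the unconditioned
cross-product ad/bc (infinite when bc = 0 and ad > 0), simpler than the
conditional MLE and sufficient for reporting direction and strength.

## Growth inhibition

Each replicate growth curve is reduced to its trapezoidal AUC over the
observed grid (no smoothing, baseline subtraction or extrapolation). The
inhibition index of a replicate is `1 − AUC / mean(control AUCs)` of the
same strain, so 0 is control-like growth and 1 is no growth; the raw-ratio
convention is available as a configuration switch. Control replicates
average to index 0 exactly by construction. Each dose is compared with the
0 µM control by Welch's t-test on the AUCs (robust to unequal variances;
two constant samples with equal means give t = 0, p = 1, with differing
means a p = 0 sentinel and a warning), and all dose-vs-control p-values of a
run form a single Benjamini–Hochberg family.

A subtlety: the standard error of the *mean index* is larger than the
standard deviation of replicate indices divided by √n, because all
replicates share the random control-mean normaliser. "Within 2 SE of zero"
statements are therefore evaluated via the Welch statistic on the underlying
AUCs, which accounts for both sources of variance.

## Exact-mass annotation

Monoisotopic masses are sums of most-abundant-isotope atomic masses
(C = 12 exactly, H = 1.00782503, D = 2.01410178, N = 14.00307401,
O = 15.99491462, S = 31.97207117, P = 30.97376200 Da). The deprotonated ion
is computed as **M − mass(H atom)** with no electron-mass correction; this
is the convention under which the three intermediate formulas reproduce the
reported calculated masses (C15H10O5 → 269.0450, C10H10O3 → 177.0552,
C10H10O4 → 193.0501). The physically stricter variant that adds the mass of
the anion's extra electron (giving 269.0455) is available behind
`electron_correction = TRUE`, default off. Report fields are rounded half-up
to 4 decimals, matching display precision; internal arithmetic keeps full
precision. Peak matching reports every (peak, formula) pair within
`tol_ppm` (default 10 ppm), sorted by absolute ppm error — ambiguity is
reported, not resolved. Deuterium labelling replaces n hydrogens with
deuterium and shifts the mass by exactly n × 1.00627675 Da, the reasoning
used to show that labelled substrate positions survive into a reaction
product.

## The synthetic-data generator

The generator produces the full input bundle with planted ground truth, so
every stage is testable without external data. What it emulates, and the
fixed study conditions:

* **Panel**: a reference degrader plus 5 degraders and 5 non-degraders,
  200 genes of 120 aa on one replicon, with an 8-gene cluster planted at
  ranks 101–108. Proteins mutate by i.i.d. per-residue substitution to a
  uniformly chosen different residue (no indels), so expected identity is
  exactly 100(1 − p): background divergence 0.05 everywhere, cluster
  divergence 0.10 in degraders; non-degraders lose each cluster gene with
  probability 1.0 (retained copies, at lower loss probabilities, mutate at
  background + 0.25, capped at 0.9). Gene loss is whole-gene. Degraders are
  labelled legume-isolated and non-degraders soil-isolated, so cluster
  presence and isolation source co-occur perfectly under the defaults.
* **Counts**: negative binomial with mean 1000 and dispersion 0.1
  (dispersion 0 falls back to Poisson), 3 replicates per condition,
  per-sample library-size factors drawn log-normally (σ = 0.2) so that
  normalisation is actually exercised; treated-condition cluster means are
  multiplied by 2^3.
* **Growth**: logistic curves `K/(1 + exp(−r(t − t0)))` with K = 1 OD,
  r = 0.35 h⁻¹, t0 = 12 h, read every 30 min for 48 h, Gaussian read noise
  SD 0.02, 6 replicates, doses 0/10/30/100 µM. For non-degraders the factor
  `1 − 0.006·dose` (floored at 0) scales **both r and K** — a rate-only
  reduction barely changes the AUC once the curve saturates within the
  horizon, whereas sub-inhibitory antimicrobial exposure lowers both growth
  rate and final yield; the top dose then produces an inhibition index
  near 0.6.
* **Peaks**: one peak per candidate formula at its theoretical [M−H]⁻ m/z
  perturbed by Normal(0, 2 ppm), plus 20 uniform decoys over m/z 50–350.

All generators are fully deterministic given the seed (sub-generators derive
seeds by fixed small offsets). What the generator does **not** emulate —
and hence what passing tests do not show about real data: phylogenetic
correlation between strains (every strain diverges independently from the
reference), indels and rearrangements, operon structure and strand bias,
count outliers and batch effects beyond a scalar library size, plate-edge
and evaporation effects in growth curves, and isotope envelopes, adducts or
in-source fragments in MS peaks.

## Numerical choices and degenerate inputs

* Problem sizes in the shipped analyses and tests: 200-gene panels for the
  end-to-end screen, 30-gene panels for fast pipeline tests, 1000 random
  tables for the Fisher cross-check, 200 random pairs of length ≤ 12 for
  the alignment oracle. These keep a full run on one CPU in minutes and are
  stated here as the package's own choices.
* Fold change uses a pseudocount (default 1 CPM), so a gene absent in both
  conditions has log2FC exactly 0 and no value is infinite.
* A sample with zero total counts, an empty protein sequence, a negative
  dose, unsorted times, an alignment of zero aligned columns (identity
  defined as 0), a formula without hydrogen passed to deprotonation — all
  are explicit errors or defined values, never NaN propagation.
* Hotspot boundaries are trimmed to candidate genes; hotspots sort by
  candidate count, then replicon, then start rank; detection is invariant
  to reversing gene order.
* `run_screen`/`run_all` reports contain no timestamps, so a rerun under
  the same seed and configuration is byte-identical.

## Known limitations

* Global alignment identity is not BLASTP identity: reported percent
  identities are internally consistent but not comparable with
  local-alignment values from the literature, and the screen's published
  defaults reflect that (see the 45% ceiling above).
* The screen is a deterministic filter, not a test: no uncertainty is
  attached to the candidate set. The trait-enrichment p-value treats
  strains as independent, with no phylogenetic correction.
* CPM composition bias (above) makes effect-size estimates conservative
  when induced genes dominate the library.
* The growth model fits no parametric curve; AUC comparisons inherit the
  observed time grid.
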