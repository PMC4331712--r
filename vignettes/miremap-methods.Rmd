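---
title: "miremap: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{miremap: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miremap)
```

This vignette is the package's own account of the models it implements,
the parameters that matter, what the synthetic-data generator does and
does not emulate, and the places where the design was genuinely open.
It states no empirical result that the test suite or the acceptance
script does not itself compute.

## 1. The analysis model

The pipeline reconstructs a miRNA-mediated regulatory network for a
two-condition (mutant vs wild-type) design with **no biological
replicates on the miRNA side** — the setting of classic two-platform
profiling studies. Its statistical commitments are deliberately modest:

* **Differential expression is fold-change-only.** Up means linear
  FC ≥ 1.5, down means FC ≤ 0.66, both inclusive; everything else is
  "none". No p-values or multiple-testing corrections are attached to DE
  calls, because with n = 1 per condition a variance model would be
  fiction. Confidence comes instead from **cross-platform intersection**:
  a miRNA counts as a high-confidence DEmiR only when the qPCR panel and
  small RNA-Seq agree on the direction. Direction conflicts (up on one
  platform, down on the other) are dropped and logged; the
  rule never fires on the bundled reference tables, which contain no
  conflicting rows.
* **The interaction evidence is curated, not predicted.** TF→miRNA edges
  come from curated tables and/or ChIP-Seq peak overlap with a promoter
  window; miRNA→target edges come from curated MTI tables. The package
  never scans motifs or predicts seed matches.
* **The inverse-expression filter encodes repression.** A curated
  miRNA→target edge survives only if the miRNA is a DEmiR, the target is
  a DEG, and the directions are opposite. Genes without DE status are
  removed entirely (only DEGs are mapped as active nodes); TFs are the
  one node class retained without DE status, since curated TF regulation
  is informative even when the TF transcript does not move.

### Array fold changes: 2^(−ΔΔCt)

`normalize_openarray()` removes miRNAs with no determined Ct inside
`[ct_min, ct_max]` (defaults 15/35) in *any* sample, averages technical
duplicate wells, quantile-normalizes the sample columns, and computes
FC = 2^(−ΔΔCt) with ΔCt taken against the endogenous control row
(default `U6`). With exactly two samples, quantile normalization reduces
to rank-wise mean substitution; average-tie ranks are interpolated
between the neighbouring sorted means. Two caveats that shaped the rest
of the package:

* QN assumes the two columns share a distribution. A strongly one-sided
  DE signal violates this, and QN then attenuates extreme-tail fold
  changes (by up to about half on the log scale) and can shift values
  near an inserted block of shifted data. This is a property of the
  method, not a bug; section 3 explains how the generator's stated world
  keeps the distortion below the calling thresholds.
* Values at the extreme rank are *pinned*: an item that is already
  rank-1 in both columns gets identical normalized values, i.e. FC = 1,
  no matter how large its true change. Hence the generator's headroom
  rule (section 3).

### Sequencing fold changes: library proportions

`seq_fold_changes()` uses FC = (KO proportion)/(WT proportion) with a
0.5 pseudocount on raw counts. Proportion normalization implies a
**composition effect**: if a large amount of expression is gained in the
mutant, every null miRNA's proportion shrinks by the same factor. The
default synthetic world keeps this factor small enough (≈ 1.2–1.4) that
null miRNAs stay above the 0.66 threshold; users simulating stronger
worlds should expect — as real studies do — globally shifted ratios.

### Promoter windows and peak overlap

The promoter of a miRNA locus is anchored at the 5′ end of the annotated
precursor: `[start − 5000, start + 1000]` on the plus strand, mirrored
for minus. The anchor choice is forced — the precursor locus is the only
coordinate available in locus-string annotations. Overlap of ≥ 1 bp with
a ChIP peak emits a TF→miRNA edge (`evidence = "chip"`); peaks carry an
optional score column with an optional cutoff, off by default. BED input
is converted from 0-based half-open to the package-wide 1-based closed
convention at the I/O boundary.

### Enrichment

`fisher_ora()` is the hypergeometric upper tail P(X ≥ k) — identical to
a one-sided Fisher's exact test. The significance flag uses the **raw**
p at α = 0.05, matching the era's practice; a BH-adjusted column is
reported alongside but does not drive the flag. Because the null is
discrete, the realized type-I rate is strictly below α; the acceptance
suite therefore checks the observed rate against the analytically
computed discrete-null expectation rather than against α itself. The
default universe is the expression table's gene set, not the union of
the collection.

## 2. Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `up_threshold` / `down_threshold` | 1.5 / 0.66 | linear FC | the field's classic cutoffs; inclusive, and 0.66 ≈ 1/1.5 |
| `ct_min` / `ct_max` | 15 / 35 | Ct | qPCR reliable-detection window |
| `adapter` | TGGAATTCTCGGGTGCCAAGG | DNA | Illumina TruSeq small-RNA 3′ adapter |
| `min_quality` | 20 | Phred | 1% error cutoff, 3′-trim semantics |
| `min_len` / `max_len` | 18 / 30 | nt | inclusive miRNA-insert window ("longer than 18, shorter than 30" read inclusively; typical mature miRNAs are 18–30 nt) |
| `max_mismatches` | 2 | nt | alignment tolerance of the original bowtie settings |
| `max_loci` | 20 | loci | multi-mapping cap |
| `min_adapter_overlap` | 7 | nt | shortest adapter prefix trusted at the read end, 1 mismatch allowed per 10 aligned bases |
| `upstream_bp` / `downstream_bp` | 5000 / 1000 | bp | promoter window |
| `alpha` | 0.05 | — | raw-p enrichment flag |

## 3. The synthetic world

`synth_config()` states a world; the generators only materialize it.
Defaults mirror the reference study's structure: a 750-miRNA panel with
48 planted up and 17 planted down miRNAs, 41 of the ups in one 250-kb
cluster on chr12; one up-hub with exactly 45 inverse-consistent DE
targets and one down-hub with 115; a 39-gene reference target set (the
miR-122 analog, de-repressed hence up in the mutant) shared by exactly
9 non-hub down miRNAs; 40 TFs of which TF1 ("cluster TF") has a ChIP
peak in every cluster member's promoter and TF2 shares a planted
6-miRNA overlap with it.

Choices a scientist would want justified:

* **Planted fold changes are log-uniform on [2.5, 10].** The lower bound
  leaves margin above the 1.5 threshold for the two known attenuations
  (QN tail shrinkage on the array; composition renormalization in the
  counts). The upper bound keeps the mutant library's composition shift
  moderate. The enormous dynamic range printed in real panel data (up to
  10^5) is deliberately **not** emulated — only direction concordance
  and the cross-platform correlation are.
* **Abundances are log-uniform over a 128-fold range, with headroom for
  planted miRNAs** so the mutant abundance stays inside the range. This
  is the "detected in both genotypes" property of real panel targets,
  and it is what protects planted fold changes from QN rank-pinning.
* **The U6 control sits in the quiet high-Ct region** (Ct =
  `baseline_ct` − 6). A control placed where the planted DE mass moves
  gets its normalized value dragged by QN and biases every ΔΔCt — the
  generator places it where ranks are stable.
* **Ct model:** Ct = `baseline_ct` − log2(abundance) + N(0, σ), two
  replicate wells per miRNA per sample, so ΔΔCt recovers log2 FC by
  construction.
* **Counts:** multinomial at `seq_depth` per sample (negative-binomial
  overdispersion available via `nb_dispersion`).
* **Cross-platform correlation** is induced by a shared latent log2-FC
  plus independent per-platform Gaussian noise. The target ρ fixes each
  platform's total noise budget at var(t)(1−ρ)/ρ; the known technical
  layers (2σ² from duplicate-well ΔΔCt; ≈ 2·n/(depth·ln²2) from
  multinomial counting) are subtracted from that budget so the
  *measured* correlation of pipeline-recomputed fold changes calibrates
  to ρ. The small residual attenuation from QN is not modelled.
* **Noise-free mode** (`noise_sd_log2 = 0`) zeroes the Ct noise, the
  platform noise, and replaces multinomial draws by rounded
  expectations. This is the regime in which the round-trip guarantees
  hold exactly: 100% planted direction recovery, exact hub degrees,
  exact cluster and co-targeting counts. With noise on, recovery is
  necessarily statistical and no exactness is claimed.
* **Exactness by construction:** hub miRNAs' background curated targets
  exclude opposite-direction DE genes, everyone's background excludes
  the reference set, and co-targeting miRNAs are chosen among non-hub
  down miRNAs — so the planted degrees, the group size 9 and the union
  39 are not merely likely but certain in noise-free mode.
* **Reads** are mature sequence + adapter + random padding to 50 nt,
  Phred 40, with an optional uniform substitution error rate (default
  0). Mature sequences are resampled if they are non-unique or would
  trigger a spurious internal adapter match, so error-free reads trim
  back to exactly the mature sequence.

What a green synthetic test does **not** establish: realistic read-error
profiles, isomiRs, hairpin structure, overdispersed biological
replication, database-scale interaction counts, or the printed dynamic
range of real qPCR panels. Tests against the bundled reference tables
cover the arithmetic of the published analysis; tests against the
synthetic world cover the machinery end to end.

## 4. Numerical and procedural choices

* All internal coordinates are 1-based closed; BED converts at I/O.
* Quantile normalization ties: average-tie ranks interpolate between
  the two neighbouring sorted means.
* The Ct filter removes a miRNA only when *no* sample has a determined
  in-range value; kept rows use all their values (a Ct of 36 in one
  sample does not delete a miRNA that is cleanly measured in the other).
* Multi-mapped reads: fractional 1/k counting among best-distance
  references; the locus cap applies to the *sum* of annotated locus
  counts over the best-distance references.
* Hub reports return the full tie-set at maximal degree — no arbitrary
  single winner.
* Chromosomal region membership is by locus start, avoiding double
  counting at region boundaries; whole-chromosome regions take every
  locus on the chromosome.
* Evidence sets are comma-joined sorted strings with set semantics;
  merging is idempotent and order-independent.
* Seeds: every generator derives a stage seed from the global seed and
  restores the caller's RNG state afterwards.

## 5. Open design decisions

* **Direction conflicts between platforms** are excluded (with a log);
  the alternative — preferring one platform — has no support in the
  data the package is modelled on.
* **"Longer than 18 and shorter than 30 nucleotides"** is read as the
  inclusive window [18, 30] nt, matching the usual span of mature
  miRNAs; both bounds are configurable.
* **Co-targeting** can be computed against all curated targets or
  restricted to DE genes (`de_genes` argument); both modes exist because
  published supplementary tables that would disambiguate the convention
  are not available.
* **DEG coverage** accepts any reference DEG list, so coverage can be
  quoted against a re-analysis list or a published list without the
  package arbitrating between them.
* **ChIP peak scores** are accepted and exposed as an optional cutoff
  but no default filtering is applied — one overlapping peak is
  evidence.

## 6. Known limitations

* Quantile normalization with two samples and one-sided DE attenuates
  extreme fold changes; the package reproduces the method faithfully
  rather than "fixing" it, and the synthetic world is designed so the
  attenuation stays below the calling thresholds.
* The quantifier matches reads against mature sequences only; it does
  not align to a genome, and genomic multi-mapping is approximated via
  the annotation's loci-per-sequence counts.
* With a single pair of samples there is no replication; every DE call
  is a fold-change statement, and the cross-platform intersection is
  the only error control.
* The enrichment stage is a generic ORA; it does not attempt to emulate
  any proprietary knowledge base or causal analysis.
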