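---
title: "Models and methods: quantifying the specificity of targeted DNA methylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: quantifying the specificity of targeted DNA methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methyledit)
```

# The problem

An EpiEditor couples a programmable DNA-binding module (catalytically dead
Cas9 plus an sgRNA, optionally with a SunTag array recruiting multiple
effector copies) to a DNA methyltransferase effector (here the fused
catalytic domains of DNMT3A and DNMT3L). Its job is to methylate the CpG
island (CGI) at the sgRNA target and silence the gene below it. Two failure
modes matter:

1. **dCas9-mediated off-targets** — the sgRNA tolerates mismatches and parks
   the effector at near-matching loci. These are enumerable from sequence,
   which is what `scan_offtargets()` does.
2. **Untargeted effector binding** — DNMT3A binds DNA on its own, so freely
   diffusing effector methylates accessible CGIs genome-wide, independent of
   the guide. This mode dominates in practice and motivates effector mutants
   with weakened DNA binding.

`methyledit` implements the measurement side: per-CpG methylation from
targeted bisulfite amplicons, genome-wide off-target signal from MBD
(methyl-CpG-binding-domain) pulldown coverage, and the summary metrics that
compare effector variants.

# The synthetic-data generator

All tests run against `simulate_genome()` / `simulate_methylome()` /
`simulate_bisulfite_reads()` / `simulate_mbd_fragments()`, which emulate the
study design with known ground truth.

**Genome.** Alternating background and CGI sequence assembled from
dinucleotides, so CpG density is an explicit dial: 0.25 per dinucleotide
inside CGIs, 0.01 outside (defaults; both config-exposed). Half the islands
are labelled constitutively *methylated*, half *unmethylated* promoter-like
islands. One unmethylated island is the on-target region and carries the
planted 20-mer protospacer + PAM at a recorded coordinate.

**Methylome.** Untreated baselines are drawn per CpG: Beta(20, 2) in
methylated islands, Beta(1, 30) elsewhere — a clearly bimodal landscape in
which methylated islands sit near 0.9 and promoter islands near 0.03. These
shapes are invented (no public per-CpG distribution accompanies the study);
they were chosen once to produce the qualitative regime the genome-wide
figures show (strong bimodality, large wild-type gain) and are exposed as
arguments. Treatment with an effector of relative untargeted DNA-binding
affinity $\theta \in (0, 1]$ ($\theta = 1$ for wild type):

* non-blocked target CpGs are set to `p_on` (default 0.85, matching the
  ~79–84% on-target averages such experiments reach);
* CpGs under the dCas9-sgRNA footprint (the protospacer 20-mer) are
  **blocked** and keep their untreated baseline;
* each unmethylated off-target island $r$ gains
  $\theta \cdot a_r \cdot p_{\max}$, clamped to 1, where the island's
  chromatin accessibility $a_r$ is drawn from Beta(2, 2) (default
  $p_{\max} = 0.6$).

The accessibility distribution is a stand-in: nothing in the source material
characterizes it, and Beta(2, 2) merely encodes "most islands are partially
accessible". Because the gain is linear in $\theta$, the ratio of mean
off-target *gains* between two effectors equals their affinity ratio exactly
— the hook the fold-reduction recovery test uses — and treated probabilities
are monotone in $\theta$ by construction.

**Bisulfite reads.** One read pair per amplicon copy, top strand only (the
assay sequences one strand). Per copy, each CpG cytosine is methylated with
its site probability; unmethylated cytosines (CpG and non-CpG) read as T with
`conversion_rate` (default 0.998, matching the >99.5% QC bar), methylated
ones with `inappropriate_conversion` (default 0.002); uniform substitution
errors (default 0.001/base) come last. Qualities are constant Q37 with an
optional planted low-quality 3′ tail (`lowq_tail`) to exercise the trimming
path. There are no adapters, PCR duplicates or indels — adapter handling
therefore reduces to quality trimming, and alignment can be ungapped.

**MBD fragments.** Candidate fragments are uniform over the genome with
Gaussian lengths (default 150 ± 30 bp); a fragment whose CpGs are methylated
per the truth is captured with probability $1 - (1-q)^{M}$, $M$ the number of
methylated CpGs on it ($q$ = `mbd_capture_q`). The implementation draws
retention from the exact marginal $1 - \prod_i (1 - q p_i)$, which is
equivalent in distribution; the test suite checks it against a brute-force
two-stage Monte-Carlo of the explicit model. Exactly `n_fragments` retained
fragments are emitted, mirroring a fixed sequencing depth.

**Seeding.** One global seed expands into per-stage child seeds through
`derive_seed(seed, stage)` (a fixed hash of the stage label), so stages are
independently reproducible and identical configurations give byte-identical
FASTQ/BED/bedGraph outputs.

What the generator does *not* emulate: transfection efficiency, FACS
sorting, SunTag stoichiometry, PCR amplification bias, CpG-density-dependent
fragmentation, or real human-genome sequence composition. Passing tests
therefore demonstrate the correctness of the computations under the stated
model, not performance on GEO data.

# Amplicon analysis choices

* **Quality trimming** removes the maximal 3′ run of bases below Q20 —
  the same threshold as the published workflow; an internal bad base
  followed by good bases is kept.
* **Merging** scans every overlap ≥ 20 nt, scores by matched bases, accepts
  when the overlap's mismatch fraction ≤ 0.1, breaks score ties toward the
  longer overlap, and takes the higher-quality base at disagreements. Pairs
  that fail are counted and dropped rather than analyzed single-end: amplicon
  design guarantees overlap, so unmerged pairs are artifacts.
* **Alignment** replaces a bisulfite mapper with reduced-alphabet ungapped
  alignment: read and reference are collapsed C→T, making conversion
  invisible, and the best-match offset wins, ties to the leftmost, accepted
  at ≥ 0.9 identity. This is the one deliberate methodological substitution:
  simulated amplicon reads are indel-free, so a full aligner would change
  nothing but the dependency list.
* **Calling** counts C as methylated and T as unmethylated at reference CpG
  cytosines, ignoring other bases and bases below Q20 (mirroring the trim
  threshold). Zero-coverage sites report a missing level rather than 0.
* **Conversion QC** uses non-CpG cytosines only (expected unmethylated), so
  it is independent of the methylation truth.
* **Region averages** are unweighted site means over the amplicon's
  analysis subset — for a 19-CpG target amplicon whose sites 16–19 sit under
  the dCas9 footprint, CpGs 1–15. Whether the original analysis averaged
  sites or reads is not documented; site-averaging is assumed. A coverage
  floor (default 100 merged reads, config-exposed; the study obtained ≥3000)
  guards against quoting means from a handful of reads.

# MBD-seq analysis choices

Coordinates are 0-based half-open throughout; bin $b$ of size $s$ covers
$[bs, (b+1)s)$, default $s = 10$ bp. Raw bin signal is the number of
fragments overlapping the bin; RPKM is
$\text{raw} \times 10^9 / (N_\text{fragments} \times s)$.

**Re-calibration.** RPKM alone is wrong in the regime where treatment
creates many new methylated islands: total pulldown mass grows, so unchanged
regions *appear* depleted. The internal re-calibration quantifies per-CGI
mean signal in the untreated sample, takes the K = 1000 most methylated
islands (ties broken by genomic order and flagged) — regions already fully
methylated, whose true signal cannot increase — and multiplies each sample by
$f_i = \text{mean}_R(\text{untreated}) / \text{mean}_R(\text{sample}_i)$.
"Average intensity" is read as the mean of per-CGI means (pooled-bin
averaging is the unchosen alternative). The untreated sample is anchored at
$f = 1$ exactly, preserving RPKM units. After re-calibration the
reference-set mean is equal across samples by construction; the acceptance
suite demonstrates the motivating regime quantitatively (a simulated 10×
mass gain depresses stable-CGI RPKM by far more than 30%, and re-calibration
restores it to within 5%).

**CGI classification** is 1-D two-means on log1p per-CGI means with
deterministic initialization at the 25th/75th percentiles (falling back to
min/max when those coincide); the boundary is the midpoint of the final
centers. All-identical signals are a degenerate-input error. The split is a
design choice — no clustering method is documented for the original
two-group subdivision; two-means is the simplest reproducible rule.

**Peak calling** is fully specified here because no tool or parameters are
documented for the original peak counts: peaks are maximal bin runs where
treated ≥ the 99th percentile of untreated non-CGI bins *and*
treated − untreated ≥ a minimum differential (defaulting to that same
threshold), runs < 100 bp discarded, then gaps ≤ 50 bp fused. It is the
simplest caller whose behavior is provable on planted truth (the tests
require 100% recovery of planted ≥200 bp, 10× gains with zero false
positives on flat background). The published genome-wide counts
(12,864 peaks, 10,921 in CGIs, 9,725 in originally unmethylated CGIs;
27,718 CGIs split 13,316/14,402) depend on the deposited human data and an
unnamed caller and are deliberately not desk-reproduced.

**Fold reduction** over originally unmethylated CGIs is
$(\bar{m}_\text{WT} - \bar{m}_\text{untr}) / (\bar{m}_\text{mut} - \bar{m}_\text{untr})$;
a non-positive mutant gain is reported as a flagged ceiling rather than a
number. The acceptance experiment tunes the mutant affinity to a true
7.8-fold gain ratio and requires recovery within 15% — the tolerance covers
the mild compression from capture nonlinearity ($1-(1-q)^M$ is concave in
methylation), which is why that experiment runs in the dilute-capture regime
$q = 0.02$.

**CGI matrices** put flanks (default 1 kb) in real coordinates and rescale
the island body to a fixed number of columns by nearest-bin lookup;
out-of-chromosome bins are NA.

# Off-target scanner choices

SpCas9 convention: NGG immediately 3′ of the 20-mer protospacer on the hit
strand; mismatches are counted over the 20-mer only, the PAM must match
exactly except at N, genome Ns never match, and bulges are not modeled
(matching how such scans are typically run). Hits are reported per position,
undeduplicated, in forward coordinates, sorted by (chrom, start, strand).
The shipped guide fixture (`inst/extdata/sgrna_guides.tsv`) carries the
ISG15 protospacer `GTTCGCTGCCTCTCAGCCGC` and the scrambled control
`GAACAGTCGCGTTTGCGACT`. The published human-genome hit counts (14 regions at
three mismatches, 94 at four) require hg19 and are documented, not tested.

# Metrics and rounding

Ratios are rounded half away from zero to 1 decimal, percentages to
integers — the convention that reproduces the printed specificity factors
(84/53 → 1.6; 64/6.36 → 10.1) exactly. Metrics that were originally computed
from unrounded internal data (factors 9.4, 2.8, 5.1; residual 56%) cannot be
regenerated exactly from printed rounded inputs — from those inputs they come
out 9.1, 2.7, 5.0 and 57% — so the tests assert them within ±0.3 (ratios) and
±1.5 points (percents) rather than guessing at the unrounded values. A zero
off-target mean makes the specificity factor infinite; it is returned as
`Inf` with a `capped` attribute instead of failing.

# Statistical checks and problem sizes

The test suite's stochastic assertions are binomial: a recovered per-CpG
level at coverage $n$ is compared to the conversion-adjusted expectation
$p_\text{eff} = 0.998\,p + 0.002\,(1-p)$ within
$z \sqrt{p_\text{eff}(1-p_\text{eff})/n}$ plus a 0.005 allowance for
sequencing errors. For the 20-truth-vector recovery check (300 site-level
comparisons at 10,000 read pairs each), $z$ is Bonferroni-adjusted so the
*family* of comparisons holds at 99% confidence — 300 independent 99%
intervals would be expected to fail about three times by chance.

Problem sizes were chosen as the package's desk-scale defaults: amplicons of
~300 bp with 15–19 CpGs, read sets of 2,000–10,000 pairs, genomes of
40–10,000 CGIs, fragment sets of 30,000–120,000. The re-calibration
demonstration uses 1,000 stable methylated islands among 10,000 CGIs
(a 10× treated mass gain) with K = 1000; the fold-recovery experiment uses
1,200 CGIs, $q = 0.02$ and 120,000 fragments per sample.

# Known limitations

* Single-strand, indel-free amplicon model; no barcode demultiplexing, no
  adapter sequence detection, no genome-scale bisulfite mapping.
* The MBD capture model ignores fragment-level biases (GC content,
  length-dependent capture) and treats CpGs independently.
* `fold_reduction` is mildly compressed by capture nonlinearity at large
  $q$; use small capture probabilities when absolute fold values matter.
* The peak caller is intentionally minimal: no local background model, no
  replicate handling, no significance estimates.
* Significance testing of on/off-target differences is out of scope; the
  package reports effect sizes only.
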