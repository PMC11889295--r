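---
title: "Methods: quality control for genome-edited crop lines"
author: "editqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quality control for genome-edited crop lines}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(editqc)
```

Before a genome-edited crop line can move toward field trials it must be
shown to be free of the transformation construct (the T-DNA and, ideally,
any vector backbone), free of unintended edits at sequence-similar
off-target sites, and agronomically equivalent to its parent apart from the
intended trait. `editqc` bundles the four analyses this requires, each
usable on its own, together with seeded simulators that generate every
input the pipeline needs, so the whole chain is testable without external
sequencing data.

## 1. Alignment-free transgene screen

### Model

Reads are decomposed into all overlapping k-mers (k = 20 by default) and
matched against the transformation construct in canonical orientation: a
read k-mer hits when it or its reverse complement equals a construct
k-mer, and one occurrence increments the count once. Each hit increments
the *start position(s)* of that k-mer on the construct, not all covered
bases. The start-position convention means an f-bp residual fragment of
the construct lights up exactly f − k + 1 consecutive positions, so a
significant run of r positions corresponds to a matched length of
r + k − 1 bp. That correspondence is what lets the screen report "a 20-bp
and a 21-bp fragment remain" rather than just "two small peaks". K-mers
containing non-ACGT codes are skipped and tallied; k-mers repeated within
the construct increment all their positions (counts in construct-internal
repeats are therefore inflated, which is documented rather than corrected).

Per position, the sample is compared against a negative control (the
unedited parent line) with an exact conditional test. With counts
$c_s, c_c$ at a position and totals $T_s, T_c$ of examined read k-mers,
condition on $m = c_s + c_c$ and test enrichment one-sidedly:

$$p = P(X \ge c_s), \quad X \sim \mathrm{Binomial}\!\left(m,\;
\frac{T_s}{T_s + T_c}\right).$$

This is exact, parameter-free, valid at zero counts, and depth-normalised
through the totals. The resulting p-values are Benjamini–Hochberg adjusted
and positions with q below the significance level (default 0.01, i.e. the
1% threshold) form maximal significant runs.

**Which positions enter the FDR family.** Positions with $m = 0$ carry no
test (their p-value is identically 1), so BH is applied across the
*testable* positions only ($m > 0$). This is the standard
independent-filtering argument: the filter statistic $m$ is exactly the
statistic the test conditions on, so filtering cannot distort the null
distribution of the p-values that remain. With a 19-kb construct of which
only a few hundred positions carry counts, filtering matters: a planted
20-bp fragment is detected from a single diagnostic k-mer whose count must
clear the BH threshold, and an FDR family padded with thousands of empty
positions would raise that threshold for no inferential gain.

**Masking.** Two signals must not be mistaken for transgene evidence, and
both are visible in the negative control or in the construct sequence
itself. First, the construct may carry host-derived sequence (a host
promoter, or any homologous segment), which legitimately attracts host
reads in *every* sample; a run is masked as `control_elevated` when more
than half of its positions have control counts at or above
max(3, 5 × the control's genome-wide mean count). A plain upper quantile
of the control track was considered and rejected: on sparse tracks (almost
all zeros, a few hundred host-homologous positions) the 99.9th percentile
falls *inside* the elevated block, so half of the background could never
be masked. Second, low-complexity sequence (e.g. a C-rich stretch) attracts
reads from unrelated repetitive loci in all samples, at counts that vary
between individuals and therefore can reach significance; a run is masked
as `low_complexity` when the mean Shannon entropy of its local k-mers is
below 1 bit. A uniform-composition 20-mer has 2 bits; the C-rich decoy
emulated by the simulator (16 C / 5 T) has about 0.7 bits, while ordinary
sequence rarely drops below 1.5 bits, so the 1-bit default separates the
two cleanly.

**Classification.** `present` when unmasked significant runs cover more
than 50% of the T-DNA's k-mer start positions; `residual_fragments` when
unmasked runs exist but all have matched length ≤ 2k + 5 (about twice the
smallest detectable fragment); `absent` when no unmasked run remains;
`inconclusive` otherwise. All thresholds are arguments. The in-silico
marker check (`marker_presence`) mirrors the usual HPT/Cas9 PCR assay: a
feature is called present when its mean count exceeds five times the
sample's non-T-DNA background.

### Detection limit

At template depth $d$ (each template emits an R1/R2 mate pair, so base
coverage is about $2d$), the single diagnostic k-mer of a 20-bp fragment
has expected count

$$\lambda \approx 2d\cdot\frac{r - k + 1}{r}\cdot(1 - e)^k,$$

with read length $r = 150$ and per-base error rate $e$. At $d = 10$ and
$e = 0.005$ this is $\lambda \approx 15.8$, while clearing BH at
$q < 0.01$ within a few-hundred-position family needs a count of about 16,
so single-fragment detection is a coin flip at that depth; at $d = 20$
($\lambda \approx 32$) it is essentially certain. Full-insertion and
no-insertion calls are robust from $d \approx 5$ upward because they rest
on thousands of positions. This detection boundary is a property of the
experiment, not of the implementation: a fragment observed ~16 times
cannot be distinguished from noise at a 1% FDR against 600 candidate
positions with fewer observations than that.

## 2. Off-target site scanning

The scan is exhaustive rather than heuristic: every window on both strands
is tested. A site is reported when the 3-nt window downstream of a 20-nt
window matches the PAM pattern under IUPAC rules (N matches anything) and
the 20-nt window is within the mismatch bound (default 3) of the
protospacer by Hamming distance. Mismatches are counted over the
protospacer only; PAM-less matches are not reported. Genome ambiguity
codes count as matches when the guide base is contained in the code's set.
Exhaustiveness makes the result set a deterministic function of the bound,
so it satisfies subset monotonicity in the bound and strand duality under
reverse complementation, both of which are tested against a naive
window-by-window oracle. Activity scoring (CFD/MIT) and bulged alignments
are out of scope; the intended use is to nominate sites for Sanger
verification, for which the report includes ±200 bp of flanking context.

## 3. Amplicon genotyping

Alleles arrive as resolved per-allele sequences (cloned amplicons or
manually resolved traces); chromatogram deconvolution is deliberately not
attempted. Each allele is aligned globally to the reference with affine
gap scoring (match +2, mismatch −4, gap open −6, gap extend −1 — chosen
so that a 13-bp deletion stays one gap instead of fragmenting; all four
are arguments). Edits are merged into clusters (gaps of more than 10
reference bp separate clusters) and indels are left-aligned through repeat
context, the VCF normalisation convention, so that identical alleles
always produce identical calls. One single-edit cluster yields type
insertion / deletion / substitution; anything else is `complex` with all
clusters listed. Substitution-only alleles are reported as their own type,
never folded into wild type.

The expected SpCas9 cut is placed 3 bp 5′ of the PAM (between protospacer
bases 17 and 18, blunt); reported cut offsets are informational and never
used to reject a call. Zygosity follows from the set of distinct alleles
attributed to a plant — wild type, homozygous, heterozygous (one edited
allele plus wild type), biallelic (two distinct edited alleles), and
mosaic for more than two distinct alleles, the operational signature of a
chimeric regenerant.

## 4. Trait statistics

Published agronomic comparisons are usually available only as
(n, mean, SD) per group, so Dunnett's many-to-one test is computed
directly from summaries: pooled variance across all groups,
$df = \sum (n_i - 1)$, and two-sided adjusted p-values
$p_i = P(\max_j |T_j| \ge |t_i|)$ under the equicorrelated multivariate t
with $\rho_{ij} = \lambda_i \lambda_j$, $\lambda_i = \sqrt{n_i/(n_i+n_0)}$.
Writing $T_i = (a_i Z_i - \lambda_i Z_0)/S$ with $a_i^2 = 1-\lambda_i^2$
factorises the probability given the shared control variate $Z_0$ and the
pooled scale $S$, and the two-dimensional integral is evaluated by
deterministic Gauss–Legendre quadrature (128 nodes per dimension;
doubling the nodes changes results by less than 1e−6, and a 10⁶-draw
Monte-Carlo oracle agrees within three simulation standard errors). The
two-sided form is used throughout because both increases and
non-differences are of interest; labels are *** / ** / * at
0.001 / 0.01 / 0.05. Equal-variance pooling is the classical Dunnett
assumption; heteroscedastic variants are out of scope. A raw-data path
(`generate_trait_data` → `summarize_trait_data`) reduces to the same
summary interface.

## 5. What the simulator does and does not emulate

The generator produces: a uniform-random host genome (default 1 Mb,
GC 0.44); a 19,074-bp construct with T-DNA spanning positions 1–12,584,
HPT and Cas9 features, a 600-bp segment copied verbatim from the host
(the host-derived background source), and a 21-bp C-rich decoy at
positions 2,069–2,089 that is additionally present in 30–50 copies per
individual genome, with the copy number drawn independently per individual
— that copy-number variation is what makes the decoy a *significant*
false-positive signal rather than mere background, reproducing the
situation where a C-rich region lights up in the comparison even though
every sample carries it. Events are `none`, `full_insertion` (the T-DNA at
a random locus) and `fragment` (one T-DNA substring per requested length,
default 20 and 21 bp). Reads are 150-bp R1/R2 pairs from uniformly placed
templates on either strand (`round(depth × L / 150)` templates, so ~2×
depth in bases) with substitution-only errors at 0.5% by default — indel
errors add little at k = 20 because any error already destroys the k-mers
covering it.

Three deliberate idealisations: insertion loci are chosen so that the
junction base differs from the construct's own flanking base, which
guarantees a planted f-bp fragment lights exactly f − k + 1 positions
(otherwise a 1-in-4 flank coincidence extends the run by one); decoy
copies never insert inside the host's homology-donor segment, because the
screen's premise is that host background is *shared* — an insertion
splitting that segment in one individual only would fabricate a private
signal indistinguishable from a real residual fragment; and the host has
no repeat families, so multi-mapping inflation is exercised only through
the decoy. Real crop genomes are gigabase-scale and repeat-rich;
the screen's statistics are depth-normalised so conclusions about the
*method* transfer, but passing tests here say nothing about, e.g.,
k-mer collisions with a 4.2-Gb genome's repeat space. Host genome scale
(1 Mb), depths (10–20×) and replicate counts (20 per event) were chosen as
the smallest sizes at which the screen's regional statistics stabilise.

## 6. Numerical and degenerate-input choices

* The exact conditional p-value is discrete and conservative at low
  counts; the null-uniformity property is therefore asserted in the
  high-coverage regime where the discrete test approaches its continuous
  limit.
* Quadrature ranges cover ±9 control SDs and the 1e−13 to 1−1e−13
  quantiles of the pooled-scale distribution.
* All-zero count tracks are legal inputs everywhere (they test as "no
  evidence"); zero totals, empty regions, all-zero variances, k larger
  than the construct, and protospacers occurring zero or multiple times
  raise typed errors rather than producing silent nonsense.
* Ties in run calling cannot occur (runs are defined by a strict
  threshold); alignment ties are broken deterministically by the alignment
  engine and then normalised by left-alignment, so downstream calls do not
  depend on the tie-break.
* All coordinates are 1-based inclusive end to end; half-open arithmetic
  exists only transiently inside the C++ kernels.

## 7. Known limitations

* The screen detects construct sequence, not its genomic location;
  insertion-locus mapping (split reads) and copy number are out of scope.
* Fragments shorter than k are invisible by construction (the simulator
  warns when asked to plant one).
* Direct-Sanger mixtures are not deconvolved; the genotyper requires
  resolved alleles and mosaicism is inferred from the allele set, not from
  trace heights.
* The scan counts protospacer mismatches only; whether a published
  mismatch count includes PAM positions can differ between tools.
* The Dunnett implementation assumes equal variances; with SDs as
  disparate as the germination trials' 0.04 vs 0.15 the pooled test is
  approximate, which is acceptable here because the conclusions are far
  from the threshold.
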