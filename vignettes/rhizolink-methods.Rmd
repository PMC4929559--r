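---
title: "Linking metabolite absence patterns to nonsense mutations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking metabolite absence patterns to nonsense mutations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizolink)
```

## The problem

Natural accessions of *Arabidopsis thaliana* differ in the secondary
metabolites their roots exude. When a metabolite is entirely undetectable in
some accessions and present in the rest, a parsimonious explanation is a
loss-of-function allele in a biosynthetic enzyme gene carried by exactly the
accessions that lack the compound. `rhizolink` implements this
genotype–phenotype matching for untargeted LC/MS root-exudate profiles of a
diversity panel (the workflow was designed around the 19 MAGIC founder
accessions): it turns an aligned feature matrix into qualitative
presence/absence patterns, turns genome variant tables into per-gene
premature-stop patterns, and reports the exact matches as candidate
gene–metabolite links.

Because the full workflow spans two data worlds (metabolomics and genomics),
the package ships a synthetic-data generator that plants known
gene–metabolite links, so every stage — and the pipeline end to end — is
testable with a known answer.

## The metabolomics side

**Containers.** A feature matrix is a wide tibble: per-feature descriptors
(`feature_id`, `mz` in Th, `rt` in minutes, a single ionisation `mode` per
matrix, since the same compound ionises differently in ESI(−) and ESI(+))
followed by one intensity column per sample. `NA` means the peak picker
detected nothing. Sample metadata records accession, replicate, batch, and a
blank flag (culture medium processed like a sample).

**Absence.** A feature is *absent* in an accession when it is undetected in
all replicates of that accession; the set of absent accessions is the
feature's *pattern*, and the pattern *length* is the set's size (a feature
missing only in Can-0 and Zu-0 has a pattern of length two). Where to draw
the detection line is a genuinely open question — we inherit the decision of
the upstream peak picker, i.e. "absent = missing in the raw matrix", and
expose a numeric `lod` override for users who prefer an explicit threshold.
Absence is always computed on the raw, pre-imputation matrix; imputation
exists only to make the clustering arithmetic possible.

**Quantitative preprocessing** for clustering proceeds in a fixed default
order: half-minimum imputation (each missing cell becomes half the feature's
minimum observed intensity — a proxy for "below the detection limit"),
natural log, per-feature z-scaling (the log base is immaterial after
z-scaling), then surrogate-variable batch correction, then blank filtering.
Running correction before the blank filter means the filter sees
batch-cleaned intensities; both orders are possible by calling the functions
in the other order, but the default is frozen for reproducibility.

**Surrogate variables.** Batch and other non-biological structure is
estimated with a deliberately simple two-step procedure: residualise each
feature on accession means, take the top right-singular vectors of the
residual matrix as surrogate variables, and choose how many by a permutation
test on the singular values (each feature's residuals permuted independently,
100 permutations, keep components while the observed singular value exceeds
the permutation 95th percentile). Because the residuals are orthogonal to the
accession design, subtracting the surrogate projections cannot remove
accession-mean differences. This is a transparent, fully testable estimator
of the same quantity the classical iteratively-reweighted surrogate-variable
algorithm targets; with strong, simple batch structure (the case here) the
two agree in what they remove. `n_sv` can be fixed by hand.

**Blank filtering.** To separate exudate features from medium/instrument
background, a Welch heteroscedastic one-way test compares all groups
(accessions plus blank), Benjamini–Hochberg-adjusted across features at
`p_adj < 0.05`, followed by an unadjusted two-sample Welch post-hoc test
against the blank, required to pass at `p < 0.05` in at least one accession.
The post-hoc stage is intentionally uncorrected — it is a confirmation step
inside features that already passed an FDR-controlled omnibus, not an
independent screen.

Two statistical caveats, both visible in our own simulations and asserted in
the test suite:

* With three replicates per group, the Welch one-way test is *liberal*: its
  denominator degrees of freedom `1/(3Λ)` collapse when every `n_i − 1 = 2`.
  Under a simulated global null with 20 groups of 3, the empirical size at
  nominal 0.05 is ≈ 0.28 (the reference implementation `stats::oneway.test`
  gives the same number — this is a property of the statistic, not of this
  implementation). For a screening filter this errs on the permissive side:
  true exudate features are virtually never lost, while a minority of
  background features ride along and are cleaned up by the downstream
  filters.
* Benjamini–Hochberg controls the false share of the *retained* set. When
  most features are genuinely differential (the designed situation), the
  effective per-feature threshold is close to raw 0.05, which again keeps
  the filter permissive rather than calibrated per background feature.

Groups left exactly constant by half-minimum imputation (e.g. the blank
replicates of a feature never detected in blanks) would have zero variance;
inside the blank filter such variances are floored at the feature's smallest
positive group variance so the statistic stays defined. The exported
`welch_anova()` keeps the strict error instead, because silent flooring is
wrong for general use.

**Normality QC.** A one-sample Kolmogorov–Smirnov test of each transformed
feature against the standard normal is reported (`ks_normality()`) but never
used to drop features — it is a diagnostic of the log/z assumption only.

## Clustering with bootstrap support

Samples are clustered by average linkage (UPGMA) on the Pearson correlation
distance `1 − r` between intensity profiles. UPGMA is written in-package
with a deterministic tie-break (merge the pair containing the smallest
original leaf indices) so that results are bit-reproducible and the same
code path serves both the metabolic and the genetic distance matrices.
Dendrograms are cut at a correlation threshold (default 0.95, i.e. height
0.05).

Cluster support uses multiscale bootstrap resampling of features: at each
scale `r` in 0.5–1.4 (step 0.1), `B` bootstrap draws of `⌈n·r⌉` features
with replacement are reclustered and `BP(r)` is the fraction of bootstrap
trees containing the cluster. `BP` is clipped to `[1/(B+1), 1−1/(B+1)]`, and
`Φ⁻¹(1 − BP(r)) = v·√r + c/√r` is fitted by weighted least squares with
binomial variance weights; the approximately unbiased support is
`AU = 1 − Φ(v − c)`. The signed distance `v` measures how far the data sit
from the cluster boundary, the curvature `c` corrects the plain bootstrap's
bias; with `c = 0` the model collapses to `AU = BP(1)`, an identity the
tests assert on synthetic counts generated from the model itself. Scales at
which the cluster appeared in all or none of the bootstrap trees carry no
information about curvature and are excluded from the fit; a cluster
recovered at every draw on every scale is reported at the clipping bound
(`1 − 1/(B+1)`) rather than through a degenerate fit. Feature resampling —
rather than sample resampling — is the appropriate scheme because features
are the replicated observations that define inter-sample correlation.

## The genomics side

Variants live in a tidy table (`accession`, `chrom`, `pos`, `ref`, `alt`);
the 19-genomes-style convention applies: accessions not listed at a locus
carry the reference allele. Multi-allelic records are split into biallelic
rows. Multi-sample VCF v4.2 import/export is provided (haploid calls coded
as homozygous genotypes).

**Genetic distances.** Variants are reduced to annotated CDS intervals
(GFF3, 1-based inclusive), and the distance between two accessions is the
number of loci at which their alleles differ — a Hamming distance over
allele vectors, so symmetry, zero diagonal and the triangle inequality hold
by construction (and are asserted on random instances). Both the
CDS-restricted and unrestricted locus counts are reported, so either
accounting convention can be audited.

**Premature stops.** Per accession and gene, the CDS variants are applied to
the genomic window right-to-left (so reference coordinates stay valid),
segment boundaries are shifted across indels (edits spanning intron
boundaries therefore act on the genomic sequence before splicing), the
segments are spliced, minus-strand genes reverse-complemented, and the
result translated from position 1 with the standard genetic code. The
protein is *prematurely terminated* when its first in-frame stop falls
strictly before the reference protein's stop. Rather than re-deriving this
decision from a multiple sequence alignment of predicted proteins, the
package compares translations directly — for SNP- and indel-induced
truncations the two approaches decide identically, and direct translation is
deterministic and dependency-free. The mechanism is classified as
`nonsense_snp`, `frameshift`, or `deletion`; deletions removing more than
10% of the CDS count as loss-of-function even when the remaining frame is
intact, covering large structural deletions that abolish the enzyme without
introducing an early stop.

The per-gene *stop pattern* is the set of accessions with a prematurely
terminated protein, computed for a user-supplied enzyme gene list; genes
with no affected accession are dropped from matching.

## Matching and the candidate funnel

Candidate features must (i) be absent in at least one accession, (ii) carry
a monoisotopic annotation, and (iii) have a median intensity over detected
values of at least 10,000 (medians over detected values only, so genuinely
strong features are not dragged under the threshold by their absent
accessions). Matching is *exact* pattern equality between the feature's
absent-accession set and the gene's stop-pattern set — no subset or
similarity matching; a feature lacking in a proper superset of a gene's
affected accessions is not evidence for that gene under this design. All
genes sharing the pattern are listed per feature (multi-gene rows flag
ambiguity); features matching no gene are reported separately. Reports are
written as TSV + JSON with a tally of candidates per pattern length and
deterministic row ordering (pattern length, then m/z).

**Isotope annotation.** The monoisotopic flag comes from a simplified
isotope annotator: features are grouped by retention time (single linkage,
0.05 min), and within a group feature B is the k-th isotope of A when the
m/z spacing matches `k·1.00336/z` within 20 ppm (charges 1–2), the mean
intensity ratio lies in [0.02, 0.8], and per-sample intensities correlate at
r ≥ 0.8. Heads of detected series are monoisotopic; the default `strict`
policy passes only them, mirroring the restrictive behaviour of full
annotation suites on real data (where the monoisotopic filter discards most
absent features); a `permissive` policy additionally passes unassigned
singletons. Full adduct dictionaries and pseudospectrum construction are out
of scope — downstream only the binary flag is consumed.

## The synthetic-data generator

The generator emulates the study design at desk scale: 19 accessions × 3
replicates (one per experiment/batch) plus 3 medium blanks, ~450 base
features, 200 genes of 60–120 codons on two chromosomes (about 40%
two-exon, both strands), 60 flagged enzyme genes, and 5 planted
gene→metabolite links (one via a 2-bp frameshift deletion, the rest via
nonsense SNPs; every planted truncation is verified by translation at
generation time and the resulting stop codon recorded). Intensities are
log-normal (`mu_log = 11`, replicate sd 0.35, i.e. typical intensities
around 6·10⁴ with medians comfortably above the 10,000 filter), with
additive per-batch shifts on the log scale (sd 0.3), censoring below a
detection limit of 500, background (medium) features present in blanks at
15%, decoy absence patterns on 25% of exudate features (sampled away from
the planted patterns unless collisions are requested explicitly), and M+1
isotope companions at +1.00336 Th with intensity ratios 0.15–0.45 (planted
features always receive a companion so they carry a monoisotopic
annotation). Background gene variants are synonymous (or stop-free missense
when an amino acid has no synonymous single-base neighbour), so planted
links are the only truncations.

What the generator does *not* emulate: correlated co-eluting compound
classes, retention-time drift, adducts and in-source fragments, realistic
allele-frequency spectra, or accession-specific quantitative (rather than
qualitative) metabolite differences. Passing tests therefore demonstrate
that the machinery is correct under the stated noise model, not that the
filters are optimally tuned for real instrument data.

Everything is emitted to plain text (FASTA, GFF3, VCF/TSV, TSV matrices,
truth JSON) and re-parsed by the same readers the pipeline uses, so the
on-disk interchange formats are round-trip tested.

## Numerical and degenerate-input choices

* Zero-variance features after log/z are dropped with a warning; a flag
  turns this into an error.
* Constant groups inside the blank filter: variance floored (see above);
  everywhere else zero variance is an error naming the group.
* UPGMA ties: smallest (min-leaf, max-leaf) pair merges first.
* Bootstrap resamples that produce a constant sample column (impossible
  correlation) are skipped and the per-scale denominator adjusted; an
  all-degenerate scale is an error.
* `AU` for clusters with fewer than two informative scales falls back to
  the clipped BP level (all-present or all-absent) or `NA`.
* Variants are applied right-to-left; overlapping edits are an error rather
  than silently reordered.
* A CDS shorter than one codon after editing is premature with mechanism
  `deletion`.
* Accessions missing from a variant record are reference — the convention
  of difference-style variant tables.

## Problem sizes used in the checks

The shipped tests run the generator at reduced scale (40–80 genes/features,
3 planted links) and the full default scale for the end-to-end recovery
check; bootstrap support uses B = 100–200 with the default 10-scale grid.
These sizes were chosen so the whole suite exercises every stage, including
two full pipeline runs, at interactive runtimes; all conclusions asserted at
the reduced scale are scale-free properties (oracle equality, pattern
recovery, determinism).

## Known limitations

* The Welch screen at n = 3 is permissive (see above); with more replicates
  it sharpens considerably, and the replicate count is a generator
  parameter precisely so this is visible in simulation.
* Exact pattern matching is brittle to a single misdetected replicate —
  a deliberate consequence of the strict absence definition; the `lod`
  override is the only knob.
* One transcript model per gene; splice variants, start-loss, missense
  severity, promoter variants and paralog redundancy are out of scope.
* Cross-ion-mode cluster reconciliation is not algorithmic; modes are
  processed separately.
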