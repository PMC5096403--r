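---
title: "Resolving and dating polyploid homeologs: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving and dating polyploid homeologs: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`hexaphase` reconstructs subgenome-specific gene copies (homeologs) from a
hexaploid seed transcriptome, dates subgenome divergence from synonymous
substitution rates, and relates homeolog-specific expression to metabolite
accumulation. This vignette is the package's own account of the models it
implements, the parameters that matter, and the design decisions taken
where the procedure left genuine choices open.

## The problem and the data model

A hexaploid such as cultivated oat carries three homeologous copies of most
genes, contributed by the A, C and D subgenomes. Two of the copies (the
putative A/D pair) are nearly identical — roughly 99% nucleotide identity —
while the third is about 7× more diverged. A conventional assembler mixes
their SNPs into chimeric transcript models, which blocks both sequence-level
analyses (divergence dating) and copy-level expression quantification.

The package therefore models a gene as a triple of coding sequences on the
tree `((2,3),1)` with an outgroup ortholog from a related diploid grass
serving as the assembly template, and a read set as paired-end short
fragments plus long single-end reads drawn from those copies.

## Read quality control

Short reads are 3′-trimmed at Phred 20: the maximal suffix containing any
base at or below Q20 past the last base above Q20 is removed ("above 20" is
read strictly, so boundary Q20 bases are trimmed — the boundary is thereby
testable). Reads are kept if ≥ 90 bases remain with no undefined base; when
only one mate of a pair survives it is retained as a singleton. Long reads
are trimmed the same way and kept if ≥ 90 nt with arithmetic mean quality
≥ Q25 and no N, after exact-duplicate removal (first occurrence wins). The
mean is computed on the post-trim read; whether to average before or after
trimming is not dictated by the procedure itself, so the package fixes the
post-trim convention explicitly. Adapter contamination is modelled as
exact-prefix tag matching; fuzzy tag matching is out of scope.

## Orthology-guided iterative consensus assembly

Reads homologous to a template are selected by a gapless seed-and-extend
local alignment (match +1, mismatch −2, shared 15-mer seeds) with a score
threshold of 40. A raw score replaces a BLAST e-value cutoff because an
e-value presupposes a database-size model the pipeline does not have; the
threshold is validated by a measured false-positive rate below 1% for
random 100-mers and ≥ 90% sensitivity for reads from a copy 10% diverged
from the template.

Mapping is gapless seed-and-extend on both strands with relaxed thresholds
(aligned-length fraction ≥ 0.75 of the read, identity ≥ 0.75 over the
aligned region); among co-optimal placements one is chosen by seeded RNG.
Gapless alignment is adequate here because the simulated (and, in the
motivating system, observed) coding sequences carry no indels — indels
concentrate in untranslated regions, which the pipeline does not
reconstruct. The consensus is the per-column majority base, ties broken
alphabetically (A < C < G < T) and zero-depth columns inheriting the
reference base — both rules fixed so they are testable. Mapping and
consensus calling repeat until the consensus stops changing, with a cap of
20 iterations to guard against oscillation. At convergence the consensus is
a fixed point: remapping and re-calling returns it unchanged. Coordinates
are 0-based half-open; reverse-strand placements contribute
reference-strand bases.

Because the fragment start positions are uniform on the reference, read
depth tapers linearly within one read length of either end; depth-dependent
guarantees (and the variant-recovery tests) therefore apply to the interior
of the reference, not its extreme columns.

## Homeolog phasing

Variant columns are called from the converged pileup when depth ≥ 10 and at
least two alleles each reach frequency ≥ 0.15 and count ≥ 4. The frequency
threshold sits below 1/3 so a homeolog present as one of three equal copies
is detectable, while 1% sequencing error stays well below it; the absolute
count guards low-depth columns. Columns are classed biallelic, triallelic
or ambiguous by the number of passing alleles; triallelic columns need no
special-casing in the clustering.

Fragments (read pairs or singletons) spanning at least one variant column
receive an allele signature. Signatures are clustered greedily: fragments
join the largest existing cluster whose consensus signature agrees with
theirs at every jointly covered variant, else found a new cluster; clusters
are then merged while any two agree at all jointly covered variants, with
informative merges (sharing at least one column) taken before vacuous ones
and larger clusters first. This explicit linkage clustering replaces the
visual inspection and Sanger confirmation used in the laboratory workflow
it automates, and is justified by parameter recovery: at the default study
conditions (true Ks 0.0137/0.10, 400 codons, 50× coverage, 1% error) the
three copies are recovered at ≥ 95% (typically ≥ 99.8%) base identity.

Per cluster, a consensus is called over the columns its fragments cover;
uncovered columns are filled from the pooled consensus. Clusters covering
less than half the template, or beyond the three largest, are demoted to
`extra_members` — the analogue of the partial assemblies and putative
pseudogene copies that real genes can produce. Of the labelled members, the
copy with the greatest mean pairwise distance to the others is named `_1`;
`_2`/`_3` are otherwise arbitrary, because sequence data cannot assign the
near-identical pair to physical subgenomes (the generator likewise labels
truth only `_1/_2/_3`).

A known limitation: where consecutive `_2`-vs-`_3` discriminating SNPs lie
further apart than a fragment span, no read links them and the greedy merge
can join segments across the pair, producing a chimera that swaps a
low-divergence region. This leaves pairwise Ks and overall identity
essentially untouched (the swapped segments are the near-identical ones)
but can misdirect strict read counting between `_2` and `_3` in that
region — the computational echo of why the laboratory workflow needed
Sanger confirmation at exactly this step.

## Synonymous rates and dating

Ks/Ka follow the classic equal-weight Nei–Gojobori (1986) scheme,
implemented from scratch as the package's core statistic. Each codon
position contributes the fraction of its possible single-nucleotide changes
that are synonymous, with changes to stop codons excluded from the
denominator. Differences between codon pairs are averaged over all k!
single-step pathways, discarding pathways through stop codons and
reweighting the survivors equally. Proportions are corrected for multiple
hits with the Jukes–Cantor formula d = −¾ ln(1 − 4p/3); ps ≥ 3/4 is a
flagged "saturated" state, never a crash. All gapped codon columns are
removed before counting. The implementation is table-driven (precomputed
per-codon site fractions and 64 × 64 pathway-averaged difference matrices)
and is verified in the tests against an independently written brute-force
enumeration oracle over every sense codon pair. Transition/transversion and
codon-usage weighting belong to the Yang–Nielsen estimator family and are
deliberately out of scope; published non-NG86 Ks columns are treated as
printed inputs to the dating arithmetic only.

Gene-level Ks values are averaged arithmetically per genome pair (saturated
genes dropped with a warning) and dated as T = Ks/(2λ) with
λ = 6.1 × 10⁻⁹ synonymous substitutions per synonymous site per year,
reported in million years rounded half-up to one decimal — the convention
that reproduces 107 of the 108 printed cells of the shipped grass
divergence table (the single discordant cell computes 55.9 against a
printed 55.8 under every rounding rule consistent with the rest of the
table).

Subgenome topology is summarized by UPGMA (average linkage on the Ks
matrix, lexical tie order, ultrametric by construction) rather than a
likelihood tree search; bootstrap support resamples codon columns — not
nucleotides, to respect codon structure — across the concatenated
multi-gene alignment, default 1000 replicates (tests and the acceptance
script use 100).

## Homeolog-specific expression

Quantification uses zero-tolerance mapping: a read counts only if it
matches a reconstructed homeolog end-to-end without mismatch, on either
strand ("minimum fraction length and minimum identity fraction of 1"). A
pair with both mates matching a common homeolog is one fragment; a mapped
singleton is one; a broken pair (one mate mapping) contributes nothing.
Fragments matching several homeologs are assigned randomly with probability
proportional to each candidate's unique-fragment count divided by its
length — the most literal reading of proportional assignment "normalized by
the transcript length", computed per sample after QC; the RNG is seeded so
assignment is reproducible.

Size factors are median-of-ratios: the per-sample median, over rows with no
zero, of the count divided by the row's geometric mean. The package
rescales the factors to geometric mean one before normalizing. The reason
is a small but exact identity: the literal estimator is invariant to global
rescaling, so the factors of any normalized matrix equal the geometric mean
of the original factors — under the geometric-mean-one convention that
constant is exactly 1 and normalization is idempotent. The literal
(unscaled) estimator remains available and is what the test suite compares
against DESeq2's implementation.

The variance-stabilizing transform is the closed-form negative-binomial
form v(x) = (2/√α)·asinh(√(αx)) with a single common dispersion α estimated
by method of moments across rows (Poisson limit 2√x as α → 0). This is a
deliberate simplification of a fitted mean–dispersion spline; accordingly
the tests assert the stabilization property (variance flat within 2× across
a 100-fold mean range), not equality with any particular library.

Diagnostics are PCA on column-centered VST values with samples as
observations, classical MDS of the Euclidean sample distances (numerically
equivalent to the PCA scores up to sign), the sample-distance matrix for
heat maps, and mean-standardized expression profiles. Stage-level analysis
averages replicates after normalization; Pearson correlations between each
homeolog's stage profile and each tocol curve (T, T3, total) are computed
over the four developmental stages, with degenerate (zero-variance)
profiles flagged rather than propagating NaN.

## The synthetic data generator

The generator defines the study conditions, not a tuning surface. Per gene
it draws an ancestral CDS uniformly from sense codons and evolves the
copies on `((2,3),1)` plus the template branch. Synonymous changes are
placed at third positions within synonymous codon classes and
nonsynonymous changes at ω = 0.1 times the synonymous rate; branch
substitution counts start from Jukes–Cantor-inverted targets and a
calibration loop remeasures realized NG86 Ks and rescales until it is
within 8–10% of the targets (true Ks is thereby a controlled quantity).
Defaults: 5 genes × 400 codons; Ks 0.0137 between copies 2 and 3, 0.10 to
copy 1, 0.30 to the template — the two divergence tiers and
template distance the method is designed for.

Reads: Poisson fragment counts around the expected abundance, uniform
positions, both strands, 100-base pairs at 300-base inserts, per-base
substitution errors at 1%, a two-state quality model (~Q38 body, ~Q12
tails on 10% of reads) sufficient to exercise the Q20 trimmer without
modelling instrument error profiles, occasional N bases, and long reads of
90 up to 861 bases at low coverage. No indels are simulated in coding
sequence. Expression: expected counts are baseline × homeolog multiplier ×
stage factor × library-size factor, observed counts negative-binomial with
dispersion 0.05. The default bias specification encodes the conditions the
analysis targets: a 7:1:7 homeolog ratio within VTE2, HGGT baseline 15-fold
above VTE2, sigmoidally rising HPPD (the tocol-linked profile, ~7× dynamic
range chosen so a designed correlation of 1 survives counting noise), and
declining VTE4_2/_3 (anti-linked). Tocol curves are affine in the linked
homeolog's stage means with Gaussian noise of 10% of the range, tocotrienol
above tocopherol throughout. Library sizes are log-normal with σ = 0.15 —
realistic sample-to-sample variation that the size factors must recover.

What passing tests on these data do *not* show: robustness to indels, UTR
variation, instrument-specific error structure (homopolymer errors of
pyrosequencing), unbalanced homeolog copy number, or the exact
retained-read tallies and unique-mapping rates of any real experiment —
those depend on real data excluded by design.

## Determinism and numerical conventions

Every stochastic step draws from a stream derived from one global seed by
fixed offsets, so whole-pipeline runs are byte-identical given (config,
seed) and each module is independently reproducible. Fixed tie-breaks:
consensus ties alphabetical; cluster merges by size then order; UPGMA ties
lexical by label. Rounding of reported MYA is half-up to one decimal.
Degenerate inputs are defined states, not crashes: saturated Ks, zero-depth
columns, zero-variance correlation profiles, empty FASTA/FASTQ records and
all-zero count rows each produce a flagged value or a named error.

## Problem sizes used by the tests and acceptance script

Unit and property tests run on 100–300-codon genes at 40–50× coverage; the
acceptance-grade checks use the full study conditions (5 genes × 400
codons, 50× coverage, 1% error) with 10–20 seed replicates for the
stochastic criteria, 100 bootstrap replicates, and read-level
quantification at a scaled fragment depth in the pipeline smoke tests.
These sizes were chosen so the full suite completes in a few minutes while
every stochastic envelope retains its designed power; the generator's
scientific defaults are never altered by tests.
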