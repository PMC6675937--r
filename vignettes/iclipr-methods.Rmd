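---
title: "Methods and design notes for iclipr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for iclipr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and coordinates

`iclipr` implements the analysis stages that turn deduplicated iCLIP
alignments and an Ensembl-style annotation into biological summaries:
crosslink tracks, randomization-FDR significant bases, kmer z-scores,
splicing/processing indices, metagene profiles, category enrichments with
bootstrap CIs, retained/detained intron sets, and expression-weighted
transcript lengths.  Upstream read processing (demultiplexing, mapping,
UMI deduplication) and downstream differential-usage fitting are out of
scope; the package consumes standard files (SAM/BAM, GTF, BED, TSV).

Internally every interval is 0-based and half-open, on both strands; the
GTF reader/writer converts from/to 1-based inclusive coordinates and BED
output is written as-is.  One convention everywhere keeps the window,
junction-offset and overlap arithmetic honest.

# Gene chunking and intron classes

Genes are flattened into the minimal set of non-overlapping *chunks* whose
boundaries are the union of all exon edges across isoforms, so every
isoform is a union of whole chunks.  Chunks overlapping more than one
gene span are discarded.  A chunk is *intronic* if it overlaps at least
one intron of the expressed transcript set (mean TPM strictly greater
than 1, mitochondrial genes removed) and no exon of any reference
isoform; *exonic* under the mirrored rule; anything else is kept with
`kind = "ambiguous"` rather than dropped, so downstream analyses can
include or exclude mixed chunks explicitly.  Overlap always means at
least one shared base; the 10-nt requirement in intronic read counting is
a property of that counting step, not of classification.  We do not try
to rescue intra-genic chunks of overlapping gene pairs: any chunk
touching two gene spans is gone, which loses a small amount of genuinely
intronic territory in dense loci but never mislabels it.

Retained introns are isoform-pair evidence: for an ordered pair (A, B)
where every intron of A occurs with identical coordinates in B, each
extra intron of B inside A's span is retained (exonic in A, spliced in
B).  The output depends only on the isoform set, not input order.

# Crosslink-site conventions

The crosslinked base of an alignment is the deletion closest to the
read's 5' end when a deletion-from-reference exists; insertions and soft
clips never qualify.  Without a deletion, truncation mode takes the base
immediately 5' of the read start (on the read strand); center mode —
appropriate for protocols that read through the crosslink — takes the
middle *aligned* base, skipping splice gaps, with the lower-middle base
chosen for even-length alignments.  We chose the middle aligned base over
the middle of the genomic span because a spliced read's genomic midpoint
can fall inside an intron the read never touched.  Sites that would fall
before position 0 are counted and skipped.  Duplicate flags are
respected, never recomputed.  Gene-level tag counting is sense-strand
only by default (`same_strand = TRUE`), matching iCLIP library chemistry;
the flag exists because antisense contamination is occasionally worth
quantifying.

# Significant bases by randomization

Each gene contributes one region of merged exons (concatenated, so the
height window runs in spliced coordinates) and one region per intron.
The height of a base is the number of tags within `half_window = 15` nt
inside the region; heights count tags with multiplicity, reading the
procedure's "number of crosslink bases" as tag count, since collapsing
multi-tag bases would make the statistic insensitive to exactly the
strong sites it is meant to find.  Tags are re-placed uniformly at random
within the region (with replacement — collisions are legitimate
rearrangements), 100 times by default, and

\[ \mathrm{FDR}(h) = \frac{\mu_h + \sigma_h}{P_h} \]

with \(P_h\) the observed fraction of bases at height at least \(h\).
The source procedure mixes "height > h" and "height ≥ h"; we use ≥ on
both the observed and randomized side for internal consistency (the
difference is one grid step) and expose `strict = TRUE` for the other
reading.  \(\sigma_h\) is the population (n-divisor) standard deviation
over randomizations, switchable to the sample version.  Heights whose
observed fraction would be zero cannot occur among reported bases; the
degenerate case is defined as maximally significant for completeness.
Bases with FDR below 0.1 are significant, and significant bases within
15 nt merge into clusters.  Every base whose *height* qualifies is
reported, not only bases carrying a tag (`tagged_only = TRUE` restricts
to crosslinked bases); replicate-reproducibility filtering is a set
operation on cluster tables left to the caller.

# Kmer z-scores and control correction

Merged-exon sequences are scanned for all \(4^k\) kmers (T ≡ U, N never
matches); \(f_s\) sums the height at every match start transcriptome-wide,
and \(z_s = (f_s - \mu_s)/\sigma_s\) over 100 within-gene randomizations
of the tag positions, heights recomputed each time.  A kmer with zero
randomization variance has undefined z and is reported NA.  Because
crosslinking itself prefers uridine-rich sequence in both the pulldown
and the FLAG-only control, the ranking statistic is the residual from an
ordinary least-squares regression of test z on control z, fitted over
every kmer with defined z in both sets — no outlier trimming, since
trimming would have to know which kmers are "really" enriched.  Uracil
content as an explicit covariate was considered and left out: the control
library carries the same bias, so the single regression already absorbs
it; a two-covariate variant is a one-line extension for users who lack a
matched control.  The 3'UTR-restricted analysis is the same machinery run
on 3'UTR intervals.

# Splicing and processing indices

Junction reads are classified per junction with strand-oriented rules:
spliced reads must splice at exactly the annotated coordinates and touch
both flanking exons; EI/IE reads must align contiguously across the
boundary with at least 3 nt on each side.  An unspliced read spanning the
entire intron satisfies both boundary rules and is counted once, as EI,
keeping the classes disjoint.  The flattened index formula is ambiguous
between a sum of per-junction ratios and a ratio of sums; we compute the
ratio of sums, which is defined at sparse junctions where per-junction
ratios divide by zero, and expose `per_junction = TRUE` for the
distributional view.  `junction_subset = "first_only"` restricts to each
transcript's 5'-most junction.

For the processing index, the terminal poly(A) site of a gene is the
3'-most site (strand-aware) overlapping its expressed transcripts.  The
50-nt windows split half-open at the cleavage boundary: the upstream
window includes the last transcribed base, the downstream window starts
at the boundary.  Since upstream signal comes from processed plus
unprocessed molecules and downstream signal from unprocessed only,
\(u - d\) estimates the processed contribution and
\(\mathrm{PI} = \log_2(\Sigma d / \Sigma(u-d))\).  We keep the printed
formula's orientation (numerator = downstream); the figure-legend
wording that suggests the inverse is one sign flip away.  Genes with
\(d > u\) (sampling noise) would contribute *negative* processed
estimates; they are clamped to zero before summation and their count
reported, which biases PI slightly downward rather than letting noisy
genes cancel real signal.

# Profiles

Whole-gene metagenes bin each gene's merged exons into `n_bins` equal
bins; flanks are covered by `n_flank_bins` bins whose width equals that
gene's exonic bin width, so flank scaling follows gene length.  Per-gene
profiles are normalized to their total (zero-tag genes dropped) and
summed; both the raw sum and an area-normalized version are available,
since the choice only rescales the display.  UTR/CDS/UTR profiles use
20/100/70 bins, per-bin counts divided by bin size, per-transcript
normalization to 1, summed over transcripts, and finally divided
elementwise by the identical profile of an RNA-seq track, which cancels
UTR mis-annotation; empty RNA-seq bins give NA with a warning rather
than an arbitrary pseudo-count.  Junction profiles use internal junctions
only (first and last excluded), require both flanking exons to be at
least `flank` nt, count tags in transcript coordinates, normalize per
junction, and normalize the summed profile to 1.  Offset 0 is the first
base of the downstream exon and −1 the last base of the upstream exon,
so "a peak at −24" means 24 nt into the upstream exon — fixing an
off-by-one the verbal description leaves open.

# Enrichment bootstrap

Category enrichment is the log2 ratio of summed test to summed control
tags.  Confidence intervals are percentile bootstrap — "the central 95%
of resampled values" is exactly the percentile method, so BCa would be a
different statistic — resampling genes, or exons when the categories are
exon classes, with replacement within each category; the category map is
fixed across draws.  No pseudo-counts: a category or draw with zero
control tags is reported missing/excluded (with a count) instead of
being inflated.  Nuclear/cytoplasmic lncRNA labels are consumed as an
input category file, not recomputed.

# Detained introns

Constitutive-intron chunks are counted with primary, uniquely mapping
reads at a 10-nt minimum overlap.  Size factors are the median-of-ratios
estimator (median taken in log space, matching the standard
implementation).  Effective lengths
\(L^{eff}_j = L^G_j + L_{read} - 20 - M_j\) count the positions a
counted read could start from, with \(M_j\) masked (multimappable)
positions supplied as BED intervals or a per-intron vector; the read
length is a single global parameter because it is a property of the
sequencing run.  Weights \(w_j = L^{eff}_j / \Sigma_i L^{eff}_i\)
redistribute each gene's normalized intronic total into null replicates
\(N_{i,r} = w_i \Sigma_j C_{j,r}\), one per real replicate, conserving
per-gene totals to machine precision; zero-weight introns are excluded.

The observed/null comparison is a negative-binomial Wald test written
in-package rather than delegated, because the null-construction and the
test together *are* this module's contribution.  Per-intron dispersions
come from the method of moments on within-group variability, averaged
across the two groups, then shrunk halfway toward a trend
\(\alpha(\mu) = a_0 + a_1/\mu\) fitted across introns — the same
mean-dispersion structure the standard NB machinery assumes, without its
empirical-Bayes machinery; with three replicates per group the trend
dominates, which is the intended behaviour.  Wald statistics use
\(\mathrm{Var}(\log \bar{x}) \approx (1/\mu + \alpha)/n\) per group,
p-values are two-sided, FDR is Benjamini–Hochberg (the procedure used
wherever "FDR" appears unqualified), and a detained call additionally
requires the observed mean to be at least 4 times the null mean.  The
4-fold filter makes the call set robust to the exact dispersion
treatment, which is why concordance with any particular external
implementation is not the validation target — parameter recovery on
synthetic data is.

Binding-density bins take log2(tags/size) per chunk (chunks under 10 bp
excluded), split the range of finite densities into three equal-width,
right-closed bins Low/Medium/High; zero-tag chunks have undefined
density and go to Low (reported), and a degenerate range puts everything
in Low.

# APA lengths

The weighted length of a gene in a sample is
\(\Sigma_t \mathrm{TPM}_t L_t / \Sigma_t \mathrm{TPM}_t\) — TPM because
the input is a transcript quantification table, and usage weighting
should not double-count length the way count weighting would.  The
per-gene change is the log2 ratio of condition means; genes undefined in
either condition are omitted.  The shorter/longer tally is a reporting
helper with a user cutoff, since meaningful cutoffs depend on the
dataset.

# The synthetic-data generators

The generators define the conditions every stochastic test runs under,
chosen once to be a desk-scale caricature of a mammalian transcriptome:
4–8 exons per gene, log-normal exon lengths around 150 nt (close to the
human median) and intron lengths around 300 nt (short-intron regime,
keeping region randomizations cheap), Poisson background crosslinking at
0.02 tags/nt, single-base peaks 24 nt upstream of junctions at 20 times
the expected background height, 30% of genes with a retained-intron
isoform pair, negative-binomial intronic counts (dispersion 0.05, three
replicates, library scale factors 1/1.25/0.8) with one detained intron
planted in half the genes at exactly 8 times the null mean it will
receive — solved as a fixed point, since inflating an intron also
inflates its own weighted null; the construction requires the intron's
weight to be below 1/fold, which is why DI genes carry 10 introns.
Junction reads are emitted as minimal SAM (2:1:1:1 S:EI:IE:other, 15-nt
anchors) so the real readers are exercised.  Two-condition expression
tables move 50% of the long isoform's usage onto a half-length isoform,
giving closed-form expected length changes.  All generators are
deterministic given the seed, with fixed per-generator seed offsets.

What the generators do **not** emulate: sequencing error, fragment-length
and UMI structure, mappability-driven coverage bias, overlapping genes,
antisense transcription, expression-dependent crosslinking efficiency,
and real motif grammar (planted kmers sit in otherwise uniform-random
sequence).  Passing the recovery tests therefore demonstrates the
*algorithms* are correct and calibrated under their stated model, not
that real libraries meet that model.

# Problem sizes and numerical tolerances

The test suite and acceptance script run at: 200 genes for peak-calling
sensitivity (100 randomizations per region), 20 seeded repetitions of
the 6-mer recovery (50 genes of 1 kb, 100 randomizations, test and
control), 5 000 introns for detained-intron recovery, 200 repetitions of
the bootstrap-coverage experiment at 200 genes with 200 bootstrap draws,
and 15–20 instances per brute-force oracle comparison.  Exact statements
(conservation, oracle equivalence, closed forms) are asserted at
machine precision (1e−9 or tighter); stochastic recoveries use the
margins stated in the tests (e.g. sensitivity at least 0.9, empirical
FDR at most twice nominal).  These sizes complete in a few minutes on
one CPU while leaving the stochastic assertions far from their margins.

# Known limitations

* Chunk classification is unstranded, like the interval-intersection
  tools it mirrors; antisense overlap can render chunks ambiguous.
* The NB test's dispersion shrinkage is deliberately simple; with many
  replicates a per-intron estimate would be preferable.
* `call_significant` recomputes the randomization null per region; for
  very deep tracks a shared-height-distribution approximation would be
  faster but is not what the procedure specifies.
* Junction-read classification assigns whole-intron unspliced reads to
  EI by convention; callers needing symmetric treatment should classify
  at `min_anchor` large enough to exclude them.
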