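---
title: "Methods: signature refitting, cohort discrimination and saturation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature refitting, cohort discrimination and saturation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigrefit)
```

This vignette is the package's own account of the methods it implements: the
models, the tunable parameters and their defaults, the numerical choices, what
the synthetic-data generator does and does not emulate, and the design
decisions taken where the underlying procedure admitted more than one
reasonable formalization.

## SBS-96 classification

A somatic single-base substitution is classified by its substitution type and
its two flanking bases, always expressed on the pyrimidine strand: an event
with a purine reference base (A or G) is reverse-complemented — alleles and
flanks alike — before lookup. This yields 6 substitution types (C>A, C>G,
C>T, T>A, T>C, T>G) × 16 flanking contexts = 96 channels. Channel order is
the canonical COSMIC order (substitution blocks in the order above, flanks
ordered A, C, G, T within each block), so catalogues and reference TSVs align
with published material without reindexing. The classification is closed
under reverse complement by construction; the test suite verifies this
exhaustively over all 192 valid (ref, alt, up, down) quadruples.

Variant coordinates are 1-based (VCF convention); interval files are 0-based
half-open (BED convention). Conversion happens once, at the I/O boundary.

Records whose flanking context contains a non-ACGT base, or which sit at a
contig boundary, are dropped and counted in a discard tally rather than
raising an error — real genomes contain Ns and telomeric edges. A record
whose stated reference base disagrees with the genome is dropped with a
warning by default (`on_ref_mismatch = "error"` upgrades this to a hard
failure for pipelines that treat it as corruption). Only true SBS events are
consumed; indels and MNVs in input files are skipped with a count.

## Filters

* **VAF filter** (`filter_vaf`): keeps records with variant allele fraction
  at or above `min_vaf` (default 0.10, threshold inclusive). Records without
  a VAF are kept by default, since site-only VCFs are common; `strict = TRUE`
  drops them.
* **Blacklist filter** (`blacklist_filter`): removes records at listed
  (chrom, pos) sites — the practical residue of a pooled-normal
  ("metanormal") analysis, in which recurrent artefact and germline-leakage
  positions are identified once and excluded thereafter. The operation is a
  set difference and therefore idempotent.
* **Region partition** (`partition_by_region`): each mutation gets exactly
  one compartment label. Where annotations overlap (an exon of one gene over
  an intron of another), precedence is exonic > intronic > extragenic;
  positions covered by no interval default to extragenic. Overlap handling
  has no single convention in annotation files, so the package fixes one and
  documents it; the brute-force per-mutation interval scan in the tests pins
  the behaviour.
* **Panel subsetting** (`subset_to_panel`): retains mutations inside a
  targeted-panel footprint, emulating in-silico panel extraction from
  broader sequencing.

## Refitting model

Per sample, exposures solve the non-negative least-squares problem
min ‖y − S e‖₂ s.t. e ≥ 0, where y is the raw 96-channel count vector and S
the column-stochastic reference. The solver is the Lawson–Hanson active-set
algorithm written for this package (`nnls`): coordinates enter the passive
set by the largest dual gradient, the passive subproblem is solved by QR, and
infeasible coordinates are stepped back to the boundary. At the solution the
Karush–Kuhn–Tucker conditions hold: no exposure can be perturbed (respecting
non-negativity) without increasing the residual. The tests verify this
directly by ±1e-6 perturbation, against an independent NNLS implementation,
and against a brute-force simplex grid search at step 1e-3.

Numerical choices:

* The dual-feasibility tolerance defaults to
  `10 · eps · max|S| · max(dim)` — scale-aware, so fitting counts and fitting
  frequencies behave identically (NNLS is scale-equivariant; the tests assert
  it).
* Cosine similarity is computed between the **raw count profile** and the
  reconstruction `S e`. Since cosine is scale-invariant, pre-normalizing
  counts would change nothing; fitting on counts keeps raw exposures on the
  interpretable mutations-attributed scale.
* Normalized contributions divide by `Σ e`, not by the mutation total; the
  unexplained residual fraction `1 − Σe/n` is reported separately rather than
  silently absorbed.
* A profile entirely outside the reference span fits to all-zero exposures;
  its cosine is defined as 0 (with a warning) and the sample is flagged not
  assigned. An all-zero input profile is an error — fitting is undefined.
* The assignment threshold is 0.9, read inclusively: cosine = 0.9 exactly is
  assigned; strictly below is "not assigned".

The sparse backend (`method = "sparse"`) emulates strict-fitting tools:
starting from the NNLS support, it repeatedly removes the signature whose
removal least degrades the cosine, as long as that degradation stays below
`drop_tolerance` (default 0.01 cosine units — a package choice, documented as
emulation rather than a canonical value), then refits on the survivors. With
`drop_tolerance = 0` the NNLS support is returned unchanged.

## Signature sets and flatness

The package ships editable aetiology sets for COSMIC-style references:
mismatch-repair deficiency {SBS6, SBS15, SBS20, SBS21, SBS25, SBS26, SBS44},
*POLE* {SBS10a, SBS10b} and flat {SBS3, SBS5, SBS8, SBS40, SBS89}. SBS25 is
kept in the MMRd stratification set although COSMIC ascribes it a
chemotherapy-related aetiology — the set is a stratification tool, not an
aetiological claim, and the discrepancy is flagged here deliberately. Set
members absent from a loaded reference are dropped with a warning.

A signature is **flat** when no channel carries 5% or more of its mass
(`is_flat`, strict inequality at the 0.05 boundary). The threshold is a
fraction: for scale, the uniform signature already puts ≈1.04% on every
channel, so a literal 0.05 *percent* criterion would be unsatisfiable for any
normalized 96-vector; 5% is the interpretation under which the canonical flat
signatures qualify and spiky ones do not. The threshold is a parameter for
users who want a stricter or looser notion.

## Cohort statistics

`delta_stat` computes the difference of median set contributions between two
annotated groups, oriented so the signature-bearing group comes first —
positive delta means discrimination in the expected direction, and swapping
the groups flips the sign exactly. Medians of even-sized groups are the mean
of the central order statistics (R's default). Not-assigned samples are
**included** in the medians by default; `compare_cohort(assigned_only =
TRUE)` provides the alternative, since excluding unreliable fits is equally
defensible and the choice can matter for small cohorts.

Group differences are tested with the two-sided Wilcoxon rank-sum test
(`ranksum_test`, wrapping `stats::wilcox.test`): the exact null distribution
when the combined sample size is ≤ 12 and the data are tie-free, otherwise
the normal approximation with continuity and tie (midrank) correction. The
exact branch is pinned against a brute-force enumeration over all
assignments for group sizes up to 5. Significance footnotes follow the
conventional mapping (\*, \*\*, \*\*\*, \*\*\*\* for p < 0.05, 0.01, 0.001,
0.0001; boundaries strict). No multiple-testing correction is applied by
default — the comparative table reports raw p-values, with an optional
Benjamini–Hochberg column (`p_adjust = "BH"`) for users scanning many cells.

`compare_cohort` runs the Cartesian product of backends × references ×
compartments and emits one long-format row per (configuration, set, group
pair) in a deterministic order; every cell equals the corresponding
standalone call bit-for-bit, which the tests check.

## Saturation analysis and the minimum mutation count

For each sample, `saturation_analysis` subsamples the mutation list without
replacement at fractions 5%–95% in 5% steps (19 fractions), five replicates
each — 95 points per sample at the defaults. Subset size is
`floor(fraction × n)`, chosen over rounding for determinism. Each subset's
own profile is rebuilt and refitted, and the recorded cosine compares the
subset profile with *its own* reconstruction (the per-sample quality readout
one would compute on a dataset of that size); `against = "full"` scores
subset fits against the full-sample profile instead, as a sensitivity
analysis.

Randomness is hierarchical: every (master seed, sample, fraction, replicate)
tuple is hashed to its own 31-bit seed (a small multiplicative string hash
whose arithmetic stays in the exactly-representable double range), so any
single point can be reproduced in isolation, replicates are independent, and
the full grid is bit-reproducible across runs on R's default generator.

`minimum_mutations` turns the point cloud into one number. All points are
pooled as (mutation count, cosine) pairs; the pooled count range is split
into equal-width bins (default 10, i.e. decile width); the median cosine is
computed per bin; and the reported minimum is the lower edge of the first bin
from which every occupied bin's median stays at or above the threshold — a
*sustained*-crossing rule, so a single lucky bin below a later dip cannot
win. Reading one number off a median curve admits many formalizations; this
binned sustained rule is the package's explicit, reproducible choice, and
raising the threshold provably never lowers the answer (tested). Two
numerical details: bin membership uses right-closed handling for the maximum
(so the largest count belongs to the last bin), and medians are compared to
the threshold with a 1e-9 tolerance, because the median of an even bin
straddling a crossing is the mean of two floats and can land a machine
epsilon below the intended value. When the threshold is never sustained the
function returns a "not reached" result carrying the best median attained —
not an error, since that outcome is informative. Per-sample crossings are
reported alongside for inspection.

## The synthetic-data generator

The simulator exists so that every pipeline stage can be exercised against
known ground truth without any external download.

* `make_genome` draws a uniform-random ACGT sequence (default 100 kb — large
  enough that all 32 pyrimidine-normalized trinucleotide contexts occur
  hundreds of times per compartment, small enough for seconds-scale tests)
  and overlays alternating exonic/intronic/extragenic blocks (default 1 kb)
  that partition the sequence.
* `make_reference` builds spiky signatures (75% of mass on three random
  channels, rejection-sampled until all pairwise cosines are below 0.5, so
  mixtures are identifiable) and flat signatures (near-uniform Gamma draws
  whose maximum channel sits far below the 5% flatness cutoff).
* `simulate_catalogue` is the probabilistic core: channel counts are one
  multinomial draw of size n from the mixture `S e`.
* `simulate_cohort` realizes each drawn channel as a concrete variant record
  at a genome position whose trinucleotide context matches, with the
  genome-strand alleles (purine-strand positions emit complemented alleles).
  Positions are indexed once per context; within-sample collisions are
  redrawn so records are unique, and rebuilding the catalogue from the
  emitted records reproduces the drawn counts *exactly* — the round-trip the
  tests assert, including through TSV and VCF serialization. VAFs are
  uniform on [0.1, 1] by default, with an optional sub-threshold spike-in to
  exercise the VAF filter. A configurable fraction of records
  (`artefact_rate`) is drawn from a designated artefact signature and placed
  at dedicated blacklist positions (a reserved share of each context's
  position pool, `blacklist_share`, default 0.2), so blacklist filtering
  removes exactly the planted artefacts.

What the generator deliberately does **not** emulate: human base composition
and trinucleotide frequencies, mutation-rate covariates (replication timing,
chromatin, transcription-strand asymmetry), clonal structure in VAFs,
sequencing error models, and real COSMIC signature shapes. Passing tests
therefore demonstrate the correctness of the machinery — classification,
fitting, statistics, determinism — and the recoverability of planted signal
under multinomial sampling; they do not certify performance on real tumours,
where signature collinearity (notably among flat signatures) is far more
punishing than between rejection-separated synthetic ones.

## Problem sizes in the test suite

The validation suite simulates at desk scale, chosen so each property is
measured with comfortable statistical margin: grid-search oracle comparisons
on 100 random 3-signature instances (simplex step 1e-3); recovery curves at
n ∈ {100, 300, 1000, 10000} mutations with 50 replicates; the planted
two-group delta at 30+30 samples × 5000 mutations; region-stratified
ordering over 20 seeded runs of 3 samples × 1500 mutations on 60 kb genomes;
blacklist filtering on 10 000 records at artefact rate 0.3. The full suite
and the acceptance script each run in about a minute on one CPU.

## Known limitations

* Refitting assumes the reference spans the sample's processes; signal from
  absent processes is smeared over present signatures rather than flagged
  (only the cosine drop hints at it). No de novo extraction is provided.
* No bootstrap or Bayesian uncertainty on exposures; the saturation analysis
  is the package's (orthogonal) answer to "how stable is this fit".
* Transcriptional-strand-aware (SBS-192) classification, doublet and indel
  signatures are out of scope.
* Read-level filters (e.g. first/last-read-position support) cannot be
  applied to VCF-level input and are assumed done upstream.
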