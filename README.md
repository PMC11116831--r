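# sigrefit

Comparative mutational-signature refitting for somatic variant catalogues.

Tumours accumulate somatic single-base substitutions (SBS) whose trinucleotide
contexts carry the imprint of the mutational processes that generated them.
`sigrefit` is an R toolkit for the refitting side of that analysis — deciding
how much each *known* reference signature contributes to a sample — and for
the quality-control questions that decide whether such an assignment can be
trusted at all: How well is the profile reconstructed? How many mutations does
a sample need before the fit stabilizes? Do the fitted contributions actually
separate biologically annotated groups (mismatch-repair-deficient vs
proficient, *POLE*-mutated vs wild-type)? How much does the answer change with
the reference catalogue, the fitting backend, the genomic compartment, or a
position blacklist?

It is aimed at cancer-genomics analysts who work from VCF or tabular variant
calls and COSMIC-style signature TSVs, and who need the whole path from
variants to cohort statistics to be scriptable, seeded and testable — real
catalogues are supplied by the user; a fully synthetic simulator with known
ground truth ships with the package.

## The model

For a sample with SBS-96 count vector `y` (96 trinucleotide-context channels
in canonical COSMIC order) and a reference matrix `S` (96 × K,
column-stochastic), exposures `e` are estimated by non-negative least squares

    min ‖y − S e‖₂   subject to  e ≥ 0

solved with the Lawson–Hanson active-set algorithm. Normalized contributions
`e / Σe` give the fraction of mutations attributed to each signature.
Reconstruction quality is the cosine similarity

    cos(y, S e) = y·Se / (‖y‖ ‖Se‖)

and a sample is **not assigned** when this falls below 0.9. A second, sparse
backend greedily removes signatures while the cosine degradation per removal
stays below a tolerance, emulating strict-fitting tools.

On top of the per-sample fit:

* **Group discrimination** — for a signature set *M* (e.g. the
  mismatch-repair-deficiency set) and two annotated groups, the delta
  statistic is the difference of median set contributions,
  `Δ = median_A(Σ_{k∈M} ê_k) − median_B(…)`, tested with a Wilcoxon rank-sum
  test (exact for small tie-free samples).
* **Saturation analysis** — each sample's mutation list is subsampled on a
  19-point fraction grid (5%–95%, step 5%, five replicates), each subset is
  refitted, and the minimum mutation count at which the median cosine
  sustainably clears 0.9 is reported.
* **Region stratification** — mutations are partitioned into exonic /
  intronic / extragenic compartments (precedence exonic > intronic >
  extragenic) and fitted per compartment.
* **Blacklist filtering** — recurrent artefact/germline positions (a
  "metanormal"-style list) are removed before fitting.

## Worked example

Everything below is synthetic and seeded, so it reproduces exactly.

```r
library(sigrefit)

genome <- make_genome(length = 50000, seed = 11)          # random genome + compartments
ref    <- make_reference(n_spiky = 3, n_flat = 1, seed = 12)

spec <- cohort_spec(
  groups = list(
    list(label = "MMRd-like", n_samples = 3, exposures = c(0.55, 0.25, 0.10, 0.10)),
    list(label = "MMRp-like", n_samples = 3, exposures = c(0.05, 0.45, 0.20, 0.30))),
  mutations_per_sample = 2000, seed = 13)
sim <- simulate_cohort(spec, ref, genome)

muts      <- filter_vaf(sim$mutations, min_vaf = 0.10)    # VAF >= 10%
catalogue <- build_catalogue(muts, genome)                # SBS-96 counts
fit       <- fit_signatures(catalogue, ref)               # NNLS refit
fit
#> Signature fit (nnls backend) against reference 'synthetic'
#>   samples: 6  signatures: 4
#>   cosine similarity: median 0.9984 (range 0.9970-0.9991)
#>   assigned (cosine >= 0.90): 6 / 6
```

Every sample reconstructs above the 0.9 reliability threshold, so all six are
assigned. `summary(fit)` shows the per-sample detail — the first group's top
signature is SIMS1 at contributions near the planted 0.55, the second group's
is SIMS2:

```r
summary(fit)[, c("sample", "cosine", "top_signature", "top_contribution")]
#>        sample    cosine top_signature top_contribution
#> 1 MMRdlike_01 0.9991184         SIMS1        0.5591360
#> 2 MMRdlike_02 0.9989575         SIMS1        0.5526178
#> 3 MMRdlike_03 0.9982886         SIMS1        0.5454988
#> 4 MMRplike_01 0.9970775         SIMS2        0.4213319
#> 5 MMRplike_02 0.9985264         SIMS2        0.4420952
#> 6 MMRplike_03 0.9970361         SIMS2        0.4391522
```

The delta statistic recovers the planted contribution gap between the groups
(0.55 vs 0.05 on SIMS1):

```r
delta_stat(set_contribution(fit, "SIMS1"), sim$annotation,
           "MMRd-like", "MMRp-like", set_label = "SIMS1")
#>   set_label   group_a   group_b  median_a   median_b     delta p_value code n_a n_b
#> 1     SIMS1 MMRd-like MMRp-like 0.5526178 0.05601747 0.4966004     0.1   ns   3   3
```

With three samples per group the exact two-sided rank-sum p-value cannot go
below 0.1 — the delta is real but a 3+3 cohort cannot certify it, which is
precisely the kind of readout the toolkit is meant to surface. At 30+30
samples the same construction yields p < 1e-10 (see the acceptance script).

A command-line interface over the same functions lives at
`inst/cli/sigrefit.R` (subcommands `simulate`, `matrix`, `compare`,
`saturation`, driven by a YAML config).

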