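---
title: "Quantifying host and symbiont protein in holobiont metaproteomes"
author: "holoSpC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying host and symbiont protein in holobiont metaproteomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holoSpC)
```

## The scientific problem

Animals that live in obligate nutritional symbiosis with bacteria — gutless
marine annelids are the canonical case — are analyzed as *holobionts*: host
and symbionts are extracted, digested and measured together in one shotgun
proteomics run. Two questions drive the downstream analysis this package
implements:

1. **How much of the holobiont's protein belongs to the symbionts, and does
   that share change between physiological conditions?** If starved hosts
   digest their symbionts, the symbiont share of total protein should drop
   relative to freshly collected animals, and the drop should survive a
   replicate-level significance test.
2. **Do particular host proteins carry the residues that their proposed
   function requires?** Two residue-level screens recur in this setting:
   whether peptidoglycan recognition proteins (PGRPs) retain the complete
   conserved amidase active site (loss of a single residue abolishes
   catalysis) and whether their binding groove favors DAP-type
   peptidoglycan, typical of gram-negative symbionts; and whether an
   extracellular hemoglobin chain carries a *free* cysteine at the conserved
   sulfide-binding position.

Answering the first question from spectral counts requires a chain of
post-search steps, each of which embodies a modeling decision. This vignette
documents those decisions and the package's validation strategy.

## The quantification model

### From spectra to protein groups

De novo transcriptome assemblies inflate the protein search database with
near-identical variants (isoforms, fragments, allelic and strain variants).
Quantifying each entry separately double-counts peptides, so entries are
collapsed by greedy centroid clustering at a global-alignment identity of
at least 90% (`greedyCluster()`): records are visited longest-first, each
joins the first seed it matches at or above the threshold, otherwise it
founds a new group. The seed — the group's longest member — represents the
group and provides its length `L`. Identity is the number of identically
aligned residues divided by the shorter sequence's length (so a fragment
contained in a longer protein scores 1), under BLOSUM62 with affine gap
costs of 10 (open) and 1 (extend). These alignment parameters are
conventional defaults; the threshold is the scientifically meaningful
tunable.

### Peptide uniqueness and shared-spectra balancing

After grouping, peptide uniqueness is re-assessed at the group level
(`reassessUniqueness()`): a peptide is *unique* when every database protein
containing it (exact substring; I and L are treated as distinct residues)
lies in one group, *shared* otherwise. Each shared peptide's spectral count
`S` is split among the sharing groups proportionally to their unique
evidence in the same sample: group `g` receives `S * U_g / sum(U_h)`, with
`U_g` its unique spectral count (`balanceSpectra()`). When no sharing group
has unique evidence, the count is split equally — the only symmetric choice
in the degenerate case. Balancing conserves the per-sample spectral total
exactly, which the test suite asserts to 1e-9 relative tolerance on random
sharing structures.

Two readings of "proportion of uniquely identified peptides" are defensible:
proportion of unique *spectra* (our default, `method = "spectra"`) or of
unique peptide *species* (`method = "peptides"`). Spectra weighting is the
default because spectral counts, not peptide species, are the abundance
currency of the whole pipeline; both are implemented. Balancing is performed
per sample, not on pooled counts, so that samples remain independent units
for the downstream test.

### Normalized spectral counts

Balanced counts are converted to normalized spectral counts
(`computeNSpC()`), the NSAF-derived measure: `SAF_i = SpC_i / L_i` and
`nSpC_i = SAF_i / sum_j SAF_j`, the sum running over a *normalization
universe* in the same sample. Two universes matter:

* **holobiont** (host + symbiont, contaminants excluded) — the universe on
  which host-vs-symbiont fractions are computed;
* **host** — reproduces the convention of host protein tables in which
  nSpC values are scaled so each sample's host proteins sum to 10,000.

The group length used is the seed length. The seed is the longest, most
complete member, which makes `SAF` a conservative per-residue rate; a mean
member length would be distorted by assembly fragments. On the
`"per_10000"` scale values are multiplied by 10,000. A sample with zero
total SAF over the universe has no defined normalization; the package emits
zeros with a warning rather than NaNs.

### Identification filtering

Before quantification, PSMs and groups pass the standard target-decoy
filters (`computeQvalues()`, `filterIdentifications()`): PSM q-values from
the decoy/target ratio at each score threshold (running minimum from the
worst score up; tied scores share a block value), a q-value cutoff of 0.02,
at least two spectra per protein group, and the group evidence rule of at
least two distinct peptides with at least one unique to the group. The
FDR estimator is the plain `D/T` ratio; the `(2D)/(T+D)` variant differs
only by a factor that the q-value cutoff absorbs, and `D/T` is the more
transparent choice. A protein-level FDR (decoy groups passing the same
rules / target groups passing) is reported and flagged above 3%.

One caveat is worth stating plainly: protein-level FDR is a large-database
statistic. On a synthetic database of ~50 entries, the decoy PSMs that
legitimately survive a 2% PSM-level q-value cutoff concentrate on the ~50
mirrored decoy proteins, so every decoy protein accumulates enough spectra
to "pass" and the protein FDR saturates at 1 — the report flags this on
every fixture-scale run. In a realistic search (about 1.3 million entries)
the same decoy PSMs scatter over six orders of magnitude more entries and
the protein FDR lands in the low percent range. The flag is therefore
informative at real scale and an expected artifact at fixture scale; the
filter logic itself is exercised by constructed small cases in the tests.

### Comparing conditions

The symbiont share of holobiont protein per sample is the summed symbiont
nSpC over summed host-plus-symbiont nSpC (`taxonFractions()`); the ratio is
invariant to scale and universe because the per-sample normalization factor
cancels. Conditions are compared with the classic pooled-variance Student's
t-test (`pooledTTestSummary()`, `compareConditions()`), two-tailed, which
can be computed from printed summary tables (mean, sd, n) as well as raw
replicates — the two routes agree to 1e-12 by construction and are tested
against `stats::t.test(var.equal = TRUE)`. Welch's form is available behind
a flag but is not the default: with three replicates per condition the
pooled form is the field's standard reporting choice, and it is the form
that reproduces published p-values from printed summary statistics.

## The synthetic holobiont generator

No machine-readable raw data accompany the study design this package
validates against, so validation rests on a generator
(`generateDatabase()`, `simulatePSMs()`) whose defaults *are* the study
conditions:

* two conditions, `fresh` and `starved`, with symbiont spectral fractions
  0.295 and 0.187 and three biological replicates each;
* 50,000 target spectra per sample — chosen for test power: it puts the
  binomial noise well below the replicate noise, as in a real multi-hour
  2D-LC-MS/MS acquisition where per-sample spectral totals reach tens to
  hundreds of thousands;
* multiplicative Gaussian noise (sd 0.03) on each replicate's symbiont
  fraction, clamped to [0, 1] — small enough that a 3-vs-3 t-test on a
  ~0.11 fraction difference is decisively powered, as published;
* 30 host and 20 symbiont base proteins of 150–450 residues, six of which
  receive a 95%-identity point-substituted variant — the redundancy the
  grouping step must collapse;
* per-protein abundance weights drawn log-normally (meanlog 0, sdlog 1)
  within taxon; spectra are allocated to proteins proportionally to
  weight × length. The length factor is deliberate: longer proteins yield
  more peptides and hence more spectra, which is precisely the bias NSAF
  normalization exists to remove, so the generator makes the length
  correction testable;
* each spectrum is assigned a fully-tryptic peptide (length >= 5, up to two
  missed cleavages) of its protein uniformly; target scores are N(8, 1) and
  decoy scores N(6, 1) — a two-standard-deviation separation that yields
  smooth, monotone q-values — with decoys making up 10% of the final table.

`GroundTruth` records, per sample, the perturbed and realized symbiont
*spectral* fraction and additionally the *length-corrected* symbiont
fraction implied by the drawn weights and lengths. The distinction matters:
the estimator is length-corrected, so its target is the length-corrected
truth. With finitely many proteins, the weighted mean length of the two
taxa differ by chance, so the nSpC-scale fraction sits a few points off the
spectral fraction — an offset that is a property of the simulated proteome,
not an estimator error. Recovery is therefore judged against the
nSpC-scale truth (the acceptance tolerance is two percentage points).

What the generator does **not** emulate: spectrum-level detail (m/z,
retention time, charge), peptide detectability differences (flyability),
score dependence on peptide properties, and shared peptides *between* the
two taxa (random sequences essentially never share tryptic peptides; the
sharing machinery is exercised by constructed cases instead). Passing tests
therefore demonstrate the correctness of the post-search arithmetic and the
statistical behavior of the design — not robustness to search-engine
artifacts on real spectra.

## Numerical and design choices

* **Ordering determinism.** Clustering visits records by length descending
  with ties broken by identifier in C-locale order; seeds are tried in
  creation order. Identical seeds give byte-identical outputs.
* **X residues** (from `N`-containing codons in six-frame translation,
  `extractOrfs()`) never count as identical in alignments.
* **ORF definition** is stop-to-stop, the default of classic ORF finders,
  with an optional ATG-initiated mode; the minimum length default is 40
  residues. Reverse-frame coordinates are reported on the forward strand.
* **Decoys** are whole-protein sequence reversals with the reserved id
  prefix `rev_`; palindromic sequences (decoy = target) are warned about.
* **Screen calls** are `indeterminate` exactly when an annotated position
  falls in an alignment gap — a mismatch elsewhere never rescues a call,
  and an unmapped position never counts as a mismatch. "Free cysteine"
  means cysteine at the sulfide-binding position where that position is not
  itself a conserved disulfide position; the fuller structural argument
  (hydrophobic cluster analysis of the sulfide-binding domain) is out of
  scope.
* **Annotated positions are data, not code.** The catalytically required
  amidase residues and the DAP-specificity groove residues are published in
  curated alignments; the package ships a synthetic example annotation
  bundle (`inst/extdata/synthetic_screen_*`) and reads real ones from a
  four-column TSV (`readAnnotationTable()`).

## Problem sizes used in validation

The test suite runs the full pipeline on the default fixture (56 database
entries, 6 samples x 50,000 spectra), a 100-seed re-acquisition panel for
the power of the condition contrast, a 1,000-seed null panel (via the
generator's realized-fraction fast path, which is distributionally
identical to counting taxon draws in full PSM tables) for type-I-error
calibration, 200 random instances (<= 20 sequences) against a brute-force
clustering oracle, and 200 random PSM lists (<= 50 entries) against an
exhaustive q-value oracle. These sizes were chosen so that every stochastic
assertion has comfortable margins at the configured noise levels.

## Known limitations

* Greedy centroid clustering is order-dependent by construction; it matches
  the behavior of the standard tools but is not a globally optimal
  clustering.
* Quantification is spectral-count based; intensity-based quantification
  and parsimony-style protein inference beyond the stated grouping are
  non-goals.
* The protein-level FDR report saturates on desk-scale databases (see
  above).
* Only two-condition designs are supported by `compareConditions()`; with a
  single comparison there is no multiple-testing machinery.

## A worked example

```{r example, eval = FALSE}
cfg <- generatorConfig()            # the study-design defaults
db  <- generateDatabase(cfg)
sim <- simulatePSMs(db$database, db$truth, cfg)

qm <- quantifyHolobiont(sim$psms, db$database,
                        design = as.data.frame(truthSamples(sim$truth)))
taxonFractions(qm)
compareConditions(qm, as.data.frame(truthSamples(sim$truth)))
```

The README shows this example with the numbers it prints.
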