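---
title: "Models and methods behind nomeclone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nomeclone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nomeclone)
```

This vignette is the package's own account of its models, parameter
choices and numerical decisions. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The measurement model

Clone-based NOMe-seq reads single molecules. Intact chromatin is treated
with a GpC methyltransferase that methylates only enzyme-accessible GpC
dinucleotides; bisulfite conversion then turns every *unmethylated*
cytosine into thymine while methylated cytosines are protected. Each
sequenced clone therefore encodes, along one molecule:

* at **GCH** sites (GpC not followed by G), whether the exogenous enzyme
  reached the site — *retained C = accessible, converted T =
  inaccessible*;
* at **HCG** sites (CpG not preceded by G), the endogenous CpG
  methylation state — *retained C = methylated*;
* at **GCG** sites the two signals are confounded; the package always
  calls them ambiguous and says so in every report. This is the
  standard resolution of the GpC/CpG overlap.
* remaining **CH** cytosines carry no methylation and act as
  per-molecule conversion controls: their converted fraction is the
  clone's bisulfite conversion efficiency.

The four classes partition the cytosines of the reference; that
partition is property-tested on 1,000 random sequences (a problem size
chosen to keep the default suite brisk; the property is
length-independent).

Only the top (bisulfite-converted sense) strand is modelled, both in the
simulator and in calling: clone sets from TA cloning are sequenced from
one strand, and bottom-strand GpC calling would require a separate
registry.

## Alignment and calling

Clones are registered to the *fully converted* reference (every C→T) by
global alignment with free end gaps (`Biostrings::pairwiseAlignment`,
affine gaps, opening 6 / extension 2). The substitution matrix scores
C/T pairs as matches — the degeneracy that bisulfite data demand — but
identity is then assessed asymmetrically, over the **non-degenerate
columns only** (reference bases other than C), where the clone must
match the original base. Clones are rejected when their length deviates
more than 20% from the reference or their non-degenerate identity falls
below 80%; both thresholds are arguments.

At each registry site, an aligned clone C is RETAINED, T CONVERTED, and
a gap or any other base AMBIGUOUS. Clone-level QC removes clones with
conversion efficiency below 0.95 (over CH sites) or more than 20%
ambiguous calls (over GCH+HCG sites); clone-screening criteria are
conventional rather than assay-prescribed, so both are explicit
arguments and every removal is reported with its reason. Clones with no
assessable CH site keep an undefined efficiency and are retained — on
synthetic amplicons built without CH cytosines the filter would
otherwise discard everything.

Coordinates are 0-based half-open everywhere inside the package (BED
order); display labels use signed distance to the anchor ("−9.9 kb"
style) via the reference's `genomic_offset`.

## Accessibility statistics

Per GCH site the percentage of inaccessibility is
`100 · n_inaccessible / (n_inaccessible + n_accessible)`. "Total
molecules" is read as *molecules with a determinate call at that site*:
ambiguous molecules leave the denominator, and a site where every
molecule is ambiguous is flagged undefined rather than silently
reported as 0%.

The windowed profile averages per-site percentages over fixed 100-bp
windows tiling the amplicon — an unweighted mean over sites, the
simplest reading of averaging "over a distance of 100 bp"; windows with
no defined site are flagged empty, never interpolated.

For condition comparisons one GCH site per 100-bp stride is selected.
Whether a fixed site or a pooled window is intended is genuinely open;
the package takes the site **nearest the window center** (ties to the
smaller coordinate) as a defensible, documented choice, and the full
site list can be supplied instead.

Each selected site is tested on the 2×2 table of condition ×
(accessible, inaccessible):

* **Chi-square** (df = 1), continuity correction off by default — the
  assay's convention does not state the variant, and the uncorrected
  statistic matches the textbook Pearson formula that the test suite
  verifies by exhaustive sweep over all tables with margins ≤ 20.
* **Exact option**: a conditional exact test, *mid-p* by default. At
  clone depth (≈15 molecules per arm) the plain conditional test is
  severely conservative: enumerating the binomial-margin null gives a
  true size near 0.017 at nominal α = 0.05, while the mid-p variant —
  which counts outcomes exactly as probable as the observed table at
  half weight — restores ≈ 0.04. This choice was made from that
  enumeration, before any simulation was run; `midp = FALSE` gives the
  plain test. The acceptance script measures the mid-p size under a
  simulated null (accessibility 0.5 in both arms, 15 clones per arm,
  1,000 replicates).
* P-values are reported per site without multiple-testing adjustment by
  default, matching per-site reporting conventions; Benjamini–Hochberg
  or any `p.adjust` method is available via `p_adjust`.

A zero margin (e.g. both arms fully accessible) makes either statistic
undefined; such sites are flagged, not zero-filled.

## Footprints and open runs

Per molecule, maximal runs of consecutive inaccessible GCH sites are
footprints. Ambiguous sites **bridge** a run but never extend its ends;
the span is measured between the outermost inaccessible sites,
inclusive (`end − start + 1`). No extrapolation toward the midpoints of
the flanking accessible sites is attempted — the conservative choice;
with extrapolation a footprint could only grow, so the reported span is
a lower bound. Runs spanning ≥ 150 bp (the size needed to accommodate a
nucleosome) are classed `NUCLEOSOME_SIZED`. Note the geometric
consequence, which the acceptance script exercises: a 147-bp occupancy
on a 10-bp GpC grid places at most 141 bp between its outermost covered
sites, so true mono-nucleosomes sit just below the 150-bp class while
their boundaries are still recovered to within one GpC spacing.

Accessible runs are called by the same machinery with polarity
reversed (`NDR_SIZED` at ≥ 147 bp, one nucleosome); on matrices without
ambiguous calls the two are exact duals, which is property-tested.

Run-length rules are the whole story by design: no HMM or changepoint
segmentation is attempted, keeping the calls auditable molecule by
molecule.

## Endogenous methylation and CpG-rich regions

Methylation maps reuse the identical alignment/calling path restricted
to HCG sites — NOMe-seq and genomic-bisulfite inputs differ only in
which site classes are interpreted. Per-site percent methylation uses
determinate calls only; profile comparison reports per-site differences
with no attached test by default (none is standard for lollipop-style
contrasts), flagging sites that lack determinate calls on either side.

The CpG-rich scan follows the classic island-searcher definition:
200-bp windows at step 1 must reach 55% GC and observed/expected CpG
`(n_CpG · L)/(n_C · n_G)` ≥ 0.65; overlapping passing windows merge;
each merged region is **trimmed to begin and end at a CpG
dinucleotide** and then re-checked against all three thresholds
including the 500-bp minimum length. The trimming step matters: step-1
windows that straddle an island's edge can pass while mostly covering
flank, so without trimming region boundaries would overhang the true
island by up to a window width. Regions containing no CpG at all are
left untrimmed, so degenerate thresholds (0, 0, 1) return the whole
sequence. A window with no C or no G has observed/expected defined as
0. All thresholds are arguments (and CLI flags); the scan is verified
against a brute-force per-substring checker on random sequences up to
2 kb.

## qPCR quantification

Percent of input is the dilution-adjusted ΔCt,
`100 · input_fraction · E^(Ct_input − Ct_IP)`, with the amplification
factor `E` fixed at 2.0 by default — no standard curves are modelled —
and configurable per call. FAIRE signals use the same arithmetic with
the aqueous-phase DNA as numerator. Fold enrichment (target vs control
region) and induction (treatment vs vehicle) are plain ratios;
replicate summaries are **mean and range** (not SD), matching
duplicate-PCR reporting, and ranges propagate through ratios by min/max
arithmetic. Relative expression is ΔΔCt against a reference transcript.
Input dilution fractions are required metadata on every record — they
cannot be inferred from Ct values.

The Ct simulator writes `Ct = baseline − log2(quantity) + N(0, σ)`, so
at σ = 0 every quantification inverts it exactly; the suite checks the
closed forms, monotonicity in simulated openness, and — because a fold
estimate combines four replicate-mean Cts, making its log2 error
N(0, σ) at σ = 0.2 with 4 replicates — that recovered folds are
median-unbiased with ≈95% inside the corresponding 1.96σ factor.

## The synthetic-data generator

The generator is first-class, tested code, and defines the conditions
under which the pipeline's guarantees are demonstrated:

* **References** place GpC sites on a regular grid (spacing ≥ 3 bp so
  the following base stays A/T) and CpG sites inside requested blocks
  on a 3-bp grid; all filler is drawn from {A, T} so no accidental
  contexts arise. Spacing, block positions and densities are arguments.
* **Chromatin states** form a weighted mixture; each state has
  protected intervals plus linker and occluded (leakage) accessibility
  probabilities. A mixture of with- and without-NDR states reproduces
  the situation where an NDR exists in only some cells.
* **Noise** collapses the two-step enzyme incubation into a single
  per-site efficiency; clone sampling, enzyme action, conversion
  (unmethylated C→T; methylated C→T at the inappropriate rate) and
  per-base substitution error are independent Bernoulli events. The
  defaults (efficiency 0.95, conversion 0.995, inappropriate 0.005,
  error 0.001) are values a practitioner would call realistic for a
  saturating enzyme treatment, near-complete conversion and Sanger
  reads; the achieved rates of any given experiment are unknown, which
  is exactly why they are free parameters rather than constants.
* **Clone depth** defaults to 15, the customary minimum number of
  sequenced positive clones per amplicon and experiment.
* **Ground truth** (state label, protection, accessibility and
  methylation flags per clone and site) is emitted as a sidecar table
  keyed by clone id, so tests compare against it directly instead of
  re-inferring it from sequence.

What the generator does **not** emulate — and hence what passing tests
cannot certify about real data: Sanger chromatogram quality and
basecalling error structure, cloning-vector sequence and PCR duplicates,
strand-specific conversion artefacts, heterogeneous enzyme kinetics
along the molecule, and linked (non-independent) protection between
neighbouring sites beyond what the protected intervals impose.

Guarantee-bearing simulations use fixed problem sizes chosen as
adequate for their statistics: zero-noise round trips at 15–25 clones;
accessibility recovery at 200 clones per arm (linker accessibility 0.8
vs 0.2, perfect noise so the target probabilities are exact — the
recovery statement concerns the calling chain, not noise estimation);
the generator's own law of large numbers at 2,000 clones; the null
calibration at 1,000 replicates of 15 + 15 clones.

## Determinism and the CLI

Every generator takes a seed and runs under a local RNG state, restoring
the caller's stream; identical seeds give byte-identical FASTA/TSV/BED
outputs, which the suite verifies across two full shell-pipeline runs.
Bubble charts and lollipop maps are written as hand-emitted SVG —
deterministic text — in the conventional encoding (filled circles
accessible/methylated, open circles inaccessible/unmethylated, pink
bars per-molecule nucleosome-sized footprints; bars are drawn per
molecule, not as a consensus track). Each CLI stage writes a JSON
manifest (inputs, parameters, seed, package version, output checksums)
sufficient to re-run it, removes partial outputs on failure, and
rejects unknown flags.

## Known limitations

* Amplicon/clone scale only: no genome-wide NOMe-seq or methylome
  support, no paired-end short reads, no bottom-strand calling.
* GCG sites are discarded rather than modelled; amplicons rich in GCG
  lose reporters.
* The exact test conditions on margins; its mid-p size is near nominal
  on average but not guaranteed per-table.
* Footprint spans are lower bounds (outermost-site rule); users wanting
  midpoint extrapolation must compute it from the flanking site
  coordinates.
* Ct values are taken as given — no amplification-curve processing, and
  efficiency corrections are per-call constants, not calibrated curves.
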