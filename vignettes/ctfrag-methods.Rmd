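---
title: "Allele-specific cfDNA fragment-length analysis with ctfrag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-specific cfDNA fragment-length analysis with ctfrag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctfrag)
```

## The problem

Cell-free DNA (cfDNA) in plasma is mostly nucleosome-protected fragments with
a modal length near 167–168 bp. The tumor-derived subset (ctDNA) often has a
different length distribution than the wild-type background — typically
shorter, but in samples with very low mutant allele frequency (MAF) the
mutant fragments can instead be *longer*. Because the allele of each
sequenced fragment at a hotspot SNV is observable, the mutant and wild-type
length distributions can be profiled separately within one sample, and a
fragment-size selection (physical gel band or in-silico gate) changes the
measured MAF in a predictable direction.

`ctfrag` implements that analysis end to end for deep targeted sequencing of
a hotspot SNV panel:

1. **Extraction** — from aligned paired-end reads, collect every DNA template
   whose aligned span covers a hotspot and recover its fragment length from
   the template-length field (`|TLEN|`, SAM column 9).
2. **Typing** — read the base aligned to the variant position on each
   covering mate by a CIGAR-aware walk and label the fragment `mutant`,
   `wild`, or `unresolved`.
3. **Profiling** — per-allele length histograms with modal peak(s) and
   medians; NGS MAF `n_mut / (n_mut + n_wt)`; a frequency stratum; and a
   `Short/Long/Normal/Other` description of the mutant population.
4. **Size selection** — apply length gates (default `[130,160)` and
   `[160,230]` bp) and report per-gate MAF and enrichment.
5. **ddPCR quantification** — invert the Poisson occupancy model on droplet
   counts to estimate per-channel template rates and the MAF.

A seeded simulator generates aligned SAM + reference FASTA for arbitrary
per-allele length models, so the whole pipeline is testable without plasma
data.

## Fragment extraction and allele typing

A fragment is observed through two primary alignment records (one per mate).
Records are filtered before anything else: secondary and supplementary
alignments, unmapped reads or mates, `TLEN = 0` records, mapping quality
below `min_mapq` (default 20), and — by default — pairs not flagged proper.
Surviving records are deduplicated by template name; the record with positive
TLEN is canonical. The fragment length is defined as `|TLEN|`, the
outermost-coordinate span of the pair; mates that overlap each other (fragment
shorter than twice the read length) are unproblematic because TLEN is still
the template span.

The base aligned to the hotspot is located by walking the CIGAR from the
record's leftmost position: `M/=/X` consume query and reference, `I/S` query
only, `D/N` reference only. The typing rule is conservative: a fragment is
`mutant` only if **all** covering mates read the alternate base, `wild` only
if all read the reference base; disagreement between mates, a third base, a
deletion spanning the position, ambiguous pairing (more than two primary
records per name), or no usable call all yield `unresolved`. Unresolved
fragments are counted and reported but excluded from MAF and from the
per-allele profiles. Base quality is ignored by default (`min_base_quality =
0`); a threshold can be set, in which case a low-quality call becomes no
call.

The defaults `min_mapq = 20` and `require_proper_pair = TRUE` are pragmatic
conventions for hybrid-capture data; no published thresholds exist for this
procedure, so both are exposed.

## Length profiles, peaks and classification

`length_profile()` keeps the raw integer histogram. The median uses the usual
order-statistic convention (mean of the two central values for even counts,
so half-integer medians such as 169.5 occur). Peaks are **all** local maxima
of the raw histogram whose count is at least `peak_fraction` (default 0.8)
times the tallest bin, in ascending length order. This multi-peak rule exists
because real mutant profiles can be bimodal (e.g. peaks at 158 and 191 bp in
a low-MAF sample); a single-argmax rule would hide that structure. No
smoothing is applied by default — at hotspot-level depths of a few thousand
fragments the raw histogram is stable — but a moving-average window
(`smooth_window`, odd, bp) is available for ragged profiles.

`classify_sample()` compares the mutant median against the wild median:
differences of at least `delta` (default 3 bp) are `Short`/`Long`; within
`delta`, a unimodal mutant profile is `Normal` and a multimodal profile whose
modes straddle the wild median is `Other`. Fewer than `min_support` (default
5) mutant fragments is `Insufficient`. This rule is a reconstruction: the
descriptive labels it mirrors were applied to patient samples without a
stated algorithm, and at least one published labelling (a "Long" call at a
+0.5 bp median difference) is not reproducible by any pure median rule. The
3 bp default separates clearly shifted profiles from sampling noise at
typical depths; it is deliberately exposed rather than hard-coded.

Frequency strata are `below_lod` (< 0.1%), `low` (0.1–1%), `medium` (1–10%),
`high` (10–100%). The printed bounds overlap, so the implementation fixes
them as half-open below and closed at 1: the boundary values 0.001, 0.01 and
0.10 map upward.

## In-silico size selection

The default gates `[130,160)` and `[160,230]` mirror gel bands cut at 130–160
and 160–230 bp. Two physical bands share the 160 bp boundary; since one
fragment cannot end up in two gel slices, the gates are made to partition by
the lower-closed/upper-open convention, with the terminal gate closed above.
Per gate, `gate_report()` recomputes the MAF on gated counts and reports
`enrichment = maf_gated / maf_ungated` (undefined — `NA`, never 0 — when a
gate captures no typed fragment or the ungated MAF is 0). When the mutant
length distribution stochastically dominates the wild one, the expected MAF
in any upper-tail gate is at least the ungated MAF; the test suite verifies
this by exhaustive enumeration over randomized discrete distributions, and
verifies both enrichment directions through the full simulate → SAM →
extract → gate path.

## ddPCR quantification

With templates Poisson-distributed over droplets, the fraction of negative
droplets on a channel estimates `exp(-lambda)`, so
`lambda = -ln(1 - n_pos/n_total)` is the mean template count per droplet and
`conc = lambda / droplet_volume` (1 nL droplets by default) the
concentration. The MAF is `lambda_mut / (lambda_mut + lambda_wt)`, invariant
to droplet volume. The two channels are treated as independent single-plex
counts — duplex probe competition within a droplet is not modeled, as there
is no data to parameterize it. A fully positive channel is *saturated*
(`lambda` infinite) and is an error, not a clamp: quantification from a
saturated channel would be arbitrary, and table-level drivers record the
error per row and continue.

## What the simulator emulates — and what it does not

`simulate_fragments()` + `fragments_to_sam()` emulate the observable
structure of a deep targeted library at one locus: 151 bp paired-end reads,
fragments placed uniformly over the positions that span the hotspot,
per-allele lengths from configurable models, deterministic
(`round(maf * n)`) or binomial allele assignment, and SAM output whose TLEN
carries each fragment length exactly, with the allele base planted in every
covering mate and MD/NM tags consistent. The default wild-type model is
`frag_normal(168, 10)` — a discretized normal at the mononucleosomal mode;
the mutant model family is left to configuration because only peaks and
medians of real mutant profiles are reported in the literature this emulates,
not a distribution family. Droplet simulation draws per-droplet template
counts Poisson per channel.

Not emulated: PCR duplicates and UMIs, capture bias along the fragment-length
axis, base-quality structure (an optional uniform per-base substitution error
exists, default 0), indels, multi-locus haplotypes, and alignment artifacts —
the simulator writes already-aligned records, so aligner behavior is out of
scope. Passing end-to-end tests therefore demonstrates bookkeeping fidelity
(lengths, counts, MAF, gating arithmetic) and correct typing on clean
alignments, not robustness to real-library noise.

Auto-fabricated references are refused for hotspot positions beyond 2 Mb: a
seeded random chromosome of genomic size would be pointless, so fixture
panels use small coordinates and real panels should supply a FASTA.

## Numerical and design choices

* Hotspot coordinates are 1-based (variant-file convention) everywhere a user
  sees them; fragment starts in the truth table are 0-based. Conversion
  happens only at I/O boundaries.
* Only SNV hotspots are supported; MNVs and indels are rejected at panel
  construction.
* `round()` in deterministic assignment uses R's banker's rounding; at the
  sample sizes used in tests (e.g. 0.7475 × 10000 = 7475) this is exact.
* Degenerate inputs are errors with stable messages: empty panel, empty
  fragment set ("no fragments"), zero typed fragments ("no typed
  fragments"), saturated ddPCR channel, both channels empty ("no template
  detected").
* Every generator takes an explicit integer seed and is a pure function of
  its arguments; commands record the seed and a config checksum in a
  provenance header on every output file.

Test problem sizes are chosen to keep the full suite fast while leaving no
statistical ambiguity: exact checks use point-mass length models (any
mismatch is a hard failure at n as small as a few hundred), stochastic checks
use 10^4–10^6 droplets or 1000–10000 fragments with 3–4 standard-error
margins under fixed seeds.

## A worked example

```{r}
hs <- hotspot_panel("EGFR-T790M", "EGFR", "sim1", pos = 600, ref = "C", alt = "T")
frags <- simulate_fragments(hs, true_maf = 0.05, n_templates = 4000,
                            wild_model = frag_normal(168, 10),
                            mutant_model = frag_normal(200, 12), seed = 31)
sam <- tempfile(fileext = ".sam")
fragments_to_sam(frags, hs, sam_path = sam, seed = 31)

ext <- extract_pairs_at_hotspot(sam, hs)
typed <- type_fragments(ext$observations, hs)
summarize_locus(typed, hs)
gate_report(typed, size_gates("130-160,160-230"))
```

With mutant fragments centered at 200 bp against a 168 bp wild background,
the upper gate enriches the MAF and the lower gate depletes it — the
in-silico counterpart of extracting the longer gel band to improve detection
of a low-frequency mutation.

## Known limitations

* Fragment length comes from TLEN alone; chimeric or split alignments are
  excluded rather than resolved.
* The Short/Long/Normal/Other rule is a reconstruction (above); borderline
  samples near `delta` should be inspected, not trusted to the label.
* The ddPCR model ignores droplet volume variation and fluorescence
  thresholding ("rain"); counts are taken as given.
* `unresolved` fragments dilute nothing in MAF but are not an error model:
  with real data, systematic unresolved calls (e.g. strand damage) would
  bias per-allele profiles and should be examined via the filter tallies in
  the run log.
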