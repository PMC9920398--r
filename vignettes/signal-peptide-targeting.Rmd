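---
title: "Profiling dual-targeting signal peptides and quantifying organelle targeting efficiency"
author: "sptarget"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling dual-targeting signal peptides and quantifying organelle targeting efficiency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sptarget)
```

## The problem

Bacterial signal peptides carry a tripartite structure — a basic n-region,
a hydrophobic h-region, and a polar c-region ending in an AxA
signal-peptidase site. When such a peptide is expressed in plant cells it
can be read by a different targeting machinery than the one it evolved
for: the PmoB signal peptide of the methanotroph *Methylosinus
trichosporium* OB3b, which directs its protein to the inner membrane in
bacteria, sends a GFP reporter to plant **mitochondria**, with a faint ER
component. `sptarget` packages the desk analyses behind that observation:
sequence-level profiling of the determinants (amphipathicity, charge,
targeting motifs), programmatic construction of the mutant panel used to
dissect them, and the image-based targeting-efficiency statistic used to
compare constructs — exercised on synthetic confocal-like fields with
known ground truth.

## Sequence profiling

The bundled 117-nt coding sequence translates (standard genetic code) to
the 39-residue peptide

```{r}
sp <- pmob_signal_peptide()
sp
```

Region boundaries are **inputs**, not predictions. The defaults (n = 1–14,
h = 15–33, c = 34–39) are anchored on sequence features: the VGKLL motif
opens the h-region, the two n-region glutamates are E5/E9, and the AxA
site (A37-E38-A39) closes the c-region. Any boundaries can be supplied via
`region_boundaries()`.

### Amphipathicity

The Eisenberg hydrophobic moment of a window of N residues is

$$\mu_H = \frac{1}{N}\left\|\sum_{n=0}^{N-1} H_n\,
(\cos\delta n, \sin\delta n)\right\|, \qquad \delta = 100^\circ,$$

with $H_n$ from the Fauchère–Pliska octanol/water scale — the scale used
by HeliQuest, which produced the published per-window values; the
Kyte–Doolittle scale is bundled for comparison but plays no part in the
reference numbers. An 11-residue window matches the length of the first
predicted N-terminal helix:

```{r}
prof <- sliding_profile(sp$sequence, window_size = 11)
head(prof, 3)
hydrophobic_moment("MKALERMAELA")
```

The N-terminal window scores $\mu_H \approx 0.52$, a strongly amphipathic
helix; published HeliQuest output prints 0.517, and the package accepts a
±0.01 band to absorb third-decimal differences between published variants
of the scale. The moment profile peaks at the very N-terminus, while mean
hydrophobicity rises toward the h-region. `helical_wheel()` projects the
helix axially (residue $p$ at $(p-1)\cdot100^\circ$); for the N-terminal
11-mer every charged/polar residue falls in the half-plane opposite the
moment vector.

### Charge

`net_charge()` counts side-chain formal charges only (K, R = +1; D, E =
−1; H neutral) and adds +1 for the free α-amino group when the span starts
at residue 1 (on by default). Under this convention the n-region scores
+2, matching the published figure: one net side-chain charge
(K2 + R6 + R14 − E5 − E9) plus the terminal amine. Whether the published
+2 included the terminus is not stated anywhere we could check; the
convention is explicit and switchable precisely because of that ambiguity.

### Motifs

Three consensus scanners, all reporting every (possibly overlapping)
1-based window match:

* `scan_tom20()` — the mitochondrial import receptor motif ϕxβϕϕ
  (ϕ hydrophobic, x any, β basic). The ϕ class {A,I,L,M,F,V,W,Y}
  deliberately includes alanine and tyrosine: the canonical instances in
  this peptide, LERMA and VGKLL, end in A and require M. On the native
  peptide the scan returns exactly those two matches, at 4 and 15.
* `scan_tat()` — the bacterial twin-arginine consensus S/T-R-R-x-F-L-K
  with polar x; the default x set {S,T,N,Q,Y,C,G} excludes charged
  residues because the consensus only says "polar". The PmoB peptide has
  no match.
* `find_cleavage_axa()` — A-x-A triplets near the C-terminus; the triplet
  ending at the last residue (AEA at 37–39) is flagged canonical.

These are pattern scanners only; probabilistic presequence scores and
secondary-structure predictions from external trained models are out of
scope by design.

## The mutant panel

`build_panel()` constructs the standard panel against the native
coordinate frame (substitutions validated against the native residue,
then deletions): spS (M7S, kills LERMA), spΔH (h-region deleted), spH
(S→I in the h-region), spR (E38R, arginine at −2), spA (E5A + E9A),
spΔ1–4 (serial deletions tiling the h-region), spΔN (n-region deleted),
spΔN2 (first half of the n-region), spjustH (h-region alone). In code the
deletion constructs carry ASCII names: `spDH`, `spD1`–`spD4`, `spDN`,
`spDN2`.

Where the published alignments are not machine-readable the defaults are
inferred and configurable: spH mutates **both** h-region serines (S22,
S33) because the text says only "serine to isoleucine in the h-region";
spΔ1–4 tile 15–33 in four near-equal spans; spΔN2 removes residues 1–7.
`panel_report()` recomputes every feature (length, net charge, Tom20
count, maximal windowed µH, h-region mean hydrophobicity) from each
mutant's own sequence — nothing is inherited from the native row, which
is what makes the report a regression check on the whole sequence stack.

```{r}
panel <- build_panel(pmob_signal_peptide())
panel_report(panel)[1:4, c("name", "length", "net_charge", "tom20_matches")]
```

## Synthetic confocal fields

`generate_field()` emulates the statistical structure the quantification
assumes, not optics: a smooth star-shaped cell region; mitochondria as
compact discs (radius ~4 px, SD 0.8) with a Gaussian point-spread edge;
a faint reticulate ER mesh (persistent random walks) in the reporter
channel only; uniform cytosol; optional Poisson shot noise plus Gaussian
read noise; 8-bit quantisation. The stain channel carries the puncta
only, mirroring a rhodamine-type mitochondrial dye; cross-talk is not
modelled. A seed fully determines the output, and ground-truth masks are
returned alongside the channels.

Numerical choices worth knowing:

* **PSF edge.** The punctum profile is a disc convolved with a Gaussian
  of σ = 0.5 px. At ~130 nm/px sampling of a 1024×1024 field this matches
  a diffraction-limited FWHM of roughly 140–190 nm. `psf_sigma = 0` gives
  hard-edged discs — the noiseless-construction limit in which
  segmentation recovers the constructed contrast exactly.
* **Experiment structure.** `generate_experiment()` reproduces the
  two-construct design: 60 cells per group in 3 batches by default, a
  log-normal per-batch brightness factor (SD 0.08) shared by all channels
  — emulating plant-to-plant variation without claiming a literature
  noise model — and per-cell mitochondrion counts drawn Poisson around
  the spec value, because real cells differ in mitochondrial content.
* **What it does not emulate.** No optics (PSF beyond the punctum edge),
  no 3-D stacks, no photobleaching, no cross-talk, no spatial
  autocorrelation in the noise. Passing tests show the *measurement
  pipeline* behaves; they say nothing about segmentation robustness on
  real tissue.

## The targeting-efficiency statistic

Per cell, `measure_cell()` computes the mean reporter intensity over the
cell mask, applies **Yen's maximum-correlation threshold** to the
within-mask histogram (candidates 0–254 on the 256-bin histogram, empty
classes skipped, ties to the lowest level, foreground strictly above),
and reports the segmented-pixel mean over the cell mean
(`intensity_ratio`, ≥ 1 whenever anything is segmented) and the segmented
area fraction. No background subtraction is performed — whether the
published ratios used one is unstated, so the assumption is surfaced
rather than hidden. Thresholding within the mask (rather than the whole
image) is the generalisable contract for multi-cell fields.

Two groups are compared with a two-sided Mann–Whitney U test
(`mann_whitney()`): midrank U, exact p by enumeration of rank assignments
when $n_1+n_2 \le 12$ without ties, otherwise a tie-corrected normal
approximation with continuity correction. The continuity correction is
what keeps the approximation within 0.031 of exact everywhere in the
small-sample regime (worst case over all possible U with
$n_1, n_2 \ge 3$, established by exhaustive enumeration — a uniform 0.01
agreement is not achievable at these sizes). Only one comparison is made
per experiment, so no multiplicity correction applies.

## Simulation studies

The published per-cell ratios (3.5 ± 0.8 vs 6.5 ± 2.4) came from
microscopy data that is not available, so they are not reproduction
targets. What the package validates instead, via `null_calibration()` and
`power_calibration()`, is the behaviour of the statistic under known
truth:

* **Null calibration** — two groups from the *same* field spec, 15 cells
  per group, 200 replicate experiments: the intensity-ratio test rejects
  at 0.05 in ≈5% of runs.
* **Power and specificity** — punctum peak 90 vs 200 (the ~2× contrast
  of the published comparison), 30 cells per group, 100 replicates: the
  intensity ratio is detected at p < 0.01 in ≥95% of runs while the area
  fraction stays non-significant (median p > 0.1), reproducing the
  significant-ratio / non-significant-area pattern that distinguishes
  brighter mitochondria from more or larger mitochondria.

The simulation fields are 160 px with ~10 puncta: per-cell ratios depend
on contrasts and relative areas, not absolute field size, and the smaller
fields keep hundreds of replicate experiments cheap. These sizes, like
every generator default, were fixed once as the study conditions.

## Known limitations

* Yen's threshold hugs the background mode: with a PSF edge it admits
  part of the punctum skirt, so the segmented-pixel mean underestimates
  the disc-mask mean by 15–20% at realistic radii. Ratios are therefore
  comparable *between* groups measured the same way, not absolute
  contrast estimates.
* On near-unimodal histograms (no real foreground) Yen is unstable at
  small pixel counts; a few thousand pixels are needed before its
  behaviour settles.
* Region boundaries and several mutant spans are figure-inferred
  defaults, flagged as configurable rather than claimed as ground truth.
* The exact Mann–Whitney path enumerates rank assignments and is meant
  for the small-sample regime only; larger samples take the normal
  approximation, as in standard practice.
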