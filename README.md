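# sptarget

Tools for dissecting the dual mitochondrial/ER targeting determinants of
bacterial signal peptides expressed in plant cells, built around the PmoB
signal peptide of *Methylosinus trichosporium* OB3b (GenBank U31650.2).
The package is aimed at molecular cell biologists who want the desk half
of such a study to be scripted and testable: tripartite (n/h/c) sequence
profiling, construction of the standard mutant panel, and the
image-based targeting-efficiency statistic used to compare constructs —
validated on synthetic two-channel confocal-like fields with known ground
truth.

## What it computes

**Amphipathicity.** The Eisenberg hydrophobic moment of an N-residue
window at the ideal α-helical period,

```
μH = (1/N) ‖ Σₙ Hₙ (cos 100°n, sin 100°n) ‖,   n = 0 … N−1,
```

with per-residue hydrophobicities `Hₙ` from the Fauchère–Pliska
(HeliQuest) scale, plus per-window mean hydrophobicity and helical-wheel
projections.

**Motifs.** Scanners for the Tom20 mitochondrial-import consensus ϕxβϕϕ
(ϕ hydrophobic, x any, β basic), the bacterial twin-arginine TAT
consensus S/T-R-R-x-F-L-K, and the AxA signal-peptidase cleavage site.

**Mutant panel.** Named substitution/deletion edit lists applied in the
native coordinate frame (spS, spΔH, spH, spR, spA, spΔ1–4, spΔN, spΔN2,
spjustH), with a per-mutant feature report recomputed from each mutant
sequence.

**Targeting efficiency.** Per cell: mean reporter intensity over the cell
mask, Yen maximum-correlation threshold of the within-mask histogram,
mean intensity of the segmented (mitochondrial) pixels over the cell
mean (`intensity_ratio`), and segmented area fraction; groups are
compared with a two-sided Mann–Whitney U test (exact by enumeration for
n₁+n₂ ≤ 12 without ties, tie- and continuity-corrected normal
approximation otherwise).

**Synthetic fields.** A seeded generator for 8-bit two-channel
confocal-like images — cell region, mitochondrial puncta with a Gaussian
PSF edge, faint reticulate ER, diffuse cytosol, Poisson/Gaussian noise —
with ground-truth masks, used to calibrate the statistic (null rejection
rate, power under a 2× contrast offset).

## Worked example

```r
library(sptarget)

sp <- pmob_signal_peptide()
sp
#> <signal_peptide> PmoB_sp (39 aa), cleavage after 39
#>   n: MKALERMAELATGR
#>   h: VGKLLGLSVAAAVAATAAS
#>   c: VAPAEA

head(sliding_profile(sp$sequence, window_size = 11), 3)
#>   start end window_sequence    mean_H       muH
#> 1     1  11     MKALERMAELA 0.3190909 0.5202688
#> 2     2  12     KALERMAELAT 0.2309091 0.5174067
#> 3     3  13     ALERMAELATG 0.3209091 0.4328880

scan_tom20(sp$sequence)
#>                 motif_name start matched
#> 1 tom20_phi_x_beta_phi_phi     4   LERMA
#> 2 tom20_phi_x_beta_phi_phi    15   VGKLL

net_charge(sp$sequence, c(1, 14))
#> [1] 2
```

The N-terminal 11-mer is a strongly amphipathic helix (μH ≈ 0.52; the
HeliQuest-published value is 0.517), the peptide carries exactly two
Tom20-type motifs — LERMA in the n-region helix and VGKLL at the start of
the h-region — and the n-region nets +2 (side chains plus the free
N-terminal amine). A two-group synthetic imaging comparison:

```r
ex <- generate_experiment(calibration_field_spec(90),
                          calibration_field_spec(200),
                          cells_per_group = 10, batches = 3, seed = 42)
cells <- measure_experiment(ex)
compare_groups(cells[cells$group == "A", ], cells[cells$group == "B", ],
               "intensity_ratio")
#> Two-group comparison of intensity_ratio
#>   group A: 3.8919 +/- 0.2247 (n = 10)
#>   group B: 5.7322 +/- 0.5570 (n = 10)
#>   Mann-Whitney U = 0.0, two-sided p = 0.0001827
```

Group B's brighter mitochondria roughly double the per-cell
mitochondrial/total intensity ratio, which the rank test detects; the
segmented *area* fraction stays non-significant under the same contrast
change (see `power_calibration()`), distinguishing brighter mitochondria
from more or larger ones.

The full orchestrated workflows are `run_sequence_analysis()` (profile,
wheel, motif scans, mutant panel, CSV/JSON/FASTA reports) and
`run_imaging_experiment()` (simulate → measure → compare, with per-cell
CSV and comparison JSON). The methods vignette
(`vignettes/signal-peptide-targeting.Rmd`) documents the model,
parameter conventions and known limitations.

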