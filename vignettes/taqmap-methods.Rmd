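---
title: "Mapping causal genes from endonuclease-induced rearrangements: models and methods"
author: "taqmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping causal genes from endonuclease-induced rearrangements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taqmap)
```

## The experimental design this package models

Transient activation of a restriction endonuclease (TaqI, recognizing the
palindromic four-base site TCGA) in a living hybrid diploid yeast induces
double-strand breaks genome-wide. Repair of those breaks produces large-scale
rearrangements: break-induced repair (BIR) copies the homologous chromosome
from a breakpoint to the chromosome end, short gene conversions (sGC) copy an
interstitial tract, mis-segregation gains or loses whole chromosomes, and
end-joining creates translocations, interstitial deletions or circular
chromosomes. In a hybrid of two divergent parents (~0.7% SNV divergence), BIR
and sGC convert heterozygous markers to one parent's alleles — loss of
heterozygosity (LOH) — which short-read sequencing reads out through
allele-specific depth. Selecting mutants for a phenotype (here: loss of
flocculation, screened by sampling the planktonic fraction of a settling
culture) and aggregating LOH across the selected cohort localizes the causal
loci: windows where many independent mutants are homozygous are candidate
regions, and whole-chromosome losses concentrate on the homolog carrying the
dominant causal allele.

`taqmap` implements this workflow end to end on simulated data with known
truth: a forward simulator (`build_hybrid_genome()`, `plant_events()`,
`simulate_taq_cohort()`, `simulate_evidence()`), a rearrangement caller
(`call_events()` and its parts), a cohort-level hotspot mapper
(`window_homozygosity()`, `aggregate_cohort()`, `test_hotspots()`,
`candidate_genes()`, `aneuploidy_frequency()`), the small-variant filter
chain and coding-consequence annotation used for a spontaneous-mutagenesis
arm (`apply_filter_chain()`, `annotate_consequence()`,
`simulate_serial_passage()`), and the phenotype statistics
(`flocculation_score()`, `welch_t()`, `relative_expression()`).

## The synthetic world

The default genome (`pipeline_config()`) is a desk-scale stand-in for the
12-Mb yeast genome: twelve chromosomes of 0.12–0.42 Mb (3.6 Mb total), with
SNV markers placed uniformly at density 0.007 — the divergence of an
SK1-background × S288C-background fusion. Real chromosome sizes are supported
through `chrom_lengths`. All double-strand-break-derived breakpoints snap to
the nearest TCGA site of the parent-A haplotype.

The phenotype follows a three-locus architecture
(`default_phenotype_model()`):

* a **structural adhesin locus** (`FLO1`-like) in the subtelomeric region of
  the smallest chromosome, whose tandem-repeat length sets adhesion: parent A
  carries 10 repeat units, parent B 18, and longer arrays flocculate more;
* a **transcriptional activator** (`FLO8`-like) strictly required for
  adhesin expression, functional only in parent A (the parent-B allele
  carries a natural nonsense polymorphism);
* a **repressor** (`SFL1`-like) functional only in parent B, whose
  functional dosage attenuates expression.

The score is $f(r_{\max}) \cdot \mathbb{1}[\text{activator present}] \cdot
\rho^{d}$ with $f$ linear between 8 and 18 repeat units (clamped to $[0,1]$),
$\rho = 0.4$ per functional repressor copy, and $d$ the repressor dosage
counted over homolog copies. The ancestral hybrid therefore scores
$1 \times 1 \times 0.4 = 0.4$. Only the directions of these effects are
empirically established (longer repeats flocculate more; activator loss
abolishes; repressor homozygosity reduces); the coefficients are package
defaults, chosen once so that every single-locus disruption (score 0, 0.08
or 0.064) falls below the default selection threshold 0.2 while the ancestor
stays above it.

Selection is rejection sampling: mutants are drawn with a Poisson number of
events (mean 4), scored, and kept only below the threshold, emulating
recovery of non-flocculent cells from the planktonic fraction. Event kinds
follow a configurable mixture weighted toward homologous-recombination
outcomes (sGC 0.35, BIR 0.35, aneuploidy loss 0.10 / gain 0.05, TL 0.09,
circularization 0.035, deletion 0.025); per-event-class rates per break are
not calibrated to any published count. Break-derived events hit chromosomes
in proportion to length (target size); aneuploidy instead weights
chromosomes by $1/L$, reflecting that mis-segregation of gene-rich large
chromosomes is rarely tolerated — this is what concentrates chromosome
losses on the small structural-locus chromosome's parent-B homolog, the
analogue of the dominant chromosome-I loss seen in such screens.

Drawn event sets are constrained to be *non-interacting*: footprints of
copy- or state-altering events may not overlap (or come within 5 kb) on a
chromosome, even across homologs, and interstitial tracts stay 2.5 kb clear
of chromosome ends. Overlapping conversions on opposite homologs cancel in
read evidence, loss plus gain of one chromosome is indistinguishable from
copy-neutral LOH, and tracts separated by no heterozygous marker fuse; such
composites are real biology but not attributable to single events, so the
generator redraws them. `plant_events()` itself only rejects same-homolog
overlaps, so interacting configurations can still be constructed explicitly.

### The evidence model

Each homolog copy contributes reads at rate `mean_depth/2 × copy number`
(default depth 50×), carrying the parental allele the homolog holds at each
marker. `dispersion = 0` returns exact expectations (the noiseless oracle
mode), `1` draws independent Poisson depths per homolog, `> 1` a negative
binomial with variance `dispersion × mean`. Window coverage is the window
mean of the same draws, so marker and window tracks are mutually consistent.
True junctions emit supporting reads at `junction_support_rate × mean_depth`
(default 15 reads at 50×); a Poisson background of spurious junctions with
support 1–3 (below the default `min_support = 5`) models mapping artifacts.

The generator does **not** emulate base-level reads, sequencing error,
mapping bias, repetitive-sequence pileups, GC bias, or subclonal mixtures. A
green test against this world establishes that the caller's logic is correct
under its stated noise model, not that it is robust to real-library
artifacts.

## The caller

* **Marker genotyping**: B-allele fraction below 0.15 → homozygous parent A,
  above 0.85 → parent B, between → heterozygous; total depth under 10 → no
  call. The band is binomially plausible at 50×: a true heterozygote at
  depth 50 leaves the band with probability ~$10^{-7}$.
* **Segmentation**: majority vote over 5-marker windows (ties and edges keep
  the raw call) removes isolated miscalls without blurring events of 20+
  markers, then maximal constant-state runs become segments; boundaries
  fall midway between the flanking markers of a state change, and runs under
  5 markers merge into their larger neighbor.
* **Classification** follows the coverage-reciprocity rule: a LOH segment
  with preserved total coverage (donor allele up, recipient down) is
  homologous repair — BIR if the segment touches a chromosome end, sGC if
  interstitial; terminality alone decides, with no length cutoff. A segment
  with lost coverage is a deletion when a junction bridges its own two
  boundaries (or no junction exists), and a translocation when a
  high-support junction links a boundary to another locus. When reciprocal
  coverage and a junction-to-elsewhere co-occur, the copy-neutral reading
  wins and the call is flagged `ambiguous`; a bridging junction always
  outranks a coincidental junction to elsewhere.
* **Aneuploidy**: median per-homolog window coverage across the chromosome
  below 0.25 of single-copy (loss) or above 1.5 (gain), gated on the
  chromosome-wide total moving accordingly (below 0.75 / above 1.25 of
  diploid). The total gate separates true copy-number change from
  copy-neutral whole-chromosome LOH, which also shifts allele-specific
  coverage.
* **Circularization**: one homolog's coverage lost on both terminal
  stretches *including total coverage* (BIR keeps total coverage; a missing
  arc does not), retained between two interior breakpoints, with a junction
  joining arc-right-end to arc-left-end. Windows straddling a breakpoint are
  mixed and excluded from the purity checks. Without the joining junction
  the pattern is reported as two terminal deletions.
* **Breakpoint refinement**: coverage boundaries snap to a junction within
  the search window (nearest first, then higher support, then lower
  coordinate); un-snapped boundaries are flagged approximate.
* Reciprocal translocations are copy- and LOH-neutral, so their parental
  homolog cannot be determined from this evidence; TL calls carry `NA`
  homolog and are matched by their unordered locus pair.

All thresholds live in `caller_config()` and are echoed into outputs.

## Hotspot mapping

Per mutant, homozygous vs heterozygous markers are counted in 10-kb tiling
windows; the bounded fraction $n_{hom}/(n_{hom}+n_{het})$ is reported (the
literal hom/het odds is a secondary column, NA when no heterozygous marker
remains — the bounded form avoids division by zero and is a monotone
transform of the odds). A mutant counts toward a window when its fraction is
≥ 0.9 or a called LOH segment covers at least half the window (robust at
segment edges). The background rate $p_0$ is the genome-wide mean of $k/M$
excluding the top 5% of windows, floored at half a pseudo-count so a
degenerate all-zero background cannot produce zero p-values; each window is
tested with the one-sided binomial tail $P(X \ge k \mid M, p_0)$ and
BH-corrected. The formal test is this package's addition — peak reading in
the motivating experiments was visual — and every report header notes it.
Genes overlapping merged hotspot intervals are ranked by hotspot q-value,
then overlap fraction, then coordinates.

## Phenotype statistics

The flocculation score is $1 - \mathrm{OD(P)}/\mathrm{OD(T)}$ (planktonic
over dispersed-total OD600), clipped to $[0,1]$ with raw $\mathrm{OD(P)} >
\mathrm{OD(T)}$ flagged. Group comparisons use Welch's unequal-variance $t$
with Welch–Satterthwaite degrees of freedom. Relative expression uses
$2^{-\Delta\Delta C_t}$ against a housekeeping reference and a control
strain; the exact normalization scheme is not dictated by the source
protocols, and $2^{-\Delta\Delta C_t}$ was chosen as the field standard —
it is invariant to constant shifts of all $C_t$ values and fixes the control
at 1. Star annotations follow the usual (0.05, 0.01, 0.001) convention.

The serial-passage arm evolves a flocculent haploid (functional activator,
18-unit array, score 1) under daily planktonic transfers: Poisson point
mutations over a gene panel (classified nonsense/missense/silent through the
standard code; 30% of missense changes are treated as disabling) and rare
structural events at the adhesin locus (repeat contraction, e.g. 18 → 8, or
subtelomeric deletion), with survival weight $1 - 0.9 \times \mathrm{score}$
per cycle. Defaults (rate 0.15/genome/cycle over the panel, 20 cycles,
population 100, 18 reported clones) give clones carrying a handful of
mutations each, matching the scale of published evolved-clone tables.

## Numerical and interface conventions

Coordinates are 0-based half-open internally and converted at the VCF/GFF3
boundary (1-based inclusive). The variant filter chain applies all nine
clauses with strict inequalities exactly as printed (`DP > 15 & MQM > 30 &
QUAL/AO > 10 & SAF > 0 & SAR > 0 & RPR > 1 & RPL > 1 & QUAL > 100 &
AF = 1`), with `QUAL/AO` failing by definition at `AO = 0` and the `AF`
equality absorbing a 1e-9 text-float round-trip; multi-allelic records are
decomposed per alternate allele before filtering. Tandem repeats are counted
from the smallest self-match period with ≥ 90% identity, counting complete
units at ≥ 90% identity to the consensus. Randomness always flows from one
root seed through deterministic child-seed derivation, so identical
configuration and seed reproduce every artifact byte-identically.

## Known limitations

* Desk-scale genomes inflate the relative footprint of passenger BIR tracts,
  so the windowed LOH background sits near 10–15% rather than the few
  percent a full-size genome would give. With a 30-mutant cohort and
  threshold selection — where a single disrupted locus suffices for
  selection, so the three causal loci share roughly 1.1 causal hits per
  mutant — the weakest locus reaches only ~30% penetrance and does not
  reliably clear the BH-corrected hotspot test. Recovering all three loci in
  nearly every 30-mutant screen at desk scale is therefore not expected; the
  chromosome-loss bias toward the structural homolog, by contrast, is a
  robust readout, and single-locus architectures are recovered with high
  penetrance.
* The caller assumes events are separable; compound loci (overlapping
  conversions on both homologs, fused adjacent tracts) are reported as
  composite calls rather than reconstructed.
* Junction-graph assembly of complex fusions, raw-read simulation, and
  alignment are out of scope.
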