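---
title: "Mapping fibrinogen citrullination sites and citrullination-responsive expression modules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping fibrinogen citrullination sites and citrullination-responsive expression modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(citmap)
```

## The problem

Citrullination is the enzymatic deimination of arginine to citrulline by
peptidylarginine deiminases (PAD2, PAD4). On fibrinogen — the abundant
plasma and synovial-fluid clotting protein built from paired α, β and γ
chains — citrullination matters twice over in rheumatoid arthritis: the
modified protein is a major autoantigen, and it loses fibrinogen's
inhibitory effect on osteoclast formation. `citmap` implements the two
computational stages that support this biology:

1. **Site mapping.** Locating citrullinated arginines on fibrinogen chains
   from MALDI-TOF peptide-mass fingerprints of tryptic digests.
2. **Transcriptome modules.** Classifying genes that respond to fibrinogen
   in monocytes by whether citrullination of the fibrinogen reverses that
   response, and scoring gene-set enrichment within each class.

Both stages come with simulators that plant known truth, so every claim the
package makes is checked end-to-end against data whose answer is known.

## Stage 1: the mass-spectrometric model

### Why citrullination is hard to see in a fingerprint

Citrullination changes a residue mass by only +0.984 Da (loss of an imine,
gain of a carbonyl). Worse, trypsin cannot cleave C-terminal to citrulline,
so a citrullinated peptide co-elutes in the mass list with what looks like
an ordinary missed cleavage: the +0.984 Da shift on a longer peptide is not
distinguishable from a missed-cleavage variant at typical MALDI-TOF
accuracy. The resolving trick is chemical: phenylglyoxal (PGM) condenses
specifically with citrulline under acidic conditions and adds **+116.026
Da per citrulline** (phenylglyoxal, C8H6O2 = 134.037 Da, minus one water).
A peak that shifts by `n × 117.010` Da between the underivatized and
PGM-treated digests carries exactly `n` citrullines.

### Mass arithmetic

All masses are monoisotopic. For a peptide with residue set $\{r_i\}$, $k$
citrullines, and PGM derivatization:

$$\mathrm{MH}^+ = \sum_i m(r_i) + m_{\mathrm{H_2O}} + m_{\mathrm{H^+}}
  + k\,\Delta_{\mathrm{cit}} + k\,\Delta_{\mathrm{PGM}}$$

with $m_{\mathrm{H_2O}} = 18.010565$, $m_{\mathrm{H^+}} = 1.007276$,
$\Delta_{\mathrm{cit}} = 0.984016$ and $\Delta_{\mathrm{PGM}} =
116.026215$ Da. Monoisotopic rather than average masses reproduce the
reference peptide MH+ values to two decimal places, which settles a choice
the original report leaves implicit. Charge states above 1+ and isotope
envelopes are out of scope: MALDI ions are treated as singly protonated.
The constants, the residue table and the pKa set can be overridden from a
YAML file (`load_mass_config()`); a fixed cysteine modification such as
carbamidomethylation is expressed there as a residue-mass override (none is
applied by default, since no alkylation step is part of the modelled
protocol).

### Digestion with blocked cleavage

`digest()` applies the Keil rule (cleave after K/R, never before proline).
`enumerate_candidates()` layers citrullination on top with three rules that
encode the trypsin–citrulline interaction:

* a citrullinated internal arginine is a *blocked* cleavage site and does
  **not** consume the missed-cleavage budget — this mirrors the inherent
  ambiguity between citrullination and miscleavage;
* an uncitrullinated internal K/R cleavage site does, up to `max_missed`;
* a peptide whose C-terminal arginine sits at an internal cleavage boundary
  cannot carry citrulline there, because trypsin could not have cut after a
  citrulline. Arginines before proline and a chain-terminal arginine are
  free to be citrullinated.

Defaults are `max_missed = 2` and `max_cit = 3` per peptide; every
reference peptide needs at most two of either. The enumeration is verified
in the test suite against an exhaustive oracle that checks every
`(start, end, citrullination subset)` triple directly against these
invariants on random chains.

### Matching and site assignment

`match_peaks()` assigns each observed peak to at most one candidate within
a ±0.2 Da window (the default; ppm mode is available). 0.2 Da was chosen to
cover the 0.02–0.19 Da gaps between the reference observed m/z values and
their theoretical masses, typical of externally calibrated MALDI-TOF. Ties
are broken deterministically — smallest absolute error, fewest
modifications, fewest missed cleavages, lowest start, smallest site set —
and equal-mass positional isomers (two candidates differing only in *which*
arginine is citrullinated) are flagged `ambiguous` rather than silently
resolved. Intensity is carried through but never scores anything.

`assign_sites()` declares a chain position citrullinated when a matched
PGM-derivatized candidate carries citrulline there; the stricter
`require_paired_native` mode additionally demands the same candidate's
native peak, i.e. an observed pair split by exactly $k\,\Delta_{\mathrm{PGM}}$.
`compare_runs()` intersects two site tables (e.g. PAD2 vs PAD4 treatments)
on (chain, position).

### The reference fixture

`fibrinogen_reference()` ships the published bovine-fibrinogen fingerprint:
seven observed peaks, their peptides with printed coordinates and
unmodified MH+ values, and the PAD2/PAD4 site annotations. Running the
pipeline over it recovers five α-chain sites, two β-chain sites and one
γ-chain site, and the PAD2-vs-PAD4 comparison gives 7 PAD4 sites of which
6 are shared:

```{r reference}
ref <- fibrinogen_reference()
res <- map_sites(ref$chains, ref$peaks, tolerance_da = 0.2)
res$sites[, c("chain_id", "position", "n_evidence", "ambiguous")]
compare_runs(res$sites, ref$pad4_sites)
```

Two design points deserve note. First, the full chain sequences are not
part of the reference data, so the fixture's chains are *synthetic*
scaffolds: the real peptides at their real coordinates, glycine filler
between them, a lysine before each peptide. Placements were screened
exhaustively so that no two candidates with different site sets fall within
the matching tolerance of each other (exact positional isomers excepted —
those are the ambiguity groups above; the single-adduct β peak at 1542.76
is one, since either R21 or R24 alone fits it, and only the two-adduct peak
at 1659.69 pins down both). Second, the printed MH+ of the γ peptide
`IHDVTGRDCQDVANK` reproduces from its sequence like every other (maximum
discrepancy across all seven: 0.004 Da), so the γ site needs no special
handling.

## Stage 2: the transcriptome model

### Module definitions

The design has three conditions — vehicle, fibrinogen, citrullinated
fibrinogen — measured in each of ≥ 2 donors on a log2 scale. With
`fc_threshold` (default 1.0 log2 unit):

* a gene is **UP**/**DN** per donor if fibrinogen − vehicle exceeds the
  threshold in that direction, **NC** otherwise; the concordant call
  requires *every* donor to agree, otherwise `discordant`;
* among concordant genes, **reversal** means citrullinated-fibrinogen −
  fibrinogen opposes the fibrinogen direction by at least
  `reversal_threshold` (default 1.0) in every donor (a majority-vote mode
  exists but is off by default);
* **module 1** = concordant UP, not reversed; **module 2** = concordant UP
  or DN, reversed; **module 3** = concordant DN, not reversed; a gene whose
  citrullination response concordantly *amplifies* the fibrinogen direction
  is left unlabelled (`none`), since no such gene is part of the module
  scheme being modelled.

The labels are mutually exclusive by construction and invariant to gene and
donor order. The original array counts (thousands of regulated genes,
modules of 660/130/937) are not reproducible from first principles — the
raw arrays are not deposited and the significance criterion was never
printed — so the thresholds here are explicit, documented parameters, and
everything quantitative is validated on simulated data instead.

### Enrichment scoring

`enrichment_score()` is the weighted Kolmogorov–Smirnov-like running sum:
down the ranked list, hits add $|s_i|^w / \sum_{hits}|s_j|^w$, misses
subtract $1/(N - N_{hit})$, and ES is the extremum of largest magnitude.
At $w = 0$ it reduces to the classical KS statistic, which the tests verify
against a closed-form ECDF oracle; at $w = 1$ (the default) it agrees with
an independent GSEA implementation (`fgsea`) to 1e-8.

`permutation_nes()` normalizes by gene-label permutation — with two donors
a phenotype permutation has no support, so random gene sets of matching
size form the null. NES divides ES by the mean |null ES| of matching sign;
FDR q-values follow the standard two-tail procedure on the pooled null NES.
Defaults: 1000 permutations, weight 1. A `tail_warning` column flags sets
whose matching-sign null contains fewer than 10 values. Under a null of
random rankings and random sets the q-values are approximately uniform
(the acceptance suite checks mean and quantiles over 200 draws).

## The simulators, and what they do not emulate

`simulate_spectrum()` emits the theoretical MH+ of every candidate whose
citrullination set is a subset of the planted sites (PGM-derivatized when
`pgm = TRUE`), adds Gaussian m/z jitter (default σ = 0.05 Da), then Poisson
decoy peaks uniform over the observed m/z range (default rate 0). It does
not model isotope envelopes, matrix clusters, adducts or intensity
structure — so recovering planted sites here demonstrates the matching and
bookkeeping logic, not robustness to real MALDI artefacts.

`simulate_expression()` plants module structure on a flat log2 baseline
(default 8): ±2.0 log2 units of fibrinogen effect, 2.0 of citrullination
reversal for module-2 genes (random sign), Gaussian noise σ = 0.3 per
measurement, two donors. Default module fractions (3.3% / 0.65% / 4.7%)
mirror the relative module sizes of genome-scale monocyte arrays. Real
array features — probe effects, correlated noise across conditions,
intensity-dependent variance — are not emulated, so the ≥ 0.95 label
accuracy shown on simulation bounds performance only under independent
Gaussian noise.

Both simulators are bit-reproducible given their config and seed, and both
return truth records sufficient to score recall, precision and accuracy
without looking inside the generator.

```{r recovery}
chain <- ref$chains$alpha
sim <- simulate_spectrum(chain, c(140, 145), mz_jitter_sd = 0.05,
                         decoy_rate = 1, seed = 7)
found <- map_sites(chain, sim$peaks, tolerance_da = 0.2)$sites
found$position
```

## Numerical and design choices

* **Isoelectric point.** `isoelectric_point()` solves net charge = 0 by
  bisection (tolerance 1e-6 pH) under Henderson–Hasselbalch with the EMBOSS
  pKa set; citrulline contributes no side-chain charge. Only orderings are
  asserted — citrullination lowers pI, which is what moves 2-DE spots
  toward acidic pH — never absolute values, because absolute pI depends
  strongly on the pKa table chosen.
* **Tie-breaking** in peak matching is fully deterministic (documented
  order above) so that site maps are reproducible for a fixed input.
* **Degenerate inputs.** Empty peak lists and empty candidate tables
  return empty results, not errors; unknown residues, non-arginine
  citrullination positions, negative counts and missing design conditions
  raise named errors.
* **Problem sizes.** The test and acceptance runs use 200 random chains of
  length ≤ 30 for the digestion oracle, 10 fixed seeds for spectrum
  recovery, 5000-gene simulations over 10 seeds for module accuracy, and
  200 null draws at 200 permutations for q-value calibration — sizes at
  which the brute-force oracles remain exact and the statistical checks
  are stable.

## Known limitations

* Site-level ambiguity between equal-mass positional isomers is detected
  and reported, but resolving it requires MS/MS data, which the package
  does not model.
* FDR estimation for site assignment (target–decoy style) is out of scope;
  the decoy mechanism in the simulator characterizes matching behaviour,
  it is not an error-control procedure.
* Cross-experiment consolidation of sites seen in only some replicate runs
  (as happens for one of the β-chain sites) is left to the user; the
  pipeline reports per-run tables and `compare_runs()` to combine them.
* With two donors the enrichment null is gene-label permutation by
  necessity; its q-values are calibrated under independence of genes, and
  correlated expression would make them optimistic.
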