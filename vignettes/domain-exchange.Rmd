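---
title: "Detecting domain exchange between membrane and soluble proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting domain exchange between membrane and soluble proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domex)
```

## The problem

Membrane proteins expose large parts of themselves — periplasmic or
extracellular loops and domains ("outside"), cytoplasmic ones ("inside") —
to the same aqueous folding environment as ordinary soluble proteins.
Structural comparison can therefore reveal shared domains between the two
classes even when their sequences have diverged beyond the reach of
sequence search, and a conserved catalytic neighbourhood on top of a shared
fold is evidence that function travelled with the domain. `domex`
implements that whole chain of reasoning as composable, testable pieces:
structural alignment, similarity screening with membrane-topology rules,
functional-site shell statistics, membrane-distance geometry, and the SSEA
sequence-level screen, together with a synthetic-structure generator that
plants known ground truth for every one of those stages.

## Structural alignment

The aligner is an iterative dynamic-programming heuristic in the TM-align
mould, maximising the TM-score

$$\mathrm{TM} = \frac{1}{L_{\mathrm{target}}}\sum_{i=1}^{L_{\mathrm{ali}}}
\frac{1}{1 + (d_i/d_0)^2},\qquad
d_0(L) = \max\{1.24\,(L-15)^{1/3} - 1.8,\; 0.5\}\ \text{Å},$$

over residue correspondences that are strictly increasing in both chains.

**Seeding.** Gapless threading of the two chains at fragment lengths
$L$, $L/2$ and $L/4$ ($L$ = shorter chain) over a strided grid of diagonal
shifts, each seed scored by the TM-score of its own superposition; when
H/E/C secondary-structure strings are attached, one further seed comes
from a DP alignment of those strings. The six best seeds are refined.

**Iteration.** Each round superposes (Kabsch) on the current pairs, fills
the similarity matrix $S_{ij} = 1/(1 + d_{ij}^2/d_0^2)$, and re-aligns by
global affine-gap DP with gap-open $-0.6$ and gap-extend $0$ (the TM-align
convention; both are arguments). Iteration stops when a pair set repeats
exactly or after 30 rounds; across seeds, ties on TM-score break toward
larger aligned length, then smaller RMSD. TM-scores are reported under a
score-maximising superposition obtained by re-superposing on
distance-trimmed subsets (cutoffs ∞, 8 Å, max(4.5, d₀)) and keeping the
best — the standard refinement that keeps a few bad pairs from dragging
the score.

**Normalisation.** The headline `tm_score` uses
$L_{\mathrm{target}} = \min(N_A, N_B)$. The screening context compares
chains of very different sizes — a whole membrane protein against a lone
soluble domain — and the shorter-chain normalisation makes shared-domain
detection symmetric in the argument order. Both per-chain normalisations
(`tm_score_a`, `tm_score_b`) are always reported alongside, since
published 0.5-thresholds do not always say which normalisation they mean.

**Reported pairs.** The final DP pass, being global, can append a few
residue pairs that are tens of Å apart (membrane helices "aligned" to
nothing in particular at negligible score). Reported alignments therefore
drop pairs beyond `trim_distance = 8` Å under the final superposition;
RMSD, identity and aligned length all refer to the trimmed set, which is
what one means by "the shared domain". The DP itself always runs
untrimmed.

**Degenerate input.** Kabsch refuses collinear point sets (the rotation
about the common axis is undetermined) and fewer than three points; the
reflection branch of the SVD solution is never accepted, preserving
chirality. Structures under 20 residues are rejected outright — below
that, TM-scores are not meaningful.

## Screening rules

The similarity filter is exactly the printed selection: RMSD < 5 Å,
aligned length > 100 residues, TM-score > 0.5, every inequality strict —
a pair sitting exactly on any threshold fails, and the tests pin that
convention. Two topology rules follow:

- **TM overlap.** Pairs whose aligned membrane-protein residues are less
  than 90% extramembrane are removed (`min_extramembrane = 0.9`,
  configurable). The source analyses state only that similarity "within
  the transmembrane region" was removed; 0.9 is this package's
  operationalisation and is exposed as a knob.
- **Disconnected loops.** Aligned extramembrane residues are grouped into
  maximal chain runs separated by TM segments; the pair is removed when no
  single run holds ≥ 80% of them (`dominant_segment = 0.8`, configurable).
  Again the underlying criterion ("several disconnected extramembrane
  loops") comes with no number, so dominance, not run count, was chosen:
  it is insensitive to a stray residue in a second loop.

Side assignment is the majority inside/outside label over aligned non-TM
residues, ties going to "outside" (the overwhelmingly more common side)
with a warning. Redundancy reduction is a greedy length-descending pass
merging sequences whose global-alignment identity (PAM-250, linear gap 11,
identity = matches / alignment columns) strictly exceeds 30% — the role a
PISCES cull plays, without reproducing its PSI-BLAST machinery. Domain
annotations transfer only above strictly 90% coverage of the domain range.

## Functional-site shells

First-shell residues lie within 5 Å (Cα–Cα) of a site residue,
second-shell residues within 5 Å of the first shell; sites belong to
neither shell, and sites, shells and rest partition the chain — an
invariant the tests check on every fixture. Distances use Cα only because
a Cα trace is all the reader guarantees; the radius is an argument. The
shell-vs-rest statistic partitions alignment columns (including internal
gap columns) by whether the membrane-side residue is a site or shell
member — site columns count as shell, because the statistic contrasts the
functional neighbourhood with the remainder — and sums PAM-250 with −11
per gap-containing column (linear: one published number, no affine
extension to invent). Shell score plus rest score equals the
whole-alignment score by construction, and both raw sums and per-column
means are reported; raw sums depend heavily on how many columns each part
has, so per-column means are what the package's own summaries compare.

## Membrane geometry and the rank test

The membrane frame comes from a JSON sidecar (rotation, translation, slab
surfaces, per-residue TM/inside/outside labels) standing in for
PDBTM/TMHMM output. A domain's membrane distance is the gap between its
Cα centroid ("average of all the coordinates", read as Cα because that is
the guaranteed atom) and the *nearer slab surface* — not the midplane —
with the side taken from the centroid's sign. The transform into the
membrane frame is deliberately not idempotent, so structures carry a frame
flag and a second application is an error.

`mann_whitney_u()` uses midranks, exact two-sided p by enumerating all
$\binom{n}{n_A}$ assignments when $n \le 12$, and otherwise the normal
approximation with tie correction and a 0.5 continuity correction.
P-values are two-sided throughout (the source reports single p-values
without declaring sidedness). `wilcox.test()` serves as an independent
oracle in the tests, never as the implementation.

## SSEA

H/E/C strings are run-length encoded; two element sequences are aligned by
global DP where pairing same-type elements contributes the shorter
element's length and everything else contributes zero, normalised to
$100 \cdot 2S/(L_A + L_B)$. This reproduces the "percentage of secondary
structure similarity" character of the cited method — identical strings
score exactly 100, disjoint types exactly 0 — while the cited method's
precise gap handling is not restated anywhere; the scheme above is this
package's contract, checked against exhaustive enumeration for small
element counts. DP ties break toward the upper-left predecessor, making
the traceback deterministic.

Cutoff training follows the published protocol: 100 pairs per set drawn
without replacement, integer cutoffs 0–100 scanned classifying
score ≥ c as positive, 1000 replicates. "Works best for separating" is
operationalised as balanced accuracy (robust to the 923-vs-210 class
imbalance); the per-replicate choice takes the smallest maximiser and the
final cutoff is the mode of the replicates (ties to the smallest). The
training cohort's score model (`"crossing50"`) uses Normal(65, 10) and
Normal(35, 10) clamped to [0, 100]: symmetric about the published cutoff
of 50, with the spread fixed so that the full 923/210 sets separate at
the published order of magnitude (p below 1e-100) — a narrower or wider
spread would contradict that printed separation. One caveat worth stating:
because every replicate resamples the *same* 210-pair negative set, the
replicate argmaxes are strongly correlated and the trained mode inherits
the cohort's own sampling noise of roughly ±2 cutoff units around 50;
that is the protocol's intrinsic resolution at these set sizes, not an
implementation artefact.

The probability curve bins scored pairs (default width 10) and reports
the empirical fraction with RMSD < 5 Å per bin, with a Spearman trend
statistic over occupied bin midpoints; empty bins are omitted rather than
interpolated.

## The synthetic generator

The generator emulates, with planted ground truth, everything the pipeline
consumes:

- **Membrane proteins.** Ideal TM helices (rise 1.5 Å/residue, radius
  2.3 Å, 100°/residue — consecutive Cα ≈ 3.8 Å) spanning a ±15 Å slab,
  joined by short loops; one loop carries a compact three-helix bundle
  domain whose centroid is placed at a chosen distance from the membrane
  surface on a chosen side. Region labels follow the construction
  geometry; the chain is then moved to a random laboratory frame and the
  annotation stores the inverse transform, so the membrane-frame machinery
  is genuinely exercised.
- **Counterparts.** The domain is copied, perturbed with isotropic
  Gaussian Cα noise rescaled (a three-step proportional fixed point on the
  post-superposition RMSD — exact and monotone, so no root-finder is
  needed) to hit the target RMSD within 10%, and mutated to the target
  identity within 2 points, with an exact identical-position count;
  first/second shells of designated sites can be frozen, and the
  generator *errors* when the frozen set exceeds the identity budget
  rather than silently missing its target.
- **Cohorts.** Labelled scored pairs for SSEA training (positives
  RMSD < 5 Å, negatives > 10 Å, both at 5–15% identity) and logistic-model
  cohorts for probability-curve recovery; `simulate_study()` assembles
  whole membrane/soluble screening cohorts with a planted
  fraction-with-counterpart and planted outside fraction, pairing the rest
  with unrelated decoy bundles so the filters have genuine negatives.

What the generator does **not** emulate: side chains and real packing,
loop chemistry, non-ideal helices, sequence composition biases,
experimental coordinate error, oligomers, or homology relationships
subtler than "noisy copy vs unrelated decoy". Passing tests on synthetic
cohorts therefore demonstrate that the algorithms recover what was
planted under controlled conditions — correspondence, thresholds,
statistics — not that real membrane proteomes behave this way. The two
worked validation pairs are likewise generator stand-ins built at the
published pair characteristics (116 residues at 4.7% identity with two
conserved cysteines; 218 residues at 13.2% identity with conserved
shells); running the package on the real PDB entries requires only the
coordinate files and the same function calls, but their absolute shell
similarity sums are properties of the real coordinates that a stand-in
cannot and does not claim to reproduce.

## Problem sizes and determinism

The test suite and the acceptance script use the study's own scales where
they matter — 923/210 SSEA training pairs with 100 × 1000 resampling,
504/102 membrane-distance cohorts, 10,000-pair probability curves,
100-seed parameter-recovery sweeps — and a 30-protein cohort for the
end-to-end pipeline, which exercises every stage in a few seconds per run.
Every stochastic step takes an explicit seed, generators restore the
caller's RNG state, and a repeated run with the same seed reproduces every
report byte for byte (a property the pipeline tests assert).

## Known limitations

- The aligner is a heuristic: it matches an exhaustive-optimum oracle for
  the DP step and recovers planted correspondences essentially perfectly
  at realistic noise, but it does not guarantee byte-level agreement with
  any particular TM-align binary, and sequence-order-independent or
  flexible alignment is out of scope.
- Shell extraction and membrane distances are Cα-based; all-atom variants
  would need full-atom input the IO layer deliberately does not require.
- `read_pdb_chain()` reads single chains, first NMR model only, no mmCIF.
- The redundancy reduction approximates a PISCES-style cull with the
  package's own global-alignment identity; absolute cluster counts on real
  sets will differ from PISCES's PSI-BLAST-derived ones.
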