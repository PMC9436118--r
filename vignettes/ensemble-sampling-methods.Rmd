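---
title: "Sampling alternate protein conformations by MSA alanine mutagenesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sampling alternate protein conformations by MSA alanine mutagenesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The idea

AlphaFold2-class predictors infer residue–residue distances largely from
the co-evolution signal in the multiple sequence alignment (MSA): positions
that are in contact in the folded protein accumulate correlated
substitutions. For proteins that interconvert between conformations — the
open and closed states of a kinase, the inward- and outward-open states of
a membrane transporter — the MSA carries signal for *both* states, but the
predictor usually returns only the one it weighs most heavily.

This package perturbs that signal directly. Replacing a *set of contacting
residues* with alanine **across every sequence of the MSA** erases the
co-evolution evidence for those specific contacts while leaving the rest of
the alignment intact. Re-folding with the mutated MSA (and the matching
mutant query sequence) lets the network attend to the remaining signal,
which frequently corresponds to an alternate conformation. Scanning the
whole chain window by window turns this into a systematic conformational
sampling protocol; targeting a known interface (for instance the contacts
between the N- and C-terminal halves of a pseudo-symmetric transporter)
turns it into a directed one.

## The pipeline, stage by stage

### 1. Scan region (`scan_region`)

Termini of predicted models are often low-confidence tails that would
contribute spurious "contacts". Both ends are truncated wherever per-residue
pLDDT is *below the mean* pLDDT of the model; internal dips are kept, since
a flexible loop between well-predicted domains is exactly the kind of
region worth probing. Equality with the mean counts as confident, so a
uniform-confidence model is not trimmed at all.

### 2. Window scan and contact tabulation (`enumerate_windows`, `window_contacts`)

The trimmed region is tiled with non-overlapping windows of
`window_length = 11` residues (`stride = window_length`). Eleven residues
is roughly three helical turns — the scale of the secondary-structure
elements whose packing changes in domain motions — and tiling rather than
sliding keeps the number of folding jobs near (protein length)/(window
length). When the region length is not a multiple of the window, the final
window is re-anchored at `end − window_length + 1`: every residue is
scanned exactly once except for a small overlap at the C-terminal end,
which keeps window sizes (and hence set statistics) comparable.

For each window, every residue pair (i in the window, j elsewhere) whose
*minimum heavy-atom distance* is ≤ `contact_cutoff = 4` Å is tabulated.
Four ångströms spans polar and ionic interactions, including water-mediated
ones; the distance is over all heavy atoms (backbone and side chain), not
Cα, because side-chain contacts are precisely the ones that encode packing.
Partners within `sequence_exclusion = 4` positions of the window are
omitted so that local secondary structure (i, i+4 helical contacts) is not
destabilized. Both members of each qualifying pair enter the mutation set
by default — removing both sides of a contact perturbs its co-evolution
signal maximally — with `mutate = "window"` / `"partners"` available for
one-sided designs. Windows with no qualifying contact are flagged and
excluded from mutagenesis. Alanines and glycines inside qualifying pairs
are listed like any other residue; alanizing an alanine is simply a no-op
downstream, which keeps the bookkeeping order-independent.

### 3. MSA mutagenesis (`a3m_mutate`)

a3m files represent the alignment compactly: the query is uppercase and
gapless; in homologs, `-` is a gap at a query match column and lowercase
letters are insertions relative to the query. The package enforces the
resulting invariant — uppercase + `-` counts equal the query length for
every entry — on read, after every mutation, and in the synthetic
generator.

Substitution is defined *only* for match columns: the selected query
positions are mapped to each entry's match states, every non-gap character
there becomes alanine (configurable via `to_residue`), gaps are left
untouched (a sequence that lacks a residue offers no co-evolution signal to
erase), and insertions are never modified because they have no query
equivalent. Non-standard letters (X, B, Z, U) at a selected match column
are replaced like any residue — only `-` is exempt. The query row is
mutated too, and the mutant query is what gets folded; folding a wild-type
sequence against a mutant alignment would reintroduce the erased signal at
the sequence level.

### 4. Folding backend (`run_campaign`)

Each mutated alignment (plus the unmodified one, which provides the
baseline set) is folded `runs_per_set = 3` times with distinct random
seeds, `models_per_run = 5` models each: 15 models per set, and
`(n_sets + 1) × 15` models per campaign. Folding is behind a minimal
contract — `fold(msa_path, seed)` returning models with per-residue pLDDT —
with two implementations: a ColabFold adapter that shells out to
`colabfold_batch` with templates disabled (templates would bias the
predictor back toward known conformations), and a deterministic mock
backend over the hinge toy described below. Seed plumbing depends on the
installed ColabFold exposing a `--random-seed` flag; where it does not,
run-to-run variability comes only from ColabFold's own seeding, and the
campaign manifest records the runs either way. Completed runs are detected
on disk, so interrupted campaigns resume without refolding.

### 5. Set-level quality filtering (`filter_sets`)

Aggressively alanizing an interface sometimes produces genuinely misfolded
models. These are filtered at the *set* level: a poisoned MSA tends to
poison all 15 of its models, and set-level filtering cannot be gamed by a
single lucky model. With M the median and S the standard deviation of all
pooled model scores (lower = better, MolProbity convention), sets whose
mean score exceeds `M + S` are discarded. "Standard deviation of the mean"
is read here as the pooled sample standard deviation — one standard
deviation above the median of all models; a standard-error reading would
make the threshold shrink as 1/√n with campaign size, discarding nearly
everything in large campaigns, but it is available behind
`spread = "sem"` for completeness. Scores are supplied per model via a
plain CSV (`read_score_table`) so any external scorer can be used; the
built-in `clash_proxy_score` is a steric-overlap count per 1000 atoms
(excluding intra-residue and sequence-adjacent pairs) — a deliberately
minimal geometric score, *not* a MolProbity reimplementation, suitable for
ranking grossly distorted models.

### 6. Ensemble analysis (`tm_score`, `ensemble_rmsf`, `ensemble_pca`, `prune_outliers`)

All comparisons are same-sequence, so TM-scores use a *fixed residue
correspondence* (by sequence index between models, by author residue
number against experimental structures, with an `exclude` filter for
regions like unresolved terminal helices); no sequence-independent
structural alignment is attempted. The score is
TM = max over superpositions of (1/L_ref) Σ 1/(1 + (d_i/d0(L_ref))²) with
d0 = 1.24·(L_ref − 15)^⅓ − 1.8, floored at 0.5 Å for chains of ≤ 21
residues where the formula turns non-physical. The maximization follows
the standard heuristic — superpositions seeded from contiguous fragments
at several lengths, each refined by re-superposing on the residues within
a distance cutoff until the selection stabilizes, over a small schedule of
cutoffs — and is checked in the tests against an independent dense-seed
search. Normalization is by the reference length, so scores against two
references of different length are not symmetric; both normalizations of
the reference-vs-reference score are reported in `tm_landscape`.

Superposition is the Kabsch algorithm (SVD with a determinant correction,
so mirror images are never matched). RMSF and PCA superpose all models
onto an iteratively refined mean: fit all to a reference, average,
re-reference, until the mean moves < 1e-4 Å (≤ 100 iterations). PCA is
then ordinary covariance PCA of the flattened Cα deviations. Reference
structures are projected onto the model-derived components but excluded
from the covariance fit by default — the experimental structures are
placed on the landscape the models define, not allowed to define it.
Component signs are fixed (largest-magnitude loading positive) so plots
are reproducible; projections are invariant to model order up to that
sign convention.

The published protocol removes PCA outliers by manual inspection and
repeats until none remain. The automated surrogate here removes models
whose PC1 or PC2 coordinate lies more than `k = 3.5` MAD-based robust
standard deviations from the componentwise median, refits, and iterates
to a fixed point; every removal is logged and an explicit manual exclusion
list is honored first. The componentwise rule was chosen over a radial
distance rule because the radial distribution of a well-behaved cluster
has heavy enough tails that a radius test at practical k removes inliers;
componentwise robust z at 3.5 corresponds to a ~5e-4 per-component false
positive rate under normality.

## The synthetic test system

Real validation of this method needs GPU folding; the package therefore
ships a synthetic system with the statistical structure the pipeline
assumes, used by every test and by `scripts/acceptance.R`.

The **hinge toy** (`hinge_spec`, `make_hinge_ensemble`) is a two-domain
protein: two 25-residue idealized helices joined by a 5-residue linker,
with the second domain rotated about a laterally offset hinge axis. At
hinge angles near 150° the domains pack against each other and the contact
scan finds interface windows; near 120° they separate. Conformations are
sampled uniformly over the angle range (default 120–155°; a second,
orthogonal 10–30° mode is available with `modes = 2`) with isotropic
Gaussian coordinate noise (default 0.1 Å; acceptance checks use 0.3 Å) on
all atoms — matching the additive-deviation assumption of coordinate PCA.
Geometry is idealized: backbone N, CA, C, O plus a Cβ stub, no side
chains, cyclic alanine-free sequence so every alanization is observable.
This keeps all contact and clash oracles exhaustively enumerable; it is a
statistical stand-in, not a protein. The deliberately closed conformations
interpenetrate slightly (as genuinely misfolded predicted models do);
clash-free fixtures for the clash-score tests use the extended chain.

The **mock folding backend** reads the (possibly alanized) query from the
a3m and shifts its sampled hinge-angle distribution by
`effect_angle × (fraction of designated interface positions alanized)` —
default 150° → 120° when the full interface is erased. This gives the
end-to-end test a programmed, recoverable effect: unmodified-MSA models
and interface-mutated models must separate along PC1 by the projected
programmed displacement (within sampling noise). What passing these tests
shows is that every stage — scanning, mutation bookkeeping, folding
orchestration, filtering, PCA — transmits a known conformational signal
faithfully. What it cannot show is that a real predictor responds to real
MSA mutagenesis; that link is the method's published, GPU-scale result,
not something a synthetic backend can certify.

Synthetic **a3m alignments** (`make_synthetic_a3m`) have controllable
depth, identity, gap fraction and insertion rate, so the gap-skip
accounting of mutation is exercised; synthetic **score tables**
(`make_score_table`) are Gaussian around 1.7 ± 0.08 (the band where real
composite geometry scores of sound models concentrate) with designated
outlier sets shifted upward. The filter-recall checks plant a single
outlier set among ten or more with a +1.2 shift, i.e. at least three
pooled standard deviations even after the contamination inflates the pool
— the regime the set filter is designed for. With contamination
approaching half the sets the pooled statistics break down and recall is
not guaranteed; that is a property of the median/SD rule itself.

## Numerical choices and degenerate inputs

* Residue indexing: all positional APIs use the 1-based sequence index of
  the query; author residue numbers are kept only for matching against
  experimental structures. Models with residues missing relative to the
  query are handled by correspondence intersection, and excluded regions
  are dropped from scoring via the `exclude` argument.
* Multi-chain PDB files default to the first protein chain;
  `require_single_chain = TRUE` makes ambiguity an error. Hydrogens are
  ignored everywhere; for altlocs the highest-occupancy conformer is kept,
  making all distances deterministic.
* Kabsch on collinear point sets is an error (the rotation is undefined);
  TM-score requires ≥ 15 correspondence pairs (the d0 formula's domain);
  RMSF requires ≥ 2 models; PCA ≥ 3 conformations; pruning refuses to
  remove the last models.
* A window shorter than `window_length` (region shorter than the window)
  yields a single window over the region. An alignment entry violating
  match-column conservation is a hard error naming the entry — silently
  repairing it would corrupt the position mapping of every downstream
  substitution.
* All generators take explicit seeds and restore the caller's RNG state;
  identical seeds give byte-identical output.

## Problem sizes used in the checks

The shipped tests and the acceptance script run entirely on the hinge toy
(55 residues, ~270 heavy atoms), with ensembles of 15–105 models, 100-model
PCA recovery runs, 200 synthetic alignments and 100 synthetic score
tables. These sizes make every brute-force oracle (O(atom²) contact and
clash enumeration, dense-seed TM search) exact and fast while leaving the
code paths identical to production use; campaigns over real proteins
differ only in scale and in the folding backend.

## Known limitations

* The clash proxy ranks gross distortion only; for publication-grade
  filtering, feed real MolProbity scores through the CSV interface.
* TM-scores use fixed correspondences: comparing across different
  sequences, or when register shifts are plausible, requires a true
  structural aligner upstream.
* The outlier pruner works in the PC1/PC2 plane, mirroring the manual
  protocol; structure that is outlying only in PC3+ is not pruned.
* Whether the published protocol alanizes only window residues or both
  contact partners is not specified by its description; both are supported
  and the default (both) is this package's choice.
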