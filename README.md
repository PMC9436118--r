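# alamsa

Conformational ensemble sampling by in-silico alanine mutagenesis of
multiple sequence alignments, for AlphaFold2-class structure predictors.

## The problem

Deep-learning structure predictors read residue–residue contacts out of the
co-evolution signal in a multiple sequence alignment (MSA) and, for
proteins that alternate between conformations — kinases opening and closing
over substrates, membrane transporters switching between inward- and
outward-open states — usually return only one of them. `alamsa` implements
the MSA-manipulation protocol that unlocks the others: erase the
co-evolution evidence for one set of contacts by mutating those positions
to alanine **across every sequence of the alignment**, re-fold, and the
predictor attends to the remaining signal, which often encodes an alternate
conformation.

The package covers the full campaign around an external folding backend
(ColabFold, or a deterministic mock for testing):

1. **Scan** — trim the initial model's termini where pLDDT falls below the
   model mean; tile the trimmed region with 11-residue windows; for each
   window tabulate all residues within 4 Å (minimum heavy-atom distance) of
   it, omitting partners closer than 4 positions in sequence. Targeted mode
   accepts residue lists or an interface defined by two residue groups.
2. **Mutate** — map the tabulated positions onto the a3m match columns and
   alanize them in every sequence, skipping gaps and never touching
   insertions; emit one mutated MSA + mutant query per set, with a JSON
   manifest planning 3 runs × 5 models = 15 models per set.
3. **Fold** — run the backend per set and seed; collect, label and resume.
4. **Filter** — discard whole sets whose mean quality score exceeds the
   pooled median plus one pooled standard deviation (scores via CSV from
   any scorer, e.g. MolProbity; a clash-count proxy is built in).
5. **Analyze** — TM-score (fixed correspondence,
   `TM = max (1/L_ref) Σ 1/(1+(d_i/d0)²)`, `d0 = 1.24(L_ref−15)^⅓ − 1.8`),
   Kabsch RMSD, per-residue RMSF after iterative superposition onto the
   ensemble mean, coordinate PCA of Cα deviations with references projected
   onto the model-derived components, and iterative robust outlier pruning
   of the PC1/PC2 plane.

A synthetic two-domain hinge protein, synthetic a3m alignments and
synthetic score tables (see `vignettes/ensemble-sampling-methods.Rmd`) make
the whole pipeline testable offline; every geometric operation is checked
against brute-force oracles.

## Worked example

```r
library(alamsa)

spec <- hinge_spec()                              # two-domain toy protein
init <- hinge_model(spec, 150, model_id = "initial")  # closed-like start

sets <- scan_sets(init)                           # pLDDT trim + window scan
scan_region(init)
#> start   end
#>     4    52
sets[[2]]
#> MutationSet 'w015_025' - 24 position(s)

aln <- make_synthetic_a3m(query = query_sequence(init), depth = 16, seed = 42)
man <- emit_campaign(aln, sets, "campaign")       # mutated a3m per set + plan
man$expected_total_models
#> [1] 90                                          # (5 sets + unmodified) x 15

iface <- targeted_set(init, 1:25, 31:55, set_id = "iface")  # interface mode
be  <- mock_backend(spec, interface_positions = iface$positions)
ens <- run_campaign("campaign", be, base_seed = 7)
#> ModelEnsemble: 90 models in 6 set(s)

refA <- hinge_model(spec, 150, model_id = "closed_ref")
refB <- hinge_model(spec, 120, model_id = "open_ref")
tm_score(refA, refB)                              # reference-vs-reference
#> [1] 0.531
rmsd_global(refA, refB)
#> [1] 7.74

tm_landscape(ens$models[1:4], refA, refB)[, 1:4]
#>             model_id set_id  tm_a  tm_b
#> 1 unmodified_run1_m1   <NA> 0.990 0.532
#> 2 unmodified_run1_m2   <NA> 0.990 0.533
#> 3 unmodified_run1_m3   <NA> 0.991 0.533
#> 4 unmodified_run1_m4   <NA> 0.992 0.534

ensemble_pca(ens$models, references = list(refA, refB))
#> PCAResult: 92 conformations, 90 components; PC1 99% PC2 0%
```

Unmodified-MSA models score TM ≈ 0.99 against the closed reference and
≈ 0.53 against the open one (the reference-vs-reference value — they are
the closed state). The campaign's mutant sets spread along PC1, which
carries 99% of the coordinate variance: the hinge mode. Filtering and
pruning then proceed with `filter_sets(read_score_table("scores.csv"))`
and `prune_outliers(...)`.

A thin command-line front end over the same functions ships in
`inst/cli/alamsa.R` (subcommands `scan`, `mutate`, `run`, `filter`, `pca`,
`fixtures`).

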