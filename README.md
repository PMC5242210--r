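# asbscaffold

Analog series-based (ASB) scaffolds from bioactive compound collections.

## The problem

Medicinal chemists organize compounds around *scaffolds* — core structures
that carry a series of analogs. The classical Bemis–Murcko definition
(rings plus linkers, all R-groups removed) is general but chemically
blunt: adding a ring as an R-group changes the scaffold, and no reaction
information is retained. The analog series-based scaffold is a different
definition, built on matched molecular pairs (MMPs):

- An **MMP** is a pair of compounds differing by a chemical modification at
  a single site; it decomposes into a shared **core** and two exchanged
  substituents.
- A **RECAP-MMP** restricts the cut to retrosynthetic (RECAP) bond types —
  bonds formed by common reactions (amide, ester, amine, urea, ether,
  olefin, quaternary N, aromatic N–aliphatic C, lactam N–aliphatic C,
  aromatic C–aromatic C, sulfonamide) — so every MMP corresponds to a
  plausible chemical transformation. Size restrictions keep pairs
  analog-like: substituents ≤ 13 heavy atoms, core ≥ 2× the larger
  substituent.
- An **analog series** is a connected component of the network whose nodes
  are compounds and whose edges are MMP relationships.
- A **structural key (SK) compound** forms an MMP with *every* other member
  of its series.
- The **ASB scaffold** of a series is the largest MMP core (by heavy-atom
  count) of an SK compound that backs an MMP relationship to every other
  analog. When no single core qualifies, a minimum set of SK cores jointly
  covering all analog relationships (**core cover**) is reported instead.

Because ASB scaffolds are derived only from series of active compounds,
each one arrives annotated with target activity — the starting point for
privileged-substructure analysis and target-directed library design.

The package implements the full pipeline for ChEMBL-style activity tables:
high-confidence curation (direct human-target interactions, confidence 9,
exact Ki/IC50 values, geometric-mean aggregation within one order of
magnitude), RECAP single-cut fragmentation, size-constrained MMP
generation by core indexing, series extraction, SK/scaffold/cover
identification and stage statistics. Structure-level primitives are
delegated to RDKit through a bundled Python helper; everything else is R.

## Requirements and installation

R (≥ 4.1) with `igraph` and `jsonlite`, plus a Python 3 interpreter with
`rdkit` importable, found as `python` on the PATH (override with
`options(asbscaffold.python = ...)` or the `ASB_PYTHON` environment
variable).

```sh
R CMD INSTALL .
# run the test suite
Rscript -e 'testthat::test_dir("tests/testthat", package = "asbscaffold", load_package = "installed")'
```

## Worked example

Three N-alkyl benzamides with Ki values against one target:

```r
library(asbscaffold)

acts <- data.frame(
  compound_id = c("BZM1", "BZM2", "BZM3"),
  smiles = c("CNC(=O)c1ccccc1", "CCNC(=O)c1ccccc1", "CCCNC(=O)c1ccccc1"),
  target_id = "CHEMBL204", organism = "Homo sapiens",
  relationship_type = "D", confidence_score = 9L,
  standard_type = "Ki", standard_relation = "=",
  standard_value = c(120, 35, 18), standard_units = "nM")

fit <- asb_scaffolds(acts)
fit$scaffolds
#>   series_id       scaffold heavy_atoms source_sk n_qualifying_cores n_members
#> 1    S00001 *C(=O)c1ccccc1           8      BZM1                  1         3
fit$sk_compounds$compound_id
#> [1] "BZM1" "BZM2" "BZM3"
```

All three amide bonds cleave at the same benzoyl core, the three compounds
form a 3-clique in the MMP network (one series, every member an SK
compound), and the shared 8-heavy-atom core `*C(=O)c1ccccc1` is the ASB
scaffold. The attachment point is written as the wildcard atom `*`.

At a larger scale, the bundled generator builds a seeded synthetic world
of 25 designed analog series (sizes 2–10, with substituent-size and
core-ratio boundary cases and two-site series whose truth is a core cover)
plus 50 inert decoys:

```r
fx <- generate_fixture(fixture_spec(seed = 1))
fit <- asb_scaffolds(fx$activities)
fit
#> Analog series-based scaffold analysis
#>   compounds:       177 (curated, unique structures)
#>   MMPs:            372 over 295 network edges
#>   analog series:   25
#>   with SK:         25
#>   ASB scaffolds:   21
#>   core covers:     4 (series without a single qualifying core)
summary(fit)
#>  statistic          all_series with_sk   with_asb
#>  Analog series (n)  25         25 (100%) 21 (84%)
#>  Single target      20         20        16
#>  Multiple targets   5          5         5
#>  Compounds (n)      125        125       101
#>  SK compounds (n)   -          105       101
#>  Analog series size 2-10       2-10      2-10
#>  Mean               5.0        5.0       4.8
#>  Targets (n)        10         10        10
```

The 21 scaffolds and 4 covers match the designed ground truth exactly
(`fx$truth`); the 52 compounds outside the series are the 50 decoys plus
the two members designed to violate the size constraints.

## Command line

A thin CLI over the same functions supports stage-wise runs
(`curate`, `mmp`, `series`, `scaffold`, `stats`, `simulate`, `run-all`):

```sh
Rscript inst/scripts/asb-scaffold.R simulate --seed 1 --out fixture
Rscript inst/scripts/asb-scaffold.R run-all --input fixture/activities.tsv --out results
```

`run-all` writes every stage table (compounds, fragments, MMPs, network
edges, series, SK compounds, qualifying cores, scaffolds, covers,
statistics) plus a manifest with stage counts and file hashes.

## Acceptance script

`scripts/acceptance.R` regenerates the seeded synthetic world, runs the
complete pipeline on it, verifies that series membership and decoy
isolation match the designed truth, prints the stage summary and writes a
JSON result file:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Vignette

`vignettes/asb-scaffold-methodology.Rmd` documents the method, its
parameters and defaults, the RECAP dialect choices, the synthetic-data
design and the known limitations.
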