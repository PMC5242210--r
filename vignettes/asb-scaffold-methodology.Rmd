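---
title: "Analog series-based scaffolds: methodology and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analog series-based scaffolds: methodology and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains what the package computes, which assumptions and
parameter choices are baked in, what the synthetic-data generator does and
does not emulate, and where the genuinely open design decisions were made.

## The method

The pipeline turns a raw activity table into a set of analog series-based
(ASB) scaffolds in seven stages.

**1. Curation.** Activity records are reduced to a high-confidence subset:
direct target interactions (relationship type `"D"`), assay confidence
score 9, human targets (`"Homo sapiens"`), Ki or IC50 endpoints, exact
measurements only (`"="`; records qualified by `>`, `<` or `~` are
discarded), units convertible to nM. Replicate potencies for one
compound–target–endpoint triple are combined as a geometric mean, provided
all values fall into the same order of magnitude; otherwise the triple is
discarded entirely. "Same order of magnitude" is operationalized as
`max/min <= 10` — the tightest natural reading of a one-log-unit dynamic
range — and is configurable (`curation_config(max_fold_range = ...)`).
Ki- and IC50-derived values are never averaged together: the two endpoint
classes are aggregated separately, and a compound–target pair having either
annotation counts as active. Structures are canonicalized (RDKit canonical
SMILES), salts stripped to the largest covalent component with a
diagnostic, and compounds deduplicated by canonical string. Stereoisomers
are distinct compounds: canonicalization preserves stereochemistry, which
is the lossless choice.

**2. Fragmentation.** Every acyclic bond matching a retrosynthetic RECAP
rule is cut once (single-cut only: an MMP is defined by a modification at
exactly one site, so multiple simultaneous cuts are never taken). Each cut
yields a fragment pair in both orientations — each side once as core, once
as substituent — with the attachment point written as the wildcard atom.
Duplicate pairs arising from molecular symmetry are collapsed.

**3. MMP generation.** Fragment pairs are indexed by exact canonical core
string. Two compounds form an MMP for a core iff both produce that core
from a single cut with different substituents, so grouping by core and
pairing within groups is equivalent to all-pairs comparison but scales
with the number of fragment pairs; the equivalence is asserted against a
brute-force oracle in the test suite. Size restrictions keep pairs
analog-like: the larger exchanged substituent may have at most 13 heavy
atoms (roughly a condensed two-ring system with up to three extra atoms,
which we treat as a consequence of the cap rather than an additional
topological filter) and the core must be at least twice the size of the
larger substituent. The ratio is compared against the larger substituent
only, exactly as stated in the size-restriction rule.

**4. Network and series.** Nodes are compounds, edges are MMP
relationships (a pair sharing several cores is one edge carrying all of
them). Analog series are the connected components; every series has at
least two members because isolated compounds never enter the network.
Series of size 2 are deliberately retained. No pruning beyond connected
components is performed.

**5. SK compounds.** A structural key compound has within-series degree
`size - 1`. A series may have none (e.g. a chordless 4-cycle of MMP
relationships); such series contribute no scaffold.

**6. ASB scaffold.** A core of an SK compound *qualifies* when an MMP with
exactly that core links the SK compound to every other member. The ASB
scaffold is the largest qualifying core by heavy-atom count. Two choices
here were genuinely open:

- *Tie-break.* Only "the largest" is specified; equal-sized candidates are
  resolved by lexicographic order of the canonical string, which is
  deterministic and toolkit-reproducible.
- *Pooling.* Qualifying cores are pooled across all SK compounds of a
  series (the permissive reading of "an MMP core of an SK compound"); each
  scaffold records its `source_sk`, so the stricter per-compound reading
  can be recovered from the output.

**7. Core cover.** For series with SK compounds but no single qualifying
core, a minimum-cardinality set of SK cores whose covered-member sets
jointly span the series is computed. A core covers the SK compounds that
possess it plus every member reached from such an SK compound via that
core. The minimum is found by exact subset enumeration up to 20 candidate
cores (the observed candidate counts at fixture scale are far below this)
and by greedy set cover beyond, with the method recorded per series. A
defensive branch returns no cover when some member is unreachable from all
SK cores, although the SK definition makes that impossible.

Stage statistics mirror the conventional three-column reporting layout
(all series / with SK / with ASB scaffold) with percentages against the
all-series column, single/multi-target splits from the union of member
target sets, size ranges and one-decimal means.

## The RECAP dialect

RECAP names eleven bond types but not a single canonical SMARTS encoding,
and published implementations differ in detail. The shipped rule table
(`inst/extdata/recap_rules.tsv`) is therefore plain data: eleven bond
SMARTS, each with atoms `:1` and `:2` flanking the cut bond, in priority
order (a bond matched by several rules is attributed to the first). Notable
choices, all auditable and overridable by passing a different file to
`recap_rules()`:

- Ring bonds are never cut, in any rule.
- Acyclic bonds between two aromatic-ring carbons are cut even when the
  rings belong to different fused systems (the permissive biaryl reading).
- Amide, urea and sulfonamide nitrogens must have degree ≥ 2: a primary
  amide C–N bond is not cleaved, matching common RECAP implementations.
- Amine cuts exclude nitrogens that are amide-, urea- or
  sulfonamide-like, so those bonds are attributed to their specific rules.
- Ether cuts exclude ester oxygens; both C–O bonds of a true ether are
  cuttable.

## Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `max_substituent_heavy_atoms` | 13 | heavy atoms | analog-sized transformations; cap on the larger exchanged substituent |
| `core_to_substituent_ratio` | 2.0 | ratio | core must dominate the variable part; compared to the larger substituent |
| `max_fold_range` | 10 | fold | "same order of magnitude" for replicate potency aggregation |
| `confidence_score` | 9 | — | highest assay confidence only |
| `max_exact_cover` | 20 | cores | exact set-cover enumeration limit; greedy beyond |

All boundaries are inclusive: a 13-atom substituent passes the cap, and a
core exactly twice the larger substituent passes the ratio. The test suite
pins this behavior at 12/13/14 atoms and 1.9/2.0/2.1 ratios, both as
arithmetic and with real molecules.

## The synthetic stated world

The generator (`fixture_spec()`, `generate_fixture()`) emulates what the
method needs to be right about, at desk scale and with exact ground truth:

- **Series** are one template core joined with distinct R-groups at a
  single RECAP-cleavable bond (amide, ester, aryl ether — rules that are
  unambiguous across dialects). Templates and R-groups are pure
  hydrocarbons apart from the functional group, so no unplanned cleavable
  bonds exist, cross-series shared cores are impossible, and the designed
  core is provably the largest qualifying core. By default 25 series with
  2–10 members.
- **Boundary series** place substituents at 12, 13 and 14 heavy atoms
  around a 26-atom core (13 is simultaneously at the cap and exactly half
  the core) and at 2, 3, 4 and 5 atoms around an 8-atom core (4 is exactly
  the 2.0 ratio; 5 must leave its compound isolated).
- **Two-site series** vary one base compound independently at an ether and
  an amide site: only the base is an SK compound, no single core qualifies,
  and the designed minimum core cover has size 2.
- **Decoys** (50 by default) are saturated pure-carbon structures with no
  cleavable bond at all; they pass curation and must end up in no series.
- **Activities** are log-uniform potencies in 1–10^4 nM with occasional
  replicates within a two-fold range, drawn under the spec seed; they are
  irrelevant to the scaffold logic but guarantee every compound survives
  curation. Targets follow a small pool with a configurable multi-target
  fraction.

What the generator does *not* emulate — and hence what a green test does
not establish: realistic structure–activity relationships, heteroatom-rich
scaffolds whose fragmentation is dialect-sensitive, promiscuous cores
linking thousands of compounds, measurement noise spanning orders of
magnitude, or the scale of a full ChEMBL extraction. Full-scale counts
additionally depend on the RECAP dialect and curation snapshot, so exact
reproduction of published large-scale numbers is outside what the fixture
world can certify; the corresponding acceptance check runs only when a
ChEMBL 21 export is supplied and is reported honestly as failing
otherwise.

## Numerical and degenerate-input choices

- Series, SK tables, scaffolds and covers are sorted deterministically;
  series identifiers are assigned by the lexicographically smallest member.
  Identical input, configuration and seed give byte-identical outputs.
- Unparseable structures, unknown units and missing fields reject the
  record (with per-reason counts in the curation report), never the batch.
- Empty inputs produce empty, correctly-typed outputs throughout; the
  statistics renderer prints `-` for undefined cells.
- Cutting a stereo-defined double bond (olefin rule) loses E/Z information
  in the fragments; such a fragment pair cannot round-trip to its parent.
  This affects reassembly-based verification only, not MMP correctness,
  and is inherent to single-bond fragment notation.
- The Python bridge is called once per table, not per molecule; interpreter
  start-up (~1 s) dominates small calls, so all fragmentation and joining
  is batched.

## Known limitations

- No chemistry toolkit exists natively in R here, so canonicalization and
  fragmentation run through a bundled RDKit helper; a Python interpreter
  with `rdkit` is a hard runtime requirement.
- Only single-cut MMPs are generated; multi-site transformations appear as
  core covers, not scaffolds, by design.
- Consensus scaffolds (maximum common substructure over cover cores) and
  multiple scaffolds per series are deliberately not implemented.
- Tautomers are not enumerated; two tautomeric notations are distinct
  compounds unless the toolkit normalizes them.
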