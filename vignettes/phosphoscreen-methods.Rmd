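---
title: "Screening phosphotyrosine mimetics: methods and design choices"
author: "phosphoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening phosphotyrosine mimetics: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphoscreen)
```

## The problem

SH2 domains recognize phosphotyrosine: a phosphate group docked into a
positively charged pocket. In STAT3 that pocket is organized around Lys591
and Arg609. A small molecule that places a phosphate (or phosphate mimic)
onto those residues can block the phosphotyrosine-dependent protein-protein
interaction, which is why phenolic natural-product fragments — cheap,
diverse, and synthetically phosphorylatable in one or two steps — are an
attractive starting library: esterifying a phenolic O-H with
-PO(OH)2 converts each fragment into a phosphotyrosine
mimetic.

`phosphoscreen` implements the computational side of that campaign as a
reusable pipeline:

1. **ingest** a compound library (`.smi`/SDF) into canonical records;
2. **filter** it to natural-product-derived phenolic fragments
   (scaffold-tree matching, phenol presence, molecular weight, reactive
   moieties);
3. **phosphorylate** the surviving phenols in silico;
4. **dock** the products via a pluggable engine (an external command such as
   AutoDock Vina, or a deterministic built-in mock);
5. **triage** the poses by phosphate-to-residue distance criteria;
6. **rank** the survivors for visual inspection.

Each stage is an exported function; `run_pipeline()` chains them with
checkpoints, and the `inst/scripts/phosphoscreen` entry point exposes the
same stages as shell subcommands. The docking engines themselves are out of
scope by design: the gateway prepares inputs, shells out, and parses
multi-model PDBQT output, nothing more.

## Compound normalization

Library entries are normalized once on ingestion: the largest covalent
fragment is kept (ZINC-style vendor entries are often salts; ties break by
higher molecular weight, then lexicographically smallest canonical SMILES),
and the OpenBabel canonical SMILES of that fragment becomes the record's
identity. Normalization is idempotent, which the test suite asserts on
generated libraries. Input stereochemistry is preserved in the records and
never invented; the filters and the phosphorylation site logic are
stereochemistry-agnostic.

Unparseable entries are skipped, counted, and logged — a large vendor file
always contains a few rejects, and aborting on the first one would make the
funnel's first stage useless.

## Scaffold-tree filtering

"Natural-product-derived" is operationalized the way scaffold-tree methods
do it: a molecule's **ring scaffold** (Murcko framework: rings plus linkers,
side chains removed, exocyclic double-bonded atoms kept so that e.g. the
chromone carbonyl survives) is walked down to smaller **parent scaffolds**
by deleting one peripheral ring at a time — a peripheral ring shares at most
one bond with the rest of the ring system. A compound matches the scaffold
set when any scaffold in that chain canonically equals a set entry
(`exact-scaffold` mode), or, alternatively, when a set entry matches as a
substructure (`substructure` mode).

The shipped default set (benzene, biphenyl, naphthalene, indole, chromone,
flavone, coumarin, quinoline, purine, steroid tetracycle) is deliberately
small, documented, and replaceable through `scaffold_set()`: the scientific
content of a real campaign — which structural elements count as
natural-product-derived — is configuration, not code. The mechanism
(scaffold extraction, tree traversal, canonical comparison) is what the
package owns.

Two numerical choices in the traversal deserve a note:

* **Ring perception.** Rings are the shortest cycles through each cyclic
  bond, a superset of the SSSR that is stable and cheap; peripheral-ring
  analysis only needs ring membership of atoms and bonds, not a minimal
  basis.
* **Repair after ring deletion.** Deleting a ring can orphan aromatic bonds
  (e.g. removing the benzene of a tetralin). Aromatic bonds that no longer
  lie on an all-aromatic cycle are demoted to single bonds and the affected
  atoms topped up with hydrogens to standard valence — a *saturated repair*.
  Chemistry-aware scaffold-tree prioritization rules are intentionally not
  reimplemented; the traversal enumerates every peripheral deletion instead
  of choosing one canonical parent.

## The fragment filters

Stages run in the fixed order parse → scaffold → phenol → MW → reactive.
The pass set is an intersection, so it is independent of stage order (the
suite verifies this against independently computed per-stage predicates);
only the attributed *first failing stage* in the decisions table depends on
the order. Choices:

* **Phenol**: SMARTS `[OX2H][c]` — a one-hydrogen oxygen on an aromatic
  carbon. Catechols and polyphenols count and are reported; nothing excludes
  them by default.
* **Molecular weight**: average MW from standard atomic weights, implicit
  hydrogens included, computed before phosphorylation (the step order of the
  campaign) and gated strictly: MW < 500 g/mol passes, MW = 500 fails.
* **Reactive moieties**: a named, overridable electrophile exclusion set
  (Michael acceptor, aldehyde, alkyl/benzyl halide, epoxide, acyl halide,
  isocyanate, anhydride). The Michael-acceptor pattern is matched first so
  that an enal is attributed to the more specific class.

## Virtual O-phosphorylation

Each phenolic O-H is replaced by O-PO(OH)2, written as the
**neutral dihydrogen phosphate**: protonation states are a
docking-preparation concern, and engines assign charges downstream.
Multi-phenol fragments default to `enumerate-all-sites` with symmetric
de-duplication (hydroquinone yields one product, 4-methylcatechol two);
`first-site-only` and `error-on-multiple` policies are available because the
right multiplicity answer is campaign-specific. Products always satisfy:
exactly one phosphorus more than the parent, four more heavy atoms, a
monoisotopic mass gain of +79.96633 Da, and
`dephosphorylate(phosphorylate(x)) == normalize(x)` — the suite checks all
four over hundreds of generated fragments.

Implementation note: transforms are graph edits exchanged with OpenBabel as
MOL2 text, because MOL2 carries OpenBabel's aromaticity perception and
formal charges. MOL2 has no implicit-hydrogen field, and OpenBabel stops
refilling valence once any explicit hydrogen is present, so the internal
graphs are fully explicit-H and every edit maintains the hydrogen count
itself. Because the interchange carries no meaningful coordinates,
stereo descriptors cannot survive it: **edited structures (scaffolds and
phospho products) are emitted stereo-stripped**, while untouched library
records keep their input stereochemistry. For scaffold matching this is the
desired behavior; for product tables it is a documented limitation.

## Docking gateway and the mock engine

`docking_job_spec()` has **no default search box**: a docking grid is a
scientific decision tied to the receptor, so the configuration must supply
center and size. The external engine is a command template with
`{receptor} {ligand} {out} {center_x} ... {seed}` placeholders; per-ligand
failures are recorded, never fatal, and ligand order is preserved.

The mock engine exists so the full pipeline, including pose parsing and
triage, runs deterministically without any third-party binary. It places
the ligand's phosphorus (or first heavy atom) at the box center, its
covalent neighbors at 1.6 Å along the axes — so the phosphate group is
recoverable by the same covalent-range rule used on real poses — and the
remaining atoms on a 1.5 Å lattice away from the anchor. Scores are
`-(heavy atoms)/10 + 0.1 * (pose - 1)`: deterministic, non-decreasing in
pose rank, and dependent only on the input. Two runs from the same
configuration are byte-identical. The mock makes no claim of physical
realism; it exercises code paths with analytically predictable geometry.

## Distance triage

Pose models are searched for phosphate groups (each phosphorus plus the
oxygens within 1.9 Å — a generous covalent ceiling), and the minimum
pairwise distance from the selected phosphate atoms to each addressed
residue atom set is measured exactly (no tolerance: the suite compares
against a brute-force oracle). The default criteria require phosphate atoms
within 4.0 Å of Arg609 NH1/NH2/NE **and** of Lys591 NZ on chain A —
4.0 Å being a standard salt-bridge/hydrogen-bond contact ceiling. The
published campaigns' exact thresholds live in supporting material that is
not machine-readable here, which is precisely why every piece — residues,
atom names, chain, ceiling, ligand atom selector, pose policy — is
configuration: known criteria can be dropped in verbatim.

Residues are addressed by PDB **author numbering with an explicit chain**,
so labels like "Arg609" mean the same thing in the configuration and in the
literature. Alternate locations resolve to the highest occupancy (ties keep
altloc A); waters are excluded; coordinates are taken as exact file values.
Pass/fail uses unrounded distances with `<=`; reports print to 0.01 Å.

Ranking sorts passing ligands by engine score ascending, ties by smaller
sum of criterion distances, then ligand id — stable and total, so reruns
and reorderings cannot shuffle the report.

## Synthetic fixtures: what they do and do not show

`generate_library()` plants a known composition: phenolic scaffold-matching
fragments below 500 g/mol (templated decorated hydroxy-aryl cores), over-MW
phenols (long-chain decorations), reactive phenols (one default-set
electrophile each), non-phenolic scaffold matchers, and acyclics. Class
membership is provable by construction — templates, not random molecule
generation — and the seed only shuffles decorations and record order, so
recovering exactly the planted pass count is a sharp correctness check of
the whole filter stack. `generate_receptor_and_poses()` plants pose
geometry the same way: a minimal, explicitly non-physical receptor carrying
Lys591 NZ at the origin and Arg609 NH1 at (4, 0, 0), and ligands whose
nearest phosphate atom sits on the perpendicular bisector of those
nitrogens at exactly the planted distance (3.0 Å for passers, 8.0 Å for
failers by default, both safely on either side of the 4.0 Å ceiling).

What passing on fixtures does **not** show: that the default scaffold set
approximates any published natural-product classification, that the mock
scores correlate with binding, or that the 4.0 Å ceiling reproduces any
particular published hit list. Those depend on replaceable configuration
and on external engines. The fixtures validate mechanism, not chemistry or
biology — real screening data re-enters through the same interfaces
(`.smi`/SDF in, PDB receptor, PDBQT poses).

The test suite and the acceptance script run the planted-composition
checks at 1,000 compounds per seed (20 seeds in the suite), phosphorylation
invariants over 500 generated phenols, and the full mock-engine pipeline at
a few hundred compounds — sizes chosen so the whole suite completes in
about a minute on a laptop while every count remains exact.

## Pipeline bookkeeping

The six-stage funnel counts **parent compounds** at every stage: a parent
survives phosphorylation, docking, or triage when at least one of its
phospho products does. Site enumeration can legitimately produce more
products than parents, which would otherwise break the funnel's defining
monotonicity (`n_out <= n_in`, stages chaining); product-level counts stay
available in the per-stage artifact tables. Checkpoints hash stage inputs
(file content plus the relevant slice of configuration), so `--resume`
skips exactly the stages whose inputs are unchanged, and editing a
downstream threshold does not invalidate upstream work.

## Known limitations

* Scaffold content: the default set is a documented stand-in, not a
  published classification; supply your own `scaffold_set()` for a real
  campaign.
* Stereochemistry is stripped from edited structures (see above).
* The saturated repair after ring deletion does not reproduce
  chemistry-aware scaffold-tree rules (no prioritization, no
  retained-substituent rules).
* No PAINS or property filters beyond MW; no tautomer enumeration; no 3D
  conformer generation (delegated to the external engine's preparation
  tools).
* `min_distance` is exact but quadratic in atom-set sizes — appropriate for
  phosphate-versus-residue sets, not for whole-protein contact maps.
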