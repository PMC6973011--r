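# phosphoscreen

Library generation and pose triage for docking-based discovery of
phosphotyrosine-mimetic SH2-domain ligands.

SH2 domains bind phosphotyrosine through a positively charged pocket — in
STAT3, Lys591 and Arg609. A productive way to find small-molecule blockers
of that interaction is to start from **phenolic natural-product fragments**,
convert each phenolic O–H *in silico* into a dihydrogen phosphate ester
(O–PO(OH)₂), dock the phosphorylated library against the pocket, and keep
only poses that place the phosphate group in contact with the pocket's key
residues. `phosphoscreen` implements that campaign as a reusable,
configurable six-stage pipeline:

| stage | function | what it does |
|---|---|---|
| ingest | `read_compound_library()` | `.smi`/SDF → canonical, salt-stripped records |
| filter | `apply_fragment_filters()` | scaffold tree → phenol → MW < 500 → reactive moieties |
| phosphorylate | `phosphorylate_library()` | phenolic O–H → O–PO(OH)₂, site-enumeration policies |
| dock | `run_docking()` | pluggable engine: external command (e.g. AutoDock Vina) or deterministic mock |
| triage | `apply_distance_criteria()` | phosphate–residue minimum distances vs. configured ceilings |
| rank | `rank_hits()` | score, then contact-distance sum, then id |

Every scientific knob — the scaffold set defining "natural-product-derived",
the phenol SMARTS, the MW bound, the electrophile exclusion list, the
residues/atoms/ceilings of the distance criteria, the docking box — is
configuration, not code. A synthetic-fixture generator
(`generate_library()`, `generate_receptor_and_poses()`) plants libraries of
known composition and poses of known geometry, so the whole pipeline is
testable end-to-end with exact expected counts and no external data or
binaries.

Chemistry (SMILES parsing, canonicalization, SMARTS, masses, aromaticity)
is delegated to OpenBabel via the Bioconductor packages ChemmineR and
ChemmineOB; receptors are parsed with bio3d.

## Worked example

```r
library(phosphoscreen)

# a 1,000-compound synthetic library: 300 planted full-pass phenolic
# fragments, 200 over-weight, 150 reactive, 250 non-phenolic, 100 acyclic
gen <- generate_library(library_spec(seed = 7), "library.smi", "truth.tsv")
lib <- read_compound_library("library.smi")

res <- apply_fragment_filters(lib, filter_config())
res$funnel
#> screening funnel:
#>   parse         1000 ->      1000
#>   scaffold      1000 ->       900
#>   phenol         900 ->       650
#>   mw             650 ->       450
#>   reactive       450 ->       300
```

The funnel reads like a screening campaign's: each row is one filter, and
the 300 survivors are exactly the planted full-pass class (scaffold match,
≥ 1 phenolic hydroxyl, MW < 500 g/mol, no electrophile). Phosphorylation
then converts each survivor into its phosphate ester:

```r
prods <- phosphorylate_library(res$passed)
nrow(prods); mean(prods$mass_delta_mono)
#> [1] 300
#> [1] 79.96633
```

— one product per fragment here (single sites), each heavier by the
monoisotopic mass of HPO₃. Docking and triage run the same way against a
toy receptor with planted geometry (4 of 10 ligands in contact):

```r
fx  <- generate_receptor_and_poses(pose_fixture_spec(10, 4, seed = 7))
rec <- parse_receptor(fx$receptor_path)
poses <- lapply(names(fx$pose_paths),
                function(id) parse_pose_file(fx$pose_paths[[id]], id))
tr <- apply_distance_criteria(poses, rec, default_distance_criteria(4.0))
tr$funnel
#> screening funnel:
#>   distance_triage        10 ->         4
head(rank_hits(tr$hits)[, c("rank", "ligand_id", "score", "d_ARG609", "d_LYS591")])
#>   rank ligand_id score d_ARG609 d_LYS591
#> 1    1    lig002  -8.6 2.999949 2.999949
#> 2    2    lig004  -8.2 2.999949 2.999949
#> 3    3    lig005  -8.0 2.999949 2.999949
#> 4    4    lig010  -7.0 2.999949 2.999949
```

The four passing ligands are the planted ones, and their measured
phosphate–residue distances recover the planted 3.0 Å to within the
fixtures' coordinate resolution. `run_pipeline()` chains all stages from a
`pipeline_config()` (or a YAML file) with per-stage checkpoints and
`--resume`; the same pipeline is scriptable from a shell via the installed
entry point:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts/phosphoscreen", package="phosphoscreen"))') \
    make-fixtures --out fixtures --seed 7
```

Subcommands: `make-fixtures`, `filter`, `phosphorylate`, `dock`, `triage`,
`run-all`. For a real campaign, point the config at your own library, your
receptor PDB, your scaffold set, and an external engine command template —
the mock engine and fixtures are for validation only.

## Documentation

The methods vignette (`vignettes/phosphoscreen-methods.Rmd`) explains the
model and every design decision: the scaffold-tree traversal and its
ring-repair rule, the filter definitions and boundaries, the neutral-acid
phosphorylation convention, the mock engine's geometry, residue addressing,
and what passing the synthetic fixtures does and does not demonstrate.
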