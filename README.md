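# capriqa

Quality assessment of predicted protein–protein complexes with the CAPRI
protocol, as an R package.

## The problem

Blind docking experiments (and anyone benchmarking a docking or assembly
pipeline) need to decide, objectively, how close a predicted complex is to
the experimentally determined one. The community standard is the CAPRI
assessment protocol. For a model of a receptor–ligand complex it computes:

- **f(nat)** — the fraction of the target's residue–residue contacts
  (heavy-atom pairs within 5 Å) reproduced in the model, and **f(non-nat)**,
  the fraction of the model's contacts absent from the target;
- **L-rms** — backbone RMSD of the ligand over the common residue set after
  optimally superposing the receptor (Kabsch), with the residual ligand
  mis-orientation angle **θ_L** and centre-of-mass displacement **d_L**;
- **I-rms** — backbone RMSD of the interface residues (any heavy atom
  within 10 Å of the partner) after superposing those residues themselves;
- a **clash** count (cross-subunit atom pairs below 3 Å); models with more
  clashes than the submission population's mean + 2 SD are disqualified.

Models are then ranked into four tiers:

| tier | f(nat) | | L-rms | | I-rms |
|---|---|---|---|---|---|
| high (\*\*\*) | ≥ 0.5 | and | ≤ 1.0 | or | ≤ 1.0 |
| medium (\*\*) | ≥ 0.3 | and | ≤ 5.0 | or | ≤ 2.0 |
| acceptable (\*) | ≥ 0.1 | and | ≤ 10.0 | or | ≤ 4.0 |
| incorrect | everything else | | | | |

Homo-oligomeric targets complicate all of this: the "correct" interface may
be ambiguous (crystal contacts mimic small biological interfaces), identical
chains can be matched to the target in many ways, and a tetramer is only
right if *one* chain assignment reproduces all its interfaces at once.
capriqa handles this by enumerating candidate target interfaces (optionally
including crystal-symmetry images) ranked by buried surface area, scoring
every model subunit pair against every assessed interface over all
sequence-compatible chain assignments, and providing a simultaneous
multi-interface check for higher-order assemblies. A sequence-dependent
GDT_TS-style score assesses each subunit's own accuracy, and tally/report
functions aggregate per-target and per-group rankings. A seeded synthetic
generator builds toy dimers/tetramers and rigid-body decoys with closed-form
expected metrics, so the whole pipeline is testable without any external
data.

## Worked example

```r
library(capriqa)

# a synthetic C2 homodimer target and a perturbed decoy of it
target <- make_c2_dimer(make_subunit(30, "helix", seed = 2), 10)
decoy  <- make_decoys(target, list(decoy_spec(
  translation = c(0, 2, 3), angle = 8, axis = c(0, 1, 0))))$models[[1]]

m <- capri_metrics(decoy, target)
print(m)
#> CAPRI metrics: f(nat) 0.500, f(non-nat) 0.700
#>   L-rms 3.15 A, theta_L 8.0 deg, d_L 2.57 A, I-rms 1.49 A
#>   clashes 1
classify(m)
#> [1] medium
```

Half the native contacts survive the 3.6 Å displacement + 8° twist, and the
ligand RMSD of 3.15 Å (≤ 5) puts the model in the medium tier — it would
need f(nat) ≥ 0.5 *and* an RMSD under 1 Å for high. The oligomer-aware
route does the same through interface enumeration and chain matching:

```r
iff <- enumerate_interfaces(target, min_area = 2)
rec <- assess_model(decoy, target, interfaces = iff)
print(rec)
#> Assessment of model 't3.61_r8_n0' vs target 'synth-helix-30-c2'
#>   interface 1: medium     f(nat) 0.50, L-rms 3.15, I-rms 1.49
#>   best: interface 1 (medium)
```

For real data, `read_pdb()` reads (optionally gzipped) PDB files,
`generate_crystal_neighbors()` adds symmetry images from operators read
with `read_operators()`, `classify_batch()` applies population clash
disqualification, and `tally_groups()` / `summarize_target()` /
`write_report()` produce the ranking tables. A thin command-line wrapper is
installed at `inst/exec/assess` (subcommands `score`, `interfaces`,
`rank`, `gdt`, `synth`).

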