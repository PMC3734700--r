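# qmclust

Tools for modelling **enzymatic enantioselectivity with the quantum-chemical
cluster approach**: truncated active-site models treated at a high level of
theory, with truncation points locked at their crystallographic coordinates
and the missing protein replaced by a dielectric continuum.

The motivating system is an epoxide hydrolase that desymmetrizes a *meso*
epoxide: the nucleophilic water can attack either of two symmetry-equivalent
epoxide carbons (C1 or C2), giving the *S,S*- or *R,R*-configured diol. The
enantiomeric excess is then set entirely by the difference between the two
activation barriers. `qmclust` handles everything around the
electronic-structure calculation itself:

* **Cluster building** — select residues from a PDB structure, sever
  declared bonds, cap each cut with a link hydrogen, lock caps and
  attachment atoms (`build_cluster`, `place_cap_hydrogen`), add hydrogens
  from geometric templates with explicit protonation states
  (`add_hydrogens`), and derive point-mutant models from idealized
  side-chain templates that inherit the parent's chi1 torsion
  (`mutate_residue`, `apply_variant`).
* **QM job management** — engine-agnostic job specs with deterministic ids,
  a table-lookup engine for externally computed energies, and a closed-form
  toy engine for desk testing (`build_job`, `run_engine`,
  `parse_results_table`).
* **Energetics** — corrected total energies
  `E = E_el(sp) + ZPE(opt) + dE_solv + dE_disp`, activation barriers and the
  barrier difference `ddE = E‡(TS_C2) − E‡(TS_C1)` per variant
  (`total_energy`, `barrier`, `delta_delta_barrier`).
* **Selectivity** — transition-state-theory conversion
  `ddG = RT·ln[(1+ee)/(1−ee)]` and its inverse `ee = tanh(ddG/2RT)`,
  Boltzmann (Curtin–Hammett) weighting over TS ensembles, and a
  calculated-versus-experimental sign-agreement report (`ee_to_ddg`,
  `ddg_to_ee`, `boltzmann_ee`, `selectivity_report`). Sign convention:
  negative = *R,R*-favored.
* **Geometry diagnostics** — valence-angle probes (e.g. the nucleophilic
  O–C–O attack angle), Kabsch superposition, and stationary-point overlay
  consistency checks (`vec_angle`, `superpose`, `conformer_consistency`).
* **Fixtures & CLI** — a deterministic toy active-site generator
  (`generate_toy_site`) standing in for a crystal structure at desk scale,
  and a staged pipeline with one CLI verb per stage (`run_pipeline`,
  `qmclust_cli`).

## Worked example

The bundled example config wires the toy site, a ladder of six mutants
(two residues mutated in R1 up to four in R3/S3), a lookup table of QM
energy components, and experimental selectivities:

```r
library(qmclust)
cfg <- write_example_config()
res <- run_pipeline(cfg, out_dir = tempfile(), seed = 1)
res$barriers
#>   variant barrier_C1 barrier_C2 delta_delta
#> 1      WT       15.7       15.6        -0.1
#> 2      R1       14.3       13.1        -1.2
#> 3      R2       14.0       13.6        -0.4
#> 4      R3       15.3       14.3        -1.0
#> 5      S1       14.7       16.1         1.4
#> 6      S2       13.9       17.5         3.6
#> 7      S3       13.2       16.6         3.4
attr(res$selectivity, "summary")
#> [1] "sign agreement: 7/7 variants at T = 298.15 K"
```

`barrier_C1`/`barrier_C2` are the activation barriers (kcal/mol) for attack
at the two epoxide carbons; a negative `delta_delta` means the C2 pathway —
and hence the *R,R* product — is favored. The report compares each
calculated difference against the experimental value (converted from ee
where the experiment reports ee): here every variant's calculated
preference matches the experimentally observed enantiomer.

Converting selectivities by hand:

```r
ee_to_ddg(-0.14)   # 14% ee favoring R,R  -> -0.167 kcal/mol
ddg_to_ee(2.0)     # 2 kcal/mol S,S bias  -> ee 0.934
boltzmann_ee(ts_energies_RR = c(13.1, 13.9), ts_energies_SS = 14.3)
#> [1] -0.8103038  (R,R-favored: the lowest R,R TS lies 1.2 kcal/mol below)
```

## Command line

```sh
Rscript inst/scripts/qmclust make-fixture --seed 1 --out site.pdb
Rscript inst/scripts/qmclust report --config run.cfg --out results/
```

Verbs `build-model`, `mutate`, `jobs`, `barriers`, `report` run successive
prefixes of the pipeline; every output file records the config hash and
seed, and reruns are byte-identical under the lookup engine.

## File formats

* **Results table** (`parse_results_table`): whitespace-delimited with
  columns `job_id electronic_energy zpe solvation dispersion converged
  n_imag`, energies in kcal/mol.
* **Experimental table** (`read_experimental`): `variant ee_percent
  favored_product ddg` — each row uses either the ee pair or `ddg`.
* **Config** (`parse_config`): flat `[section]` / `key = value` text; see
  `write_example_config()` for a complete example.
* **Structures**: PDB (frozen/cap flags persisted in `REMARK 250 QMCLUST`
  records) and XYZ.
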