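# dynofp

Dynamic interaction fingerprints and activation-state analysis for
GPCR–ligand molecular-dynamics trajectories.

## What it does

Structural pharmacologists studying opioid receptors (and class-A GPCRs
generally) explain ligand affinity and efficacy differences through three
kinds of trajectory-derived evidence: how *often* each pharmacophoric
contact occurs, how *well* docking poses reproduce a reference binding
mode, and how much of the time the receptor spends in active-like,
intermediate, or inactive-like conformations. `dynofp` implements that
analysis layer as a tested R package:

- **Interaction detection** — per-frame geometric detectors for ionic
  contacts, hydrogen bonds, single-water-mediated hydrogen bonds,
  hydrophobic contacts, cation–π interactions and steric clashes, with
  every cutoff exposed in `interaction_criteria()`.
- **Occurrence statistics** — for monitored interactions, the percentage
  of frames with at least one positive event, per replicate and averaged
  over replicates (`occurrence_frequencies()`), single-pair occupancies
  (`pair_occupancy()`), and interaction-distance profiles with quartile
  summaries (`distance_profile()`).
- **Pose rescoring** — `evaluate_pose()` counts matched entries of a
  reference interaction fingerprint, `filter_constraint()` enforces a
  maximum distance (default 5.5 Å, inclusive) between the ligand's
  protonated ring amine and the D3.32 γ-carbon, and `rank_poses()` orders
  by score with ties broken by that distance.
- **Activation states** — the TM6 deflection `d` is the Cα–Cα distance
  between residues 6.31 (bottom of TM6) and 4.40 (bottom of TM4) in
  Ballesteros–Weinstein numbering. Against crystal-derived references
  `A` (active) and `I` (inactive), a frame is `active_like` if
  `d ≥ A − τ`, `inactive_like` if `d ≤ I + τ`, else `intermediate`
  (`τ = 0` by default). `tm5_tm6_bridge_occupancy()` reports the
  K5.39–E6.58 salt-bridge occupancy that couples TM5 to TM6 and opposes
  the activation-related TM6 outward movement.
- **Ballesteros–Weinstein numbering** — `assign_bw_numbers()` labels
  residues by constant offset from per-helix x.50 anchors
  (`anchor_table()`, built-ins for MOR/DOR/KOR/NOP), and
  `pairwise_identity()` provides global-alignment identity/similarity.
- **Synthetic ground truth** — `synthetic_spec()`, `generate_template()`
  and `render_trajectory()` build toy 7TM receptor–ligand systems whose
  contact occupancies, water bridges and state fractions follow exact
  or Bernoulli schedules, so every statistic above can be validated
  against known truth without running MD.

Structures are read from PDB (via bio3d), trajectories from DCD or a
plain CSV frame dialect (`frame,atom_index,x,y,z` in Å); configs are
YAML; reports are CSV/JSON. `inst/cli/dynofp.R` is a thin Rscript driver
(`simulate`, `analyze`, `poses`, `states` subcommands) over the same
functions.

## Worked example

Render a κ-opioid-receptor-like synthetic system with the built-in
occupancy schedule and recover it:

```r
library(dynofp)

spec <- synthetic_spec("KOR", n_frames = 1000, n_replicates = 5, seed = 42)
res  <- render_trajectory(generate_template(spec), spec)

occurrence_frequencies(res$replicates, schedule_definitions(spec))
#>   itype    ligand_group partner rep_1 rep_2 rep_3 rep_4 rep_5 mean_frequency
#> 1    PI morphinan_amine     138 100.0 100.0 100.0 100.0 100.0          100.0
#> 2    PI secondary_amine     209  12.5  12.5  12.5  12.5  12.5           12.5
#> 3    NI     carboxylate     227  63.3  63.3  63.3  63.3  63.3           63.3
#> 4    NI     carboxylate     200  15.7  15.7  15.7  15.7  15.7           15.7
#> 5    PI             227     297  45.6  45.6  45.6  45.6  45.6           45.6

tm5_tm6_bridge_occupancy(res$replicates[[1]])
#> [1] 45.6

state_fractions(res$replicates, schedule_state_reference(spec))
#> <state_profile> KOR
#>   frames: 5000
#>   active_like  intermediate inactive_like
#>          40.0          51.9           8.1
```

Row by row: the morphinan-amine–D3.32 salt bridge is present in every
frame (the anchor interaction of cationic opioid ligands); the ligand
carboxylate contacts K227^5.39 in 63.3 % of frames and the ECL2 lysine
in 15.7 %; the secondary amine reaches E209^ECL2 in 12.5 %. The TM5–TM6
bridge (K227^5.39–E297^6.58) is formed 45.6 % of the time, and the
receptor sits in the intermediate band of the TM6 deflection in 51.9 %
of pooled frames — the exact scheduled ground truth, recovered by the
full detection-and-counting pipeline rather than read back from the
generator.

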