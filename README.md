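# spla2kit

Trajectory analysis and free-energy/kinetics computations for interfacial
phospholipase simulations — human group IIA secreted phospholipase A2
(hGIIA sPLA2) bound to mixed phosphatidylcholine/phosphatidylserine
bilayers is the motivating system.

sPLA2 hydrolyzes the sn-2 ester bond of membrane phospholipids, and only
does so efficiently from a lipid interface. Two chemical mechanisms
compete for the hydrolysis step: a **single-water** pathway (one water,
activated by His47, attacks the ester carbon C while Ca²⁺ stabilizes the
oxyanion) and an **assisting-water** pathway (a second water relays the
proton between the nucleophile and His47). Deciding between them takes a
chain of analyses that this package packages as reusable, tested,
tibble-first R functions:

* **I/O** — multi-frame PDB/XYZ coordinates, two-column time series and
  WHAM-style umbrella metadata, into tidy trajectory tables
  (`read_structure()`, `read_timeseries()`, `read_umbrella_metadata()`).
* **Membrane interface** — upper-leaflet phosphate reference plane,
  per-residue penetration depth Δz = z̄(P) − z(cog), buried-residue
  hotspots (max-depth beyond the pooled x̄−σ band, merged along the
  sequence), in-plane density maps, residue–substrate minimum distances
  with a 5 Å shell rule (`reference_plane()`, `penetration_depth()`,
  `find_buried_hotspots()`, `density_map()`, `residue_min_distance()`).
* **Solvation** — radial distribution functions about an atom or bond
  midpoint, shell occupancies, coordination numbers, Shrake–Rupley SASA
  (`rdf()`, `shell_statistics()`, `coordination_number()`, `sasa()`).
* **Conformations** — geometric classification of catalytic microstates
  (d(Nδ–H) < 2.5 Å, d(C–O) < 4.0 Å, bridge < 2.5 Å; strict inequalities),
  H-bond occupancy, KDE clustering in the d(Nδ–C)/d(Ca–O) plane
  (`catalytic_distances()`, `classify_conformations()`,
  `cluster_microstates()`, `state_distance_summary()`).
* **Free energy** — self-consistent WHAM on umbrella windows with
  time-block equilibration diagnostics and barrier/ΔG extraction
  (`wham_solve()`, `time_block_check()`, `profile_features()`), with
  F(ξ) = −RT ln P(ξ) zeroed at its minimum.
* **Path finding** — climbing-image nudged elastic band on analytic
  surfaces, saddle verification by Hessian signature, CV projection
  (`neb_optimize()`, `verify_saddle()`, `project_path()`).
* **Kinetics** — Eyring conversions k = (k_BT/h)·exp(−ΔG‡/RT), turnover
  from specific activity, and the population-weighted two-pathway rate
  comparison with ΔΔG‡ = RT·ln(ratio) decomposed into population and
  barrier terms (`eyring_rate()`, `eyring_barrier()`,
  `kcat_from_specific_activity()`, `compare_pathways()`).
* **Residue energetics** — per-residue activation-energy contributions by
  point-charge residue deletion, ΔΔE_a = E_int(TS) − E_int(R), with the
  acid/base axis coordinate for display (`residue_deletion_scan()`,
  `axis_projection()`).
* **Synthetic data** — seeded generators for every input the pipeline
  consumes (membrane fixtures, active-site ensembles with planted state
  populations and distance laws, biased Monte Carlo umbrella windows,
  charge fixtures), so each stage is testable without the original
  simulations (`gen_membrane_trajectory()`,
  `gen_active_site_trajectory()`, `sample_biased_windows()`,
  `gen_charge_states()`).

Results come back as tibbles or light S3 objects with `tidy()`,
`glance()` and `autoplot()` methods.

## Worked example

From the experimental specific activity to the pathway comparison:

```r
library(spla2kit)

kcat <- kcat_from_specific_activity(33.9, molar_mass_kg_mol = 13.9)
round(kcat, 2)
#> 7.85
round(eyring_barrier(kcat), 2)
#> 16.91

compare_pathways(rbind(
  pathway_kinetics("single_water",    population = 0.75, barrier = 17.0),
  pathway_kinetics("assisting_water", population = 0.04, barrier = 19.0)))
#> Pathway comparison at 310.15 K
#>   single_water is 481-fold (~500) faster than assisting_water
#>   effective ddG  = +3.81 kcal/mol
#>     population term +1.81, barrier term +2.00 kcal/mol
```

An interfacial assay turning over at 33.9 μmol min⁻¹ mg⁻¹ (enzyme molar
mass 13.9 kg/mol) corresponds to k_cat ≈ 7.85 s⁻¹, i.e. an apparent
barrier of ≈16.9 kcal/mol — between the two computed pathway barriers.
Weighting each pathway's Eyring rate by the abundance of its productive
conformation makes the assisting-water route ~500× slower, an effective
barrier penalty of +3.8 kcal/mol, of which +1.8 comes from scarcity of
its reactant conformation and +2.0 from its higher intrinsic barrier.

Classifying a synthetic active-site ensemble and recovering its planted
structure:

```r
traj <- gen_active_site_trajectory(active_site_fixture_spec(n_frames = 1000),
                                   seed = 1)
rec <- classify_conformations(catalytic_distances(traj))
attr(rec, "populations")
#> # A tibble: 3 × 2
#>   label           fraction
#>   <chr>              <dbl>
#> 1 single_water       0.751
#> 2 assisting_water    0.042
#> 3 nonproductive      0.207

dplyr::filter(state_distance_summary(rec), distance == "d_ca_o_wat")
#> # A tibble: 3 × 5
#>   label           distance    mean    sd     n
#>   <fct>           <chr>      <dbl> <dbl> <int>
#> 1 single_water    d_ca_o_wat  3.59 1.44    751
#> 2 assisting_water d_ca_o_wat  4.79 0.242    42
#> 3 nonproductive   d_ca_o_wat  7.59 0.648   207
```

The planted 75%/4% state split and the water–Ca²⁺ distance laws
(3.6 ± 1.5 Å single-water, 4.8 ± 0.2 Å assisting-water) come back through
the full geometry → distances → classification pipeline.

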