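# dimerscope

Tools for predicting and characterizing **weak, transient protein
homodimers** — the kind formed by membrane-anchored small GTPases, whose
complexes are too short-lived to crystallize and too dilute to see in
solution. The package implements the computational arm of a
dock–filter–characterize–validate workflow:

- **Docked-pose clustering** (greedy-leader on interface Cα RMSD, with the
  conventional 5% enrichment cutoff) and three **empirical viability
  filters**: the interface must involve reactive (co-evolving or
  probe-predicted) residues and regular secondary structure, the
  effector-binding loop of each protomer must stay solvent exposed, and both
  lipid anchors must point to the same membrane face.
- **Interface metrics**: Shrake–Rupley solvent-accessible surface area and
  buried interface area ΔSASA = SASA(A) + SASA(B) − SASA(AB) (0.14 nm
  probe), hydrogen bonds (0.3 nm / 20° criterion), hydrophobic carbon–carbon
  contacts (0.38 nm), salt bridges, π-stacking, inter-monomer
  centre-of-mass distance d_COM, relative monomer orientation δ, and a
  quasi-symmetry score for homodimer interfaces.
- **Binding thermodynamics from a potential of mean force**: the mean force
  along d_COM is integrated to W(r), referenced to the flat unbound region
  (d_COM > 4.6 nm), and converted to a standard-state association constant
  via the 1-D radial configurational integral

  K_a = (1/V°) ∫_bound 4π r² exp(−W(r)/RT) dr,   V° = 1.661 nm³,

  with K_d = 1/K_a and ΔG_bind = RT ln(K_d / 1 M). Pointwise mean-force
  errors are propagated to K_d by parametric resampling.
- **Computational alanine scanning**: rigid side-chain truncation to Cβ plus
  a transparent pairwise interaction energy (Coulomb with distance-dependent
  dielectric ε = 4r, 12-6 Lennard-Jones), ranking interfacial residues by
  ΔΔE = E_mut − E_wt.
- **Residue co-evolution**: mutual information with average-product
  correction, z-standardized, with sequence weighting and gap masking;
  hotspot mapping onto structure gated by score (> 2.0) and solvent
  exposure. Precomputed coupling tables from external tools are read
  directly.
- **Spatial statistics**: Ripley's K / L(r) − r with isotropic edge
  correction, weighted mean curves, bootstrap group comparisons, and CSR /
  Thomas-process simulators — the machinery used for nanocluster analysis of
  immuno-EM gold-particle maps.
- **Synthetic-data generators** with known ground truth for every input
  class (ideal helical dimers with planted salt bridges and π-stacks,
  alignments with planted covarying columns, mean-force profiles of known
  well depth and hence known K_d, pose ensembles with planted clusters),
  so the whole pipeline is testable end to end without external data.

All lengths are nm (PDB I/O converts from Å), energies kcal/mol,
temperatures K, concentrations molar.

## Worked example

Build a synthetic helix homodimer with two planted inter-monomer salt
bridges (Lys101(A)–Glu107(B) and Glu98(A)–Arg97(B)), characterize its
interface, scan it, and estimate a binding constant from a noisy synthetic
mean-force profile constructed to have a true K_d of 5 mM:

```r
library(dimerscope)

fx <- build_helix_dimer(helix_dimer_plan())
d  <- fx$dimer
com_distance(d)                        # 1.05 nm
delta_sasa(d)$delta_total              # 7.64 nm^2 buried
salt_bridges(d)
#>   basic_chain basic_resid acidic_chain acidic_resid type distance
#> 1           A         101            B          107 K->E     0.32
#> 2           B          97            A           98 R->E     0.32

head(scan_interface(d)[, c("chain", "resid", "resname", "ddE", "rank")], 4)
#>   chain resid resname      ddE rank
#> 1     B   107     GLU 5.324618    1
#> 2     A   101     LYS 4.857544    2
#> 3     A    98     GLU 3.447307    3
#> 4     B    97     ARG 3.402292    4

depth <- depth_for_kd(5e-3)            # well depth giving true Kd = 5 mM
prof  <- synth_mean_force(pmf_plan(depth = depth, noise_sd = 0.5, seed = 1))$profile
est   <- kd_from_pmf(integrate_mean_force(prof), force_stderr = prof$stderr)
est
#> BindingEstimate: Kd = 0.00538 M (deltaG = -3.11 kcal/mol at 300 K), bound [2.60, 3.76] nm
```

The planted bridge partners top the alanine-scan ranking, and the noisy
profile recovers K_d = 5.4 ± 1.0 mM (ΔG_bind ≈ −3.1 kcal/mol) — a weak,
transient complex.

The full pipeline (synthesize or load poses → cluster → filter →
characterize → scan) runs from one config:

```r
res <- run_pipeline(list(seed = 2, out_dir = "run", n_poses = 100))
res$survivors          # 4 viable dimer models out of 6 major clusters
```

A thin command-line wrapper is included at
`inst/scripts/dimerscope.R` (`run`, `synth`, `pmf`, `ripley` subcommands).

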