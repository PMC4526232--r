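# dynallo

Force-distribution and entropy analysis of dynamic allostery in homodimeric
proteins.

Allosteric regulation does not always move atoms: in proteins such as the
catabolite activator protein (CAP), binding of the first effector barely
changes the mean structure of the second binding site yet lowers its affinity
by orders of magnitude. The coupling is carried by *fluctuations* — by how
ligand binding redistributes internal motions and inter-residue forces.
`dynallo` implements the analysis stack used to dissect this kind of dynamic
(entropic) allostery from molecular-dynamics-style data: coordinate
trajectories and per-frame inter-atomic pairwise forces. It is written for
computational structural biologists who have (or simulate) multi-replica
trajectories of a two-protomer system in several liganded states and want to
locate allosteric pathways and quantify entropic binding penalties.

## What it computes

**Residue-pairwise force networks (force distribution analysis).** From
atom-pair force vectors F<sub>ij</sub>, the residue-pair force is the norm of
the vector sum,

    F_uv = || Σ_{i∈u, j∈v} F_ij ||,

computed per frame and then averaged over time and over independent replicas
(time-averaged pairwise forces stay non-zero at equilibrium, unlike atomic
forces). Differences of these averages between liganded states,
ΔF<sub>uv</sub>, are thresholded (|ΔF| ≥ cutoff, in pN) and the largest
connected component of the resulting graph is the reported allosteric
network. The punctual stress S<sub>u</sub> = Σ<sub>v</sub> ⟨F<sub>uv</sub>⟩
and its protomer difference over replica subsets serve as the convergence
diagnostic.

**Configurational entropy.** Two estimators, both harmonic-approximation
based, differing in how mode frequencies are extracted:
quasi-harmonic (QH), ω<sub>k</sub> = √(k<sub>B</sub>T/λ<sub>k</sub>) from the
eigenvalues of the mass-weighted coordinate covariance, and force-covariance
(FC), ω<sub>k</sub> = √(μ<sub>k</sub>/k<sub>B</sub>T) from the mass-weighted
atomic force covariance. Each retained mode contributes the quantum
harmonic-oscillator entropy; state differences are reported as
−TΔS in kcal/mol with a bootstrap over replicas.

**Order parameters.** Methyl-axis S²<sub>axis</sub> from the second moments
of the axis unit vector (windowed, 3 ns default), and residue dihedral order
parameters S = ⟨cos χ⟩² + ⟨sin χ⟩², with before-minus-after state
differences (positive = flexibility gain).

**Collective motions.** PCA of the coordinate covariance, projections of
trajectories and structure sets onto eigenvectors, motion matrices
(differences of Cα–Cα distance matrices, fitting-free) and their Pearson
correlation, RMSF/B-factor conversion (B = 8π²/3 · RMSF²), and local RMSD
ensembles fitted on a 6 Å neighbourhood.

**Distance metrics.** Minimal inter-residue distances, state classification
by the inflection points of a reference distance distribution, hydrogen-bond
occurrence and residue-pair non-bonded (LJ + Coulomb) energies.

**Synthetic ground truth.** Because every one of these estimators needs
validation, the package ships a generator of C2-symmetric elastic-network
dimers: Gaussian ensembles drawn from the exact covariance
k<sub>B</sub>T·H⁺ of a known spring Hessian (so the analytic mode-spectrum
entropy is the true entropy), exact spring forces, ligand binding as added
springs, and planted inter-protomer pathway edges whose recovery can be
scored. All tests run against these analytic oracles.

## Worked example

Plant a two-edge inter-protomer pathway in a 20-residue-per-protomer dimer,
stiffen it by Δk = 400 kJ/mol/nm², and recover it from sampled forces:

```r
library(dynallo)

model <- build_enm_dimer(20, seed = 1)
chain <- pathway_chain(model, from = 1, to = 21)   # crosses the interface
model <- plant_pathway(model, data.frame(u = chain$u, v = chain$v, dk = 400))
perturbed <- perturb_pathway(model)

spec  <- ensemble_spec(n_replicas = 3, n_frames = 1000, temperature = 300, seed = 1)
ens_a <- sample_ensemble(model, spec, state = "apo")
ens_b <- sample_ensemble(perturbed, ensemble_spec(3, 1000, seed = 2), state = "holo")

tab_a <- average_table(residue_pair_forces(pairwise_forces_from_model(model, ens_a)))
tab_b <- average_table(residue_pair_forces(pairwise_forces_from_model(perturbed, ens_b)))
delta <- force_difference(tab_a, tab_b)
threshold_network(delta, cutoff_pN = 7)$edges
#>   label_u label_v delta_pN component
#> 1     A:1    A:10 13.52985         1
#> 2    A:10     B:1 14.02345         1
```

The largest component at a 7 pN cutoff is exactly the planted chain
A:1 – A:10 – B:1 (residue labels are `protomer:residue`; B is the second
protomer, the prime convention of homodimer work). Background pairs sit
around 1 pN, an order of magnitude below the planted signal.

Entropy estimators against the analytic ground truth of the same model:

```r
analytic_entropy(model)
#> entropy_result [analytic] selection=full T=300K
#>   114 modes, S = 2.83884 kJ/mol/K, -TS = -203.55 kcal/mol
quasi_harmonic_entropy(ens_a)
#> entropy_result [QH] selection=full T=300K
#>   114 modes, S = 2.83013 kJ/mol/K, -TS = -202.925 kcal/mol
force_covariance_entropy(atomic_forces_from_model(model, ens_a))
#> entropy_result [FC] selection=full T=300K
#>   114 modes, S = 2.82714 kJ/mol/K, -TS = -202.711 kcal/mol
```

Both estimates land within 0.5% of the analytic value at 3 × 1000 frames.
A full three-state (apo / one ligand / two ligands) run — networks at two
cutoffs, stress and convergence, entropy table, order-parameter differences,
projections, distance classification, with a provenance manifest — is one
call:

```r
run_pipeline(system.file("extdata", "demo_config.yaml", package = "dynallo"),
             out_dir = "dynallo_demo")
```

or from the shell via `Rscript inst/scripts/run_pipeline.R --config ... --out ...`.

## Limitations

The package analyses forces and coordinates; it does not run MD or
instrument an MD engine for pairwise-force output. The synthetic dimer is a
harmonic stand-in with Gaussian statistics — see the methods vignette
(`vignettes/dynamic-allostery.Rmd`) for what it does and does not emulate,
and for every numerical convention (mode retention, superposition groups,
bandwidths, unit system).
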