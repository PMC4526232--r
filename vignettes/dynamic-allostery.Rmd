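---
title: "Methods: force networks, entropy estimators and their synthetic ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: force networks, entropy estimators and their synthetic ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`dynallo` analyses dynamic allostery in homodimeric proteins from two kinds
of trajectory-derived data: Cartesian coordinates and inter-atomic pairwise
forces. This vignette documents the models and conventions behind each
analysis — the assumptions, the tunable parameters with their units and
defaults, the numerical choices, and what the bundled synthetic generator
does and does not emulate. Everything quantitative claimed here is computed
by the test suite or by `scripts/acceptance.R`; nothing is quoted from
elsewhere.

## Unit system

All internal quantities use nm, amu, kJ/mol, ps and K. This system is
self-consistent for dynamics (1 amu·nm²/ps² = 1 kJ/mol), so angular
frequencies from mass-weighted Hessians or covariances come out directly in
rad/ps. Forces cross the user boundary in pN
(1 kJ·mol⁻¹·nm⁻¹ = 1.66054 pN); distances in output tables are Å where the
structural-biology convention expects them (RMSF, B-factors, minimal
distances); entropic contributions are reported as −TΔS in kcal/mol at the
simulation temperature (default 300 K).

## The synthetic dimer: what it is and why

Every estimator in the package is validated against a system whose answers
are known exactly. The generator (`build_enm_dimer`) produces a C2-symmetric
dimer of compact, globular protomers: pseudo-atoms placed roughly uniformly
in a ball (golden-angle spiral), jittered with a seeded Gaussian
(sd 0.02 nm) that is applied to protomer A and mirrored, so the two-fold
symmetry is exact. All node pairs within the contact cutoff (default 1.2 nm)
are joined by harmonic springs (default k = 500 kJ/mol/nm²) whose
equilibrium length is the build-time distance — the model is an exact
stationary point of its own potential, and its mass-weighted Hessian defines
the analytic mode spectrum.

The compact geometry is a deliberate choice. An extended (helix-like)
protomer pair has ultra-soft hinge modes with displacement standard
deviations of ~0.5 nm at 300 K; at such amplitudes the spring forces are
strongly nonlinear and the harmonic-limit identities that the entropy
validation relies on break down by several percent. The ball geometry keeps
the softest mode's amplitude near 0.13 nm, where the exact forces stay
within a fraction of a percent of their linearisation.

Two granularities exist: one node per residue (default; sufficient for force
networks, entropy, motions) and four nodes per residue — N, CA, C and a
side-chain centroid — which adds backbone φ/ψ dihedral definitions and a
CA→side-chain pseudo-methyl axis per residue, so dihedral and axis order
parameters are computable. Side-chain dihedrals (χ) are only defined when a
topology supplies explicit quadruples, since a single centroid node cannot
carry a torsion.

**Sampling.** `sample_ensemble` draws displacements with the exact
covariance k_B·T·H⁺ (pseudo-inverse over the non-rigid modes). The default
sampler draws frames i.i.d.; this makes the analytic entropy the exact
entropy of the sampled distribution and decouples estimator testing from
integrator error. A Langevin option evolves each mode as an
exactly-discretised Ornstein–Uhlenbeck process with correlation time
γ/λ_k (friction γ default 2·10⁴ amu/ps), for analyses where time correlation
matters (windowed order parameters); its stationary covariance is identical.
All randomness flows from one integer seed through a fixed per-replica map
(`replica_seed`), so replica r is bitwise identical no matter how many
replicas are requested.

**Ligands and pathways.** Ligand binding is realised as a single extra node
attached by one spring per pocket residue (to the side-chain node where one
exists). An `attach = "both"` option grips side chain and backbone of each
pocket residue; this is the variant that measurably stiffens the pocket's
axis order parameters, because a hub connected only to side-chain tips
constrains their relative positions but barely their orientation relative to
the backbone. Planted pathways are residue-pair springs whose stiffness
differs by Δk between two states; `pathway_chain` designs them along
shortest contact-graph routes so an inter-protomer chain actually crosses
the interface.

**What the generator does not emulate.** No solvent, no anharmonic force
field, no barostat/thermostat artefacts, no conformational transitions, no
real protein geometry. Passing the validation suite therefore demonstrates
that the estimators are implemented correctly and converge on harmonic
ensembles — not that any particular real system satisfies their
assumptions.

## Force distribution analysis

The residue-pair force is computed per frame as the norm of the vector sum
of atom-pair forces between the two residues, and only then averaged — first
over frames within a replica, then unweighted over replicas (replicas are
equal-length independent runs). The alternative order (average the vectors,
then take the norm) discards the fluctuation contribution that makes
time-averaged pairwise forces non-zero at equilibrium; the per-frame-norm
order is the default and the basis of all downstream tables.

State differences ΔF_uv subtract mean tables entry-wise, treating pairs
absent from one state as zero; the residue universes must agree, so ligand
pseudo-residues are dropped (`include_ligand = FALSE`) when differencing
states with different ligand counts. Network edges use |ΔF| ≥ cutoff —
sign-insensitive, since the reported networks are undirected; the signed
table is preserved for reporting. Connected components are ordered by
residue count, ties broken by summed |ΔF| then by lexicographically smallest
residue label, making the "largest component" deterministic. The 40 and
50 pN presets are the standard cutoffs for all-atom force fields; synthetic
spring models produce gentler perturbations, so the demo config uses
proportionally smaller values.

The convergence diagnostic exploits the homodimer symmetry: for each
replica-subset size k, the per-residue punctual stress is recomputed from
the subset average and the mean absolute difference between C2-partner
residues recorded, averaged over all subsets (or a seeded random sample of
2000 when binomial counts explode). On a symmetric system this curve must
fall as sampling accumulates; a plateau above zero signals un-converged
force differences.

## Entropy estimators

Both estimators assume a harmonic system and differ only in frequency
extraction. QH: eigenvalues λ of the mass-weighted coordinate covariance
give ω = √(k_B·T/λ). FC: eigenvalues μ of the covariance of f_i/√m_i give
ω = √(μ/(k_B·T)); for a harmonic oscillator ⟨f²⟩/m = ω²k_B·T, so the two
coincide in the harmonic limit. Each retained mode contributes the quantum
harmonic-oscillator entropy
s(ω) = k_B[x/(eˣ−1) − ln(1−e⁻ˣ)], x = ħω/k_B·T — the quantum form, matching
the estimator literature the method descends from, though at protein-like
frequencies it is numerically close to the classical limit.

Numerical conventions, in the order they bite:

* **Superposition (QH).** Frames are least-squares fitted (mass-weighted
  Kabsch) onto the mean structure of the analysis selection, with the
  selection itself as the fit group, so the removed rigid-body variance is
  coherent with the retained modes. After superposition the six rigid-body
  directions survive as near-zero-variance modes — i.e. as the *largest*
  apparent frequencies — and are dropped by a relative eigenvalue floor of
  1e-9. A rank deficiency beyond six triggers a warning and the extra null
  modes are dropped too.
* **Rigid-body handling (FC).** Force sums over the whole system vanish
  identically (translations) but are orthogonal to rotations only to first
  order in the displacement; the quadratic remainder shows up as three
  spurious small-μ modes whose s(ω) is large. When the selection covers the
  whole system and reference coordinates are available, mass-weighted forces
  are therefore projected off the six rigid-body directions of the reference
  structure before the eigendecomposition; remaining zero-variance modes are
  dropped at a relative floor of 1e-10. On the validation dimer this changes
  the n = 1e5 relative error from several percent to under one percent.
* **Selections.** "mainchain" is N, CA, C, O; "protein" excludes heteroatom
  (ligand) pseudo-residues — the right choice when comparing states with
  different ligand counts, since entropies are extensive in the selection.
  Every result records its selection, and differences across selections are
  refused.
* **Uncertainty.** Results keep per-replica sufficient statistics (n, sums,
  crossproducts), so `entropy_difference` can bootstrap over replicas by
  re-pooling moments — no re-superposition or re-eigendecomposition of raw
  frames — and report a 95% band around −TΔS.

**Anharmonicity and the choice of the quartic toy.** The claim that
force-based frequencies tolerate anharmonicity better than coordinate-based
ones is regime-dependent, and the package's validation states the regime
precisely. For a *stiffening* symmetric quartic (V = k/2·x² + ε·x⁴, ε > 0)
exact quadrature against a finite-difference Schrödinger reference shows QH
is actually the less biased of the two at every ε — entropy depends only
logarithmically on the frequency, and ⟨x²⟩ is the better-behaved moment
there. The advantage of FC appears in the *multi-well* regime: a quartic
double well (V = −|k₂|/2·x² + ε·x⁴) with a barrier of a few k_B·T makes the
coordinate covariance conflate inter-well spread with softness, inflating
the QH entropy without bound as the wells separate, while the force
covariance keeps tracking the local curvature. The packaged toy
(`anharmonic_bias_experiment`) uses k₂ = −2500 kJ/mol/nm²,
ε = 20000 kJ/mol/nm⁴, m = 110 amu, T = 300 K — a ~7.8 k_B·T barrier — where
QH overshoots by ~+37% and FC undershoots by ~−21% of the exact quantum
entropy; the toy is sampled exactly (inverse-CDF of the Boltzmann density),
so the comparison has no integrator or sampling-bias confounder. This
two-state landscape, not the gently stiffened single well, is also the
caricature of a protein side chain hopping between rotamers.

## Order parameters

The axis order parameter of a unit-vector series is
S² = 3/2[⟨x²⟩² + ⟨y²⟩² + ⟨z²⟩² + 2⟨xy⟩² + 2⟨xz⟩² + 2⟨yz⟩²] − 1/2, the
standard second-moment form with the factor 2 on all three cross terms
(dimensional consistency with S² ∈ [0, 1] requires it). Trajectories are
superposed first (global rotation would otherwise depress S²), cut into
non-overlapping windows (default 3 ns), and the per-window values averaged
over windows and replicas. Windowing matters for slow exchange: for a
two-site jump process the windowed estimate exceeds the whole-trajectory
value, which is the motional-narrowing inequality the tests exercise. The
wobble-in-cone generator inverts S = cosθ₀(1 + cosθ₀)/2 to produce series
with a prescribed S², giving the estimator a closed-form oracle.

Dihedral order parameters use circular moments, S = ⟨cos χ⟩² + ⟨sin χ⟩²,
over the concatenated state ensemble (internal coordinates, no fitting);
per-residue values average the residue's defined dihedrals (φ, ψ, plus χ
where a topology defines them). The von Mises closed form
S = (I₁(κ)/I₀(κ))² is the oracle. State differences are reported as
S_before − S_after, so positive means flexibility gained after the event.

## Motions and structure metrics

PCA eigen-decomposes the coordinate covariance of the (superposed)
selection; eigenvector signs are fixed by making the largest-magnitude
component positive, and requesting more modes than frames−1 truncates with a
warning. Motion matrices are differences of Cα–Cα distance matrices —
internal coordinates, hence invariant to rigid placement of either
conformation — and are compared by Pearson correlation over the unique
off-diagonal entries (zero-variance input yields NA with a warning).
Eigenvector-derived motion matrices displace the mean by ±√eigenvalue
(configurable). RMSF converts to B-factors via B = 8π²/3·RMSF². Local RMSD
fits each frame on the residues within 0.6 nm of the target in the
reference (target excluded) before measuring the target's RMSD, so local
rearrangements are visible under arbitrary global motion; the reference
should be the average over all states so that state ensembles share a frame.

Distance-distribution classification smooths the reference sample with a
Gaussian kernel and finds the two inflection points flanking the dominant
mode. Two numerical points: curvature needs a wider bandwidth than density —
the detector uses the normal-reference n^(−1/9) rate (never below the
Silverman density bandwidth) — and the second derivative of the KDE is
evaluated analytically (f″ = 1/(nh³)·Σ(u²−1)φ(u)) rather than by finite
differences of the estimated curve, which are hopelessly noisy. For a
Gaussian reference the detected limits are μ±σ (widened by
√(1+(h/σ)²) from smoothing) and the three integrals come out
0.159/0.683/0.159. Explicit limits can be supplied to reproduce a published
interval convention, and are echoed in all outputs. Hydrogen-bond occurrence
defaults to donor–acceptor ≤ 3.5 Å plus a D–H···A angle ≥ 150° when
hydrogens exist; coarse models fall back to distance-only, flagged in the
result. Non-bonded pair energies use Lorentz–Berthelot combination and the
MD-unit Coulomb prefactor 138.935 kJ·mol⁻¹·nm·e⁻², no cutoff, dielectric
configurable (default 1).

## Pipeline, formats, provenance

`run_pipeline` drives the whole workflow from one YAML config with explicit
unit suffixes in field names (`temperature_K`, `cutoffs_pN`, `window_ps`) —
the analyses mix pN, kcal/mol, Å and ns, and silent unit mistakes are the
classic failure mode. Synthetic mode builds apo / one-ligand / two-ligand
states (the second pocket is the C2 image of the first) and writes force
tables, difference networks at the configured cutoffs (TSV plus a PyMOL
script), stress and convergence curves, an entropy table for both estimators
and both selections, order-parameter differences, mode-1 projections,
RMSF/B-factors and distance classifications, along with the model PDB, a
YAML ground-truth sidecar (labelled synthetic) and a manifest carrying the
config echo, its hash and the seed. Reruns with the same config are
byte-identical; numeric TSVs are written at 10 significant digits for that
reason. Trajectory-file mode validates all paths before any computation and
runs the coordinate-based analyses on externally supplied data.

On-disk formats are plain text and round-trip losslessly (17 significant
digits): a frame-per-block trajectory format, a pairwise-force format
(`frame <t>` headers, `i j fx fy fz` records, 1-based serials, i < j,
absent records meaning zero force), TSV edge lists with protomer-labelled
residues, and PDB via `bio3d` (serials are 1-based in files, 0-based
internally only at the parser boundary). The pairwise-force format is this
package's declaration — pairwise-force dumps have no standard on-disk form.

## Validation problem sizes

The acceptance checks run, per fresh seed: entropy recovery on a
40-node dimer at 10³–10⁵ frames (both estimators within 2% of the analytic
entropy at 10⁵); the double-well bias comparison at 2·10⁵ exact Boltzmann
samples; planted-pathway recovery on 20-residue-per-protomer dimers with
Δk = 400 over 20 seeds (detection cutoff set a priori at half the smallest
predicted pathway signal, computed from the exact model covariances — the
measured signal-to-background exceeds 20, recovery is complete and
contamination zero); order-parameter oracles at 10⁵ vectors/angles;
machine-precision checks on PCA reconstruction and motion-matrix
correlations; and the nine-replica convergence curve averaged over five
seeds. These sizes were chosen as the smallest at which the statistical
tolerances above are comfortably non-marginal.

## Known limitations

Pairwise forces are available only from models or from files — the package
does not instrument an MD engine. The FC estimator's rigid-body projection
needs reference coordinates and a whole-body selection; partial selections
fall back to the spectral floor alone. The entropy estimators inherit the
harmonic approximation's blindness to mode anharmonicity beyond what their
respective covariances capture, and the double-well analysis above shows
that neither estimator is uniformly superior. Dihedral definitions for
coarse models cover the backbone only. The classification detector assumes
a unimodal-dominant reference; pathological references should use explicit
limits.
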