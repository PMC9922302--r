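# idpgem

Generative ensemble modeling of intrinsically disordered peptides (IDPs)
in R: a residue-level coarse-grained (CG) simulator, a sequence-conditional
generative adversarial network (GAN) that emits C-alpha conformations
directly, and the complete metric suite for comparing conformational
ensembles.

## Who this is for

IDPs have no stable fold; their physical state is a broad conformational
ensemble that molecular dynamics (MD) samples only at substantial cost.
`idpgem` is for computational structural biologists who want to (1)
generate reference CG ensembles for peptides of 20-200 residues, (2)
train a conditional generative model that maps per-residue Gaussian
latents plus a one-hot sequence straight to 3D C-alpha coordinates —
sampling whole ensembles in a forward pass, with no kinetic barriers —
and (3) quantify how close two ensembles are.

## The models

**CG potential** (kJ/mol, nm), one bead per residue:

U = Σ ½·4184·(l−0.38)² + Σ ½·4.184·(θ−π)²
  + Σ 4(ε+ε_cπ)[(σij/r)¹⁰ − (σij/r)⁵] + Σ (A_iA_j + A0_iA0_j)·e^(−r/κ)/r

with per-residue radii from mean residue volumes, ε = 0.40/0.41 kJ/mol
(polar/non-polar), a 0.3 kJ/mol cation-π bonus for (R,K)×(F,Y,W) pairs,
A_i = sign(q_i)·√(0.75|q_i|) for charges q = ±1 (R/K, D/E), a polar
solvation repulsion A0 = 0.05, Debye length κ = 1 nm, 3 nm cutoff.
Langevin dynamics (BAOAB, friction 0.01/ps, 0.02 ps steps, 298 K) with
analytic forces in compiled code; the reference protocol runs five
independent 1000 ns trajectories saving frames every 200 ps.

**GAN**: a transformer generator G(z, a) with self-attention over
residues (one weight set for any length) against per-length
spectral-normalized MLP discriminators reading standardized pairwise
distances plus the one-hot sequence — E(3)- and reflection-invariant by
construction. Objectives: non-saturated (with a steric clash penalty
E_C weighted w_C = 0.3), hinge with top-k and coordinate-noise
annealing, and Wasserstein with gradient penalty. All networks and
backpropagation are plain R matrix code; no deep-learning framework is
required.

**Metrics**: contact-map log-MSE (MSE_c), mean-distance MSE (MSE_d),
average per-pair histogram Kullback-Leibler divergence (aKLD_d),
Hungarian-matched earth-mover's distance over dRMSD (EMD-dRMSD),
radius-of-gyration KLD (KLD_r), median CG energy difference (MED), PCA
potentials of mean force, and nearest-neighbor memorization searches.
C-alpha pseudo-torsion tools (a trained handedness selector and mirror
correction) and a sampling-efficiency benchmark round out the suite.

## Worked example

```r
library(idpgem)
ff <- forcefield_parameters()

# a 20-residue charge-block peptide: EEEEEKKKKKEEEEEKKKKK
seq <- make_fixture_sequences("charge_blocks", 20)[[1]]

# short reference simulation: 5 runs x 10 ns, frames every 200 ps
ens <- reference_protocol(seq, ff, scale = 0.01, seed = 1)
n_frames(ens)
#> [1] 250
mean(rg_values(ens))
#> [1] 1.184306
cg_energy(get_frame(ens, 1), seq, ff)
#> bond 26.3008 + angle 22.8757 + short -8.8183 + long -1.4776 = 38.8806 kJ/mol
```

Overall dimensions resemble a neutral polymer (mean radius of gyration
1.18 nm, essentially the poly-alanine value), but the contact structure
is sequence-specific: at sequence separations of five or more,
opposite-charge (E-K) pairs are in contact about three times as often as
same-charge pairs (0.024 versus 0.008 in a 5,000-frame reference run),
an asymmetry absent in poly-alanine — the pattern a conditional
generator has to learn. Training the tiny-preset GAN on such data and
comparing 1,000 generated conformations against a held-out trajectory:

```r
data <- list(reference_protocol(seq, ff, scale = 0.2, seed = 1))  # 5000 frames
cfg  <- training_configuration(preset = "tiny", seed = 1)
model <- train_gan(data, cfg)
gen <- sample_ensemble(model, seq, 1000, seed = 2)
metric_report(data[[1]], gen, seq, ff)
```

prints the six-score record; values near zero mean the generated
ensemble is statistically close to the simulation (see the methods
vignette for what each score measures and typical desk-scale values).

A thin command-line interface wraps the same functions
(`inst/cli/idpgem.R`): subcommands `fixtures`, `simulate`, `train`,
`generate`, `evaluate`, `benchmark`.

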