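---
title: "Generative ensemble modeling of disordered peptides: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generative ensemble modeling of disordered peptides: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(idpgem)
```

# Overview

`idpgem` couples three components around a single data model (sequences,
C-alpha conformations, conformational ensembles, all coordinates in nm):

1. a residue-level coarse-grained (CG) force field with a Langevin
   simulator, the source of reference and training ensembles;
2. a sequence-conditional generative adversarial network (GAN) that emits
   C-alpha conformations directly from per-residue Gaussian latents;
3. an ensemble-comparison metric suite plus chirality post-processing and
   a sampling-efficiency benchmark.

Intrinsically disordered peptides (IDPs) are the target system: they lack
a stable fold, so their physical state is a broad conformational
ensemble, and any generator must be judged distributionally, not against
a single structure.

# The coarse-grained model

Each residue is one bead at the C-alpha position. The potential has four
terms (energies kJ/mol, lengths nm):

* harmonic bonds, $\tfrac12 k_{bond}(l - l_0)^2$ with
  $k_{bond} = 4184$ kJ mol$^{-1}$ nm$^{-2}$, $l_0 = 0.38$ nm;
* harmonic angles, $\tfrac12 k_{angle}(\theta - \pi)^2$ with
  $k_{angle} = 4.184$ kJ mol$^{-1}$ rad$^{-2}$;
* a 10-5 contact term over non-bonded pairs ($|i-j| \ge 2$, 3 nm cutoff,
  minimum image), $4(\varepsilon + \varepsilon_{c\pi})
  [(\sigma_{ij}/r)^{10} - (\sigma_{ij}/r)^5]$ with
  $\sigma_{ij} = \sigma_i + \sigma_j$, per-residue well depths 0.40
  (polar) / 0.41 (non-polar) kJ/mol and a cation-pi bonus of 0.3 kJ/mol
  for (R,K) x (F,Y,W) pairs;
* a screened long-range term $(A_iA_j + A0_iA0_j)\,e^{-r/\kappa}/r$ with
  $A_i = \mathrm{sign}(q_i)\sqrt{0.75\,|q_i|}$ ($q = +1$ for R/K, $-1$
  for D/E), and a polar-solvation repulsion $A0_i = 0.05$ for polar
  residues.

Choices the model definition leaves open, fixed here and overridable via
`forcefield_parameters()`:

* **Pair well depth.** The depths are stated per residue class; the pair
  value is the arithmetic mean of the two per-residue values, which
  reproduces the $-\varepsilon$ minimum at $r = 2^{1/5}\sigma_{ij}$ for a
  like pair.
* **Radii.** $\sigma_i$ is the radius of a sphere with the mean residue
  volume (a standard volume table shipped as
  `extdata/residue_volumes.csv`), e.g. $\sigma_A = 0.277$ nm.
* **Polarity split.** Polar = {R,K,D,E,N,Q,H,S,T,Y,C,W}; non-polar =
  {A,V,L,I,P,F,M,G}.
* **Screening length.** $\kappa = 1.0$ nm, a physiological Debye length.
* **Exclusions.** Only directly bonded pairs ($|i-j| = 1$) are excluded
  from non-bonded terms; angle partners ($i, i+2$) interact non-bonded.
* **Masses.** Uniform 110 g/mol (average residue mass); equilibrium
  ensembles are mass-independent.

The model is achiral: the energy is invariant under reflections (a tested
property), which is why generated C-alpha traces need no handedness until
one models chiral (all-atom-derived) data.

# Simulation protocol

`langevin_simulate()` integrates Langevin dynamics with the BAOAB
splitting (any scheme passing the equilibrium-distribution tests would
do; BAOAB has small configurational bias at these time steps). Defaults:
friction 0.01 ps$^{-1}$, 0.02 ps production timestep, 298 K, frames
every 200 ps, a 300 nm cubic box with minimum-image convention, 5000
steepest-descent minimization steps and 20,000 equilibration steps at
0.01 ps. `reference_protocol()` runs five independent trajectories of
1000 ns each (25,000 frames at full scale) from fresh self-avoiding-walk
starts; `scale` shrinks each run proportionally while preserving the
200 ps frame spacing. The self-avoiding walk (bond 0.38 nm, all pair
distances at least 0.38 nm, at most 1000 rejection retries per bead) is
a pragmatic initializer; any non-overlapping start would serve.

At the low friction used, instantaneous kinetic energy decorrelates on
the $1/\gamma = 100$ ps scale, so equilibrium estimators built on a
single short trajectory carry percent-level sampling noise; the package's
own validation therefore averages replicate dimer runs (20 x 5e5 steps)
when checking equipartition and the quadrature bond-length oracle.

# The adversarial model

The generator is a transformer: per-residue inputs are the latent rows
$z_i \in \mathbb{R}^{n_z}$ and one-hot residue identities, embedded
linearly, summed with sinusoidal position encodings, processed by
post-LayerNorm self-attention blocks (pre-LN available), and mapped
position-wise to 3D coordinates. Because attention spans all positions,
one set of weights serves any chain length. Two additions address how a
small network turns i.i.d. per-residue noise into the *global*
fluctuation modes a polymer ensemble needs: every position also receives
the chain-mean of $z$ as extra channels (a global latent summary), and
each block plus the output head re-reads the latent directly, a short
path that the trunk normalizations cannot attenuate.

The head emits per-residue *displacement vectors* accumulated along the
chain into coordinates (`head_mode = "displacement"`). This
parameterization matters at small scale: emitting absolute coordinates
makes the mean structure easy but global fluctuations hard, and tiny
models mean-collapse (generated radius-of-gyration spread an order of
magnitude below the data); displacement accumulation is a random walk at
initialization, so ensemble diversity is the default and training only
has to shape it. An exponential moving average of the generator weights
(decay 0.999) is kept during training and used for sampling, a standard
variance reduction for adversarial generators. Both choices are
configurable; `head_mode = "absolute"` reproduces the plain
coordinate-emitting head.

Discriminators are per-length MLPs on E(3)-invariant features: the
flattened upper triangle of the distance matrix, standardized per
sequence separation $k$ by the training-set mean and standard deviation
($s_k$ floored at $10^{-4}$ nm), concatenated with the flattened one-hot
sequence; three spectral-normalized affine layers (one power iteration
per step), leaky rectifiers (slope 0.2), sigmoid in probability mode.
Distance features make training invariant to rigid motions *and*
reflections, matching the achiral CG model; an optional pseudo-torsion
augmentation (`use_torsions`) breaks reflection invariance for chiral
data.

Three objectives are implemented and share the clash term
$E_C = \sum_{|i-j|\ge 3} \max(x_t - x_{ij}, 0)$, weighted by
$w_C = 0.3$ in the generator loss; $x_t$ defaults to 0.59 nm, or is
estimated from training data as the 0.001 quantile (linear
interpolation) of non-bonded distances:

* `nonsaturated`: $L_D = -\mathbb{E}\log D(x) - \mathbb{E}\log(1-D(G(z)))$,
  $L_G = -\mathbb{E}\log D(G(z)) + w_C \mathbb{E} E_C$;
* `hinge_topk`: hinge discriminator loss; the generator term keeps the
  $\lceil \nu B \rceil$ highest-scoring fakes, $\nu$ decaying by
  $\gamma = 0.99$ per epoch (floor: one sample), with coordinate noise
  $\sigma_0 = 0.025$ nm on the real data annealed linearly to zero over
  the first quarter of the epochs;
* `wasserstein_gp`: critic loss with gradient penalty $\lambda = 10$ and
  five critic iterations per generator step. The penalty's weight
  gradient is computed analytically for the piecewise-linear critic
  (exact almost everywhere) and is finite-difference tested.

Optimization uses one Adam per network ($\beta_1 = 0$, $\beta_2 = 0.9$;
learning rates 0.00025 / 0.0004). Training epochs follow the crop plan:
each sequence maps to the nearest crop length (`L_train` = 20, 50, 80,
110 at full scale; ties to the smaller length), random re-sampling tops
every length up to exactly `c_max` assignments, and each assignment
contributes `n_frames` randomly sampled frames with fresh random crop
offsets — a data-augmentation scheme. Batches contain one crop length
only.

All networks, backpropagation, spectral normalization and Adam are
implemented in base R matrix code; there is no deep-learning framework
dependency anywhere in the package.

## The tiny preset

Full-scale training (thousands of sequences, 7.5M frames/epoch, 50
epochs) is a GPU-scale undertaking. The `tiny` preset keeps every loss
definition and only shrinks sizes: $n_z = 8$, 2 blocks, $d_{model} = 32$,
4 heads, MLP hidden widths 64. Desk-scale studies train on two L = 20
fixture peptides — poly-alanine (a random polymer without
sequence-specific interactions) and an E/K charge-block peptide
(charge-segregated: opposite-charge residue pairs contact several times
more often than same-charge pairs at equal separation, while overall
dimensions stay polymer-like)
— using four of the five reference trajectories (4,000 frames per
peptide), holding out the fifth for evaluation. The validation recipe
uses batch 16 (at fixed data volume the update count, not the batch
size, limits convergence: batch 64 over the same frames stalls at twice
the divergence), 1,750 frames per sequence per epoch and 30 epochs,
about 3-4 minutes per run on one CPU core. This reaches per-pair
distance divergences (aKLD_d) around 0.07-0.15 and radius-of-gyration
divergences (KLD_r) around 0.06-0.23 against held-out simulation, with
under 1% of non-bonded distances below the clash threshold.

What passing at this scale does and does not show: it demonstrates that
the full pipeline — simulation, featurization, adversarial optimization,
clash control, metric evaluation — is correct and that the conditional
model separates two sequence classes; it does not demonstrate
transferability to unseen sequences or lengths, which requires the
full-scale data diversity.

One full-scale phenomenon does *not* reproduce at desk scale: the
clash-term ablation. At full scale, removing the stereochemical term
leaves most metrics intact but floods the ensembles with close contacts
(a median-energy blow-up). At desk scale the `w_C = 0` ablation roughly
doubles the clash fraction (to ~1%) but nothing like the full-scale
contrast: the per-length discriminators already see every standardized
pair distance of these short chains and suppress clashes on their own,
and the displacement head's local geometry is easy to match. With the
absolute-coordinate head the ablation even produces *zero* clashes —
its mean-collapsed samples sit at clash-free average distances. The
clash term remains in the default objective (it measurably lowers the
clash fraction and deep-contact tail) but its desk-scale effect is
modest by construction.

# Evaluation metrics

All metrics compare a generated against a reference ensemble and are
distance-based, hence E(3)- and reflection-invariant:

* **MSE_c** — mean squared difference of log contact frequencies
  (8 A threshold; pseudo-count 0.01 for zero frequencies).
* **MSE_d** — mean squared difference of mean pair distances (nm²).
* **aKLD_d** — mean over pairs of a 50-bin histogram KLD (pooled
  min-max range, pseudo-count 0.001 substituted without renormalizing,
  natural log), reference distribution first.
* **EMD-dRMSD** — Hungarian assignment between equal-size (seeded)
  subsamples minimizing total dRMSD; the mean matched dRMSD is reported.
  Exact assignment is used up to the default cap of 1,000 conformations;
  the assignment cost matrix uses a Gram-product factorization, and
  matched pairs are re-evaluated exactly.
* **KLD_r** — histogram KLD of radius-of-gyration samples.
* **MED** — median generated minus median reference total CG energy.
* **PCA PMFs** — free energies $-k_BT\ln f$ on a 40x40 grid over the
  first two principal components of the *reference* distance features;
  empty cells are missing, not infinite.
* **Memorization search** — per generated conformation, the nearest
  training-set neighbor by dRMSD after cropping to a common length.

Numerical conventions worth stating: natural logarithms wherever a bare
log appears; histogram bin edges span the closed pooled range with the
right-most bin closed; a degenerate (zero-width) range returns a KLD of
0 with a warning; pseudo-counts substitute zeros without renormalizing
the remaining bins (the literal reading of the rule).

# Chirality

`ca_torsions()` computes dihedrals over consecutive C-alpha quadruplets
with the sign convention pinned by the quadruplet
(0,0,0),(1,0,0),(1,1,0),(1,1,1) giving $+\pi/2$; collinear triples give
`NA`. The handedness selector embeds each torsion as its sine/cosine
pair, reuses the generator-style transformer trunk with a mean-pooled
logistic head, and trains on conformations paired with their mirror
images. `select_mirror_image()` keeps a conformation scored at or above
0.5 (ties keep) and otherwise returns its reflection — which never
changes any interatomic distance. Training on synthetic chiral traces
(internal-coordinate builds with torsion-sign bias) stands in for
all-atom-derived ensembles, which are outside this package's scope.

# Sampling-efficiency benchmark

`kld_r_convergence_trace()` tracks KLD_r of a growing sample against a
fixed long reference; `detect_plateau()` stops at the first point whose
running-minimum divergence is not improved (absolute tolerance $10^{-3}$,
a noise allowance the rule itself needs) by any point within the next
`window` = 1000 samples; `simulator_crossing_time()` finds the first
simulator prefix *strictly* better than the plateau value. Wall-clock
times are recorded but never asserted in tests — they are hardware
facts — so the logic is validated on scripted traces.

# Reproducibility

Every stochastic operation draws from an isolated seeded stream that
leaves the session RNG untouched; C++ simulation streams derive their
seeds from the R-side stream. Fixed seeds give bit-identical
trajectories, training logs, weights and samples. Checkpoints
(`save_checkpoint()`) are self-describing containers with weights,
architecture numbers, standardizer tables and a configuration hash.

# Known limitations

* The per-residue radii and polarity table are reconstructed from the
  stated rules, not from published numbers; absolute energies shift
  accordingly (all comparisons here are internal to one parameter set).
* The tiny GAN is validated on two fixture peptides; conditional
  transfer to arbitrary sequences is a full-scale property.
* EMD-dRMSD at the default cap is an estimate of the 10,000-conformation
  assignment; its value depends mildly on the subsample seed.
* The Wasserstein mode's gradient penalty ignores the measure-zero
  activation-kink set of the piecewise-linear critic.
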