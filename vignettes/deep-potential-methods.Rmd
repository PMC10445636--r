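---
title: "Deep Potential models in deeppotr: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep Potential models in deeppotr: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deeppotr)
```

## The model

A Deep Potential is a neural-network interatomic potential.  Each atom $i$
contributes an atomic energy
$E_i = \mathcal{F}\!\left(\mathcal{D}(\mathbf{r}_i, \{\mathbf{r}_j\}_{j \in n(i)})\right)$,
where $n(i)$ are the neighbors within a cutoff $r_c$, $\mathcal{D}$ is a
symmetry-respecting descriptor of the local environment and $\mathcal{F}$ a
fitting network.  The frame energy is the atomic sum
$E = \sum_i E_i$, forces are $F_{i\alpha} = -\partial E/\partial r_{i\alpha}$
and, under periodic boundary conditions, the virial is the cell derivative
$\Xi_{\alpha\beta} = -\sum_\gamma (\partial E/\partial h_{\gamma\alpha})\,h_{\gamma\beta}$
at fixed fractional coordinates.  Because the energy depends on coordinates
only through minimum-image pair vectors, the package evaluates the virial
equivalently as
$\Xi = -\sum_p (\partial E/\partial \mathbf{r}_p) \otimes \mathbf{r}_p$
over ordered neighbor pairs — this is what the cell-strain finite-difference
tests check.  Energies are in eV, lengths in Å, forces in eV/Å; no unit
conversion happens anywhere in the package.

All differentiable quantities ride on a small reverse-mode autodiff tape of
matrix primitives (`R/autodiff.R`).  Training gradients of force and virial
losses need mixed second derivatives
$\partial^2 E/\partial\theta\,\partial\mathbf{r}$; these are computed
exactly by forward-over-reverse differentiation: the directional derivative
(JVP) of the energy along the loss cotangent is itself built out of tape
primitives and then reverse-swept.  No finite differences enter any
gradient used in training.

## The switching function

All smooth descriptors are built on
$$s(r) = \begin{cases} 1/r, & r < r_s,\\
\dfrac{1}{r}\left[x^3(-6x^2 + 15x - 10) + 1\right], & r_s \le r < r_c,\\
0, & r \ge r_c,\end{cases} \qquad x = \frac{r - r_s}{r_c - r_s},$$
which is continuous up to the second derivative everywhere, including at
$r_s$ and $r_c$.  This regularity is what makes forces and virials of the
smooth descriptors continuous as atoms cross the cutoff; it is verified by
finite differences in the acceptance suite.  The same quintic bracket (the
polynomial without the $1/r$ prefactor) reappears as the interpolation
weight of the pairwise-potential blend, so that blend is also $C^2$.

## Descriptors

* **`loc_frame`** — rows $(1/r_{ij},\, x_{ij}/r_{ij}^2,\, y_{ij}/r_{ij}^2,\,
  z_{ij}/r_{ij}^2)$ in a per-atom frame built by Gram–Schmidt from the two
  nearest neighbors (ties broken by atom index, species ignored).  It is
  rotation-invariant but *not* smooth: the descriptor jumps when the two
  nearest neighbors exchange ranking or when a neighbor crosses the cutoff.
  The package keeps it for completeness and the tests document the
  discontinuity rather than hide it.
* **`se_e2_a`** — the smooth two-body embedding descriptor
  $D_i = \frac{1}{N_c^2}\,G_i^{\mathsf T} R_i R_i^{\mathsf T} G_i^<$, where
  the rows of $R_i$ are $s(r_{ij})\,(1, \hat{\mathbf r}_{ij})$ and each row
  of $G_i$ is an embedding network applied to $s(r_{ij})$.  $G_i^<$ keeps
  the first $M_<$ (`axis_neuron`) columns.
* **`se_e2_r`** — radial-only variant, $D_i = \frac{1}{N_c}\sum_j (G_i)_j$.
  Padded neighbor slots contribute the zero-input embedding of their
  species block, so a departing neighbor ($s \to 0$) fades continuously
  into the padding value; this preserves smoothness at the price of an
  $N_c$-dependent constant offset, which the fitting network absorbs.
* **`se_e3`** — three-body embedding:
  $D_i = \frac{1}{N_c^2} (R_i R_i^{\mathsf T}) : G_i$ with
  $(G_i)_{jk}$ an embedding of the angular scalar
  $(\theta_i)_{jk} = (R_i)_j \cdot (R_i)_k$.  Padded rows of $R_i$ are zero,
  so padding vanishes from the contraction exactly.
* **`se_atten`** — the attention-based descriptor.  The two-body embedding
  (with type embeddings of center and neighbor appended to the input) is
  refined by `attn_layer` scaled-dot-product attention layers whose weights
  are softmax$(QK^{\mathsf T}/\sqrt{d_k})$ gated element-wise by
  $\hat R \hat R^{\mathsf T}$ (normalized direction overlaps), followed by a
  residual layer-norm update.  Design choices where the printed formulas are
  silent: softmax is taken first and rows are not re-normalized after
  gating; layer normalization acts over the feature axis with learnable
  scale and shift; the value width equals the embedding width $M$ so the
  residual addition is shape-consistent; $\hat G^<$ takes the leading
  columns of the *post-attention* embedding.  Padded slots never enter the
  attention because per-atom computations index real neighbors only —
  equivalent to giving padded slots $-\infty$ logits and zero gating.
* **`hybrid`** — concatenation of child descriptors in configuration order,
  each with its own cutoff and neighbor list.

For multiple species the embedding parameters are routed per
(center, neighbor) species pair ($N_t^2$ networks), per neighbor species
($N_t$ networks), or shared through a type embedding, in which case the
one-hot species index is mapped to a learned vector that is appended to the
embedding (and optionally fitting) inputs.

The environment matrix is used raw — no mean/standard-deviation shift is
applied to $s(r)$ or the descriptor.  This is a deliberate simplification;
its practical consequence is that descriptor magnitudes are small and the
fitting network's first layer must learn an amplification, which makes
training slower than it would be with input standardization (see the
training section for the schedule chosen to compensate).

## Fitting heads

The scalar (energy) head is one network per species, or a single shared
network with the type embedding appended.  Optional per-atom parameters
(`numb_aparam` columns) and per-frame parameters (`numb_fparam`, broadcast
over atoms) are appended to the descriptor.  Before training, the final
bias of each species' fitting network is initialized from a least-squares
fit of frame energies against species counts, so initial predictions start
on the label scale — standard practice, chosen here because it removes a
large, trivially removable component of the initial loss.

Tensor heads reuse the two-body embedding intermediates: with
$B = G_i^{\mathsf T} R_i$ and its directional columns $B_{[2:4]}$, the
vector head is $T^{(1)}_i = \frac{1}{N_c} \mathcal{F}_1(D_i)\, B_{[2:4]}$
and the matrix head
$T^{(2)}_i = \frac{1}{N_c^2} B_{[2:4]}^{\mathsf T}\,\mathrm{diag}(\mathcal{F}_2(D_i))\,B_{[2:4]}$.
Equivariance (vector: $T \to TU$; matrix: $T \to U^{\mathsf T} T U$) holds
by construction; the matrix head is symmetric because the fitting output
enters both sides of the contraction.

## Range correction, long-range electrostatics, pair interpolation

**DPRc** marks each atom `QM` or `MM`.  The switching function is zeroed
for MM–MM pairs — so forces between MM atoms vanish identically — and MM
atoms have the vacuum image of their fitting network, $\mathcal{F}(0)$,
subtracted, so an isolated MM atom contributes exactly zero energy.

**DPLR** adds a reciprocal-space electrostatic energy of Gaussian-smeared
charges,
$E_{\mathrm{ele}} = \frac{k_e}{2\pi V} \sum_{m \ne 0,\ \|m\| \le L}
\frac{e^{-\pi^2 m^2/\beta^2}}{m^2} |S(m)|^2$, with the structure factor
summing ionic charges at atom positions and Wannier-centroid charges at
positions predicted by a dipole tensor model.  Decisions: the squared
structure factor is read as the complex modulus squared (the energy must be
real); the wave-vector set is the integer triples of the reciprocal-lattice
basis with $\|m\| \le L$, both signs included; and an explicit Coulomb
constant ($k_e = 14.399645$ eV·Å·e⁻²) makes the units eV, since the printed
sum carries no unit bookkeeping.  Real-space Ewald terms, self-energy and
charge-neutralization corrections are out of scope.

**Pair interpolation** blends the model with a tabulated pairwise
potential: $E_i = (1 - w_i) E_i^{\mathrm{model}} + w_i E_i^{\mathrm{pair}}$
with $w_i$ the quintic bracket of $u_i = (\sigma_i - r_a)/(r_b - r_a)$ and
$\sigma_i$ the softmin of the neighbor distances
($\sigma_i = \sum_j r_{ij} e^{-r_{ij}/\alpha_s} / \sum_j e^{-r_{ij}/\alpha_s}$).
The table is evaluated with a **natural cubic spline**, not a cubic
Hermite: the blend is required to be twice continuously differentiable and
a cubic Hermite interpolant is only $C^1$, while the natural cubic spline
is $C^2$ throughout.  Radii outside the tabulated range are an error.
Atoms with no neighbors get $w_i = 0$ (pure model) by construction.

## Compression

One-input embedding networks (two-body $s$, three-body $\theta$) are
replaced by piecewise fifth-order polynomials on an even grid.  The six
coefficients per interval reproduce the network's value and first two
derivatives at both endpoints, so the table is a two-point quintic Hermite
interpolant: exact at nodes, $C^2$ across them, with error decreasing as
$\Delta x^6$.  Network derivatives come from exact layer-by-layer
propagation of $(y, y', y'')$ — analytic, not finite differences.  The
tabulation domain is the input range observed in the training data; a
coarser second table extends it five-fold for configurations outside the
training range, and beyond that evaluation is a hard error.  The merged
contraction computes $G^{\mathsf T} R$ directly from the table over the
real neighbors only ("precise indexing"); padded slots cannot contribute
because their environment rows are exactly zero.  ReLU-family activations
are rejected at tabulation time (discontinuous first derivative).
Attention and local-frame descriptors are not compressible, and neither is
type-embedding routing (its embedding input is multi-dimensional).

## Trainer

The learning rate decays exponentially in steps:
$\gamma(\tau) = \gamma_0 r^{\lfloor \tau/s \rfloor}$ with
$r = (\gamma_{\mathrm{stop}}/\gamma_0)^{s/\tau_{\mathrm{stop}}}$.  The loss
is a prefactor-weighted sum of per-frame MSE terms — energy and virial
normalized by $N$, forces by $3N$ — with prefactors interpolating between
their start and limit values with weight $\gamma(\tau)/\gamma_0$.  Variants:
per-atom force weights, and a relative force loss dividing each atom's
residual by $|F^*| + \nu$ (default $\nu = 0.01$ eV/Å, also the default
protection constant of the relative model deviation; the value is ours, no
canonical one exists).  The optimizer is Adam with
$\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$; batches draw
frames with replacement from one system.  An energy-difference label can be
attached per frame; it is treated as a labeled quantity, not a difference
of two model evaluations.

Multi-task training shares the descriptor (and type-embedding) parameters
across tasks while each task owns its fitting network; at every step one
task is picked at random and a single Adam step updates the shared and
task-own parameters only.  Each task keeps its own Adam moments.

Parameter initialization (nowhere specified canonically): weights
$\sim \mathcal N(0, 1/\sqrt{N_1 + N_2})$, biases $\sim \mathcal N(0, 1)$,
trainable timesteps $\sim \mathcal N(0.1, 0.001)$.  One seed governs all
initialization and batching; every stochastic routine takes an explicit
seed, and fixed-seed runs are bit-reproducible.

## Model deviation and candidate selection

For an ensemble of models trained from independent initializations, the
per-atom force deviation is
$\epsilon_{F,i} = \sqrt{\langle \| F_i(\theta_k) - \langle F_i \rangle \|^2 \rangle}$
and the virial deviation is $\frac{1}{N}$ times the per-component ensemble
standard deviation — the $1/N$ is read as multiplying the square root
(the printed normalization is ambiguous; the choice is isolated in one
function).  Summaries (max/mean/min over atoms or components) feed the
concurrent-learning selection rule: candidates are frames with
$\theta_{\mathrm{low}} \le \epsilon_{F,\max} < \theta_{\mathrm{high}}$, and
the fraction below $\theta_{\mathrm{low}}$ is reported as the accurate
ratio.  The upper threshold defaults to 0.15 eV/Å above the lower one.

## Synthetic data: what it emulates and what it does not

The generator stands in for the ab initio labelers that produce real
training data.  Configurations are uniform in the cell with a
minimum-distance rejection (default 3.0 Å) plus a Gaussian jitter (0.15 Å)
playing the role of thermal disorder; labels are the exact
truncated-and-shifted Lennard-Jones energy, analytic forces, and analytic
virial under the minimum image.  The reference study system is 16
argon-like atoms ($\varepsilon = 0.0104$ eV, $\sigma = 3.4$ Å) in a 12 Å
periodic cube with a 5.5 Å interaction cutoff — a density and force scale
(label force RMS ≈ 0.18 eV/Å) typical of a simple liquid.  A second
generator produces exactly rotation-equivariant per-atom vector labels
(switched sums of neighbor unit vectors) for the tensor head.

What passing tests on these data do **not** show: LJ is a pair potential,
so recovery experiments cannot probe how well descriptors capture genuine
many-body character; the uniform-plus-jitter sampling has no Boltzmann
structure; and a single species with one thermodynamic state says nothing
about transferability across composition or temperature.  The suite
demonstrates the machinery (symmetries, gradients, optimization), not
chemical accuracy on real systems.

## Problem sizes and numerical choices

The test and acceptance workloads are sized for a single desk CPU: symmetry
suites run 50 random 16-atom frames per descriptor at FP64 with a $10^{-12}$
tolerance; force checks compare against central finite differences at step
$10^{-4}$ Å; the end-to-end recovery experiment trains embedding
(25, 50, 100) and fitting (240, 240, 240, 1) networks with $M_< = 16$ on
190 training frames (5% held out) for 13000 Adam steps at
$\gamma_0 = 2\times10^{-3} \to \gamma_{\mathrm{stop}} = 10^{-4}$, batch
size 2, with energy, force *and* virial supervision
(`start_pref_v = 0.1`, `limit_pref_v = 1`).  The slow decay and the added
virial term were chosen by convergence experiments: the unstandardized
descriptor inputs noted above make the fitting network learn an input
amplification first, which a fast-decaying schedule starves, and the nine
virial components per frame are supervision the generator provides for
free.  Tie-breaks are always by
atom index after quantized distance (the 64-bit neighbor key), which makes
neighbor ordering, and hence every downstream computation, deterministic.
Degenerate inputs are errors, not silent fallbacks: zero interatomic
distance, collinear local-frame axes, radii beyond a pair table, inputs
beyond a compression grid's extended domain.

## Known limitations

Minimum-image neighbor search only (no cell lists, no multi-image
replication): the cutoff must stay below half the smallest cell height.
The 64-bit neighbor key bounds species index ($< 9223$), distance
($< 92$ Å) and atom index ($< 10^5$).  Training is single-threaded and
desk-scale; no GPU path, no distributed training, no MD-engine integration.
The local-frame descriptor's force discontinuities are inherent to its
construction.  Long-range electrostatics implements the reciprocal-space
sum only.
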