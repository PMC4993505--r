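---
title: "Adaptive finite elements for membrane electrodiffusion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive finite elements for membrane electrodiffusion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`pnpadapt` solves the Poisson–Nernst–Planck (PNP) system for a set of ionic
species $c_k$ and the electric potential $V$ on two-dimensional domains made
of an intracellular electrolyte, a membrane, and an extracellular
electrolyte:

$$\partial_t c_k = \nabla\cdot\big(D_k \nabla c_k + \tilde D_k\, c_k \nabla V\big),
\qquad -\nabla\cdot(\varepsilon \nabla V) = F \sum_k z_k c_k ,$$

with the electro-diffusive mobility $\tilde D_k = D_k z_k F/(RT)$ — the
unique choice for which the zero-flux steady state is the Boltzmann
distribution $c_k \propto e^{-z_k F V/(RT)}$.  Ionic concentrations and
diffusion are confined to the electrolyte ($D_k = 0$ and $c_k = 0$ on the
membrane, implemented by excluding membrane elements from the concentration
spaces rather than by penalisation, which would make the diffusion operator
singular).  The membrane only enters Poisson's equation, with
$\varepsilon_{mem} = 40\,\varepsilon_0$ against $80\,\varepsilon_0$ in
water.

The default species are K⁺, Na⁺ and one aggregate anion A⁻ with
intracellular concentrations (155, 12, 167.02) mM and extracellular (4, 145,
149) mM.  The cytosol therefore carries a net charge of $-0.02$ mM; at the
zero-flux steady state that charge accumulates in nanometre Debye layers
($\lambda_D \approx 0.73$ nm inside, $0.77$ nm outside) against the
membrane faces.

### Units

Everything internal is in (µm, ms, mM, mV); 1 mM = 1 mol·m⁻³.  Diffusion
coefficients are then $O(1)$ µm²·ms⁻¹ and the thermal voltage is
$RT/F = 24.08$ mV at 279.45 K (6.3 °C, the canonical squid-axon
temperature).  Poisson's equation is divided through by the Faraday
constant: its source is then the plain signed concentration sum (mM) and the
permittivity carries the $1/F$ (see `eps_scaled()`).  `assemble_charge_matrix()`
accordingly uses $F = 1$ in internal units.

### Boundary conditions

The outer boundary of each extracellular band — its far edge *and* its two
lateral ends — is the bath: Dirichlet values $c_k = c_k^0$, $V = 0$.  The
lateral ends of the intracellular strip (and of the membrane) are closed
(homogeneous Neumann).  This makes the benchmark genuinely two-dimensional:
where the membrane meets the lateral boundary the boundary condition
changes type, and the numerical error concentrates at those four membrane-end
junctions as well as in the Debye layers.

## Discretisation

Quadratic (P2) Lagrange triangles for every field, with vertex and
edge-midpoint dofs; a 7-point degree-5 triangle rule and 3-point Gauss edge
rule integrate every product of P2 functions in the blocks exactly.
Interface dofs belong simultaneously to the global potential space and the
electrolyte-restricted concentration spaces.  Dirichlet conditions are
imposed by keeping the full vectors and solving for corrections on free
dofs only (elimination with lifting).

Time stepping is BDF2 (backward Euler on the first step, where no second
history level exists); each implicit step solves the coupled nonlinear
system by Newton–Raphson on the full block system — all species and the
potential simultaneously, with both drift linearisation blocks
($D_{cc}$ and $D_{cv}$) present in residual and tangent.  Dropping both is
known to diverge; simplified tangents are deliberately not offered.  The
step size follows the iteration-count rule: grow by $f_{min}$ when Newton
needed fewer than $N_{min}$ iterations, shrink by $f_{max}$ above $N_{max}$,
within $[10^{-6}, 0.05]$ ms.  Defaults ($N_{min..max} = 3..6$,
$f = 0.2$, $\Delta t_0 = 10^{-4}$ ms, Newton tolerance $10^{-9}$ on the
scaled correction norm, 12 iterations maximum) are package choices; rejected
steps (non-convergence or a negative concentration — never clipped, which
would destroy conservation) retry at half the step.

### The linear solver

The coupled Newton system
$$\begin{pmatrix} A & B \\ S & D_v \end{pmatrix}
  \begin{pmatrix}\delta_c\\ \delta_V\end{pmatrix} = -
  \begin{pmatrix} r_c \\ r_v \end{pmatrix},\qquad
  A = \mathrm{blockdiag}_k\,(\gamma M + D^k + D_{cc}^k)$$
is solved exactly (to $10^{-12}$ relative residual, verified on the true
residual each solve) by right-preconditioned GMRES with a block-LDU
preconditioner: exact sparse LU factorisations of the per-species advection–
diffusion blocks, and a CHOLMOD Cholesky factorisation of the
*Debye-screened* Poisson block
$D_v + \sum_k (z_k^2/V_T)\, M(c_k)$ — the screening mass is the exact
Schur-complement limit at electrochemical equilibrium, which is why the
iteration typically converges in under ten matrix applications near
equilibrium.  The closed intracellular region makes the stationary species
blocks rank-one deficient; the redundant equation is replaced by the species
mass constraint, imposed through a Sherman–Morrison rank-one update of a
sparsely regularised factorisation (factoring the dense constraint row
directly would destroy sparsity).

The screened-Poisson block switches form with the step size: at very small
steps the ionic response is diffusion limited and the Schur complement is
stiffness-like (a term $\kappa\nabla^2$ with $\kappa = \sum_k z_k^2 D_k
c_k/(V_T\gamma)$); at moderate steps the step-damped Boltzmann screening
mass is the better model.  Stationary (steady-state) solves run this
Newton iteration on the time-derivative-free system.  When an iterate leaves the Newton basin — a
freshly remeshed geometry with a transferred initial guess can do that —
the solver falls back to pseudo-transient continuation: backward-Euler
steps with a geometrically growing step length until the solution rate
stalls, then Newton.  On strongly anisotropic meshes the correction norm
floors at the linear-algebra accuracy; a residual reduction below
$10^{-9}$ of the initial residual is then accepted as convergence.

## Hodgkin–Huxley membrane currents

On the nodal faces $\Gamma_{inn}$ the molar flux of K⁺ and Na⁺ is driven by
classic squid-axon HH kinetics: $I_K = (\bar g_{Kv} n^4 + g_{KL})(V_m-E_K)$,
$I_{Na} = (\bar g_{Nav} m^3 h + g_{NaL})(V_m-E_{Na})$, $f_k = I_k/(z_k F)$,
with the conductances of the node-of-Ranvier parameter set
($\bar g_{Kv} = 36$, $\bar g_{Nav} = 120$, $g_{KL} = 0.435$,
$g_{NaL} = 0.065$ mS·cm⁻²).  Since the model runs at the canonical HH
temperature, the classic rate functions are used unchanged (no Q10), shifted
so that their anchor sits at the leak-balanced rest.  Reversal potentials
are recomputed each step from the probe-point concentrations.  Gating is
lumped — one $(m,h,n)$ triple for the node, advanced by the exact
exponential update $x \leftarrow x_\infty + (x-x_\infty)e^{-\Delta t/\tau_x}$
at the frozen membrane potential; this keeps $x\in[0,1]$ unconditionally
and composes exactly.  The paired fluxes on the intracellular and
extracellular faces are equal and opposite: the membrane stores no ions.
The action potential is triggered by a constant inward Na⁺ stimulus flux
(default 1 mA·cm⁻² equivalent — the magnitude is not a published value and
is exposed in the configuration) during the first 0.5 ms.

## Hierarchical error estimation and mesh adaptation

The estimator enriches the P2 solution with a per-element cubic correction
$c^{(3)}$: a continuous gradient $g$ is recovered from the broken gradient
by patch least squares (per region — gradients jump across the membrane
interfaces), quadratic fits at the vertices with ridge-regularised normal
equations (anisotropic patches otherwise inject derivative spikes), midside
values averaged from the endpoint fits.  On each element the (constant)
third derivatives of $c^{(3)}$ are matched to the second derivatives of
$g$ — the mixed conditions, reachable from both components, are closed by
least squares — and all lower-order content is set to zero about the
centroid, which makes the correction energy rotation invariant.  The
element error measures are the exactly integrated $L^2$ norm (refinement /
coarsening) and $H^1$ seminorm (swapping / moving) of that cubic.

A global target $e_\Omega$ is distributed as
$e_\top^2 = e_\Omega^2\,\mathrm{meas}(\top)/\mathrm{meas}(\Omega)$.  Each
outer iteration solves, estimates, then applies one sweep of:

* **edge refinement** — an edge is cut at its midpoint when its patch error
  exceeds the patch target and the *predicted* post-split error (children
  inherit the parent's derivative estimates) is closer to the target;
  triangles with 1/2/3 marked edges split into 2/3/4 children, tagged edges
  split with their tag;
* **node elimination** — the reverse test on vertex patches; cavities are
  retriangulated by quality-greedy ear clipping; vertices on tagged lines
  are only removed along straight same-tag runs, corners never;
* **edge swapping** — flip when the quadrilateral's $H^1$ error strictly
  decreases (ties never flip; region-boundary edges never flip);
* **node displacement** — steepest descent on the patch $H^1$ error with a
  short backtracking line search, boundary nodes sliding only along their
  line; a simultaneous (Jacobi) update with global validity repair.

Derivative estimates are frozen during a sweep (split children inherit
them, merged and flipped elements take area-weighted means) and recomputed
from a fresh solve each outer iteration.  One sweep per outer iteration is
the default: marked edges are judged with estimates inherited from before
the sweep, so stacking several sweeps between solves cascades refinements
on stale information and overshoots the equidistributed mesh; with a solve
between sweeps the loop stabilizes in ten to fifteen iterations.  The
adaptation driver uses the potential's correction by default (the quantity
the benchmark error measures); `combined_correction` accepts any set of
scaled fields when the whole solution vector should steer the mesh.  Anisotropy is produced purely by
swapping and moving — no metric tensor machinery — and the
$H^1$-minimising moves stretch elements along the membrane exactly where
the solution varies only normally.  All operations maintain positive
orientation, region conformity and tag integrity, and refuse changes that
would create aspect ratios beyond $10^9$ or collapse areas (a tenth of the
current area per accepted move at most).

The loop stops when the node count changes by less than 1% over an outer
iteration and the global estimate is within 10% of target, or after
`max_outer` iterations.

### What adaptation can and cannot see

The estimate is computed *from the discrete solution*.  On a mesh so coarse
that the Debye layer leaves no trace in the solution, the estimator is
blind to it: the estimate-versus-resolution curve is non-monotone (small on
resolved meshes, large on marginal ones, small again on blind ones), so
very coarse targets have a spurious "blind" fixed point.  The benchmark
studies therefore start the loop from a mildly graded mesh whose first
layer (0.25 nm) resolves the Debye length — the counterpart of the
generator-produced initial mesh the method is normally started from — and
use decreasing targets, each point continuing from the previous mesh.
This limitation is inherent to a-posteriori estimation of boundary-layer
problems, not specific to the hierarchical estimator.

## The slab benchmark and its exact value

Two parallel membranes ($y \in \pm[0.434, 0.534]$ µm, length 4 µm,
extracellular bands 0.4 µm — far thicker than the Debye length, so the bath
boundary is harmless).  With no transmembrane flux the net cytosolic charge
is conserved; by symmetry each membrane screens half of it, and a Gauss box
from the mid-plane into the (charge-free) membrane gives the exact
face-to-face drop
$$V_{mem} = \frac{F\sum_k z_k c^{0}_{k,intra}\,(d_{intra}/2)\,d_{mem}}
 {\varepsilon_0\varepsilon_{mem}} = -235.64 \text{ mV}.$$
The benchmark error is
$|\,\Delta V_{exact} - (V_\eta(x_a) - V_\eta(x_b))\,|$ at the control
points $x_a = (2, 0.434)$, $x_b = (2, 0.534)$, invariant under the gauge
$V \mapsto V + c$.  A useful structural identity: testing the discrete
Poisson equation with a ramp across the membrane shows that the
*x-average* of the discrete drop equals the exact value whenever the
species masses are exact — the pointwise error at the control points is
carried entirely by the two-dimensional error components (membrane-end
junctions, Debye layers).

The same machinery provides the Debye length (`debye_length`), the
linearised decay profile $V_s e^{-x/\lambda_D}$, and the cylindrical-shell
capacitance $2\pi\varepsilon_0\varepsilon_{mem}L/\log((D+d)/d)$, whose
per-area nodal value ($\approx 1.8$ µF·cm⁻² at $\varepsilon_{mem} = 40$)
motivates that deliberately unphysiological permittivity.

## Study design and problem sizes

`run_convergence_study()` compares three meshing strategies on the slab at
desk scale: uniform refinements (element cap kept at $2\times10^4$),
tailored meshes (geometric grading $h_0 r^k$ towards each face, jointly
refined with the horizontal resolution), and the adaptive loop at a
decreasing sequence of $e_\Omega$.  Errors are measured against the
Gauss's-law value and orders fitted as the log–log slope of error against
vertex count.  The node-of-Ranvier demonstration runs the transient system
with HH currents for 10 ms on a section meshed with modest grading: it is a
qualitative reproduction (spike shape, Na⁺/K⁺ concentration transients,
non-affine cross-membrane potential at the myelin step); the deliberately
coarse resolution keeps the run in minutes.  Two consequences of the
dimensional reduction are handled explicitly.  First, the plane section has
a different membrane area-to-volume ratio than the cylinder, so the
three-dimensional net cytosolic charge would rest the section near
$-219$ mV; `section_species()` rescales the anion excess so that the
section's equilibrium equals the leak-balanced rest (the same kind of
equivalence correction as tuning the membrane permittivity to a target
capacitance).  Because the discrete equilibrium also depends on how well
the mesh resolves the Debye layer, the demonstration measures the discrete
rest by a short channel-free relaxation and applies the rescaling against
that measured value.  Second, gates are initialised in their resting
configuration at the leak-balanced anchor, not at the instantaneous
potential of the not-yet-equilibrated initial state, and the stimulus and
upstroke window is integrated under an explicit step cap (10 µs) because
the lumped gating is advanced at frozen potential over each step.

## Known limitations

* 2D only; no curved boundaries; P2 only (the accuracy argument for
  quadratic interpolation is part of the design).
* The estimator constant $\beta$ of the hierarchical bound is never
  computed; the estimate is used relatively, for equidistribution.
* Adaptation on transient runs re-uses the initial-condition mesh; the
  re-adaptation-over-time idea is exposed (`adapt_mesh` on snapshots) but
  not automated.
* The estimator blind spot on feature-hiding meshes, discussed above.
* Gating is deterministic and lumped; no stochastic channels, no Ca²⁺,
  no GHK flux form (the constant-field assumption fails exactly where this
  model is interesting).
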