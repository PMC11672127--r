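---
title: "Pathway sampling with a roto-translationally invariant potential"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway sampling with a roto-translationally invariant potential}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtip)
```

## The problem

Automated discovery of bimolecular and termolecular reactions needs a way to
push candidate reactants together without prescribing a reaction coordinate.
Internal-coordinate biases (distances, angles) require deciding in advance
which bonds will form. This package instead builds the bias from a *metric on
whole configurations* in pristine Cartesian coordinates: the minimum, over
proper rigid motions $S$, of the Frobenius norm between two
atom-ordered coordinate sets,

$$ d(P_1, P_2) \;=\; \min_{S \in SE(3)} \lVert P_1 - S\,P_2 \rVert_F . $$

Because the minimisation quotients out rotation and translation, $d$ — and
every function built from it — is invariant under rigid motions of either
configuration, so a bias constructed from it conserves total momentum and
angular momentum (the net force and torque of our bias gradient vanish to
machine precision; the tests assert $10^{-8}$).

## Alignment modes and the quaternion key matrix

With centroids aligned, the rotational problem is solved by spectral
factorisation of the standard $4\times4$ real symmetric quaternion key matrix
built from the cross-covariance of the centred coordinates. We sign the key
matrix so that the *optimal* rotation corresponds to the *minimum* eigenvalue
$\lambda_1$ of the spectrum $\lambda_1 \le \lambda_2 \le \lambda_3 \le
\lambda_4$. All four eigenvectors are kept: each is a stationary rotation of
the least-squares problem (an *alignment mode*) with distance $d_i$ obeying
the residual identity

$$ d_i^2 = E_0 + 2\lambda_i, \qquad
   E_0 = \lVert P_1^c \rVert_F^2 + \lVert P_2^c \rVert_F^2 . $$

Numerically we evaluate each $d_i$ by applying the mode rotation and taking
the norm directly — the identity loses half the significant digits when
$d_i \to 0$ (an exact rigid copy came out as $\sim 3\times10^{-7}$ through the
identity, versus $10^{-12}$ by direct evaluation) — and we assert the identity
itself in the test suite. Quaternions $q$ and $-q$ give the same rotation, so
rotation matrices, not quaternions, are the canonical output. At every
stationary rotation the residual $P_1 - S_iP_2$ is orthogonal to all three
$SO(3)$ generator fields applied to $S_iP_2$; the suite checks this to
$10^{-8}$, and checks $d_1$ against a brute-force Euler-grid minimisation to
$10^{-4}$ Å.

Atom correspondence is positional (no permutation search) and coordinates are
not mass-weighted; the sampler guarantees consistent ordering between the
current configuration and its destination. The homogeneous fourth component
$(x,y,z,1)$ is retained conceptually — the $4\times4$ motion matrices have
last row $(0,0,0,1)$ — and contributes exactly zero to every mode distance,
which the suite asserts rather than assumes.

## The combined bias and why four modes

A bias built from $d_1$ alone is continuous but not continuously
differentiable: when $\lambda_1$ and $\lambda_2$ cross, the optimal-rotation
branch switches and the derivative of $d_1$ jumps. Crossings are not exotic —
they occur exactly when $\sigma_2 = \sigma_3$ with a reflection-like
cross-covariance, and the *destination* configurations used here (molecular
centroids coincided, often with coincident atoms) sit at or near full
degeneracy. We therefore combine all four modes with Boltzmann weights over
the eigenvalue gaps,

$$ w_i = \frac{e^{-(\lambda_i - \lambda_1)/\tau}}
              {\sum_j e^{-(\lambda_j - \lambda_1)/\tau}}, \qquad
   E_\text{bias} = -(a\,n)\sum_i w_i\,
   e^{-d_i^2 / 2\sigma^2}, $$

which is primarily governed by $d_1$ when $\lambda_1$ is well separated,
weights degenerate modes exactly equally (distances within a degenerate block
are equal by construction, so the value is eigenbasis-independent), and is
smooth through crossings. The suite drives a family of configurations through
an exact $\lambda_1=\lambda_2$ crossing (singular values $3,\,1+t,\,1-t$ with
negative-determinant correspondence): the single-mode variant shows an $O(1)$
derivative jump, the combined form a bounded difference quotient two orders of
magnitude smaller.

The algebraic shapes of the weighting and of the step-growing Gaussian are
this package's own; they are chosen to satisfy the qualitative contract above
(single-mode dominance in the separated limit, equal weighting under
degeneracy, continuity, linear depth growth) rather than to match any
particular published constants, and both are exposed as configuration.

### Gradient

The bias gradient uses the envelope property — each $d_i$ is differentiated
at its stationary rigid motion, so no rotation derivatives appear — and
differentiates the weights exactly through the eigenvalues: by the residual
identity, $\partial\lambda_i/\partial p = -(P_2^c R_i^T)$, which needs only
the eigenvectors already in hand, never their derivatives. The result matches
central finite differences to $\sim10^{-10}$ relative error away from
degeneracies (the suite requires $10^{-5}$). Exactly at a degeneracy the
per-mode split of the gradient is basis-dependent while the energy is not;
the damped-descent relaxation tolerates this, and in the fully degenerate
two-atom case the gradient reduces to the unambiguous single-Gaussian form.

One consequence of the multi-mode combination: the destination is the exact
stationary point of the *single-mode* Gaussian, but the combined form adds
non-optimal-mode terms whose gradients do not vanish exactly there. This is
immaterial in practice (the real PES dominates near contact) and is pinned
down in the tests.

### Defaults

| parameter | default | units | rationale |
|---|---|---|---|
| `depth_increment` (a) | 1.0 | kcal/mol per step | gentle schedule: the bias deepens by one unit per outer step, so barrier crossing is resolved to a few steps |
| `width` (sigma) | `max(1, d_1(P_ini, P_des)/3)` | Å | frozen at sampling start; scales the Gaussian to the initial separation so the far-field pull is non-negligible |
| `temperature` (tau) | `0.1 (lambda_4 - lambda_1 + 1e-12)` | Å² (eigenvalue units) | recomputed per evaluation; an adaptive gap fraction keeps smoothing active at every scale |
| `max_modes` | 4 | — | the combined form; `1` exposes the unsmoothed variant |

## Toy reactive surfaces

The real-PES contract is two callables — energy and gradient — and the
built-in toy surfaces implement it pairwise: reactive element pairs get a
Morse well $D[(1-e^{-\alpha(r-r_e)})^2 - 1]$ plus a Gaussian barrier bump
$h\,e^{-(r-r_b)^2/2w^2}$; non-reactive pairs a soft exponential repulsion
$A\,e^{-r/\rho}$ (exponential rather than $r^{-12}$: optimizer-friendly).
There is no bond-topology state, so "reaction" is purely geometric — exactly
what the sampler's energy-drop detection must recognise. Three-body terms are
omitted; the termolecular fixture emulates a catalyst with a weakly binding
third particle.

`scan_barrier()` is the independent oracle: a dense 1-D scan (default
$10^5$ points) with golden-section refinement reports the association barrier
(the interior maximum between the well and the approach plateau — the
short-range repulsive wall is excluded), its position, and the well depth.
The packaged diatomic surface (D = 20, alpha = 1.5, r_e = 1.2 Å, h = 24 at
2.5 Å, w = 0.3 Å) has barrier 18.81 kcal/mol and well depth 20.0 kcal/mol —
below the climb threshold and above the drop threshold respectively; the
h = 135 variant raises the barrier to 129.7 kcal/mol, above the climb
threshold.

An external engine can stand behind the same contract through a command
template (`{xyz_in}`/`{out}` placeholders); none of the tests require one.

## The sampling protocol

Reactants (two or three molecules, repetition allowed) are placed with their
molecular centroids at 5 Å from the common centroid — antipodal for two,
trigonal in a random plane for three, with uniformly random orientations from
seeded unit quaternions and a 2 Å interatomic clash floor (redrawn up to 100
times). The destination is the same configuration with every molecular
centroid translated to the global centroid, internal geometries untouched.
The placement radius, the climb threshold (115 kcal/mol), the drop threshold
(12.5 kcal/mol) and the 32-attempt batch size are the protocol's stated
conditions and are the package defaults.

Each outer step $n$ deepens the bias and relaxes the biased surface by up to
20 damped-steepest-descent iterations (backtracking line search, 0.1 Å
per-atom displacement cap). Both termination criteria are monitored at every
iteration:

* `climb_exceeded` when $E_n - E_\text{ini} > E_\text{climb}$ — the molecules
  are unreactive or misaligned at this energy scale;
* `reaction_found` when $E_\text{max} - E_n > E_\text{drop}$, the signature
  of bond formation; the bias is then removed and a local optimization on the
  real PES yields the product.

$E_\text{ini}$ is taken after an initial bias-free relaxation of the
placement (`relax_initial = FALSE` restores the raw-placement reference). On
the toy diatomic this relaxation settles into the shallow pre-barrier
encounter complex (-1.19 kcal/mol), so recorded climbs are referenced to that
physically sensible state. The running maximum $E_\text{max}$ is tracked at
iteration granularity — per-outer-step sampling could hop over the transition
region between records — so the recorded maximum brackets the scan-oracle
barrier to within 2 kcal/mol in reacting runs; the returned trajectory is
down-sampled to one frame per outer step. Convergence tests use per-atom
gradient *norms*: a max-component test would depend on the molecular
orientation and make nominally identical attempts behave differently.

`max_steps` bounds the outer loop (the schedule is otherwise unbounded);
the default is 500. One sizing consequence worth knowing: with a 1 kcal/mol
depth increment, pushing a pair up a ~130 kcal/mol barrier far enough to
certify `climb_exceeded` at the 115 kcal/mol threshold takes roughly 1100
steps of force balance against the bump's flank, so the high-barrier
demonstrations run with `max_steps = 2000`.

Determinism: all randomness flows from the seed; attempt $i$ of a batch uses
`seed + i - 1`, and identical seeds reproduce trajectories to $10^{-10}$.

## From endpoints to reactions

Bonds are perceived by distance: atoms bond iff
$r_{ij} < s\,(R_i + R_j)$ with $s = 1.2$ and single-bond covalent radii from
the standard Cordero compilation — except hydrogen, set to the older
Slater-type 0.37 Å, because with 0.31 Å the H₂ bond (0.741 Å) leaves the
detection band below $s = 1.2$ and the perception would not be stable across
the 1.05–1.3 scale band that the suite enforces on ten reference molecules.
Bond orders are not perceived; composition plus connectivity distinguishes
every species handled here (HCN vs HNC, for example), which is a documented
limitation rather than an oversight.

Graphs are canonicalised with an element-coloured exact canonical-form search
(BLISS, via igraph); the key embeds the composition string, making
cross-composition collisions impossible. The suite verifies *equal keys iff
isomorphic* exhaustively against an all-permutations oracle on every
connected labelled graph with up to four C/H/N/O atoms, and by random
relabelling on larger molecules. Endpoint pairs are compared as species-key
multisets: no change means a conformational event (an energy drop alone is
not a reaction); species unchanged on both sides are catalysts/spectators,
never reactants or products.

## Network analysis

Elementary reactions carry activation free energies in kcal/mol; barriers
quoted only as ranges are stored as intervals and route search uses the
conservative upper bound. Reachability is hypergraph-style: a reaction fires
only when *all* reactants and catalysts are already reachable, products
become reachable, stoichiometric counts are ignored (species are reachable or
not), and arrows are stored in their exothermic direction without
auto-generated reverses. A reaction with an unknown barrier can fire only
under an infinite barrier ceiling.

`minimax_route()` finds a route minimising the largest barrier used — binary
search over the sorted barrier values with reachability checks, then backward
chaining of a supporting route; the minimality argument guarantees the
extracted route attains the bottleneck exactly. `rank_alternatives()`
iterates with the previous bottleneck reaction excluded, id-lexicographic on
ties. Correctness is checked against exhaustive subset enumeration on all
small test networks and an independent threshold-sweep implementation on the
packaged table.

`effective_barrier()` computes the energetic span of a validated
(alternating, intermediate-terminated) free-energy profile:
$\max_j [G(TS_j) - \min_{i \le j} G(I_i)]$, the barrier with respect to the
most stable preceding intermediate, ties toward the later transition state,
invariant under constant shifts. The network layer optimises elementary
barriers; profile-level spans are computed only where a full profile is
supplied, and the two numbers are reported separately — the packaged table
carries elementary barriers, so profile-level literature spans are out of
scope for the packaged data.

On the packaged table, seeded with CO, H₂, H₂O and NH₃, the minimax route to
glycine is bottlenecked by R1 — the ammonia-catalysed synthesis of formic
acid, 45.5 kcal/mol — with everything downstream (amide formation,
two-hydrogen-transfer hydrogenation, dehydration to formaldimine, coupling
with formic acid) cheaper; excluding ammonia from the seeds disconnects
glycine entirely, since every entry into organic chemistry in this table runs
through R1 or the pricier R2. Serine bottlenecks at R42 (47.9) and alanine at
R37 (55.4). These are elementary-barrier minimax values, deliberately not
comparable to profile-referenced spans.

## What the synthetic fixtures do and do not show

The toy surfaces have smooth, low-dimensional landscapes with a single
association barrier per pair; passing the sampler tests shows the protocol's
threshold logic, bias mechanics and bookkeeping are correct, not that the
method will enumerate reactions of a real tight-binding surface with many
competing channels, conformers and entropy. The reaction table carries fixed
literature-style barrier annotations consumed as data; the network layer's
guarantees (exact minimax, catalyst semantics) are independent of where the
numbers come from. The endpoint fixture for reaction extraction is synthetic
(separated standard geometries), constructed in code.

## Numerical choices and limitations

* Damped steepest descent with backtracking was chosen over quasi-Newton for
  robustness on strongly biased, occasionally degenerate surfaces; iteration
  counts, gains and caps are configurable.
* Tie-breaks: route extraction prefers earlier firing rounds then smaller
  ids; the energetic span prefers the later transition state.
* Degenerate inputs: empty configurations, symbol mismatches, unsorted
  eigenvalues, non-positive temperatures, malformed files and unsatisfiable
  placements raise typed errors with the offending item named.
* Intramolecular reactions are out of scope: the bias pulls whole molecules
  together and has no mechanism to activate a single molecule against itself.
* The sampler is not a transition-state finder: the recorded maximum brackets
  the barrier from above on 1-D toy surfaces, but no Hessian or refinement
  step is attempted.
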