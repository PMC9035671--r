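# modecomp

Elastic-network normal modes and comparison of macromolecular
conformational states, in R.

Structural biology increasingly produces *several* structures of the same
machine — open and closed channel states, assembly intermediates, frames of
a relaxation trajectory — and the question shifts from "what does it look
like" to "how do its intrinsic motions differ between states, and do they
point from one state toward another". modecomp implements the
normal-mode side of that comparison for people who work with PDB models at
desk scale: structural bioinformaticians, modellers validating integrative
models, and methods developers who need a transparent, fully testable ENM
stack.

## What it computes

Given a structure with $N$ atoms, modecomp builds an elastic network (one
spring per atom pair within a cutoff $r_c$, default 10 Å, uniform force
constant) and computes the low-frequency normal modes — eigenpairs
$(\lambda_i, u_i)$ of the mass-weighted Hessian $M^{-1/2}HM^{-1/2}$ — via
rotation–translation block (RTB) reduction: each residue contributes its
six rigid degrees of freedom, the Hessian is projected into that subspace,
and eigenvectors are lifted back to Cartesian displacements. On top of the
modes:

* **Subspace overlap** between two states' mode sets:
  $o_i = \sum_j (\hat u_i \cdot q_j)^2 \in [0,1]$, the squared projection
  of each Cα-restricted mode of set *a* onto the orthonormalised span of
  set *b*'s, in both directions.
* **Transition decomposition**: the linear combination of state A's modes
  that least-squares-minimises the distance to state B after Cα
  superposition, with the cumulative curve
  $\mathrm{RMSD}_k = \sqrt{\mathrm{RMSD}_0^2 - \frac1N\sum_{i\le k}p_i^2}$
  and per-mode contributions (marginal and solo).
* **Mode animation** as multi-model PDB, either linear or as per-block
  *screw* transforms (rotation about a fitted axis plus translation along
  it) that keep blocks rigid at finite amplitude.
* **Pairwise Cα RMSD matrices** over any selection, with atoms paired by
  chain/residue/name identity.
* **Interface contact analysis** of multi-model trajectories: residue pairs
  within a heavy-atom cutoff (default 4.5 Å), the fraction of a reference
  frame's contacts conserved per frame, per-motif interface tables, and
  atom-pair distance series.
* **Synthetic data with ground truth**: helices, two-domain hinge
  structures, conformers displaced along known modes, and trajectories with
  prescribed contact-break schedules and register-shift events.

## Worked example

Two conformational states of a synthetic two-domain protein: state B is
state A displaced along its two softest hinge modes plus 0.05 Å of noise.

```r
library(modecomp)

a <- make_two_domain_hinge(15, seed = 1)
net <- build_network(a, cutoff = 10)
net
#> elastic_network: 34 nodes, 235 springs, cutoff 10 A

modes <- compute_modes(net, n_modes = 20)
modes
#> mode_set: 20 modes over 34 atoms (lambda_1 = 7.123e-05, lambda_20 = 0.143)

b <- perturb_along_modes(a, modes, c("1" = 2.5, "4" = -1.5),
                         noise_sigma = 0.05, seed = 2)$structure

fit <- transition_fit(modes, b)
fit
#> transition_fit: 20 modes, 34 paired atoms; RMSD 0.166 -> 0.090 A (45.8% reduced)
round(fit$rmsd_k[1:6], 3)
#> [1] 0.166 0.115 0.115 0.115 0.097 0.096
round(fit$solo / sum(fit$solo), 2)[1:6]
#> [1] 0.77 0.00 0.00 0.17 0.01 0.00

modes_b <- compute_modes(build_network(b, cutoff = 10), n_modes = 20)
subspace_overlap(modes, modes_b)
#> overlap_profile: 20/20 modes over 34 paired atoms; mean overlap (first 10): a->b 0.998, b->a 0.997
```

Reading the numbers: the 20 lowest modes of state A close 45.8 % of the
0.166 Å Cα gap to state B; the curve drops steeply at mode 1 and mode 4
(the planted modes — together 94 % of the solo contributions), and the
residual 0.090 Å is the planted noise floor, which no mode combination
should explain. The two states share essentially their whole low-frequency
mode subspace (mean overlap ≈ 1), as expected for a small perturbation of
the same fold.

The same stages are scriptable from a shell via the installed
`exec/modecomp` dispatcher (`modes`, `compare`, `transition`,
`rmsd-matrix`, `contacts`, `distance`, `simulate` subcommands), each
writing tab-separated tables plus a run log.

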