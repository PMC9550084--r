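---
title: "The FOD-M model: methods, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The FOD-M model: methods, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fodm)
```

## The model

The fuzzy oil drop (FOD) model treats a folded, water-soluble protein as an
"intelligent micelle": the aqueous environment drives hydrophobic residues
toward the center of the molecule and polar residues toward the surface, so
the idealized hydrophobicity density over the protein body is a 3D Gaussian
centered on the molecule. The package quantifies how closely a real
structure realizes this ideal, and — in the modified (FOD-M) form — how
strongly an external, non-polar factor (a membrane, a binding partner, a
disulfide-imposed constraint) must distort the Gaussian field to account
for what is observed.

Every residue is reduced to one *effective atom* at the unweighted mean of
its atom coordinates. Over the $N$ effective atoms of a *structural unit*
(a complex, a chain, or an explicitly delimited domain) four per-residue
distributions are built, each normalized to sum 1:

* **T (theoretical)** — the 3D Gaussian evaluated at each effective atom:
  $T_i \propto \exp\!\big(\tfrac{-(x_i-\bar x)^2}{2\sigma_x^2}\big)
  \exp\!\big(\tfrac{-(y_i-\bar y)^2}{2\sigma_y^2}\big)
  \exp\!\big(\tfrac{-(z_i-\bar z)^2}{2\sigma_z^2}\big)$,
  in the unit's principal-axis frame.
* **O (observed)** — Levitt's pairwise hydrophobic interaction sums:
  $O_i \propto \sum_{j \ne i} (H^r_i + H^r_j)\, w(r_{ij})$ with
  $w(r) = 1 - \tfrac12\big(7\rho^2 - 9\rho^4 + 5\rho^6 - \rho^9\big)$,
  $\rho = r/c$, zero beyond the cutoff $c = 9$ Å. $H^r$ is the residue's
  intrinsic hydrophobicity.
* **R (reference)** — uniform, $R_i = 1/N$: no spatial organization of
  hydrophobicity at all.
* **M (environment-modified)** —
  $M_i = \big[T_i + K\,(T_{\mathrm{MAX}} - T_i)_n\big]_n$, where the
  subscript $n$ denotes division by the vector's sum. The
  $(T_{\mathrm{MAX}}-T_i)$ term is the *inverted* field of a fully
  hydrophobic (membrane-like) environment; the coefficient $K \ge 0$ sets
  the consensus between aqueous ($K=0$, $M=T$) and inverted regimes.

Distributions are compared by the Kullback–Leibler divergence entropy
$D_{KL}(P|Q) = \sum_i P_i \log_2 (P_i/Q_i)$ (bits). Two summary statistics
follow:

$$RD = \frac{D_{KL}(O|T)}{D_{KL}(O|T) + D_{KL}(O|R)}, \qquad
RD_{K_{opt}} = \frac{D_{KL}(O|T)}{D_{KL}(O|T) + D_{KL}(O|M_{opt})}.$$

$RD < 0.5$ means the observed distribution is closer to the Gaussian core
than to structureless uniformity — a hydrophobic core is present
(*FOD-ordered*). The optimal $K$ is the grid value minimizing
$D_{KL}(O|M(K))$: the smallest environmental modification that explains
the observation.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `cutoff` | 9 | Å | Levitt interaction cutoff; $w(c)=0$ exactly |
| `k_grid` | 0–5 by 0.1 | — | K search grid |
| `margin` | 0 | Å | padding added to each principal-axis extent before $\sigma = \text{extent}/3$ |
| `threshold` | 2.3 | Å | SG–SG distance defining a disulfide bond |
| `scale` | Kyte–Doolittle, min–max to [0,1] | — | intrinsic hydrophobicity $H^r$ |
| `eps` | 1e-12 | — | floor on O entries before normalization |

**The σ convention.** The Gaussian's parameters are taken from the unit
itself: center = mean effective-atom position, axes = principal components
of the centered cloud, and $\sigma_j$ = (maximum absolute coordinate along
axis $j$ + margin) / 3, so the molecule spans three standard deviations of
its own field. Principal-axis sign ambiguity is resolved
deterministically (largest-magnitude loading positive); the T profile is
unaffected because the Gaussian is even along each axis. Degenerate
(collinear) clouds are rejected.

**The hydrophobicity scale.** The method's published description does not
fix a specific intrinsic scale. The package ships the Kyte–Doolittle
hydropathy index min–max normalized to [0, 1] and accepts any user scale
from a two-column text file (`read_hydro_scale()`). RD is moderately
scale-dependent, which is why comparisons against published per-protein RD
values should carry a tolerance of a few hundredths.

**K grid.** All published optimal-K values we are aware of are multiples
of 0.1, and the inverted regime saturates well below 5, so the default grid
0–5 in steps of 0.1 brackets practical cases with headroom. Ties break
toward the smallest K: prefer the least environmental modification
consistent with the data.

## Numerical conventions

* **Epsilon floor.** $D_{KL}(O|\cdot)$ requires $O_i > 0$. A residue with
  no neighbor inside the 9 Å cutoff would get $O_i = 0$, so O entries are
  floored at 1e-12 before normalization; a warning reports every
  activation. T and M are strictly positive by construction.
* **Flat T.** If all $T_i$ are equal, $(T_{\mathrm{MAX}}-T_i)$ is
  identically zero and the inner normalization is 0/0; M is then defined
  as T (warned).
* **$RD_{K_{opt}}$ at $D_{KL}(O|T)=0$.** When O equals T both divergences
  vanish; the statistic is defined as its limit, 0. When the optimum is
  $K=0$ with $D_{KL}(O|T)>0$, $RD_{K_{opt}} = 0.5$ exactly.
* **Profile sums** are asserted to 1 ± 1e-9.
* **RD at the cutoff.** RD exactly 0.5 counts as "no core": the core
  criterion is strictly $RD < 0.5$.

## Fragment (IDR) status

The status of a fragment — an intrinsically disordered region, a
disulfide-covered segment — is always evaluated *inside its parent unit's
field*: the Gaussian parameters are fitted once on the whole unit and
reused unchanged. T and O are restricted to the fragment's residues and
renormalized to sum 1 within it, R becomes $1/n_{\text{fragment}}$, and the
M profile uses the fragment-local maximum of T. (Because restriction
followed by renormalization rescales T uniformly, taking the local maximum
before or after renormalizing is equivalent.) Residue ranges are inclusive
and in author numbering; numbers unresolved in the structure — residues
missing from the deposited model — are skipped and reported.

## Classification

For an (RD of unit, RD of IDR) pair the quadrants at the 0.5 cutoff define
four groups: Group 1 (both < 0.5, FOD-ordered), Group 2 (both ≥ 0.5,
FOD-unordered), Group 3 (unit < 0.5 ≤ IDR, FOD-unordered), Group 4 (IDR
< 0.5 ≤ unit, FOD-ordered). The K coefficients are segmented into
low (0 ≤ K ≤ 0.5), mid (0.5 < K < 1.5) and high (K ≥ 1.5) ranges — water-
dominated, partially modified, and strongly modified (membrane-like)
environments — with the boundary values 0.5 and 1.5 assigned to low and
high respectively.

Cohort-level scatter analysis fits ordinary least squares of the IDR RD on
the unit RD, separately for rows above and below the identity line.
`eliminate_to_target()` is a deterministic surrogate for visual outlier
pruning: it repeatedly removes the point with the largest absolute residual
from the current fit until the Pearson correlation reaches the target.
Being residual-driven rather than visual, it will generally retain a
different set than a human curator; its outputs are demonstrations, not
reference values.

## The synthetic generator

`generate_synthetic()` produces effective-atom clouds with known
ground-truth behavior, so every statistic in the package is testable
without any structure downloads:

* geometry: an isotropic Gaussian cloud (sd 6 Å — compact globular-domain
  dimensions) or an α-helix-like curve (radius 2.3 Å, rise 1.5 Å/residue,
  100°/residue);
* arrangement: `core_sorted` assigns the largest intrinsic
  hydrophobicities to the residues with the highest T (an ideal micelle —
  RD well below 0.5, optimal K near 0), `inverted` assigns them
  outside-in (RD above 0.5, K ≥ 1), `shuffled` permutes them randomly,
  and `k_target` manufactures O directly as $M(K^\*)$ from the cloud's own
  T, optionally perturbed by Dirichlet noise;
* the seed fixes all randomness; identical seeds give bit-identical
  output, and the caller's RNG stream is left untouched.

**The documented small-noise level.** For `k_target` clouds the noise is
Dirichlet with concentration $c$: per-entry sd $\approx \sqrt{1/(nc)}$.
One K grid step changes $M$ per entry by roughly $0.1/\big((1+K)n\big)$
(the $1/(1+K)$ factor comes from the outer normalization). Requiring the
noise sd to stay below half of that for $n = 60$, $K \le 2.5$ gives
$c \gtrsim 4\times10^5$; the documented level is $c = 5\times10^5$, at
which recovered K stays within one grid step of the target.

What the generator does *not* emulate: chain connectivity, sterics,
secondary structure, realistic packing densities. Regime-level RD is
therefore directional (low vs high), not a fixed number — tests assert
orderings and bounds, not point values — and passing them shows the
statistics behave as designed, not that any particular protein will score
a particular RD.

**Problem sizes.** The validation suite uses units of 25–116 residues and
20-seed replicate batches at $n = 60$; these sizes put every regime
comfortably in its asymptotic behavior while keeping the whole suite in
seconds.

## Known limitations

* Single-conformer analysis: altloc A, model 1 (ensemble averaging only on
  request). No structure repair; unresolved residues are simply absent.
* Domain boundaries must be supplied explicitly; there is no database
  lookup.
* RD depends on the chosen intrinsic scale; cross-study comparisons should
  use one scale throughout.
* The K search is grid-based by design; no continuous optimization is
  attempted, matching how the coefficient is reported in practice.
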