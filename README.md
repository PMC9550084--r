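# fodm

Hydrophobic-core profiling of protein structures with the fuzzy oil drop
model and its environment-modified extension (FOD-M), and classification
of intrinsically disordered regions (IDRs) by the ordering of their
hydrophobic core.

## The problem

Water-soluble globular proteins tend to bury hydrophobic residues
centrally, like a micelle. The FOD model formalizes this: the idealized
hydrophobicity density over a *structural unit* (complex, chain, or
domain) is a 3D Gaussian, and the degree to which a real structure
realizes it is measured per residue. Proteins shaped by factors other than
water — membranes, binding partners, disulfide constraints — deviate from
the Gaussian in a characteristic "inverted" way, which the FOD-M extension
captures with a single environment coefficient *K*.

For each structural unit the package builds four normalized per-residue
distributions over the effective atoms (one point per residue, the mean of
its atom coordinates):

* **T** — the 3D Gaussian (σ per principal axis = max extent / 3),
* **O** — observed hydrophobicity from Levitt pairwise interactions
  within 9 Å, using an intrinsic residue scale,
* **R** — uniform 1/N,
* **M(K)** — `[T + K·(T_MAX − T)_n]_n`, the consensus between the aqueous
  field and its membrane-like inversion (`_n` = normalize to sum 1).

and the statistics

```
RD       = D_KL(O|T) / (D_KL(O|T) + D_KL(O|R))          # < 0.5: core present
K_opt    = argmin_K D_KL(O|M(K))                        # grid 0..5 step 0.1
RD_Kopt  = D_KL(O|T) / (D_KL(O|T) + D_KL(O|M_opt))
```

An IDR is profiled *inside its parent unit's field* (same Gaussian
parameters, profiles renormalized over the fragment, fragment-local
T_MAX). Pairs (RD of unit, RD of IDR) fall into four groups at the 0.5
cutoff — both ordered (Group 1, FOD-ordered), both unordered (Group 2),
ordered unit / unordered IDR (Group 3), and the reverse (Group 4,
FOD-ordered) — giving a hydrophobic-core-based alternative to
secondary-structure IDR taxonomy. Disulfide-covered fragments and batch
cohorts (with K-range segmentation and regression of IDR RD on unit RD)
are handled by the same machinery.

Audience: structural bioinformaticians studying intrinsically disordered
proteins, membrane-influenced folding, or hydrophobic-core integrity.

## Worked example

```r
library(fodm)

# a 60-residue synthetic unit with an ideal centric core, written as PDB
syn <- generate_synthetic(synthetic_spec(n = 60, assignment = "core_sorted",
                                         seed = 9))
write_synthetic_pdb(syn, "demo.pdb")

# unit status + status of its C-terminal 20 residues as a "fragment IDR"
res <- analyze_structure("demo.pdb", chains = "A",
                         fragments = list(tail = c(41, 60)))
print(res$unit)
#> FOD-M result for demo (n = 60)
#>   RD      = 0.154  (hydrophobic core present at cutoff 0.5)
#>   K_opt   = 0.1
#>   RD_Kopt = 0.507
#>   D_KL(O|T) = 0.1307  D_KL(O|R) = 0.7167  D_KL(O|M_opt) = 0.1270 bits
print(res$fragments$tail)
#> FOD-M result for demo [tail] (n = 20)
#>   RD      = 0.158  (hydrophobic core present at cutoff 0.5)
#>   K_opt   = 0.0
#>   RD_Kopt = 0.500
#>   D_KL(O|T) = 0.1681  D_KL(O|R) = 0.8967  D_KL(O|M_opt) = 0.1681 bits

g <- classify_group(res$unit$rd, res$fragments$tail$rd)
#> Group 1, FOD-ordered
```

Both RD values sit far below 0.5 — the observed hydrophobicity is much
closer to the Gaussian core (D_KL(O|T) = 0.13 bits) than to structureless
uniformity (0.72 bits) — and the optimal K ≈ 0 says no external field is
needed to explain the arrangement: a Group 1, FOD-ordered pair. The same
geometry with the hydrophobicity assignment inverted scores RD = 0.827
with K_opt = 3.3: a strongly membrane-like arrangement, no core.

A thin command-line wrapper covers the same workflows
(`analyze`, `batch`, `synth`, `ss`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/fodm.R", package="fodm"))')" \
    analyze --structure demo.pdb --chain A --fragment A:41-60
```

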