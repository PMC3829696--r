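# dinucontext

Dinucleotide frequencies in genomes and transcripts deviate strongly from
what mononucleotide composition predicts: CpG is depleted several-fold in
methylated vertebrate DNA, TpA/UpA is suppressed almost universally, and the
size of these biases varies systematically with G+C content. `dinucontext`
models such biases as the *equilibrium consequence of context-dependent
mutation* and provides the machinery to fit that model to sequence data:
which neighbor-dependent mutation rates, at what strength, best explain the
observed dinucleotide composition of a genome, a set of mRNAs, or a virus
family?

The package is aimed at molecular-evolution researchers who want a
mechanistic, mutation-level explanation for composition biases rather than a
purely descriptive odds ratio.

## The model

Each substitution Y→W proceeds at an HKY-style default rate

```
Q[Y,W] = θ        toward C or G   (transversions)
       = 1 − θ    toward A or T   (transversions)
       × κ        for transitions (A↔G, C↔T)
```

where θ is the equilibrium G+C content of the default process and κ the
transition/transversion ratio. Inside a trinucleotide XYZ the rate is
modified multiplicatively by the two flanking bases:

```
r(X, Y→W, Z) = f(X, Y→W) · Q[Y,W] · f(Y→W, Z)
```

There are 96 context factors `f` (48 upstream, 48 downstream), all
defaulting to 1. Double-stranded DNA imposes strand symmetry
`f(X, Y→W) = f(Y′→W′, X′)`, leaving 48 free factors; single-stranded (RNA)
sequences keep all 96. The notation `C>T,G` denotes C mutating to T when
followed by G — the classical methylation-deamination context.

Writing `d_XY` for the proportion of dinucleotide XY and `m_X` for the
mononucleotide margins, and assuming overlapping dinucleotides that share a
middle base are independent (`t_ijk = d_ij d_jk / m_j`), the composition
evolves by 16 coupled equations

```
d d_xy / du = Σ_{ijk} t_ijk Σ_{l≠j} r(i, j→l, k) · b((x,y), (i, j→l, k))
```

where `b` counts the net change of xy copies when ijk becomes ilk (always in
−2…2). Solving to stationarity gives the model's o/e ratio
`M_XY = d_XY / (m_X m_Y)` as a function of equilibrium G+C content ω.
Tabulating M over a θ grid and interpolating yields model curves that are
fitted to observed profiles by minimizing

```
RMS(F) = sqrt( Σ_n Σ_xy ( R_{n,xy} − M_xy(ω_n, F) )² / 16N )
```

with greedy forward selection: at each stage every not-yet-selected factor
is optimized jointly with κ and the previously selected factors, and the
factor giving the largest RMS reduction enters the model. Model error is
reported baseline-corrected: the RMS of per-dinucleotide quadratic fits
(the best smooth description of the data) is subtracted, removing
irreducible sampling scatter.

A Gillespie sequence-evolution simulator implements the same rates
stochastically; it serves as the independent oracle for the deterministic
solver and generates fixtures with known ground truth. A companion module
tallies SNP records by mutation type and 3′ flanking base and normalizes
them to context-blind expectations, connecting fitted factors to directly
observed mutation spectra.

## Worked example

Evolve five synthetic "organisms" spanning a G+C gradient under CpG
hypermutation (κ = 3, `C>T,G` = 12), then recover the planted mutation from
their composition alone:

```r
library(dinucontext)

fv <- factor_vector(kappa = 3, mode = "dna", factors = c("C>T,G" = 12))
equilibrium(0.5, fv)
#> Equilibrium state: theta = 0.5, omega (G+C) = 0.420673, residual = 2.2e-16
#> o/e ratios:
#>     AA     AC     AG     AT     CA     CC     CG     CT     GA     GC     GG
#> 0.9059 1.0000 1.1296 1.0000 1.3513 1.1203 0.2173 1.1296 0.9126 1.0000 1.1203
#>     GT     TA     TC     TG     TT
#> 1.0000 0.9025 0.9126 1.3513 0.9059

profiles <- equilibrium_profiles(fv, seq(0.3, 0.7, by = 0.1),
                                 length = 50000, seed = 42)
baseline <- fit_quadratic_baseline(profiles)
fit <- greedy_fit(profiles, mode = "dna", max_k = 1,
                  theta_grid = seq(0.10, 0.90, by = 0.05),
                  baseline_rms = baseline$baseline_rms)
fit
#> Greedy context-factor fit (DNA mode, M = 49)
#> stage 0: kappa = 20.000, RMS = 0.253027
#> stage 1: C,G>A (= C>T,G) value 11.466, kappa = 3.457, RMS = 0.019143,
#>          corrected error = 0.007061
```

The equilibrium shows the canonical signature of methylation-driven C→T
hypermutation: CpG suppressed to 0.22 of expectation, the decay products
TpG and CpA equally enriched at 1.35, and equilibrium G+C pulled from 0.50
down to 0.42. Stage 1 of the greedy fit selects the planted factor (shown
with its strand-symmetric alias: `C,G>A` ≡ `C>T,G`) and recovers its rate
(11.5 vs the true 12) and κ (3.5 vs 3) from 50 kb of sequence per
composition point; the corrected model error drops from 0.25 to 0.007.
At stage 0 no context factor is active, the model curve is flat at 1 for
every κ, and the reported κ is therefore arbitrary — κ only becomes
identifiable once a context factor enters.

A command-line interface wrapping the same functions is installed as
`exec/dinucontext` (subcommands `scan`, `curve`, `fit`, `simulate`,
`snp-context`, `fixtures`, `run`).

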