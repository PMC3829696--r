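---
title: "Context-dependent mutation models for dinucleotide composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-dependent mutation models for dinucleotide composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dinucontext)
```

## The scientific question

Dinucleotide observed/expected ratios — the frequency of an ordered base
pair divided by the product of its mononucleotide frequencies — are among
the most stable compositional signatures of genomes. CpG sits far below 1
in methylated vertebrate DNA; TpA/UpA is suppressed nearly everywhere;
TpG and CpA are correspondingly enriched; and all of these vary smoothly
with G+C content. `dinucontext` asks a mechanistic question: which
*neighbor-dependent mutation rates* would, at mutational equilibrium,
produce the composition we observe?

## The rate model

The default, context-free process is an HKY-style matrix: substitutions
toward C or G occur at rate $\theta$, toward A or T at $1-\theta$, and
transitions (A$\leftrightarrow$G, C$\leftrightarrow$T) are scaled by
$\kappa$. Under this process alone the stationary mononucleotide
composition is $m_C = m_G = \theta/2$, so $\theta$ *is* the equilibrium G+C
content, for every $\kappa$. The matrix is used unnormalized: only
equilibria are interpreted, so the overall time scale is arbitrary and no
substitutions-per-year calibration is implied.

Context enters multiplicatively. For a trinucleotide $XYZ$,

$$ r(X,\, Y{\to}W,\, Z) \;=\; f(X,\, Y{\to}W)\; Q_{YW}\; f(Y{\to}W,\, Z), $$

with 48 upstream and 48 downstream factors, all defaulting to 1. The two
factors act independently: raising one to 0.7 and the other to 2 multiplies
the default rate by 1.4. In double-stranded DNA, strand symmetry equates
each upstream factor with a downstream factor on the complementary strand,
$f(X, Y{\to}W) = f(Y'{\to}W', X')$, halving the free parameters to 48 (+
$\kappa$); the classical methylation context `C>T,G` is the same free
parameter as `C,G>A`. Single-stranded (RNA) sequences, where polymerase-
and selection-driven asymmetries are real, keep all 96 (+ $\kappa$) free.
Internally both modes use the DNA alphabet; U is a display alias for T, so
one code path serves both.

## Equilibrium composition under trinucleotide independence

The state is the 16-vector of dinucleotide proportions $d_{xy}$, with
margins $m_x$. Overlapping dinucleotides sharing a middle base are treated
as independent, $t_{ijk} = d_{ij} d_{jk} / m_j$ — the standard closure that
makes the dynamics finite-dimensional. Each substitution event
$(i, j{\to}l, k)$ then occurs with flux $t_{ijk}\, r(i, j{\to}l, k)$ and
changes dinucleotide counts by the change-count function $b$: +1 for $il$
and $lk$, −1 for $ij$ and $jk$ (net values always in $-2\ldots2$). Every
event creates two dinucleotides and destroys two, so $\sum d_{xy}$ is
conserved exactly, as are the four margin-consistency differences
$\sum_i d_{iX} - \sum_i d_{Xi}$.

**Numerical solution.** Integration starts from the independent product
composition at the default-process stationary proportions — the choice is
immaterial to the answer (any interior composition relaxes to the same
equilibrium, which we verify stochastically) but makes convergence fast and
deterministic. The solver is compiled: classical RK4 relaxation with step
size bounded by the fastest total event rate, run until the residual
$\max |{\rm d}d/{\rm d}u|$ falls below $10^{-5}$, followed by a damped
least-squares Newton polish to $10^{-13}$. Because the flow conserves four
linear quantities the raw $16\times16$ Jacobian is singular; the Newton
system is therefore augmented with the probability-sum and
margin-consistency constraints, which keeps the iteration on the physical
leaf. Solves are accepted only below a $10^{-10}$ residual (default) and
typically finish in well under a millisecond, which matters because the
greedy fit performs on the order of $10^5$ of them. Terms with
$m_j < 10^{-14}$ are dropped (the removable singularity of
$d_{ij}d_{jk}/m_j$).

Two closed-form facts anchor the solver: with all factors 1 the equilibrium
is the independent product (every o/e ratio 1, $\omega = \theta$, any
$\kappa$), and in strand-symmetric DNA mode the equilibrium satisfies
$d_{XY} = d_{Y'X'}$. Both are asserted to $10^{-8}$ in the tests. The full
nonlinear field is checked against a brute-force triple-loop summation
written directly from the definitions, to $10^{-12}$.

## Model curves and interpolation

For fitting, equilibria are tabulated over a $\theta$ grid — by default
0.05 to 0.95 in steps of 0.02 (46 points), covering the observed G+C span
of typical data (roughly 20–80%) with margin — storing the equilibrium G+C
$\omega(\theta)$ and the 16 model o/e ratios $M_{XY} = d_{XY}/(m_X m_Y)$.
$\omega$ must be strictly monotone over the grid (asserted; otherwise
interpolation in $\omega$ would be ill-posed). Predictions at an observed
G+C value use piecewise-linear interpolation per dinucleotide, with no
extrapolation outside the tabulated $\omega$ range. Linear interpolation is
monotone-safe; halving the grid step changes interpolated values by at most
$\sim 10^{-3}$ over $\omega \in [0.2, 0.8]$ (dominated by the curvature of
the CpG curve), which is far below the $\sim 0.03$ sampling scatter of
50 kb composition profiles, so the default grid is not a practical error
source.

## The RMS objective and baseline correction

The fit minimizes
$\mathrm{RMS}(F) = \sqrt{\sum_n \sum_{xy} (R_{n,xy} - M_{xy}(\omega_n, F))^2 / 16N}$
over the profiles' observed ratios. Undefined ratios (a base absent from a
profile) are excluded with the divisor reduced accordingly, and the same
convention is used for the quadratic baselines so the subtraction is
like-for-like: the *baseline-corrected model error* is the model RMS minus
the RMS of independent per-dinucleotide ordinary-least-squares quadratics
in $\omega$ — the best smooth description the data admit, hence the
irreducible scatter. A corrected error near zero means the mutation model
explains everything a free quadratic could.

Sampling scatter itself is modelled as
$\mathrm{RMS}(L) = a/L^b + c$, fitted by bounded nonlinear least squares
(`minpack.lm`), with $c$ the model error remaining at infinite fragment
length. For the reference coefficients $a = 2.2$, $b = 0.42$, $c = 0.0095$
the evaluation at 50,000 bp gives 0.0329. (Evaluating the same formula at
the mean mRNA length of ~2,463 bases gives $\approx 0.092$, not the 0.0994
sometimes quoted alongside these coefficients; the package implements the
formula and leaves the small discrepancy unexplained rather than
reverse-engineering it.)

## Stage optimization and greedy selection

Parameters are optimized in log space — $\kappa \in [0.2, 20]$, factors in
$[1/100, 100]$, bounds enforced by a smooth penalty — with derivative-free
Nelder–Mead (Brent line search in the one-parameter case), multi-started
from the previous stage's optimum and from the defaults. The search is
deterministic given its inputs. Greedy forward selection then evaluates, at
each stage, every not-yet-selected candidate jointly re-optimized with
$\kappa$ and all previously selected factors, keeping the candidate with
the lowest achieved RMS and recording the full per-candidate ledger (the
"alternatives" trace). Selection stops at `max_k` factors (default 8) or
when the best relative RMS reduction falls below $10^{-4}$ (configurable).
Candidates within $10^{-9}$ of each other tie-break lexicographically.
Because each stage's optimum remains feasible at the next stage, the RMS
trajectory is non-increasing by construction. Equilibrium solves are
memoized on (factors, grid) rounded to $10^{-10}$, the dominant cost of
the inner loop.

Two identifiability caveats are worth knowing. First, with no active
factors the model curve is identically 1 for every $\kappa$, so the
stage-0 "$\kappa$-only" fit cannot identify $\kappa$ from composition data;
$\kappa$ becomes identifiable only jointly with at least one active factor.
Second, raising a rate $f(Y{\to}W, Z) = v$ and lowering its reverse
$f(W{\to}Y, Z) = 1/v$ change the context-specific rate *ratio* identically
and push the equilibrium the same way, but the equivalence is only
approximate — the competing substitution channels are unchanged — and
degrades as $v$ grows (measured maximum o/e differences at $\theta = 0.5$:
0.05 at $v=2$, 0.27 at $v=6$, 0.40 at $v=12$). This near-degeneracy at
small effect sizes motivates the reporting convention: fitted factors below
1 are presented as the reverse mutation with value $1/v$, flagged as
reciprocal-reported.

Profile sets whose G+C values are all equal carry no compositional trend;
they are accepted with a warning rather than rejected, since the 16 ratios
at a single $\omega$ still constrain the factors weakly.

## The stochastic simulator

The simulator is the package's independent ground truth: an explicit
sequence in which each site mutates at $r(i, j{\to}l, k)$ given its current
neighbors, sampled by the Gillespie algorithm over a Fenwick tree of
per-site rates, with only the mutated site and its two neighbors updated
per event. The sequence is circular by default so every site has two
neighbors, matching the infinite-sequence assumption of the deterministic
model; a linear mode with fixed ends exists for comparison. The event
budget defaults to 30 expected substitutions per site — far past relaxation
for all factor magnitudes used here — and equilibration is checked by
comparing dinucleotide proportions at the 75% and 100% checkpoints against
a two-sample binomial band (overlapping windows roughly double the
binomial variance, and the band accounts for that). Runs are reproducible:
the seed is mandatory and identical seeds give bitwise-identical sequences.

What the generator emulates: a homogeneous, neutral, context-dependent
point-mutation process at stationarity, across a G+C gradient. What it does
not: selection (including codon structure), rate heterogeneity along the
sequence, indels, recombination, CpG-island-like spatial structure, and
finite-population effects. Passing the recovery tests therefore shows the
estimator is correct *for data generated by the model's own mechanism*; on
real genomes the fitted factors absorb whatever mixture of mutation and
selection shapes composition, and the corrected model error quantifies how
much structure the mechanism fails to capture.

Comparisons between simulator and deterministic solver use Monte-Carlo
standard errors estimated by block decomposition (40 blocks per sequence),
since overlapping windows make plain binomial errors underestimates. Across
the acceptance sweep (5 random factor vectors × 3 $\theta$ values, 200 kb
each) agreement is within 3 block-SE cell-wise up to the expected
multiplicity of 240 simultaneous comparisons — deviations are
non-systematic across seeds, confirming that the trinucleotide-independence
closure introduces no measurable bias at these factor magnitudes (the
closure audit in the test suite bounds the residual
$|t_{ijk} - d_{ij}d_{jk}/m_j|$ below 0.02 including sampling noise).

## SNP flanking-context spectra

Given SNP records (ref, alt, 5′ flank, 3′ flank), the package tallies the
12 mutation types by 3′ flanking base and normalizes each cell by the count
a context-blind process would produce: expected$(Y{\to}W, Z)$ =
total$(Y{\to}W) \times \mathrm{freq}(YZ) / \sum_{Z'} \mathrm{freq}(YZ')$.
Conditioning on the mutating base and normalizing within each mutation type
cancels overall transition/transversion skew by construction, so a
context-independent process yields enrichment 1 in all 48 cells regardless
of $\kappa$ — the property the null tests assert — and enrichments are
invariant to global rescaling of the dinucleotide frequency table. This is
the package's precise reading of a normalization usually described only in
words; alternatives that additionally weight by per-type rates cancel in
the ratio and give the same null. Records are taken strand-as-reported; no
reverse-complement folding of complementary mutation classes is applied.
Only the 3′ (downstream) context is spanned; joint 5′×3′ (96-class)
spectra are out of scope.

## Defaults, units and problem sizes

| Parameter | Default | Meaning |
|---|---|---|
| $\theta$ grid | 0.05–0.95 step 0.02 | curve tabulation span (G+C fraction) |
| $\kappa$ bounds | [0.2, 20] | transition/transversion ratio |
| factor bounds | [0.01, 100] | symmetric around 1 in log space |
| `max_k` | 8 | factors allowed to leave their default |
| stop rule | rel. ΔRMS < $10^{-4}$ | "no further reduction" |
| fragment length | 50,000 bp | genomic scan window |
| min mRNA length | 2,500 b | short-transcript filter (configurable) |
| remainder rule | keep ≥ half fragment | avoids noisy short tails |
| equilibrium tol | $10^{-10}$ (polish $10^{-13}$) | max $|{\rm d}d/{\rm d}u|$ |
| simulator budget | 30 subs/site | events per sequence |

The test suite exercises recovery at sequence lengths of 20–200 kb and
profile sets of 4–14 composition points with tabulation grids of 13–17
points — sizes chosen so each property is measured well inside its noise
floor while the whole suite runs in minutes; all scale linearly upward for
production analyses (a full 46-point-grid greedy DNA fit costs on the order
of $10^5$ equilibrium solves).

## Known limitations

- The trinucleotide-independence closure is an approximation; its error is
  below Monte-Carlo resolution at the factor magnitudes tested (up to ~12)
  but is not proven small for extreme factor combinations.
- Fitted factors are point estimates; no standard errors are attached
  (reproducibility is assessed by data-resampling instead).
- Trinucleotide-context mutation processes (e.g. CpHpG methylation in
  plants) are outside the model class, as are time-calibrated rates and
  likelihood-based phylogenetic inference.
- $\kappa$ is unidentifiable without at least one active context factor
  (see above); treat stage-0 $\kappa$ values as arbitrary.
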