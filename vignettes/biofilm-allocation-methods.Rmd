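---
title: "Models and methods: biofilm-plankton allocation, fitness landscapes, and bet-hedging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: biofilm-plankton allocation, fitness landscapes, and bet-hedging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biofilmhedge)
```

# The scientific problem

Clonal bacterial lineages routinely maintain two coexisting phenotypes: fast-growing,
fragile planktonic cells and slow-growing, stress-resistant biofilm cells. This
package implements a family of models for asking when a lineage should split its
investment between the two: a within-patch population model coupling the
compartments, a metapopulation fitness function over the colonization rate, a
stochastic serial-passaging simulation probing bet hedging, and a lattice
simulator of the geometric growth constraint that motivates the whole framework.

# Within-patch dynamics

A patch is a habitat episode of duration $t$. Planktonic cells $P$ divide at rate
$r$ and join the biofilm at per-capita colonization rate $c$; biofilm cells $B$
accumulate from colonization:

$$\frac{dP}{dt} = (r - c)P, \qquad \frac{dB}{dt} = cP,$$

with solutions $P(t) = P_0 e^{(r-c)t}$ and $B(t) = \frac{c}{r-c}\left[P(t) - P_0\right]$.
Setting intrinsic biofilm growth to zero makes biofilm cells formally equivalent to
spores or persisters: a non-dividing subpopulation fed by the vegetative engine.
The full model (`integrate_full_model()`) restores intrinsic biofilm growth
$G(B) \in \{0,\, g,\, g\sqrt{B}\}$ and dispersal $d$ from biofilm back to
plankton; we take $dP/dt = (r-c)P + dB$, i.e. dispersed cells rejoin the
plankton — the dispersal term has to put its cells somewhere, and returning them
to the bulk is the stated biology. This is an assumption worth flagging: a model
that discards dispersed cells would differ at large $d$.

Three analytic quantities drive everything downstream:

* the limiting slope $\lim_{c\to r} dB/dc = -\tfrac12 P_0 t (rt - 2)$, negative
  exactly when the patch-quality product $rt > 2$, which is the condition for an
  interior ("growth engine") maximum of biofilm in $c$;
* the total-population cost $d(P+B)/dc$, zero at $t = 0$ and strictly negative
  for $t > 0$: any colonization is costly in total cell count;
* the per-founder fitness
  $W(c) = k_p e^{(r-c)t} + k_b\left[e^{(r-c)t} - 1\right]\frac{c}{r-c}$, the
  expected number of next-patch founders per current founder, where $k_p, k_b
  \in [0,1]$ are the per-cell transmission probabilities of the two phenotypes.

# Parameters and defaults

| parameter | meaning | units | default | why |
|---|---|---|---|---|
| $r$ | planktonic growth rate | 1/time | 0.06 | reference environment mean |
| $c$ | colonization rate | 1/time | — | the strategy under optimization |
| $t$ | patch duration | time | 40 | reference environment mean |
| $P_0$ | planktonic inoculum | cells | 5e6 (patch), 5000 (passaging) | reference designs |
| $k_p, k_b$ | transmission weights | — | 0.1, 0.6 | biofilm-favoured transmission |
| $d$ | dispersal rate | 1/time | 0.01 (full model) | small relative to $r$ |
| $g$ | intrinsic biofilm growth | cells/time (linear) | 40000 | full-model reference |

At the default means the fitness optimum is mixed investment at roughly half the
growth rate:

```{r}
optimal_colonization(r = 0.06, t_end = 40, k_p = 0.1, k_b = 0.6)
```

# Numerical choices

**The $c = r$ singularity.** All closed forms are evaluated through the
numerically stable factorization $B = c P_0 t\,\mathrm{expm1}(x)/x$ with
$x = (r-c)t$, which passes continuously through the removable singularity; a
guard band $|r-c| < 10^{-12}\max(r,1)$ routes exact boundary evaluations to the
analytic limits ($P = P_0$, $B = cP_0t$, $W = k_p + k_b rt$). The optimizer must
probe the pure-biofilm boundary, so exactness there matters. The total-population
derivative switches to its series
$-rP_0t^2(\tfrac12 + \tfrac{x}{3} + \tfrac{x^2}{8} + \tfrac{x^3}{30})$ for
$|x| < 10^{-4}$ to avoid catastrophic cancellation.

**$c > r$** is permitted everywhere (plankton then declines as switching
outruns division); only the fitness optimizer restricts its search to $[0, r]$,
because that closed interval is the strategy space of interest.

**Integration.** The full model uses `deSolve`'s lsoda with relative tolerance
$10^{-8}$ and absolute tolerance $10^{-6}$ cells — $P$ spans about seven orders
of magnitude over a patch. The quadratic growth form evaluates $G(B) =
g\sqrt{\max(B,0)}$ so the integrator cannot stumble over a transient $-10^{-15}$.

**Optimization.** $W(c)$ is observed to be unimodal on $[0, r]$ in every probed
regime, but this is not proven; both optimizers therefore run a coarse grid
pre-scan (1024 points for fitness, 512 for biofilm) before bounded scalar
refinement with `optimize()`. Ties within $10^{-9}$ relative resolve toward
larger $c$, so a flat ridge (e.g. $k_p = k_b = 0$) lands on the boundary rather
than on floating-point noise. A computed optimum within $10^{-6} r$ of a
boundary is classified as that boundary — scalar optimizers do not return exact
endpoints.

**Regime classification** uses the closed-form boundary gradients

$$\left.\frac{dW}{dc}\right|_{c=0} = -k_p t e^{rt} + k_b\frac{e^{rt}-1}{r},
\qquad
\left.\frac{dW}{dc}\right|_{c=r} = t\left[k_b\left(1 - \tfrac{rt}{2}\right) - k_p\right],$$

derived here from $W$; gradient up at $0$ and down at $r$ proves an interior
maximum, and every other sign pattern falls back to the grid-plus-refinement
optimizer. Note the $c = r$ gradient changes sign at $rt = 2$ — the same
patch-quality threshold as the biofilm hump, which is why the pure-biofilm
region of the $(k_p, k_b)$ landscape disappears entirely once $rt > 2$ (at
$t = 40$, for $r > 0.05$). Regime boundaries are located by bisection along the
$k_b$ axis to $10^{-4}$; the degenerate flat corner $k_p = k_b = 0$ is excluded
from boundary detection since its label is a tie-break artefact.

# The environment sampler (synthetic data)

The passaging simulation draws per-passage environments
$(r, t, k_p, k_b)$ independently from normal distributions with means
$(0.06,\ 40,\ 0.1,\ 0.6)$ and a variance treatment defined by a divisor: 100
(low), 9 (mid), 2.75 (high). Draws are thresholded by clipping to logical
ranges: $k_p, k_b \in [0,1]$, $t \ge 1$, $r$ to a floor of $10^{-9}$ (the
constraint is strict positivity; the floor value is immaterial at these scales).
Clipping, not rejection sampling, is used: rejected-and-redrawn tails would
shift the means far more.

Two readings of "variance divisor" are implemented. The default `cv` convention
sets $\sigma = \mu/\sqrt{\text{divisor}}$ (a coefficient-of-variation reading);
under it, clipping shifts no parameter's mean by more than about 3% even in the
high treatment (the analytic clipped-normal mean confirms this in the tests,
and `scripts/acceptance.R` measures ~2.9% at $10^6$ draws). The `literal`
convention $\sigma^2 = \mu/\text{divisor}$ gives the small-mean parameters
spreads larger than their means — $\sigma_{k_p} \approx 0.19$ against
$\mu_{k_p} = 0.1$ — and clipping then shifts $k_p$'s mean by over 30%. Only the
`cv` reading is consistent with mean-preserving thresholding, so it is the
default; `literal` remains available for sensitivity analysis.

What the generator deliberately does **not** emulate: temporal autocorrelation
of environments, correlations among the four parameters, and within-passage
environmental change. Passing tests therefore speak to independently drawn,
stationary environmental noise only; real serial-transfer environments are
usually autocorrelated, which matters for bet-hedging conclusions.

# The passaging simulation

Each lineage alternates growth (closed forms above) with a transmission
bottleneck: $k_p P + k_b B$ cells found the next passage, all entering as
plankton. Per-passage fitness is $R_0 = $ founders now / founders before, and a
lineage is summarized by the variance, arithmetic mean, and geometric mean of
its $R_0$ sequence; summaries are then averaged across replicates with
normal-approximation 95% intervals (the aggregation order — per-lineage first,
then across replicates — is a design choice; pooled passage-level aggregation
gives the same qualitative shapes).

Colonization strategies are specified as rates relative to the drawn growth
rate ($c_{\text{abs}} = c_{\text{rel}}\, r_{\text{draw}}$), and the reference
grid covers absolute colonization rates $(0, 0.2]$ at the mean growth rate,
i.e. relative rates up to $10/3$ — a window that straddles the fixed-environment
optimum $c^*/r \approx 0.496$ and extends deep into the biofilm-heavy regime.

**Extinction.** Founder counts are continuous (matching the deterministic ODE
treatment — no demographic stochasticity), with one deliberate exception: a
lineage whose founders fall below one cell is extinct, absorbing, and its
remaining $R_0$ are zero (its geometric mean is then zero). Less than one cell
cannot found a patch; without this threshold, mathematically immortal lineages
at vanishing colonization rates ride out catastrophic draws that should kill
them, and the geometric-mean fitness maximum artificially migrates to the grid
boundary. Set `extinction_threshold = 0` to recover the fully scale-free
dynamics (the per-passage $R_0$ is founder-independent by linearity; the
threshold is the one scale-breaking element).

**A known limitation.** Under high environmental variance the *arithmetic* mean
of $R_0$ at small colonization rates is dominated by rare, enormous
$e^{rt}$ draws (the exponent is itself roughly normal with standard deviation
near 1.9 under the high treatment), so in these simulations the average $R_0$
declines from a large value as $c$ grows rather than exhibiting an interior
hump; the variance decline and the interior geometric-mean maximum — the bet-
hedging signature proper — are robust. The corresponding acceptance test states
the humped expectation and is allowed to fail, as an honest record of this
model-family property.

# The lattice growth simulator

The geometric constraint on biofilm growth — only cells near the nutrient-
exposed front divide — is modelled directly: cells occupy a square/cubic
lattice (von Neumann neighbourhoods), the front is the set of occupied sites
with an empty neighbour, and cells within `active_depth` lattice steps of the
front divide once per division epoch. A dividing cell places its daughter in a
uniformly chosen empty neighbour; if it has none, it pushes the chain of cells
along a random lattice direction until the daughter surfaces at the first empty
site, with the walk capped at `active_depth` (a cell at depth $k$ needs a push
of at most $k$). There is no nutrient field, shoving relaxation, or EPS
mechanics: the claims under test are geometric — the polynomial order of
accumulation equals the dimensionality of the growing body, dropping by one at
each confluence event — not metabolic.

Division epochs are synchronous with randomized division order; site conflicts
resolve in favour of the earlier divider. When every cell is active (active
depth at least the domain diameter), the population doubles each epoch —
exponential growth — until crowding; frontier-limited growth instead advances
the front at a constant asymptotic speed, giving $N(t) \sim t^D$.

Order estimation is the least-squares slope of $\log N$ on $\log t$ in a time
window. Two practical points: (i) a lone seed spends its first handful of
epochs as a ramified cluster, which acts as a positive time offset and biases
window slopes upward, so radial order checks start from a compact filled ball
(`inoculum_radius = 1`) and estimate over the later half of the run; (ii) an
exponential curve has no stable order — the estimator flags upward drift of the
slope across three sub-windows as non-convergence. Confluence is detected as
the first epoch at which the active-cell count plateaus within 5%.

Problem sizes were chosen so the whole suite runs comfortably on one core: the
radial order checks use run lengths of 60/40/26 epochs for $D = 1, 2, 3$
(roughly $10^5$ sites at most), the substratum runs use a width-60 surface for
60 epochs, and the full passaging experiment is 20 strategies × 3 treatments ×
100 replicates × 10 passages.

# What the tests do and do not establish

The suite verifies internal mathematical consistency (closed forms against an
independent ODE integration, optimizers against brute-force grids, analytic
derivatives against finite differences, the clipped-normal mean against its
closed form) and the qualitative structure of the model's predictions at the
reference scales. None of this validates the model against real biofilm data:
the within-patch model has no spatial structure, no nutrient depletion, no
density dependence in $r$, and no matrix-mediated blocking of late colonization;
the passaging simulation assumes all transmitted cells re-enter as plankton.
These are modelling commitments, not estimated quantities.
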