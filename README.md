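# biofilmhedge

Population-dynamic and evolutionary models of the trade-off between
fast-growing planktonic cells and stress-resistant, slow-growing biofilm
cells in bacterial lineages. The package is aimed at microbial ecologists
and evolutionary modellers who want to ask, quantitatively: when should a
clonal lineage split its investment between a fragile "growth engine" and
a durable but growth-limited refuge — and how much of that answer is
division of labor versus bet hedging?

## The models

**Within-patch dynamics.** Planktonic cells *P* divide at rate *r* and
colonize the biofilm *B* at per-capita rate *c*:

    dP/dt = (r − c) P        P(t) = P0 e^{(r−c)t}
    dB/dt = c P              B(t) = c/(r−c) · [P(t) − P0]

The limiting slope of B in c as c → r is −½ P0 t (rt − 2): whenever the
patch-quality product *rt* exceeds 2, the biofilm is maximized at an
*interior* colonization rate — exponentially dividing plankton act as an
engine for biofilm production. A full numerical variant adds intrinsic
biofilm growth (linear or quadratic) and dispersal back to the plankton.

**Fitness over a patchy life cycle.** With per-cell transmission
probabilities k_p and k_b, the per-founder fitness (a reproductive number)
is

    W(c) = k_p e^{(r−c)t} + k_b [e^{(r−c)t} − 1] · c/(r−c)

maximized over c ∈ [0, r]. The optimum classifies each environment as
pure plankton (c* = 0), mixed (0 < c* < r), or pure biofilm (c* = r);
the package maps these regimes and their boundaries over the (k_p, k_b)
unit square.

**Bet hedging under environmental noise.** A serial-passaging simulator
alternates growth and transmission while (r, t, k_p, k_b) are redrawn
each passage from normal distributions under low/mid/high variance
treatments (clipped to logical ranges), recording per-passage R0 and
summarizing lineages by the variance, mean and geometric mean of R0.
Lineages falling below one founding cell go extinct.

**Growth geometry.** A minimal lattice simulator with a hard active-layer
rule shows why biofilm growth is polynomial rather than exponential:
cumulative cell count grows like t^D for a D-dimensional body, dropping
one order at each confluence event.

## Worked example

Half-maximal colonization in a favourable patch (r = 0.06, t = 40):

```r
p <- within_patch_params(r = 0.06, c = 0.03, t_end = 40)
solve_trajectory(p, times = c(0, 10, 20, 30, 40))
#>   time        P        B
#>      0  5000000        0
#>     10  6749294  1749294
#>     20  9110594  4110594
#>     30 12298016  7298016
#>     40 16600585 11600585
```

Both compartments grow roughly exponentially: the plankton at rate r − c,
the biofilm as a constant multiple c/(r − c) of it (here equal shares).
The fitness-optimal strategy for biofilm-favoured transmission:

```r
optimal_colonization(r = 0.06, t_end = 40, k_p = 0.1, k_b = 0.6)
#> Optimal colonization strategy
#>   r = 0.06, t = 40, k_p = 0.1, k_b = 0.6
#>   c* = 0.0297809  (c*/r = 0.4963)  regime: mixed
#>   W(c*) = 1.7241
```

Even though biofilm cells transmit six times better, the optimum routes
only half the maximal rate into the biofilm — the other half keeps the
planktonic engine running. A small passaging experiment shows the hedge:

```r
ex <- run_experiment(c_rel_grid = c(0.5, 1.5, 3), treatments = c("low", "high"),
                     n_replicates = 20, seed = 1)
summary(ex)
#>    treatment c_rel statistic    mean  ci_lo   ci_hi
#>         high   0.5    var_R0 199.216 -4.759 403.190
#>         high   1.5    var_R0   0.629  0.482   0.776
#>         high   3.0    var_R0   0.192  0.162   0.221
#>         high   0.5  gmean_R0   1.354  1.104   1.604
#>         ...
```

Raising colonization collapses the variance in R0 by three orders of
magnitude under high environmental noise — biofilm investment buys
insurance — while the geometric-mean fitness peaks at intermediate rates.
`reproduce_figure()` regenerates each headline analysis (time series,
regime landscapes, the full passaging experiment, growth-geometry curves)
as CSV plus plots with a self-describing metadata sidecar.

## Vignette

`vignettes/biofilm-allocation-methods.Rmd` documents the model
assumptions, every tunable parameter with units and defaults, the
numerical choices (singularity handling, integrator tolerances, optimizer
design, lattice rules), what the environment generator does and does not
emulate, and known limitations.
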