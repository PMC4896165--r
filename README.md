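# catdep

Exploring dependence between categorical variables by combining Bayesian
profile clustering with graphical log-linear model search.

## The problem

Epidemiologists and geneticists routinely ask which of their categorical
covariates — exposures, genotypes, behaviours — *combine*, not just which
have marginal effects. The standard answer is a graphical log-linear model
for the contingency table: an undirected graph on the covariates whose
complete subsets are the interaction terms, with absent edges encoding
conditional independence. But the model space explodes
(`2^(P(P-1)/2)` graphs: ~3.5×10¹³ for P = 10, 2⁴⁹⁵⁰ for P = 100) and the
table becomes unmanageably sparse long before P reaches 100.

`catdep` implements a two-stage strategy:

1. **Profile clustering with variable selection.** A Dirichlet-process
   mixture of product multinomials partitions subjects by their covariate
   profiles. Cluster-specific binary switches γ<sub>pc</sub> flag the
   covariates that drive the partition, via

       P(x.p = x | z_i = c) = φ_pc(x)^γ_pc · π_p(x)^(1−γ_pc),

   with a spike-and-slab prior on each covariate's selection probability
   ρ<sub>p</sub>. If a covariate's switches are never active it is
   *marginally independent of all the others* (a one-directional theorem:
   the converse does not hold) and can be removed before any log-linear
   model is fitted — collapsing both the table and the graph space.
2. **Evidence-informed reversible jump.** The switch draws are condensed
   into a P×P matrix of cluster-size-weighted co-selection evidence,
   rescaled to maximum 1. Small entries reliably flag absent edges; the
   reversible-jump sampler over graphical models uses the matrix to propose
   additions of well-supported edges and removals of poorly supported ones,
   reaching the high-probability region in fewer iterations than uniform
   proposals.

Fitted objects come with broom-style `tidy()`/`glance()` methods and
`autoplot()` ggplot2 graphics; everything tabular is a tibble.

## Worked example

### Stage 1 — which covariates cluster the subjects?

The built-in worked population has six three-level covariates and three
latent clusters (weights 0.3/0.3/0.4); `x5` and `x6` are identical across
clusters, hence pure noise.

```r
library(catdep)
pop <- illustration_population()
d   <- sample_population(pop, 1000, seed = 7)

ch <- dp_cluster(d, burnin = 500, iter = 1000, seed = 8)
tidy(ch)
#> # A tibble: 6 × 6
#>   covariate rho_median rho_mean rho_q25 rho_q75 p_zero
#>   <chr>          <dbl>    <dbl>   <dbl>   <dbl>  <dbl>
#> 1 x1             0.836   0.797    0.705   0.924  0
#> 2 x2             0.826   0.782    0.683   0.920  0
#> 3 x3             0.787   0.756    0.641   0.904  0
#> 4 x4             0.810   0.773    0.662   0.906  0
#> 5 x5             0       0.0251   0       0      0.844
#> 6 x6             0       0.0381   0       0      0.788
```

The selection probabilities separate cleanly: posterior medians around 0.8
for the four structural covariates, exactly zero (posterior mass on the
spike: `p_zero`) for the two noise covariates. The representative partition
and its summary profiles code each cluster/covariate/level as `>` (more
likely than in the whole sample), `<` (less likely) or `0` (no difference):

```r
part <- representative_partition(similarity(ch), 1:8)
summarize_profiles(ch, part)
#> <profile_summary> 4 representative clusters
#>   cluster  size x1    x2    x3    x4    x5    x6
#> 1      NA    NA 0.84  0.83  0.79  0.81  0     0
#> 2       1    34 000   000   000   000   000   000
#> 3       2   451 >><   >><   >0<   >0<   000   000
#> 4       3   303 <<>   <<>   <0>   <0>   000   000
#> 5       4   212 <0>   <0>   >0<   >0<   000   000
```

(The header row carries the median selection probabilities; switched-off
covariates show `000` everywhere, by construction.)

### Stage 2 — screening and informed model search

The flagship use case is a sparse binary design: 10 covariates, of which
`A–D` form one interaction clique and `H–J` another, with `E`, `F`, `G`
independent of everything (a scaled-down replica of the first built-in
simulation design).

```r
sim <- simulate_preset(1, n = 2000, seed = 21)
ch  <- dp_cluster(sim$data, burnin = 1500, iter = 2500, seed = 22)
round(rho_medians(ch), 2)
#>    A    B    C    D    E    F    G    H    I    J
#> 0.80 0.81 0.87 0.86 0.00 0.00 0.00 0.76 0.69 0.63

scr <- screen_covariates(rho_medians(ch), spec = sim$spec)
scr
#> <covariate_screen> threshold 0.15
#> kept (7): A B C D H I J
#> dropped (3): E F G
#> model space: 2^45 -> 2^21 graphs; cells: 1024 -> 128
```

Screening removed exactly the three independent covariates, shrinking the
graph space from 2⁴⁵ to 2²¹ models. The evidence matrix (`build_tgamma`)
then steers the reversible-jump search over the remaining seven covariates:

```r
tg  <- build_tgamma(ch)
keep <- dplyr::select(sim$data, dplyr::all_of(scr$kept))
tab  <- as_contingency(keep, sim$spec[scr$kept])
rj <- rj_search(tab, "b", tgamma = tg[scr$kept, scr$kept],
                iters = 10000, burnin = 2000, seed = 23)
rj
#> <rj_chain> strategy (b), 10000 iterations
#> best model: ABCD+HIJ  (posterior 0.907, first hit at iteration 453)
#> model-move acceptance: 4.6%
#>   model       visits posterior
#> 1 ABCD+HIJ      7260    0.908
#> 2 ABCD+HIJ+AJ    239    0.0299
#> 3 ABCD+HIJ+DJ    126    0.0158
```

The search recovers the generating model `ABCD+HIJ` with posterior visit
frequency 0.91; the uniform strategy (`"a"`) on the same data first reaches
it at iteration 512 versus 453 for the informed one, a gap that widens on
harder designs. `run_pipeline()` chains all of these stages behind one
call, and `inst/scripts/catdep` exposes them as shell subcommands
(`simulate`, `cluster`, `tgamma`, `rjsearch`, `pipeline`).

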