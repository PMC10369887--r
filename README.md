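# celldensity

Continuous cell-state density estimation for single-cell data.

Single-cell experiments sample cells from a continuous phenotypic landscape.
How densely each region of that landscape is populated carries biology:
stable, abundant populations are dense, while rare transitional states —
the cells actually executing fate decisions — are sparse. `celldensity`
infers a **continuous log-density function** over a Euclidean cell-state
space (typically diffusion components), evaluable at any state, instead of
cluster-level abundance counts or per-cell 1/kNN heuristics.

It is written for computational biologists analyzing scRNA-seq or scATAC-seq
embeddings: density landscapes of differentiation, time-series densities
across developmental stages, and the chromatin-priming analyses that build
on them.

## The model

For a cell state $x$ with nearest-neighbor distance $r$ in $d$ dimensions,
a locally homogeneous Poisson point process of intensity $\rho$ gives the
nearest-neighbor law

$$ f_{NN}(r \mid \rho) = \exp(-\rho\,b(r,d))\,\rho\,\frac{db(r,d)}{dr}, $$

with $b(r,d)$ the volume of the $d$-ball. The log-density
$f = \log \rho$ gets a Gaussian-process prior
$f \sim \mathcal{GP}(m, \mathrm{Matern52}(l))$ with a data-driven length
scale $l = \exp(3 + \overline{\log d_n})$ and a prior mean $m$ set 10
log-units below the 1st percentile of closed-form per-cell estimates.
Inference is MAP over whitened latent coefficients (L-BFGS-B, analytic
gradients); above 5000 cells the GP is sparsified with k-means landmark
(inducing-point) states. Extensions: a product Matérn kernel over
measurement time for time-continuous densities with interpolation and time
derivatives; trajectory-marginal cell-type proportions; density-weighted
gene change scores; primed vs lineage-specific chromatin accessibility
scores and in-silico-ChIP TF binding scores.

## Worked example

```r
library(celldensity)

# a simulated differentiation tree with exact ground-truth density
sim <- simulate_tree_gmm(n = 5000, dim = 10, seed = 1)
fit <- cell_density(sim$states)
fit
#> Cell-state density model (full GP)
#>   cells: 5000  state dims: 10  density dim: 10
#>   landmarks: 5000  length scale: 0.4288  prior mean: -0.3245
#>   optimizer: converged (83 objective evaluations)

# agreement with the exact mixture truth
cor(predict(fit), gmm_log_density(sim$truth, sim$states),
    method = "spearman")
#> [1] 0.946

# the fitted function is continuous: evaluate anywhere
predict(fit, sim$states[1:2, ] + 0.05)
#>  cell_1  cell_2
#> 21.9864 21.0731
```

`predict()` returns log-densities; on this landscape the fitted values span
roughly −6 (deserted stretches between branches) to +51 (the most compact
pools — this simulated manifold is thin, so densities per unit 10-D volume
are large). The Spearman correlation of 0.946 with the exact ground truth
says the landscape's ordering — which states are rare versus common — is
recovered almost perfectly. For time series, `cell_density_time(states, times)` fits one
continuous density over state × time; `predict(fit, x, time = t)`
interpolates between measured timepoints and
`density_time_derivative(fit, x, t)` gives the local rate of density
change.

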