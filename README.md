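# sensegain

Quantifying the fitness value of individually sensed information in growing
cell populations.

Microbial populations hedge against fluctuating environments by switching
phenotypes in response to noisy sensory signals. When the signal is shared
by the whole population ("common sensing" — think an extracellular cue),
classic results bound the fitness value of the signal by its directed
information about the environment. Real sensing is *individual*: each cell
draws its own noisy signal, the population diversifies, and selection then
amplifies the lineages that happened to sense correctly. `sensegain`
computes exactly how much extra fitness that individuality is worth, and
verifies the fluctuation relations that govern it.

For a discrete-time model over finite environment ($y$), signal ($z$) and
phenotype ($x$) spaces — Markov environment $T_{EF}(y'|y)$, sensing kernel
$T_S(z'|z,y')$, switching kernel $T_F(x'|x,z')$, log replication rates
$k(x,y)$ — the package provides:

* **exact path-ensemble calculators**: population fitness with individual
  sensing $\Psi_i[Y_t]$ and common sensing $\Psi_c[Y_t,Z_t]$ by
  transfer-matrix recursion, causally conditioned path probabilities, and
  retrospective (selection-biased) path distributions;
* **information measures**: the fitness gain
  $G = \langle\Psi_i\rangle - \langle\Psi_c\rangle \ge 0$ of individual
  over common sensing, the allocation-fidelity quantities $\sigma[Y_t]$,
  $\gamma_t$ and $P_\gamma$ under a metabolic decomposition
  $e^{k(x,y)} = e^{k_{\max}(y)} T_K(y|x)$, directed information
  $I[Z_t \to Y_t]$, and the Bayesian-inference loss $D_{\rm loss}$;
* **fluctuation relations**: detailed, integral
  ($\langle e^{-(\Psi_i-\Psi_c)}\rangle = 1$,
  $\langle e^{-(\gamma_t-\sigma)}\rangle = 1$) and average relations,
  checked both by exhaustive enumeration and by seeded Monte Carlo with
  convergence tracking;
* **closed-form optimal strategies**: Bayesian-posterior switching with
  delta allocation, which eliminates $D_{\rm loss}$ and attains the
  common-sensing bound $\langle\Psi_c\rangle - \langle\Psi_0\rangle \le I$;
* a YAML model-configuration format, a bundled three-state example model,
  trajectory simulation, deterministic TSV outputs and a small CLI.

## Worked example

The bundled model has two nutrient-rich environment states with matched
specialist phenotypes (growth 2.24 matched / 0.32 mismatched), a
nutrient-poor state (0.08), a binary signal that is 80% reliable in rich
states and uninformative in the poor one, and 95%-faithful
signal-tracking switching.

```r
library(sensegain)
m <- load_model(example_model_path())
m
#> <sg_model> 2 phenotypes x 3 environments x 2 signals
#>   phenotypes:   s1x, s2x
#>   environments: s1y, s2y, s3y
#>   signals:      s1z, s2z
#>   sensing memoryless, switching memoryless, decomposition attached

measures_report(m, 1:4)
#>   t psi_i_avg psi_c_avg psi0_avg      G I_directed   Dloss gamma kl_q_pgamma
#> 1 1    0.3039    0.1656  -0.3894 0.1383     0.3169 -0.2381 1.283      0.5897
#> 2 2    0.6079    0.3312   0.1559 0.2767     0.4586  0.2833 1.467      1.0155
#> 3 3    0.9118    0.4968   0.7013 0.4150     0.6002  0.8048 1.652      1.4413
#> 4 4    1.2157    0.6624   1.2467 0.5534     0.7419  1.3262 1.836      1.8672
```

At every horizon the individual-sensing fitness exceeds the common-sensing
fitness by exactly `G` (here ≈ 0.138 per step): the value of drawing your
own noisy signal rather than sharing one. The integral fluctuation
relation behind that gain holds exactly, and its Monte Carlo estimator
converges:

```r
ifr_exact(m, "g", t = 4)
#> [1] 1

ifr_monte_carlo(m, "g", t = 20, n = 1e5, seed = 1)
#> <fr_report> relation 'g', t = 20, n = 100000 (seed 1)
#>   final running average = 1.009934 (sample max 33.6)
```

(The sample maximum is reported because the integrand is heavy-tailed:
single lucky histories carry weight 30+ even though the mean is 1.)

A command-line wrapper for simulation, enumeration, measure reports, FR
verification and strategy bounds ships in `inst/cli/sensegain.R`:

```sh
Rscript inst/cli/sensegain.R reproduce-figures --seed 0 --out out/
```

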