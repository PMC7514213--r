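---
title: "The fitness value of individually sensed information"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The fitness value of individually sensed information}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sensegain)
```

## The model

`sensegain` studies a clonal population growing in discrete time in a
fluctuating environment. Four finite-state processes interact in a fixed
causal order within each step
$y_{\tau+1} \to z_{\tau+1} \to x_{\tau+1} \to \text{replication}$:

* the **environment** $y \in S_y$ follows a Markov chain with transition
  kernel $T_{EF}(y'|y)$ and initial law $p_E(y_0)$;
* each organism receives a **sensing signal** $z \in S_z$ from a kernel
  $T_S(z'|z, y')$ conditioned on the *updated* environment (the memoryless
  case $T_S(z'|y')$ is typical);
* the organism switches its **phenotype** $x \in S_x$ with kernel
  $T_F(x'|x, z')$;
* it then multiplies by $e^{k(x', y')}$, where $k(x,y)$ is the log
  replication rate. There is no replication at $\tau = 0$.

Two sensing modes are compared. Under **individual sensing** every organism
draws its own signal, so the population carries a joint abundance
$N_t(x, z)$ over phenotype and signal. Under **common sensing** a single
signal realization $Z_t$ is shared by all organisms. Fitness is the log
total growth,
$\Psi_i[Y_t] = \ln N_t / N_0$ for individual sensing (a function of the
environment history only, because the signals are summed over) and
$\Psi_c[Y_t, Z_t]$ for common sensing. Both are computed exactly by
transfer-matrix recursions (`fitness_individual()`, `fitness_common()`),
equal to exhaustive path sums
$\Psi_i = \ln \langle e^{K} \rangle_{P_{F,S}}$ with
$K[X_t, Y_t] = \sum_{\tau=0}^{t-1} k(x_{\tau+1}, y_{\tau+1})$ the
historical fitness.

Tracing a grown population backward in time biases path statistics toward
lineages that grew: the **retrospective distributions**
$P_{Bi}[Z_t|Y_t] \propto e^{K - \Psi_i} P_F P_S$
(`retrospective_sensing_dist()`) quantify this selection bias.

## Fitness gain, fidelity and information measures

The pathwise difference $g = \Psi_i - \Psi_c$ satisfies a detailed
fluctuation relation $e^{-g} = P_{Bi}[Z_t|Y_t]/P_S[Z_t \| Y_t]$ and hence
the integral relation $\langle e^{-g} \rangle = 1$, which forces
$G = \langle g \rangle \ge 0$: *on average, individually sensed information
is worth at least as much as the same signal shared by everyone*. The gain
`fitness_gain_G()` is the KL divergence between forward and retrospective
signal-path measures; it is earned by selection acting on organisms that
happened to sense correctly.

With a **metabolic allocation decomposition**
$e^{k(x,y)} = e^{k_{\max}(y)} T_K(y|x)$ — each phenotype allocates a
fraction $T_K(y|x)$ of its resources to environment $y$ — the fitness
splits pathwise as $\Psi_i = K_{\max}[Y_t] + \ln P_{KFS}[Y_t|Y_t]$, where
$P_{KFS}[Y'_t|Y_t]$ (`pkfs()`) is the probability that resources follow
allocation history $Y'_t$ while the environment realizes $Y_t$. Relative
to the no-sensing benchmark $\Psi_0 = K_{\max} + \ln Q$, the gain of
individual sensing is $\sigma[Y_t] = \ln(P_{KFS}[Y_t|Y_t]/Q[Y_t])$, with
total fidelity $\gamma_t = \ln \sum_{Y_t} P_{KFS}[Y_t|Y_t]$ and tilted
measure $P_\gamma = e^{-\gamma_t} P_{KFS}[Y_t|Y_t]$
(`gamma_and_pgamma()`). A second integral relation
$\langle e^{-(\gamma_t - \sigma)} \rangle_Q = 1$ follows from
$P_\gamma$ being normalized.

For a Markov environment and memoryless sensing, the joint law factorizes
through Bayes' theorem (`bayes_kernels()`) into a signal predictive
$T_{SB}(z'|y)$ and an environment posterior $T_{SB}(y'|z', y)$, giving the
pointwise **directed information** $i[Z_t \to Y_t]$ from signal to
environment (the direction that bounds fitness — note this is the reverse
of the more common environment-to-signal convention) and the balance
identities
$\langle\Psi_i\rangle = \langle\Psi_0\rangle + I + G - D_{\rm loss}$ and
$\langle\Psi_c\rangle = \langle\Psi_0\rangle + I - D_{\rm loss}$, where
$D_{\rm loss}$ (`dloss()`) measures how far switching-plus-allocation is
from implementing exact sequential Bayesian inference.

When phenotypes can be identified with environments, the closed-form
optimal strategy (`optimal_strategy()`) is delta allocation
$T_K^*(y|x) = \delta_{x,y}$ — with off-diagonal log replication rates
equal to $-\infty$, since a fully committed phenotype cannot grow
elsewhere — together with posterior switching
$T_F^*(x'|x, z') = T_{SB}(y'|z', y)$. It drives $D_{\rm loss}$ to zero, so
the common-sensing gain attains its bound
$\langle\Psi_c\rangle - \langle\Psi_0\rangle \le I$, while individual
sensing still adds $G^* \ge 0$ on top.

## The role of the initial environment state

The package follows the definitions above literally, which makes one
boundary convention load-bearing. $K_{\max}$ sums from $\tau = 1$, and the
allocation path weight $P_K[Y_t \| X_t]$ constrains only
$y_1, \dots, y_t$: the cascade carries no distribution over the state at
time 0. Consequences, verified exactly in the test suite:

* the relations for $g$ and $\gamma_t - \sigma$ integrate to 1 for **any**
  initial distribution $p_E$, as do all the average identities above;
* the third integral relation, for
  $\Psi_0 + i + g - \Psi_i$, integrates to the **number of initial
  environment states in the support of** $p_E$. It reads 1 — and
  $D_{\rm loss}$ is a true (non-negative) divergence with the optimal
  strategy reaching 0 — exactly when the population starts from a known
  environmental state. `ifr_exact()` documents and reproduces both
  regimes; tests of the $D_{\rm loss}$ theorems therefore fix a point-mass
  initial state, and `dloss()` notes the $-\ln|S_y|$ lower bound that
  applies otherwise.

In `pkfs()` the time-0 coordinate of the allocation history is tied to the
realized $y_0$, which makes $P_{KFS}[\cdot|Y_t]$ a normalized distribution
over full-length histories and keeps $\gamma_t$ equal to the sum of
diagonal terms over all $(t+1)$-length histories. The initial marginal
used in the Bayesian factorization is
$p(z_0) = \sum_{y_0} p_S(z_0|y_0)\, p_E(y_0)$.

## The bundled model and defaults

The configuration returned by `example_model_path()` encodes a
three-state environment: two nutrient-rich states that the population's
two specialist phenotypes are adapted to (growth factor 2.24 when matched,
0.32 when mismatched) and a nutrient-poor state (0.08 for both), with a
binary signal read correctly with probability 0.8 in rich states and
uninformatively (0.5) in the poor one, and 0.95-reliable signal-tracking
switching. Defaults chosen here and used throughout:

* **initial distributions**: $p_E$ = stationary distribution of $T_{EF}$
  (here $(5/11, 5/11, 1/11)$); $p_S(z_0|y_0)$ and $p_F(x_0|z_0)$ = the
  memoryless kernels applied at time 0. All three are overridable in the
  configuration.
* **decomposition pin**: with two phenotypes and three environments the
  system $\sum_y e^{k(x,y) - k_{\max}(y)} = 1$ is underdetermined by one
  degree of freedom; the bundled configuration pins
  $e^{k_{\max}} = 0.16$ in the poor state, giving $e^{k_{\max}} = 5.12$
  in both rich states and allocations $(0.4375, 0.0625, 0.5)$ per
  phenotype. $\gamma_t$, $\sigma$ and $P_\gamma$ depend on this choice;
  $G$, $I$, $D_{\rm loss}$ and every integral relation do not.
* **tolerances**: conditional tables must be row-stochastic within
  $10^{-9}$ (configs carry few significant digits; sub-tolerance float
  error is renormalized, anything larger is a hard error). Exact
  identities are asserted at $10^{-10}$, averages at $10^{-9}$.
* **enumeration guard**: exhaustive sums refuse to materialize more than
  $10^7$ histories unless overridden, so an accidental $t = 20$
  enumeration fails fast instead of exhausting memory.
* **log domain**: all single-path recursions run in log space with
  log-sum-exp; the batch engine propagates linear-domain tables with
  per-step renormalization, accumulating the log of the removed mass.
  Zero probabilities propagate as $-\infty$ with the convention
  $0 \cdot e^{-\infty} = 0$.

## What the generator and the tests do (and do not) show

`random_model()` draws kernel rows from the flat simplex and log rates
uniformly on $[-1, 1]$ by default (or induces them from a random
decomposition), which exercises the identities far from the structured
fixture. These are *synthetic* stress tests: the fluctuation relations are
theorems, so their verification validates the implementation, not the
biology. The model itself deliberately omits carrying capacity,
cell–cell interaction, feedback from the population onto the environment,
and demographic noise — given $(Y_t, Z_t)$ the recursions are
deterministic, so only environment and signal are random.

## Numerical choices for sampled runs

Monte Carlo verification (`ifr_monte_carlo()`) samples $(Y_t, Z_t)$
forward with one seeded RNG stream; draws are vectorized group-by-state in
a fixed order, so a run is fully reproducible from `(n, seed)`. Sampled
runs default to horizon $t = 20$. The integrands $e^{-g}$ and especially
$e^{-(\gamma_t - \sigma)}$ are heavy-tailed (rare histories dominate, as
in Jarzynski-type estimators), so reports carry the sample maximum next to
the running average; at $n = 10^5$ the $g$-relation average sits within
three standard errors of 1 even at $t = 20$, while the fidelity relation
needs shorter horizons for comparable accuracy. Exhaustive cross-checks in
the tests use $t \le 5$ (up to $3^6 \cdot 2^6$ weighted terms), where
every identity is verified to $10^{-10}$; ensemble comparisons use
$10^5$ realizations.

## Limitations

* Exact information measures require exhaustive enumeration, so they are
  limited to short horizons and small alphabets; only $\gamma_t$ has a
  polynomial-time exact contraction at any horizon.
* The closed-form optimal strategy requires $|S_x| = |S_y|$, a Markov
  environment and memoryless sensing; no numerical optimizer over
  $(T_F, T_K)$ is included, and the package makes no claim about the true
  maximizer of the individual-sensing fitness.
* Continuous state spaces, time-inhomogeneous kernels and age- or
  size-structured populations are out of scope.
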