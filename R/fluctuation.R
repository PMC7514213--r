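# ---------------------------------------------------------------------------
# Fluctuation relations. Three relations are tracked:
#   "g"          e^{-(Psi_i - Psi_c)}                 averaged over Q[Yt, Zt]
#   "gamma_sigma" e^{-(gamma_t - sigma[Yt])}          averaged over Q[Yt]
#   "psi0_i_g"   e^{-(Psi_0 + i + g - Psi_i)}         averaged over Q[Yt, Zt]
# The first two integrate to exactly 1 for any initial environment
# distribution. The third integrates to the number of initial environment
# states with positive probability: its reference measure carries no
# distribution over y0, so the identity reads 1 only when the population
# starts from a known environmental state (point-mass initial distribution).
# ---------------------------------------------------------------------------

.FR_RELATIONS <- c("g", "gamma_sigma", "psi0_i_g")

#' Pathwise fitness difference between individual and common sensing
#'
#' `g[Yt, Zt] = Psi_i[Yt] - Psi_c[Yt, Zt]`.
#'
#' @param model an `sg_model`.
#' @param Yt environment history.
#' @param Zt common-signal history of the same horizon.
#' @return Scalar `g`.
#' @export
fitness_difference_g <- function(model, Yt, Zt) {
  fitness_individual(model, Yt) - fitness_common(model, Yt, Zt)
}

#' Residual of the detailed fluctuation relation for g
#'
#' Checks `e^{-g[Yt,Zt]} = PBi[Zt|Yt] / PS[Zt||Yt]` over every joint history
#' with positive forward probability; the left side uses the two fitness
#' recursions, the right side the retrospective signal distribution
#' normalized by its explicit sum over signal histories.
#'
#' @param model an `sg_model`.
#' @param t horizon.
#' @param guard enumeration guard.
#' @return Maximum absolute residual.
#' @export
check_detailed_fr_g <- function(model, t, guard = .DEFAULT_GUARD) {
  ny <- length(model$spaces$environments)
  nz <- length(model$spaces$signals)
  Yg <- .enum_idx(ny, t, guard)
  Zg <- .enum_idx(nz, t, guard)
  lnq <- .batch_env_logprob(model, Yg)
  worst <- 0
  for (iy in seq_len(nrow(Yg))) {
    if (lnq[iy] == -Inf) next
    y <- Yg[iy, ]
    Ymat <- matrix(y, nrow(Zg), t + 1L, byrow = TRUE)
    lnS <- .batch_sensing_logprob(model, Zg, Ymat)
    psi_c <- .batch_psi_c(model, Ymat, Zg)
    psi_i <- fitness_individual(model, y)
    # PBi normalized by the explicit sum over signal histories
    lb <- lnS + psi_c
    pbi <- exp(lb - logsumexp(lb))
    sup <- lnS > -Inf
    resid <- abs(exp(psi_c[sup] - psi_i) - pbi[sup] / exp(lnS[sup]))
    if (length(resid)) worst <- max(worst, resid)
  }
  worst
}

#' Exact integral fluctuation relation expectation
#'
#' Exhaustively averages the integrand of the chosen relation under the
#' forward measure. Relations `"g"` and `"gamma_sigma"` integrate to 1 for
#' any model; `"psi0_i_g"` integrates to the number of initial environment
#' states in the support of `pE` (1 for a deterministic start).
#'
#' @param model an `sg_model` (decomposition required except for `"g"`).
#' @param relation one of `"g"`, `"gamma_sigma"`, `"psi0_i_g"`.
#' @param t horizon.
#' @param guard enumeration guard.
#' @return Scalar expectation.
#' @export
ifr_exact <- function(model, relation = .FR_RELATIONS, t,
                      guard = .DEFAULT_GUARD) {
  relation <- match.arg(relation)
  if (relation == "gamma_sigma") {
    Yg <- .enum_idx(length(model$spaces$environments), t, guard)
    lnq <- .batch_env_logprob(model, Yg)
    gam <- gamma_total(model, t)
    sup <- lnq > -Inf
    sigma <- .batch_pkfs_diag(model, Yg[sup, , drop = FALSE]) - lnq[sup]
    return(sum(exp(lnq[sup]) * exp(sigma - gam)))
  }
  grids <- .joint_grid(model, t, guard)
  sup <- grids$lw > -Inf
  Y <- grids$Y[sup, , drop = FALSE]
  Z <- grids$Z[sup, , drop = FALSE]
  psi_c <- .batch_psi_c(model, Y, Z)
  if (relation == "g") {
    psi_i <- .batch_psi_i(model, Y)
    return(sum(exp(grids$lw[sup] + psi_c - psi_i)))
  }
  # psi0_i_g: integrand e^{-(Psi_0 + i + g - Psi_i)} = e^{Psi_c - Psi_0 - i}
  if (is.null(model$decomposition))
    stopf("model has no metabolic-allocation decomposition attached")
  psi0 <- .batch_kmax(model, Y) + .batch_env_logprob(model, Y)
  di <- .batch_bayes(model, Y, Z)$pointwise
  sum(exp(grids$lw[sup] + psi_c - psi0 - di))
}

#' Monte Carlo verification of an integral fluctuation relation
#'
#' Samples environment/signal history pairs forward from the model, evaluates
#' the relation's integrand on each sample, and tracks the running average,
#' which converges to the exact expectation (1 for relations `"g"` and
#' `"gamma_sigma"`). The integrands are heavy-tailed: rare histories carry
#' integrand values far above 1, so the report also records the sample
#' maximum to make convergence stalls visible.
#'
#' @param model an `sg_model` (decomposition required except for `"g"`).
#' @param relation one of `"g"`, `"gamma_sigma"`, `"psi0_i_g"`.
#' @param t horizon.
#' @param n number of samples.
#' @param seed integer seed; identical `(n, seed)` give identical reports.
#' @param exact also compute the exhaustive expectation (small `t` only).
#' @param guard enumeration guard for the exact value.
#' @return An object of class `fr_report`: a list with `relation`,
#'   `integrand_samples`, `running_average`, `exact_value` (or `NA`),
#'   `n_samples`, `seed`, `t`, `sample_max`.
#' @export
ifr_monte_carlo <- function(model, relation = .FR_RELATIONS, t = 20, n,
                            seed = 0, exact = FALSE,
                            guard = .DEFAULT_GUARD) {
  relation <- match.arg(relation)
  stopifnot(n >= 1)
  if (relation != "g" && is.null(model$decomposition))
    stopf("model has no metabolic-allocation decomposition attached")
  set.seed(seed)
  h <- .sample_histories(model, t, n)
  integrand <- switch(
    relation,
    g = {
      psi_i <- .batch_psi_i(model, h$Y)
      psi_c <- .batch_psi_c(model, h$Y, h$Z)
      exp(psi_c - psi_i)
    },
    gamma_sigma = {
      gam <- gamma_total(model, t)
      sigma <- .batch_pkfs_diag(model, h$Y) - .batch_env_logprob(model, h$Y)
      exp(sigma - gam)
    },
    psi0_i_g = {
      psi_c <- .batch_psi_c(model, h$Y, h$Z)
      psi0 <- .batch_kmax(model, h$Y) + .batch_env_logprob(model, h$Y)
      di <- .batch_bayes(model, h$Y, h$Z)$pointwise
      exp(psi_c - psi0 - di)
    })
  structure(list(relation = relation,
                 integrand_samples = integrand,
                 running_average = cumsum(integrand) / seq_len(n),
                 exact_value = if (exact) ifr_exact(model, relation, t, guard)
                               else NA_real_,
                 n_samples = n, seed = seed, t = t,
                 sample_max = max(integrand)),
            class = "fr_report")
}

#' @export
print.fr_report <- function(x, ...) {
  cat(sprintf("<fr_report> relation '%s', t = %d, n = %d (seed %d)\n",
              x$relation, x$t, x$n_samples, x$seed))
  cat(sprintf("  final running average = %.6f (sample max %.3g)\n",
              x$running_average[x$n_samples], x$sample_max))
  if (!is.na(x$exact_value))
    cat(sprintf("  exact expectation     = %.12f\n", x$exact_value))
  invisible(x)
}

#' Residuals of the average fluctuation relations
#'
#' Exhaustively checks the average identities linking the fitness averages to
#' the information measures: the gain identity `<Psi_i> - <Psi_c> = G`, the
#' pathwise fitness decomposition `Psi_i = Kmax + ln PKFS[Yt|Yt]`, the
#' fidelity identity `<Psi_i> = <Psi_0> + gamma_t - D[Q||P_gamma]`, and the
#' directed-information balances
#' `<Psi_i> = <Psi_0> + I + G - Dloss` and `<Psi_c> = <Psi_0> + I - Dloss`.
#'
#' @param model an `sg_model`; rows beyond the gain identity require a
#'   decomposition (and memoryless sensing for the balances).
#' @param t horizon.
#' @param guard enumeration guard.
#' @return A data frame with columns `relation`, `lhs`, `rhs`, `residual`.
#' @export
average_fr_report <- function(model, t, guard = .DEFAULT_GUARD) {
  av <- psi_averages(model, t, guard)
  G <- fitness_gain_G(model, t, guard)
  rows <- data.frame(relation = "gain", lhs = av$psi_i - av$psi_c, rhs = G,
                     stringsAsFactors = FALSE)
  if (!is.null(model$decomposition)) {
    Yg <- .enum_idx(length(model$spaces$environments), t, guard)
    lnq <- .batch_env_logprob(model, Yg)
    sup <- lnq > -Inf
    Ys <- Yg[sup, , drop = FALSE]
    fit_resid <- max(abs(.batch_psi_i(model, Ys) -
                           (.batch_kmax(model, Ys) +
                              .batch_pkfs_diag(model, Ys))))
    fid <- gamma_and_pgamma(model, t, guard)
    rows <- rbind(rows,
                  data.frame(relation = "fitness_decomposition",
                             lhs = fit_resid, rhs = 0),
                  data.frame(relation = "fidelity",
                             lhs = av$psi_i,
                             rhs = av$psi0 + fid$gamma_total -
                               fid$kl_env_pgamma))
    if (model$sensing$memoryless) {
      I <- directed_information(model, t, guard)
      dl <- dloss(model, t, guard)
      rows <- rbind(rows,
                    data.frame(relation = "individual_balance",
                               lhs = av$psi_i,
                               rhs = av$psi0 + I + G - dl),
                    data.frame(relation = "common_balance",
                               lhs = av$psi_c,
                               rhs = av$psi0 + I - dl))
    }
  }
  rows$residual <- rows$lhs - rows$rhs
  rows
}
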