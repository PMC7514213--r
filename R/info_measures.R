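# ---------------------------------------------------------------------------
# Information measures: the fitness gain of individual sensing, allocation
# fidelity (sigma, gamma_t, P_gamma), the Bayesian causal decomposition of
# the joint environment/signal law, directed information, and the
# Bayesian-inference loss.
#
# Directed information here runs from the signal history to the environment
# history (Z -> Y): it measures how sharply the signal path pins down the
# realized environment path, which is the direction that bounds fitness.
#
# KL terms follow the 0 log 0 = 0 convention; if the forward measure puts
# mass outside the reference support the divergence is reported as +Inf.
# ---------------------------------------------------------------------------

#' Fitness gain of individual over common sensing
#'
#' The KL divergence between the forward joint law of (signal, environment)
#' histories and its selection-biased retrospective counterpart; equal to the
#' exact average fitness difference `<Psi_i> - <Psi_c>` when the common
#' signal follows the same statistics as the individual sensing signal.
#' Always non-negative.
#'
#' @param model an `sg_model`.
#' @param t horizon.
#' @param guard enumeration guard on the number of joint histories.
#' @return Scalar `G >= 0`.
#' @export
fitness_gain_G <- function(model, t, guard = .DEFAULT_GUARD) {
  ny <- length(model$spaces$environments)
  nz <- length(model$spaces$signals)
  Yg <- .enum_idx(ny, t, guard)
  Zg <- .enum_idx(nz, t, guard)
  nY <- nrow(Yg); nZ <- nrow(Zg)
  if (nY * nZ > guard) stopf("joint enumeration exceeds the guard")
  lnq <- .batch_env_logprob(model, Yg)
  psi_i <- .batch_psi_i(model, Yg)
  YY <- Yg[rep(seq_len(nY), each = nZ), , drop = FALSE]
  ZZ <- Zg[rep(seq_len(nZ), times = nY), , drop = FALSE]
  lnS <- .batch_sensing_logprob(model, ZZ, YY)
  lw <- rep(lnq, each = nZ) + lnS
  # ln PBi[Zt|Yt] = ln PS + Psi_c - Psi_i, so the log-ratio is Psi_i - Psi_c
  lr <- rep(psi_i, each = nZ) - .batch_psi_c(model, YY, ZZ)
  w <- exp(lw)
  sup <- w > 0
  sum(w[sup] * lr[sup])
}

#' Probability of an allocation history given the realized environment
#'
#' `PKFS[Yt'|Yt]`: the probability that the cascade sensing -> switching ->
#' metabolic allocation commits resources to environment history `Yt'` while
#' the population actually experiences `Yt`. The time-0 state of the
#' allocation history is tied to the realized `y0` (allocation starts with
#' the first transition), making `PKFS[.|Yt]` a normalized distribution over
#' full-length histories.
#'
#' @param model an `sg_model` with a decomposition attached.
#' @param Yt_alloc allocation history.
#' @param Yt_actual realized environment history of the same horizon.
#' @return Scalar probability.
#' @export
pkfs <- function(model, Yt_alloc, Yt_actual) {
  exp(.pkfs_log(model, Yt_alloc, Yt_actual))
}

.pkfs_log <- function(model, Yt_alloc, Yt_actual) {
  if (is.null(model$decomposition))
    stopf("model has no metabolic-allocation decomposition attached")
  ya <- .hist_idx(Yt_alloc, model$spaces$environments, "environment")
  y <- .hist_idx(Yt_actual, model$spaces$environments, "environment")
  if (length(ya) != length(y)) stopf("allocation and realized horizons differ")
  if (ya[1] != y[1]) return(-Inf)
  nx <- length(model$spaces$phenotypes)
  nz <- length(model$spaces$signals)
  lnTS <- log(model$sensing$kernel)
  lnTF <- log(model$switching$kernel)
  lnTK <- log(model$decomposition$TK)
  logW <- matrix(log(t(model$switching$initial)), nx, nz) +
    matrix(log(model$sensing$initial[y[1], ]), nx, nz, byrow = TRUE)
  for (tau in seq_len(length(y) - 1L)) {
    yn <- y[tau + 1L]; yan <- ya[tau + 1L]
    B <- matrix(-Inf, nx, nz)
    for (zp in seq_len(nz))
      B[, zp] <- .lse_rows(logW + matrix(lnTS[, yn, zp], nx, nz, byrow = TRUE))
    new <- matrix(-Inf, nx, nz)
    for (xp in seq_len(nx))
      for (zp in seq_len(nz))
        new[xp, zp] <- lnTK[xp, yan] + logsumexp(B[, zp] + lnTF[, zp, xp])
    logW <- new
  }
  logsumexp(logW)
}

#' Pathwise fidelity gain of individual sensing
#'
#' `sigma[Yt] = ln( PKFS[Yt|Yt] / Q[Yt] )`, the log-odds of allocating
#' resources to the realized environment history relative to how probable
#' that history was. Satisfies `Psi_i[Yt] = Kmax[Yt] + ln PKFS[Yt|Yt]`
#' exactly.
#'
#' @param model an `sg_model` with a decomposition attached.
#' @param Yt environment history with `Q[Yt] > 0`.
#' @return Scalar `sigma[Yt]`.
#' @export
sigma_of_history <- function(model, Yt) {
  lq <- env_logprob(model, Yt)
  if (lq == -Inf) stopf("sigma is undefined on a zero-probability environment history")
  .pkfs_log(model, Yt, Yt) - lq
}

#' Fidelity report: sigma, total fidelity and the tilted path measure
#'
#' Enumerates all environment histories at horizon `t` and returns the
#' pathwise fidelity gains `sigma[Yt]`, the total fidelity
#' `gamma_t = ln sum_Yt PKFS[Yt|Yt]`, the tilted measure
#' `P_gamma[Yt] = e^{-gamma_t} PKFS[Yt|Yt]`, and `D[Q || P_gamma]`. The
#' average identity `<sigma>_Q = gamma_t - D[Q || P_gamma]` holds exactly.
#'
#' @param model an `sg_model` with a decomposition attached.
#' @param t horizon.
#' @param guard enumeration guard.
#' @return An object of class `fidelity_report`: a list with
#'   `sigma_by_history` (named vector; `+Inf` where `Q[Yt] = 0`),
#'   `gamma_total`, `p_gamma` (named probability vector) and
#'   `kl_env_pgamma`.
#' @export
gamma_and_pgamma <- function(model, t, guard = .DEFAULT_GUARD) {
  if (is.null(model$decomposition))
    stopf("model has no metabolic-allocation decomposition attached")
  ys <- model$spaces$environments
  Yg <- .enum_idx(length(ys), t, guard)
  ld <- .batch_pkfs_diag(model, Yg)     # ln PKFS[Yt|Yt]
  lnq <- .batch_env_logprob(model, Yg)
  gam <- logsumexp(ld)
  pg <- exp(ld - gam)
  nm <- .join_hist(Yg, ys)
  sigma <- ld - lnq
  names(sigma) <- names(pg) <- nm
  structure(list(sigma_by_history = sigma,
                 gamma_total = gam,
                 p_gamma = pg,
                 kl_env_pgamma = sum(xlogxy(exp(lnq), pg))),
            class = "fidelity_report")
}

#' @export
print.fidelity_report <- function(x, ...) {
  cat(sprintf("<fidelity_report> %d environment histories\n",
              length(x$p_gamma)))
  cat(sprintf("  gamma_t          = %.6f\n", x$gamma_total))
  cat(sprintf("  D[Q || P_gamma]  = %.6f\n", x$kl_env_pgamma))
  fin <- is.finite(x$sigma_by_history)
  cat(sprintf("  sigma range      = [%.4f, %.4f] over supp(Q)\n",
              min(x$sigma_by_history[fin]), max(x$sigma_by_history[fin])))
  invisible(x)
}

#' Bayesian causal decomposition of the environment/signal law
#'
#' For a Markov environment and memoryless sensing, the joint forward law
#' factorizes as `PS[Yt, Zt] = PSB[Yt || Zt] PSB[Zt || Yt-1]`, built from the
#' one-step signal predictive `TSB(z'|y) = sum_{y'} TS(z'|y') TEF(y'|y)` and
#' the environment posterior `TSB(y'|z', y)` obtained by Bayes' theorem. The
#' marginal initial signal law is `p(z0) = sum_{y0} pS(z0|y0) pE(y0)`.
#'
#' @param model an `sg_model` with memoryless sensing.
#' @return An object of class `bayes_kernels`: a list with
#'   `signal_predictive` (`[y, z']`), `env_posterior` (`[y, z', y']`),
#'   `initial_signal` (`p(z0)`) and `initial_posterior` (`[z0, y0]`).
#' @export
bayes_kernels <- function(model) {
  if (!model$sensing$memoryless)
    stopf("the Bayesian causal decomposition requires memoryless sensing")
  ny <- length(model$spaces$environments)
  nz <- length(model$spaces$signals)
  TEF <- model$env$transition
  TS <- matrix(model$sensing$kernel[1, , ], ny, nz,
               dimnames = dimnames(model$sensing$kernel)[c(2, 3)])
  predictive <- TEF %*% TS        # [y, z']
  posterior <- array(0, c(ny, nz, ny),
                     dimnames = list(model$spaces$environments,
                                     model$spaces$signals,
                                     model$spaces$environments))
  for (y in seq_len(ny))
    for (zp in seq_len(nz))
      posterior[y, zp, ] <- if (predictive[y, zp] > 0)
        TEF[y, ] * TS[, zp] / predictive[y, zp] else 0
  pE <- model$env$initial
  pz0 <- as.vector(crossprod(model$sensing$initial, pE))
  names(pz0) <- model$spaces$signals
  post0 <- matrix(0, nz, ny, dimnames = list(model$spaces$signals,
                                             model$spaces$environments))
  for (z in seq_len(nz))
    post0[z, ] <- if (pz0[z] > 0) model$sensing$initial[, z] * pE / pz0[z] else 0
  structure(list(signal_predictive = predictive, env_posterior = posterior,
                 initial_signal = pz0, initial_posterior = post0),
            class = "bayes_kernels")
}

#' Pointwise directed information from signal to environment
#'
#' `i[Zt -> Yt] = ln PSB[Yt || Zt] - ln Q[Yt]`, where `PSB[Yt || Zt]` is the
#' product of Bayesian environment posteriors along the path.
#'
#' @param model an `sg_model` with memoryless sensing.
#' @param Zt signal history.
#' @param Yt environment history with `Q[Yt] > 0`.
#' @return Scalar pointwise directed information.
#' @export
pointwise_directed_info <- function(model, Zt, Yt) {
  z <- .hist_idx(Zt, model$spaces$signals, "signal")
  y <- .hist_idx(Yt, model$spaces$environments, "environment")
  if (length(z) != length(y)) stopf("signal and environment horizons differ")
  if (env_logprob(model, y) == -Inf)
    stopf("pointwise directed information is undefined on a zero-probability environment history")
  .batch_bayes(model, matrix(y, 1), matrix(z, 1))$pointwise
}

#' Directed information from the signal to the environment history
#'
#' Exhaustive average of the pointwise directed information under the joint
#' forward law; non-negative.
#'
#' @param model an `sg_model` with memoryless sensing.
#' @param t horizon.
#' @param guard enumeration guard on the number of joint histories.
#' @return Scalar `I >= 0`.
#' @export
directed_information <- function(model, t, guard = .DEFAULT_GUARD) {
  grids <- .joint_grid(model, t, guard)
  b <- .batch_bayes(model, grids$Y, grids$Z)
  w <- exp(grids$lw)
  sup <- w > 0
  sum(w[sup] * b$pointwise[sup])
}

# the full (Yt, Zt) grid with forward log-weights ln Q + ln PS
.joint_grid <- function(model, t, guard = .DEFAULT_GUARD) {
  ny <- length(model$spaces$environments)
  nz <- length(model$spaces$signals)
  Yg <- .enum_idx(ny, t, guard)
  Zg <- .enum_idx(nz, t, guard)
  nY <- nrow(Yg); nZ <- nrow(Zg)
  if (nY * nZ > guard) stopf("joint enumeration exceeds the guard")
  YY <- Yg[rep(seq_len(nY), each = nZ), , drop = FALSE]
  ZZ <- Zg[rep(seq_len(nZ), times = nY), , drop = FALSE]
  lw <- rep(.batch_env_logprob(model, Yg), each = nZ) +
    .batch_sensing_logprob(model, ZZ, YY)
  list(Y = YY, Z = ZZ, lw = lw)
}

#' Loss from imperfect implementation of sequential Bayesian inference
#'
#' `D[ PS[Yt, Zt] || PK,F[Yt|Zt] PSB[Zt || Yt-1] ]`, where
#' `PK,F[Yt|Zt] = sum_Xt PK[Yt || Xt] PF[Xt || Zt]` is the law with which
#' switching plus allocation assign resources to environment histories given
#' the signal. Zero exactly when the strategy implements the Bayesian
#' posterior path measure on the support. The reference measure is
#' normalized only when the initial environment state is deterministic; with
#' a stochastic initial state the value can be negative (bounded below by
#' `-ln |Sy|`), because the allocation cascade carries no distribution over
#' the state at time 0.
#'
#' @param model an `sg_model` with a decomposition and memoryless sensing.
#' @param t horizon.
#' @param guard enumeration guard on the number of joint histories.
#' @return Scalar divergence (`+Inf` if forward mass escapes the reference
#'   support).
#' @export
dloss <- function(model, t, guard = .DEFAULT_GUARD) {
  if (is.null(model$decomposition))
    stopf("model has no metabolic-allocation decomposition attached")
  grids <- .joint_grid(model, t, guard)
  lref <- .batch_lnpkf(model, grids$Y, grids$Z) +
    .batch_bayes(model, grids$Y, grids$Z)$ln_psb_signal
  w <- exp(grids$lw)
  sup <- w > 0
  if (any(lref[sup] == -Inf)) return(Inf)
  sum(w[sup] * (grids$lw[sup] - lref[sup]))
}

#' Exact information-measure report over a range of horizons
#'
#' One row per horizon with the exact averages `<Psi_i>`, `<Psi_c>`,
#' `<Psi_0>`, the fitness gain `G`, directed information, the
#' Bayesian-inference loss, the total fidelity `gamma_t` and
#' `D[Q || P_gamma]`.
#'
#' @param model an `sg_model` with a decomposition and memoryless sensing.
#' @param horizons integer vector of horizons.
#' @param guard enumeration guard.
#' @return A data frame with columns `t`, `psi_i_avg`, `psi_c_avg`,
#'   `psi0_avg`, `G`, `I_directed`, `Dloss`, `gamma`, `kl_q_pgamma`.
#' @export
measures_report <- function(model, horizons, guard = .DEFAULT_GUARD) {
  rows <- lapply(horizons, function(t) {
    av <- psi_averages(model, t, guard)
    fid <- gamma_and_pgamma(model, t, guard)
    data.frame(t = t, psi_i_avg = av$psi_i, psi_c_avg = av$psi_c,
               psi0_avg = av$psi0, G = av$gain,
               I_directed = directed_information(model, t, guard),
               Dloss = dloss(model, t, guard),
               gamma = fid$gamma_total,
               kl_q_pgamma = fid$kl_env_pgamma)
  })
  do.call(rbind, rows)
}
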