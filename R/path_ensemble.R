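# ---------------------------------------------------------------------------
# Exact single-path operations: path log-probabilities, historical fitness,
# and the population fitness recursions (transfer-matrix dynamic programming
# in log domain). The causal order within one step is
#   y_{tau+1} -> z_{tau+1} -> x_{tau+1} -> replication by e^{k(x_{tau+1}, y_{tau+1})}
# and no replication happens at tau = 0.
# ---------------------------------------------------------------------------

# row-wise log-sum-exp of a small matrix
.lse_rows <- function(M) {
  m <- apply(M, 1, max)
  out <- m + log(rowSums(exp(M - m)))
  out[m == -Inf] <- -Inf
  out
}

#' Log-probability of an environment history
#'
#' Markov path weight `ln Q[Yt] = ln pE(y0) + sum ln TEF(y_{tau+1}|y_tau)`.
#' `-Inf` is returned for zero-probability paths.
#'
#' @param model an `sg_model`.
#' @param Yt environment history (labels or state indices, times `0..t`).
#' @return Scalar log-probability.
#' @export
env_logprob <- function(model, Yt) {
  y <- .hist_idx(Yt, model$spaces$environments, "environment")
  lp <- log(model$env$initial[y[1]])
  if (length(y) > 1L) {
    tr <- model$env$transition[cbind(y[-length(y)], y[-1])]
    lp <- lp + sum(log(tr))
  }
  unname(lp)
}

#' Causally conditioned log-probability of a signal history
#'
#' `ln PS[Zt || Yt] = ln pS(z0|y0) + sum ln TS(z_{tau+1}|z_tau, y_{tau+1})`:
#' the factor for step `tau` conditions on the environment already updated to
#' `y_{tau+1}` (causal conditioning).
#'
#' @param model an `sg_model`.
#' @param Zt signal history.
#' @param Yt environment history of the same horizon.
#' @return Scalar log-probability.
#' @export
sensing_logprob <- function(model, Zt, Yt) {
  z <- .hist_idx(Zt, model$spaces$signals, "signal")
  y <- .hist_idx(Yt, model$spaces$environments, "environment")
  if (length(z) != length(y)) stopf("signal and environment horizons differ")
  lp <- log(model$sensing$initial[y[1], z[1]])
  t <- length(z) - 1L
  if (t > 0L) {
    kr <- model$sensing$kernel[cbind(z[1:t], y[2:(t + 1)], z[2:(t + 1)])]
    lp <- lp + sum(log(kr))
  }
  unname(lp)
}

#' Causally conditioned log-probability of a phenotype history
#'
#' `ln PF[Xt || Zt] = ln pF(x0|z0) + sum ln TF(x_{tau+1}|x_tau, z_{tau+1})`.
#'
#' @param model an `sg_model`.
#' @param Xt phenotype history.
#' @param Zt signal history of the same horizon.
#' @return Scalar log-probability.
#' @export
switching_logprob <- function(model, Xt, Zt) {
  x <- .hist_idx(Xt, model$spaces$phenotypes, "phenotype")
  z <- .hist_idx(Zt, model$spaces$signals, "signal")
  if (length(x) != length(z)) stopf("phenotype and signal horizons differ")
  lp <- log(model$switching$initial[z[1], x[1]])
  t <- length(x) - 1L
  if (t > 0L) {
    kr <- model$switching$kernel[cbind(x[1:t], z[2:(t + 1)], x[2:(t + 1)])]
    lp <- lp + sum(log(kr))
  }
  unname(lp)
}

#' Historical fitness of a phenotype/environment path
#'
#' Cumulative log replication rate `K[Xt, Yt] = sum_{tau=0}^{t-1}
#' k(x_{tau+1}, y_{tau+1})`; the time-0 pair contributes nothing.
#'
#' @param model an `sg_model`.
#' @param Xt phenotype history.
#' @param Yt environment history of the same horizon.
#' @return Scalar log-fitness.
#' @export
historical_fitness <- function(model, Xt, Yt) {
  x <- .hist_idx(Xt, model$spaces$phenotypes, "phenotype")
  y <- .hist_idx(Yt, model$spaces$environments, "environment")
  if (length(x) != length(y)) stopf("phenotype and environment horizons differ")
  if (length(x) == 1L) return(0)
  sum(model$replication$lograte[cbind(x[-1], y[-1])])
}

#' Maximum-rate component of the historical fitness
#'
#' `Kmax[Yt] = sum_{tau=1}^{t} kmax(y_tau)` for the attached
#' metabolic-allocation decomposition.
#'
#' @param model an `sg_model` with a decomposition attached.
#' @param Yt environment history.
#' @return Scalar log-fitness.
#' @export
kmax_fitness <- function(model, Yt) {
  if (is.null(model$decomposition))
    stopf("model has no metabolic-allocation decomposition attached")
  y <- .hist_idx(Yt, model$spaces$environments, "environment")
  if (length(y) == 1L) return(0)
  sum(model$decomposition$kmax[y[-1]])
}

#' Population fitness under individual sensing
#'
#' Propagates the joint phenotype/signal log-abundance table one environment
#' step at a time (log-domain transfer matrix), starting from
#' `N0(x, z) = pS(z|y0) pF(x|z)`. Equal to the log of the exhaustive path sum
#' of `e^K` over phenotype and signal histories weighted by their causally
#' conditioned path probabilities.
#'
#' @param model an `sg_model`.
#' @param Yt environment history.
#' @return Scalar log-fitness `Psi_i[Yt]` (0 at horizon 0).
#' @export
fitness_individual <- function(model, Yt) {
  y <- .hist_idx(Yt, model$spaces$environments, "environment")
  nx <- length(model$spaces$phenotypes)
  nz <- length(model$spaces$signals)
  lnTS <- log(model$sensing$kernel)
  lnTF <- log(model$switching$kernel)
  k <- model$replication$lograte
  # N0(x, z) = pS(z|y0) * pF(x|z), carried as [x, z]
  logN <- matrix(log(t(model$switching$initial)), nx, nz) +
    matrix(log(model$sensing$initial[y[1], ]), nx, nz, byrow = TRUE)
  for (tau in seq_len(length(y) - 1L)) {
    yn <- y[tau + 1L]
    B <- matrix(-Inf, nx, nz)
    for (zp in seq_len(nz))
      B[, zp] <- .lse_rows(logN + matrix(lnTS[, yn, zp], nx, nz, byrow = TRUE))
    new <- matrix(-Inf, nx, nz)
    for (xp in seq_len(nx))
      for (zp in seq_len(nz))
        new[xp, zp] <- k[xp, yn] + logsumexp(B[, zp] + lnTF[, zp, xp])
    logN <- new
  }
  logsumexp(logN)
}

#' Population fitness under common sensing
#'
#' Propagates the phenotype log-abundance vector conditioned on the realized
#' common signal history, starting from `N0(x) = pF(x|z0)`.
#'
#' @param model an `sg_model`.
#' @param Yt environment history.
#' @param Zt common-signal history of the same horizon.
#' @return Scalar log-fitness `Psi_c[Yt, Zt]`.
#' @export
fitness_common <- function(model, Yt, Zt) {
  y <- .hist_idx(Yt, model$spaces$environments, "environment")
  z <- .hist_idx(Zt, model$spaces$signals, "signal")
  if (length(y) != length(z)) stopf("environment and signal horizons differ")
  lnTF <- log(model$switching$kernel)
  k <- model$replication$lograte
  logn <- log(model$switching$initial[z[1], ])
  for (tau in seq_len(length(y) - 1L)) {
    yn <- y[tau + 1L]; zn <- z[tau + 1L]
    logn <- vapply(seq_along(logn), function(xp)
      k[xp, yn] + logsumexp(logn + lnTF[, zn, xp]), numeric(1))
  }
  logsumexp(logn)
}

#' Retrospective distribution over signal histories
#'
#' The distribution of signal histories read backward from a grown population
#' under individual sensing: the forward law reweighted by realized growth,
#' `PBi[Zt|Yt] = sum_Xt e^{K - Psi_i} PF PS`. Computed by one common-sensing
#' recursion per signal history.
#'
#' @param model an `sg_model`.
#' @param Yt environment history.
#' @param guard enumeration guard on the number of signal histories.
#' @return Named probability vector over all dash-joined signal histories, in
#'   lexicographic order.
#' @export
retrospective_sensing_dist <- function(model, Yt, guard = .DEFAULT_GUARD) {
  y <- .hist_idx(Yt, model$spaces$environments, "environment")
  zs <- model$spaces$signals
  t <- length(y) - 1L
  Zmat <- .enum_idx(length(zs), t, guard)
  Ymat <- matrix(y, nrow(Zmat), t + 1L, byrow = TRUE)
  lw <- .batch_sensing_logprob(model, Zmat, Ymat) +
    .batch_psi_c(model, Ymat, Zmat) - fitness_individual(model, y)
  p <- exp(lw)
  names(p) <- .join_hist(Zmat, zs)
  p
}

#' Retrospective distribution over phenotype histories
#'
#' `PBc[Xt|Yt, Zt] = e^{K - Psi_c} PF[Xt || Zt]`: the phenotype-history
#' distribution seen when tracing a common-sensing population backward.
#'
#' @param model an `sg_model`.
#' @param Yt environment history.
#' @param Zt common-signal history.
#' @param guard enumeration guard on the number of phenotype histories.
#' @return Named probability vector over all dash-joined phenotype histories.
#' @export
retrospective_phenotype_dist <- function(model, Yt, Zt,
                                         guard = .DEFAULT_GUARD) {
  y <- .hist_idx(Yt, model$spaces$environments, "environment")
  z <- .hist_idx(Zt, model$spaces$signals, "signal")
  if (length(y) != length(z)) stopf("environment and signal horizons differ")
  xs <- model$spaces$phenotypes
  t <- length(y) - 1L
  Xmat <- .enum_idx(length(xs), t, guard)
  psi_c <- fitness_common(model, y, z)
  lw <- vapply(seq_len(nrow(Xmat)), function(i) {
    historical_fitness(model, Xmat[i, ], y) +
      switching_logprob(model, Xmat[i, ], z)
  }, numeric(1)) - psi_c
  p <- exp(lw)
  names(p) <- .join_hist(Xmat, xs)
  p
}
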