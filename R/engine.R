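# ---------------------------------------------------------------------------
# Batch engine: the same population recursions as fitness_individual() /
# fitness_common(), vectorized across many histories at once. States are
# propagated in linear domain with per-row renormalization, accumulating the
# log of the removed mass, so horizons of hundreds of steps cannot overflow.
# State order for the joint (x, z) table is column-major with x fastest.
# ---------------------------------------------------------------------------

.batch_env_logprob <- function(model, Ymat) {
  lp <- log(model$env$initial[Ymat[, 1]])
  TEF <- model$env$transition
  for (tau in seq_len(ncol(Ymat) - 1L))
    lp <- lp + log(TEF[cbind(Ymat[, tau], Ymat[, tau + 1L])])
  unname(lp)
}

.batch_sensing_logprob <- function(model, Zmat, Ymat) {
  lp <- log(model$sensing$initial[cbind(Ymat[, 1], Zmat[, 1])])
  kr <- model$sensing$kernel
  for (tau in seq_len(ncol(Ymat) - 1L))
    lp <- lp + log(kr[cbind(Zmat[, tau], Ymat[, tau + 1L], Zmat[, tau + 1L])])
  unname(lp)
}

.batch_kmax <- function(model, Ymat) {
  km <- model$decomposition$kmax
  if (ncol(Ymat) == 1L) return(numeric(nrow(Ymat)))
  rowSums(matrix(km[Ymat[, -1, drop = FALSE]], nrow(Ymat)))
}

# per-environment transfer matrices over the joint (x, z) state;
# weight "ek" gives the growth recursion, "tk" the allocation-probability one
.step_mats_xz <- function(model, weight) {
  nx <- length(model$spaces$phenotypes)
  nz <- length(model$spaces$signals)
  ny <- length(model$spaces$environments)
  TF <- model$switching$kernel
  TS <- model$sensing$kernel
  wtab <- switch(weight, ek = exp(model$replication$lograte),
                 tk = model$decomposition$TK)
  lapply(seq_len(ny), function(v) {
    M <- matrix(0, nx * nz, nx * nz)
    for (zp in seq_len(nz))
      for (xp in seq_len(nx))
        M[, xp + (zp - 1L) * nx] <-
          as.vector(outer(TF[, zp, xp], TS[, v, zp])) * wtab[xp, v]
    M
  })
}

.init_xz <- function(model, y0) {
  nx <- length(model$spaces$phenotypes)
  nz <- length(model$spaces$signals)
  m0 <- matrix(t(model$switching$initial), nx, nz) *
    matrix(model$sensing$initial[y0, ], nx, nz, byrow = TRUE)
  as.vector(m0)
}

# propagate the joint (x, z) recursion for every row of Ymat; returns the
# per-row log total mass (and the whole time series when per_time = TRUE)
.batch_chain_xz <- function(model, Ymat, weight = "ek", per_time = FALSE) {
  if (weight == "tk" && is.null(model$decomposition))
    stopf("model has no metabolic-allocation decomposition attached")
  n <- nrow(Ymat); tp1 <- ncol(Ymat)
  mats <- .step_mats_xz(model, weight)
  W <- matrix(0, n, ncol(mats[[1]]))
  for (v in sort(unique(Ymat[, 1]))) {
    r <- which(Ymat[, 1] == v)
    W[r, ] <- matrix(.init_xz(model, v), length(r), ncol(W), byrow = TRUE)
  }
  s <- numeric(n)
  S <- if (per_time) matrix(0, n, tp1)
  for (tau in seq_len(tp1 - 1L) + 1L) {
    yv <- Ymat[, tau]
    for (v in sort(unique(yv))) {
      r <- which(yv == v)
      W[r, ] <- W[r, , drop = FALSE] %*% mats[[v]]
    }
    rs <- rowSums(W)
    pos <- rs > 0
    s[pos] <- s[pos] + log(rs[pos])
    s[!pos] <- -Inf
    W[pos, ] <- W[pos, , drop = FALSE] / rs[pos]
    if (per_time) S[, tau] <- s
  }
  if (per_time) list(psi = s, series = S) else s
}

.batch_psi_i <- function(model, Ymat, per_time = FALSE)
  .batch_chain_xz(model, Ymat, "ek", per_time)

# log PKFS[Yt|Yt] for every row (allocation history = realized history)
.batch_pkfs_diag <- function(model, Ymat)
  .batch_chain_xz(model, Ymat, "tk")

# per-(environment, signal) transfer matrices over the phenotype state
.step_mats_x <- function(model, weight) {
  nx <- length(model$spaces$phenotypes)
  nz <- length(model$spaces$signals)
  ny <- length(model$spaces$environments)
  TF <- model$switching$kernel
  wtab <- switch(weight, ek = exp(model$replication$lograte),
                 tk = model$decomposition$TK)
  out <- vector("list", ny * nz)
  for (v in seq_len(ny))
    for (w in seq_len(nz))
      out[[(v - 1L) * nz + w]] <-
        sweep(matrix(TF[, w, ], nx, nx), 2, wtab[, v], "*")
  out
}

.batch_chain_x <- function(model, Ymat, Zmat, weight = "ek",
                           per_time = FALSE) {
  if (weight == "tk" && is.null(model$decomposition))
    stopf("model has no metabolic-allocation decomposition attached")
  n <- nrow(Ymat); tp1 <- ncol(Ymat)
  nz <- length(model$spaces$signals)
  mats <- .step_mats_x(model, weight)
  W <- model$switching$initial[Zmat[, 1], , drop = FALSE]
  s <- numeric(n)
  S <- if (per_time) matrix(0, n, tp1)
  for (tau in seq_len(tp1 - 1L) + 1L) {
    cc <- (Ymat[, tau] - 1L) * nz + Zmat[, tau]
    for (v in sort(unique(cc))) {
      r <- which(cc == v)
      W[r, ] <- W[r, , drop = FALSE] %*% mats[[v]]
    }
    rs <- rowSums(W)
    pos <- rs > 0
    s[pos] <- s[pos] + log(rs[pos])
    s[!pos] <- -Inf
    W[pos, ] <- W[pos, , drop = FALSE] / rs[pos]
    if (per_time) S[, tau] <- s
  }
  if (per_time) list(psi = s, series = S) else s
}

.batch_psi_c <- function(model, Ymat, Zmat, per_time = FALSE)
  .batch_chain_x(model, Ymat, Zmat, "ek", per_time)

# log PK,F[Yt|Zt] = log sum_Xt PK[Yt||Xt] PF[Xt||Zt]
.batch_lnpkf <- function(model, Ymat, Zmat)
  .batch_chain_x(model, Ymat, Zmat, "tk")

# pointwise directed information and the causal signal-path log-probability
.batch_bayes <- function(model, Ymat, Zmat, bk = bayes_kernels(model)) {
  TEF <- model$env$transition
  pE <- model$env$initial
  i <- log(bk$initial_posterior[cbind(Zmat[, 1], Ymat[, 1])]) -
    log(pE[Ymat[, 1]])
  lps <- log(bk$initial_signal[Zmat[, 1]])
  for (tau in seq_len(ncol(Ymat) - 1L)) {
    i <- i + log(bk$env_posterior[cbind(Ymat[, tau], Zmat[, tau + 1L],
                                        Ymat[, tau + 1L])]) -
      log(TEF[cbind(Ymat[, tau], Ymat[, tau + 1L])])
    lps <- lps + log(bk$signal_predictive[cbind(Ymat[, tau], Zmat[, tau + 1L])])
  }
  list(pointwise = unname(i), ln_psb_signal = unname(lps))
}

# forward-sample n environment/signal history pairs (caller seeds the RNG)
.sample_histories <- function(model, t, n) {
  ny <- length(model$spaces$environments)
  nz <- length(model$spaces$signals)
  TEF <- model$env$transition
  Y <- matrix(0L, n, t + 1L)
  Y[, 1] <- sample.int(ny, n, replace = TRUE, prob = model$env$initial)
  for (tau in seq_len(t))
    for (v in seq_len(ny)) {
      r <- which(Y[, tau] == v)
      if (length(r))
        Y[r, tau + 1L] <- sample.int(ny, length(r), replace = TRUE,
                                     prob = TEF[v, ])
    }
  Z <- matrix(0L, n, t + 1L)
  for (v in seq_len(ny)) {
    r <- which(Y[, 1] == v)
    if (length(r))
      Z[r, 1] <- sample.int(nz, length(r), replace = TRUE,
                            prob = model$sensing$initial[v, ])
  }
  kr <- model$sensing$kernel
  for (tau in seq_len(t))
    for (zv in seq_len(nz))
      for (yv in seq_len(ny)) {
        r <- which(Z[, tau] == zv & Y[, tau + 1L] == yv)
        if (length(r))
          Z[r, tau + 1L] <- sample.int(nz, length(r), replace = TRUE,
                                       prob = kr[zv, yv, ])
      }
  list(Y = Y, Z = Z)
}

#' Total allocation fidelity
#'
#' `gamma_t = ln sum_Yt PKFS[Yt|Yt]`: the log total probability, summed over
#' all environment histories, that sensing, switching and metabolic
#' allocation together commit resources to exactly the history that occurs.
#' Computed by an exact transfer-matrix contraction over the joint
#' (phenotype, signal) state, so any horizon is feasible; independent of the
#' environment's own statistics.
#'
#' @param model an `sg_model` with a decomposition attached.
#' @param t horizon.
#' @return Scalar `gamma_t`.
#' @export
gamma_total <- function(model, t) {
  if (is.null(model$decomposition))
    stopf("model has no metabolic-allocation decomposition attached")
  nx <- length(model$spaces$phenotypes)
  nz <- length(model$spaces$signals)
  ny <- length(model$spaces$environments)
  TF <- model$switching$kernel
  TS <- model$sensing$kernel
  TK <- model$decomposition$TK
  G <- matrix(0, nx * nz, nx * nz)
  for (zp in seq_len(nz))
    for (xp in seq_len(nx)) {
      cz <- vapply(seq_len(nz), function(z)
        sum(TK[xp, ] * TS[z, , zp]), numeric(1))
      G[, xp + (zp - 1L) * nx] <- as.vector(outer(TF[, zp, xp], cz))
    }
  v <- as.vector(matrix(t(model$switching$initial), nx, nz) *
                   matrix(colSums(model$sensing$initial), nx, nz, byrow = TRUE))
  s <- 0
  for (tau in seq_len(t)) {
    v <- as.vector(v %*% G)
    tot <- sum(v)
    s <- s + log(tot)
    v <- v / tot
  }
  s + log(sum(v))
}

#' Exact ensemble-average fitness components
#'
#' Exhaustively enumerates environment (and signal) histories and returns the
#' exact averages of the individual-sensing fitness, the common-sensing
#' fitness, and (when a decomposition is attached) the no-sensing benchmark
#' `Psi_0 = Kmax + ln Q`, together with the fitness gain
#' `G = <Psi_i> - <Psi_c>`.
#'
#' @param model an `sg_model`.
#' @param t horizon.
#' @param guard enumeration guard on the number of joint histories.
#' @return List with `psi_i`, `psi_c`, `psi0` (or `NA`), `gain`, and the
#'   number of weighted joint terms `n_terms`.
#' @export
psi_averages <- function(model, t, guard = .DEFAULT_GUARD) {
  ny <- length(model$spaces$environments)
  nz <- length(model$spaces$signals)
  Yg <- .enum_idx(ny, t, guard)
  Zg <- .enum_idx(nz, t, guard)
  nY <- nrow(Yg); nZ <- nrow(Zg)
  if (nY * nZ > guard)
    stopf("joint enumeration of %g terms exceeds the guard", nY * nZ)
  lnq <- .batch_env_logprob(model, Yg)
  psi_i <- .batch_psi_i(model, Yg)
  wq <- exp(lnq)
  sup <- wq > 0
  psi_i_avg <- sum(wq[sup] * psi_i[sup])

  YY <- Yg[rep(seq_len(nY), each = nZ), , drop = FALSE]
  ZZ <- Zg[rep(seq_len(nZ), times = nY), , drop = FALSE]
  lw <- rep(lnq, each = nZ) + .batch_sensing_logprob(model, ZZ, YY)
  psi_c <- .batch_psi_c(model, YY, ZZ)
  w <- exp(lw)
  sup2 <- w > 0
  psi_c_avg <- sum(w[sup2] * psi_c[sup2])

  psi0_avg <- NA_real_
  if (!is.null(model$decomposition)) {
    psi0 <- .batch_kmax(model, Yg) + lnq
    psi0_avg <- sum(wq[sup] * psi0[sup])
  }
  list(psi_i = psi_i_avg, psi_c = psi_c_avg, psi0 = psi0_avg,
       gain = psi_i_avg - psi_c_avg, n_terms = sum(sup2))
}
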