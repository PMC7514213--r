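# ---------------------------------------------------------------------------
# Stochastic realizations and population trajectories. Given a realized
# environment (and common-signal) history the recursions are deterministic;
# only the environment and the signal are random. Initial abundance is
# normalized to total 1, so the log total abundance IS the fitness.
# ---------------------------------------------------------------------------

#' Sample one environment/signal realization
#'
#' Draws an environment history from its Markov law and a signal history from
#' the causally conditioned sensing law (the common signal is assumed to
#' follow the same statistics as an individual sensor).
#'
#' @param model an `sg_model`.
#' @param t horizon.
#' @param seed integer seed.
#' @return List with character vectors `env` and `signal` (times `0..t`).
#' @export
sample_realization <- function(model, t, seed) {
  stopifnot(t >= 0)
  set.seed(seed)
  h <- .sample_histories(model, t, 1L)
  list(env = model$spaces$environments[h$Y[1, ]],
       signal = model$spaces$signals[h$Z[1, ]])
}

#' Run the population recursions along one realization
#'
#' Propagates both populations: the individual-sensing joint
#' (phenotype, signal) abundance table and the common-sensing phenotype
#' abundance vector, recording per-time log abundances and the fitness
#' trajectories. The final fitness values coincide with
#' [fitness_individual()] and [fitness_common()].
#'
#' @param model an `sg_model`.
#' @param Yt environment history.
#' @param Zt common-signal history of the same horizon.
#' @return An object of class `trajectory_record`: a list with
#'   `env_history`, `signal_history`, `log_abundance_individual`
#'   (`(t+1) x x x z` array), `log_abundance_common` (`(t+1) x x` matrix),
#'   `psi_i`, `psi_c` (numeric vectors, 0 at time 0).
#' @export
run_trajectory <- function(model, Yt, Zt) {
  y <- .hist_idx(Yt, model$spaces$environments, "environment")
  z <- .hist_idx(Zt, model$spaces$signals, "signal")
  if (length(y) != length(z)) stopf("environment and signal horizons differ")
  t <- length(y) - 1L
  nx <- length(model$spaces$phenotypes)
  nz <- length(model$spaces$signals)
  lnTS <- log(model$sensing$kernel)
  lnTF <- log(model$switching$kernel)
  k <- model$replication$lograte

  Ai <- array(-Inf, c(t + 1L, nx, nz),
              dimnames = list(NULL, model$spaces$phenotypes,
                              model$spaces$signals))
  Ac <- matrix(-Inf, t + 1L, nx,
               dimnames = list(NULL, model$spaces$phenotypes))
  psi_i <- psi_c <- numeric(t + 1L)

  logN <- matrix(log(t(model$switching$initial)), nx, nz) +
    matrix(log(model$sensing$initial[y[1], ]), nx, nz, byrow = TRUE)
  logn <- log(model$switching$initial[z[1], ])
  Ai[1, , ] <- logN
  Ac[1, ] <- logn
  for (tau in seq_len(t)) {
    yn <- y[tau + 1L]; zn <- z[tau + 1L]
    B <- matrix(-Inf, nx, nz)
    for (zp in seq_len(nz))
      B[, zp] <- .lse_rows(logN + matrix(lnTS[, yn, zp], nx, nz, byrow = TRUE))
    new <- matrix(-Inf, nx, nz)
    for (xp in seq_len(nx))
      for (zp in seq_len(nz))
        new[xp, zp] <- k[xp, yn] + logsumexp(B[, zp] + lnTF[, zp, xp])
    logN <- new
    logn <- vapply(seq_len(nx), function(xp)
      k[xp, yn] + logsumexp(logn + lnTF[, zn, xp]), numeric(1))
    Ai[tau + 1L, , ] <- logN
    Ac[tau + 1L, ] <- logn
    psi_i[tau + 1L] <- logsumexp(logN)
    psi_c[tau + 1L] <- logsumexp(logn)
  }
  structure(list(env_history = model$spaces$environments[y],
                 signal_history = model$spaces$signals[z],
                 log_abundance_individual = Ai,
                 log_abundance_common = Ac,
                 psi_i = psi_i, psi_c = psi_c),
            class = "trajectory_record")
}

#' @export
print.trajectory_record <- function(x, ...) {
  t <- length(x$psi_i) - 1L
  cat(sprintf("<trajectory_record> horizon t = %d\n", t))
  cat("  env:    ", paste(x$env_history, collapse = " "), "\n")
  cat("  signal: ", paste(x$signal_history, collapse = " "), "\n")
  cat(sprintf("  final Psi_i = %.4f, Psi_c = %.4f\n",
              x$psi_i[t + 1L], x$psi_c[t + 1L]))
  invisible(x)
}

#' Ensemble averages of the fitness trajectories
#'
#' Samples `n` environment/signal realizations and returns per-time sample
#' means and standard errors of the individual-sensing fitness, the
#' common-sensing fitness and (when a decomposition is attached) the
#' no-sensing benchmark `Psi_0`.
#'
#' @param model an `sg_model`.
#' @param t horizon.
#' @param n number of realizations.
#' @param seed integer seed.
#' @return A data frame with columns `time`, `mean_psi_i`, `se_psi_i`,
#'   `mean_psi_c`, `se_psi_c` and, with a decomposition, `mean_psi0`,
#'   `se_psi0`.
#' @export
ensemble_summary <- function(model, t, n, seed) {
  stopifnot(n >= 1)
  set.seed(seed)
  h <- .sample_histories(model, t, n)
  si <- .batch_psi_i(model, h$Y, per_time = TRUE)$series
  sc <- .batch_psi_c(model, h$Y, h$Z, per_time = TRUE)$series
  se <- function(M) apply(M, 2, stats::sd) / sqrt(nrow(M))
  out <- data.frame(time = 0:t,
                    mean_psi_i = colMeans(si), se_psi_i = se(si),
                    mean_psi_c = colMeans(sc), se_psi_c = se(sc))
  if (!is.null(model$decomposition)) {
    km <- model$decomposition$kmax
    lnq0 <- log(model$env$initial[h$Y[, 1]])
    S0 <- matrix(0, n, t + 1L)
    acc <- lnq0
    for (tau in seq_len(t)) {
      acc <- acc + km[h$Y[, tau + 1L]] +
        log(model$env$transition[cbind(h$Y[, tau], h$Y[, tau + 1L])])
      S0[, tau + 1L] <- acc
    }
    S0[, 1] <- lnq0
    out$mean_psi0 <- colMeans(S0)
    out$se_psi0 <- se(S0)
  }
  out
}
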