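# brute-force path-sum oracles, written as plain products over enumerated
# paths (no transfer matrices, no log domain) so they are independent of the
# package's dynamic-programming code paths

all_idx <- function(m, t) {
  n <- m^(t + 1)
  out <- matrix(0L, n, t + 1L)
  for (j in seq_len(t + 1L))
    out[, j] <- rep(seq_len(m), each = m^(t + 1L - j), times = m^(j - 1L))
  out
}

oracle_prob_S <- function(model, z, y) {
  p <- model$sensing$initial[y[1], z[1]]
  for (tau in seq_len(length(z) - 1L))
    p <- p * model$sensing$kernel[z[tau], y[tau + 1], z[tau + 1]]
  p
}

oracle_prob_F <- function(model, x, z) {
  p <- model$switching$initial[z[1], x[1]]
  for (tau in seq_len(length(x) - 1L))
    p <- p * model$switching$kernel[x[tau], z[tau + 1], x[tau + 1]]
  p
}

oracle_prob_Q <- function(model, y) {
  p <- model$env$initial[y[1]]
  for (tau in seq_len(length(y) - 1L))
    p <- p * model$env$transition[y[tau], y[tau + 1]]
  unname(p)
}

oracle_growth <- function(model, x, y) {
  g <- 1
  for (tau in seq_len(length(x) - 1L))
    g <- g * exp(model$replication$lograte[x[tau + 1], y[tau + 1]])
  g
}

# Psi_i as the full path sum over phenotype AND signal histories
oracle_psi_i <- function(model, y) {
  t <- length(y) - 1L
  Xg <- all_idx(length(model$spaces$phenotypes), t)
  Zg <- all_idx(length(model$spaces$signals), t)
  tot <- 0
  for (i in seq_len(nrow(Xg)))
    for (j in seq_len(nrow(Zg)))
      tot <- tot + oracle_growth(model, Xg[i, ], y) *
        oracle_prob_F(model, Xg[i, ], Zg[j, ]) *
        oracle_prob_S(model, Zg[j, ], y)
  log(tot)
}

oracle_psi_c <- function(model, y, z) {
  t <- length(y) - 1L
  Xg <- all_idx(length(model$spaces$phenotypes), t)
  tot <- 0
  for (i in seq_len(nrow(Xg)))
    tot <- tot + oracle_growth(model, Xg[i, ], y) *
      oracle_prob_F(model, Xg[i, ], z)
  log(tot)
}

# retrospective signal-history distribution by full (Xt, Zt) enumeration
oracle_pbi <- function(model, y) {
  t <- length(y) - 1L
  Xg <- all_idx(length(model$spaces$phenotypes), t)
  Zg <- all_idx(length(model$spaces$signals), t)
  w <- numeric(nrow(Zg))
  for (j in seq_len(nrow(Zg)))
    for (i in seq_len(nrow(Xg)))
      w[j] <- w[j] + oracle_growth(model, Xg[i, ], y) *
        oracle_prob_F(model, Xg[i, ], Zg[j, ]) *
        oracle_prob_S(model, Zg[j, ], y)
  w / sum(w)
}

# PKFS[Y'|Y] by triple enumeration over (Xt, Zt)
oracle_pkfs <- function(model, ya, y) {
  if (ya[1] != y[1]) return(0)
  t <- length(y) - 1L
  TK <- model$decomposition$TK
  Xg <- all_idx(length(model$spaces$phenotypes), t)
  Zg <- all_idx(length(model$spaces$signals), t)
  tot <- 0
  for (i in seq_len(nrow(Xg))) {
    pk <- 1
    for (tau in seq_len(t)) pk <- pk * TK[Xg[i, tau + 1], ya[tau + 1]]
    if (pk == 0) next
    for (j in seq_len(nrow(Zg)))
      tot <- tot + pk * oracle_prob_F(model, Xg[i, ], Zg[j, ]) *
        oracle_prob_S(model, Zg[j, ], y)
  }
  tot
}

# exact <Psi_i> and <Psi_c> by exhaustive averaging with oracle fitnesses
oracle_averages <- function(model, t) {
  Yg <- all_idx(length(model$spaces$environments), t)
  Zg <- all_idx(length(model$spaces$signals), t)
  ai <- ac <- 0
  for (i in seq_len(nrow(Yg))) {
    q <- oracle_prob_Q(model, Yg[i, ])
    if (q == 0) next
    ai <- ai + q * oracle_psi_i(model, Yg[i, ])
    for (j in seq_len(nrow(Zg))) {
      ps <- oracle_prob_S(model, Zg[j, ], Yg[i, ])
      if (ps > 0)
        ac <- ac + q * ps * oracle_psi_c(model, Yg[i, ], Zg[j, ])
    }
  }
  list(psi_i = ai, psi_c = ac)
}
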