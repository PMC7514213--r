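# ---------------------------------------------------------------------------
# Closed-form Bayes-optimal strategies and fitness/information bounds.
#
# When the phenotype and environment spaces can be identified, the strategy
# that makes switching-plus-allocation implement sequential Bayesian
# inference is: delta allocation TK*(y|x) = [y = y(x)] with the maximum rate
# taken from the matched diagonal of the replication table, and a switching
# kernel equal to the Bayesian posterior of the next environment state given
# the signal. Off-diagonal replication becomes log-rate -Inf: a phenotype
# that commits everything to one environment cannot grow in any other.
# ---------------------------------------------------------------------------

#' Bayes-optimal switching and allocation strategy
#'
#' Requires `|Sx| = |Sy|` (phenotypes identified with environments, by label
#' order unless `bijection` reorders them), a Markov environment and
#' memoryless sensing. The initial switching distribution is the initial
#' Bayesian environment posterior, so that with a deterministic initial
#' environment state the strategy reproduces the Bayesian posterior path
#' measure exactly and its inference loss vanishes.
#'
#' @param model an `sg_model`.
#' @param bijection integer or character vector mapping each phenotype to an
#'   environment label (default: label order).
#' @return An object of class `strategy_pair`: a list with `switching` (a
#'   switching-model list) and `allocation` (`kmax`, `TK`).
#' @seealso [apply_strategy()], [evaluate_bounds()]
#' @export
optimal_strategy <- function(model, bijection = NULL) {
  sp <- model$spaces
  nx <- length(sp$phenotypes); ny <- length(sp$environments)
  nz <- length(sp$signals)
  if (nx != ny)
    stopf("the closed-form optimal strategy requires |Sx| = |Sy| (got %d and %d)",
          nx, ny)
  if (!model$sensing$memoryless)
    stopf("the closed-form optimal strategy requires memoryless sensing")
  bij <- if (is.null(bijection)) seq_len(ny)
         else .hist_idx(bijection, sp$environments, "environment")
  if (length(bij) != nx || anyDuplicated(bij))
    stopf("bijection must map the %d phenotypes onto distinct environments", nx)
  bk <- bayes_kernels(model)
  # switching kernel TF*(x'|x, z') = posterior(y(x') | z', y(x))
  fk <- array(0, c(nx, nz, nx))
  for (x in seq_len(nx))
    fk[x, , ] <- matrix(bk$env_posterior[bij[x], , bij], nz, nx)
  pF0 <- bk$initial_posterior[, bij, drop = FALSE]
  TK <- matrix(0, nx, ny)
  TK[cbind(seq_len(nx), bij)] <- 1
  kmax <- model$replication$lograte[cbind(match(seq_len(ny), bij), seq_len(ny))]
  names(kmax) <- sp$environments
  structure(list(
    switching = list(kernel = fk, initial = pF0),
    allocation = list(kmax = kmax, TK = TK)),
    class = "strategy_pair")
}

#' Replace a model's switching and replication by a strategy pair
#'
#' The replication table is rebuilt from the strategy's allocation,
#' `k(x, y) = kmax(y) + ln TK(y|x)` (so zero allocation gives log-rate
#' `-Inf`), and the decomposition is attached.
#'
#' @param model an `sg_model`.
#' @param strategy a `strategy_pair`.
#' @return A new `sg_model`.
#' @export
apply_strategy <- function(model, strategy) {
  stopifnot(inherits(strategy, "strategy_pair"))
  al <- strategy$allocation
  lograte <- sweep(log(al$TK), 2, al$kmax, "+")
  model_bundle(model$spaces,
               env = list(transition = model$env$transition,
                          initial = model$env$initial),
               sensing = list(kernel = model$sensing$kernel,
                              initial = model$sensing$initial),
               switching = strategy$switching,
               replication = list(lograte = lograte),
               decomposition = list(kmax = al$kmax, TK = al$TK))
}

#' Random strategy pair (for property sweeps)
#'
#' Memoryless switching rows and allocation rows from the flat simplex;
#' `kmax` uniform on `[-rate_scale, rate_scale]`.
#'
#' @param model an `sg_model` (provides the space sizes).
#' @param seed integer seed.
#' @param rate_scale half-width of the `kmax` range.
#' @return A `strategy_pair`.
#' @export
random_strategy <- function(model, seed, rate_scale = 1) {
  set.seed(seed)
  sp <- model$spaces
  nx <- length(sp$phenotypes); ny <- length(sp$environments)
  nz <- length(sp$signals)
  structure(list(
    switching = list(kernel = runif_simplex(nz, nx)),
    allocation = list(kmax = stats::runif(ny, -rate_scale, rate_scale),
                      TK = runif_simplex(nx, ny))),
    class = "strategy_pair")
}

#' Fitness and information bounds under a strategy
#'
#' Evaluates, under the given switching/allocation strategy (environment and
#' sensing kept from `model`), the exact common- and individual-sensing
#' fitness gains over the no-sensing benchmark, the directed information, and
#' the inference loss. With a deterministic initial environment the
#' common-sensing gain never exceeds the directed information (equality at
#' the Bayes-optimal strategy), while individual sensing adds the
#' selection gain `G` on top.
#'
#' @param model an `sg_model` with memoryless sensing.
#' @param strategy a `strategy_pair`.
#' @param t horizon.
#' @param guard enumeration guard.
#' @return A one-row data frame with columns `t`, `common_gain`
#'   (`<Psi_c> - <Psi_0>`), `individual_gain` (`<Psi_i> - <Psi_0>`),
#'   `directed_info`, `G_star`, `dloss`, `ineq_slack`
#'   (`directed_info - common_gain`, non-negative when the inference-loss
#'   bound applies) and `balance_residual`
#'   (`individual_gain - directed_info - G_star + dloss`, zero identically).
#' @export
evaluate_bounds <- function(model, strategy, t, guard = .DEFAULT_GUARD) {
  m2 <- apply_strategy(model, strategy)
  av <- psi_averages(m2, t, guard)
  I <- directed_information(m2, t, guard)
  dl <- dloss(m2, t, guard)
  common_gain <- av$psi_c - av$psi0
  individual_gain <- av$psi_i - av$psi0
  data.frame(t = t, common_gain = common_gain,
             individual_gain = individual_gain,
             directed_info = I, G_star = av$gain, dloss = dl,
             ineq_slack = I - common_gain,
             balance_residual = individual_gain - I - av$gain + dl)
}
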