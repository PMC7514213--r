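# ---------------------------------------------------------------------------
# Model containers
#
# A model bundle holds everything the population recursions need:
#   * spaces      -- ordered label lists for phenotypes (x), environments (y)
#                    and sensing signals (z)
#   * env         -- Markov environment: transition[y, y'] (row-stochastic),
#                    initial distribution pE(y0)
#   * sensing     -- signal kernel TS(z'|z, y') stored as kernel[z, y', z'],
#                    initial pS(z0|y0) stored as initial[y0, z0],
#                    memoryless flag (kernel constant in its first index)
#   * switching   -- phenotype kernel TF(x'|x, z') stored as kernel[x, z', x'],
#                    initial pF(x0|z0) stored as initial[z0, x0]
#   * replication -- log replication-rate table k(x, y) as lograte[x, y]
#                    (log offspring per time step; -Inf allowed, meaning the
#                    phenotype cannot grow at all in that environment)
#   * decomposition -- optional metabolic-allocation decomposition
#                    e^{k(x,y)} = e^{kmax(y)} * TK(y|x), kmax as a log-scale
#                    vector over y and TK as allocation[x, y]
#
# All conditional tables are stored with the conditioning state indexing the
# first dimension(s) and the target state last, so every slice along the
# target dimension is a probability distribution.
# ---------------------------------------------------------------------------

.STOCH_TOL <- 1e-9

#' Construct a set of state spaces
#'
#' @param phenotypes,environments,signals character vectors of unique state
#'   labels for the phenotype, environment and sensing-signal spaces.
#' @return An object of class `state_spaces`.
#' @export
state_spaces <- function(phenotypes, environments, signals) {
  for (nm in c("phenotypes", "environments", "signals")) {
    v <- get(nm)
    if (length(v) < 1L) stopf("state space '%s' must be non-empty", nm)
    if (anyDuplicated(v)) stopf("state space '%s' has duplicate labels", nm)
  }
  structure(list(phenotypes = as.character(phenotypes),
                 environments = as.character(environments),
                 signals = as.character(signals)),
            class = "state_spaces")
}

# check a row-stochastic table and renormalize the sub-tolerance float error
.check_rows <- function(m, what) {
  if (any(!is.finite(m)) || any(m < 0))
    stopf("table '%s' has negative or non-finite entries", what)
  if (is.matrix(m)) {
    s <- rowSums(m)
    bad <- which(abs(s - 1) > .STOCH_TOL)
    if (length(bad))
      stopf("rows of '%s' conditioned on '%s' do not sum to 1 (sum = %.12g)",
            what, paste(rownames(m)[bad], collapse = ","), s[bad[1]])
    m / s
  } else { # 3-d array: distributions along the last dimension
    s <- apply(m, c(1, 2), sum)
    bad <- which(abs(s - 1) > .STOCH_TOL, arr.ind = TRUE)
    if (nrow(bad) > 0)
      stopf("'%s' conditioned on (%s, %s) does not sum to 1 (sum = %.12g)",
            what, dimnames(m)[[1]][bad[1, 1]], dimnames(m)[[2]][bad[1, 2]],
            s[bad[1, 1], bad[1, 2]])
    sweep(m, c(1, 2), s, "/")
  }
}

.check_probvec <- function(p, what) {
  if (any(!is.finite(p)) || any(p < 0))
    stopf("'%s' has negative or non-finite entries", what)
  if (abs(sum(p) - 1) > .STOCH_TOL)
    stopf("'%s' does not sum to 1 (sum = %.12g)", what, sum(p))
  p / sum(p)
}

#' Assemble and validate a model bundle
#'
#' Validates label consistency and row-stochasticity (tolerance `1e-9`; any
#' larger violation is an error, smaller float error is renormalized), then
#' returns the bundle consumed by every other function in the package.
#'
#' @param spaces a [state_spaces()] object.
#' @param env list with `transition` (matrix `[y, y']`) and optionally
#'   `initial` (distribution over environments; default: the stationary
#'   distribution of `transition`).
#' @param sensing list with `kernel` (either a matrix `[y', z']` for
#'   memoryless sensing or an array `[z, y', z']`) and optionally `initial`
#'   (matrix `[y0, z0]`; default: the memoryless kernel applied to `y0`).
#' @param switching list with `kernel` (matrix `[z', x']` or array
#'   `[x, z', x']`) and optionally `initial` (matrix `[z0, x0]`; default:
#'   the memoryless kernel applied to `z0`).
#' @param replication list with `lograte` (matrix `[x, y]`, natural-log
#'   scale; `-Inf` allowed).
#' @param decomposition optional metabolic-allocation decomposition, a list
#'   with `kmax` (log-scale vector over y) and `TK` (matrix `[x, y]`,
#'   rows = allocation distributions over environments).
#' @return An object of class `sg_model`.
#' @export
model_bundle <- function(spaces, env, sensing, switching, replication,
                         decomposition = NULL) {
  stopifnot(inherits(spaces, "state_spaces"))
  nx <- length(spaces$phenotypes)
  ny <- length(spaces$environments)
  nz <- length(spaces$signals)

  # environment
  TEF <- as.matrix(env$transition)
  if (!all(dim(TEF) == c(ny, ny)))
    stopf("environment transition must be %d x %d", ny, ny)
  dimnames(TEF) <- list(spaces$environments, spaces$environments)
  TEF <- .check_rows(TEF, "environment transition")
  pE <- env$initial %||% stationary_distribution(TEF)
  pE <- .check_probvec(as.numeric(pE)[seq_len(ny)], "initial environment distribution")
  names(pE) <- spaces$environments

  # sensing: promote a memoryless matrix [y', z'] to the full [z, y', z'] array
  sk <- sensing$kernel
  if (is.matrix(sk)) {
    if (!all(dim(sk) == c(ny, nz)))
      stopf("memoryless sensing kernel must be %d x %d", ny, nz)
    sk <- aperm(array(sk, c(ny, nz, nz)), c(3, 1, 2))
    s_memoryless <- TRUE
  } else {
    if (!all(dim(sk) == c(nz, ny, nz)))
      stopf("sensing kernel must be %d x %d x %d", nz, ny, nz)
    s_memoryless <- max(apply(sk, c(2, 3), function(v) diff(range(v)))) < 1e-12
  }
  dimnames(sk) <- list(spaces$signals, spaces$environments, spaces$signals)
  sk <- .check_rows(sk, "sensing kernel")
  pS0 <- sensing$initial
  if (is.null(pS0)) {
    if (!s_memoryless)
      stopf("sensing kernel has memory; an explicit initial pS(z0|y0) is required")
    pS0 <- matrix(sk[1, , ], ny, nz)
  }
  pS0 <- as.matrix(pS0)
  if (!all(dim(pS0) == c(ny, nz))) stopf("sensing initial must be %d x %d", ny, nz)
  dimnames(pS0) <- list(spaces$environments, spaces$signals)
  pS0 <- .check_rows(pS0, "initial sensing distribution")

  # switching
  fk <- switching$kernel
  if (is.matrix(fk)) {
    if (!all(dim(fk) == c(nz, nx)))
      stopf("memoryless switching kernel must be %d x %d", nz, nx)
    fk <- aperm(array(fk, c(nz, nx, nx)), c(3, 1, 2))
    f_memoryless <- TRUE
  } else {
    if (!all(dim(fk) == c(nx, nz, nx)))
      stopf("switching kernel must be %d x %d x %d", nx, nz, nx)
    f_memoryless <- max(apply(fk, c(2, 3), function(v) diff(range(v)))) < 1e-12
  }
  dimnames(fk) <- list(spaces$phenotypes, spaces$signals, spaces$phenotypes)
  fk <- .check_rows(fk, "switching kernel")
  pF0 <- switching$initial
  if (is.null(pF0)) {
    if (!f_memoryless)
      stopf("switching kernel has memory; an explicit initial pF(x0|z0) is required")
    pF0 <- matrix(fk[1, , ], nz, nx)
  }
  pF0 <- as.matrix(pF0)
  if (!all(dim(pF0) == c(nz, nx))) stopf("switching initial must be %d x %d", nz, nx)
  dimnames(pF0) <- list(spaces$signals, spaces$phenotypes)
  pF0 <- .check_rows(pF0, "initial switching distribution")

  # replication
  k <- as.matrix(replication$lograte)
  if (!all(dim(k) == c(nx, ny))) stopf("replication lograte must be %d x %d", nx, ny)
  if (any(is.nan(k)) || any(k == Inf))
    stopf("replication lograte entries must not be NaN or +Inf")
  dimnames(k) <- list(spaces$phenotypes, spaces$environments)

  model <- structure(
    list(spaces = spaces,
         env = list(transition = TEF, initial = pE),
         sensing = list(kernel = sk, initial = pS0, memoryless = s_memoryless),
         switching = list(kernel = fk, initial = pF0, memoryless = f_memoryless),
         replication = list(lograte = k),
         decomposition = NULL),
    class = "sg_model")

  if (!is.null(decomposition))
    model <- attach_decomposition(model, decomposition$kmax, decomposition$TK)
  model
}

#' Attach a metabolic-allocation decomposition to a model
#'
#' Checks the allocation rows and the recomposition identity
#' `e^{k(x,y)} = e^{kmax(y)} * TK(y|x)` (tolerance `1e-9`).
#'
#' @param model an `sg_model`.
#' @param kmax log-scale vector of per-environment maximum replication rates.
#' @param TK allocation matrix `[x, y]`, each row a distribution over
#'   environments.
#' @return The model with `$decomposition` set.
#' @export
attach_decomposition <- function(model, kmax, TK) {
  sp <- model$spaces
  kmax <- as.numeric(kmax)
  if (length(kmax) != length(sp$environments) || any(!is.finite(kmax)))
    stopf("kmax must be a finite vector over the %d environments",
          length(sp$environments))
  names(kmax) <- sp$environments
  TK <- as.matrix(TK)
  dimnames(TK) <- list(sp$phenotypes, sp$environments)
  TK <- .check_rows(TK, "allocation TK")
  recomposed <- exp(sweep(log(TK), 2, kmax, "+"))
  if (max(abs(recomposed - exp(model$replication$lograte))) > .STOCH_TOL)
    stopf("decomposition does not recompose e^{k(x,y)} within 1e-9")
  model$decomposition <- list(kmax = kmax, TK = TK)
  model
}

#' Stationary distribution of a row-stochastic transition matrix
#'
#' @param P transition matrix `[from, to]`, rows summing to 1.
#' @return Probability vector `p` with `p %*% P = p`.
#' @export
stationary_distribution <- function(P) {
  n <- nrow(P)
  A <- rbind(t(P) - diag(n), rep(1, n))
  p <- qr.solve(A, c(rep(0, n), 1))
  p <- pmax(p, 0)
  p <- p / sum(p)
  names(p) <- rownames(P)
  p
}

# ---------------------------------------------------------------------------
# Replication-rate decomposition
# ---------------------------------------------------------------------------

#' Decompose a replication table into maximum rates and allocations
#'
#' Solves, for `u(y) = e^{-kmax(y)}`, the linear system
#' `sum_y e^{k(x,y)} u(y) = 1` (one equation per phenotype `x`) so that
#' `TK(y|x) = e^{k(x,y)} u(y)` is row-stochastic. When there are more
#' environments than phenotypes the system is underdetermined and entries of
#' `e^{kmax}` must be pinned explicitly.
#'
#' @param replication either an `sg_model` or a list with `lograte`.
#' @param pin named numeric vector of pinned `e^{kmax(y)}` values (linear, not
#'   log, scale), e.g. `c(s3y = 0.16)`.
#' @return A list with log-scale `kmax` and allocation matrix `TK`; when a
#'   model was supplied, the model with the decomposition attached.
#' @export
decompose_replication <- function(replication, pin = NULL) {
  model <- NULL
  if (inherits(replication, "sg_model")) {
    model <- replication
    k <- model$replication$lograte
  } else k <- as.matrix(replication$lograte)
  E <- exp(k)
  envs <- colnames(E)
  u <- rep(NA_real_, ncol(E))
  names(u) <- envs
  if (!is.null(pin)) {
    if (is.null(names(pin)) || !all(names(pin) %in% envs))
      stopf("pin names must be environment labels")
    if (any(pin <= 0)) stopf("pinned e^{kmax} values must be positive")
    u[names(pin)] <- 1 / pin
  }
  free <- which(is.na(u))
  pinned <- setdiff(seq_along(u), free)
  rhs <- rep(1, nrow(E)) - if (length(pinned))
    as.numeric(E[, pinned, drop = FALSE] %*% u[pinned]) else 0
  if (length(free) > 0L) {
    A <- E[, free, drop = FALSE]
    qrA <- qr(A)
    if (qrA$rank < length(free))
      stopf("decomposition is underdetermined (rank %d < %d unknowns); pin more e^{kmax} entries",
            qrA$rank, length(free))
    sol <- qr.coef(qrA, rhs)
    resid <- max(abs(A %*% sol - rhs))
    if (resid > .STOCH_TOL)
      stopf("decomposition is infeasible: least-squares residual %.3g", resid)
    if (any(sol <= 0))
      stopf("decomposition requires e^{kmax} > 0 but the solved system gives a non-positive rate")
    u[free] <- sol
  } else if (max(abs(rhs)) > .STOCH_TOL) {
    stopf("pinned e^{kmax} values are inconsistent: allocation rows sum to %.12g, not 1",
          1 - min(rhs))
  }
  kmax <- -log(u)
  TK <- sweep(E, 2, u, "*")
  if (is.null(model)) list(kmax = kmax, TK = TK)
  else attach_decomposition(model, kmax, TK)
}

# ---------------------------------------------------------------------------
# Random models (fixture generator for property checks)
# ---------------------------------------------------------------------------

#' Generate a random model bundle
#'
#' Kernel rows are drawn from the flat simplex; log replication rates are
#' uniform on `[-rate_scale, rate_scale]` (or induced from random `kmax` and
#' allocation rows when `with_decomposition = TRUE`, in which case the
#' decomposition is attached). Identical seeds give identical bundles.
#'
#' @param sizes integer vector `(n_phenotypes, n_environments, n_signals)`.
#' @param seed integer seed.
#' @param rate_scale positive half-width of the log replication-rate range.
#' @param memoryless generate memoryless sensing/switching kernels?
#' @param env_init one of `"random"`, `"stationary"`, `"point"` (point mass on
#'   the first environment label).
#' @param with_decomposition derive the replication table from a random
#'   allocation decomposition and attach it.
#' @return An `sg_model`.
#' @export
random_model <- function(sizes, seed, rate_scale = 1, memoryless = TRUE,
                         env_init = c("random", "stationary", "point"),
                         with_decomposition = FALSE) {
  stopifnot(length(sizes) == 3L, all(sizes >= 1L))
  env_init <- match.arg(env_init)
  set.seed(seed)
  nx <- sizes[1]; ny <- sizes[2]; nz <- sizes[3]
  sp <- state_spaces(sprintf("x%d", seq_len(nx)),
                     sprintf("y%d", seq_len(ny)),
                     sprintf("z%d", seq_len(nz)))
  TEF <- runif_simplex(ny, ny)
  pE <- switch(env_init,
               random = as.numeric(runif_simplex(1, ny)),
               stationary = NULL,        # filled in by model_bundle default
               point = c(1, rep(0, ny - 1)))
  if (memoryless) {
    sensing <- list(kernel = runif_simplex(ny, nz))
    switching <- list(kernel = runif_simplex(nz, nx))
  } else {
    sk <- array(0, c(nz, ny, nz))
    for (z in seq_len(nz)) for (y in seq_len(ny))
      sk[z, y, ] <- runif_simplex(1, nz)
    fk <- array(0, c(nx, nz, nx))
    for (x in seq_len(nx)) for (z in seq_len(nz))
      fk[x, z, ] <- runif_simplex(1, nx)
    sensing <- list(kernel = sk, initial = runif_simplex(ny, nz))
    switching <- list(kernel = fk, initial = runif_simplex(nz, nx))
  }
  decomposition <- NULL
  if (with_decomposition) {
    kmax <- stats::runif(ny, -rate_scale, rate_scale)
    TK <- runif_simplex(nx, ny)
    k <- sweep(log(TK), 2, kmax, "+")
    decomposition <- list(kmax = kmax, TK = TK)
  } else {
    k <- matrix(stats::runif(nx * ny, -rate_scale, rate_scale), nx, ny)
  }
  model_bundle(sp,
               env = list(transition = TEF, initial = pE),
               sensing = sensing, switching = switching,
               replication = list(lograte = k),
               decomposition = decomposition)
}

#' @export
print.sg_model <- function(x, ...) {
  sp <- x$spaces
  cat(sprintf("<sg_model> %d phenotypes x %d environments x %d signals\n",
              length(sp$phenotypes), length(sp$environments),
              length(sp$signals)))
  cat("  phenotypes:  ", paste(sp$phenotypes, collapse = ", "), "\n")
  cat("  environments:", paste(sp$environments, collapse = ", "), "\n")
  cat("  signals:     ", paste(sp$signals, collapse = ", "), "\n")
  cat(sprintf("  sensing %s, switching %s, decomposition %s\n",
              if (x$sensing$memoryless) "memoryless" else "with memory",
              if (x$switching$memoryless) "memoryless" else "with memory",
              if (is.null(x$decomposition)) "absent" else "attached"))
  invisible(x)
}
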