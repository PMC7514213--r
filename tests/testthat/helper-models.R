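# shared model fixtures, built once per test run

fixture_model <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- load_model(example_model_path())
    m
  }
})

# same model with the environment started from a known state
point_start <- function(model, state = 1L) {
  p <- rep(0, length(model$spaces$environments))
  p[state] <- 1
  names(p) <- model$spaces$environments
  model$env$initial <- p
  model
}

# constant replication rate: growth factors out of every path sum
constant_k_model <- function(c = 0.3, seed = 42) {
  m <- random_model(c(2, 2, 2), seed)
  m$replication$lograte[] <- c
  m
}

# deterministic sensing: the signal is a copy of the environment
deterministic_sensing_model <- function(seed = 4) {
  m <- random_model(c(2, 2, 2), seed)
  m$sensing$kernel[1, , ] <- diag(2)
  m$sensing$kernel[2, , ] <- diag(2)
  m$sensing$initial <- diag(2)
  dimnames(m$sensing$initial) <- list(m$spaces$environments, m$spaces$signals)
  m
}

# every stage deterministic and matched: resources always follow the realized
# environment, so the diagonal allocation probability is 1 for every history
perfect_machinery_model <- function(seed = 8) {
  m <- deterministic_sensing_model(seed)
  m$switching$kernel[1, , ] <- diag(2)
  m$switching$kernel[2, , ] <- diag(2)
  m$switching$initial <- diag(2)
  dimnames(m$switching$initial) <- list(m$spaces$signals, m$spaces$phenotypes)
  kmax <- c(0.5, 0.2)
  m$replication$lograte <- sweep(log(diag(2)), 2, kmax, "+")
  dimnames(m$replication$lograte) <- list(m$spaces$phenotypes,
                                          m$spaces$environments)
  attach_decomposition(m, kmax = kmax, TK = diag(2))
}

one_state_model <- function() {
  model_bundle(state_spaces("x1", "y1", "z1"),
               env = list(transition = matrix(1, 1, 1)),
               sensing = list(kernel = matrix(1, 1, 1)),
               switching = list(kernel = matrix(1, 1, 1)),
               replication = list(lograte = matrix(0.4, 1, 1)),
               decomposition = list(kmax = 0.4, TK = matrix(1, 1, 1)))
}
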