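# ---------------------------------------------------------------------------
# YAML model configuration
#
# Schema (all probability tables are nested maps keyed FIRST by the
# conditioning state, i.e. every inner map is one probability distribution;
# this is the transpose of the usual printed matrix convention in which the
# column indexed by the conditioning state sums to 1):
#
#   spaces:
#     phenotypes:   [s1x, s2x]
#     environments: [s1y, s2y, s3y]
#     signals:      [s1z, s2z]
#   environment:
#     transition: {s1y: {s1y: 0.70, s2y: 0.25, s3y: 0.05}, ...}
#     initial: stationary          # keyword or explicit map {s1y: 0.5, ...}
#   sensing:
#     kernel: {s1y: {s1z: 0.8, s2z: 0.2}, ...}        # memoryless TS(z'|y')
#     # or, with memory, {z: {y': {z': p}}} for TS(z'|z, y')
#     initial: from_kernel         # keyword or map {y0: {z0: p}}
#   switching:
#     kernel: {s1z: {s1x: 0.95, s2x: 0.05}, ...}      # memoryless TF(x'|z')
#     initial: from_kernel
#   replication:
#     rates_are_exponentiated: true
#     table: {s1x: {s1y: 2.24, s2y: 0.32, s3y: 0.08}, ...}
#   decomposition:                 # optional; values are e^{kmax(y)}
#     pin: {s3y: 0.16}
#
# Unlisted entries of a distribution default to probability 0.
# ---------------------------------------------------------------------------

.map_to_matrix <- function(m, rows, cols, what) {
  if (is.null(m)) stopf("configuration is missing table '%s'", what)
  out <- matrix(0, length(rows), length(cols), dimnames = list(rows, cols))
  for (r in names(m)) {
    if (!r %in% rows) stopf("'%s': unknown state label '%s'", what, r)
    for (cc in names(m[[r]])) {
      if (!cc %in% cols) stopf("'%s': unknown state label '%s'", what, cc)
      out[r, cc] <- as.numeric(m[[r]][[cc]])
    }
  }
  out
}

.map_depth <- function(m) if (is.list(m[[1]][[1]])) 3L else 2L

#' Load a model bundle from a YAML configuration file
#'
#' See the schema documented in the package vignette: every probability table
#' is a nested map keyed first by the conditioning state, so each inner map is
#' one distribution. Replication rates may be given on the natural-log scale
#' or as multiplicative factors (`rates_are_exponentiated: true`). An optional
#' `decomposition` section requests the metabolic-allocation decomposition,
#' with `pin` supplying fixed `e^{kmax(y)}` entries where the system is
#' underdetermined.
#'
#' @param path path to a YAML model configuration.
#' @return A validated `sg_model`.
#' @seealso [write_model()], [model_bundle()], [decompose_replication()]
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stopf("config file '%s' does not exist", path)
  cfg <- yaml::read_yaml(path)
  for (sec in c("spaces", "environment", "sensing", "switching", "replication"))
    if (is.null(cfg[[sec]])) stopf("configuration is missing section [%s]", sec)
  sp <- state_spaces(cfg$spaces$phenotypes, cfg$spaces$environments,
                     cfg$spaces$signals)
  xs <- sp$phenotypes; ys <- sp$environments; zs <- sp$signals

  TEF <- .map_to_matrix(cfg$environment$transition, ys, ys,
                        "environment transition")
  pE <- cfg$environment$initial
  if (is.character(pE)) {
    if (pE != "stationary") stopf("unknown environment initial keyword '%s'", pE)
    pE <- NULL
  } else if (!is.null(pE)) {
    v <- rep(0, length(ys)); names(v) <- ys
    v[names(pE)] <- as.numeric(unlist(pE))
    pE <- v
  }

  sk <- cfg$sensing$kernel
  if (is.null(sk)) stopf("configuration is missing table 'sensing kernel'")
  if (.map_depth(sk) == 2L) {
    kernel <- .map_to_matrix(sk, ys, zs, "sensing kernel")
  } else {
    kernel <- array(0, c(length(zs), length(ys), length(zs)),
                    dimnames = list(zs, ys, zs))
    for (z in names(sk))
      kernel[z, , ] <- .map_to_matrix(sk[[z]], ys, zs, "sensing kernel")
  }
  s_init <- cfg$sensing$initial
  s_init <- if (is.null(s_init) || identical(s_init, "from_kernel")) NULL
            else .map_to_matrix(s_init, ys, zs, "sensing initial")

  fk <- cfg$switching$kernel
  if (is.null(fk)) stopf("configuration is missing table 'switching kernel'")
  if (.map_depth(fk) == 2L) {
    fkernel <- .map_to_matrix(fk, zs, xs, "switching kernel")
  } else {
    fkernel <- array(0, c(length(xs), length(zs), length(xs)),
                     dimnames = list(xs, zs, xs))
    for (x in names(fk))
      fkernel[x, , ] <- .map_to_matrix(fk[[x]], zs, xs, "switching kernel")
  }
  f_init <- cfg$switching$initial
  f_init <- if (is.null(f_init) || identical(f_init, "from_kernel")) NULL
            else .map_to_matrix(f_init, zs, xs, "switching initial")

  ktab <- .map_to_matrix(cfg$replication$table, xs, ys, "replication table")
  if (isTRUE(cfg$replication$rates_are_exponentiated)) ktab <- log(ktab)

  model <- model_bundle(
    sp,
    env = list(transition = TEF, initial = pE),
    sensing = list(kernel = kernel, initial = s_init),
    switching = list(kernel = fkernel, initial = f_init),
    replication = list(lograte = ktab))

  if (!is.null(cfg$decomposition)) {
    pin <- cfg$decomposition$pin
    pin <- if (is.null(pin)) NULL else unlist(pin)
    model <- decompose_replication(model, pin = pin)
  }
  model
}

.matrix_to_map <- function(m) {
  out <- lapply(seq_len(nrow(m)), function(i) as.list(m[i, ]))
  names(out) <- rownames(m)
  out
}

#' Serialize a model bundle back to YAML
#'
#' Writes all tables at full precision so that `load_model(write_model(m))`
#' reproduces the tables of `m`.
#'
#' @param model an `sg_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  sp <- model$spaces
  slice1 <- function(a, i) {
    d <- dim(a)
    matrix(a[i, , ], d[2], d[3], dimnames = dimnames(a)[c(2, 3)])
  }
  arr_to_map <- function(a) {
    out <- lapply(seq_len(dim(a)[1]), function(i) .matrix_to_map(slice1(a, i)))
    names(out) <- dimnames(a)[[1]]
    out
  }
  cfg <- list(
    spaces = list(phenotypes = sp$phenotypes, environments = sp$environments,
                  signals = sp$signals),
    environment = list(transition = .matrix_to_map(model$env$transition),
                       initial = as.list(model$env$initial)),
    sensing = list(
      kernel = if (model$sensing$memoryless)
        .matrix_to_map(slice1(model$sensing$kernel, 1))
      else arr_to_map(model$sensing$kernel),
      initial = .matrix_to_map(model$sensing$initial)),
    switching = list(
      kernel = if (model$switching$memoryless)
        .matrix_to_map(slice1(model$switching$kernel, 1))
      else arr_to_map(model$switching$kernel),
      initial = .matrix_to_map(model$switching$initial)),
    replication = list(rates_are_exponentiated = FALSE,
                       table = .matrix_to_map(model$replication$lograte)))
  if (!is.null(model$decomposition))
    cfg$decomposition <- list(pin = as.list(exp(model$decomposition$kmax)))
  writeLines(yaml::as.yaml(cfg, precision = 17), path)
  invisible(path)
}

#' Path of the bundled three-state example configuration
#'
#' A three-environment (two nutrient-rich states and one nutrient-poor
#' state), two-phenotype, two-signal model used throughout the examples and
#' tests, with a pinned metabolic-allocation decomposition
#' (`e^{kmax} = 0.16` in the nutrient-poor state).
#'
#' @return File path of the YAML configuration.
#' @export
example_model_path <- function() {
  system.file("extdata", "three_state_model.yaml", package = "sensegain",
              mustWork = TRUE)
}
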