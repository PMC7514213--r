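# ---------------------------------------------------------------------------
# Histories: ordered state sequences over one of the three finite alphabets.
# Internally every history is an integer index vector; user-facing functions
# accept either labels or indices.
# ---------------------------------------------------------------------------

.DEFAULT_GUARD <- 1e7

# convert labels/indices to validated integer indices into `labels`
.hist_idx <- function(h, labels, what) {
  if (length(h) < 1L) stopf("%s history must have length >= 1", what)
  if (is.numeric(h)) {
    i <- as.integer(h)
    if (any(i < 1L | i > length(labels)))
      stopf("%s history contains out-of-range state indices", what)
  } else {
    i <- match(as.character(h), labels)
    if (anyNA(i))
      stopf("%s history contains labels not in the %s alphabet", what, what)
  }
  i
}

.space_labels <- function(model, space = c("environment", "signal", "phenotype")) {
  switch(match.arg(space),
         environment = model$spaces$environments,
         signal = model$spaces$signals,
         phenotype = model$spaces$phenotypes)
}

# all |alphabet|^(t+1) index sequences, lexicographic, one row per history
.enum_idx <- function(m, t, guard = .DEFAULT_GUARD) {
  n <- m^(t + 1)
  if (n > guard)
    stopf("enumeration of %g histories exceeds the guard of %g; raise `guard` to override",
          n, guard)
  n <- as.integer(round(n))
  out <- matrix(0L, n, t + 1L)
  for (j in seq_len(t + 1L))
    out[, j] <- rep(seq_len(m), each = m^(t + 1L - j), times = m^(j - 1L))
  out
}

#' Enumerate all histories over an alphabet
#'
#' @param alphabet character vector of state labels.
#' @param t horizon; histories have `t + 1` entries (times `0..t`).
#' @param guard refuse enumerations larger than this many histories.
#' @return Character matrix with one history per row, in lexicographic order.
#' @export
enumerate_histories <- function(alphabet, t, guard = .DEFAULT_GUARD) {
  idx <- .enum_idx(length(alphabet), t, guard)
  matrix(alphabet[idx], nrow(idx), ncol(idx))
}

.join_hist <- function(mat, labels) {
  apply(matrix(labels[mat], nrow(mat)), 1, paste, collapse = "-")
}

#' Exhaustive environment-history ensemble with forward log-weights
#'
#' @param model an `sg_model`.
#' @param t horizon.
#' @param guard enumeration guard (number of histories).
#' @return A data frame of class `path_ensemble` with columns `history`
#'   (dash-joined labels) and `log_weight` (`ln Q[Yt]`); exhaustive ensembles
#'   log-sum-exp to 0.
#' @export
env_path_ensemble <- function(model, t, guard = .DEFAULT_GUARD) {
  ys <- model$spaces$environments
  idx <- .enum_idx(length(ys), t, guard)
  lw <- .batch_env_logprob(model, idx)
  structure(data.frame(history = .join_hist(idx, ys), log_weight = lw,
                       stringsAsFactors = FALSE),
            kind = "exhaustive", horizon = t, alphabet = ys,
            class = c("path_ensemble", "data.frame"))
}
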