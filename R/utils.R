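# internal numerical helpers

# log(sum(exp(x))) guarded against all -Inf
logsumexp <- function(x) {
  m <- max(x)
  if (m == -Inf) return(-Inf)
  m + log(sum(exp(x - m)))
}

# draw n rows from the flat simplex of dimension k
runif_simplex <- function(n, k) {
  if (k == 1L) return(matrix(1, n, 1))
  g <- matrix(stats::rexp(n * k), n, k)
  g / rowSums(g)
}

# x * log(x / y) with the 0 log 0 = 0 convention; +Inf when x > 0, y = 0
xlogxy <- function(x, y) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] * (log(x[pos]) - log(y[pos]))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
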