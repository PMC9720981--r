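# Internal helpers shared across modules.

# Derive a 32-bit-safe stream seed for unit `index` from a global seed.
# Subject-level streams keep individual draws stable when cohort sizes change.
stream_seed <- function(seed, index) {
  (as.double(seed) * 48271 + as.double(index) * 7919) %% 2147483562 + 1
}

# Draw once from a Dirichlet with mean `mean` (sums to 1) and concentration
# `precision`; returns a vector summing to 1.
rdirichlet1 <- function(mean, precision) {
  alpha <- mean * precision
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) <= 0) {
    # pathological underflow: fall back to the mean vector
    return(mean)
  }
  g / sum(g)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Deterministic non-cryptographic hash of an R object (Horner rolling hash
# over its deparsed form, mod 2^31 - 1), returned as hex. Used to stamp
# pipeline artifacts so equal configs yield equal hashes.
config_hash <- function(x) {
  txt <- paste(deparse(x, control = c("keepNA", "keepInteger", "showAttributes")),
               collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 0
  m <- 2147483647
  for (b in bytes) h <- (h * 31 + b) %% m
  sprintf("%08x", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_immflow <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "immflow_error")))
}
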