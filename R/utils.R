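# Small internal helpers shared across modules.

sigmoid <- function(x) 1 / (1 + exp(-x))

# Add a bias (row) vector to every row of a matrix without transposes.
# Relies on column-major layout: rep(b, each = n) aligns with columns.
add_bias <- function(M, b) M + rep(b, each = nrow(M))

# Row-wise maximum of a matrix via repeated pmax (fast for modest ncol).
row_max <- function(M) {
  mx <- M[, 1L]
  nc <- ncol(M)
  if (nc > 1L) for (j in 2:nc) mx <- pmax(mx, M[, j])
  mx
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so seeded operations do not perturb the session stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Stable short hash of an R object (FNV-1a over its serialization), used to
# stamp experiment outputs with a configuration fingerprint.
config_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2L)
  h <- 2166136261
  p <- 16777619
  for (byte in as.integer(raw)) {
    # xor into the low byte (h can exceed the integer range, so do it
    # arithmetically)
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), byte)
    # multiply by the FNV prime mod 2^32, split into 16-bit halves so every
    # intermediate stays exactly representable in a double
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (((hi * p) %% 65536) * 65536 + lo * p) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
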