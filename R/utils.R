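# Internal helpers shared across modules.

# Row-major off-diagonal cell index for an n x n matrix: (1,2), (1,3), ...,
# (2,1), (2,3), ... Used everywhere a matrix is flattened to a dyad vector so
# that every matrix in a model lines up cell-for-cell.
offdiag_index <- function(n) {
  r <- rep(seq_len(n), each = n)
  c <- rep(seq_len(n), times = n)
  keep <- r != c
  list(row = r[keep], col = c[keep])
}

# Enumerate all permutations of 1..n (rows of the returned matrix).
# Guarded: exhaustive permutation inference is only offered for small n.
all_permutations <- function(n) {
  n <- as.integer(n)
  stopifnot(n >= 1L, factorial(n) <= 1e6)
  if (n == 1L) {
    return(matrix(1L, 1L, 1L))
  }
  sub <- all_permutations(n - 1L)
  m <- nrow(sub)
  out <- matrix(0L, m * n, n)
  for (pos in seq_len(n)) {
    rows <- ((pos - 1L) * m + 1L):(pos * m)
    out[rows, pos] <- n
    out[rows, seq_len(n)[-pos]] <- sub
  }
  out
}

# Derive k child seeds from one parent seed, each usable with set.seed().
# Keeps every derived seed strictly below 2^31.
split_seed <- function(seed, k) {
  if (is.null(seed)) {
    return(rep(list(NULL), k))
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  as.list(sample.int(.Machine$integer.max, k))
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Run code with a locally-set seed, leaving the caller's RNG stream untouched.
# seed = NULL means "use (and advance) the global stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Semicolon-joined membership strings used in the scans table.
join_members <- function(x) {
  vapply(x, function(v) paste(v, collapse = ";"), character(1))
}

split_members <- function(x) {
  out <- strsplit(as.character(x), ";", fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}
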