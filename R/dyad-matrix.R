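#' Directed weighted dyadic matrix
#'
#' Light container for the n x n matrices the network analyses consume:
#' proximity per party-hour, per-sequence-type communication rates, binary
#' attribute similarity. The diagonal is structurally zero (an individual has
#' no dyad with itself) and node labels are carried as dimnames.
#'
#' @param values numeric square matrix with identical row/column labels.
#' @param name measure label, e.g. "proximity" or "persistence".
#' @param directed logical; similarity matrices are undirected, rate
#'   matrices directed.
#' @param zero_diagonal how to treat a nonzero diagonal: "error" rejects it,
#'   "zero" silently zeroes it, "warn" zeroes it with a warning.
#' @return an object of class \code{dyad_matrix} (a matrix with attributes).
#' @export
dyad_matrix <- function(values, name = "measure", directed = TRUE,
                        zero_diagonal = c("error", "zero", "warn")) {
  zero_diagonal <- match.arg(zero_diagonal)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    stop("dyad_matrix values must be square, got ",
         nrow(values), " x ", ncol(values))
  }
  labels <- rownames(values)
  if (is.null(labels)) {
    labels <- colnames(values)
  }
  if (is.null(labels)) {
    labels <- paste0("N", seq_len(nrow(values)))
  }
  if (anyDuplicated(labels)) {
    stop("duplicate node labels in dyad_matrix")
  }
  if (!is.null(colnames(values)) && !identical(colnames(values), labels)) {
    stop("row and column labels of a dyad_matrix must match")
  }
  dimnames(values) <- list(labels, labels)
  if (!all(is.finite(values))) {
    stop("dyad_matrix values must be finite")
  }
  if (any(diag(values) != 0)) {
    if (zero_diagonal == "error") {
      stop("dyad_matrix diagonal must be zero (self-dyads are undefined)")
    }
    if (zero_diagonal == "warn") {
      warning("nonzero diagonal zeroed in dyad_matrix '", name, "'")
    }
    diag(values) <- 0
  }
  structure(values,
            name = name,
            directed = isTRUE(directed),
            class = c("dyad_matrix", class(values)))
}

#' @export
as.matrix.dyad_matrix <- function(x, ...) {
  attr(x, "name") <- NULL
  attr(x, "directed") <- NULL
  class(x) <- "matrix"
  x
}

as_dyad_matrix <- function(x, name = NULL) {
  if (inherits(x, "dyad_matrix")) {
    return(x)
  }
  dyad_matrix(x, name = name %||% deparse(substitute(x)))
}

node_labels <- function(m) rownames(m)

#' @export
print.dyad_matrix <- function(x, ...) {
  cat(sprintf("dyad_matrix '%s' (%s), %d nodes\n",
              attr(x, "name"), if (attr(x, "directed")) "directed" else
                "undirected", nrow(x)))
  print(as.matrix(x), ...)
  invisible(x)
}

#' Flatten a dyadic matrix to its off-diagonal dyad vector
#'
#' Off-diagonal entries are returned in fixed row-major dyad order
#' ((1,2), (1,3), ..., (2,1), (2,3), ...), the order shared by every matrix
#' entering a model so that dyads line up across outcome and predictors.
#'
#' @param m a \code{dyad_matrix} or labeled square matrix.
#' @param mask optional logical matrix (same shape); cells marked TRUE are
#'   dropped from the vector, consistently for every matrix in a model.
#' @return numeric vector of length n(n-1) minus masked cells.
#' @export
dyad_vectorize <- function(m, mask = NULL) {
  m <- as_dyad_matrix(m)
  n <- nrow(m)
  idx <- offdiag_index(n)
  v <- m[cbind(idx$row, idx$col)]
  if (!is.null(mask)) {
    mask <- as.matrix(mask)
    if (!identical(dim(mask), dim(unclass(m)))) {
      stop("mask dimensions do not match the matrix")
    }
    v <- v[!mask[cbind(idx$row, idx$col)]]
  }
  v
}

#' Rebuild a dyadic matrix from an off-diagonal dyad vector
#'
#' Inverse of \code{\link{dyad_vectorize}} (without a mask): entries are
#' placed back in row-major dyad order with a zero diagonal.
#'
#' @param v numeric vector of length n(n-1).
#' @param labels node labels of the target matrix.
#' @inheritParams dyad_matrix
#' @export
dyad_devectorize <- function(v, labels, name = "measure", directed = TRUE) {
  n <- length(labels)
  if (length(v) != n * (n - 1)) {
    stop("vector length ", length(v), " does not match ", n, " nodes")
  }
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  idx <- offdiag_index(n)
  m[cbind(idx$row, idx$col)] <- v
  dyad_matrix(m, name = name, directed = directed)
}
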