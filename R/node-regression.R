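# Node-level analysis: degree centralities of dyadic matrices and
# regression of a node outcome on node covariates with node-label
# permutation inference (the outcome vector is permuted across nodes, the
# standard exchangeability argument for node-level network regression).

#' Degree centrality of a directed weighted matrix
#'
#' Outdegree (row sums) measures behaviour the node directs at others;
#' indegree (column sums) behaviour directed at the node. The diagonal is
#' excluded (it is structurally zero in a \code{\link{dyad_matrix}}).
#'
#' @param m a \code{\link{dyad_matrix}} or labeled square matrix.
#' @param direction "out" or "in".
#' @return named numeric vector over nodes.
#' @export
degree <- function(m, direction = c("out", "in")) {
  direction <- match.arg(direction)
  m <- as.matrix(as_dyad_matrix(m))
  diag(m) <- 0
  if (direction == "out") rowSums(m) else colSums(m)
}

#' Node-level permutation regression
#'
#' OLS of a node outcome on node covariates; the null distribution of every
#' coefficient is built by permuting the outcome vector across nodes and
#' refitting. Two-sided p with the (+1)/(+1) estimator in sampled mode, or
#' the exact proportion over all n! node permutations in exhaustive mode.
#' Standardized coefficients come from z-scored columns; because the
#' permutation statistic is the raw coefficient and permuting y leaves its
#' own scale fixed, p-values are invariant to affine rescaling of y.
#'
#' @param y numeric node outcome vector.
#' @param X data.frame or matrix of node covariates (one row per node).
#' @param n_perm number of sampled permutations.
#' @param seed RNG seed.
#' @param exhaustive,exhaustive_limit see \code{\link{qap_correlation}}.
#' @return object of class \code{node_regression_result}.
#' @export
node_permutation_regression <- function(y, X, n_perm = 2000, seed = NULL,
                                        exhaustive = NULL,
                                        exhaustive_limit = 5040) {
  y <- as.numeric(y)
  X <- as.matrix(as.data.frame(X))
  storage.mode(X) <- "double"
  n <- length(y)
  if (nrow(X) != n) {
    stop("X must have one row per node")
  }
  if (anyNA(y) || anyNA(X)) {
    stop("missing values are not allowed in node regression")
  }
  if (stats::sd(y) == 0) {
    stop("outcome vector is constant")
  }
  if (is.null(colnames(X))) {
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  D <- cbind(`(Intercept)` = 1, X)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    dropped <- colnames(D)[qrD$pivot[(qrD$rank + 1):ncol(D)]]
    stop("design matrix is rank deficient; collinear predictors: ",
         paste(dropped, collapse = ", "))
  }
  beta_all <- qr.coef(qrD, y)
  resid <- qr.resid(qrD, y)
  dof <- n - ncol(D)
  sigma2 <- if (dof > 0) sum(resid^2) / dof else NA_real_
  XtXinv <- chol2inv(qr.R(qrD))
  se_all <- sqrt(sigma2 * diag(XtXinv))
  r_squared <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  zX <- scale(X)
  if (any(attr(zX, "scaled:scale") == 0)) {
    const <- colnames(X)[attr(zX, "scaled:scale") == 0]
    stop("constant predictor(s): ", paste(const, collapse = ", "))
  }
  std_beta <- qr.coef(qr(cbind(1, zX)), as.vector(scale(y)))[-1]
  names(std_beta) <- colnames(X)

  is_exhaustive <- decide_exhaustive(n, exhaustive, exhaustive_limit)
  if (is_exhaustive) {
    pm <- all_permutations(n)
    Yp <- matrix(y[t(pm)], nrow = n)
    n_perm_used <- nrow(pm)
  } else {
    perms <- with_seed(seed, replicate(n_perm, sample.int(n),
                                       simplify = FALSE))
    Yp <- vapply(perms, function(p) y[p], numeric(n))
    n_perm_used <- n_perm
  }
  # all permutation fits at once: beta* = (D'D)^-1 D' y*
  A <- XtXinv %*% t(D)
  B <- A %*% Yp # (k+1) x n_perm
  k <- ncol(X)
  p_values <- numeric(k)
  names(p_values) <- colnames(X)
  for (i in seq_len(k)) {
    hits <- sum(abs(B[i + 1, ]) >= abs(beta_all[i + 1]) - TIE_TOL)
    p_values[i] <- if (is_exhaustive) {
      hits / n_perm_used
    } else {
      (1 + hits) / (1 + n_perm_used)
    }
  }

  structure(list(outcome_name = "y",
                 predictor_names = colnames(X),
                 coefficients = beta_all[-1],
                 intercept = unname(beta_all[1]),
                 standardized_coefficients = std_beta,
                 standard_errors = se_all[-1],
                 p_values = p_values,
                 r_squared = r_squared,
                 n_permutations = n_perm_used,
                 exhaustive = is_exhaustive,
                 seed = seed,
                 n_nodes = n),
            class = "node_regression_result")
}

#' @export
print.node_regression_result <- function(x, ...) {
  cat(sprintf("Node-level permutation regression: %s ~ %s\n",
              x$outcome_name, paste(x$predictor_names, collapse = " + ")))
  cat(sprintf("%d nodes, R-squared %.4f, %s %d permutations\n",
              x$n_nodes, x$r_squared,
              if (x$exhaustive) "exhaustive over" else "sampled",
              x$n_permutations))
  tab <- data.frame(coef = x$coefficients,
                    std_coef = x$standardized_coefficients,
                    se_ols = x$standard_errors,
                    p = x$p_values)
  print(round(tab, 4))
  invisible(x)
}

#' Centrality model: proximity outdegree on sequence-type degrees
#'
#' Outcome: each focal's proximity outdegree (total time in proximity given
#' to others). Predictors: out- and in-degree of the rapid, single and
#' persistence rate networks, plus node controls: proximity directed at
#' cycling (oestrous) females, proximity directed at maternal kin, and the
#' focal's sex and age (as two columns by default, or one combined z-scored
#' composite).
#'
#' @param networks named list from \code{\link{build_networks}}.
#' @param attrs attribute table aligned with the network labels.
#' @param n_perm,seed,exhaustive,exhaustive_limit passed to
#'   \code{\link{node_permutation_regression}}.
#' @param sex_age "separate" (male indicator and age in years) or
#'   "combined" (single column: z(age) + z(male indicator)).
#' @return a \code{node_regression_result}.
#' @export
run_centrality_model <- function(networks, attrs, n_perm = 2000, seed = NULL,
                             exhaustive = NULL, exhaustive_limit = 5040,
                             sex_age = c("separate", "combined")) {
  sex_age <- match.arg(sex_age)
  needed <- c("proximity", "rapid", "single", "persistence", "kin")
  missing_nets <- setdiff(needed, names(networks))
  if (length(missing_nets) > 0) {
    stop("missing networks: ", paste(missing_nets, collapse = ", "))
  }
  prox <- as.matrix(as_dyad_matrix(networks$proximity))
  labs <- rownames(prox)
  if (!identical(labs, attrs$id)) {
    stop("attribute table ids must match network labels, in order")
  }
  needed_cols <- c("sex", "age", "reproductive_status")
  miss <- setdiff(needed_cols, names(attrs))
  if (length(miss) > 0) {
    stop("attrs is missing control columns: ", paste(miss, collapse = ", "))
  }

  y <- degree(networks$proximity, "out")
  cyc_f <- attrs$sex == "female" & attrs$reproductive_status == "cycling"
  oestrous_prox <- rowSums(prox[, cyc_f, drop = FALSE])
  kin_m <- as.matrix(as_dyad_matrix(networks$kin))
  kin_prox <- rowSums(prox * (kin_m > 0))

  X <- data.frame(oestrous_proximity = oestrous_prox,
                  kin_proximity = kin_prox)
  male <- as.numeric(attrs$sex == "male")
  if (sex_age == "separate") {
    X$sex <- male
    X$age <- attrs$age
  } else {
    X$sex_age <- as.vector(scale(attrs$age)) + as.vector(scale(male))
  }
  for (net in c("rapid", "single", "persistence")) {
    X[[paste0(net, "_outdegree")]] <- degree(networks[[net]], "out")
    X[[paste0(net, "_indegree")]] <- degree(networks[[net]], "in")
  }
  res <- node_permutation_regression(y, X, n_perm = n_perm, seed = seed,
                                     exhaustive = exhaustive,
                                     exhaustive_limit = exhaustive_limit)
  res$outcome_name <- "proximity_outdegree"
  res
}
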