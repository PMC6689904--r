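# Permutation inference for dyadic matrices: QAP correlation and multiple
# regression QAP with Double-Dekker semi-partialling (DSP).
#
# The null for dyadic data must preserve the dependence structure of rows
# and columns, so permutations are simultaneous identical row-and-column
# relabelings of a matrix, never independent shuffles of the dyad vector.
# In DSP, each predictor's null is built by residualizing that predictor's
# matrix on the remaining predictors dyad-wise, relabeling the residual
# matrix, substituting it for the predictor and refitting; this is robust to
# network autocorrelation in the outcome.

# Tolerance used when comparing |stat*| >= |stat|: the observed statistic and
# the identity-relabeling replicate are computed by different numerical
# routes, so exact ties must not be lost to 1e-15 round-off. Ties count
# toward rejection (conservative).
TIE_TOL <- 1e-8

check_same_labels <- function(mats) {
  labs <- lapply(mats, function(m) rownames(as.matrix(m)))
  if (length(unique(labs)) != 1) {
    stop("all matrices in a model must share identical node labels")
  }
  labs[[1]]
}

# Decide between exhaustive enumeration of all n! relabelings and random
# sampling. Exhaustive mode replaces sampling automatically when n! is small
# enough to afford exactness.
decide_exhaustive <- function(n, exhaustive, exhaustive_limit) {
  use_exhaustive <- if (is.null(exhaustive)) {
    factorial(n) <= exhaustive_limit
  } else {
    isTRUE(exhaustive)
  }
  if (use_exhaustive && factorial(n) > 1e6) {
    stop("exhaustive enumeration requested for n = ", n,
         " (", factorial(n), " relabelings) - too many")
  }
  use_exhaustive
}

resolve_permutations <- function(n, n_perm, seed, exhaustive,
                                 exhaustive_limit) {
  if (decide_exhaustive(n, exhaustive, exhaustive_limit)) {
    perms <- all_permutations(n)
    list(exhaustive = TRUE,
         perms = lapply(seq_len(nrow(perms)), function(i) perms[i, ]),
         n_perm = nrow(perms))
  } else {
    perms <- with_seed(seed, replicate(n_perm, sample.int(n),
                                       simplify = FALSE))
    list(exhaustive = FALSE, perms = perms, n_perm = n_perm)
  }
}

# Relabel rows and columns of m by p and return its off-diagonal vector
# (row-major dyad order), optionally dropping masked cells.
relabel_vector <- function(m, p, idx, keep = NULL) {
  v <- m[cbind(p[idx$row], p[idx$col])]
  if (is.null(keep)) v else v[keep]
}

mask_keep <- function(mask, idx) {
  if (is.null(mask)) {
    return(NULL)
  }
  !as.matrix(mask)[cbind(idx$row, idx$col)]
}

#' QAP correlation between two dyadic matrices
#'
#' Pearson correlation of the off-diagonal dyad vectors, with a permutation
#' p-value obtained by relabeling the rows and columns of \code{x}
#' simultaneously. Two-sided: the p-value is the share of relabelings with
#' \code{|r*| >= |r|}. In sampled mode the (+1)/(+1) estimator is used, so p
#' is never 0; in exhaustive mode (all n! relabelings, chosen automatically
#' for small n) the p-value is the exact proportion.
#'
#' @param x,y \code{\link{dyad_matrix}} objects (or labeled square matrices)
#'   with identical labels.
#' @param n_perm number of sampled relabelings (ignored in exhaustive mode).
#' @param seed RNG seed for the permutation stream.
#' @param mask optional logical matrix; TRUE cells are dropped from both
#'   dyad vectors (the mask itself is never relabeled).
#' @param exhaustive force (TRUE) or forbid (FALSE) exhaustive enumeration;
#'   NULL picks it automatically when n! <= \code{exhaustive_limit}.
#' @param exhaustive_limit largest n! enumerated automatically.
#' @return list with r, p, n_perm, exhaustive, seed.
#' @export
qap_correlation <- function(x, y, n_perm = 2000, seed = NULL, mask = NULL,
                            exhaustive = NULL, exhaustive_limit = 5040) {
  labs <- check_same_labels(list(x, y))
  n <- length(labs)
  idx <- offdiag_index(n)
  keep <- mask_keep(mask, idx)
  xm <- as.matrix(as_dyad_matrix(x))
  xv <- dyad_vectorize(x, mask)
  yv <- dyad_vectorize(y, mask)
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
    stop("correlation undefined: a dyad vector has zero variance")
  }
  r_obs <- stats::cor(xv, yv)
  plan <- resolve_permutations(n, n_perm, seed, exhaustive, exhaustive_limit)
  r_star <- vapply(plan$perms, function(p) {
    stats::cor(relabel_vector(xm, p, idx, keep), yv)
  }, numeric(1))
  hits <- sum(abs(r_star) >= abs(r_obs) - TIE_TOL)
  p <- if (plan$exhaustive) {
    hits / plan$n_perm
  } else {
    (1 + hits) / (1 + plan$n_perm)
  }
  list(r = r_obs, p = p, n_perm = plan$n_perm,
       exhaustive = plan$exhaustive, seed = seed)
}

#' MRQAP regression with Double-Dekker semi-partialling
#'
#' Ordinary least squares of the outcome dyad vector on the predictor dyad
#' vectors (with intercept), with per-predictor permutation p-values built
#' by semi-partialling: predictor i's matrix is regressed dyad-wise on the
#' remaining predictors, the residuals are re-formed as a matrix, relabeled
#' (rows and columns simultaneously), substituted for predictor i, and the
#' model refit. Residualization is done on raw vectors; standardized
#' coefficients (from z-scored vectors) are reported separately so p-values
#' never depend on scaling. Classical OLS standard errors are included for
#' reference only; they are not permutation-valid.
#'
#' @param y outcome \code{\link{dyad_matrix}}.
#' @param xs named list of predictor matrices sharing y's labels.
#' @param n_perm sampled relabelings per predictor (default 2000).
#' @param seed seed for the permutation streams; one independent stream is
#'   derived per predictor, so results do not depend on evaluation order.
#' @param mask optional logical matrix of dyads to drop (listwise).
#' @param exhaustive,exhaustive_limit see \code{\link{qap_correlation}}.
#' @return object of class \code{mrqap_result}: outcome_name,
#'   predictor_names, coefficients, standardized_coefficients,
#'   standard_errors (classical OLS), p_values, r_squared, n_permutations,
#'   exhaustive, seed, n_dyads.
#' @export
mrqap_dsp <- function(y, xs, n_perm = 2000, seed = NULL, mask = NULL,
                      exhaustive = NULL, exhaustive_limit = 5040) {
  if (!is.list(xs) || length(xs) == 0) {
    stop("xs must be a nonempty list of predictor matrices")
  }
  if (is.null(names(xs)) || any(!nzchar(names(xs)))) {
    names(xs) <- paste0("x", seq_along(xs))
  }
  labs <- check_same_labels(c(list(y), xs))
  n <- length(labs)
  idx <- offdiag_index(n)
  keep <- mask_keep(mask, idx)

  yv <- dyad_vectorize(y, mask)
  X <- vapply(xs, dyad_vectorize, numeric(length(yv)), mask = mask)
  X <- matrix(X, ncol = length(xs), dimnames = list(NULL, names(xs)))
  k <- ncol(X)
  m <- length(yv)
  if (stats::sd(yv) == 0) {
    stop("outcome matrix is constant off the diagonal")
  }

  D <- cbind(`(Intercept)` = 1, X)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    dropped <- colnames(D)[qrD$pivot[(qrD$rank + 1):ncol(D)]]
    stop("design matrix is rank deficient; collinear predictors: ",
         paste(dropped, collapse = ", "))
  }
  beta_all <- qr.coef(qrD, yv)
  resid <- qr.resid(qrD, yv)
  dof <- m - ncol(D)
  sigma2 <- sum(resid^2) / dof
  XtXinv <- chol2inv(qr.R(qrD))
  se_all <- sqrt(sigma2 * diag(XtXinv))
  r_squared <- 1 - sum(resid^2) / sum((yv - mean(yv))^2)

  # standardized coefficients from z-scored vectors
  zX <- scale(X)
  if (any(attr(zX, "scaled:scale") == 0)) {
    const <- colnames(X)[attr(zX, "scaled:scale") == 0]
    stop("constant predictor(s): ", paste(const, collapse = ", "))
  }
  std_beta <- qr.coef(qr(cbind(1, zX)), as.vector(scale(yv)))[-1]
  names(std_beta) <- colnames(X)

  is_exhaustive <- decide_exhaustive(n, exhaustive, exhaustive_limit)
  exh_perms <- NULL
  n_perm_used <- n_perm
  if (is_exhaustive) {
    pm <- all_permutations(n)
    exh_perms <- lapply(seq_len(nrow(pm)), function(r) pm[r, ])
    n_perm_used <- nrow(pm)
  }
  seeds <- split_seed(seed, k)
  p_values <- numeric(k)
  names(p_values) <- colnames(X)

  for (i in seq_len(k)) {
    others <- D[, -(i + 1), drop = FALSE]
    Q <- qr.Q(qr(others))
    e_x <- X[, i] - Q %*% crossprod(Q, X[, i])
    e_y <- yv - Q %*% crossprod(Q, yv)
    b_obs <- beta_all[i + 1]

    # residuals re-formed as a matrix (masked cells stay 0), then relabeled
    e_full <- numeric(n * (n - 1))
    if (is.null(keep)) {
      e_full <- as.vector(e_x)
    } else {
      e_full[keep] <- as.vector(e_x)
    }
    E <- matrix(0, n, n)
    E[cbind(idx$row, idx$col)] <- e_full

    perms <- if (is_exhaustive) {
      exh_perms
    } else {
      with_seed(seeds[[i]], replicate(n_perm_used, sample.int(n),
                                      simplify = FALSE))
    }
    XV <- vapply(perms, function(p) relabel_vector(E, p, idx, keep),
                 numeric(m))
    XT <- XV - Q %*% crossprod(Q, XV)
    ss <- colSums(XT^2)
    b_star <- ifelse(ss > 0, colSums(XT * as.vector(e_y)) / ss, 0)
    hits <- sum(abs(b_star) >= abs(b_obs) - TIE_TOL)
    p_values[i] <- if (is_exhaustive) {
      hits / n_perm_used
    } else {
      (1 + hits) / (1 + n_perm_used)
    }
  }

  structure(list(outcome_name = attr(as_dyad_matrix(y), "name") %||% "y",
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
                 n_dyads = m),
            class = "mrqap_result")
}

#' @export
print.mrqap_result <- function(x, ...) {
  cat(sprintf("MRQAP (Double-Dekker semi-partialling): %s ~ %s\n",
              x$outcome_name, paste(x$predictor_names, collapse = " + ")))
  cat(sprintf("%d dyads, R-squared %.4f, %s %d permutations, seed %s\n",
              x$n_dyads, x$r_squared,
              if (x$exhaustive) "exhaustive over" else "sampled",
              x$n_permutations,
              if (is.null(x$seed)) "none" else x$seed))
  tab <- data.frame(coef = x$coefficients,
                    std_coef = x$standardized_coefficients,
                    se_ols = x$standard_errors,
                    p = x$p_values)
  print(round(tab, 4))
  invisible(x)
}

#' Run the six dyadic hypothesis models as a batch
#'
#' Model recipes over the built networks, all controlling for the four
#' attribute similarities (age, sex, kinship, oestrous):
#' \describe{
#'   \item{h1_proximity}{proximity ~ attributes + rapid + single +
#'     persistence rates.}
#'   \item{h2_rapid, h2_persistence, h2_single}{each sequence-type rate ~
#'     attributes + the three response-type rates.}
#'   \item{h3_proximity}{proximity ~ attributes + response-absent +
#'     response-present rates.}
#'   \item{h4_proximity}{proximity ~ attributes + the three response-type
#'     rates.}
#' }
#'
#' @param networks named list from \code{\link{build_networks}}.
#' @param n_perm permutations per predictor.
#' @param seed one seed; per-model seeds are derived from it.
#' @param mask optional dyad mask applied to every model.
#' @return named list of \code{mrqap_result} objects.
#' @export
run_hypothesis_models <- function(networks, n_perm = 2000, seed = NULL,
                                  mask = NULL) {
  attrs_x <- c("age", "sex", "kin", "oestrous")
  resp_types <- c("visual_tactile_gesture", "activity_change",
                  "vocalisation")
  specs <- list(
    h1_proximity = list(y = "proximity",
                        x = c(attrs_x, "rapid", "single", "persistence")),
    h2_rapid = list(y = "rapid", x = c(attrs_x, resp_types)),
    h2_persistence = list(y = "persistence", x = c(attrs_x, resp_types)),
    h2_single = list(y = "single", x = c(attrs_x, resp_types)),
    h3_proximity = list(y = "proximity",
                        x = c(attrs_x, "absent", "present")),
    h4_proximity = list(y = "proximity", x = c(attrs_x, resp_types)))

  needed <- unique(unlist(lapply(specs, function(s) c(s$y, s$x))))
  missing_nets <- setdiff(needed, names(networks))
  if (length(missing_nets) > 0) {
    stop("missing networks: ", paste(missing_nets, collapse = ", "))
  }
  seeds <- split_seed(seed, length(specs))
  out <- vector("list", length(specs))
  names(out) <- names(specs)
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    out[[i]] <- mrqap_dsp(networks[[s$y]], networks[s$x], n_perm = n_perm,
                          seed = seeds[[i]], mask = mask)
  }
  out
}
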