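# Independent oracles used across the suite. These deliberately use
# different formulations/code paths than the package implementation.

# Segmentation oracle: union-find over all event pairs, connecting two
# events iff they share signaller/recipient/context and are within the
# window of each other. Transitive closure of the pairwise rule equals the
# consecutive-gap chain rule on sorted streams.
oracle_segment <- function(events, max_gap = 30) {
  n <- nrow(events)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j &&
          events$signaller[i] == events$signaller[j] &&
          events$recipients[i] == events$recipients[j] &&
          events$context[i] == events$context[j] &&
          abs(events$time_s[i] - events$time_s[j]) <= max_gap) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# Tally oracle: plain double loop over scans x sequences.
oracle_tally <- function(scans, sequences, labels, scan_interval = 2) {
  n <- length(labels)
  p10 <- party <- matrix(0L, n, n, dimnames = list(labels, labels))
  w10 <- lapply(strsplit(scans$within10_members, ";"),
                function(v) v[nzchar(v)])
  pm <- lapply(strsplit(scans$party_members, ";"),
               function(v) v[nzchar(v)])
  for (i in seq_len(nrow(scans))) {
    a <- match(scans$focal_id[i], labels)
    for (b in pm[[i]]) party[a, match(b, labels)] <-
        party[a, match(b, labels)] + 1L
    for (b in w10[[i]]) p10[a, match(b, labels)] <-
        p10[a, match(b, labels)] + 1L
  }
  C <- list()
  for (cl in c("single", "rapid", "persistence")) {
    C[[cl]] <- matrix(0L, n, n, dimnames = list(labels, labels))
  }
  excluded <- 0L
  for (k in seq_len(nrow(sequences))) {
    placed <- FALSE
    for (i in seq_len(nrow(scans))) {
      t0 <- scans$time_min[i] * 60
      if (scans$focal_id[i] == sequences$signaller[k] &&
          sequences$first_time_s[k] >= t0 &&
          sequences$first_time_s[k] < t0 + scan_interval * 60) {
        if (sequences$recipient[k] %in% w10[[i]]) {
          a <- match(sequences$signaller[k], labels)
          b <- match(sequences$recipient[k], labels)
          cl <- sequences$cls[k]
          C[[cl]][a, b] <- C[[cl]][a, b] + 1L
          placed <- TRUE
        }
        break
      }
    }
    if (!placed) excluded <- excluded + 1L
  }
  list(p10 = p10, party = party, C = C, excluded = excluded)
}

# Brute-force QAP correlation over every relabeling, via direct matrix
# permutation and cor() on the off-diagonal entries.
oracle_qap_cor <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  n <- nrow(x)
  offv <- function(m) m[row(m) != col(m)]
  r_obs <- cor(offv(x), offv(y))
  perms <- oracle_all_perms(n)
  hits <- 0L
  for (p in perms) {
    if (abs(cor(offv(x[p, p]), offv(y))) >= abs(r_obs)) hits <- hits + 1L
  }
  list(r = r_obs, p = hits / length(perms))
}

oracle_all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in oracle_all_perms(n - 1)) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

# Brute-force Double-Dekker semi-partialling MRQAP over every relabeling:
# residualize predictor i on the others with lm(), permute the residual
# matrix, substitute, refit with lm(), compare coefficients.
oracle_mrqap_dsp <- function(y, xs) {
  y <- as.matrix(y)
  xs <- lapply(xs, as.matrix)
  n <- nrow(y)
  offv <- function(m) m[row(m) != col(m)]
  tomat <- function(v) {
    m <- matrix(0, n, n)
    m[row(m) != col(m)] <- v
    m
  }
  yv <- offv(y)
  X <- sapply(xs, offv)
  fit <- lm(yv ~ X)
  beta <- coef(fit)[-1]
  perms <- oracle_all_perms(n)
  p_out <- numeric(ncol(X))
  for (i in seq_len(ncol(X))) {
    others <- X[, -i, drop = FALSE]
    e_i <- if (ncol(others) > 0) {
      resid(lm(X[, i] ~ others))
    } else {
      resid(lm(X[, i] ~ 1))
    }
    E <- tomat(e_i)
    hits <- 0L
    for (p in perms) {
      Xp <- X
      Xp[, i] <- offv(E[p, p])
      b_star <- coef(lm(yv ~ Xp))[1 + i]
      if (abs(b_star) >= abs(beta[i]) - 1e-10) hits <- hits + 1L
    }
    p_out[i] <- hits / length(perms)
  }
  list(beta = beta, p = p_out)
}

# Brute-force node permutation regression over every permutation of y.
oracle_node_reg <- function(y, X) {
  X <- as.matrix(X)
  fit <- lm(y ~ X)
  beta <- coef(fit)[-1]
  perms <- oracle_all_perms(length(y))
  hits <- integer(length(beta))
  for (p in perms) {
    b_star <- coef(lm(y[p] ~ X))[-1]
    hits <- hits + (abs(b_star) >= abs(beta) - 1e-10)
  }
  list(beta = beta, p = hits / length(perms))
}

# Random labeled square matrix with zero diagonal.
random_dyad_matrix <- function(n, labels = sprintf("N%02d", seq_len(n)),
                               name = "rand") {
  m <- matrix(rnorm(n * n), n, n, dimnames = list(labels, labels))
  diag(m) <- 0
  dyad_matrix(m, name = name)
}

# Outcome with row/column random effects: the autocorrelated null that
# motivates semi-partialling.
autocorrelated_outcome <- function(n, labels = sprintf("N%02d", seq_len(n)),
                                   sd_row = 1, sd_col = 1, sd_noise = 1) {
  a <- rnorm(n, sd = sd_row)
  b <- rnorm(n, sd = sd_col)
  m <- outer(a, rep(1, n)) + outer(rep(1, n), b) +
    matrix(rnorm(n * n, sd = sd_noise), n, n)
  dimnames(m) <- list(labels, labels)
  diag(m) <- 0
  dyad_matrix(m, name = "autocorr_y")
}

# tiny empty sequence table with the columns tally_dyads needs
empty_seq_table <- function() {
  data.frame(signaller = character(0), recipient = character(0),
             cls = character(0), first_time_s = numeric(0),
             response_present = logical(0),
             response_category = character(0), stringsAsFactors = FALSE)
}

packaged_attrs <- function() {
  read_attributes(system.file("extdata", "sonso_attributes.csv",
                              package = "gestnet"))
}
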