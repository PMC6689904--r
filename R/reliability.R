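# Inter-coder agreement: unweighted Cohen's kappa on nominal codes, and the
# per-response-type report in which each category is binarized to
# present/absent and kappa is computed independently per category.

#' Cohen's kappa for two coders
#'
#' Chance-corrected agreement kappa = (p_o - p_e) / (1 - p_e), where p_o is
#' the observed agreement and p_e the chance agreement from the marginal
#' products. Unweighted: categories are nominal. If both coders are
#' perfectly predictable from the margins (p_e = 1, i.e. each coder uses a
#' single category), kappa is defined as 1 when they agree completely and is
#' an error otherwise.
#'
#' @param pairs either a data.frame with columns coder1 and coder2, or a
#'   vector of first-coder codes (then \code{coder2} must be given).
#' @param coder2 second coder's codes when \code{pairs} is a vector.
#' @param categories optional explicit category set; defaults to the union
#'   of observed codes. Codes outside the set are an error.
#' @return kappa, a number in [-1, 1].
#' @export
cohens_kappa <- function(pairs, coder2 = NULL, categories = NULL) {
  if (is.data.frame(pairs)) {
    if (!all(c("coder1", "coder2") %in% names(pairs))) {
      stop("pairs data.frame needs coder1 and coder2 columns")
    }
    c1 <- as.character(pairs$coder1)
    c2 <- as.character(pairs$coder2)
  } else {
    if (is.null(coder2)) {
      stop("supply coder2 when pairs is a vector")
    }
    c1 <- as.character(pairs)
    c2 <- as.character(coder2)
  }
  if (length(c1) != length(c2)) {
    stop("coders must rate the same items")
  }
  if (length(c1) == 0) {
    stop("no coding pairs supplied")
  }
  if (is.null(categories)) {
    categories <- sort(unique(c(c1, c2)))
  } else {
    bad <- setdiff(unique(c(c1, c2)), categories)
    if (length(bad) > 0) {
      stop("codes outside the declared category set: ",
           paste(bad, collapse = ", "))
    }
  }
  f1 <- factor(c1, levels = categories)
  f2 <- factor(c2, levels = categories)
  tab <- table(f1, f2)
  nn <- sum(tab)
  p_o <- sum(diag(tab)) / nn
  p_e <- sum(rowSums(tab) * colSums(tab)) / nn^2
  if (1 - p_e < 1e-12) {
    if (p_o >= 1 - 1e-12) {
      return(1)
    }
    stop("degenerate marginals: chance agreement is 1 but coders disagree")
  }
  (p_o - p_e) / (1 - p_e)
}

#' Per-category kappa report from presence/absence binarization
#'
#' For each response category, both coders' codes are binarized to "did this
#' item get that category?" and kappa is computed on the binary codes, so
#' every category gets its own chance-corrected agreement, mirroring
#' per-response-type reliability reporting. A category on which the
#' binarized margins are degenerate (a coder never, or always, used it) is
#' flagged and its kappa is the degenerate-rule value (1 on full agreement,
#' NA otherwise).
#'
#' @param pairs data.frame with columns coder1 and coder2.
#' @param categories categories to report; defaults to all observed codes.
#' @return data.frame with columns category, kappa, n, degenerate.
#' @export
kappa_report <- function(pairs, categories = NULL) {
  if (!all(c("coder1", "coder2") %in% names(pairs))) {
    stop("pairs data.frame needs coder1 and coder2 columns")
  }
  if (nrow(pairs) == 0) {
    stop("no coding pairs supplied")
  }
  c1 <- as.character(pairs$coder1)
  c2 <- as.character(pairs$coder2)
  if (is.null(categories)) {
    categories <- sort(unique(c(c1, c2)))
  }
  rows <- lapply(categories, function(cat) {
    b1 <- ifelse(c1 == cat, "present", "absent")
    b2 <- ifelse(c2 == cat, "present", "absent")
    degenerate <- length(unique(b1)) == 1 || length(unique(b2)) == 1
    kap <- tryCatch(cohens_kappa(b1, b2,
                                 categories = c("absent", "present")),
                    error = function(e) NA_real_)
    data.frame(category = cat, kappa = kap, n = length(b1),
               degenerate = degenerate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
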