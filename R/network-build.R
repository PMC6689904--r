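# Construction of the dyadic matrices the regressions consume: integer
# tallies from scan samples and coded sequences, communication rates per
# hour of co-proximity, proximity per party-hour, and binary attribute
# similarity matrices.

#' Tally scan co-occurrence and communication counts per directed dyad
#'
#' For each ordered dyad (A, B): \code{party} counts scans of focal A with B
#' in A's party, \code{p10} counts scans with B within 10 m of A, and the
#' communication counts record sequences A directed to B, split by sequence
#' class and by response annotation. A sequence is attributed to the scan
#' interval containing its first gesture (the scan of its signaller whose
#' interval covers that time). Sequences whose recipient was not within 10 m
#' at that scan, or that fall outside any scan of their signaller, are
#' excluded from the communication counts but tallied in
#' \code{excluded_sequences}.
#'
#' @param scans data.frame of focal scans (follow_id, focal_id, scan_index,
#'   time_min, party_members, within10_members).
#' @param sequences data.frame of coded sequences from
#'   \code{\link{segment_sequences}}.
#' @param labels node labels; defaults to the sorted union of ids seen in
#'   the scans. Sequences referencing ids outside this set are an error.
#' @param scan_interval minutes represented by one scan (default 2).
#' @return list of class \code{dyad_tallies}: labels, scan_interval, matrices
#'   \code{party} and \code{p10}, a list \code{comm} of count matrices (one
#'   per sequence class and per response grouping: present, absent,
#'   activity_change, vocalisation, visual_tactile_gesture), and
#'   \code{excluded_sequences}.
#' @export
tally_dyads <- function(scans, sequences, labels = NULL, scan_interval = 2) {
  party_list <- split_members(scans$party_members)
  w10_list <- split_members(scans$within10_members)
  if (is.null(labels)) {
    labels <- sort(unique(c(scans$focal_id,
                            unlist(party_list, use.names = FALSE))))
  }
  n <- length(labels)
  zero <- matrix(0L, n, n, dimnames = list(labels, labels))

  unknown <- setdiff(unique(c(scans$focal_id,
                              unlist(party_list, use.names = FALSE),
                              unlist(w10_list, use.names = FALSE))),
                     labels)
  if (length(unknown) > 0) {
    stop("scans reference unknown ids: ", paste(unknown, collapse = ", "))
  }

  party <- zero
  p10 <- zero
  foc <- match(scans$focal_id, labels)
  for (i in seq_len(nrow(scans))) {
    pm <- match(party_list[[i]], labels)
    if (length(pm) > 0) {
      party[foc[i], pm] <- party[foc[i], pm] + 1L
    }
    wm <- match(w10_list[[i]], labels)
    if (length(wm) > 0) {
      p10[foc[i], wm] <- p10[foc[i], wm] + 1L
    }
  }

  comm_groups <- c(sequence_classes(), "present", "absent",
                   response_categories())
  comm <- stats::setNames(replicate(length(comm_groups), zero,
                                    simplify = FALSE), comm_groups)
  excluded <- 0L

  if (nrow(sequences) > 0) {
    bad <- setdiff(unique(c(sequences$signaller, sequences$recipient)),
                   labels)
    if (length(bad) > 0) {
      stop("sequences reference unknown ids: ",
           paste(bad, collapse = ", "))
    }
    scan_start <- scans$time_min * 60
    scan_end <- scan_start + scan_interval * 60
    for (k in seq_len(nrow(sequences))) {
      sg <- sequences$signaller[k]
      rc <- sequences$recipient[k]
      t1 <- sequences$first_time_s[k]
      hit <- which(scans$focal_id == sg & scan_start <= t1 & t1 < scan_end)
      ok <- FALSE
      if (length(hit) >= 1) {
        hit <- hit[1]
        ok <- rc %in% w10_list[[hit]]
      }
      if (!ok) {
        excluded <- excluded + 1L
        next
      }
      a <- match(sg, labels)
      b <- match(rc, labels)
      cls <- sequences$cls[k]
      comm[[cls]][a, b] <- comm[[cls]][a, b] + 1L
      if (isTRUE(sequences$response_present[k])) {
        comm[["present"]][a, b] <- comm[["present"]][a, b] + 1L
        cat_k <- sequences$response_category[k]
        if (cat_k %in% response_categories()) {
          comm[[cat_k]][a, b] <- comm[[cat_k]][a, b] + 1L
        }
      } else {
        comm[["absent"]][a, b] <- comm[["absent"]][a, b] + 1L
      }
    }
  }

  structure(list(labels = labels, scan_interval = scan_interval,
                 party = party, p10 = p10, comm = comm,
                 excluded_sequences = excluded),
            class = "dyad_tallies")
}

#' Communication rate per hour of co-proximity
#'
#' Converts counts to the dyadic communication rate: events A directed to B
#' per hour A and B spent within 10 m, where each scan stands for one
#' \code{scan_interval}-minute exposure window. With counts C and scan
#' tallies P10, the rate is (C x 60) / (P10 x interval). Dyads with zero
#' proximity exposure get rate 0 and are flagged in the "zero_exposure"
#' attribute.
#'
#' @param tallies a \code{\link{tally_dyads}} result.
#' @param what which count matrix to convert: a sequence class ("single",
#'   "rapid", "persistence") or a response grouping ("present", "absent",
#'   "activity_change", "vocalisation", "visual_tactile_gesture").
#' @return a directed \code{\link{dyad_matrix}} of rates per hour, with a
#'   logical "zero_exposure" attribute marking unobserved dyads.
#' @export
communication_rate <- function(tallies, what) {
  stopifnot(inherits(tallies, "dyad_tallies"))
  what <- match.arg(what, names(tallies$comm))
  C <- tallies$comm[[what]]
  P10 <- tallies$p10
  denom <- P10 * tallies$scan_interval # minutes of co-proximity
  rate <- matrix(0, nrow(C), ncol(C), dimnames = dimnames(C))
  pos <- denom > 0
  rate[pos] <- (C[pos] * 60) / denom[pos]
  out <- dyad_matrix(rate, name = what, directed = TRUE)
  flag <- !pos
  diag(flag) <- FALSE
  attr(out, "zero_exposure") <- flag
  out
}

#' Proximity time per hour spent in the same party
#'
#' Minutes per party-hour that B was within 10 m of focal A: with P10 and
#' party scan counts, 60 x P10 / party, which always lies in [0, 60].
#' Dyads never seen in the same party get 0 and are flagged in the
#' "zero_exposure" attribute.
#'
#' @param tallies a \code{\link{tally_dyads}} result.
#' @return a directed \code{\link{dyad_matrix}} named "proximity".
#' @export
proximity_rate <- function(tallies) {
  stopifnot(inherits(tallies, "dyad_tallies"))
  P10 <- tallies$p10
  party <- tallies$party
  if (any(P10 > party)) {
    stop("inconsistent tallies: within-10 m count exceeds party count")
  }
  prox <- matrix(0, nrow(P10), ncol(P10), dimnames = dimnames(P10))
  pos <- party > 0
  prox[pos] <- 60 * P10[pos] / party[pos]
  out <- dyad_matrix(prox, name = "proximity", directed = TRUE)
  flag <- !pos
  diag(flag) <- FALSE
  attr(out, "zero_exposure") <- flag
  out
}

#' Binary attribute similarity matrices
#'
#' Symmetric 0/1 matrices over ordered dyads, with zero diagonal:
#' \describe{
#'   \item{sex}{1 iff same sex.}
#'   \item{age}{1 iff absolute age difference is 5 years or less.}
#'   \item{oestrous}{1 iff one member is male and the other a cycling
#'     female (the reproductively active pairing).}
#'   \item{kin}{1 iff a mother-offspring link connects the pair (maternal
#'     kinship from the mother_id column).}
#' }
#'
#' @param attrs attribute table (id, sex, age, reproductive_status,
#'   mother_id).
#' @param kind one of "sex", "age", "oestrous", "kin".
#' @return an undirected binary \code{\link{dyad_matrix}}.
#' @export
similarity_matrix <- function(attrs, kind = c("sex", "age", "oestrous",
                                              "kin")) {
  kind <- match.arg(kind)
  n <- nrow(attrs)
  ids <- attrs$id
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  if (kind == "sex") {
    m[] <- outer(attrs$sex, attrs$sex, "==") * 1
  } else if (kind == "age") {
    if (!("age" %in% names(attrs)) || any(is.na(attrs$age))) {
      stop("age similarity requires a complete age column")
    }
    m[] <- (abs(outer(attrs$age, attrs$age, "-")) <= 5) * 1
  } else if (kind == "oestrous") {
    cyc_f <- attrs$sex == "female" & attrs$reproductive_status == "cycling"
    male <- attrs$sex == "male"
    m[] <- (outer(male, cyc_f, "&") | outer(cyc_f, male, "&")) * 1
  } else {
    if (!("mother_id" %in% names(attrs))) {
      stop("kin similarity requires a mother_id column")
    }
    mom <- match(attrs$mother_id, ids)
    for (i in seq_len(n)) {
      if (!is.na(mom[i])) {
        m[i, mom[i]] <- 1
        m[mom[i], i] <- 1
      }
    }
  }
  diag(m) <- 0
  dyad_matrix(m, name = paste0(kind, "_similarity"), directed = FALSE)
}

#' Build every matrix the hypothesis models need
#'
#' Convenience wrapper: tallies the scans and sequences, then assembles the
#' proximity matrix, the three sequence-type rate matrices, the five
#' response-grouping rate matrices, and the four attribute similarity
#' matrices, all sharing the node labels of \code{attrs}.
#'
#' @param attrs attribute table.
#' @param scans focal scan table.
#' @param sequences coded sequence table.
#' @param scan_interval minutes per scan.
#' @param drop_zero_exposure if TRUE, a combined mask of dyads with no
#'   proximity exposure is attached (as attribute "mask") for listwise
#'   deletion in the models; by default zero-exposure dyads keep rate 0.
#' @return named list of \code{\link{dyad_matrix}} objects (proximity,
#'   single, rapid, persistence, present, absent, activity_change,
#'   vocalisation, visual_tactile_gesture, age, sex, oestrous, kin) plus the
#'   tallies under "tallies".
#' @export
build_networks <- function(attrs, scans, sequences, scan_interval = 2,
                           drop_zero_exposure = FALSE) {
  tallies <- tally_dyads(scans, sequences, labels = attrs$id,
                         scan_interval = scan_interval)
  nets <- list(proximity = proximity_rate(tallies))
  for (w in names(tallies$comm)) {
    nets[[w]] <- communication_rate(tallies, w)
  }
  nets$age <- similarity_matrix(attrs, "age")
  nets$sex <- similarity_matrix(attrs, "sex")
  nets$oestrous <- similarity_matrix(attrs, "oestrous")
  nets$kin <- similarity_matrix(attrs, "kin")
  if (drop_zero_exposure) {
    mask <- attr(nets$proximity, "zero_exposure") |
      attr(nets$single, "zero_exposure")
    attr(nets, "mask") <- mask
  }
  nets$tallies <- tallies
  nets
}
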