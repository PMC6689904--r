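# Synthetic fission-fusion study generator.
#
# Produces the three raw inputs the pipeline consumes -- an attribute table,
# scan-sampled focal follows, and a time-stamped gesture event log -- with a
# known dyad-level latent sociality that modulates both proximity and the
# persistence-sequence initiation rate. Everything downstream (sequence
# coding, network construction, permutation inference) can therefore be
# validated against planted structure.

# Stage-specific child seeds so each generator op is individually
# deterministic under the config seed.
stage_seed <- function(cfg, stage) {
  stages <- c("population", "sociality", "follows", "events")
  split_seed(cfg$seed, length(stages))[[match(stage, stages)]]
}

#' Generate (or load) the focal-individual attribute table
#'
#' With \code{use_packaged_attributes = TRUE} in the config, returns the packaged
#' Sonso community table of 12 adults (6 males, 6 females with printed ages
#' and reproductive statuses). Otherwise samples a cohort with the requested
#' composition: \code{n_males} males (reproductive status not applicable),
#' \code{n_cycling_females} cycling females, remaining females alternately
#' pregnant/nursing, ages uniform on \code{age_range}, and
#' \code{n_kin_pairs} planted mother-son links.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @return data.frame with columns id, sex, age, reproductive_status,
#'   mother_id.
#' @export
generate_population <- function(config) {
  validate_synthetic_config(config)
  if (config$use_packaged_attributes) {
    return(read_attributes(system.file("extdata", "sonso_attributes.csv",
                                       package = "gestnet",
                                       mustWork = TRUE)))
  }
  n <- config$n_individuals
  with_seed(stage_seed(config, "population"), {
    ids <- sprintf("N%02d", seq_len(n))
    sex <- c(rep("male", config$n_males),
             rep("female", n - config$n_males))
    status <- rep("not_applicable", n)
    females <- which(sex == "female")
    if (length(females) > 0) {
      cyc <- females[seq_len(config$n_cycling_females)]
      status[cyc] <- "cycling"
      rest <- setdiff(females, cyc)
      status[rest] <- rep(c("pregnant", "nursing"),
                          length.out = length(rest))
    }
    ages <- sample(seq(config$age_range[1], config$age_range[2]), n,
                   replace = TRUE)
    mother <- rep(NA_character_, n)
    n_kin <- min(config$n_kin_pairs, config$n_males, length(females))
    if (n_kin > 0) {
      sons <- which(sex == "male")[seq_len(n_kin)]
      # prefer mothers old enough to be plausible (>= 12 y older)
      for (k in seq_len(n_kin)) {
        cand <- females[ages[females] >= ages[sons[k]] + 12 &
                          !(ids[females] %in% mother)]
        if (length(cand) == 0) {
          cand <- females[!(ids[females] %in% mother)]
        }
        if (length(cand) > 0) {
          mother[sons[k]] <- ids[cand[1]]
        }
      }
    }
    data.frame(id = ids, sex = sex, age = as.numeric(ages),
               reproductive_status = status, mother_id = mother,
               stringsAsFactors = FALSE)
  })
}

#' Draw the latent dyad-level sociality matrix
#'
#' Sociality is modeled as i.i.d. log-normal per unordered dyad and
#' symmetrized: a positive, right-skewed quantity, like observed proximity
#' durations. It is the single hidden variable coupling proximity and
#' persistence-sequence rates in the generator.
#'
#' @param attrs attribute table from \code{\link{generate_population}}.
#' @param config a \code{\link{synthetic_config}}.
#' @return symmetric \code{\link{dyad_matrix}} named "sociality" with zero
#'   diagonal.
#' @export
generate_sociality <- function(attrs, config) {
  validate_synthetic_config(config)
  stopifnot(nrow(attrs) >= 1)
  n <- nrow(attrs)
  m <- matrix(0, n, n, dimnames = list(attrs$id, attrs$id))
  if (n > 1) {
    with_seed(stage_seed(config, "sociality"), {
      ut <- upper.tri(m)
      m[ut] <- stats::rlnorm(sum(ut), config$sociality_meanlog,
                             config$sociality_sdlog)
      m[lower.tri(m)] <- t(m)[lower.tri(m)]
    })
  }
  dyad_matrix(m, name = "sociality", directed = FALSE)
}

# Standardized log-sociality: the unitless scale on which the party,
# proximity and persistence-rate effects act. sdlog = 0 degenerates to 0.
sociality_z <- function(sociality, config) {
  s <- as.matrix(sociality)
  z <- matrix(0, nrow(s), ncol(s), dimnames = dimnames(s))
  if (config$sociality_sdlog > 0) {
    off <- s > 0
    z[off] <- (log(s[off]) - config$sociality_meanlog) /
      config$sociality_sdlog
  }
  diag(z) <- 0
  z
}

logit_prob <- function(base, slope, z) {
  eta <- stats::qlogis(base)
  if (is.finite(eta)) {
    eta <- eta + slope * z
  } else {
    eta <- rep(eta, length(z))
  }
  stats::plogis(eta)
}

#' Simulate scan-sampled focal follows
#'
#' Each focal individual is followed \code{n_follows_per_focal} times; a
#' follow is \code{scans_per_follow} instantaneous scans at
#' \code{scan_interval}-minute spacing recording party membership and
#' within-10 m membership. A non-focal joins the focal's party with
#' probability increasing in dyadic sociality, and is within 10 m only if in
#' the party, again with probability increasing in sociality. Follows are
#' laid out on a global clock with 30-min gaps so events from different
#' follows can never be confused as one sequence.
#'
#' @param attrs attribute table.
#' @param sociality latent sociality matrix matching \code{attrs}.
#' @param config a \code{\link{synthetic_config}}.
#' @return data.frame with columns follow_id, focal_id, scan_index, time_min
#'   (absolute minutes), party_members and within10_members
#'   (semicolon-joined id lists).
#' @export
simulate_focal_follows <- function(attrs, sociality, config) {
  validate_synthetic_config(config)
  ids <- attrs$id
  stopifnot(identical(rownames(as.matrix(sociality)), ids))
  n <- length(ids)
  z <- sociality_z(sociality, config)

  effort <- config$effort_multiplier %||% 1
  n_follows <- pmax(0L, as.integer(round(
    config$n_follows_per_focal * rep_len(effort, n))))

  focal_per_follow <- rep(ids, n_follows)
  total_follows <- length(focal_per_follow)
  follow_len <- config$scans_per_follow * config$scan_interval
  follow_start <- (seq_len(total_follows) - 1) * (follow_len + 30)

  scans <- data.frame(
    follow_id = rep(sprintf("F%04d", seq_len(total_follows)),
                    each = config$scans_per_follow),
    focal_id = rep(focal_per_follow, each = config$scans_per_follow),
    scan_index = rep(seq_len(config$scans_per_follow), total_follows),
    stringsAsFactors = FALSE)
  scans$time_min <- rep(follow_start, each = config$scans_per_follow) +
    (scans$scan_index - 1) * config$scan_interval

  n_scans <- nrow(scans)
  scans$party_members <- character(n_scans)
  scans$within10_members <- character(n_scans)
  if (n > 1 && n_scans > 0) {
    with_seed(stage_seed(config, "follows"), {
      rowid <- rep(seq_len(n_scans), each = n - 1)
      focal_idx <- match(scans$focal_id, ids)[rowid]
      other_idx <- unlist(lapply(match(scans$focal_id, ids),
                                 function(i) seq_len(n)[-i]),
                          use.names = FALSE)
      zv <- z[cbind(focal_idx, other_idx)]
      p_party <- logit_prob(config$party_base_prob, config$party_slope, zv)
      p_prox <- logit_prob(config$prox_base_prob, config$proximity_slope, zv)
      in_party <- stats::runif(length(zv)) < p_party
      within10 <- in_party & (stats::runif(length(zv)) < p_prox)

      fill_members <- function(sel) {
        out <- rep("", n_scans)
        grp <- split(ids[other_idx[sel]], rowid[sel])
        out[as.integer(names(grp))] <- vapply(grp, paste, character(1),
                                              collapse = ";")
        out
      }
      scans$party_members <- fill_members(in_party)
      scans$within10_members <- fill_members(within10)
    })
  }
  scans
}

gesture_pool <- function() {
  data.frame(
    gesture_label = c("arm_raise", "reach", "beckon", "head_nod",
                      "touch", "embrace", "poke", "tap_other",
                      "slap_ground", "object_shake", "clap"),
    modality = c("visual", "visual", "visual", "visual",
                 "tactile", "tactile", "tactile", "tactile",
                 "auditory", "auditory", "auditory"),
    stringsAsFactors = FALSE)
}

context_pool <- function() c("grooming", "travel", "feeding", "resting")

# Timing signature of one planted sequence: gap ranges stay well inside each
# class's defining region (rapid < 1 s, persistence response-waiting 1-5 s)
# so that re-coding by the timing rules recovers the class exactly.
planted_gaps <- function(cls, n_gestures) {
  if (n_gestures < 2) {
    return(numeric(0))
  }
  if (cls == "rapid") {
    stats::runif(n_gestures - 1, 0.1, 0.8)
  } else {
    stats::runif(n_gestures - 1, 1.5, 4.5)
  }
}

#' Simulate the gesture event log over simulated follows
#'
#' For every 2-min scan interval and every individual within 10 m of the
#' focal, sequence initiations are drawn per class from a Poisson law with
#' the configured per-proximity-hour intercepts; the persistence rate is
#' multiplied by exp(effect x standardized log sociality). Each initiated
#' sequence is laid down with gaps inside its class's defining region
#' (rapid < 1 s, persistence 1.5-4.5 s) and sequences of the same dyad are
#' separated by at least 40 s so the timing rules recover the planted class
#' exactly. Each sequence carries a response annotation drawn from the
#' class-conditional category probabilities. Sequences that cannot be placed
#' inside their 2-min interval with full separation (possible only at
#' improbably high per-interval counts) are dropped and counted in the
#' "dropped_sequences" attribute.
#'
#' @param scans output of \code{\link{simulate_focal_follows}}.
#' @param sociality latent sociality matrix.
#' @param config a \code{\link{synthetic_config}}.
#' @return data.frame of gesture events (event_id, time_s, signaller,
#'   recipients, gesture_label, modality, context, sequence_hint,
#'   response_present, response_category), sorted by time.
#' @export
simulate_gesture_events <- function(scans, sociality, config) {
  validate_synthetic_config(config)
  stopifnot(nrow(scans) >= 1)
  ids <- rownames(as.matrix(sociality))
  z <- sociality_z(sociality, config)
  interval_s <- config$scan_interval * 60
  classes <- sequence_classes()
  rates <- config$rate_intercepts[classes]
  pool <- gesture_pool()
  rp <- config$response_category_probs

  generate <- function() {
    w10 <- split_members(scans$within10_members)
    n_w10 <- lengths(w10)
    cell_scan <- rep(seq_len(nrow(scans)), n_w10)
    cell_recipient <- unlist(w10, use.names = FALSE)
    if (length(cell_scan) == 0) {
      return(empty_events())
    }
    cell_signaller <- scans$focal_id[cell_scan]
    zv <- z[cbind(match(cell_signaller, ids), match(cell_recipient, ids))]

    # per-interval Poisson means, persistence modulated by sociality
    per_interval <- config$scan_interval / 60
    counts <- sapply(classes, function(cl) {
      lam <- rates[[cl]] * per_interval
      if (cl == "persistence") {
        lam <- lam * exp(config$persistence_sociality_effect * zv)
      }
      stats::rpois(length(zv), lam)
    })
    counts <- matrix(counts, ncol = length(classes),
                     dimnames = list(NULL, classes))

    keep <- rowSums(counts) > 0
    if (!any(keep)) {
      return(empty_events())
    }
    cell_scan <- cell_scan[keep]
    cell_recipient <- cell_recipient[keep]
    cell_signaller <- cell_signaller[keep]
    counts <- counts[keep, , drop = FALSE]

    # process intervals in time order, tracking the last event time of every
    # directed dyad so consecutive sequences never fall inside one 30-s
    # segmentation window
    ord <- order(scans$time_min[cell_scan], cell_signaller, cell_recipient)
    last_end <- new.env(parent = emptyenv())
    dropped <- 0L
    recs <- vector("list", length(ord))
    seq_counter <- 0L
    for (ii in seq_along(ord)) {
      i <- ord[ii]
      t0 <- scans$time_min[cell_scan[i]] * 60
      key <- paste0(cell_signaller[i], ">", cell_recipient[i])
      prev <- if (!is.null(last_end[[key]])) last_end[[key]] else -Inf
      cls_here <- rep(classes, counts[i, ])
      if (length(cls_here) > 1) {
        cls_here <- sample(cls_here)
      }
      cursor <- max(t0 + stats::runif(1, 0, 3),
                    prev + 40 + stats::runif(1, 0, 5))
      out_rows <- vector("list", length(cls_here))
      for (j in seq_along(cls_here)) {
        cls <- cls_here[j]
        if (cursor > t0 + interval_s - 2) {
          dropped <- dropped + 1L
          next
        }
        n_g <- if (cls == "single") 1L else min(2L + stats::rpois(1, 0.7), 4L)
        gaps <- planted_gaps(cls, n_g)
        times <- cursor + cumsum(c(0, gaps))
        g_idx <- sample.int(nrow(pool), n_g, replace = TRUE)
        resp <- sample(colnames(rp), 1, prob = rp[cls, ])
        seq_counter <- seq_counter + 1L
        recipients <- cell_recipient[i]
        if (config$multi_recipient && stats::runif(1) < 0.1) {
          members <- w10[[cell_scan[i]]]
          recipients <- paste(members, collapse = ";")
        }
        out_rows[[j]] <- data.frame(
          time_s = times,
          signaller = cell_signaller[i],
          recipients = recipients,
          gesture_label = pool$gesture_label[g_idx],
          modality = pool$modality[g_idx],
          context = sample(context_pool(), 1),
          sequence_hint = sprintf("S%05d_%s", seq_counter, cls),
          response_present = resp != "absent",
          response_category = if (resp == "absent") "" else resp,
          stringsAsFactors = FALSE)
        last_end[[key]] <- max(times)
        cursor <- max(times) + 40 + stats::runif(1, 0, 5)
      }
      recs[[ii]] <- do.call(rbind, out_rows)
    }
    events <- do.call(rbind, recs)
    if (is.null(events) || nrow(events) == 0) {
      return(empty_events())
    }
    events <- events[order(events$time_s, events$signaller,
                           events$recipients), , drop = FALSE]
    events <- cbind(event_id = sprintf("E%06d", seq_len(nrow(events))),
                    events, stringsAsFactors = FALSE)
    rownames(events) <- NULL
    attr(events, "dropped_sequences") <- dropped
    events
  }
  with_seed(stage_seed(config, "events"), generate())
}

empty_events <- function() {
  out <- data.frame(event_id = character(0), time_s = numeric(0),
                    signaller = character(0), recipients = character(0),
                    gesture_label = character(0), modality = character(0),
                    context = character(0), sequence_hint = character(0),
                    response_present = logical(0),
                    response_category = character(0),
                    stringsAsFactors = FALSE)
  attr(out, "dropped_sequences") <- 0L
  out
}

#' Run the whole generator: attributes, sociality, follows, events
#'
#' @param config a \code{\link{synthetic_config}}.
#' @return list with elements attrs, sociality, scans, events, config.
#' @export
simulate_gesture_study <- function(config) {
  attrs <- generate_population(config)
  sociality <- generate_sociality(attrs, config)
  scans <- simulate_focal_follows(attrs, sociality, config)
  events <- simulate_gesture_events(scans, sociality, config)
  list(attrs = attrs, sociality = sociality, scans = scans,
       events = events, config = config)
}
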