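# Sequence coding: segment a time-stamped gesture event log into sequences
# (same signaller, same recipient, same context, consecutive gestures no more
# than 30 s apart) and classify each as a single gesture, a rapid sequence
# (no response-waiting pause, all gaps < 1 s) or a persistence sequence
# (at least one response-waiting pause of >= 1 s).

#' Classify a gesture sequence from its inter-gesture gaps
#'
#' Timing rules: one gesture is a "single"; two or more gestures with every
#' gap below \code{response_wait_min} form a "rapid" sequence (no pause long
#' enough for response waiting); two or more gestures with at least one gap
#' of \code{response_wait_min} or longer form a "persistence" sequence (the
#' signaller waited for a response before gesturing again). The boundary is
#' inclusive: a gap of exactly 1 s counts as response waiting. Gaps between
#' \code{response_wait_max} and the 30-s segmentation window are treated as
#' persistence by default; see \code{strict_wait_window} in
#' \code{\link{segment_sequences}} for the alternative reading.
#'
#' @param gaps numeric vector of inter-gesture gaps in seconds (length
#'   n_gestures - 1; empty for a lone gesture).
#' @param response_wait_min,response_wait_max bounds of the response-waiting
#'   window in seconds.
#' @return one of "single", "rapid", "persistence".
#' @export
classify_sequence <- function(gaps, response_wait_min = 1,
                              response_wait_max = 5) {
  gaps <- as.numeric(gaps)
  if (any(!is.finite(gaps)) || any(gaps < 0)) {
    stop("gaps must be finite nonnegative seconds")
  }
  if (length(gaps) == 0) {
    return("single")
  }
  if (any(gaps >= response_wait_min)) "persistence" else "rapid"
}

#' Segment a gesture event log into sequences
#'
#' Events are sorted by time and partitioned: a new sequence starts whenever
#' the signaller, the recipient, or the context changes, or the gap to the
#' previous gesture of the same signaller/recipient/context stream exceeds
#' 30 s (inclusive window: a gap of exactly 30 s still belongs to the same
#' sequence). Multi-recipient events (semicolon-joined recipient lists) are
#' expanded to one event per recipient first, so each directed dyad gets its
#' own stream. Each resulting sequence is classified by
#' \code{\link{classify_sequence}} and carries the response annotation of its
#' first event.
#'
#' @param events data.frame with at least time_s, signaller, recipients,
#'   context; optionally event_id, response_present, response_category.
#' @param max_gap sequence window in seconds (default 30).
#' @param strict_wait_window if TRUE, gaps above \code{response_wait_max}
#'   also split sequences, so persistence pauses are confined to the
#'   1-5 s response-waiting window.
#' @param response_wait_min,response_wait_max passed to
#'   \code{\link{classify_sequence}}.
#' @return data.frame of sequences: sequence_id, signaller, recipient,
#'   context, cls, n_gestures, first_time_s, last_time_s, gaps (list column),
#'   event_ids (list column), response_present, response_category.
#' @export
segment_sequences <- function(events, max_gap = 30,
                              strict_wait_window = FALSE,
                              response_wait_min = 1,
                              response_wait_max = 5) {
  required <- c("time_s", "signaller", "recipients", "context")
  missing_cols <- setdiff(required, names(events))
  if (length(missing_cols) > 0) {
    stop("events is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(events) == 0) {
    return(empty_sequences())
  }
  if (!("event_id" %in% names(events))) {
    events$event_id <- sprintf("E%06d", seq_len(nrow(events)))
  }
  if (!("response_present" %in% names(events))) {
    events$response_present <- NA
  }
  if (!("response_category" %in% names(events))) {
    events$response_category <- NA_character_
  }

  # expand multi-recipient events to one per recipient
  rec_list <- split_members(events$recipients)
  if (any(lengths(rec_list) == 0)) {
    stop("every event must have at least one recipient")
  }
  idx <- rep(seq_len(nrow(events)), lengths(rec_list))
  ev <- events[idx, , drop = FALSE]
  ev$recipient <- unlist(rec_list, use.names = FALSE)
  if (any(ev$recipient == ev$signaller)) {
    stop("signaller listed among its own recipients")
  }

  ev <- ev[order(ev$signaller, ev$recipient, ev$context, ev$time_s), ,
           drop = FALSE]
  same_stream <- c(FALSE,
                   ev$signaller[-1] == ev$signaller[-nrow(ev)] &
                     ev$recipient[-1] == ev$recipient[-nrow(ev)] &
                     ev$context[-1] == ev$context[-nrow(ev)])
  gap <- c(NA_real_, diff(ev$time_s))
  split_here <- !same_stream | gap > max_gap
  if (strict_wait_window) {
    split_here <- split_here | (same_stream & gap > response_wait_max)
  }
  seq_id <- cumsum(split_here)

  grp <- split(seq_len(nrow(ev)), seq_id)
  out <- lapply(grp, function(rows) {
    times <- ev$time_s[rows]
    gaps <- diff(times)
    data.frame(
      signaller = ev$signaller[rows[1]],
      recipient = ev$recipient[rows[1]],
      context = ev$context[rows[1]],
      cls = classify_sequence(gaps, response_wait_min, response_wait_max),
      n_gestures = length(rows),
      first_time_s = times[1],
      last_time_s = times[length(times)],
      response_present = ev$response_present[rows[1]],
      response_category = ev$response_category[rows[1]],
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  # order sequences by first gesture time for stable ids
  ord <- order(res$first_time_s, res$signaller, res$recipient)
  res <- res[ord, , drop = FALSE]
  res$gaps <- lapply(grp[ord], function(rows) diff(ev$time_s[rows]))
  res$event_ids <- lapply(grp[ord], function(rows) ev$event_id[rows])
  res <- cbind(sequence_id = sprintf("Q%05d", seq_len(nrow(res))), res,
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

empty_sequences <- function() {
  data.frame(sequence_id = character(0), signaller = character(0),
             recipient = character(0), context = character(0),
             cls = character(0), n_gestures = integer(0),
             first_time_s = numeric(0), last_time_s = numeric(0),
             response_present = logical(0),
             response_category = character(0),
             stringsAsFactors = FALSE)
}

#' Attach a response annotation to coded sequences
#'
#' Responses are annotations on the sequence, one of three nominal
#' categories: a goal-directed activity change, a vocalisation, or a visual
#' or tactile gesture by the recipient. A category is only meaningful when a
#' response is present.
#'
#' @param sequences data.frame from \code{\link{segment_sequences}}.
#' @param present logical vector (recycled) flagging a response.
#' @param category character vector (recycled); must be one of
#'   "activity_change", "vocalisation", "visual_tactile_gesture" where
#'   \code{present} is TRUE, and is ignored (stored as "") elsewhere.
#' @return the sequences with response_present / response_category replaced.
#' @export
attach_response <- function(sequences, present, category = NA_character_) {
  n <- nrow(sequences)
  present <- rep_len(as.logical(present), n)
  category <- rep_len(as.character(category), n)
  bad <- present & !(category %in% response_categories())
  if (any(bad)) {
    stop("unknown response category: ",
         paste(unique(category[bad]), collapse = ", "),
         " (expected one of ",
         paste(response_categories(), collapse = ", "), ")")
  }
  sequences$response_present <- present
  sequences$response_category <- ifelse(present, category, "")
  sequences
}

#' Draw a seeded random sample of sequences for reliability coding
#'
#' Mirrors the reliability workflow in which a fixed-size random sample of
#' coded sequences is re-coded by a second coder.
#'
#' @param sequences data.frame of coded sequences.
#' @param k sample size (without replacement).
#' @param seed RNG seed for reproducible sampling.
#' @return the sampled rows, in draw order.
#' @export
kappa_sample <- function(sequences, k, seed = NULL) {
  k <- as.integer(k)
  if (k < 0 || k > nrow(sequences)) {
    stop("k must be between 0 and the number of sequences (",
         nrow(sequences), ")")
  }
  rows <- with_seed(seed, sample.int(nrow(sequences), k))
  sequences[rows, , drop = FALSE]
}
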