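#' Configuration for the synthetic fission-fusion study generator
#'
#' Bundles every knob of the synthetic study: cohort composition, focal-follow
#' design, the dyad-level latent sociality distribution, how sociality maps
#' onto party membership and within-10 m proximity, per-sequence-type gesture
#' initiation rates, the planted sociality effect on persistence sequences,
#' and class-conditional response-category probabilities.
#'
#' Defaults emulate the field design the pipeline assumes: 12 adults (6 males,
#' 3 cycling females among 6 females), 18-min focal follows of nine scans at
#' 2-min spacing, about 25 follows per focal, sequence-type base rates equal
#' to the observed per-proximity-hour means (single 1.27, rapid 0.45,
#' persistence 0.11), and a baseline within-10 m probability calibrated so
#' mean dyadic proximity is about 23.3 min per party-hour.
#'
#' @param n_individuals number of focal adults.
#' @param n_males number of males (reproductive status not applicable).
#' @param n_cycling_females females in oestrus (status "cycling"); remaining
#'   females are split between "pregnant" and "nursing".
#' @param age_range integer range (years) ages are drawn from, uniformly.
#' @param n_follows_per_focal focal follows per individual.
#' @param scans_per_follow instantaneous scans per follow.
#' @param scan_interval minutes between scans (and scan exposure window).
#' @param sociality_meanlog,sociality_sdlog log-normal parameters of the
#'   latent per-dyad sociality; sdlog = 0 collapses to a constant.
#' @param party_base_prob probability a non-focal is in the focal's party at
#'   a scan, for a dyad of average sociality.
#' @param party_slope effect (per SD of log sociality) on the party logit.
#' @param prox_base_prob probability of being within 10 m given in-party, for
#'   a dyad of average sociality.
#' @param proximity_slope effect (per SD of log sociality) on the within-10 m
#'   logit.
#' @param rate_intercepts named numeric: baseline sequence initiations per
#'   hour of co-proximity for classes single, rapid, persistence.
#' @param persistence_sociality_effect log-rate effect (per SD of log
#'   sociality) planted on the persistence initiation rate only.
#' @param response_category_probs 3 x 4 matrix (rows single, rapid,
#'   persistence; columns absent, activity_change, vocalisation,
#'   visual_tactile_gesture) of response annotation probabilities, each row
#'   summing to 1.
#' @param n_kin_pairs mother-son links planted in the attribute table.
#' @param effort_multiplier optional per-focal multiplier on
#'   \code{n_follows_per_focal} (recycled), mimicking uneven sampling.
#' @param multi_recipient if TRUE, a small fraction of sequences is broadcast
#'   to every individual within 10 m at the scan (panthoot-like); off by
#'   default.
#' @param use_packaged_attributes if TRUE, \code{\link{generate_population}}
#'   returns the packaged 12-individual Sonso community attribute table
#'   instead of sampling one.
#' @param seed RNG seed; identical config and seed give byte-identical
#'   outputs.
#' @return a validated list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_individuals = 12,
                             n_males = 6,
                             n_cycling_females = 3,
                             age_range = c(15, 46),
                             n_follows_per_focal = 25,
                             scans_per_follow = 9,
                             scan_interval = 2,
                             sociality_meanlog = 0,
                             sociality_sdlog = 1,
                             party_base_prob = 0.5,
                             party_slope = 0.5,
                             prox_base_prob = 0.365,
                             proximity_slope = 1,
                             rate_intercepts = c(single = 1.27,
                                                 rapid = 0.45,
                                                 persistence = 0.11),
                             persistence_sociality_effect = 0.66,
                             response_category_probs = default_response_probs(),
                             n_kin_pairs = 3,
                             effort_multiplier = NULL,
                             multi_recipient = FALSE,
                             use_packaged_attributes = FALSE,
                             seed = NULL) {
  cfg <- list(n_individuals = as.integer(n_individuals),
              n_males = as.integer(n_males),
              n_cycling_females = as.integer(n_cycling_females),
              age_range = as.numeric(age_range),
              n_follows_per_focal = as.integer(n_follows_per_focal),
              scans_per_follow = as.integer(scans_per_follow),
              scan_interval = as.numeric(scan_interval),
              sociality_meanlog = as.numeric(sociality_meanlog),
              sociality_sdlog = as.numeric(sociality_sdlog),
              party_base_prob = as.numeric(party_base_prob),
              party_slope = as.numeric(party_slope),
              prox_base_prob = as.numeric(prox_base_prob),
              proximity_slope = as.numeric(proximity_slope),
              rate_intercepts = rate_intercepts,
              persistence_sociality_effect =
                as.numeric(persistence_sociality_effect),
              response_category_probs = response_category_probs,
              n_kin_pairs = as.integer(n_kin_pairs),
              effort_multiplier = effort_multiplier,
              multi_recipient = isTRUE(multi_recipient),
              use_packaged_attributes = isTRUE(use_packaged_attributes),
              seed = if (is.null(seed)) NULL else as.integer(seed))
  validate_synthetic_config(cfg)
  class(cfg) <- "synthetic_config"
  cfg
}

sequence_classes <- function() c("single", "rapid", "persistence")

response_categories <- function() {
  c("activity_change", "vocalisation", "visual_tactile_gesture")
}

# Class-conditional response annotation probabilities. Chosen so that
# (i) marginal response-type rates match the observed per-proximity-hour
# means (activity change 0.58, vocalisation 0.47, visual/tactile 0.08 out of
# a total gesture rate of 1.83) given the class mix, and (ii) the planted
# signs hold: vocalisation dominates responses to rapid sequences, activity
# change dominates responses to persistence.
default_response_probs <- function() {
  m <- rbind(single      = c(0.444, 0.379, 0.122, 0.055),
             rapid       = c(0.250, 0.050, 0.680, 0.020),
             persistence = c(0.200, 0.700, 0.080, 0.020))
  colnames(m) <- c("absent", response_categories())
  m
}

validate_synthetic_config <- function(cfg) {
  stopifnot(cfg$n_individuals >= 1,
            cfg$scans_per_follow >= 1,
            cfg$n_follows_per_focal >= 1,
            cfg$scan_interval > 0,
            cfg$sociality_sdlog >= 0)
  if (cfg$n_males < 0 || cfg$n_males > cfg$n_individuals) {
    stop("inconsistent composition: n_males must be between 0 and ",
         "n_individuals")
  }
  n_females <- cfg$n_individuals - cfg$n_males
  if (cfg$n_cycling_females < 0 || cfg$n_cycling_females > n_females) {
    stop("inconsistent composition: n_cycling_females exceeds the number ",
         "of females")
  }
  probs <- c(cfg$party_base_prob, cfg$prox_base_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("party_base_prob and prox_base_prob must lie in [0, 1]")
  }
  ri <- cfg$rate_intercepts
  if (!all(sequence_classes() %in% names(ri)) || any(ri < 0)) {
    stop("rate_intercepts must be a nonnegative vector named ",
         paste(sequence_classes(), collapse = ", "))
  }
  rp <- cfg$response_category_probs
  if (!is.matrix(rp) ||
      !all(sequence_classes() %in% rownames(rp)) ||
      !all(c("absent", response_categories()) %in% colnames(rp))) {
    stop("response_category_probs must be a matrix with rows ",
         paste(sequence_classes(), collapse = ", "), " and columns absent, ",
         paste(response_categories(), collapse = ", "))
  }
  if (any(rp < 0) || any(abs(rowSums(rp) - 1) > 1e-8)) {
    stop("each row of response_category_probs must be a probability ",
         "distribution summing to 1")
  }
  if (length(cfg$age_range) != 2 || any(cfg$age_range < 0) ||
      cfg$age_range[1] > cfg$age_range[2]) {
    stop("age_range must be a nondecreasing pair of nonnegative years")
  }
  invisible(cfg)
}
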