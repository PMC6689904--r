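# The synthetic fission-fusion generator: composition, determinism,
# planted timing signatures, and distributional checks against the
# configured laws.

test_that("population composition and determinism", {
  cfg <- synthetic_config(seed = 5)
  pop <- generate_population(cfg)
  expect_equal(nrow(pop), 12L)
  expect_equal(sum(pop$sex == "male"), 6L)
  expect_equal(sum(pop$reproductive_status == "cycling"), 3L)
  expect_true(all(pop$reproductive_status[pop$sex == "male"] ==
                    "not_applicable"))
  expect_true(all(pop$age >= 0))
  expect_false(anyDuplicated(pop$id) > 0)
  # planted mother-son links
  expect_equal(sum(!is.na(pop$mother_id)), 3L)
  # forced composition: all males
  pop2 <- generate_population(synthetic_config(n_individuals = 2,
                                               n_males = 2,
                                               n_cycling_females = 0,
                                               n_kin_pairs = 0, seed = 1))
  expect_equal(pop2$sex, c("male", "male"))
  # determinism
  expect_identical(generate_population(cfg), generate_population(cfg))
  # inconsistent composition rejected
  expect_error(synthetic_config(n_individuals = 4, n_males = 6),
               "composition")
  expect_error(synthetic_config(n_individuals = 4, n_males = 2,
                                n_cycling_females = 3), "composition")
})

test_that("the packaged fixture flag returns the 12 Sonso adults", {
  cfg <- synthetic_config(use_packaged_attributes = TRUE)
  pop <- generate_population(cfg)
  expect_equal(pop$id, c("BB", "HW", "KT", "KU", "KW", "ML", "MS", "NB",
                         "NK", "RH", "SQ", "ZM"))
  expect_equal(sum(pop$sex == "male"), 6L)
  expect_equal(pop$age[pop$id == "NB"], 46)
  expect_equal(pop$reproductive_status[pop$id == "KU"], "pregnant")
  expect_equal(sum(pop$reproductive_status == "cycling"), 3L)
})

test_that("latent sociality matrix: shape, degenerate and distributional", {
  cfg <- synthetic_config(seed = 3)
  pop <- generate_population(cfg)
  s <- generate_sociality(pop, cfg)
  sm <- as.matrix(s)
  expect_true(isSymmetric(sm))
  expect_true(all(diag(sm) == 0))
  expect_true(all(sm[row(sm) != col(sm)] > 0))
  # one individual: no dyads
  cfg1 <- synthetic_config(n_individuals = 1, n_males = 1,
                           n_cycling_females = 0, n_kin_pairs = 0, seed = 1)
  s1 <- generate_sociality(generate_population(cfg1), cfg1)
  expect_equal(as.matrix(s1), matrix(0, 1, 1, dimnames = list("N01", "N01")))
  # zero variance: all off-diagonal entries equal
  cfg0 <- synthetic_config(sociality_sdlog = 0, seed = 2)
  s0 <- as.matrix(generate_sociality(generate_population(cfg0), cfg0))
  off <- s0[row(s0) != col(s0)]
  expect_true(all(off == off[1]))
  # Monte-Carlo: empirical mean within 3 SE of the log-normal mean over
  # ~1e4 dyads
  cfgbig <- synthetic_config(n_individuals = 142, n_males = 71,
                             n_cycling_females = 30, seed = 8)
  pop_big <- generate_population(cfgbig)
  sb <- as.matrix(generate_sociality(pop_big, cfgbig))
  draws <- sb[upper.tri(sb)] # 142*141/2 = 10011 independent draws
  mu <- exp(cfgbig$sociality_meanlog + cfgbig$sociality_sdlog^2 / 2)
  sigma2 <- (exp(cfgbig$sociality_sdlog^2) - 1) * mu^2
  se <- sqrt(sigma2 / length(draws))
  expect_lt(abs(mean(draws) - mu), 3 * se)
})

test_that("focal follow simulation: design shape and probability extremes", {
  cfg <- synthetic_config(seed = 21, n_follows_per_focal = 2)
  pop <- generate_population(cfg)
  soc <- generate_sociality(pop, cfg)
  scans <- simulate_focal_follows(pop, soc, cfg)
  expect_equal(nrow(scans), 12 * 2 * 9)
  expect_equal(unname(table(scans$focal_id)["N01"]), 18L)
  expect_equal(sort(unique(scans$scan_index)), 1:9)
  # scan timestamps spaced scan_interval minutes within a follow
  one <- scans[scans$follow_id == scans$follow_id[1], ]
  expect_equal(diff(one$time_min), rep(cfg$scan_interval, 8))
  # within-10 m members always a subset of the party
  pm <- strsplit(scans$party_members, ";")
  wm <- strsplit(scans$within10_members, ";")
  expect_true(all(mapply(function(w, p) all(w %in% p), wm, pm)))
  # zero party probability: every scan has empty party
  cfg0 <- synthetic_config(seed = 21, party_base_prob = 0,
                           n_follows_per_focal = 2)
  s0 <- simulate_focal_follows(pop, soc, cfg0)
  expect_true(all(s0$party_members == ""))
  expect_true(all(s0$within10_members == ""))
  # certainty: everyone within 10 m at every scan
  cfg1 <- synthetic_config(seed = 21, party_base_prob = 1,
                           prox_base_prob = 1, n_follows_per_focal = 2)
  s1 <- simulate_focal_follows(pop, soc, cfg1)
  expect_true(all(vapply(strsplit(s1$within10_members, ";"), length,
                         integer(1)) == 11))
  # determinism
  expect_identical(simulate_focal_follows(pop, soc, cfg),
                   simulate_focal_follows(pop, soc, cfg))
})

test_that("higher-sociality dyads are seen within 10 m more often", {
  # planted monotone slope: top sociality tercile beats bottom tercile in
  # observed within-10 m scan fraction, over ~1e3 follows
  cfg <- synthetic_config(seed = 31, n_follows_per_focal = 90)
  pop <- generate_population(cfg)
  soc <- generate_sociality(pop, cfg)
  scans <- simulate_focal_follows(pop, soc, cfg)
  tal <- tally_dyads(scans, empty_seq_table(), labels = pop$id)
  # every focal has the same number of scans, so raw p10 counts are
  # comparable across dyads
  sv <- as.matrix(soc)[row(as.matrix(soc)) != col(as.matrix(soc))]
  fv <- tal$p10[row(tal$p10) != col(tal$p10)]
  terc <- cut(sv, quantile(sv, c(0, 1 / 3, 2 / 3, 1)),
              include.lowest = TRUE, labels = FALSE)
  expect_gt(mean(fv[terc == 3]), mean(fv[terc == 1]))
})

test_that("gesture events: zero rates, planted classes, Poisson counts", {
  cfg <- synthetic_config(seed = 77, n_follows_per_focal = 5)
  pop <- generate_population(cfg)
  soc <- generate_sociality(pop, cfg)
  scans <- simulate_focal_follows(pop, soc, cfg)
  # zero rates: empty log
  cfg0 <- synthetic_config(seed = 77, rate_intercepts = c(single = 0,
                                                          rapid = 0,
                                                          persistence = 0))
  expect_equal(nrow(simulate_gesture_events(scans, soc, cfg0)), 0L)
  # planted classes recovered exactly by the coder (round trip)
  ev <- simulate_gesture_events(scans, soc, cfg)
  expect_gt(nrow(ev), 0)
  seqs <- segment_sequences(ev)
  planted <- unname(sub(".*_", "", vapply(seqs$event_ids, function(ids) {
    ev$sequence_hint[match(ids[1], ev$event_id)]
  }, character(1))))
  expect_identical(seqs$cls, planted)
  # every planted sequence id maps to exactly one recovered sequence
  expect_equal(length(unique(ev$sequence_hint)), nrow(seqs))
  # determinism: byte-identical CSVs under the same seed
  ev2 <- simulate_gesture_events(scans, soc, cfg)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_events(ev, f1); write_events(ev2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("sequence initiations follow the configured Poisson rates", {
  # flat sociality so every dyad shares one rate; count sequences against
  # lambda * T with a 3-sigma Poisson band
  rates <- c(single = 2, rapid = 1.2, persistence = 0.6)
  cfg <- synthetic_config(seed = 19, n_follows_per_focal = 40,
                          sociality_sdlog = 0, party_base_prob = 1,
                          prox_base_prob = 1, rate_intercepts = rates,
                          persistence_sociality_effect = 0)
  pop <- generate_population(cfg)
  soc <- generate_sociality(pop, cfg)
  scans <- simulate_focal_follows(pop, soc, cfg)
  ev <- simulate_gesture_events(scans, soc, cfg)
  seqs <- segment_sequences(ev)
  # exposure: every dyad within 10 m at every scan
  T_hours <- nrow(scans) * 11 * cfg$scan_interval / 60
  counts <- table(factor(seqs$cls, levels = names(rates)))
  for (cl in names(rates)) {
    lam_T <- rates[[cl]] * T_hours
    expect_lt(abs(counts[[cl]] - lam_T), 3 * sqrt(lam_T))
  }
})

test_that("response annotations follow the class-conditional categories", {
  cfg <- synthetic_config(seed = 55, n_follows_per_focal = 40)
  st <- simulate_gesture_study(cfg)
  seqs <- segment_sequences(st$events)
  rp <- cfg$response_category_probs
  # vocalisation should dominate responses to rapid sequences,
  # activity change those to persistence (planted signs)
  rap <- seqs[seqs$cls == "rapid" & seqs$response_present, ]
  per <- seqs[seqs$cls == "persistence" & seqs$response_present, ]
  expect_gt(mean(rap$response_category == "vocalisation"), 0.5)
  expect_gt(mean(per$response_category == "activity_change"), 0.5)
  # observed absence rate near the configured one for singles
  sing <- seqs[seqs$cls == "single", ]
  p_abs <- rp["single", "absent"]
  se <- sqrt(p_abs * (1 - p_abs) / nrow(sing))
  expect_lt(abs(mean(!sing$response_present) - p_abs), 4 * se)
})

test_that("uneven effort multiplier scales follow counts per focal", {
  cfg <- synthetic_config(seed = 2, n_follows_per_focal = 4,
                          effort_multiplier = c(2, rep(1, 11)))
  pop <- generate_population(cfg)
  soc <- generate_sociality(pop, cfg)
  scans <- simulate_focal_follows(pop, soc, cfg)
  follows_per <- table(unique(scans[c("follow_id", "focal_id")])$focal_id)
  expect_equal(unname(follows_per[["N01"]]), 8L)
  expect_equal(unname(follows_per[["N02"]]), 4L)
})
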