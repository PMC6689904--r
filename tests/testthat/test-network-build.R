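# Dyadic matrix construction: integer tallies, rate formulas, attribute
# similarity coding.

sequence_classes_vec <- function() c("single", "rapid", "persistence")

simple_scans <- function() {
  # one follow of A: B within 10 m in 6 of 9 scans, in party in all 9;
  # C in party in 3 scans, never within 10 m
  data.frame(
    follow_id = "F0001", focal_id = "A", scan_index = 1:9,
    time_min = seq(0, 16, by = 2),
    party_members = c(rep("B;C", 3), rep("B", 6)),
    within10_members = c(rep("", 3), rep("B", 6)),
    stringsAsFactors = FALSE)
}

seq_row <- function(signaller, recipient, cls, t, present = TRUE,
                    category = "activity_change") {
  data.frame(signaller = signaller, recipient = recipient, cls = cls,
             first_time_s = t, response_present = present,
             response_category = if (present) category else "",
             stringsAsFactors = FALSE)
}

test_that("tallies count scans and attribute sequences to scan intervals", {
  scans <- simple_scans()
  seqs <- rbind(
    seq_row("A", "B", "single", 6 * 60 + 10), # scan 4: B within 10 m
    seq_row("A", "B", "persistence", 8 * 60 + 5, present = FALSE),
    seq_row("A", "B", "rapid", 2 * 60 + 1)) # scan 2: B not within 10 m
  tal <- tally_dyads(scans, seqs, labels = c("A", "B", "C"))
  expect_equal(tal$p10["A", "B"], 6L)
  expect_equal(tal$party["A", "B"], 9L)
  expect_equal(tal$party["A", "C"], 3L)
  expect_equal(tal$p10["A", "C"], 0L)
  expect_equal(tal$comm$single["A", "B"], 1L)
  expect_equal(tal$comm$persistence["A", "B"], 1L)
  expect_equal(tal$comm$rapid["A", "B"], 0L) # excluded: not within 10 m
  expect_equal(tal$excluded_sequences, 1L)
  expect_equal(tal$comm$present["A", "B"], 1L)
  expect_equal(tal$comm$absent["A", "B"], 1L)
  expect_equal(tal$comm$activity_change["A", "B"], 1L)
  # empty event log leaves proximity tallies unchanged, all C zero
  tal0 <- tally_dyads(scans, empty_seq_table(), labels = c("A", "B", "C"))
  expect_equal(tal0$p10, tal$p10)
  expect_true(all(tal0$comm$single == 0))
  # unknown node is an error
  bad <- seq_row("A", "Z", "single", 10)
  expect_error(tally_dyads(scans, bad, labels = c("A", "B", "C")),
               "unknown ids")
})

test_that("tallies equal the brute-force double loop on random inputs", {
  set.seed(88)
  for (rep in 1:5) {
    cfg <- synthetic_config(seed = rep * 101, n_follows_per_focal = 2,
                            n_individuals = 5, n_males = 3,
                            n_cycling_females = 1, n_kin_pairs = 1)
    st <- simulate_gesture_study(cfg)
    seqs <- segment_sequences(st$events)
    tal <- tally_dyads(st$scans, seqs, labels = st$attrs$id)
    ora <- oracle_tally(st$scans, seqs, st$attrs$id)
    expect_equal(unname(tal$p10), unname(ora$p10))
    expect_equal(unname(tal$party), unname(ora$party))
    for (cl in sequence_classes_vec()) {
      expect_equal(unname(tal$comm[[cl]]), unname(ora$C[[cl]]))
    }
    expect_equal(tal$excluded_sequences, ora$excluded)
  }
})

test_that("communication rate follows the per-proximity-hour formula", {
  scans <- simple_scans()
  tal <- tally_dyads(scans, seq_row("A", "B", "single", 370),
                     labels = c("A", "B", "C"))
  # C = 1, P10 = 6 scans of 2 min -> 12 min -> rate 60/12 = 5 per hour
  ca <- communication_rate(tal, "single")
  expect_equal(ca["A", "B"], 5)
  # worked arithmetic from the definition: C=1, P10=30 scans -> 1 per hour
  tal$p10["A", "B"] <- 30L
  expect_equal(communication_rate(tal, "single")["A", "B"], 1)
  # zero counts give zero rate; zero exposure flagged, rate 0
  expect_equal(communication_rate(tal, "rapid")["A", "B"], 0)
  expect_true(attr(communication_rate(tal, "single"),
                   "zero_exposure")["A", "C"])
  expect_equal(communication_rate(tal, "single")["A", "C"], 0)
})

test_that("rates agree with independent minutes-based bookkeeping", {
  set.seed(13)
  for (rep in 1:20) {
    n <- 4
    labels <- LETTERS[1:n]
    tal <- structure(list(
      labels = labels, scan_interval = 2,
      party = matrix(sample(0:20, n * n, TRUE), n, n,
                     dimnames = list(labels, labels)),
      p10 = NULL, comm = NULL, excluded_sequences = 0L),
      class = "dyad_tallies")
    tal$p10 <- matrix(vapply(as.vector(tal$party),
                             function(k) sample(0:k, 1), integer(1)),
                      n, n, dimnames = list(labels, labels))
    diag(tal$party) <- 0L; diag(tal$p10) <- 0L
    C <- matrix(rpois(n * n, 3), n, n, dimnames = list(labels, labels))
    diag(C) <- 0L
    tal$comm <- list(single = C)
    ca <- communication_rate(tal, "single")
    prox <- proximity_rate(tal)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        minutes_w10 <- tal$p10[i, j] * 2
        minutes_party <- tal$party[i, j] * 2
        exp_ca <- if (minutes_w10 > 0) C[i, j] / (minutes_w10 / 60) else 0
        exp_prox <- if (minutes_party > 0) {
          minutes_w10 / (minutes_party / 60)
        } else {
          0
        }
        expect_equal(ca[i, j], exp_ca)
        expect_equal(prox[i, j], exp_prox)
      }
    }
    # bounds and equivariance
    offv <- prox[row(as.matrix(prox)) != col(as.matrix(prox))]
    expect_true(all(offv >= 0 & offv <= 60))
    tal2 <- tal
    tal2$comm$single <- C * 2L
    expect_equal(as.matrix(communication_rate(tal2, "single")),
                 as.matrix(ca) * 2)
    tal3 <- tal
    tal3$p10 <- tal$p10 * 2L; tal3$party <- tal$party * 2L
    expect_equal(as.matrix(proximity_rate(tal3)), as.matrix(prox))
  }
})

test_that("proximity rate is 60 when always within 10 m, 0 when never", {
  scans <- simple_scans()
  tal <- tally_dyads(scans, empty_seq_table(), labels = c("A", "B", "C"))
  tal$p10["A", "B"] <- tal$party["A", "B"]
  prox <- proximity_rate(tal)
  expect_equal(prox["A", "B"], 60)
  expect_equal(prox["A", "C"], 0)
  # inconsistent tallies rejected
  tal$p10["A", "C"] <- 5L
  expect_error(proximity_rate(tal), "exceeds party count")
})

test_that("similarity matrices reproduce the printed dyad counts", {
  attrs <- packaged_attrs()
  age <- as.matrix(similarity_matrix(attrs, "age"))
  off <- row(age) != col(age)
  expect_equal(sum(age[off] == 1), 30)
  expect_equal(sum(age[off] == 0), 102)
  oes <- as.matrix(similarity_matrix(attrs, "oestrous"))
  expect_equal(sum(oes[off] == 1), 36)
  expect_equal(sum(oes[off] == 0), 96)
  sex <- as.matrix(similarity_matrix(attrs, "sex"))
  expect_equal(sum(off), 132) # 12 nodes -> 132 ordered dyads
  # symmetry and zero diagonal for every kind
  for (kind in c("sex", "age", "oestrous")) {
    m <- as.matrix(similarity_matrix(attrs, kind))
    expect_true(isSymmetric(m))
    expect_true(all(diag(m) == 0))
    expect_true(all(m %in% c(0, 1)))
  }
})

test_that("kin similarity follows mother links; errors are informative", {
  attrs <- data.frame(id = c("M1", "S1", "F2", "S2"),
                      sex = c("female", "male", "female", "male"),
                      age = c(40, 15, 35, 12),
                      reproductive_status = c("nursing", "not_applicable",
                                              "cycling", "not_applicable"),
                      mother_id = c(NA, "M1", NA, "F2"),
                      stringsAsFactors = FALSE)
  kin <- as.matrix(similarity_matrix(attrs, "kin"))
  expect_equal(sum(kin), 4) # two mother-son pairs, both directions
  expect_equal(kin["M1", "S1"], 1)
  expect_equal(kin["S1", "M1"], 1)
  expect_equal(kin["M1", "F2"], 0)
  attrs$age <- NA
  expect_error(similarity_matrix(attrs, "age"), "age")
})


test_that("build_networks assembles consistent, complete matrices", {
  cfg <- synthetic_config(seed = 12, n_follows_per_focal = 4)
  st <- simulate_gesture_study(cfg)
  seqs <- segment_sequences(st$events)
  nets <- build_networks(st$attrs, st$scans, seqs)
  expected <- c("proximity", "single", "rapid", "persistence", "present",
                "absent", "activity_change", "vocalisation",
                "visual_tactile_gesture", "age", "sex", "oestrous", "kin")
  expect_true(all(expected %in% names(nets)))
  for (nm in expected) {
    expect_s3_class(nets[[nm]], "dyad_matrix")
    expect_identical(rownames(as.matrix(nets[[nm]])), st$attrs$id)
  }
  # drop_zero_exposure attaches a mask over unobserved dyads
  nets2 <- build_networks(st$attrs, st$scans, seqs,
                          drop_zero_exposure = TRUE)
  mask <- attr(nets2, "mask")
  expect_true(is.matrix(mask))
  expect_equal(sum(diag(mask)), 0)
})
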