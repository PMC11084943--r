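test_that("preference curve bins choices correctly", {
  all_adv <- make_trials(seq(0, 3599, by = 60), "ADV")
  expect_equal(preference_curve(all_adv), rep(100, 6))

  alternating <- make_trials(seq(0, 3599, by = 50), c("ADV", "DIS"))
  expect_true(all(preference_curve(alternating) == 50))

  one_bin <- make_trials(c(rep(100, 7), rep(200, 3)),
                         c(rep("ADV", 7), rep("DIS", 3)))
  expect_equal(preference_curve(one_bin)[1], 70)
  # bins without choices are missing, not zero
  expect_true(all(is.na(preference_curve(one_bin)[2:6])))

  expect_error(preference_curve(all_adv[0, ]), "empty")
  expect_error(preference_curve(all_adv, bin_seconds = 700), "divide")
})

test_that("gambling score counts the last 20 minutes", {
  tr <- make_trials(c(seq(0, 2399, length.out = 30),
                      seq(2400, 3599, length.out = 20)),
                    c(rep("DIS", 30), rep("ADV", 18), rep("DIS", 2)))
  expect_equal(rgt_score(tr), 90)
  tr2 <- make_trials(seq(2400, 3599, length.out = 20), c("ADV", "DIS"))
  expect_equal(rgt_score(tr2), 50)
  tr3 <- make_trials(seq(2400, 3599, length.out = 10),
                     c(rep("ADV", 2), rep("DIS", 8)))
  expect_equal(rgt_score(tr3), 20)
  early <- make_trials(seq(0, 2000, by = 100), "ADV")
  expect_warning(s <- rgt_score(early), "no choices")
  expect_true(is.na(s))
})

test_that("decision-maker classification is a strict-boundary partition", {
  expect_equal(classify_dm(c(90, 70, 30, 29.9, NA)),
               c("GDM", "INT", "INT", "PDM", NA))
  expect_error(classify_dm(101), "\\[0, 100\\]")
  # total deterministic partition of [0, 100]
  grid <- seq(0, 100, by = 0.5)
  cls <- classify_dm(grid)
  expect_false(anyNA(cls))
  expect_identical(cls, classify_dm(grid))
  expect_setequal(unique(cls), c("GDM", "INT", "PDM"))
})

test_that("scores are invariant to trial order within bins", {
  set.seed(5)
  tr <- make_trials(runif(40, 0, 3600), sample(c("ADV", "DIS"), 40, TRUE))
  shuffled <- tr[sample(nrow(tr)), ]
  expect_equal(rgt_score(tr), rgt_score(shuffled))
  expect_equal(preference_curve(tr), preference_curve(shuffled))
})

test_that("flexibility score follows the relocated non-preferred option", {
  # preferred side left during the original task
  rgt <- make_trials(seq(2400, 3599, length.out = 10), "ADV",
                     side = c(rep("left", 8), rep("right", 2)))
  rev80 <- make_trials(seq(2400, 3599, length.out = 10), "ADV",
                       side = c(rep("right", 8), rep("left", 2)),
                       task = "REV")
  f <- flexibility_score(rgt, rev80)
  expect_equal(f$flex_score, 80)
  expect_equal(f$flex_class, "flexible")

  rev50 <- make_trials(seq(2400, 3599, length.out = 10), "ADV",
                       side = c("left", "right"), task = "REV")
  expect_equal(flexibility_score(rgt, rev50)$flex_class, "undecided")

  rev_low <- make_trials(seq(2400, 3599, length.out = 1000), "ADV",
                         side = c(rep("right", 399), rep("left", 601)),
                         task = "REV")
  f3 <- flexibility_score(rgt, rev_low)
  expect_equal(f3$flex_score, 39.9)
  expect_equal(f3$flex_class, "inflexible")

  tied <- make_trials(seq(2400, 3599, length.out = 10), "ADV",
                      side = c("left", "right"))
  expect_warning(ft <- flexibility_score(tied, rev80), "tied")
  expect_true(is.na(ft$flex_class))
})

test_that("discounting stability rules", {
  expect_equal(pdt_stability(c(80, 78), "training"),
               list(stable = TRUE, mean = 79, pair = 1L))
  expect_false(pdt_stability(c(72, 50), "training")$stable)
  st <- pdt_stability(c(40, 49), "testing")
  expect_true(st$stable)
  expect_equal(st$mean, 44.5)
  expect_false(pdt_stability(c(40, 55, 80), "testing")$stable)
  expect_false(pdt_stability(80, "training")$stable)
  # first qualifying pair wins
  expect_equal(pdt_stability(c(90, 60, 75, 80), "training")$pair, 3L)
})

test_that("discounting AUC over the odds transform", {
  # flat curve at the training preference integrates to exactly 1
  expect_equal(discounting_auc(rep(80, 4), 80), 1)
  # single trapezoid: P = (1, 0.5), normalized y = (1, 0.5)
  expect_equal(discounting_auc(25, 50, probabilities = 0.5), 0.75)
  # odds arithmetic from the printed formula
  expect_equal(1 / 0.09 - 1, 10.1111, tolerance = 1e-4)
  expect_equal(1 / 0.33 - 1, 2.0303, tolerance = 1e-4)
  expect_error(discounting_auc(rep(50, 4), 0), "positive")
})

test_that("AUC is scale invariant and monotone in the curve", {
  set.seed(11)
  probs <- c(0.33, 0.20, 0.14, 0.09)
  for (i in 1:20) {
    y <- runif(4, 10, 90); train <- runif(1, 50, 95)
    a <- discounting_auc(y, train, probs)
    expect_equal(discounting_auc(3 * y, 3 * train, probs), a)
    bump <- y + runif(4, 0, 10)
    expect_gte(discounting_auc(bump, train, probs), a)
  }
})

test_that("social ratios and odor preference", {
  d <- data.frame(subject_id = "S1", hab = 10, e1 = 25, e2 = 15, e3 = 10)
  r <- srt_ratios(d)
  expect_equal(r$sp_ratio, 2.5)
  expect_equal(r$stm_ratio, 2.5)
  # no-recognition signature: E1 = E3 gives STM exactly 1
  expect_equal(srt_ratios(data.frame(hab = 5, e1 = 12, e3 = 12))$stm_ratio, 1)
  expect_equal(srt_ratios(data.frame(hab = 12, e1 = 12, e3 = 6))$sp_ratio, 1)
  expect_warning(z <- srt_ratios(data.frame(hab = 0, e1 = 5, e3 = 5)), "zero")
  expect_true(is.na(z$sp_ratio))

  expect_equal(odor_preference(30, 10), 75)
  expect_equal(odor_preference(10, 10), 50)
  expect_equal(odor_preference(0, 20), 0)
  expect_error(odor_preference(0, 0), "positive")
})

test_that("neurochemistry normalization is batch-wise to control means", {
  rec <- data.frame(
    subject_id = c("a", "b", "c"), batch_id = "B1",
    treatment = c("Tph2-wt", "Tph2-wt", "Tph2-kd"),
    fiveht = c(10, 14, 9.6), fivehiaa = c(3, 5, 4), trp = c(30, 28, 29))
  nn <- normalize_neurochem(rec)
  expect_equal(nn$normalized_5ht[3], 80)
  expect_equal(mean(nn$normalized_5ht[1:2]), 100)
  expect_equal(nn$hiaa_trp_ratio, rec$fivehiaa / rec$trp)
  # control-only batch: all normalized means exactly 100
  ctrl <- rec; ctrl$treatment <- "Tph2-wt"
  expect_equal(mean(normalize_neurochem(ctrl)$normalized_5hiaa), 100)
  # per-batch rescaling of raw inputs leaves normalized output unchanged
  scaled <- rec
  scaled[c("fiveht", "fivehiaa", "trp")] <- scaled[c("fiveht", "fivehiaa", "trp")] * 3.7
  expect_equal(normalize_neurochem(scaled)$normalized_5ht, nn$normalized_5ht)
  # batch without controls is an error
  orphan <- rec; orphan$treatment <- "Tph2-kd"
  expect_error(normalize_neurochem(orphan), "control")
})

test_that("high-serotonin outlier exclusion is strict and arm-wise", {
  rec <- data.frame(subject_id = sprintf("s%d", 1:11),
                    treatment = "Tph2-wt",
                    normalized_5ht = c(rnorm(10, 100, 2), 300))
  out <- exclude_5ht_outliers(rec)
  expect_equal(out$excluded$subject_id, "s11")
  expect_equal(nrow(out$kept), 10)
  expect_length(out$log, 1)
  # sd = 0: nobody exceeds mean + 2sd
  flat <- data.frame(subject_id = 1:5, treatment = "x", normalized_5ht = 100)
  expect_equal(nrow(exclude_5ht_outliers(flat)$excluded), 0)
  # "higher than" is strict: with sd = 0 every value sits exactly at the
  # mean + 2sd bound and must be kept (covered above); a wide two-point arm
  # also keeps its top values because the bound exceeds the maximum
  rec2 <- data.frame(subject_id = 1:4, treatment = "x",
                     normalized_5ht = c(80, 80, 200, 200))
  expect_equal(nrow(exclude_5ht_outliers(rec2)$excluded), 0)
  expect_warning(exclude_5ht_outliers(
    data.frame(subject_id = 1:2, treatment = "y",
               normalized_5ht = c(1, 2))), "fewer than 3")
})
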