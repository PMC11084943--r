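# trial simulation is the slow part; metadata-only configs (tasks = none)
# keep the generator tests fast
meta_config <- function(...) cohort_config(tasks = character(0), ...)

small_config <- function(tasks = c("RGT", "REV", "PDT")) cohort_config(
  n_wt = 8L, n_kd = 8L,
  phenotype_counts = list(wt = c(GDM = 6L, INT = 1L, PDM = 1L),
                          kd = c(GDM = 4L, INT = 2L, PDM = 2L)),
  batch_size = 4L, tasks = tasks)

test_that("default cohort reproduces the study's group structure", {
  co <- generate_cohort(meta_config(), seed = 1)
  tab <- table(co$subjects$treatment, co$subjects$phenotype_truth)
  expect_equal(unname(tab["Tph2-wt", c("GDM", "INT", "PDM")]),
               c(49, 8, 3), ignore_attr = TRUE)
  expect_equal(unname(tab["Tph2-kd", c("GDM", "INT", "PDM")]),
               c(39, 10, 9), ignore_attr = TRUE)
  # batches hold 6 subjects per arm while both arms last
  b1 <- table(co$subjects$treatment[co$subjects$batch_id == "B01"])
  expect_equal(unname(b1), c(6, 6), ignore_attr = TRUE)
  expect_error(
    cohort_config(n_wt = 5, phenotype_counts = list(
      wt = c(GDM = 1L, INT = 1L, PDM = 1L),
      kd = c(GDM = 39L, INT = 10L, PDM = 9L))),
    "sum to the group sizes")
})

test_that("generator is deterministic given config and seed", {
  cfg <- small_config()
  a <- generate_cohort(cfg, seed = 11)
  b <- generate_cohort(cfg, seed = 11)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$trials, b$trials)
  expect_identical(a$srt, b$srt)
  expect_identical(a$neurochem, b$neurochem)
  expect_false(identical(a$trials,
                         generate_cohort(cfg, seed = 12)$trials))
})

test_that("trial table semantics: tasks, sides, probabilities", {
  co <- generate_cohort(small_config(), seed = 21)
  expect_setequal(unique(co$trials$task), c("RGT", "REV", "PDT"))
  expect_true(all(is.na(co$trials$session_prob[co$trials$task != "PDT"])))
  expect_setequal(unique(co$trials$session_prob[co$trials$task == "PDT"]),
                  c(1, 0.33, 0.20, 0.14, 0.09))
  # the reversed task swaps the options' physical sides
  s1 <- co$trials[co$trials$subject_id == co$subjects$subject_id[1], ]
  rgt_adv_side <- unique(s1$side[s1$task == "RGT" & s1$option == "ADV"])
  rev_adv_side <- unique(s1$side[s1$task == "REV" & s1$option == "ADV"])
  expect_length(rgt_adv_side, 1)
  expect_false(rgt_adv_side == rev_adv_side)
  # pellet conservation through the whole table
  sch <- make_rgt_schedule()
  rgt <- co$trials[co$trials$task == "RGT", ]
  expect_equal(sum(rgt$pellets),
               sum(sch$option_payouts[rgt$option]), ignore_attr = TRUE)
})

test_that("social durations carry the preference and memory structure", {
  co <- generate_cohort(meta_config(), seed = 31)
  sr <- srt_ratios(co$srt)
  kd_pdm <- co$subjects$treatment == "Tph2-kd" &
    co$subjects$phenotype_truth == "PDM"
  expect_true(all(sr$e1 > sr$hab))                    # social preference
  expect_gt(mean(sr$stm_ratio[!kd_pdm]), 1.6)        # recognition
  expect_equal(mean(sr$stm_ratio[kd_pdm]), 1, tolerance = 0.15)
  expect_true(all(sr$sp_ratio > 1))
})

test_that("neurochemistry reproduces configured knockdown effects", {
  co <- generate_cohort(meta_config(), seed = 41)
  nn <- normalize_neurochem(co$neurochem)
  kd <- nn$treatment == "Tph2-kd"
  expect_equal(mean(nn$normalized_5ht[!kd]), 100, tolerance = 1e-10)
  expect_equal(mean(nn$normalized_5ht[kd]), 79, tolerance = 8)
  expect_equal(mean(nn$normalized_5hiaa[kd]), 75, tolerance = 8)
  expect_equal(mean(nn$normalized_trp[kd]), 100, tolerance = 8)

  # null effect: both arms center at 100
  co0 <- generate_cohort(
    meta_config(kd_effects = c(fiveht = 0, fivehiaa = 0, trp = 0)),
    seed = 42)
  nn0 <- normalize_neurochem(co0$neurochem)
  expect_equal(mean(nn0$normalized_5ht[nn0$treatment == "Tph2-kd"]), 100,
               tolerance = 8)
  expect_true(all(co$neurochem[c("fiveht", "fivehiaa", "trp")] > 0))
})

test_that("scoring a simulated cohort fills every contract column", {
  co <- generate_cohort(small_config(), seed = 51)
  sc <- score_cohort(co)
  expect_equal(nrow(sc$scores), 16)
  expect_true(all(c("rgt_score", "dm_class", "mean_latency", "flex_score",
                    "flex_class", "auc", "sp_ratio", "stm_ratio",
                    "odor_pref", "normalized_5ht") %in% names(sc$scores)))
  expect_false(anyNA(sc$scores$rgt_score))
  expect_false(anyNA(sc$scores$sp_ratio))
  expect_true(all(sc$scores$auc > 0, na.rm = TRUE))
  expect_true(all(sc$subjects$phenotype_called %in% c("GDM", "INT", "PDM")))
  # discounting is steeper for knockdown PDMs by construction
  kd_pdm <- sc$subjects$treatment == "Tph2-kd" &
    sc$subjects$phenotype_truth == "PDM"
  expect_lt(mean(sc$scores$auc[kd_pdm], na.rm = TRUE),
            mean(sc$scores$auc[!kd_pdm], na.rm = TRUE))
})
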