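#' Preference curve over time bins
#'
#' Percentage of advantageous choices per time bin of a single gambling-task
#' session (default: six 10-min bins of a 60-min session). Bins without any
#' choice are `NA`, never zero.
#'
#' @param trials Trial records of one RGT (or reversed-RGT) session.
#' @param bin_seconds Bin width in seconds; must divide `session_duration`.
#' @param session_duration Session length in seconds.
#' @return Numeric vector of percentages (0-100), one per bin.
#' @export
preference_curve <- function(trials, bin_seconds = 600,
                             session_duration = 3600) {
  if (is.null(trials) || nrow(trials) == 0L) stop("empty trial set")
  if (session_duration %% bin_seconds != 0)
    stop("bin_seconds must divide session_duration")
  nb <- session_duration / bin_seconds
  bin <- pmin(floor(trials$t_choice / bin_seconds) + 1L, nb)
  adv <- trials$option == "ADV"
  out <- rep(NA_real_, nb)
  for (b in seq_len(nb)) {
    sel <- bin == b
    if (any(sel)) out[b] <- 100 * mean(adv[sel])
  }
  out
}

#' Gambling-task score: % advantageous choices in the last 20 minutes
#'
#' The classification statistic of the task: the percentage of advantageous
#' choices among those made in the final third of the session (choices with
#' `t_choice` in `[2400, 3600)` by default). If the subject made no choice
#' in the window the score is `NA` with a warning (mirroring the exclusion
#' of subjects whose choice pattern cannot be classified).
#'
#' @param trials Trial records of one RGT session.
#' @param window Two-element numeric; the scoring window in seconds.
#' @return Percentage in `[0, 100]`, or `NA`.
#' @export
rgt_score <- function(trials, window = c(2400, 3600)) {
  if (is.null(trials) || nrow(trials) == 0L) stop("empty trial set")
  sel <- trials$t_choice >= window[1] & trials$t_choice < window[2]
  if (!any(sel)) {
    warning("no choices in the scoring window; score is NA")
    return(NA_real_)
  }
  100 * mean(trials$option[sel] == "ADV")
}

#' Decision-maker classification
#'
#' Scores above 70 are good decision makers (GDM), below 30 poor decision
#' makers (PDM), everything in between (including exactly 70 and 30)
#' intermediate (INT). Missing scores stay unclassified (`NA`).
#'
#' @param score Score(s) on the 0-100 scale.
#' @return Character vector of `"GDM"`, `"INT"`, `"PDM"` or `NA`.
#' @examples
#' classify_dm(c(90, 70, 29.9, NA))
#' @export
classify_dm <- function(score) {
  if (any(!is.na(score) & (score < 0 | score > 100)))
    stop("scores must lie in [0, 100]")
  ifelse(is.na(score), NA_character_,
         ifelse(score > 70, "GDM", ifelse(score < 30, "PDM", "INT")))
}

#' Mean magazine latency of a session
#'
#' Mean latency to visit the food magazine after a rewarded choice; an index
#' of the motivation for the reward ("Lat" in the behavioral network).
#'
#' @param trials Trial records of one session.
#' @return Mean latency in seconds.
#' @export
mean_magazine_latency <- function(trials) {
  mean(trials$magazine_latency, na.rm = TRUE)
}

#' Score one gambling-task session
#'
#' @param trials Trial records of one RGT session.
#' @return A list with `pref_curve`, `rgt_score`, `mean_latency` and
#'   `dm_class`.
#' @export
rgt_result <- function(trials) {
  score <- rgt_score(trials)
  list(pref_curve = preference_curve(trials),
       rgt_score = score,
       mean_latency = mean_magazine_latency(trials),
       dm_class = classify_dm(score))
}

#' Reversed-task flexibility score and class
#'
#' The flexibility score is the preference, during the last 20 min of the
#' reversed session, for the location (side) that carried the non-preferred
#' option during the original task. The preferred side is the majority side
#' of the last-20-min original-task choices; a tie leaves the subject
#' unclassified. Scores above 60 are flexible, below 40 inflexible,
#' in between (inclusive) undecided.
#'
#' @param rgt_trials,rev_trials Trial records of the original and reversed
#'   sessions of one subject.
#' @param window Scoring window in seconds.
#' @return A list with `flex_score` and `flex_class` (`NA` on a tie).
#' @export
flexibility_score <- function(rgt_trials, rev_trials,
                              window = c(2400, 3600)) {
  in_win <- function(tr) tr[tr$t_choice >= window[1] & tr$t_choice < window[2], ]
  rw <- in_win(rgt_trials)
  vw <- in_win(rev_trials)
  if (nrow(rw) == 0L || nrow(vw) == 0L)
    return(list(flex_score = NA_real_, flex_class = NA_character_))
  n_left <- sum(rw$side == "left")
  n_right <- sum(rw$side == "right")
  if (n_left == n_right) {
    warning("tied side preference in the original task; no flexibility class")
    return(list(flex_score = NA_real_, flex_class = NA_character_))
  }
  preferred <- if (n_left > n_right) "left" else "right"
  other <- if (preferred == "left") "right" else "left"
  score <- 100 * mean(vw$side == other)
  cls <- if (score > 60) "flexible" else if (score < 40) "inflexible" else "undecided"
  list(flex_score = score, flex_class = cls)
}

#' Session-to-session stability of discounting preferences
#'
#' Training phase (P = 1): stable when two consecutive sessions are both at
#' or above 70% large-reward choices and differ by at most 15 percentage
#' points. Testing phase (P < 1): stable when two consecutive sessions
#' differ by at most 10 percentage points. Returns the mean of the first
#' qualifying pair.
#'
#' @param session_prefs Ordered per-session preferences (% large-reward
#'   choices).
#' @param phase `"training"` or `"testing"`.
#' @return A list with `stable` (logical), `mean` (of the first stable
#'   pair, `NA` when unstable) and `pair` (index of the first session of
#'   the pair).
#' @export
pdt_stability <- function(session_prefs, phase = c("training", "testing")) {
  phase <- match.arg(phase)
  if (length(session_prefs) < 2L)
    return(list(stable = FALSE, mean = NA_real_, pair = NA_integer_))
  for (i in seq_len(length(session_prefs) - 1L)) {
    a <- session_prefs[i]; b <- session_prefs[i + 1L]
    ok <- if (phase == "training") a >= 70 && b >= 70 && abs(a - b) <= 15
          else abs(a - b) <= 10
    if (ok) return(list(stable = TRUE, mean = mean(c(a, b)), pair = i))
  }
  list(stable = FALSE, mean = NA_real_, pair = NA_integer_)
}

#' Per-probability large-reward preferences of a PDT subject
#'
#' Groups the subject's PDT trials by the session's scheduled probability,
#' computes the per-session percentage of large-reward (`NP5`) choices, and
#' applies the stability rule of [pdt_stability()] per probability (training
#' rule at P = 1, testing rule below).
#'
#' @param trials PDT trial records of one subject.
#' @return A data.frame with columns `prob`, `pref` (mean of the first
#'   stable pair; `NA` when never stable), `stable`, `n_sessions`.
#' @export
pdt_preferences <- function(trials) {
  trials <- trials[trials$task == "PDT", , drop = FALSE]
  if (nrow(trials) == 0L) stop("no PDT trials")
  probs <- sort(unique(trials$session_prob), decreasing = TRUE)
  out <- lapply(probs, function(p) {
    tp <- trials[trials$session_prob == p, , drop = FALSE]
    sess <- split(tp, tp$session_id)
    sess <- sess[order(names(sess))]
    prefs <- vapply(sess, function(tr) 100 * mean(tr$option == "NP5"),
                    numeric(1))
    st <- pdt_stability(unname(prefs),
                        if (p == 1) "training" else "testing")
    data.frame(prob = p, pref = st$mean, stable = st$stable,
               n_sessions = length(sess))
  })
  do.call(rbind, out)
}

#' Discounting area under the curve over the odds transform
#'
#' Preferences are normalized to the training (P = 1) preference and plotted
#' against odds `(1/P) - 1` rescaled to `[0, 1]` by the maximum odds; the
#' AUC is the trapezoidal integral of that curve, so a curve flat at the
#' training preference has AUC exactly 1.
#'
#' @param pref_by_prob Preferences (% large-reward choices) per probability.
#' @param training_pref Preference at P = 1; must be positive.
#' @param probabilities Probabilities matching `pref_by_prob`; the P = 1
#'   anchor (odds 0, normalized preference 1) is added if absent.
#' @return The AUC (dimensionless, >= 0).
#' @examples
#' discounting_auc(25, 50, probabilities = 0.5)  # 0.75
#' @export
discounting_auc <- function(pref_by_prob, training_pref,
                            probabilities = c(0.33, 0.20, 0.14, 0.09)) {
  if (!is.finite(training_pref) || training_pref <= 0)
    stop("training preference must be positive")
  stopifnot(length(pref_by_prob) == length(probabilities))
  if (!any(probabilities == 1)) {
    probabilities <- c(1, probabilities)
    pref_by_prob <- c(training_pref, pref_by_prob)
  }
  if (anyNA(pref_by_prob)) return(NA_real_)
  odds <- 1 / probabilities - 1
  ord <- order(odds)
  x <- odds[ord] / max(odds)
  y <- pref_by_prob[ord] / training_pref
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Full PDT result for one subject
#'
#' @param trials PDT trial records of one subject.
#' @return A list with `preferences` (the [pdt_preferences()] table),
#'   `odds`, `training_pref` and `auc` (`NA` when any level never reached
#'   stability).
#' @export
pdt_result <- function(trials) {
  prefs <- pdt_preferences(trials)
  training <- prefs$pref[prefs$prob == 1]
  testing <- prefs[prefs$prob < 1, , drop = FALSE]
  auc <- if (length(training) == 1L && is.finite(training) && training > 0)
    discounting_auc(testing$pref, training, testing$prob)
  else NA_real_
  list(preferences = prefs, odds = 1 / prefs$prob - 1,
       training_pref = if (length(training)) training else NA_real_,
       auc = auc)
}

#' Social-recognition ratios
#'
#' Social preference is the ratio of interaction time in the first encounter
#' to habituation (E1/Hab); short-term social recognition memory is the
#' ratio of the first to the third encounter (E1/E3). A ratio near 1 for
#' E1/E3 is the no-recognition signature. Zero denominators give `NA`.
#'
#' @param durations A data.frame with columns `hab`, `e1`, `e3` (and
#'   optionally `subject_id`, `e2`).
#' @return The input with `sp_ratio` and `stm_ratio` columns added.
#' @export
srt_ratios <- function(durations) {
  stopifnot(all(c("hab", "e1", "e3") %in% names(durations)))
  if (any(durations[c("hab", "e1", "e3")] < 0, na.rm = TRUE))
    stop("interaction durations must be >= 0")
  sp <- ifelse(durations$hab > 0, durations$e1 / durations$hab, NA_real_)
  stm <- ifelse(durations$e3 > 0, durations$e1 / durations$e3, NA_real_)
  if (anyNA(sp) || anyNA(stm))
    warning("zero denominator(s); ratios flagged missing")
  durations$sp_ratio <- sp
  durations$stm_ratio <- stm
  durations
}

#' Social-odor preference
#'
#' Percentage of dish-interaction time spent at the used (social) bedding.
#'
#' @param used_s,fresh_s Interaction seconds with used and fresh bedding.
#' @return Percentage in `[0, 100]`.
#' @export
odor_preference <- function(used_s, fresh_s) {
  if (any(used_s < 0 | fresh_s < 0)) stop("durations must be >= 0")
  tot <- used_s + fresh_s
  if (any(tot == 0)) stop("total interaction time must be positive")
  100 * used_s / tot
}

#' Batch-wise normalization of neurochemistry
#'
#' Normalizes each analyte per batch to the mean of the control
#' (`Tph2-wt`) subjects of that batch, expressed as a percentage (controls
#' average exactly 100 per batch by construction), and adds the
#' 5-HIAA/tryptophan ratio computed on raw values.
#'
#' @param records Data.frame with columns `batch_id`, `treatment` and the
#'   raw analytes `fiveht`, `fivehiaa`, `trp`.
#' @param control Treatment label of the control arm.
#' @return The input with `normalized_5ht`, `normalized_5hiaa`,
#'   `normalized_trp` and `hiaa_trp_ratio` columns added.
#' @export
normalize_neurochem <- function(records, control = "Tph2-wt") {
  need <- c("batch_id", "treatment", "fiveht", "fivehiaa", "trp")
  stopifnot(all(need %in% names(records)))
  if (any(records[c("fiveht", "fivehiaa", "trp")] <= 0, na.rm = TRUE))
    stop("raw neurochemistry values must be positive")
  out <- records
  map <- c(fiveht = "normalized_5ht", fivehiaa = "normalized_5hiaa",
           trp = "normalized_trp")
  for (a in names(map)) {
    ctrl_means <- tapply(records[[a]][records$treatment == control],
                         records$batch_id[records$treatment == control],
                         mean)
    if (!all(unique(records$batch_id) %in% names(ctrl_means)))
      stop("every batch must contain at least one control subject")
    out[[map[[a]]]] <- 100 * records[[a]] / ctrl_means[records$batch_id]
  }
  out$hiaa_trp_ratio <- records$fivehiaa / records$trp
  rownames(out) <- NULL
  out
}

#' Exclude high-serotonin outliers
#'
#' Removes subjects whose normalized 5-HT strictly exceeds the mean + 2
#' standard deviations of their treatment arm (a value exactly at the bound
#' is kept). Arms with fewer than 3 subjects are left untouched with a
#' warning.
#'
#' @param records Data.frame with `normalized_5ht` and `treatment` columns.
#' @return A list with `kept`, `excluded` (data.frames) and `log`
#'   (character, one entry per exclusion).
#' @export
exclude_5ht_outliers <- function(records) {
  stopifnot(all(c("normalized_5ht", "treatment") %in% names(records)))
  drop <- logical(nrow(records))
  log <- character(0)
  for (arm in unique(records$treatment)) {
    sel <- records$treatment == arm
    if (sum(sel) < 3L) {
      warning("arm '", arm, "' has fewer than 3 subjects; no exclusion applied")
      next
    }
    v <- records$normalized_5ht[sel]
    lim <- mean(v) + 2 * stats::sd(v)
    out <- sel & records$normalized_5ht > lim
    drop <- drop | out
    if (any(out))
      log <- c(log, sprintf(
        "excluded %s (arm %s): normalized 5-HT %.1f > mean+2sd = %.1f",
        records$subject_id[out], arm, records$normalized_5ht[out], lim))
  }
  list(kept = records[!drop, , drop = FALSE],
       excluded = records[drop, , drop = FALSE],
       log = log)
}

#' Score a full cohort
#'
#' Runs every behavioral score over a generated (or loaded) cohort and
#' returns one row per subject: RGT score, decision-maker class, mean
#' magazine latency, flexibility score and class, discounting AUC, social
#' ratios, odor preference and batch-normalized neurochemistry. Also sets
#' `phenotype_called` on the subjects table.
#'
#' @param cohort An `rgt_cohort` (or a list with `subjects`, `trials`,
#'   `srt`, `neurochem` data.frames).
#' @return A list with `scores` (one row per subject) and `subjects` (with
#'   `phenotype_called` filled in).
#' @export
score_cohort <- function(cohort) {
  subjects <- cohort$subjects
  trials <- cohort$trials
  n <- nrow(subjects)

  scores <- data.frame(subject_id = subjects$subject_id,
                       rgt_score = NA_real_, dm_class = NA_character_,
                       mean_latency = NA_real_,
                       flex_score = NA_real_, flex_class = NA_character_,
                       auc = NA_real_,
                       sp_ratio = NA_real_, stm_ratio = NA_real_,
                       odor_pref = NA_real_,
                       normalized_5ht = NA_real_,
                       normalized_5hiaa = NA_real_,
                       normalized_trp = NA_real_,
                       hiaa_trp_ratio = NA_real_,
                       stringsAsFactors = FALSE)

  if (!is.null(trials) && nrow(trials)) {
    tr_by_subj <- split(trials, trials$subject_id)
    for (i in seq_len(n)) {
      tr <- tr_by_subj[[subjects$subject_id[i]]]
      if (is.null(tr)) next
      rgt <- tr[tr$task == "RGT", , drop = FALSE]
      rev <- tr[tr$task == "REV", , drop = FALSE]
      pdt <- tr[tr$task == "PDT", , drop = FALSE]
      if (nrow(rgt)) {
        r <- rgt_result(rgt)
        scores$rgt_score[i] <- r$rgt_score
        scores$dm_class[i] <- r$dm_class
        scores$mean_latency[i] <- r$mean_latency
      }
      if (nrow(rgt) && nrow(rev)) {
        f <- suppressWarnings(flexibility_score(rgt, rev))
        scores$flex_score[i] <- f$flex_score
        scores$flex_class[i] <- f$flex_class
      }
      if (nrow(pdt)) scores$auc[i] <- pdt_result(pdt)$auc
    }
  }

  if (!is.null(cohort$srt) && nrow(cohort$srt)) {
    sr <- srt_ratios(cohort$srt)
    j <- match(scores$subject_id, sr$subject_id)
    scores$sp_ratio <- sr$sp_ratio[j]
    scores$stm_ratio <- sr$stm_ratio[j]
    if (all(c("odor_used", "odor_fresh") %in% names(sr)))
      scores$odor_pref <- odor_preference(sr$odor_used, sr$odor_fresh)[j]
  }

  if (!is.null(cohort$neurochem) && nrow(cohort$neurochem)) {
    nn <- normalize_neurochem(cohort$neurochem)
    j <- match(scores$subject_id, nn$subject_id)
    scores$normalized_5ht <- nn$normalized_5ht[j]
    scores$normalized_5hiaa <- nn$normalized_5hiaa[j]
    scores$normalized_trp <- nn$normalized_trp[j]
    scores$hiaa_trp_ratio <- nn$hiaa_trp_ratio[j]
  }

  subjects$phenotype_called <- scores$dm_class[
    match(subjects$subject_id, scores$subject_id)]
  list(scores = scores, subjects = subjects)
}
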