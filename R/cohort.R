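#' Configuration of a synthetic behavioral cohort
#'
#' Collects every tunable of the synthetic-cohort generator. Defaults encode
#' the study design being emulated: 60 control (`Tph2-wt`) and 58 knockdown
#' (`Tph2-kd`) subjects with decision-maker phenotype counts 49/8/3 and
#' 39/10/9 (GDM/INT/PDM), batches of 12 animals (6 per arm), knockdown
#' neurochemistry effects of -21% (5-HT) and -25% (5-HIAA) with a 23
#' percentage-point per-subject spread and no effect on tryptophan, a social
#' preference factor of 2.5 with short-term memory ratio targets of 2.0
#' (control-like) and 1.0 (knockdown PDM, the no-recognition signature), and
#' the agent parameterizations of [phenotype_agent()].
#'
#' @param n_wt,n_kd Group sizes.
#' @param phenotype_counts Named list `wt`/`kd` of GDM/INT/PDM counts; each
#'   must sum to its group size.
#' @param batch_size Animals per batch (half per arm).
#' @param tasks Character subset of `c("RGT", "REV", "PDT")`; which operant
#'   tasks to simulate (trial generation dominates runtime).
#' @param kd_effects Multiplicative knockdown effects on raw neurochemistry
#'   (0 = none, -0.21 = 21% decrease).
#' @param neuro_subject_sd Per-subject multiplicative sd of raw
#'   neurochemistry (fraction scale; 0.23 = 23 percentage points after
#'   normalization).
#' @param batch_sd Lognormal sd of the per-batch, per-analyte multiplier.
#' @param neuro_baseline Raw baseline concentrations (arbitrary units per
#'   wet tissue weight).
#' @param sp_factor Median multiplicative increase of interaction time from
#'   habituation to the first encounter.
#' @param stm_targets Median E1/E3 ratios for `default` and `kd_pdm`
#'   subjects.
#' @param odor_pref_mean Mean preference for the social odor (0-1 scale).
#' @param pdt_base Large-reward preference at P = 1.
#' @param pdt_k Hyperbolic discounting constants over odds for `default`
#'   and `kd_pdm` subjects (larger = steeper discounting).
#' @param flex_means Mean probability of tracking the previously preferred
#'   option to its new location in the reversed task, per phenotype.
#' @param agents Named list of [agent_params] per phenotype.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(
    n_wt = 60L, n_kd = 58L,
    phenotype_counts = list(wt = c(GDM = 49L, INT = 8L, PDM = 3L),
                            kd = c(GDM = 39L, INT = 10L, PDM = 9L)),
    batch_size = 12L,
    tasks = c("RGT", "REV", "PDT"),
    kd_effects = c(fiveht = -0.21, fivehiaa = -0.25, trp = 0),
    neuro_subject_sd = 0.23,
    batch_sd = 0.15,
    neuro_baseline = c(fiveht = 0.45, fivehiaa = 0.30, trp = 3.2),
    sp_factor = 2.5,
    stm_targets = c(default = 2.0, kd_pdm = 1.0),
    odor_pref_mean = 0.65,
    pdt_base = 0.9,
    pdt_k = c(default = 0.08, kd_pdm = 0.35),
    flex_means = c(GDM = 0.55, INT = 0.50, PDM = 0.30),
    agents = list(GDM = phenotype_agent("GDM"),
                  INT = phenotype_agent("INT"),
                  PDM = phenotype_agent("PDM"))) {
  cfg <- as.list(environment())
  if (sum(cfg$phenotype_counts$wt) != cfg$n_wt ||
      sum(cfg$phenotype_counts$kd) != cfg$n_kd)
    stop("phenotype counts must sum to the group sizes")
  stopifnot(all(cfg$tasks %in% c("RGT", "REV", "PDT")),
            cfg$batch_size >= 2L, cfg$batch_size %% 2L == 0L)
  class(cfg) <- "cohort_config"
  cfg
}

# deterministic per-subject substream seeds: reproducible and stable under
# changes to the number of subjects (seeds depend only on (seed, index))
.substream <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(index)) %% 2147483629) + 1L
}

#' Generate a synthetic cohort
#'
#' Produces the four tables the downstream stages consume: subject metadata,
#' trial-level operant logs (RGT, reversed-RGT and PDT), social-recognition
#' interaction durations (plus odor-discrimination durations) and raw
#' neurochemistry. All randomness derives from `seed` through per-subject
#' substreams, so identical configuration and seed give identical tables.
#'
#' Structure emulated: phenotype-matched choice agents for the RGT; a
#' per-subject flexibility propensity for the reversed task; hyperbolic
#' discounting of the large-reward preference over odds for the PDT (steeper
#' for knockdown PDM subjects); interaction durations with E1 > Hab for all
#' subjects and E3 below E1 except for knockdown PDM subjects (E3 ~ E1); and
#' batch-structured neurochemistry with multiplicative knockdown effects on
#' 5-HT and 5-HIAA but not tryptophan.
#'
#' @param config A [cohort_config].
#' @param seed Integer seed (mandatory: the generator is a reproducibility
#'   contract).
#' @return A list of class `rgt_cohort` with data.frames `subjects`,
#'   `trials`, `srt`, `neurochem`.
#' @export
generate_cohort <- function(config = cohort_config(), seed) {
  stopifnot(inherits(config, "cohort_config"))
  seed <- as.integer(seed)

  subjects <- .make_subjects(config, seed)
  n <- nrow(subjects)

  trials <- vector("list", n)
  srt <- vector("list", n)
  for (i in seq_len(n)) {
    s <- subjects[i, ]
    trials[[i]] <- .subject_trials(s, config, .substream(seed, 3L * i))
    srt[[i]] <- .subject_srt(s, config, .substream(seed, 3L * i + 1L))
  }
  neuro <- .make_neurochem(subjects, config, .substream(seed, 2L))

  structure(
    list(subjects = subjects,
         trials = do.call(rbind, trials),
         srt = do.call(rbind, srt),
         neurochem = neuro,
         seed = seed),
    class = "rgt_cohort")
}

.make_subjects <- function(config, seed) {
  set.seed(.substream(seed, 1L))
  arms <- c(rep("Tph2-wt", config$n_wt), rep("Tph2-kd", config$n_kd))
  phen <- c(
    sample(rep(names(config$phenotype_counts$wt), config$phenotype_counts$wt)),
    sample(rep(names(config$phenotype_counts$kd), config$phenotype_counts$kd)))
  # interleave arms so every batch holds batch_size/2 subjects per arm
  half <- config$batch_size / 2L
  ord <- order(c(seq_len(config$n_wt), seq_len(config$n_kd)), arms)
  arms <- arms[ord]; phen <- phen[ord]
  n <- length(arms)
  data.frame(
    subject_id = sprintf("R%03d", seq_len(n)),
    treatment = arms,
    batch_id = sprintf("B%02d", (seq_len(n) - 1L) %/% config$batch_size + 1L),
    phenotype_truth = phen,
    adv_side = sample(c("left", "right"), n, replace = TRUE),
    stringsAsFactors = FALSE)
}

.subject_trials <- function(s, config, seed) {
  set.seed(seed)
  out <- list()
  agent <- config$agents[[s$phenotype_truth]]
  is_kd_pdm <- s$treatment == "Tph2-kd" && s$phenotype_truth == "PDM"

  if ("RGT" %in% config$tasks) {
    out$rgt <- run_session(make_rgt_schedule(), agent,
                           subject_id = s$subject_id, session_id = "RGT_1",
                           task = "RGT", adv_side = s$adv_side)
  }
  if ("REV" %in% config$tasks) {
    # probability of following the previously preferred *option* to its new
    # location; the flexibility score is computed from sides by the scorer
    fl <- stats::rbeta(1, config$flex_means[[s$phenotype_truth]] * 8,
                       (1 - config$flex_means[[s$phenotype_truth]]) * 8)
    rev_target <- if (agent$target_pref >= 0.5) fl else 1 - fl
    rev_agent <- agent_params(
      initial_pref = 0.5, target_pref = rev_target, drift_rate = 0.15,
      choice_noise = agent$choice_noise, handling_time = agent$handling_time,
      latency_meanlog = agent$latency_meanlog,
      latency_sdlog = agent$latency_sdlog)
    out$rev <- run_session(make_rgt_schedule(), rev_agent,
                           subject_id = s$subject_id, session_id = "REV_1",
                           task = "REV", adv_side = s$adv_side,
                           swap_sides = TRUE)
  }
  if ("PDT" %in% config$tasks) {
    k <- if (is_kd_pdm) config$pdt_k[["kd_pdm"]] else config$pdt_k[["default"]]
    out$pdt <- .pdt_sessions(s, config, k)
  }
  do.call(rbind, out)
}

# simulate PDT sessions per probability level until the stability rule is
# met (training: both >= 70 and <= 15 pp apart; testing: <= 10 pp apart)
.pdt_sessions <- function(s, config, k) {
  probs <- c(1, 0.33, 0.20, 0.14, 0.09)
  res <- list()
  for (p in probs) {
    odds <- 1 / p - 1
    target <- min(0.95, max(0.05, config$pdt_base / (1 + k * odds)))
    agent <- agent_params(initial_pref = target, target_pref = target,
                          drift_rate = 0, choice_noise = 0.05,
                          handling_time = 20,
                          latency_meanlog = log(1.5), latency_sdlog = 0.4)
    phase <- if (p == 1) "training" else "testing"
    prefs <- numeric(0); sess <- list()
    for (rep in 1:6) {
      tr <- run_session(make_pdt_schedule(p), agent,
                        subject_id = s$subject_id,
                        session_id = sprintf("PDT_p%03.0f_s%d", 100 * p, rep),
                        task = "PDT")
      sess[[rep]] <- tr
      np5 <- tr$option == "NP5"
      prefs <- c(prefs, 100 * mean(np5))
      if (pdt_stability(prefs, phase)$stable) break
    }
    res[[as.character(p)]] <- do.call(rbind, sess)
  }
  do.call(rbind, res)
}

.subject_srt <- function(s, config, seed) {
  set.seed(seed)
  is_kd_pdm <- s$treatment == "Tph2-kd" && s$phenotype_truth == "PDM"
  stm_target <- if (is_kd_pdm) config$stm_targets[["kd_pdm"]]
                else config$stm_targets[["default"]]
  hab <- stats::rgamma(1, shape = 16, rate = 0.8)           # median ~20 s
  spf <- stats::rlnorm(1, log(config$sp_factor), 0.25)      # E1/Hab factor
  e1 <- hab * spf
  stm <- stats::rlnorm(1, log(stm_target), 0.20)            # E1/E3 factor
  e3 <- e1 / stm
  e2 <- e1 / sqrt(stm) * stats::rlnorm(1, 0, 0.10)
  total <- stats::rgamma(1, shape = 16, rate = 0.4)         # odor dish time
  pref <- stats::rbeta(1, config$odor_pref_mean * 20,
                       (1 - config$odor_pref_mean) * 20)
  data.frame(subject_id = s$subject_id,
             hab = hab, e1 = e1, e2 = e2, e3 = e3,
             odor_used = total * pref, odor_fresh = total * (1 - pref),
             stringsAsFactors = FALSE)
}

.make_neurochem <- function(subjects, config, seed) {
  set.seed(seed)
  analytes <- c("fiveht", "fivehiaa", "trp")
  batches <- unique(subjects$batch_id)
  bmult <- matrix(stats::rlnorm(length(batches) * 3, 0, config$batch_sd),
                  nrow = length(batches),
                  dimnames = list(batches, analytes))
  n <- nrow(subjects)
  vals <- matrix(NA_real_, n, 3, dimnames = list(NULL, analytes))
  for (a in analytes) {
    eff <- ifelse(subjects$treatment == "Tph2-kd",
                  1 + config$kd_effects[[a]], 1)
    mult <- stats::rnorm(n, eff, config$neuro_subject_sd)
    mult <- pmax(mult, 0.05)                         # raw values stay positive
    vals[, a] <- config$neuro_baseline[[a]] * bmult[subjects$batch_id, a] * mult
  }
  data.frame(subject_id = subjects$subject_id,
             batch_id = subjects$batch_id,
             treatment = subjects$treatment,
             fiveht = vals[, "fiveht"], fivehiaa = vals[, "fivehiaa"],
             trp = vals[, "trp"], stringsAsFactors = FALSE)
}

#' @export
print.rgt_cohort <- function(x, ...) {
  cat("<rgt_cohort>", nrow(x$subjects), "subjects,",
      if (is.null(x$trials)) 0L else nrow(x$trials), "trials (seed",
      paste0(x$seed, ")\n"))
  print(table(x$subjects$treatment, x$subjects$phenotype_truth))
  invisible(x)
}
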