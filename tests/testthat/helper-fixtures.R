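# hand-built trial tables for scoring tests: one row per choice at the
# given times, options/sides recycled
make_trials <- function(t_choice, option, side = NULL, task = "RGT",
                        pellets = NULL, latency = 1,
                        subject_id = "S1", session_id = "s1",
                        session_prob = NA_real_) {
  n <- length(t_choice)
  option <- rep_len(option, n)
  if (is.null(side)) side <- ifelse(option %in% c("ADV", "NP5"), "left", "right")
  if (is.null(pellets)) pellets <- ifelse(option %in% c("ADV", "NP1"), 1L, 2L)
  data.frame(subject_id = subject_id, session_id = session_id, task = task,
             t_choice = t_choice, option = option, side = rep_len(side, n),
             pellets = rep_len(pellets, n), timeout = 0,
             magazine_latency = rep_len(latency, n),
             session_prob = session_prob, stringsAsFactors = FALSE)
}

# pure (deterministic) agents for the degenerate-policy examples
greedy_agent <- function(pref, ...) {
  agent_params(initial_pref = pref, target_pref = pref, drift_rate = 0,
               choice_noise = 0, ...)
}

# small balanced split-plot data set for ANOVA tests
split_plot_data <- function(n_subj = 24, n_within = 3, seed = 1,
                            trt_effect = 0, within_effect = 0) {
  set.seed(seed)
  d <- expand.grid(subject = factor(sprintf("s%02d", seq_len(n_subj))),
                   w = factor(paste0("w", seq_len(n_within))))
  trt <- factor(rep(c("A", "B"), each = n_subj / 2))
  d$trt <- trt[match(d$subject, levels(d$subject))]
  d$y <- stats::rnorm(nrow(d), sd = 1) +
    stats::rnorm(n_subj)[as.integer(d$subject)] +   # subject random effect
    (d$trt == "B") * trt_effect +
    (d$w == levels(d$w)[2]) * within_effect
  d
}

# random 2x2 count table with total at most n_max and positive margins
random_2x2 <- function(n_max = 200) {
  repeat {
    n <- sample(4:n_max, 1)
    tb <- matrix(stats::rmultinom(1, n, prob = stats::runif(4, 0.05, 1)), 2)
    if (all(rowSums(tb) > 0) && all(colSums(tb) > 0)) return(tb)
  }
}
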