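#' Stochastic choice agents for operant session simulation
#'
#' An agent is a minimal generative stand-in for a rat in an operant session.
#' Its probability of choosing the focal option (the first option of the
#' schedule: the advantageous option in the RGT, the large-reward hole in the
#' PDT) starts at `initial_pref` and drifts geometrically toward
#' `target_pref` by `drift_rate` after every choice, so preference
#' trajectories reproduce the rising / flat / falling shapes seen in
#' gambling-task preference curves. With probability `choice_noise` a choice
#' is instead uniform over the nose-poke holes (a lapse). Magazine latencies
#' after rewarded choices are lognormal.
#'
#' @param initial_pref Probability of choosing the focal option at the first
#'   trial, in `[0,1]`.
#' @param target_pref Asymptotic focal-option probability, in `[0,1]`.
#' @param drift_rate Per-choice geometric drift constant in `[0,1]`;
#'   `p <- p + drift_rate * (target_pref - p)` after each choice.
#' @param choice_noise Lapse probability of a uniform random choice.
#' @param handling_time Seconds consumed per choice cycle on top of latency
#'   and time-out (approach, double nose-poke, magazine visit).
#' @param latency_meanlog,latency_sdlog Lognormal parameters of the magazine
#'   latency, in log-seconds.
#' @return An object of class `agent_params`.
#' @examples
#' agent_params(target_pref = 0.85)
#' @export
agent_params <- function(initial_pref = 0.5, target_pref = 0.5,
                         drift_rate = 0.2, choice_noise = 0.05,
                         handling_time = 15,
                         latency_meanlog = log(2), latency_sdlog = 0.5) {
  p <- c(initial_pref, target_pref, drift_rate, choice_noise)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("initial_pref, target_pref, drift_rate and choice_noise must lie in [0,1]")
  if (!is.finite(handling_time) || handling_time <= 0)
    stop("handling_time must be positive")
  if (!is.finite(latency_meanlog) || !is.finite(latency_sdlog) ||
      latency_sdlog < 0)
    stop("latency parameters must be finite")
  structure(
    list(initial_pref = initial_pref, target_pref = target_pref,
         drift_rate = drift_rate, choice_noise = choice_noise,
         handling_time = handling_time, latency_meanlog = latency_meanlog,
         latency_sdlog = latency_sdlog),
    class = "agent_params")
}

#' Default agent parameterizations for the decision-maker phenotypes
#'
#' Good decision makers (GDM) drift toward 85% advantageous choices, poor
#' decision makers (PDM) toward 15%, intermediates (INT) stay at 50% — the
#' class centers of the >70% / <30% classification rule. PDM magazine
#' latencies are shorter (median 1.2 s vs 2 s), reflecting the
#' reward-hypersensitivity of that phenotype; the direction is a
#' configurable modeling choice.
#'
#' @param phenotype One of `"GDM"`, `"INT"`, `"PDM"`.
#' @param ... Overrides passed to [agent_params()].
#' @return An `agent_params` object.
#' @export
phenotype_agent <- function(phenotype = c("GDM", "INT", "PDM"), ...) {
  phenotype <- match.arg(phenotype)
  base <- switch(phenotype,
    GDM = list(target_pref = 0.85, latency_meanlog = log(2)),
    INT = list(target_pref = 0.50, latency_meanlog = log(2)),
    PDM = list(target_pref = 0.15, latency_meanlog = log(1.2)))
  args <- utils::modifyList(base, list(...))
  do.call(agent_params, args)
}

#' Simulate one operant session as a trial-level event log
#'
#' Event-driven simulation of a single session under a [task
#' schedule][make_rgt_schedule]. Each cycle is: choice (lapse or
#' preference-driven), pellet delivery (certain or probabilistic), magazine
#' latency if rewarded, sampled time-out, then the next choice. The session
#' clock never exceeds the schedule's duration and the output is
#' deterministic given `seed`.
#'
#' The physical `side` of each choice is recorded so that location-based
#' scores (the reversed-RGT flexibility score) can be computed: in the RGT
#' the focal option sits on `adv_side`; passing `swap_sides = TRUE`
#' simulates the reversed task in which the two options exchange locations.
#'
#' @param schedule A `task_schedule`.
#' @param agent An `agent_params` object.
#' @param seed Integer seed; if `NULL` the current RNG stream is used.
#' @param subject_id,session_id Identifiers copied into every record.
#' @param task Task label for the records; defaults to the schedule's task.
#' @param adv_side Side carrying the focal option in the un-reversed layout.
#' @param swap_sides Logical; exchange the options' locations (reversed-RGT).
#' @return A data.frame of trial records with columns `subject_id`,
#'   `session_id`, `task`, `t_choice`, `option`, `side`, `pellets`,
#'   `timeout`, `magazine_latency` (NA when no pellet was delivered) and
#'   `session_prob` (the scheduled payout probability of the large option;
#'   NA outside the PDT).
#' @examples
#' trials <- run_session(make_rgt_schedule(),
#'                       agent_params(target_pref = 1, choice_noise = 0),
#'                       seed = 1)
#' table(trials$option)
#' @export
run_session <- function(schedule, agent, seed = NULL,
                        subject_id = "S1", session_id = "s1",
                        task = schedule$task,
                        adv_side = "left", swap_sides = FALSE) {
  stopifnot(inherits(schedule, "task_schedule"), inherits(agent, "agent_params"))
  if (!is.null(seed)) set.seed(as.integer(seed))

  focal <- schedule$options[1L]
  other <- schedule$options[2L]
  other_side <- if (adv_side == "left") "right" else "left"
  side_of <- c(adv_side, other_side)
  names(side_of) <- c(focal, other)
  if (swap_sides) side_of[] <- rev(side_of)

  session_prob <- if (identical(schedule$task, "PDT"))
    schedule$payout_prob[[focal]] else NA_real_

  dur <- schedule$session_duration
  cap <- min(schedule$max_trials, ceiling(dur / agent$handling_time) + 1L)
  opt <- character(cap); tch <- numeric(cap); pel <- integer(cap)
  tout <- numeric(cap); lat <- numeric(cap)

  p <- agent$initial_pref
  t <- 0; k <- 0L
  while (t < dur && k < schedule$max_trials) {
    k <- k + 1L
    choice <- if (stats::runif(1) < agent$choice_noise) {
      # lapse: uniform over holes; holes are balanced across options
      sample(schedule$options, 1L)
    } else if (stats::runif(1) < p) focal else other

    pay <- schedule$option_payouts[[choice]]
    if (stats::runif(1) >= schedule$payout_prob[[choice]]) pay <- 0L

    latency <- if (pay > 0)
      stats::rlnorm(1, agent$latency_meanlog, agent$latency_sdlog)
    else NA_real_

    menu <- schedule$timeout_menu[[choice]]
    to <- 0
    if (nrow(menu) > 0L) {
      u <- stats::runif(1); cum <- cumsum(menu$probability)
      hit <- which(u < cum)
      if (length(hit)) to <- menu$duration[hit[1L]]
    }

    opt[k] <- choice; tch[k] <- t; pel[k] <- pay
    tout[k] <- to; lat[k] <- latency

    p <- p + agent$drift_rate * (agent$target_pref - p)
    t <- t + agent$handling_time + (if (is.na(latency)) 0 else latency) + to
  }

  idx <- seq_len(k)
  data.frame(
    subject_id = subject_id, session_id = session_id, task = task,
    t_choice = tch[idx], option = opt[idx],
    side = unname(side_of[opt[idx]]), pellets = pel[idx],
    timeout = tout[idx], magazine_latency = lat[idx],
    session_prob = session_prob, stringsAsFactors = FALSE)
}

#' @export
print.agent_params <- function(x, ...) {
  cat(sprintf(
    "<agent_params> pref %.2f -> %.2f (drift %.2f), lapse %.2f, handling %.1fs\n",
    x$initial_pref, x$target_pref, x$drift_rate, x$choice_noise,
    x$handling_time))
  invisible(x)
}
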