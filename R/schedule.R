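#' Task schedules for operant decision-making sessions
#'
#' A task schedule describes the reward contingencies of an operant session:
#' the pellet payout of each option, the (possibly stochastic) payout
#' probability, the time-out menu attached to each option, the session length
#' and the number of nose-poke holes per option.
#'
#' `make_rgt_schedule()` returns the gambling-task contingencies: an
#' advantageous option paying 1 pellet with short unpredictable time-outs
#' (6 s at probability 1/2, 12 s at 1/4, none otherwise) and a
#' disadvantageous option paying 2 pellets with long unpredictable time-outs
#' (222 s at 1/2, 444 s at 1/4, none otherwise), over a 60-min session.
#' Because of the long penalties, the small-reward option maximizes the
#' pellet yield over the hour. The residual 1/4 probability mass of each
#' time-out menu is "no time-out" (0 s).
#'
#' `make_pdt_schedule()` returns the probability-discounting contingencies:
#' a certain small option (`NP1`, 1 pellet) against a large uncertain option
#' (`NP5`, 5 pellets delivered with probability `p_large`). There are no
#' time-outs; sessions end at `session_duration` or after `max_trials`
#' choices, whichever comes first.
#'
#' @param session_duration Session length in seconds.
#' @param p_large Probability that the large option actually pays out.
#' @param max_trials Maximum number of choices in a PDT session.
#' @return An object of class `task_schedule`: a list with elements
#'   `options` (focal option first), `option_payouts`, `payout_prob`,
#'   `timeout_menu`, `session_duration`, `n_holes_per_option`, `max_trials`
#'   and `task`.
#' @examples
#' sch <- make_rgt_schedule()
#' expected_timeout(sch, "ADV")  # 6 s
#' expected_timeout(sch, "DIS")  # 222 s
#' @export
make_rgt_schedule <- function(session_duration = 3600) {
  new_task_schedule(
    task = "RGT",
    options = c("ADV", "DIS"),
    option_payouts = c(ADV = 1L, DIS = 2L),
    payout_prob = c(ADV = 1, DIS = 1),
    timeout_menu = list(
      ADV = data.frame(duration = c(6, 12), probability = c(0.5, 0.25)),
      DIS = data.frame(duration = c(222, 444), probability = c(0.5, 0.25))
    ),
    session_duration = session_duration,
    n_holes_per_option = 2L,
    max_trials = Inf
  )
}

#' @rdname make_rgt_schedule
#' @export
make_pdt_schedule <- function(p_large, session_duration = 1800,
                              max_trials = 80) {
  stopifnot(is.numeric(p_large), length(p_large) == 1L,
            p_large > 0, p_large <= 1)
  new_task_schedule(
    task = "PDT",
    options = c("NP5", "NP1"),
    option_payouts = c(NP5 = 5L, NP1 = 1L),
    payout_prob = c(NP5 = p_large, NP1 = 1),
    timeout_menu = list(
      NP5 = data.frame(duration = numeric(0), probability = numeric(0)),
      NP1 = data.frame(duration = numeric(0), probability = numeric(0))
    ),
    session_duration = session_duration,
    n_holes_per_option = 1L,
    max_trials = max_trials
  )
}

new_task_schedule <- function(task, options, option_payouts, payout_prob,
                              timeout_menu, session_duration,
                              n_holes_per_option, max_trials) {
  stopifnot(session_duration > 0, n_holes_per_option >= 1)
  if (any(option_payouts < 0)) stop("pellet payouts must be >= 0")
  for (opt in options) {
    menu <- timeout_menu[[opt]]
    if (any(menu$duration < 0)) stop("time-out durations must be >= 0")
    if (any(menu$probability < 0) || sum(menu$probability) > 1 + 1e-12)
      stop("time-out probabilities of option '", opt,
           "' must be >= 0 and sum to <= 1")
  }
  structure(
    list(task = task, options = options, option_payouts = option_payouts,
         payout_prob = payout_prob, timeout_menu = timeout_menu,
         session_duration = session_duration,
         n_holes_per_option = n_holes_per_option, max_trials = max_trials),
    class = "task_schedule")
}

#' Expected time-out duration of an option
#'
#' The mean of the option's time-out menu, counting the residual probability
#' mass as a 0 s (no) time-out.
#'
#' @param schedule A `task_schedule`.
#' @param option Option identifier, e.g. `"ADV"`.
#' @return Expected time-out in seconds.
#' @export
expected_timeout <- function(schedule, option) {
  stopifnot(inherits(schedule, "task_schedule"),
            option %in% schedule$options)
  menu <- schedule$timeout_menu[[option]]
  if (nrow(menu) == 0L) return(0)
  sum(menu$duration * menu$probability)
}

#' Indifference probability of a discounting schedule
#'
#' The payout probability of the large option at which the expected pellet
#' yield per choice of the two options is equal. For the standard 1-pellet
#' certain vs 5-pellet probabilistic schedule this is 1/5, i.e. 20%.
#'
#' @param schedule A PDT `task_schedule`; defaults to the standard one.
#' @return Indifference probability as a percentage (0-100 scale).
#' @examples
#' pdt_indifference_probability()  # 20
#' @export
pdt_indifference_probability <- function(schedule = make_pdt_schedule(1)) {
  stopifnot(inherits(schedule, "task_schedule"))
  pay <- schedule$option_payouts
  small <- min(pay); large <- max(pay)
  if (large <= 0) stop("large payout must be positive")
  # certain small reward matches p * large at p = small/large
  100 * small / large
}

#' @export
print.task_schedule <- function(x, ...) {
  cat("<task_schedule>", x$task, "-", x$session_duration, "s\n")
  for (opt in x$options) {
    eto <- expected_timeout(x, opt)
    cat(sprintf("  %s: %d pellet(s) @ p=%.2f, E[time-out]=%.1f s\n",
                opt, x$option_payouts[[opt]], x$payout_prob[[opt]], eto))
  }
  invisible(x)
}
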