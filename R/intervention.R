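#' Intervention engine configuration
#'
#' Timing constants of the context-aware intervention state machine. All
#' durations are in seconds and strictly positive; the defaults are
#' explicit, configurable choices.
#'
#' @param posture_debounce sustained poor-posture time before a vibration
#'   fires, seconds (default 5).
#' @param sedentary_limit continuous sitting/lying time before a walk
#'   prompt fires, seconds (default 1800, i.e. 30 min).
#' @param refractory minimum spacing between two events of the same cause,
#'   seconds (default 60).
#' @return An `engine_config` list.
#' @export
engine_config <- function(posture_debounce = 5, sedentary_limit = 1800,
                          refractory = 60) {
  if (posture_debounce <= 0 || sedentary_limit <= 0 || refractory <= 0) {
    stop_belt("all engine durations must be positive")
  }
  structure(list(posture_debounce = posture_debounce,
                 sedentary_limit = sedentary_limit,
                 refractory = refractory),
            class = "engine_config")
}

#' Initial intervention engine state
#'
#' @return The engine's initial state (no streaks, no past events).
#' @export
engine_init <- function() {
  list(
    last_t = -Inf,
    poor_since = NA_real_,       # start of current sit+poor streak
    sedentary_since = NA_real_,  # start of current sit/lay streak
    last_fire = c(poor_posture = -Inf, prolonged_sedentary = -Inf)
  )
}

#' Advance the intervention state machine by one observation
#'
#' Pure transition function (no side effects, fully deterministic):
#' posture monitoring is active only while the current activity is `sit`;
#' poor posture sustained for at least `posture_debounce` seconds fires one
#' belt vibration, a sitting/lying streak of at least `sedentary_limit`
#' seconds fires one walk-prompt notification. Each cause then observes the
#' `refractory` spacing (its streak clock restarts on firing), and leaving
#' the triggering state resets its clock.
#'
#' @param state engine state from [engine_init()] or a previous step.
#' @param activity current activity label (one of [ACTIVITY_LABELS]).
#' @param posture `"good"`, `"poor"`, or `NA` when posture is not assessed.
#' @param t observation time in seconds; must exceed the previous step's.
#' @param config an [engine_config()].
#' @return List with `state` (updated) and `events` (data frame with
#'   columns `t`, `channel`, `cause`, `pattern`; zero rows when nothing
#'   fired).
#' @export
intervention_step <- function(state, activity, posture, t,
                              config = engine_config()) {
  if (t <= state$last_t) {
    stop_belt("time must be strictly increasing across steps")
  }
  state$last_t <- t
  events <- empty_events()

  # sedentary streak: continuous sit or lay_down
  if (activity %in% c("sit", "lay_down")) {
    if (is.na(state$sedentary_since)) state$sedentary_since <- t
    if (t - state$sedentary_since >= config$sedentary_limit &&
        t - state$last_fire[["prolonged_sedentary"]] >= config$refractory) {
      events <- rbind(events, data.frame(
        t = t, channel = "notification", cause = "prolonged_sedentary",
        pattern = "walk_prompt", stringsAsFactors = FALSE))
      state$last_fire[["prolonged_sedentary"]] <- t
      state$sedentary_since <- t
    }
  } else {
    state$sedentary_since <- NA_real_
  }

  # posture monitoring active only while sitting
  if (identical(activity, "sit") && identical(posture, "poor")) {
    if (is.na(state$poor_since)) state$poor_since <- t
    if (t - state$poor_since >= config$posture_debounce &&
        t - state$last_fire[["poor_posture"]] >= config$refractory) {
      events <- rbind(events, data.frame(
        t = t, channel = "vibration", cause = "poor_posture",
        pattern = "posture_buzz", stringsAsFactors = FALSE))
      state$last_fire[["poor_posture"]] <- t
      state$poor_since <- t
    }
  } else {
    state$poor_since <- NA_real_
  }

  list(state = state, events = events)
}

empty_events <- function() {
  data.frame(t = numeric(0), channel = character(0), cause = character(0),
             pattern = character(0), stringsAsFactors = FALSE)
}

#' Run the intervention engine over an aligned session
#'
#' Folds [intervention_step()] over aligned activity and posture series.
#'
#' @param t numeric vector of strictly increasing times in seconds.
#' @param activity activity label per time point.
#' @param posture `"good"` / `"poor"` / `NA` per time point (default all
#'   `NA`).
#' @param config an [engine_config()].
#' @return List with `events` (time-ordered data frame `t`, `channel`,
#'   `cause`, `pattern`) and `counts` (named event count per cause).
#' @export
run_intervention <- function(t, activity, posture = NULL,
                             config = engine_config()) {
  n <- length(t)
  if (is.null(posture)) posture <- rep(NA_character_, n)
  if (length(activity) != n || length(posture) != n) {
    stop_belt("t, activity and posture series must have equal length")
  }
  state <- engine_init()
  all_events <- vector("list", n)
  for (i in seq_len(n)) {
    res <- intervention_step(state, activity[i], posture[i], t[i], config)
    state <- res$state
    if (nrow(res$events)) all_events[[i]] <- res$events
  }
  events <- do.call(rbind, c(list(empty_events()),
                             all_events[!vapply(all_events, is.null,
                                                logical(1))]))
  counts <- table(factor(events$cause,
                         levels = c("poor_posture", "prolonged_sedentary")))
  list(events = events, counts = c(counts))
}

#' Write an intervention event log as CSV
#'
#' @param events event data frame from [run_intervention()].
#' @param path output path (`t,channel,cause,pattern` header).
#' @return `path`, invisibly.
#' @export
write_event_log <- function(events, path) {
  write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
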