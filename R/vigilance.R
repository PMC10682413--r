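#' Titrating psychomotor vigilance session engine
#'
#' Runs one 48-trial session of the titrating vigilance task. On each trial
#' the stimulus appears at one of six locations after a 15-, 30- or 45-s
#' intertrial interval; a response within the current maximum stimulus
#' duration (`limit_s`) is a hit and the limit decreases by 0.25 s on the
#' next trial, otherwise the trial is a miss and the limit increases by
#' 0.25 s. The limit is floored at 0.25 s and has no upper bound. The first
#' trial of a subject's first-ever session starts at 10 s.
#'
#' @param agent A function returning one response latency in seconds
#'   (`Inf` for no response); called once per trial.
#' @param start_limit Stimulus-duration limit on the first trial (s).
#' @param n_trials Trials per session.
#' @return A tibble of trial records (`trial`, `location`, `iti_s`,
#'   `limit_s`, `outcome`, `rt_s`) with attribute `final_limit_s`, the
#'   post-update limit carried into the next session.
#' @export
titrate_session <- function(agent, start_limit = 10, n_trials = 48) {
  stopifnot(is.function(agent), start_limit >= 0.25, n_trials >= 1)
  limit <- start_limit
  location <- sample(1:6, n_trials, replace = TRUE)
  iti_s <- sample(c(15, 30, 45), n_trials, replace = TRUE)
  limit_s <- rt_s <- numeric(n_trials)
  hit <- logical(n_trials)
  for (tr in seq_len(n_trials)) {
    lat <- agent()
    if (is.na(lat) || lat < 0) stop("agent returned a negative or missing latency")
    hit[tr] <- lat <= limit
    limit_s[tr] <- limit
    rt_s[tr] <- if (hit[tr]) lat else NA_real_
    limit <- titration_next_limit(limit, if (hit[tr]) "hit" else "miss")
  }
  out <- tibble(trial = seq_len(n_trials), location = location,
                iti_s = iti_s, limit_s = limit_s,
                outcome = ifelse(hit, "hit", "miss"), rt_s = rt_s)
  attr(out, "final_limit_s") <- limit
  out
}

# staircase update: -0.25 s on a hit, +0.25 s on a miss, floored at 0.25 s
titration_next_limit <- function(limit, outcome) {
  if (outcome == "hit") max(limit - 0.25, 0.25) else limit + 0.25
}

#' Titrated reaction time of one session
#'
#' The session metric averages the reaction time on hits and, to factor in
#' failures to respond in time, the full stimulus-duration limit on misses.
#'
#' @param records Trial records of exactly one session.
#' @return One-row tibble (`titrated_rt_s`, `hits`, `n_trials`,
#'   `final_limit_s`).
#' @export
titrated_reaction_time <- function(records) {
  if (is.null(records) || nrow(records) == 0) stop("empty trial record list")
  vals <- ifelse(records$outcome == "hit", records$rt_s, records$limit_s)
  last <- nrow(records)
  tibble(
    titrated_rt_s = mean(vals),
    hits = sum(records$outcome == "hit"),
    n_trials = last,
    final_limit_s = titration_next_limit(records$limit_s[last],
                                         records$outcome[last])
  )
}

#' Per-subject per-session summaries of a vigilance trial table
#'
#' @param trials Trial-level tibble as from [run_vigilance_cohort()].
#' @return Tibble (`subject`, `group`, `session`, `titrated_rt_s`, `hits`,
#'   `final_limit_s`).
#' @export
vigilance_session_summaries <- function(trials) {
  trials %>%
    group_by(.data$subject, .data$group, .data$session) %>%
    group_modify(~ titrated_reaction_time(.x)) %>%
    ungroup()
}

#' Two-way ANOVA on titrated reaction times
#'
#' Treatment x session fixed-effects ANOVA on the per-session titrated
#' reaction times, with subjects as replicates, followed by per-session
#' Tukey HSD contrasts between groups when the treatment omnibus test is
#' significant.
#'
#' @param summaries Tibble from [vigilance_session_summaries()].
#' @param alpha Omnibus significance level gating the post-hoc tests.
#' @return List with `anova` (term table) and `tukey` (per-session group
#'   contrasts, empty when the omnibus fails).
#' @export
vigilance_anova <- function(summaries, alpha = 0.05) {
  sess <- sort(unique(summaries$session))
  per_subj <- summaries %>% count(.data$subject)
  if (length(unique(per_subj$n)) != 1 || unique(per_subj$n) != length(sess)) {
    stop("missing sessions: every subject needs all ", length(sess), " sessions")
  }
  tab <- anova_two_way(summaries, "titrated_rt_s", "group", "session")
  tukey <- tibble()
  p_grp <- tab$p[tab$effect == "group"]
  if (isTRUE(is.finite(p_grp)) && p_grp < alpha) {
    tukey <- summaries %>%
      group_by(session = .data$session) %>%
      group_modify(~ tukey_one_way(.x$titrated_rt_s, .x$group)) %>%
      ungroup()
  }
  list(anova = tab, tukey = tukey)
}
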