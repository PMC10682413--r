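#' Latent vigilance agent parameters
#'
#' Describes a simulated subject performing the titrating psychomotor
#' vigilance task. The session-level latent mean reaction time follows
#' `asymptote + (initial - asymptote) * exp(-session / tau)`; per-trial
#' latencies are lognormal around the session mean with coefficient of
#' variation `rt_cv`, and on a lapse trial the agent produces no response
#' within any finite stimulus duration.
#'
#' @param initial_rt_mean Session-0 latent mean RT (s).
#' @param asymptote_rt_mean Asymptotic latent mean RT (s).
#' @param learning_tau Learning time constant (sessions).
#' @param rt_cv Trial-to-trial coefficient of variation.
#' @param lapse_prob Per-trial lapse probability.
#' @return An `agent_params` list.
#' @export
agent_params <- function(initial_rt_mean, asymptote_rt_mean, learning_tau,
                         rt_cv = 0.25, lapse_prob = 0.03) {
  stopifnot(asymptote_rt_mean > 0,
            asymptote_rt_mean <= initial_rt_mean,
            learning_tau > 0, rt_cv >= 0,
            lapse_prob >= 0, lapse_prob < 1)
  structure(list(initial_rt_mean = initial_rt_mean,
                 asymptote_rt_mean = asymptote_rt_mean,
                 learning_tau = learning_tau,
                 rt_cv = rt_cv, lapse_prob = lapse_prob),
            class = "agent_params")
}

#' Default group agent parameters
#'
#' Controls approach an asymptotic titrated reaction time of about 2.5 s;
#' exposed groups plateau about 1 s slower and acquire the task more slowly
#' (larger learning constant, higher lapse rate).
#'
#' @return Named list of [agent_params()] (`control`, `acute`, `chronic`).
#' @export
default_agent_params <- function() {
  list(
    control = agent_params(8, 2.5, 2.5, rt_cv = 0.25, lapse_prob = 0.03),
    acute   = agent_params(8, 3.5, 5.0, rt_cv = 0.25, lapse_prob = 0.06),
    chronic = agent_params(8, 3.5, 5.0, rt_cv = 0.25, lapse_prob = 0.06)
  )
}

#' Bind per-subject agents to jittered group parameters
#'
#' @param group_params Named list of [agent_params()], one per group.
#' @param n_per_group Subjects per group.
#' @param seed Integer seed.
#' @param jitter_sd Lognormal SD of the per-subject jitter applied to the
#'   initial and asymptotic RT means and the learning constant (0 gives
#'   identical subjects within a group).
#' @return A tibble (`subject`, `group`, `params` list-column).
#' @export
generate_vigilance_agents <- function(group_params = default_agent_params(),
                                      n_per_group = 8, seed = 1,
                                      jitter_sd = 0.08) {
  stopifnot(n_per_group >= 1, jitter_sd >= 0)
  with_seed(seed, {
    rows <- list()
    for (g in names(group_params)) {
      gp <- group_params[[g]]
      stopifnot(inherits(gp, "agent_params"))
      for (i in seq_len(n_per_group)) {
        j <- if (jitter_sd > 0) exp(rnorm(3, 0, jitter_sd)) else rep(1, 3)
        asym <- gp$asymptote_rt_mean * j[1]
        init <- max(gp$initial_rt_mean * j[2], asym)
        rows[[length(rows) + 1]] <- tibble(
          subject = sprintf("%s_%02d", g, i), group = g,
          params = list(agent_params(init, asym, gp$learning_tau * j[3],
                                     gp$rt_cv, gp$lapse_prob)))
      }
    }
    bind_rows(rows)
  })
}

# latent mean RT for a session
agent_session_mean <- function(params, session) {
  with(params, asymptote_rt_mean +
         (initial_rt_mean - asymptote_rt_mean) * exp(-session / learning_tau))
}

# response-latency sampler for one session; lapses return Inf
agent_latency_fun <- function(params, session) {
  m <- agent_session_mean(params, session)
  cv <- params$rt_cv
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(m) - sdlog^2 / 2
  function() {
    if (params$lapse_prob > 0 && runif(1) < params$lapse_prob) return(Inf)
    if (cv == 0) m else exp(rnorm(1, meanlog, sdlog))
  }
}

#' Simulate a full vigilance cohort
#'
#' Runs every agent through `n_sessions` x 48-trial titrating sessions,
#' carrying the final stimulus-duration limit of each session into the next
#' (the first session starts at 10 s).
#'
#' @param agents Tibble from [generate_vigilance_agents()].
#' @param n_sessions Number of daily sessions.
#' @param seed Integer seed.
#' @return Trial-level tibble (`subject`, `group`, `session`, `trial`,
#'   `location`, `iti_s`, `limit_s`, `outcome`, `rt_s`).
#' @export
run_vigilance_cohort <- function(agents, n_sessions = 15, seed = 1) {
  with_seed(seed, {
    out <- list()
    for (r in seq_len(nrow(agents))) {
      p <- agents$params[[r]]
      limit <- 10
      for (s in seq_len(n_sessions)) {
        rec <- titrate_session(agent_latency_fun(p, s), start_limit = limit)
        limit <- attr(rec, "final_limit_s")
        rec$subject <- agents$subject[r]
        rec$group <- agents$group[r]
        rec$session <- s
        out[[length(out) + 1]] <- rec
      }
    }
    bind_rows(out) %>%
      select("subject", "group", "session", "trial", "location",
             "iti_s", "limit_s", "outcome", "rt_s")
  })
}
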