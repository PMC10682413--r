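#' Default parameters for the synthetic demand generator
#'
#' Per milk concentration: mean demand intensity `q0_mean` (reinforcers at
#' price approaching 0) and mean elasticity rate `alpha_mean`. Q0 rises and
#' alpha falls with milk concentration, so essential value (1/alpha)
#' increases monotonically with concentration. `k` is the shared range
#' constant (log10 units of consumption range); `subject_sd` scales a
#' mean-one lognormal subject random effect applied to Q0 and 1/alpha;
#' `noise` names the count-noise model applied to the model-predicted
#' consumption.
#'
#' @param k Range constant in log10 units.
#' @param subject_sd Between-subject lognormal SD (log scale).
#' @param noise `"poisson"` (reinforcer counts) or `"none"` (noiseless,
#'   continuous consumption).
#' @return A `demand_gen_params` list.
#' @export
default_demand_params <- function(k = 2, subject_sd = 0.15,
                                  noise = c("poisson", "none")) {
  noise <- match.arg(noise)
  tab <- tibble(
    milk_pct = MILK_LEVELS,
    q0_mean = c(100, 130, 170, 220),
    alpha_mean = c(3e-4, 2.2e-4, 1.6e-4, 1.2e-4)
  )
  stopifnot(all(diff(tab$q0_mean) > 0), all(diff(tab$alpha_mean) < 0),
            all(tab$q0_mean > 0), all(tab$alpha_mean > 0), k > 0,
            subject_sd >= 0)
  structure(list(table = tab, k = k, subject_sd = subject_sd, noise = noise),
            class = "demand_gen_params")
}

#' Exponential demand model prediction
#'
#' Evaluates `log10 Q = log10 Q0 + k (exp(-alpha Q0 C) - 1)` on the natural
#' consumption scale.
#'
#' @param C Price (fixed-ratio response requirement).
#' @param q0 Demand intensity.
#' @param alpha Elasticity rate.
#' @param k Range constant (log10 units).
#' @return Predicted consumption `Q`.
#' @export
demand_model <- function(C, q0, alpha, k) {
  if (any(q0 <= 0) || any(alpha <= 0)) {
    stop("q0 and alpha must be positive")
  }
  10^(log10(q0) + k * (exp(-alpha * q0 * C) - 1))
}

#' Generate synthetic demand observations
#'
#' Draws per-subject demand curves around the exponential demand model at
#' the task's fixed-ratio ladder (2, 5, 10, 30, 50). Subject heterogeneity
#' is a mean-one lognormal effect on Q0 and on essential value (1/alpha);
#' consumption is Poisson around the model prediction (or the noiseless
#' prediction itself). Treatment groups share the same generating
#' parameters by default, mirroring the absence of group effects on demand.
#'
#' @param params A [default_demand_params()] object.
#' @param n_per_group Subjects per group.
#' @param seed Integer seed.
#' @param groups Group labels to generate.
#' @return A tibble (`subject`, `group`, `milk_pct`, `price`, `consumption`)
#'   with a `latent` attribute holding each curve's generating `q0`,
#'   `alpha` and `k`.
#' @export
generate_demand <- function(params = default_demand_params(),
                            n_per_group = 8, seed = 1,
                            groups = GROUP_LEVELS) {
  stopifnot(inherits(params, "demand_gen_params"), n_per_group >= 1)
  sdl <- params$subject_sd
  with_seed(seed, {
    latent <- list(); obs <- list()
    for (g in groups) {
      for (i in seq_len(n_per_group)) {
        subj <- sprintf("%s_%02d", g, i)
        for (r in seq_len(nrow(params$table))) {
          mp <- params$table$milk_pct[r]
          q0 <- params$table$q0_mean[r] *
            (if (sdl > 0) exp(rnorm(1, 0, sdl) - sdl^2 / 2) else 1)
          ev <- (1 / params$table$alpha_mean[r]) *
            (if (sdl > 0) exp(rnorm(1, 0, sdl) - sdl^2 / 2) else 1)
          alpha <- 1 / ev
          mu <- demand_model(FR_PRICES, q0, alpha, params$k)
          q <- switch(params$noise,
                      poisson = rpois(length(mu), mu),
                      none = mu)
          latent[[length(latent) + 1]] <-
            tibble(subject = subj, group = g, milk_pct = mp,
                   q0 = q0, alpha = alpha, k = params$k)
          obs[[length(obs) + 1]] <-
            tibble(subject = subj, group = g, milk_pct = mp,
                   price = FR_PRICES, consumption = q)
        }
      }
    }
    out <- bind_rows(obs)
    attr(out, "latent") <- bind_rows(latent)
    out
  })
}
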