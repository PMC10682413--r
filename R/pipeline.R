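#' Default pipeline run configuration
#'
#' Assembles the configuration for [run_pipeline()]: either simulation
#' parameters (the default) or paths to input CSVs, the stages to run,
#' the output directory, the global seed, and the threshold overrides
#' (`r_min`, `p_alpha`, `importance_threshold`, `max_lag`).
#'
#' @param seed Global seed; every stage derives its randomness from it.
#' @param outdir Output directory (created if needed).
#' @param stages Character vector of stages to run, in dependency order a
#'   subset of `simulate`, `neurochem`, `corrnet`, `irfnet`, `granger`,
#'   `demand`, `vigilance`.
#' @param inputs Optional named list of CSV paths (`dialysate`, `demand`,
#'   `vigilance`) used instead of simulation.
#' @param r_min,p_alpha Correlation-network edge thresholds.
#' @param importance_threshold iRF edge threshold.
#' @param max_lag Granger maximum lag.
#' @param cohort A [sim_cohort_config()] (its seed is replaced by `seed`).
#' @param n_per_group_behavior Subjects per group for the behavioral tasks.
#' @param irf An [irf_config()] (its seed is replaced by a derived seed).
#' @return A `run_config` list.
#' @export
default_run_config <- function(seed = 1, outdir = tempfile("pfcnet_run_"),
                               stages = c("simulate", "neurochem", "corrnet",
                                          "irfnet", "granger", "demand",
                                          "vigilance"),
                               inputs = NULL,
                               r_min = 0.5, p_alpha = 0.05,
                               importance_threshold = 0.2, max_lag = 3,
                               cohort = sim_cohort_config(),
                               n_per_group_behavior = 8,
                               irf = irf_config()) {
  stopifnot(all(stages %in% c("simulate", "neurochem", "corrnet", "irfnet",
                              "granger", "demand", "vigilance")))
  if (!is.null(inputs) && "simulate" %in% stages) {
    stop("provide either input paths or the simulate stage, not both")
  }
  stopifnot(r_min >= -1, r_min <= 1, p_alpha > 0, p_alpha < 1,
            importance_threshold >= 0, importance_threshold <= 1, max_lag >= 1)
  cohort$seed <- as.integer(seed)
  irf$seed <- as.integer(seed) + 7000L
  structure(list(seed = as.integer(seed), outdir = outdir, stages = stages,
                 inputs = inputs, r_min = r_min, p_alpha = p_alpha,
                 importance_threshold = importance_threshold,
                 max_lag = max_lag, cohort = cohort,
                 n_per_group_behavior = n_per_group_behavior, irf = irf),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [default_run_config()]; the `cohort` block
#' mirrors [sim_cohort_config()] and the `irf` block [irf_config()].
#'
#' @param path YAML file.
#' @param outdir Optional override of the configured output directory.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path, outdir = NULL) {
  y <- yaml::read_yaml(path)
  cohort <- do.call(sim_cohort_config, as.list(y$cohort %||% list()))
  irf <- do.call(irf_config, as.list(y$irf %||% list()))
  args <- y[setdiff(names(y), c("cohort", "irf"))]
  args$cohort <- cohort
  args$irf <- irf
  if (!is.null(outdir)) args$outdir <- outdir
  do.call(default_run_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# strip non-serializable attributes before writing JSON
plain <- function(df) as.data.frame(df)

#' Run the analysis pipeline end to end
#'
#' Executes the requested stages in dependency order
#' (simulate -> neurochem -> corrnet / irfnet / granger; demand; vigilance),
#' writes every artifact into `config$outdir`, and writes a manifest
#' (`manifest.json`) recording the package version, seed, thresholds,
#' per-stage status and the MD5 of every output file. A failed stage halts
#' its dependents; independent stages still run.
#'
#' @param config A `run_config` from [default_run_config()] or
#'   [read_run_config()].
#' @return The manifest list, invisibly. `manifest$ok` is `FALSE` when any
#'   stage failed.
#' @export
run_pipeline <- function(config = default_run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$outdir, ...)
  status <- list(); files <- character()
  note <- function(f) files <<- c(files, f)
  run_stage <- function(name, deps, fun) {
    if (!name %in% config$stages) {
      status[[name]] <<- "skipped"
      return(invisible())
    }
    failed_dep <- deps[vapply(deps, function(d)
      identical(status[[d]], "failed") || identical(status[[d]], "halted"),
      logical(1))]
    if (length(failed_dep)) {
      status[[name]] <<- "halted"
      return(invisible())
    }
    res <- tryCatch({ fun(); "ok" },
                    error = function(e) {
                      message("stage ", name, " failed: ", conditionMessage(e))
                      "failed"
                    })
    status[[name]] <<- res
  }

  env <- new.env()

  run_stage("simulate", character(), function() {
    env$dialysate <- generate_dialysate(config$cohort)
    env$demand_obs <- generate_demand(n_per_group = config$n_per_group_behavior,
                                      seed = config$seed + 1L)
    agents <- generate_vigilance_agents(n_per_group = config$n_per_group_behavior,
                                        seed = config$seed + 2L)
    env$vig_trials <- run_vigilance_cohort(agents, seed = config$seed + 3L)
    readr::write_csv(env$dialysate, out("dialysate.csv"))
    readr::write_csv(env$demand_obs, out("demand.csv"))
    readr::write_csv(env$vig_trials, out("vigilance_trials.csv"))
    note(c("dialysate.csv", "demand.csv", "vigilance_trials.csv"))
  })

  if (!"simulate" %in% config$stages && !is.null(config$inputs)) {
    if (!is.null(config$inputs$dialysate))
      env$dialysate <- read_dialysate(config$inputs$dialysate)
    if (!is.null(config$inputs$demand))
      env$demand_obs <- read_demand(config$inputs$demand)
    if (!is.null(config$inputs$vigilance))
      env$vig_trials <- read_vigilance(config$inputs$vigilance)
    status$simulate <- "inputs"
  }

  run_stage("neurochem", "simulate", function() {
    env$cum <- cumulative_levels(env$dialysate)
    pct <- percent_basal_series(env$dialysate)
    comp <- compare_cumulative(env$cum)
    tc <- timecourse_anova(pct)
    readr::write_csv(env$cum, out("cumulative_levels.csv"))
    readr::write_csv(pct, out("percent_basal.csv"))
    jsonlite::write_json(
      list(t_tests = plain(comp),
           timecourse_anova = lapply(tc, function(x) plain(x$anova))),
      out("neurochem_stats.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
    note(c("cumulative_levels.csv", "percent_basal.csv", "neurochem_stats.json"))
  })

  run_stage("corrnet", c("simulate", "neurochem"), function() {
    cn <- correlation_networks(env$cum, config$r_min, config$p_alpha)
    readr::write_csv(cn$pairs, out("correlation_pairs.csv"))
    note("correlation_pairs.csv")
    for (nm in names(cn$networks)) {
      f <- paste0("corr_network_", nm, ".json")
      export_network(cn$networks[[nm]], out(f), "json")
      note(f)
    }
    ks <- unique(cn$pairs$k_mM)
    cmp <- lapply(ks, function(k) {
      r <- compare_correlation_distributions(cn$pairs %>%
        filter(.data$k_mM == k))
      list(k_mM = k, anova = plain(r$anova), tukey = plain(r$tukey))
    })
    jsonlite::write_json(cmp, out("correlation_anova.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    note("correlation_anova.json")
  })

  run_stage("irfnet", "simulate", function() {
    cfg <- config$irf
    cfg$importance_threshold <- config$importance_threshold
    nets <- irf_networks(env$dialysate, cfg)
    for (nm in names(nets)) {
      f <- paste0("irf_network_", nm, ".json")
      export_network(nets[[nm]], out(f), "json")
      note(f)
    }
    combos <- expand.grid(a = GROUP_LEVELS, b = GROUP_LEVELS,
                          k = K_LEVELS, stringsAsFactors = FALSE)
    combos <- combos[match(combos$a, GROUP_LEVELS) <
                       match(combos$b, GROUP_LEVELS), ]
    diffs <- bind_rows(lapply(seq_len(nrow(combos)), function(i) {
      na <- nets[[paste0(combos$a[i], "_", combos$k[i])]]
      nb <- nets[[paste0(combos$b[i], "_", combos$k[i])]]
      dn <- difference_network(na, nb)
      dn$edges %>% mutate(group_a = combos$a[i], group_b = combos$b[i],
                          k_mM = combos$k[i], .before = 1)
    }))
    readr::write_csv(diffs, out("irf_difference_networks.csv"))
    note("irf_difference_networks.csv")
  })

  run_stage("granger", "simulate", function() {
    cm <- causal_matrix(env$dialysate, granger_spec(max_lag = config$max_lag))
    readr::write_csv(cm$per_subject, out("granger_pvalues.csv"))
    jsonlite::write_json(plain(cm$summary), out("granger_decisions.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    note(c("granger_pvalues.csv", "granger_decisions.json"))
  })

  run_stage("demand", "simulate", function() {
    fits <- fit_demand(env$demand_obs, k_mode = "shared")
    readr::write_csv(fits %>% select(-"cov"), out("demand_fits.csv"))
    ok <- fits %>% filter(.data$status == "ok")
    anova_q0 <- demand_anova(ok %>% mutate(value = .data$q0))
    anova_ev <- demand_anova(ok %>% mutate(value = .data$essential_value))
    jsonlite::write_json(list(shared_k = attr(fits, "k"),
                              q0 = plain(anova_q0),
                              essential_value = plain(anova_ev)),
                         out("demand_anova.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    note(c("demand_fits.csv", "demand_anova.json"))
  })

  run_stage("vigilance", "simulate", function() {
    summ <- vigilance_session_summaries(env$vig_trials)
    va <- vigilance_anova(summ)
    readr::write_csv(summ, out("vigilance_sessions.csv"))
    jsonlite::write_json(list(anova = plain(va$anova), tukey = plain(va$tukey)),
                         out("vigilance_anova.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    note(c("vigilance_sessions.csv", "vigilance_anova.json"))
  })

  files <- unique(files)
  md5 <- tools::md5sum(file.path(config$outdir, files))
  manifest <- list(
    package = "pfcnet",
    version = as.character(utils::packageVersion("pfcnet")),
    seed = config$seed,
    thresholds = list(r_min = config$r_min, p_alpha = config$p_alpha,
                      importance_threshold = config$importance_threshold,
                      max_lag = config$max_lag),
    stages = status,
    outputs = lapply(seq_along(files), function(i)
      list(file = files[i], md5 = unname(md5[i]))),
    ok = !any(unlist(status) %in% c("failed", "halted"))
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
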