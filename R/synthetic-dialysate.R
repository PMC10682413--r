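#' Configuration for a synthetic microdialysis cohort
#'
#' Describes the sampling design of a K+-stimulation microdialysis session:
#' an ordered perfusate schedule (4/30/60/120 mM K+ by default), a fixed
#' number of 20-min dialysate samples per block, multiplicative measurement
#' noise and a between-subject random effect on log basal levels.
#'
#' @param n_control,n_acute,n_chronic Subjects per treatment group.
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @param k_schedule Ordered K+ levels of the perfusate blocks (mM).
#' @param samples_per_block Dialysate samples collected in each block.
#' @param sample_interval_min Minutes between consecutive samples.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   measurement noise (0 disables noise).
#' @param subject_sd Standard deviation of the between-subject random effect
#'   on the log basal level (0 disables it).
#' @return A validated `sim_cohort_config` list.
#' @export
sim_cohort_config <- function(n_control = 10, n_acute = 10, n_chronic = 8,
                              seed = 1,
                              k_schedule = c(4, 30, 60, 120),
                              samples_per_block = 4,
                              sample_interval_min = 20,
                              noise_cv = 0.25,
                              subject_sd = 0.2) {
  stopifnot(n_control >= 2, n_acute >= 2, n_chronic >= 2,
            samples_per_block >= 1, sample_interval_min > 0,
            noise_cv >= 0, subject_sd >= 0,
            length(k_schedule) >= 1, !is.unsorted(k_schedule))
  structure(
    list(n_control = n_control, n_acute = n_acute, n_chronic = n_chronic,
         seed = as.integer(seed), k_schedule = k_schedule,
         samples_per_block = samples_per_block,
         sample_interval_min = sample_interval_min,
         noise_cv = noise_cv, subject_sd = subject_sd),
    class = "sim_cohort_config"
  )
}

#' Default group-by-neurotransmitter response profiles
#'
#' One row per group x neurotransmitter x K+ block with the basal
#' concentration (`basal_mean`, nM, control scale), the group fold-change of
#' the basal level relative to control (`fold_vs_control`), and the evoked
#' response kinetics for that block: `amp_pct` (peak level as percent of
#' basal; 0 or 100 encode no response, values below 100 encode a dip),
#' `latency_min` (time from the block switch to the peak) and
#' `decay_per_min` (asymptotic exponential decay rate of the gamma-shaped
#' kernel).
#'
#' Defaults are seeded from the study's printed group contrasts: basal folds
#' DA 2.71/2.14, 5-HT 1.75/1.96 and NE (chronic) 1.60; an NE and Glu
#' acute-to-chronic separation of 2.19- and 1.45-fold; a control DA peak of
#' 394% of basal at the first post-switch 30 mM sample; a control Glu dip to
#' ~53% under 30-60 mM; control/chronic GABA peaks of ~515%/957% under
#' 120 mM; and evoked DA responsiveness abolished in both exposed groups.
#' The control DA 120 mM amplitude is calibrated so that the noiseless
#' chronic/control cumulative DA ratio at 120 mM equals `da120_fold_target`.
#'
#' @param da120_fold_target Chronic/control cumulative DA fold at 120 mM
#'   that the calibrated control amplitude reproduces in a noiseless cohort.
#' @return A tibble of profiles suitable for [generate_dialysate()].
#' @export
default_profiles <- function(da120_fold_target = 1.69) {
  basal <- c(DA = 0.8, `5HT` = 0.6, NE = 1.0, Glu = 1500, GABA = 40)
  folds <- list(
    control = c(DA = 1, `5HT` = 1, NE = 1, Glu = 1, GABA = 1),
    acute   = c(DA = 2.71, `5HT` = 1.75, NE = 0.73, Glu = 0.85, GABA = 1.05),
    chronic = c(DA = 2.14, `5HT` = 1.96, NE = 1.60, Glu = 1.23, GABA = 1.15)
  )
  # kinetics rows: nt, k, amp, latency, decay (absent rows mean no response)
  kin <- list(
    control = rbind(
      data.frame(nt = "DA",   k_mM = 30,  amp_pct = 394, latency_min = 20, decay_per_min = 0.12),
      data.frame(nt = "DA",   k_mM = 60,  amp_pct = 259, latency_min = 40, decay_per_min = 0.10),
      data.frame(nt = "DA",   k_mM = 120, amp_pct = NA,  latency_min = 30, decay_per_min = 0.10),
      data.frame(nt = "NE",   k_mM = 30,  amp_pct = 157, latency_min = 20, decay_per_min = 0.10),
      data.frame(nt = "NE",   k_mM = 60,  amp_pct = 207, latency_min = 40, decay_per_min = 0.08),
      data.frame(nt = "NE",   k_mM = 120, amp_pct = 221, latency_min = 40, decay_per_min = 0.08),
      data.frame(nt = "5HT",  k_mM = 120, amp_pct = 180, latency_min = 60, decay_per_min = 0.02),
      data.frame(nt = "Glu",  k_mM = 30,  amp_pct = 60,  latency_min = 40, decay_per_min = 0.02),
      data.frame(nt = "Glu",  k_mM = 60,  amp_pct = 53,  latency_min = 40, decay_per_min = 0.03),
      data.frame(nt = "GABA", k_mM = 120, amp_pct = 515, latency_min = 50, decay_per_min = 0.05)
    ),
    acute = rbind(
      data.frame(nt = "NE",   k_mM = 30,  amp_pct = 157, latency_min = 20, decay_per_min = 0.10),
      data.frame(nt = "NE",   k_mM = 60,  amp_pct = 207, latency_min = 40, decay_per_min = 0.08),
      data.frame(nt = "NE",   k_mM = 120, amp_pct = 221, latency_min = 40, decay_per_min = 0.08),
      data.frame(nt = "5HT",  k_mM = 120, amp_pct = 200, latency_min = 60, decay_per_min = 0.02),
      data.frame(nt = "GABA", k_mM = 120, amp_pct = 223, latency_min = 40, decay_per_min = 0.05)
    ),
    chronic = rbind(
      data.frame(nt = "NE",   k_mM = 30,  amp_pct = 130, latency_min = 20, decay_per_min = 0.10),
      data.frame(nt = "NE",   k_mM = 60,  amp_pct = 160, latency_min = 40, decay_per_min = 0.08),
      data.frame(nt = "NE",   k_mM = 120, amp_pct = 170, latency_min = 40, decay_per_min = 0.08),
      data.frame(nt = "5HT",  k_mM = 120, amp_pct = 180, latency_min = 60, decay_per_min = 0.02),
      data.frame(nt = "Glu",  k_mM = 120, amp_pct = 134, latency_min = 50, decay_per_min = 0.04),
      data.frame(nt = "GABA", k_mM = 120, amp_pct = 957, latency_min = 60, decay_per_min = 0.08)
    )
  )
  grid <- expand_grid(group = GROUP_LEVELS, nt = NT_LEVELS, k_mM = K_LEVELS)
  out <- grid %>%
    mutate(basal_mean = basal[.data$nt],
           fold_vs_control = vapply(seq_len(nrow(grid)), function(i) {
             folds[[grid$group[i]]][[grid$nt[i]]]
           }, numeric(1)))
  kin_tbl <- bind_rows(lapply(names(kin), function(g) {
    cbind(group = g, kin[[g]])
  }))
  out <- out %>%
    left_join(kin_tbl, by = c("group", "nt", "k_mM"))
  # rows with no kinetics: flat (amp 0)
  out$amp_pct[is.na(out$latency_min)] <- 0
  out$latency_min[is.na(out$latency_min)] <- 0
  out$decay_per_min[is.na(out$decay_per_min)] <- 0
  # calibrate control DA 120 mM amplitude against the cumulative fold target
  idx <- which(out$group == "control" & out$nt == "DA" & out$k_mM == 120)
  mean_g <- mean(response_kernel(c(20, 40, 60, 80),
                                 latency = out$latency_min[idx],
                                 decay = out$decay_per_min[idx]))
  chronic_fold <- folds$chronic[["DA"]]
  target_mean_resp <- chronic_fold / da120_fold_target
  out$amp_pct[idx] <- 100 * (1 + (target_mean_resp - 1) / mean_g)
  as_tibble(out)
}

# gamma-shaped kernel: unit peak at t = latency, asymptotic exponential
# decay at rate `decay`; zero for t <= 0
response_kernel <- function(t, latency, decay) {
  g <- numeric(length(t))
  pos <- t > 0
  if (latency <= 0 || decay <= 0) return(g)
  p <- decay * latency
  g[pos] <- (t[pos] / latency)^p * exp(decay * (latency - t[pos]))
  g
}

#' Default lag-1 innovation-coupling matrices
#'
#' One 5x5 matrix per group. Entry `C[i, j]` couples neurotransmitter `j` at
#' lag 1 into the innovation of neurotransmitter `i` (row = target). The
#' control matrix is near-diagonal with a reciprocal Glu-GABA coupling; the
#' exposure matrices add off-diagonal mass among the monoamines and
#' GABA-monoamine terms, emulating the reorganized (more positively
#' correlated, DA-centric) networks seen after exposure. All matrices have
#' spectral radius below 1 so the implied vector autoregression is
#' stationary.
#'
#' @return Named list of matrices (`control`, `acute`, `chronic`).
#' @export
default_coupling <- function() {
  blank <- function() {
    m <- diag(0.25, 5)
    dimnames(m) <- list(NT_LEVELS, NT_LEVELS)
    m
  }
  control <- blank()
  control["Glu", "Glu"] <- 0
  control["GABA", "GABA"] <- 0
  control["Glu", "GABA"] <- 0.6
  control["GABA", "Glu"] <- 0.6

  acute <- blank()
  acute["DA", "GABA"] <- 1.2
  acute["GABA", "DA"] <- 0.2
  acute["Glu", "DA"] <- 0.2
  acute["5HT", "DA"] <- 0.4
  acute["NE", "DA"] <- 0.4
  acute["DA", "NE"] <- 0.4

  chronic <- blank()
  chronic["DA", "DA"] <- 0.1
  chronic["DA", "GABA"] <- 1.2
  chronic["DA", "NE"] <- 1.2
  chronic["GABA", "DA"] <- 0.1
  chronic["NE", "DA"] <- 0.1
  chronic["GABA", "NE"] <- 0.3
  chronic["NE", "GABA"] <- 0.3
  chronic["Glu", "GABA"] <- 0.3
  chronic["GABA", "Glu"] <- 0.3

  out <- list(control = control, acute = acute, chronic = chronic)
  for (g in names(out)) {
    rad <- max(Mod(eigen(out[[g]], only.values = TRUE)$values))
    if (rad >= 1) stop("default coupling for ", g, " is non-stationary")
  }
  out
}

# simulate T steps of the lag-1 VAR e_t = C e_{t-1} + eta_t (eta ~ N(0, I)),
# burn in, and rescale each series to unit stationary variance
var_innovations <- function(C, n_steps, burn_in = 20) {
  p <- nrow(C)
  e <- matrix(0, n_steps + burn_in, p)
  eta <- matrix(rnorm((n_steps + burn_in) * p), ncol = p)
  for (t in 2:(n_steps + burn_in)) e[t, ] <- as.vector(C %*% e[t - 1, ]) + eta[t, ]
  e <- e[-seq_len(burn_in), , drop = FALSE]
  S <- matrix(solve(diag(p * p) - kronecker(C, C), as.vector(diag(p))), p, p)
  sweep(e, 2, sqrt(diag(S)), "/")
}

spectral_radius <- function(C) max(Mod(eigen(C, only.values = TRUE)$values))

#' Generate a synthetic dialysate table
#'
#' Simulates the long-format per-sample neurotransmitter concentrations of a
#' K+-stimulation microdialysis cohort. Each concentration is
#' `basal_mean * fold_vs_control * response(t) * subject_effect * noise`,
#' where `response(t)` follows the block's gamma-shaped kernel (unit
#' baseline, peak `amp_pct`/100), the subject effect is a mean-one lognormal
#' random effect, and the noise term is mean-one lognormal with coefficient
#' of variation `noise_cv` whose innovations propagate through the group's
#' lag-1 coupling matrix. Deterministic given `config$seed`.
#'
#' @param config A [sim_cohort_config()].
#' @param profiles Profile tibble as from [default_profiles()].
#' @param coupling Named list of group coupling matrices as from
#'   [default_coupling()].
#' @return A tibble with columns `subject`, `group`, `sample_index`,
#'   `time_min`, `k_mM`, `neurotransmitter`, `conc_nM`.
#' @export
generate_dialysate <- function(config = sim_cohort_config(),
                               profiles = default_profiles(),
                               coupling = default_coupling()) {
  stopifnot(inherits(config, "sim_cohort_config"))
  need <- expand_grid(group = GROUP_LEVELS, nt = NT_LEVELS,
                      k_mM = config$k_schedule)
  have <- profiles %>% distinct(.data$group, .data$nt, .data$k_mM)
  missing <- anti_join(need, have, by = c("group", "nt", "k_mM"))
  if (nrow(missing) > 0) {
    stop("missing profile rows for ",
         paste(missing$group, missing$nt, missing$k_mM, collapse = "; "))
  }
  for (g in GROUP_LEVELS) {
    if (is.null(coupling[[g]])) stop("missing coupling matrix for group ", g)
    if (spectral_radius(coupling[[g]]) >= 1) {
      stop("coupling matrix for ", g, " has spectral radius >= 1 (non-stationary)")
    }
  }

  spb <- config$samples_per_block
  n_blocks <- length(config$k_schedule)
  n_samples <- spb * n_blocks
  dt <- config$sample_interval_min
  # last baseline sample is t = 0
  time_min <- (seq_len(n_samples) - spb) * dt
  k_of_sample <- rep(config$k_schedule, each = spb)
  # switch into block b happens at the time of the last sample of block b-1;
  # the baseline block nominally "switches" one interval before its first sample
  block_switch <- c(time_min[1] - dt,
                    time_min[seq(spb, n_samples - spb, by = spb)])

  sdlog <- if (config$noise_cv > 0) sqrt(log(1 + config$noise_cv^2)) else 0

  counts <- c(control = config$n_control, acute = config$n_acute,
              chronic = config$n_chronic)

  prof_df <- as.data.frame(profiles)
  prof_key <- paste(prof_df$group, prof_df$nt, prof_df$k_mM)
  with_seed(config$seed, {
    rows <- lapply(GROUP_LEVELS, function(g) {
      # response multiplier per nt per sample (shared by subjects in a group)
      resp <- sapply(NT_LEVELS, function(nt) {
        r <- rep(1, n_samples)
        for (b in seq_len(n_blocks)) {
          pr <- prof_df[match(paste(g, nt, config$k_schedule[b]), prof_key), ]
          amp <- pr$amp_pct
          if (amp %in% c(0, 100)) next
          idx <- which(k_of_sample == config$k_schedule[b])
          offs <- time_min[idx] - block_switch[b]
          r[idx] <- r[idx] + (amp / 100 - 1) *
            response_kernel(offs, pr$latency_min, pr$decay_per_min)
        }
        r
      })
      pg <- prof_df[prof_df$group == g, ]
      pg <- pg[!duplicated(pg$nt), ]
      base <- setNames(pg$basal_mean * pg$fold_vs_control, pg$nt)[NT_LEVELS]
      C <- coupling[[g]][NT_LEVELS, NT_LEVELS]
      n_subj <- counts[[g]]
      conc_all <- vector("list", n_subj)
      for (i in seq_len(n_subj)) {
        subj_eff <- if (config$subject_sd > 0) {
          exp(rnorm(5, 0, config$subject_sd) - config$subject_sd^2 / 2)
        } else rep(1, 5)
        noise <- if (sdlog > 0) {
          exp(sdlog * var_innovations(C, n_samples) - sdlog^2 / 2)
        } else matrix(1, n_samples, 5)
        conc_all[[i]] <- as.vector(resp *
          rep(base * subj_eff, each = n_samples) * noise)
      }
      per_subj <- n_samples * 5
      tibble(subject = rep(sprintf("%s_%02d", g, seq_len(n_subj)),
                           each = per_subj),
             group = g,
             sample_index = rep(seq_len(n_samples), times = 5 * n_subj),
             time_min = rep(time_min, times = 5 * n_subj),
             k_mM = rep(k_of_sample, times = 5 * n_subj),
             neurotransmitter = rep(rep(NT_LEVELS, each = n_samples),
                                    times = n_subj),
             conc_nM = unlist(conc_all))
    })
    bind_rows(rows)
  })
}

#' Flat response profiles
#'
#' Profiles with every evoked amplitude set to 0 (no K+ response): each
#' series stays at its basal level up to noise. Useful for isolating the
#' noise and coupling structure in validation experiments.
#'
#' @param basal_mean Named basal levels (nM) per neurotransmitter; a single
#'   number is recycled.
#' @param fold_vs_control Named list of per-group fold vectors (defaults to
#'   1 everywhere).
#' @return A profile tibble for [generate_dialysate()].
#' @export
flat_profiles <- function(basal_mean = 1, fold_vs_control = NULL) {
  if (length(basal_mean) == 1) {
    basal_mean <- setNames(rep(basal_mean, 5), NT_LEVELS)
  }
  grid <- expand_grid(group = GROUP_LEVELS, nt = NT_LEVELS, k_mM = K_LEVELS)
  grid %>%
    mutate(basal_mean = .env$basal_mean[.data$nt],
           fold_vs_control = vapply(seq_len(nrow(grid)), function(i) {
             if (is.null(fold_vs_control)) 1
             else fold_vs_control[[grid$group[i]]][[grid$nt[i]]]
           }, numeric(1)),
           amp_pct = 0, latency_min = 0, decay_per_min = 0)
}

#' Designed coupling matrices for recovery experiments
#'
#' Single-mechanism coupling layouts whose strengths were fixed by an
#' a-priori power analysis so that each designed signal is recoverable by
#' the matching analysis at the study's sample sizes:
#'
#' * `"glu_gaba"`: one strong reciprocal Glu-GABA coupling (0.8) and
#'   near-zero elsewhere; the 4 mM correlation network should contain the
#'   Glu-GABA edge.
#' * `"da_ne"`: one strong DA -> NE coupling (0.9) with DA autocorrelation
#'   0.8; iRF-LOOP should retain the DA -> NE directed edge.
#' * `"chronic_da_drivers"`: strong GABA -> DA and NE -> DA couplings (1.6)
#'   with source autocorrelation 0.6 and a GABA <-> NE cross-term (0.3);
#'   pairwise Granger tests should find GABA -> DA and NE -> DA but not
#'   Glu -> DA.
#'
#' The named layout is applied to every group.
#'
#' @param type Which layout to build.
#' @return Named list of coupling matrices (`control`, `acute`, `chronic`).
#' @export
designed_coupling <- function(type = c("glu_gaba", "da_ne",
                                       "chronic_da_drivers")) {
  type <- match.arg(type)
  m <- diag(0.25, 5)
  dimnames(m) <- list(NT_LEVELS, NT_LEVELS)
  if (type == "glu_gaba") {
    m["Glu", "Glu"] <- 0; m["GABA", "GABA"] <- 0
    m["Glu", "GABA"] <- 0.8; m["GABA", "Glu"] <- 0.8
  } else if (type == "da_ne") {
    m <- diag(0.3, 5); dimnames(m) <- list(NT_LEVELS, NT_LEVELS)
    m["DA", "DA"] <- 0.8; m["NE", "NE"] <- 0.2
    m["NE", "DA"] <- 0.9
  } else {
    m <- diag(0.1, 5); dimnames(m) <- list(NT_LEVELS, NT_LEVELS)
    m["DA", "GABA"] <- 1.6; m["DA", "NE"] <- 1.6
    m["GABA", "GABA"] <- 0.6; m["NE", "NE"] <- 0.6
    m["GABA", "NE"] <- 0.3; m["NE", "GABA"] <- 0.3
  }
  stopifnot(spectral_radius(m) < 1)
  list(control = m, acute = m, chronic = m)
}
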