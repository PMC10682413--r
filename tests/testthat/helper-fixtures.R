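# shared fixtures built in code

# tiny dialysate table with hand-controllable values: one subject, all five
# neurotransmitters, 16 samples; conc defaults to `value` everywhere
toy_dialysate <- function(value = 2, subject = "control_01",
                          group = "control") {
  k <- rep(c(4, 30, 60, 120), each = 4)
  tidyr::expand_grid(neurotransmitter = c("DA", "5HT", "NE", "Glu", "GABA"),
                     sample_index = 1:16) |>
    dplyr::mutate(subject = subject, group = group,
                  time_min = (sample_index - 4) * 20,
                  k_mM = k[sample_index],
                  conc_nM = value)
}

# noiseless default cohort (shared across tests; built once)
noiseless_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_dialysate(sim_cohort_config(noise_cv = 0,
                                                     subject_sd = 0))
    }
    cache
  }
})

# designed cohorts used by the recovery experiments
glu_gaba_cohort <- function(seed, n = 10) {
  generate_dialysate(
    sim_cohort_config(n_control = n, n_acute = 2, n_chronic = 2,
                      seed = seed, noise_cv = 0.3, subject_sd = 0),
    profiles = flat_profiles(1),
    coupling = designed_coupling("glu_gaba"))
}

da_ne_cohort <- function(seed) {
  generate_dialysate(
    sim_cohort_config(n_control = 10, n_acute = 2, n_chronic = 2,
                      seed = seed, noise_cv = 0.4, subject_sd = 0),
    profiles = flat_profiles(1),
    coupling = designed_coupling("da_ne"))
}

chronic_driver_cohort <- function(seed) {
  generate_dialysate(
    sim_cohort_config(n_control = 2, n_acute = 2, n_chronic = 8,
                      seed = seed, noise_cv = 0.25, subject_sd = 0),
    profiles = flat_profiles(1),
    coupling = designed_coupling("chronic_da_drivers"))
}

# textbook two-way ANOVA by explicit sums of squares (balanced designs)
hand_two_way <- function(y, A, B) {
  A <- factor(A); B <- factor(B)
  gm <- mean(y)
  a <- length(levels(A)); b <- length(levels(B)); n <- length(y) / (a * b)
  mA <- tapply(y, A, mean); mB <- tapply(y, B, mean)
  mAB <- tapply(y, list(A, B), mean)
  ss_a <- b * n * sum((mA - gm)^2)
  ss_b <- a * n * sum((mB - gm)^2)
  ss_ab <- n * sum((mAB - outer(mA - gm, mB - gm, "+") - gm)^2)
  ss_tot <- sum((y - gm)^2)
  ss_err <- ss_tot - ss_a - ss_b - ss_ab
  df_err <- a * b * (n - 1)
  list(
    F_a = (ss_a / (a - 1)) / (ss_err / df_err),
    F_b = (ss_b / (b - 1)) / (ss_err / df_err),
    F_ab = (ss_ab / ((a - 1) * (b - 1))) / (ss_err / df_err),
    df_err = df_err
  )
}
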