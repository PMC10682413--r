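#' Basal neurotransmitter levels
#'
#' The basal level of a subject x neurotransmitter series is the arithmetic
#' mean of the four consecutive samples taken during 4 mM K+ perfusion.
#'
#' @param table Dialysate tibble (`subject`, `group`, `sample_index`,
#'   `time_min`, `k_mM`, `neurotransmitter`, `conc_nM`).
#' @param baseline_k K+ level of the baseline block (mM).
#' @return Tibble (`subject`, `group`, `neurotransmitter`, `basal_nM`,
#'   `zero_basal` flag).
#' @export
compute_basal <- function(table, baseline_k = 4) {
  base <- table %>% filter(.data$k_mM == baseline_k)
  n_per <- base %>% count(.data$subject, .data$neurotransmitter)
  if (nrow(n_per) == 0 || any(n_per$n < 4)) {
    stop("each subject x neurotransmitter needs all 4 baseline samples")
  }
  base %>%
    group_by(.data$subject, .data$group, .data$neurotransmitter) %>%
    summarise(basal_nM = mean(.data$conc_nM), .groups = "drop") %>%
    mutate(zero_basal = .data$basal_nM == 0)
}

#' Cumulative per-block neurotransmitter levels
#'
#' For each subject x neurotransmitter x K+ block, the cumulative level is
#' the sum (default) of the four dialysate samples in the block; the mean
#' is available as a sensitivity alternative.
#'
#' @param table Dialysate tibble.
#' @param stat `"sum"` (default) or `"mean"`.
#' @return Tibble (`subject`, `group`, `neurotransmitter`, `k_mM`,
#'   `cumulative_nM`).
#' @export
cumulative_levels <- function(table, stat = c("sum", "mean")) {
  stat <- match.arg(stat)
  gone <- setdiff(K_LEVELS, unique(table$k_mM))
  if (length(gone)) stop("missing K+ block(s): ", paste(gone, collapse = ", "))
  blocks <- table %>% distinct(.data$subject, .data$neurotransmitter, .data$k_mM) %>%
    count(.data$subject, .data$neurotransmitter)
  if (any(blocks$n != length(unique(table$k_mM)))) {
    stop("missing K+ block for some subject")
  }
  agg <- if (stat == "sum") sum else mean
  table %>%
    group_by(.data$subject, .data$group, .data$neurotransmitter, .data$k_mM) %>%
    summarise(cumulative_nM = agg(.data$conc_nM), .groups = "drop")
}

#' Percent-of-basal time courses
#'
#' Expresses each retained sample as a percentage of the subject's basal
#' level. The series keeps the last baseline sample (t = 0) and the twelve
#' post-baseline samples: 13 points per subject x neurotransmitter. Series
#' with a zero basal cannot be normalized and are excluded with a
#' diagnostic attribute.
#'
#' @param table Dialysate tibble.
#' @param baseline_k K+ level of the baseline block (mM).
#' @return Tibble (`subject`, `group`, `neurotransmitter`, `time_min`,
#'   `k_mM`, `pct_basal`) with attribute `excluded` listing dropped series.
#' @export
percent_basal_series <- function(table, baseline_k = 4) {
  basal <- compute_basal(table, baseline_k)
  excluded <- basal %>% filter(.data$zero_basal)
  keep <- basal %>% filter(!.data$zero_basal)
  out <- table %>%
    filter(.data$time_min >= 0) %>%
    inner_join(keep %>% select("subject", "neurotransmitter", "basal_nM"),
               by = c("subject", "neurotransmitter")) %>%
    mutate(pct_basal = 100 * .data$conc_nM / .data$basal_nM) %>%
    select("subject", "group", "neurotransmitter", "time_min", "k_mM",
           "pct_basal") %>%
    arrange(.data$subject, .data$neurotransmitter, .data$time_min)
  attr(out, "excluded") <- excluded %>%
    select("subject", "neurotransmitter")
  out
}

#' Pairwise group comparisons of cumulative levels
#'
#' Unpaired two-tailed t tests (pooled variance by default; Welch optional)
#' between each group pair, per neurotransmitter and K+ level, with the
#' fold change as the ratio of the second group's mean to the first's.
#' Group pairs are ordered control-acute, control-chronic, acute-chronic,
#' so e.g. an elevated acute baseline appears as fold_change > 1.
#'
#' @param levels Tibble from [cumulative_levels()].
#' @param welch Use the Welch (unequal-variance) variant.
#' @return Tibble (`neurotransmitter`, `k_mM`, `group_a`, `group_b`,
#'   `t`, `df`, `p`, `fold_change`).
#' @export
compare_cumulative <- function(levels, welch = FALSE) {
  groups <- intersect(GROUP_LEVELS, unique(levels$group))
  n_per <- levels %>% count(.data$group)
  if (any(n_per$n < 2)) stop("need at least 2 subjects per group")
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  combos <- levels %>% distinct(.data$neurotransmitter, .data$k_mM)
  bind_rows(lapply(seq_len(nrow(combos)), function(i) {
    sub <- levels %>%
      filter(.data$neurotransmitter == combos$neurotransmitter[i],
             .data$k_mM == combos$k_mM[i])
    bind_rows(lapply(pairs, function(pr) {
      x <- sub$cumulative_nM[sub$group == pr[1]]
      y <- sub$cumulative_nM[sub$group == pr[2]]
      tt <- two_sample_t(x, y, welch = welch)
      tibble(neurotransmitter = combos$neurotransmitter[i],
             k_mM = combos$k_mM[i],
             group_a = pr[1], group_b = pr[2],
             t = tt$t, df = tt$df, p = tt$p,
             fold_change = mean(y) / mean(x))
    }))
  }))
}

# unpaired two-tailed t test; degenerate zero-variance equal-mean inputs
# return t = 0, p = 1 by convention
two_sample_t <- function(x, y, welch = FALSE) {
  n1 <- length(x); n2 <- length(y)
  v1 <- var(x); v2 <- var(y)
  if (v1 == 0 && v2 == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, df = n1 + n2 - 2, p = 1))
    return(list(t = Inf * sign(mean(x) - mean(y)), df = n1 + n2 - 2, p = 0))
  }
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    t <- (mean(x) - mean(y)) / sqrt(se2)
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    df <- n1 + n2 - 2
    t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Two-way ANOVA on percent-basal time courses
#'
#' Treatment x time fixed-effects ANOVA per neurotransmitter on the
#' 13-point percent-basal series (subjects as replicates), followed by
#' Tukey HSD contrasts between groups at each time point and of each time
#' point against the t = 0 baseline within group.
#'
#' @param series Tibble from [percent_basal_series()].
#' @return Named list per neurotransmitter, each with `anova`,
#'   `tukey_groups` (between groups per time) and `tukey_vs_basal`
#'   (within group vs t = 0).
#' @export
timecourse_anova <- function(series) {
  lens <- series %>% count(.data$subject, .data$neurotransmitter)
  if (length(unique(lens$n)) != 1) stop("ragged series: unequal lengths")
  out <- list()
  for (nt in unique(series$neurotransmitter)) {
    sub <- series %>% filter(.data$neurotransmitter == nt)
    tab <- anova_two_way(sub, "pct_basal", "group", "time_min")
    tukey_groups <- sub %>%
      group_by(time_min = .data$time_min) %>%
      group_modify(~ tukey_one_way(.x$pct_basal, .x$group)) %>%
      ungroup()
    tukey_vs_basal <- sub %>%
      group_by(group = .data$group) %>%
      group_modify(~ tukey_one_way(.x$pct_basal, factor(.x$time_min))) %>%
      ungroup() %>%
      filter(grepl("(^0-)|(-0$)", .data$contrast))
    out[[nt]] <- list(anova = tab, tukey_groups = tukey_groups,
                      tukey_vs_basal = tukey_vs_basal)
  }
  out
}
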