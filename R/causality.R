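#' Specification of the pairwise Granger causality test
#'
#' @param max_lag Maximum lag order tested (lags 1..max_lag each get their
#'   own nested-OLS F test).
#' @param alpha Decision level for "A Granger-causes B".
#' @param aggregation How per-lag p-values combine into one p per ordered
#'   pair: `"min"` (minimum over lags 1..max_lag, the default) or
#'   `"max_lag"` (the max_lag test only).
#' @return A `granger_spec` list.
#' @export
granger_spec <- function(max_lag = 3, alpha = 0.05,
                         aggregation = c("min", "max_lag")) {
  stopifnot(max_lag >= 1, alpha > 0, alpha < 1)
  structure(list(max_lag = max_lag, alpha = alpha,
                 aggregation = match.arg(aggregation)),
            class = "granger_spec")
}

#' Pairwise Granger causality test
#'
#' Tests whether the history of series `a` improves prediction of series
#' `b` beyond `b`'s own history. For each lag m in 1..max_lag, the
#' restricted model regresses `b_t` on an intercept and m own lags and the
#' unrestricted model adds m lags of `a`, both on the common sample of
#' `T_eff = T - m` rows; the statistic is
#' `F = ((SSR_r - SSR_u)/m) / (SSR_u/(T_eff - 2m - 1))` with
#' `(m, T_eff - 2m - 1)` degrees of freedom.
#'
#' @param a Candidate cause series.
#' @param b Effect series (same length, time-ordered).
#' @param spec A [granger_spec()].
#' @return A `granger_result` list: `per_lag` tibble (`lag`, `F`, `df1`,
#'   `df2`, `p`), aggregated `p`, `length` (T), `spec`.
#' @export
granger_test <- function(a, b, spec = granger_spec()) {
  stopifnot(length(a) == length(b))
  T <- length(b)
  m_max <- spec$max_lag
  if (T - m_max < 2 * m_max + 2) {
    stop("series too short: need length >= ", 3 * m_max + 2,
         " for max_lag = ", m_max)
  }
  per_lag <- lapply(seq_len(m_max), function(m) {
    y <- b[(m + 1):T]
    own <- sapply(seq_len(m), function(l) b[(m + 1 - l):(T - l)])
    oth <- sapply(seq_len(m), function(l) a[(m + 1 - l):(T - l)])
    Xr <- cbind(1, own)
    Xu <- cbind(Xr, oth)
    if (qr(Xu)$rank < ncol(Xu)) {
      stop("perfectly collinear lag design (are the series identical?)")
    }
    ssr_r <- sum(lm.fit(Xr, y)$residuals^2)
    ssr_u <- sum(lm.fit(Xu, y)$residuals^2)
    t_eff <- T - m
    df2 <- t_eff - 2 * m - 1
    Fs <- ((ssr_r - ssr_u) / m) / (ssr_u / df2)
    tibble(lag = m, F = Fs, df1 = m, df2 = df2,
           p = pf(Fs, m, df2, lower.tail = FALSE))
  })
  per_lag <- bind_rows(per_lag)
  p <- switch(spec$aggregation,
              min = min(per_lag$p),
              max_lag = per_lag$p[per_lag$lag == m_max])
  structure(list(per_lag = per_lag, p = p, length = T, spec = spec),
            class = "granger_result")
}

#' Per-group causal p-value matrix over neurotransmitter pairs
#'
#' Runs [granger_test()] for every ordered neurotransmitter pair on each
#' subject's full 16-sample concentration series (all K+ blocks in time
#' order) and aggregates per-subject p-values by group: median, quartiles,
#' and the decision `median p < alpha`. The eight DA-centric families
#' (each other neurotransmitter into DA and DA into each) are flagged for
#' reporting. Subjects whose series fail the test preconditions are
#' excluded with a diagnostic count.
#'
#' @param table Dialysate tibble.
#' @param spec A [granger_spec()].
#' @return List with `per_subject` (subject-level aggregated p per ordered
#'   pair) and `summary` (per group x pair: `median_p`, `q1`, `q3`,
#'   `n_subjects`, `n_excluded`, `causal`, `da_family`).
#' @export
causal_matrix <- function(table, spec = granger_spec()) {
  nts <- intersect(NT_LEVELS, unique(table$neurotransmitter))
  groups <- intersect(GROUP_LEVELS, unique(table$group))
  series <- table %>%
    arrange(.data$subject, .data$neurotransmitter, .data$sample_index) %>%
    group_by(.data$subject, .data$group, .data$neurotransmitter) %>%
    summarise(series = list(.data$conc_nM), .groups = "drop")
  subjects <- series %>% distinct(.data$subject, .data$group)
  if (any(table(subjects$group) < 2)) stop("need >= 2 subjects per group")
  per_subject <- list(); excluded <- list()
  for (si in seq_len(nrow(subjects))) {
    subj <- subjects$subject[si]
    ss <- series %>% filter(.data$subject == subj)
    vecs <- setNames(ss$series, ss$neurotransmitter)
    for (src in nts) for (tgt in setdiff(nts, src)) {
      res <- tryCatch(granger_test(vecs[[src]], vecs[[tgt]], spec),
                      error = function(e) e)
      if (inherits(res, "error")) {
        excluded[[length(excluded) + 1]] <-
          tibble(subject = subj, group = subjects$group[si],
                 source = src, target = tgt, reason = conditionMessage(res))
      } else {
        per_subject[[length(per_subject) + 1]] <-
          tibble(subject = subj, group = subjects$group[si],
                 source = src, target = tgt, p = res$p)
      }
    }
  }
  per_subject <- bind_rows(per_subject)
  excluded <- if (length(excluded)) bind_rows(excluded) else
    tibble(subject = character(), group = character(),
           source = character(), target = character(), reason = character())
  summary <- per_subject %>%
    group_by(.data$group, .data$source, .data$target) %>%
    summarise(median_p = median(.data$p),
              q1 = quantile(.data$p, 0.25, names = FALSE),
              q3 = quantile(.data$p, 0.75, names = FALSE),
              n_subjects = dplyr::n(), .groups = "drop") %>%
    left_join(excluded %>% count(.data$group, .data$source, .data$target,
                                 name = "n_excluded"),
              by = c("group", "source", "target")) %>%
    mutate(n_excluded = ifelse(is.na(.data$n_excluded), 0L, .data$n_excluded),
           causal = .data$median_p < spec$alpha,
           da_family = .data$source == "DA" | .data$target == "DA")
  list(per_subject = per_subject, summary = summary, excluded = excluded)
}
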