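#' Configuration for iterative random forest network inference
#'
#' @param n_trees Trees per forest.
#' @param n_iterations Iterative reweighting rounds (1 reduces to a plain
#'   random forest).
#' @param train_frac Fraction of rows used for training; the rest scores
#'   held-out predictions.
#' @param importance_threshold Minimum normalized importance for a retained
#'   edge.
#' @param seed Integer seed; forests and splits are deterministic given it.
#' @param mtry Candidate features per split (`NULL` for the random-forest
#'   regression default, p/3 rounded down and floored at 1).
#' @return An `irf_config` list.
#' @export
irf_config <- function(n_trees = 500, n_iterations = 5, train_frac = 0.8,
                       importance_threshold = 0.2, seed = 1, mtry = NULL) {
  stopifnot(n_trees >= 1, n_iterations >= 1,
            train_frac > 0, train_frac < 1,
            importance_threshold >= 0, importance_threshold <= 1)
  structure(list(n_trees = n_trees, n_iterations = n_iterations,
                 train_frac = train_frac,
                 importance_threshold = importance_threshold,
                 seed = as.integer(seed), mtry = mtry),
            class = "irf_config")
}

#' Iterative random forest regression importances
#'
#' Iteration 1 fits a plain regression random forest; each later iteration
#' re-fits with per-split candidate-feature sampling weighted by the
#' previous iteration's normalized impurity importances, concentrating the
#' forest on informative features. Returns the final iteration's
#' importances normalized to sum to 1.
#'
#' @param x Data frame of predictor columns (>= 2).
#' @param y Numeric response (length `nrow(x)`, >= 8 rows, non-constant).
#' @param config An [irf_config()].
#' @return An `irf_fit` list: `importance` (named, sums to 1), `model`
#'   (final ranger forest), `config`.
#' @export
irf_fit <- function(x, y, config = irf_config()) {
  x <- as.data.frame(x)
  if (nrow(x) < 8) stop("irf_fit() needs at least 8 rows")
  if (ncol(x) < 2) stop("irf_fit() needs at least 2 features")
  if (var(y) == 0) stop("constant target: nothing to explain")
  d <- cbind(x, .target = y)
  w <- NULL
  fit <- NULL
  for (it in seq_len(config$n_iterations)) {
    args <- list(dependent.variable.name = ".target", data = d,
                 num.trees = config$n_trees, importance = "impurity",
                 seed = config$seed + it - 1, num.threads = 1,
                 verbose = FALSE, respect.unordered.factors = "order")
    if (!is.null(config$mtry)) args$mtry <- config$mtry
    # iteration 1 is exactly a plain forest (no weight vector passed)
    if (!is.null(w)) args$split.select.weights <- w
    fit <- suppressWarnings(do.call(ranger::ranger, args))
    imp <- pmax(fit$variable.importance, 0)
    w <- if (sum(imp) > 0) as.numeric(imp / sum(imp)) else NULL
  }
  imp <- pmax(fit$variable.importance, 0)
  importance <- if (sum(imp) > 0) imp / sum(imp) else imp
  structure(list(importance = importance, model = fit, config = config),
            class = "irf_fit")
}

#' iRF-LOOP directed network for one group x K+ block
#'
#' Leave-one-out prediction over variables: each neurotransmitter in turn
#' is predicted from the other four with [irf_fit()] on a seeded
#' train/test split of the block's rows (one row per subject per sample).
#' The per-target normalized importances are candidate edge weights;
#' edges at or above `importance_threshold` are retained and signed by the
#' univariate OLS slope of target on source over the block's rows. The
#' held-out R-squared per target is recorded as metadata, never used as a
#' filter.
#'
#' @param block_data Tibble with one column per neurotransmitter (rows =
#'   subject x sample within the block); extra columns are ignored.
#' @param config An [irf_config()].
#' @param group,k_mM Optional labels stored on the network.
#' @return A `directed_network` list: `nodes`, `edges` (source, target,
#'   importance, sign), `importances` (full pre-threshold matrix rows =
#'   target), `test_r2`, `group`, `k_mM`, `threshold`.
#' @export
irf_loop <- function(block_data, config = irf_config(), group = NA, k_mM = NA) {
  nts <- intersect(NT_LEVELS, names(block_data))
  if (length(nts) < length(NT_LEVELS)) {
    stop("block_data must contain all five neurotransmitter columns")
  }
  dat <- as.data.frame(block_data[, nts])
  n <- nrow(dat)
  n_train <- round(config$train_frac * n)
  if (n_train < 8 || n - n_train < 1) {
    stop("too few rows after the train/test split (need >= 8 train rows)")
  }
  imp_mat <- matrix(0, length(nts), length(nts),
                    dimnames = list(target = nts, source = nts))
  r2 <- setNames(numeric(length(nts)), nts)
  edges <- list()
  for (ti in seq_along(nts)) {
    target <- nts[ti]
    train_idx <- with_seed(config$seed + 1000L * ti,
                           sample.int(n, n_train))
    sources <- setdiff(nts, target)
    fit <- irf_fit(dat[train_idx, sources, drop = FALSE],
                   dat[[target]][train_idx],
                   irf_config(config$n_trees, config$n_iterations,
                              config$train_frac, config$importance_threshold,
                              seed = config$seed + 1000L * ti, mtry = config$mtry))
    imp_mat[target, sources] <- fit$importance[sources]
    test_idx <- setdiff(seq_len(n), train_idx)
    pred <- stats::predict(fit$model,
                           data = dat[test_idx, , drop = FALSE])$predictions
    truth <- dat[[target]][test_idx]
    sst <- sum((truth - mean(truth))^2)
    r2[target] <- if (sst > 0) 1 - sum((truth - pred)^2) / sst else NA_real_
    keep <- sources[fit$importance[sources] >= config$importance_threshold]
    for (src in keep) {
      edges[[length(edges) + 1]] <- tibble(
        source = src, target = target,
        importance = unname(fit$importance[src]))
    }
  }
  net <- structure(list(nodes = nts,
                        edges = if (length(edges)) bind_rows(edges)
                                else tibble(source = character(),
                                            target = character(),
                                            importance = numeric()),
                        importances = imp_mat, test_r2 = r2,
                        group = group, k_mM = k_mM,
                        threshold = config$importance_threshold),
                   class = "directed_network")
  sign_edges(net, block_data)
}

#' Attach regression signs to directed edges
#'
#' Sign of the univariate ordinary-least-squares slope of target on source:
#' `+1` when an increase in the source accompanies an increase in the
#' target, `-1` for suppression. A zero slope or constant source leaves
#' the sign undefined (`NA`) and flags the edge.
#'
#' @param network A `directed_network`.
#' @param samples Rows used to estimate slopes (neurotransmitter columns).
#' @return The network with `sign` and `sign_flagged` edge columns.
#' @export
sign_edges <- function(network, samples) {
  e <- network$edges
  if (nrow(e) == 0) {
    e$sign <- integer(); e$sign_flagged <- logical()
    network$edges <- e
    return(network)
  }
  sgn <- integer(nrow(e)); flag <- logical(nrow(e))
  for (i in seq_len(nrow(e))) {
    xs <- samples[[e$source[i]]]; ys <- samples[[e$target[i]]]
    if (sd(xs) == 0) { sgn[i] <- NA_integer_; flag[i] <- TRUE; next }
    slope <- ols_slope(xs, ys)
    if (slope == 0) { sgn[i] <- NA_integer_; flag[i] <- TRUE }
    else sgn[i] <- as.integer(sign(slope))
  }
  e$sign <- sgn; e$sign_flagged <- flag
  network$edges <- e
  network
}

ols_slope <- function(x, y) sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)

#' Edge-wise difference between two directed networks
#'
#' Absolute difference of retained-edge importances between two networks at
#' the same K+ level, using 0 for an edge absent from one network. The
#' `displayed` flag marks differences at or above the importance threshold.
#'
#' @param net_a,net_b `directed_network` objects with equal `k_mM`.
#' @return A `difference_network` list with the pairwise label and an edge
#'   tibble (`source`, `target`, `importance_a`, `importance_b`, `diff`,
#'   `displayed`).
#' @export
difference_network <- function(net_a, net_b) {
  if (!identical(net_a$k_mM, net_b$k_mM)) {
    stop("difference_network() requires networks at the same K+ level")
  }
  grid <- expand_grid(source = net_a$nodes, target = net_a$nodes) %>%
    filter(.data$source != .data$target)
  get_imp <- function(net, s, t) {
    hit <- net$edges$source == s & net$edges$target == t
    if (any(hit)) net$edges$importance[hit][1] else 0
  }
  ia <- mapply(get_imp, grid$source, grid$target,
               MoreArgs = list(net = net_a), USE.NAMES = FALSE)
  ib <- mapply(get_imp, grid$source, grid$target,
               MoreArgs = list(net = net_b), USE.NAMES = FALSE)
  edges <- grid %>%
    mutate(importance_a = ia, importance_b = ib,
           diff = abs(ia - ib),
           displayed = .data$diff >= net_a$threshold) %>%
    filter(.data$importance_a > 0 | .data$importance_b > 0)
  structure(list(group_pair = c(net_a$group, net_b$group),
                 k_mM = net_a$k_mM, edges = edges,
                 threshold = net_a$threshold),
            class = "difference_network")
}

#' iRF-LOOP networks for every group x K+ level
#'
#' Pivots a dialysate table to per-sample rows within each group x K+
#' block and runs [irf_loop()] on each: 3 groups x 4 K+ levels gives 12
#' directed networks.
#'
#' @param table Dialysate tibble.
#' @param config An [irf_config()]; each block derives its own seed from
#'   `config$seed` so networks are independent and reproducible.
#' @return Named list of `directed_network` objects (`group_kmM`).
#' @export
irf_networks <- function(table, config = irf_config()) {
  combos <- table %>% distinct(.data$group, .data$k_mM) %>%
    arrange(match(.data$group, GROUP_LEVELS), .data$k_mM)
  nets <- lapply(seq_len(nrow(combos)), function(i) {
    wide <- table %>%
      filter(.data$group == combos$group[i], .data$k_mM == combos$k_mM[i]) %>%
      select("subject", "sample_index", "neurotransmitter", "conc_nM") %>%
      pivot_wider(names_from = "neurotransmitter", values_from = "conc_nM")
    cfg <- config
    cfg$seed <- config$seed + 101L * i
    irf_loop(wide, cfg, group = combos$group[i], k_mM = combos$k_mM[i])
  })
  names(nets) <- paste0(combos$group, "_", combos$k_mM)
  nets
}
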