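## CSV schemas ----------------------------------------------------------
## dialysate:  subject, group, sample_index, time_min, k_mM, neurotransmitter, conc_nM
## demand:     subject, group, milk_pct, price, consumption
## vigilance:  subject, group, session, trial, location, iti_s, limit_s, outcome, rt_s
## UTF-8, comma-separated, header mandatory, "." decimal, empty fields for NA.

schema_fail <- function(rows, rule) {
  stop("schema violation (", rule, ") at data row(s) ",
       paste(head(rows, 10), collapse = ", "),
       if (length(rows) > 10) " ..." else "", call. = FALSE)
}

check_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(what, " file is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
}

#' Read and validate a dialysate CSV
#'
#' @param path CSV path with the documented dialysate schema.
#' @return Validated tibble.
#' @export
read_dialysate <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_cols(df, c("subject", "group", "sample_index", "time_min", "k_mM",
                   "neurotransmitter", "conc_nM"), "dialysate")
  bad <- which(!df$group %in% GROUP_LEVELS)
  if (length(bad)) schema_fail(bad, paste0("group must be one of ",
                                           paste(GROUP_LEVELS, collapse = "/")))
  bad <- which(!df$neurotransmitter %in% NT_LEVELS)
  if (length(bad)) schema_fail(bad, paste0("neurotransmitter must be one of ",
                                           paste(NT_LEVELS, collapse = "/")))
  bad <- which(!df$k_mM %in% K_LEVELS)
  if (length(bad)) schema_fail(bad, paste0("k_mM must be in {",
                                           paste(K_LEVELS, collapse = ", "), "}"))
  bad <- which(is.na(df$conc_nM) | df$conc_nM < 0)
  if (length(bad)) schema_fail(bad, "conc_nM must be a nonnegative number")
  grid_bad <- df %>%
    group_by(.data$subject, .data$neurotransmitter) %>%
    arrange(.data$sample_index, .by_group = TRUE) %>%
    summarise(ok = all(diff(.data$time_min) == 20) &&
                !is.unsorted(.data$k_mM), .groups = "drop")
  if (any(!grid_bad$ok)) {
    stop("broken time grid or K+ order for subject(s): ",
         paste(unique(grid_bad$subject[!grid_bad$ok]), collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Read and validate a demand CSV
#' @param path CSV path with the documented demand schema.
#' @return Validated tibble.
#' @export
read_demand <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_cols(df, c("subject", "group", "milk_pct", "price", "consumption"),
             "demand")
  bad <- which(!df$group %in% GROUP_LEVELS)
  if (length(bad)) schema_fail(bad, "unknown group label")
  bad <- which(!df$price %in% FR_PRICES)
  if (length(bad)) schema_fail(bad, paste0("price must be in {",
                                           paste(FR_PRICES, collapse = ", "), "}"))
  bad <- which(is.na(df$consumption) | df$consumption < 0)
  if (length(bad)) schema_fail(bad, "consumption must be nonnegative")
  dup <- df %>% count(.data$subject, .data$milk_pct, .data$price) %>%
    filter(.data$n > 1)
  if (nrow(dup)) {
    stop("duplicate subject x milk_pct x price records", call. = FALSE)
  }
  df
}

#' Read and validate a vigilance trial CSV
#' @param path CSV path with the documented vigilance schema.
#' @return Validated tibble.
#' @export
read_vigilance <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_cols(df, c("subject", "group", "session", "trial", "location",
                   "iti_s", "limit_s", "outcome", "rt_s"), "vigilance")
  bad <- which(!df$group %in% GROUP_LEVELS)
  if (length(bad)) schema_fail(bad, "unknown group label")
  bad <- which(!df$outcome %in% c("hit", "miss"))
  if (length(bad)) schema_fail(bad, "outcome must be hit or miss")
  bad <- which(df$limit_s < 0.25)
  if (length(bad)) schema_fail(bad, "limit_s below the 0.25 s floor")
  bad <- which(df$outcome == "hit" & (is.na(df$rt_s) | df$rt_s > df$limit_s))
  if (length(bad)) schema_fail(bad, "hits need rt_s <= limit_s")
  bad <- which(!df$iti_s %in% c(15, 30, 45))
  if (length(bad)) schema_fail(bad, "iti_s must be 15, 30 or 45")
  df
}

#' Serialize a network to JSON, GraphML or edge-list CSV
#'
#' Lossless for nodes, edges, weights/importances, signs and the labels of
#' undirected correlation networks and directed iRF networks.
#'
#' @param network A `corr_network` or `directed_network`.
#' @param path Output file path.
#' @param format `"json"`, `"graphml"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("json", "graphml", "csv")) {
  format <- match.arg(format)
  directed <- inherits(network, "directed_network")
  if (!directed && !inherits(network, "corr_network")) {
    stop("unknown network object")
  }
  edges <- network$edges
  if (format == "json") {
    payload <- list(
      type = if (directed) "directed" else "undirected",
      group = network$group, k_mM = network$k_mM,
      nodes = network$nodes,
      threshold = if (directed) network$threshold
                  else list(r_min = network$r_min, p_alpha = network$p_alpha),
      edges = edges
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  } else if (format == "graphml") {
    g <- network_to_igraph(network)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    readr::write_csv(edges, path)
  }
  invisible(path)
}

network_to_igraph <- function(network) {
  directed <- inherits(network, "directed_network")
  e <- network$edges
  el <- if (directed) cbind(e$source, e$target) else cbind(e$nt_a, e$nt_b)
  g <- igraph::graph_from_data_frame(
    d = if (nrow(e)) data.frame(from = el[, 1], to = el[, 2]) else
      data.frame(from = character(), to = character()),
    directed = directed,
    vertices = data.frame(name = network$nodes))
  if (nrow(e)) {
    if (directed) {
      igraph::E(g)$importance <- e$importance
      igraph::E(g)$sign <- as.numeric(e$sign)
    } else {
      igraph::E(g)$weight <- e$weight
      igraph::E(g)$p <- e$p
    }
  }
  g
}

#' Read a directed network back from its JSON export
#' @param path JSON file written by [export_network()].
#' @return A `directed_network` or `corr_network` (edge tibble restored).
#' @export
read_network_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- as_tibble(x$edges)
  if (identical(x$type, "directed")) {
    structure(list(nodes = x$nodes, edges = edges, group = x$group,
                   k_mM = x$k_mM, threshold = x$threshold),
              class = "directed_network")
  } else {
    structure(list(nodes = x$nodes, edges = edges, group = x$group,
                   k_mM = x$k_mM, r_min = x$threshold$r_min,
                   p_alpha = x$threshold$p_alpha),
              class = "corr_network")
  }
}
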