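#' Metric specifications
#'
#' Docking scores have heterogeneous orientations: binding free-energy
#' estimates improve downward, empirical fitness scores improve upward.
#' A metric spec records the name and orientation of each score column so
#' ranking can normalize them. The defaults cover the common three-metric
#' setup: `vina` (lower is better), `goldscore` and `chemplp` (higher is
#' better).
#'
#' @param ... named orientations, e.g.
#'   `metric_specs(vina = "lower_better", goldscore = "higher_better")`.
#'   Shorthand `"lower"`/`"higher"` accepted.
#' @return tibble `name`, `orientation`.
#' @export
metric_specs <- function(...) {
  args <- list(...)
  if (!length(args)) {
    args <- list(vina = "lower_better", goldscore = "higher_better",
                 chemplp = "higher_better")
  }
  orientation <- map_chr(args, function(o) {
    o <- as.character(o)
    if (o %in% c("lower", "lower_better")) "lower_better"
    else if (o %in% c("higher", "higher_better")) "higher_better"
    else abort(paste0("unknown orientation: ", o))
  })
  if (anyDuplicated(names(args))) abort("duplicate metric names")
  tibble(name = names(args), orientation = unname(orientation))
}

#' Rank items by one metric
#'
#' Competition ranks (1 = best) after orientation normalization; tied
#' scores share the mean of the rank positions they occupy, so the result
#' never depends on input order. Items missing the metric are excluded
#' with a warning and get `NA` ranks.
#'
#' @param scores numeric vector of metric values.
#' @param orientation `"lower_better"` or `"higher_better"`.
#' @return numeric vector of ranks (1 = best, possibly fractional).
#' @export
rank_by_metric <- function(scores, orientation = c("lower_better",
                                                   "higher_better")) {
  orientation <- match.arg(orientation)
  ok <- !is.na(scores)
  if (!any(ok)) abort("no rankable items: all scores missing")
  if (any(!ok)) {
    warn(paste0(sum(!ok), " item(s) missing metric value; excluded from ranks"))
  }
  oriented <- if (orientation == "lower_better") scores else -scores
  out <- rep(NA_real_, length(scores))
  out[ok] <- rank(oriented[ok], ties.method = "average")
  out
}

#' Borda rank aggregation over scoring metrics
#'
#' Aggregates several scoring metrics into one consensus order by the
#' Borda count: each item earns, per metric, points equal to the number of
#' items ranked below it (`n - rank`, so a clear winner earns `n - 1` per
#' metric), and items are ordered by total points descending. Only the
#' relative order matters downstream, so the point convention is
#' immaterial as long as it is fixed.
#'
#' Items missing any metric are excluded with a warning (their rows remain
#' in the output with `NA` points). Final ties break by the value of the
#' first metric in `metrics` (after orientation), then by input order.
#'
#' @param items data frame with one row per item carrying the metric
#'   columns named in `metrics`.
#' @param metrics a [metric_specs()] tibble.
#' @return a `condock_borda` object: the input with added columns
#'   `rank_<metric>`, `borda_points`, `final_rank`; also usable via
#'   [tidy()]/[glance()]/[autoplot()].
#' @export
borda_rank <- function(items, metrics = metric_specs()) {
  items <- as_tibble(items)
  if (nrow(items) < 1) abort("no items to rank")
  missing_cols <- setdiff(metrics$name, names(items))
  if (length(missing_cols)) {
    abort(paste0("items lack metric column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  complete <- stats::complete.cases(items[metrics$name])
  if (any(!complete)) {
    warn(paste0(sum(!complete), " item(s) metric-incomplete; excluded from ",
                "Borda aggregation"))
  }
  n <- sum(complete)
  if (n == 0) abort("no metric-complete items to rank")

  ranks <- matrix(NA_real_, nrow(items), nrow(metrics),
                  dimnames = list(NULL, metrics$name))
  for (k in seq_len(nrow(metrics))) {
    ranks[complete, k] <- rank_by_metric(items[[metrics$name[k]]][complete],
                                         metrics$orientation[k])
  }
  points <- rowSums(n - ranks)

  # tie-breaks: first metric's oriented value, then input order
  tb <- items[[metrics$name[1]]]
  if (metrics$orientation[1] == "higher_better") tb <- -tb
  ord <- order(-points, tb, seq_len(nrow(items)), na.last = TRUE)
  final_rank <- rep(NA_real_, nrow(items))
  final_rank[ord[seq_len(n)]] <- seq_len(n)

  out <- items
  for (k in seq_len(nrow(metrics))) {
    out[[paste0("rank_", metrics$name[k])]] <- ranks[, k]
  }
  out$borda_points <- points
  out$final_rank <- final_rank
  structure(out, metrics = metrics,
            class = c("condock_borda", class(out)))
}

#' Take the top-k of a Borda ranking
#'
#' @param result a `condock_borda` from [borda_rank()].
#' @param k how many items (default 5, the per-compound carry-forward of
#'   the consensus protocol). If fewer items exist, all are returned with
#'   a warning.
#' @return the top-k rows in final-rank order.
#' @export
top_k <- function(result, k = 5) {
  stopifnot(k >= 1)
  ranked <- result[!is.na(result$final_rank), , drop = FALSE]
  ranked <- ranked[order(ranked$final_rank), , drop = FALSE]
  if (nrow(ranked) < k) {
    warn(paste0("only ", nrow(ranked), " ranked items; returning all"))
  }
  head(ranked, k)
}

#' @export
tidy.condock_borda <- function(x, ...) {
  cols <- c(intersect(c("ligand_id", "idx_a", "idx_b", "rmsd"), names(x)),
            grep("^rank_", names(x), value = TRUE),
            "borda_points", "final_rank")
  out <- as_tibble(x)[cols]
  out[order(out$final_rank, na.last = TRUE), , drop = FALSE]
}

#' @export
glance.condock_borda <- function(x, ...) {
  tibble(n_items = nrow(x),
         n_ranked = sum(!is.na(x$final_rank)),
         n_metrics = nrow(attr(x, "metrics")),
         max_points = max(x$borda_points, na.rm = TRUE))
}

#' @export
autoplot.condock_borda <- function(object, ...) {
  long <- as_tibble(object) |>
    mutate(item = row_number()) |>
    tidyr::pivot_longer(cols = dplyr::starts_with("rank_"),
                        names_to = "metric", values_to = "rank",
                        names_prefix = "rank_")
  ggplot(long, aes(x = .data$metric, y = factor(.data$item),
                   fill = .data$rank)) +
    geom_tile() +
    scale_fill_viridis_c(direction = -1) +
    labs(x = "scoring metric", y = "item",
         fill = "rank\n(1 = best)",
         title = "Per-metric ranks feeding the Borda aggregate") +
    theme_minimal()
}
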