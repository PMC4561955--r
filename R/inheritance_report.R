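#' Cross-generation intersection of an expression category
#'
#' Counts how many genes carry the same category label (a classification
#' group such as ELD_P1, or an MPV status such as NONADDITIVE_UP) in both
#' hybrid generations — the Venn-diagram bookkeeping behind "heritable"
#' category claims.
#'
#' @param f1_calls,f2_calls data frames keyed by \code{gene_id} with the
#'   label in \code{label_col}.
#' @param category the label to intersect.
#' @param label_col column holding the label (default "group"; use
#'   "mpv_status" for additivity categories).
#' @return one-row data frame: category, n_f1, n_f2, n_both.
#' @export
intersect_category <- function(f1_calls, f2_calls, category,
                               label_col = "group") {
  g1 <- f1_calls$gene_id[f1_calls[[label_col]] == category]
  g2 <- f2_calls$gene_id[f2_calls[[label_col]] == category]
  data.frame(category = category, n_f1 = length(g1), n_f2 = length(g2),
             n_both = length(intersect(g1, g2)), stringsAsFactors = FALSE)
}

#' Two-decimal percentage, half away from zero
#'
#' \code{100 n / denominator} rounded to 2 decimals with ties going away
#' from zero — the convention that reproduces every printed percentage of
#' the source study from its printed numerator.
#'
#' @param n non-negative numerator count.
#' @param denominator positive denominator count.
#' @return percentage rounded to 2 decimals.
#' @export
percent_of <- function(n, denominator) {
  if (any(denominator <= 0)) {
    stop("percent_of: denominator must be positive", call. = FALSE)
  }
  if (any(n < 0)) stop("percent_of: n must be >= 0", call. = FALSE)
  x <- 100 * n / denominator
  sign(x) * floor(abs(x) * 100 + 0.5) / 100
}

#' Summarize a full trio analysis run
#'
#' Produces the headline statistics of a run: per-pair DE counts and their
#' percentages of the co-expressed denominator, nonadditive counts per
#' generation, per-group classification counts, and cross-generation
#' inheritance counts for every group and MPV status.
#'
#' @param f1,f2 results of \code{\link{classify_generation}} for each
#'   generation.
#' @param de_pairs named list of \code{\link{call_de}} tables (for the DE
#'   count block); names like "P1_vs_P2".
#' @param n_coexpressed the percentage denominator (co-expressed gene
#'   count).
#' @return list with \code{stats} (tidy data frame statistic/value),
#'   \code{venn} (per-category inheritance table), and \code{json} (named
#'   list mirroring \code{stats}).
#' @export
summarize_run <- function(f1, f2, de_pairs = list(), n_coexpressed = NULL) {
  stats_rows <- list()
  add <- function(name, value) {
    stats_rows[[length(stats_rows) + 1]] <<- data.frame(
      statistic = name, value = value, stringsAsFactors = FALSE)
  }
  denom <- n_coexpressed
  for (nm in names(de_pairs)) {
    de <- de_pairs[[nm]]
    n_de <- sum(de$direction != "NS")
    add(paste0("n_de_", nm), n_de)
    add(paste0("n_up_", nm), sum(de$direction == "UP"))
    add(paste0("n_down_", nm), sum(de$direction == "DOWN"))
    if (!is.null(denom)) {
      add(paste0("pct_de_", nm), percent_of(n_de, denom))
    }
  }
  for (gen in c("F1", "F2")) {
    calls <- if (gen == "F1") f1$calls else f2$calls
    n_nonadd <- sum(calls$mpv_status != "ADDITIVE")
    add(paste0("n_nonadditive_", gen), n_nonadd)
    if (!is.null(denom)) {
      add(paste0("pct_nonadditive_", gen), percent_of(n_nonadd, denom))
    }
    for (grp in GROUP_LEVELS) {
      add(paste0("n_", tolower(grp), "_", gen), sum(calls$group == grp))
    }
    add(paste0("n_eld_total_", gen),
        sum(calls$group %in% c("ELD_P1", "ELD_P2")))
  }
  venn <- do.call(rbind, c(
    lapply(GROUP_LEVELS, function(grp)
      intersect_category(f1$calls, f2$calls, grp, "group")),
    lapply(c("ADDITIVE", "NONADDITIVE_UP", "NONADDITIVE_DOWN"),
           function(st)
             intersect_category(f1$calls, f2$calls, st, "mpv_status"))))
  for (i in seq_len(nrow(venn))) {
    add(paste0("n_heritable_", tolower(venn$category[i])), venn$n_both[i])
  }
  stats <- do.call(rbind, stats_rows)
  json <- stats::setNames(as.list(stats$value), stats$statistic)
  list(stats = stats, venn = venn, json = json)
}
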