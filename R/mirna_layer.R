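#' Trio classification of the miRNA layer
#'
#' The miRNA complement runs through exactly the same machinery as the
#' protein-coding genes — median-of-ratios size factors, exact pairwise
#' tests, twelve-bin classification and the mid-parent additivity test —
#' but with the small-RNA significance convention: adjusted p strictly
#' below \code{config$fdr_mirna} (default 0.05). Nonadditively expressed
#' miRNAs above the MPV are "activated" (NONADDITIVE_UP), below it
#' "repressed" (NONADDITIVE_DOWN).
#'
#' @param mirna_ct \code{\link{count_table}} of miRNA counts for the four
#'   libraries.
#' @param generation "F1" or "F2".
#' @param config an \code{\link{analysis_config}}.
#' @return as \code{\link{classify_generation}}, with the first column
#'   named \code{mirna_id}.
#' @export
classify_mirna <- function(mirna_ct, generation = c("F1", "F2"),
                           config = analysis_config()) {
  generation <- match.arg(generation)
  sf <- size_factors_median_ratio(mirna_ct)
  res <- classify_generation(mirna_ct, generation, config,
                             size_factors = sf, alpha = config$fdr_mirna,
                             alpha_strict = TRUE)
  names(res$calls)[names(res$calls) == "gene_id"] <- "mirna_id"
  names(res$mpv)[names(res$mpv) == "gene_id"] <- "mirna_id"
  res
}

#' Correlation between miRNA and target-gene fold changes
#'
#' Expands every (miRNA, target) link of a many-to-many map into one
#' scatter point — one miRNA contributes as many points as it has targets —
#' and computes the Pearson correlation between the two log2 fold changes
#' (each taken against the mid-parent value by default), with the usual
#' t-based two-sided p on n-2 degrees of freedom. A negative r is the
#' expected signature of miRNA-mediated repression.
#'
#' @param mirna_fc data frame with \code{mirna_id} and a fold-change
#'   column; rows restricted to nonadditive/DE miRNAs when
#'   \code{restrict = TRUE} must be pre-filtered by the caller via
#'   \code{mirna_keep}.
#' @param gene_fc data frame with \code{gene_id} and a fold-change column.
#' @param target_map data frame of (mirna_id, gene_id) links.
#' @param fc_col name of the fold-change column in both tables (default
#'   "log2fc_vs_mpv").
#' @param mirna_keep,gene_keep optional logical vectors (parallel to the
#'   fold-change tables) marking members eligible for pairing; used to
#'   restrict to both-nonadditive pairs.
#' @return list: \code{r}, \code{p}, \code{n_pairs}, and \code{pairs}
#'   (data frame mirna_id, gene_id, mirna_log2fc, target_log2fc).
#' @export
mirna_target_correlation <- function(mirna_fc, gene_fc, target_map,
                                     fc_col = "log2fc_vs_mpv",
                                     mirna_keep = NULL, gene_keep = NULL) {
  if (!is.null(mirna_keep)) mirna_fc <- mirna_fc[mirna_keep, , drop = FALSE]
  if (!is.null(gene_keep)) gene_fc <- gene_fc[gene_keep, , drop = FALSE]
  mi <- match(target_map$mirna_id, mirna_fc$mirna_id)
  gi <- match(target_map$gene_id, gene_fc$gene_id)
  ok <- !is.na(mi) & !is.na(gi)
  pairs <- data.frame(mirna_id = target_map$mirna_id[ok],
                      gene_id = target_map$gene_id[ok],
                      mirna_log2fc = mirna_fc[[fc_col]][mi[ok]],
                      target_log2fc = gene_fc[[fc_col]][gi[ok]],
                      stringsAsFactors = FALSE)
  n <- nrow(pairs)
  if (n < 3) {
    stop("degenerate input: fewer than 3 miRNA-target pairs after ",
         "restriction", call. = FALSE)
  }
  if (stats::sd(pairs$mirna_log2fc) == 0 ||
      stats::sd(pairs$target_log2fc) == 0) {
    stop("correlation undefined: zero variance in fold changes",
         call. = FALSE)
  }
  r <- stats::cor(pairs$mirna_log2fc, pairs$target_log2fc)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(r = r, p = p, n_pairs = n, pairs = pairs)
}
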