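# Twelve-bin truth table, keyed "rel_P1P2|rel_HP1|rel_HP2" where GT means
# the first member of the pair is significantly higher. Bins II+XI are ELD
# toward P1 (hybrid statistically like the maternal parent), IV+IX toward
# P2; I+XII additive; V,VI,VIII above both parents; III,VII,X below both.
BIN_TABLE <- local({
  rows <- rbind(
    c("LT", "GT", "LT", "I",    "ADDITIVITY"),
    c("GT", "LT", "GT", "XII",  "ADDITIVITY"),
    c("LT", "NS", "LT", "II",   "ELD_P1"),
    c("GT", "NS", "GT", "XI",   "ELD_P1"),
    c("LT", "GT", "NS", "IV",   "ELD_P2"),
    c("GT", "LT", "NS", "IX",   "ELD_P2"),
    c("LT", "GT", "GT", "V",    "TRANSGRESSIVE_UP"),
    c("NS", "GT", "GT", "VI",   "TRANSGRESSIVE_UP"),
    c("GT", "GT", "GT", "VIII", "TRANSGRESSIVE_UP"),
    c("LT", "LT", "LT", "III",  "TRANSGRESSIVE_DOWN"),
    c("NS", "LT", "LT", "VII",  "TRANSGRESSIVE_DOWN"),
    c("GT", "LT", "LT", "X",    "TRANSGRESSIVE_DOWN"),
    c("NS", "NS", "NS", "NO_CHANGE", "CONSERVED"))
  data.frame(key = paste(rows[, 1], rows[, 2], rows[, 3], sep = "|"),
             bin = rows[, 4], group = rows[, 5], stringsAsFactors = FALSE)
})

#' Twelve-bin expression-level-dominance classification
#'
#' Maps the three pairwise significance relations of a hybrid-parent trio
#' (P1 vs P2, hybrid vs P1, hybrid vs P2; each GT, LT or NS with GT meaning
#' the first member is significantly higher) to one of the twelve canonical
#' differential-expression bins, NO_CHANGE, or AMBIGUOUS. The function is
#' total over all 27 triples: the 12 bins and NO_CHANGE cover the 13
#' internally consistent combinations; the remaining 14 contradictory ones
#' are labelled AMBIGUOUS rather than forced into a bin.
#'
#' @param rel_P1P2,rel_HP1,rel_HP2 character vectors over {GT, LT, NS}
#'   (recycled to a common length).
#' @return data frame with columns \code{bin} (I..XII, NO_CHANGE,
#'   AMBIGUOUS) and \code{group} (ADDITIVITY, ELD_P1, ELD_P2,
#'   TRANSGRESSIVE_UP, TRANSGRESSIVE_DOWN, CONSERVED, AMBIGUOUS).
#' @export
classify_trio <- function(rel_P1P2, rel_HP1, rel_HP2) {
  k <- max(length(rel_P1P2), length(rel_HP1), length(rel_HP2))
  a <- rep_len(as.character(rel_P1P2), k)
  b <- rep_len(as.character(rel_HP1), k)
  d <- rep_len(as.character(rel_HP2), k)
  ok <- c("GT", "LT", "NS")
  if (!all(c(a, b, d) %in% ok)) {
    stop("relations must be one of GT, LT, NS", call. = FALSE)
  }
  idx <- match(paste(a, b, d, sep = "|"), BIN_TABLE$key)
  bin <- ifelse(is.na(idx), "AMBIGUOUS", BIN_TABLE$bin[idx])
  group <- ifelse(is.na(idx), "AMBIGUOUS", BIN_TABLE$group[idx])
  data.frame(bin = bin, group = group, stringsAsFactors = FALSE)
}

#' Mid-parent-value additivity test
#'
#' Tests, per gene, whether a hybrid generation's expression differs from
#' the mid-parent value (MPV), the mean of the two parents' normalized
#' counts. The MPV is materialized as a pseudo-library: per-gene counts are
#' the round-half-even of the normalized mid-parent count, and the
#' pseudo-library size is the rounded mean of the two parents' normalized
#' library sizes, so the exact two-library test applies unchanged. The
#' hybrid enters with its raw counts at its normalized library size.
#'
#' @param ct a \code{\link{count_table}} with P1, P2 and the chosen hybrid.
#' @param generation "F1" or "F2".
#' @param size_factors per-sample scale factors (default all 1).
#' @param alpha FDR threshold for the nonadditive call (default 0.001).
#' @param pseudocount shift for the log2 fold change vs MPV (default 1).
#' @param alpha_strict if TRUE use q < alpha instead of q <= alpha.
#' @return data frame: gene_id, generation, mpv_norm, log2fc_vs_mpv, p, q,
#'   status in {ADDITIVE, NONADDITIVE_UP, NONADDITIVE_DOWN}.
#' @export
mpv_test <- function(ct, generation = c("F1", "F2"), size_factors = NULL,
                     alpha = 0.001, pseudocount = 1, alpha_strict = FALSE) {
  generation <- match.arg(generation)
  need <- c("P1", "P2", generation)
  missing <- setdiff(need, ct$sample_labels)
  if (length(missing)) {
    stop("sample(s) missing from table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(size_factors)) {
    size_factors <- stats::setNames(rep(1, length(ct$sample_labels)),
                                    ct$sample_labels)
  }
  sf <- size_factors
  h <- ct$counts[, generation]
  mpv_norm <- (ct$counts[, "P1"] / sf[["P1"]] +
               ct$counts[, "P2"] / sf[["P2"]]) / 2
  n_h <- ct$library_sizes[[generation]] / sf[[generation]]
  n_mpv <- round((ct$library_sizes[["P1"]] / sf[["P1"]] +
                  ct$library_sizes[["P2"]] / sf[["P2"]]) / 2)
  mpv_pseudo <- round(mpv_norm)  # round half to even, deterministic
  p <- exact_count_test(h, n_h, mpv_pseudo, n_mpv)
  q <- bh_adjust(p)
  h_norm <- h / sf[[generation]]
  l2fc <- log2_fold_change(h_norm, mpv_norm, pseudocount)
  sig <- if (alpha_strict) q < alpha else q <= alpha
  status <- rep("ADDITIVE", length(h))
  status[sig & h_norm > mpv_norm] <- "NONADDITIVE_UP"
  status[sig & h_norm < mpv_norm] <- "NONADDITIVE_DOWN"
  data.frame(gene_id = ct$gene_ids, generation = generation,
             mpv_norm = unname(mpv_norm), log2fc_vs_mpv = unname(l2fc),
             p = unname(p), q = unname(q), status = status,
             stringsAsFactors = FALSE)
}

dir_to_rel <- function(direction) {
  # DE direction of (first, second) pair -> relation alphabet
  c(UP = "GT", DOWN = "LT", NS = "NS")[direction]
}

#' Full trio classification for one hybrid generation
#'
#' Runs the three pairwise exact-test comparisons (P1 vs P2, hybrid vs P1,
#' hybrid vs P2), maps their directions to relations, applies the
#' twelve-bin classifier, and joins the mid-parent additivity test.
#'
#' @param ct a \code{\link{count_table}} with all four samples.
#' @param generation "F1" or "F2".
#' @param config an \code{\link{analysis_config}}.
#' @param size_factors per-sample scale factors (default all 1).
#' @param alpha significance threshold; defaults to \code{config$fdr_gene}.
#' @param alpha_strict strictness of the alpha rule (see
#'   \code{\link{call_de}}).
#' @return list with \code{calls} (gene_id, generation, the three
#'   relations, bin, group, mpv_status, log2fc_vs_mpv, p_mpv, q_mpv) and
#'   \code{mpv} (the full \code{\link{mpv_test}} table).
#' @export
classify_generation <- function(ct, generation = c("F1", "F2"),
                                config = analysis_config(),
                                size_factors = NULL, alpha = NULL,
                                alpha_strict = FALSE) {
  generation <- match.arg(generation)
  if (is.null(alpha)) alpha <- config$fdr_gene
  missing <- setdiff(c("P1", "P2", generation), ct$sample_labels)
  if (length(missing)) {
    stop("sample(s) missing from table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  de_pp <- call_de(ct, c("P1", "P2"), alpha, config$fc_threshold,
                   size_factors, config$pseudocount, alpha_strict)
  de_h1 <- call_de(ct, c(generation, "P1"), alpha, config$fc_threshold,
                   size_factors, config$pseudocount, alpha_strict)
  de_h2 <- call_de(ct, c(generation, "P2"), alpha, config$fc_threshold,
                   size_factors, config$pseudocount, alpha_strict)
  rel <- classify_trio(dir_to_rel(de_pp$direction),
                       dir_to_rel(de_h1$direction),
                       dir_to_rel(de_h2$direction))
  mpv <- mpv_test(ct, generation, size_factors, alpha, config$pseudocount,
                  alpha_strict)
  calls <- data.frame(gene_id = ct$gene_ids, generation = generation,
                      rel_P1P2 = unname(dir_to_rel(de_pp$direction)),
                      rel_HP1 = unname(dir_to_rel(de_h1$direction)),
                      rel_HP2 = unname(dir_to_rel(de_h2$direction)),
                      bin = rel$bin, group = rel$group,
                      mpv_status = mpv$status,
                      log2fc_vs_mpv = mpv$log2fc_vs_mpv,
                      p_mpv = mpv$p, q_mpv = mpv$q,
                      stringsAsFactors = FALSE)
  list(calls = calls, mpv = mpv)
}

#' Expressed, co-expressed and sample-specific gene sets
#'
#' A gene is expressed in a sample when its FPKM meets the presence cutoff;
#' co-expressed genes are expressed in every sample; a sample's specific
#' set is what it expresses beyond the co-expressed core.
#'
#' @param fpkm numeric FPKM matrix (genes x samples, dimnames set), as from
#'   \code{\link{compute_fpkm}}.
#' @param min_fpkm presence threshold (default 1).
#' @return list with \code{expressed} (named list of per-sample gene-id
#'   vectors), \code{co_expressed}, and \code{specific} (named list).
#' @export
expressed_sets <- function(fpkm, min_fpkm = 1) {
  stopifnot(min_fpkm >= 0)
  on <- fpkm >= min_fpkm
  genes <- rownames(fpkm)
  expressed <- lapply(seq_len(ncol(on)),
                      function(j) genes[on[, j]])
  names(expressed) <- colnames(fpkm)
  co <- genes[rowSums(on) == ncol(on)]
  specific <- lapply(expressed, function(g) setdiff(g, co))
  list(expressed = expressed, co_expressed = co, specific = specific)
}
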