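#' Hypergeometric upper-tail probability
#'
#' P(X >= k) for X ~ Hypergeometric(M, K, n): drawing a study set of n
#' genes from a background of M of which K carry the term, the chance of
#' seeing k or more carriers. Evaluated through the log-gamma machinery of
#' \code{stats::phyper}.
#'
#' @param k observed carriers in the study set.
#' @param K carriers in the background.
#' @param n study-set size.
#' @param M background size.
#' @return upper-tail probability in (0, 1].
#' @export
hypergeom_upper_tail <- function(k, K, n, M) {
  bad <- k < 0 | n < k | M < n | K < k | M < K | (n - k) > (M - K)
  if (any(bad)) {
    stop("inconsistent hypergeometric counts (need 0 <= k <= n <= M, ",
         "k <= K <= M, n - k <= M - K)", call. = FALSE)
  }
  stats::phyper(k - 1, K, M - K, n, lower.tail = FALSE)
}

#' Term over-representation analysis
#'
#' One upper-tail hypergeometric test per annotation term present in the
#' background, BH-corrected across terms; a term is significant when its
#' adjusted p falls strictly below \code{alpha}. Observed and expected
#' percentages mirror the bar-chart convention of enrichment figures:
#' observed = share of study genes carrying the term, expected = share of
#' background genes carrying it.
#'
#' @param study_set character vector of study gene ids; must be a subset of
#'   \code{background}.
#' @param meta gene metadata with list-column \code{go_terms}.
#' @param background character vector of background gene ids (e.g. the
#'   co-expressed set).
#' @param alpha significance cutoff on the BH-adjusted p (default 0.05,
#'   strict).
#' @return data frame: term_id, k, n, K, M, observed_pct, expected_pct, p,
#'   q, significant; ordered by p. Terms absent from the background are
#'   skipped.
#' @export
enrich <- function(study_set, meta, background, alpha = 0.05) {
  study_set <- unique(as.character(study_set))
  background <- unique(as.character(background))
  if (!length(study_set) || !length(background)) {
    stop("study set and background must be non-empty", call. = FALSE)
  }
  if (!all(study_set %in% background)) {
    stop("study set must be a subset of the background", call. = FALSE)
  }
  idx <- match(background, meta$gene_id)
  if (anyNA(idx)) {
    stop("background gene(s) missing from metadata: ",
         paste(utils::head(background[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  }
  bg_terms <- meta$go_terms[idx]
  n_terms <- lengths(bg_terms)
  term_of_gene <- data.frame(
    gene_id = rep(background, n_terms),
    term_id = unlist(bg_terms, use.names = FALSE),
    stringsAsFactors = FALSE)
  if (!nrow(term_of_gene)) {
    return(data.frame(term_id = character(0), k = integer(0),
                      n = integer(0), K = integer(0), M = integer(0),
                      observed_pct = numeric(0), expected_pct = numeric(0),
                      p = numeric(0), q = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE))
  }
  M <- length(background)
  n <- length(study_set)
  K_tab <- table(term_of_gene$term_id)
  in_study <- term_of_gene$gene_id %in% study_set
  k_tab <- table(factor(term_of_gene$term_id[in_study],
                        levels = names(K_tab)))
  terms <- names(K_tab)
  K <- as.integer(K_tab)
  k <- as.integer(k_tab)
  p <- hypergeom_upper_tail(k, K, n, M)
  q <- bh_adjust(p)
  out <- data.frame(term_id = terms, k = k, n = n, K = K, M = M,
                    observed_pct = 100 * k / n, expected_pct = 100 * K / M,
                    p = p, q = q, significant = q < alpha,
                    stringsAsFactors = FALSE)
  out[order(out$p, out$term_id), , drop = FALSE]
}
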