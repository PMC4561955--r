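#' Exact two-library count test (Audic-Claverie)
#'
#' Tests whether a feature's counts in two unreplicated libraries are
#' consistent with one underlying rate. Conditional on the count x in
#' library 1, the count in library 2 under the null follows
#' \deqn{p(y | x) = (n_2/n_1)^y \frac{(x+y)!}{x!\,y!\,(1+n_2/n_1)^{x+y+1}},}
#' a negative binomial with size x+1 and success probability
#' n1/(n1+n2), which is how it is evaluated here (log-space stable for
#' counts in the millions). The returned p is the doubled smaller tail,
#' clipped to 1.
#'
#' @param x,y counts in libraries 1 and 2 (vectors recycle).
#' @param n1,n2 positive library sizes.
#' @return two-sided p-values in (0, 1].
#' @export
exact_count_test <- function(x, n1, y, n2) {
  k <- max(length(x), length(y), length(n1), length(n2))
  x <- rep_len(as.numeric(x), k); y <- rep_len(as.numeric(y), k)
  n1 <- rep_len(as.numeric(n1), k); n2 <- rep_len(as.numeric(n2), k)
  if (any(!is.finite(c(x, y, n1, n2))) || any(c(n1, n2) <= 0) ||
      any(c(x, y) < 0)) {
    stop("exact_count_test: counts must be >= 0 and sizes > 0, all finite",
         call. = FALSE)
  }
  prob <- n1 / (n1 + n2)
  p_low <- stats::pnbinom(y, size = x + 1, prob = prob)
  p_high <- 1 - stats::pnbinom(y - 1, size = x + 1, prob = prob)
  pmin(1, 2 * pmin(p_low, p_high))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: with sorted p-values p_(1) <= ... <= p_(m),
#' q_(i) = min over j >= i of p_(j) m / j, clipped to 1 and mapped back to
#' the input order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return q-values, same length and order as \code{p}.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("bh_adjust: p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(p[o] * m / seq(m, 1)))
  q[order(o)]
}

#' Shifted log2 fold change
#'
#' \code{log2((a + pseudocount) / (b + pseudocount))} on normalized counts;
#' the pseudocount keeps zeros finite.
#'
#' @param a_norm,b_norm non-negative normalized expression values.
#' @param pseudocount positive shift, default 1.
#' @return log2 ratio, antisymmetric in its first two arguments.
#' @export
log2_fold_change <- function(a_norm, b_norm, pseudocount = 1) {
  stopifnot(pseudocount > 0)
  log2((a_norm + pseudocount) / (b_norm + pseudocount))
}

#' Pairwise differential-expression call for one sample pair
#'
#' Per gene: the exact test on raw counts at the raw library sizes, BH
#' adjustment across all genes of this pair, and a strict fold-change gate
#' on size-factor-normalized counts. A gene is UP when q <= alpha and
#' log2fc > log2(fc) (numerator sample higher), DOWN for the mirror, NS
#' otherwise; a fold change of exactly fc fails the gate.
#'
#' @param ct a \code{\link{count_table}} containing both samples.
#' @param pair character vector of length 2, (numerator, denominator).
#' @param alpha FDR threshold (default 0.001).
#' @param fc fold-change threshold > 1 (default 2).
#' @param size_factors optional per-sample scale factors used only for the
#'   fold change; default all 1.
#' @param pseudocount shift for the fold change (default 1).
#' @param alpha_strict if TRUE the significance rule is q < alpha (the
#'   miRNA-layer convention); default FALSE gives q <= alpha.
#' @return data frame: gene_id, x, y, log2fc, p, q, direction.
#' @export
call_de <- function(ct, pair, alpha = 0.001, fc = 2, size_factors = NULL,
                    pseudocount = 1, alpha_strict = FALSE) {
  stopifnot(length(pair) == 2)
  missing <- setdiff(pair, ct$sample_labels)
  if (length(missing)) {
    stop("sample(s) not in table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(size_factors)) {
    size_factors <- stats::setNames(rep(1, length(ct$sample_labels)),
                                    ct$sample_labels)
  }
  x <- ct$counts[, pair[1]]
  y <- ct$counts[, pair[2]]
  n1 <- ct$library_sizes[[pair[1]]]
  n2 <- ct$library_sizes[[pair[2]]]
  if (!length(x)) {
    return(data.frame(gene_id = character(0), x = numeric(0), y = numeric(0),
                      log2fc = numeric(0), p = numeric(0), q = numeric(0),
                      direction = character(0), stringsAsFactors = FALSE))
  }
  p <- exact_count_test(x, n1, y, n2)
  q <- bh_adjust(p)
  l2fc <- log2_fold_change(x / size_factors[[pair[1]]],
                           y / size_factors[[pair[2]]], pseudocount)
  sig <- if (alpha_strict) q < alpha else q <= alpha
  direction <- rep("NS", length(x))
  direction[sig & l2fc > log2(fc)] <- "UP"
  direction[sig & l2fc < -log2(fc)] <- "DOWN"
  data.frame(gene_id = ct$gene_ids, x = unname(x), y = unname(y),
             log2fc = unname(l2fc), p = unname(p), q = unname(q),
             direction = direction, stringsAsFactors = FALSE)
}
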