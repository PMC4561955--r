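#' FPKM normalization
#'
#' Converts raw fragment counts to fragments per kilobase of transcript per
#' million mapped fragments: \eqn{10^9 C / (N L)} where C is the per-gene
#' count, N the per-library mapped-fragment total and L the transcript
#' length in bp. A value is zero exactly when the underlying count is zero.
#'
#' @param ct a \code{\link{count_table}}.
#' @param meta gene metadata from \code{\link{read_gene_meta}} (or any data
#'   frame with \code{gene_id} and \code{length_bp}); every gene in
#'   \code{ct} must have a length.
#' @return numeric matrix of FPKM values, same dimnames as the counts.
#' @export
compute_fpkm <- function(ct, meta) {
  idx <- match(ct$gene_ids, meta$gene_id)
  if (anyNA(idx)) {
    stop("gene(s) missing a length: ",
         paste(utils::head(ct$gene_ids[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  }
  len <- as.numeric(meta$length_bp[idx])
  if (any(ct$library_sizes <= 0)) {
    stop("library sizes must be positive", call. = FALSE)
  }
  fpkm <- 1e9 * sweep(ct$counts, 2, ct$library_sizes, "/") / len
  fpkm
}

#' Median-of-ratios size factors
#'
#' The scaling used for count-level comparisons of the small-RNA layer:
#' each sample's factor is the median, over genes with all-positive counts,
#' of that sample's count divided by the gene's geometric mean across
#' samples. Factors are then divided by their own geometric mean so they
#' multiply to 1.
#'
#' @param ct a \code{\link{count_table}}.
#' @return numeric vector of positive size factors, named by sample, with
#'   geometric mean 1.
#' @export
size_factors_median_ratio <- function(ct) {
  m <- ct$counts
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos)) {
    stop("degenerate input: no gene has positive counts in every sample",
         call. = FALSE)
  }
  lm <- log(m[pos, , drop = FALSE])
  geo <- rowMeans(lm)
  raw <- exp(apply(lm - geo, 2, stats::median))
  sf <- raw / exp(mean(log(raw)))
  stats::setNames(sf, ct$sample_labels)
}

normalized_counts <- function(ct, size_factors) {
  sweep(ct$counts, 2, size_factors[ct$sample_labels], "/")
}
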