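# Independent oracles, deliberately implemented by different routes than
# the package code they check.

# Audic-Claverie conditional pmf straight from the Gamma-function formula,
# in log space; the package route goes through pnbinom instead.
ac_pmf_oracle <- function(yprime, x, n1, n2) {
  r <- n2 / n1
  exp(yprime * log(r) + lgamma(x + yprime + 1) - lgamma(x + 1) -
        lgamma(yprime + 1) - (x + yprime + 1) * log1p(r))
}

ac_two_sided_oracle <- function(x, n1, y, n2) {
  ys <- 0:max(y, ceiling(x * n2 / n1 + 50 * sqrt(x + 1) + 200))
  pmf <- ac_pmf_oracle(ys, x, n1, n2)
  p_low <- sum(pmf[ys <= y])
  p_high <- sum(pmf[ys >= y])
  min(1, 2 * min(p_low, p_high))
}

# BH by its textbook definition: sort, q_(i) = min_{j >= i} p_(j) m / j.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Hypergeometric upper tail by explicit enumeration of all n-subsets of a
# background of M genes of which the first K carry the term (M <= 12).
hyper_upper_enum <- function(k, K, n, M) {
  subsets <- utils::combn(M, n)
  carriers <- colSums(subsets <= K)
  mean(carriers >= k)
}

# Small count_table builder for fixtures.
make_ct <- function(mat, ids = NULL, samples = c("P1", "P2", "F1", "F2"),
                    lib = NULL) {
  mat <- as.matrix(mat)
  if (is.null(ids)) ids <- paste0("g", seq_len(nrow(mat)))
  count_table(mat, ids, samples[seq_len(ncol(mat))], library_sizes = lib)
}

# The 27-triple classification oracle, written out literally and kept
# independent of the package's lookup.
trio_oracle <- local({
  lv <- c("GT", "LT", "NS")
  grid <- expand.grid(pp = lv, h1 = lv, h2 = lv, stringsAsFactors = FALSE)
  bin <- rep("AMBIGUOUS", nrow(grid))
  grp <- rep("AMBIGUOUS", nrow(grid))
  set_row <- function(pp, h1, h2, b, g) {
    i <- which(grid$pp == pp & grid$h1 == h1 & grid$h2 == h2)
    bin[i] <<- b; grp[i] <<- g
  }
  set_row("LT", "GT", "LT", "I", "ADDITIVITY")
  set_row("GT", "LT", "GT", "XII", "ADDITIVITY")
  set_row("LT", "NS", "LT", "II", "ELD_P1")
  set_row("GT", "NS", "GT", "XI", "ELD_P1")
  set_row("LT", "GT", "NS", "IV", "ELD_P2")
  set_row("GT", "LT", "NS", "IX", "ELD_P2")
  set_row("LT", "GT", "GT", "V", "TRANSGRESSIVE_UP")
  set_row("NS", "GT", "GT", "VI", "TRANSGRESSIVE_UP")
  set_row("GT", "GT", "GT", "VIII", "TRANSGRESSIVE_UP")
  set_row("LT", "LT", "LT", "III", "TRANSGRESSIVE_DOWN")
  set_row("NS", "LT", "LT", "VII", "TRANSGRESSIVE_DOWN")
  set_row("GT", "LT", "LT", "X", "TRANSGRESSIVE_DOWN")
  set_row("NS", "NS", "NS", "NO_CHANGE", "CONSERVED")
  cbind(grid, bin = bin, group = grp, stringsAsFactors = FALSE)
})

# Planted coupled links of a simulated miRNA layer: the rows of the map
# that carry a mean adjustment (decoy links excluded).
coupled_links <- function(mir) {
  tgt <- mir$gene_truth$target_of
  names(tgt) <- mir$gene_truth$gene_id
  keep <- !is.na(tgt[mir$target_map$gene_id]) &
    tgt[mir$target_map$gene_id] == mir$target_map$mirna_id
  mir$target_map[keep, , drop = FALSE]
}
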