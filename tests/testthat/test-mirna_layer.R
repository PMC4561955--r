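pair_tables <- function(mx, gy) {
  list(m = data.frame(mirna_id = paste0("m", seq_along(mx)),
                      log2fc_vs_mpv = mx, stringsAsFactors = FALSE),
       g = data.frame(gene_id = paste0("g", seq_along(gy)),
                      log2fc_vs_mpv = gy, stringsAsFactors = FALSE),
       map = data.frame(mirna_id = paste0("m", seq_along(mx)),
                        gene_id = paste0("g", seq_along(gy)),
                        stringsAsFactors = FALSE))
}

test_that("correlation matches closed forms and the hand oracle", {
  pt <- pair_tables(c(1, 2, 3, 4), c(-1, -2, -3, -4))
  res <- mirna_target_correlation(pt$m, pt$g, pt$map)
  expect_equal(res$r, -1)
  expect_equal(res$n_pairs, 4)

  pt2 <- pair_tables(c(1, 2, 3), c(2, 4, 6))
  expect_equal(mirna_target_correlation(pt2$m, pt2$g, pt2$map)$r, 1)

  x <- c(0, 1, 2, 3); y <- c(1, 0, 2, 1)
  pt3 <- pair_tables(x, y)
  res3 <- mirna_target_correlation(pt3$m, pt3$g, pt3$map)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res3$r, r_hand, tolerance = 1e-12)
  t_hand <- r_hand * sqrt(2 / (1 - r_hand^2))
  expect_equal(res3$p, 2 * pt(-abs(t_hand), df = 2), tolerance = 1e-12)
})

test_that("correlation sign behaves under affine transforms", {
  set.seed(3)
  x <- rnorm(30); y <- -x + rnorm(30, sd = 0.2)
  pt <- pair_tables(x, y)
  r0 <- mirna_target_correlation(pt$m, pt$g, pt$map)$r
  pt_aff <- pair_tables(2 * x + 5, 0.3 * y - 7)
  expect_equal(mirna_target_correlation(pt_aff$m, pt_aff$g, pt_aff$map)$r,
               r0, tolerance = 1e-12)
  pt_neg <- pair_tables(-x, y)
  expect_equal(mirna_target_correlation(pt_neg$m, pt_neg$g, pt_neg$map)$r,
               -r0, tolerance = 1e-12)
})

test_that("degenerate pair sets raise errors", {
  pt <- pair_tables(c(1, 2), c(2, 1))
  expect_error(mirna_target_correlation(pt$m, pt$g, pt$map), "fewer than 3")
  flat <- pair_tables(c(1, 1, 1, 1), c(0, 1, 2, 3))
  expect_error(mirna_target_correlation(flat$m, flat$g, flat$map),
               "zero variance")
})

test_that("one miRNA expands to one pair per target", {
  m <- data.frame(mirna_id = "m1", log2fc_vs_mpv = 2)
  g <- data.frame(gene_id = paste0("g", 1:4),
                  log2fc_vs_mpv = c(-2.2, -1.8, -2.1, -1.9))
  map <- data.frame(mirna_id = "m1", gene_id = paste0("g", 1:4))
  expect_error(mirna_target_correlation(m, g, map), "zero variance")
  # add a second miRNA so the x-axis varies; the first still gives 4 pairs
  m2 <- rbind(m, data.frame(mirna_id = "m2", log2fc_vs_mpv = -1))
  map2 <- rbind(map, data.frame(mirna_id = "m2", gene_id = "g1"))
  res <- mirna_target_correlation(m2, g, map2)
  expect_equal(res$n_pairs, 5)
  expect_equal(sum(res$pairs$mirna_id == "m1"), 4)
})

test_that("classify_mirna is classify_generation with miRNA conventions", {
  set.seed(19)
  m <- matrix(rpois(400 * 4, 80), 400, 4)
  m[1, ] <- c(500, 500, 20, 20)  # planted repressed miRNA
  ct <- make_ct(m, lib = rep(1e6, 4))
  cfg <- analysis_config()
  res <- classify_mirna(ct, "F1", cfg)
  expect_identical(res$mpv$status[1], "NONADDITIVE_DOWN")

  sf <- size_factors_median_ratio(ct)
  ref <- classify_generation(ct, "F1", cfg, size_factors = sf,
                             alpha = cfg$fdr_mirna, alpha_strict = TRUE)
  ref_calls <- ref$calls
  names(ref_calls)[1] <- "mirna_id"
  expect_identical(res$calls, ref_calls)
})

test_that("the strict alpha rule excludes q exactly at the threshold", {
  n <- 50
  m <- matrix(rep(c(200, 200, 200, 200), each = n), n, 4)
  m[1, ] <- c(100, 100, 160, 100)
  ct <- make_ct(m, lib = rep(1e6, 4))
  res <- mpv_test(ct, "F1", alpha = 1)  # capture this gene's q
  q1 <- res$q[1]
  strict <- mpv_test(ct, "F1", alpha = q1, alpha_strict = TRUE)
  loose <- mpv_test(ct, "F1", alpha = q1, alpha_strict = FALSE)
  expect_identical(strict$status[1], "ADDITIVE")
  expect_identical(loose$status[1], "NONADDITIVE_UP")
})
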