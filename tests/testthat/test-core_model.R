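write_tsv_fixture <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("read_count_table parses, derives library sizes, keeps order", {
  f <- write_tsv_fixture(c("gene_id\tP1\tP2\tF1\tF2",
                           "gB\t10\t20\t15\t15",
                           "gA\t0\t0\t0\t0"))
  ct <- read_count_table(f)
  expect_s3_class(ct, "count_table")
  expect_identical(ct$gene_ids, c("gB", "gA"))  # input order preserved
  expect_equal(unname(ct$library_sizes), c(10, 20, 15, 15))

  zero <- write_tsv_fixture(c("gene_id\tP1\tP2\tF1\tF2",
                              "g1\t0\t0\t0\t0",
                              "g2\t0\t0\t0\t0",
                              "g3\t0\t0\t0\t0"))
  expect_equal(unname(read_count_table(zero)$library_sizes), rep(0, 4))
})

test_that("read_count_table rejects malformed input", {
  neg <- write_tsv_fixture(c("gene_id\tP1\tP2\tF1\tF2",
                             "g1\t5\t-1\t2\t2"))
  expect_error(read_count_table(neg), "negative")
  frac <- write_tsv_fixture(c("gene_id\tP1\tP2\tF1\tF2",
                              "g1\t5\t1.5\t2\t2"))
  expect_error(read_count_table(frac), "non-integer")
  dup <- write_tsv_fixture(c("gene_id\tP1\tP2\tF1\tF2",
                             "g1\t1\t1\t1\t1", "g1\t2\t2\t2\t2"))
  expect_error(read_count_table(dup), "duplicate")
  short <- write_tsv_fixture(c("gene_id\tP1\tP2\tF1", "g1\t1\t1\t1"))
  expect_error(read_count_table(short), "F2")
})

test_that("count_table validates explicit library sizes", {
  expect_error(
    count_table(matrix(5, 1, 2), "g1", c("P1", "P2"),
                library_sizes = c(4, 10)),
    "column sums")
  ct <- count_table(matrix(5, 1, 2), "g1", c("P1", "P2"),
                    library_sizes = c(100, 200))
  expect_equal(unname(ct$library_sizes), c(100, 200))
})

test_that("read_gene_meta parses lengths and term sets", {
  f <- write_tsv_fixture(c("gene_id\tlength_bp\tgo_terms",
                           "g1\t1000\tGO:0005515;GO:0008270",
                           "g2\t500\t"))
  meta <- read_gene_meta(f)
  expect_equal(meta$length_bp, c(1000L, 500L))
  expect_equal(meta$go_terms[[1]], c("GO:0005515", "GO:0008270"))
  expect_length(meta$go_terms[[2]], 0)

  bad <- write_tsv_fixture(c("gene_id\tlength_bp\tgo_terms",
                             "g3\t0\tGO:0005515"))
  expect_error(read_gene_meta(bad), "positive integer")
})

test_that("count table round-trips exactly through TSV", {
  ct <- make_ct(matrix(c(10, 20, 15, 15, 0, 0, 0, 0, 3, 1, 4, 1),
                       nrow = 3, byrow = TRUE))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(ct, f)
  back <- read_count_table(f)
  expect_identical(back$counts, ct$counts)
  expect_identical(back$gene_ids, ct$gene_ids)
  expect_equal(back$library_sizes, ct$library_sizes)
})

test_that("write_results is byte-stable and records the seed", {
  tab <- data.frame(gene_id = c("g2", "g1"), value = c(1.23456789, pi),
                    stringsAsFactors = FALSE)
  cfg <- analysis_config(seed = 42L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_results(list(res = tab), d1, cfg)
  write_results(list(res = tab), d2, cfg)
  expect_identical(readLines(file.path(d1, "res.tsv")),
                   readLines(file.path(d2, "res.tsv")))
  man <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_equal(man$seed, 42L)
  # rows sorted by id, floats at 6 significant digits
  lines <- readLines(file.path(d1, "res.tsv"))
  expect_match(lines[2], "^g1\t3.14159")

  empty <- data.frame(gene_id = character(0), value = numeric(0))
  d3 <- withr::local_tempdir()
  write_results(list(empty = empty), d3, cfg)
  expect_identical(readLines(file.path(d3, "empty.tsv")), "gene_id\tvalue")
})

test_that("read_config round-trips YAML and rejects unknown keys", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("fdr_gene: 0.01", "seed: 7"), f)
  cfg <- read_config(f)
  expect_equal(cfg$fdr_gene, 0.01)
  expect_equal(cfg$seed, 7L)
  expect_equal(cfg$fc_threshold, 2)
  writeLines("fdr_genes: 0.01", f)
  expect_error(read_config(f), "unknown config key")
})
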