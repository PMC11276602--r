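test_that("expression matrix TSV + metadata round trip preserves labels and values", {
  vals <- matrix(c(1.5, 2.25, 3.125, 4.0625, 5.5, 6.75), 3, 2,
                 dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  m <- make_expr(vals, platform = c("microarray", "rnaseq"),
                 origin_class = c("lung", "breast"))
  mp <- withr::local_tempfile(fileext = ".tsv")
  dp <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(m, mp)
  write_metadata(m, dp)
  m2 <- read_expression(mp, dp)
  expect_identical(feature_names(m2), c("g1", "g2", "g3"))
  expect_identical(sample_ids(m2), c("s1", "s2"))
  expect_equal(m2$values, m$values, tolerance = 1e-12)
  expect_identical(unname(m2$platform), c("microarray", "rnaseq"))
  expect_identical(unname(m2$origin_class), c("lung", "breast"))
})

test_that("duplicate gene rows collapse to the highest-mean row", {
  mp <- withr::local_tempfile(fileext = ".tsv")
  dp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2",
               "TP53\t5\t5",
               "KRAS\t1\t2",
               "TP53\t2\t2"), mp)
  writeLines(c("sample_id\tplatform\torigin_class",
               "s1\tp1\tlung", "s2\tp1\tlung"), dp)
  m <- read_expression(mp, dp)
  expect_identical(sort(feature_names(m)), c("KRAS", "TP53"))
  expect_equal(unname(m$values["TP53", ]), c(5, 5))
})

test_that("samples without metadata are rejected", {
  mp <- withr::local_tempfile(fileext = ".tsv")
  dp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "g1\t1\t2"), mp)
  writeLines(c("sample_id\tplatform\torigin_class", "s1\tp1\tlung"), dp)
  expect_error(read_expression(mp, dp), "unannotated sample")
})

test_that("metadata row order does not affect the join", {
  mp <- withr::local_tempfile(fileext = ".tsv")
  d1 <- withr::local_tempfile(fileext = ".tsv")
  d2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "g1\t1\t2", "g2\t3\t4"), mp)
  writeLines(c("sample_id\tplatform\torigin_class",
               "s1\tp1\tlung", "s2\tp2\tbreast"), d1)
  writeLines(c("sample_id\tplatform\torigin_class",
               "s2\tp2\tbreast", "s1\tp1\tlung"), d2)
  m1 <- read_expression(mp, d1)
  m2 <- read_expression(mp, d2)
  expect_identical(m1$platform, m2$platform)
  expect_identical(m1$origin_class, m2$origin_class)
  expect_identical(m1$values, m2$values)
})

test_that("malformed matrices are rejected", {
  mp <- withr::local_tempfile(fileext = ".tsv")
  dp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tplatform\torigin_class", "s1\tp1\tx"), dp)
  writeLines(c("gene_id\ts1", "g1\tnot_a_number"), mp)
  expect_error(read_expression(mp, dp), "non-numeric")
  writeLines("gene_id\ts1", mp)
  expect_error(read_expression(mp, dp), "empty matrix")
  expect_error(expression_matrix(matrix(NaN, 1, 1,
                                        dimnames = list("g", "s")), "p"),
               "non-finite")
  expect_error(expression_matrix(matrix(1:4, 2, 2,
                                        dimnames = list(c("g", "g"), c("a", "b"))),
                                 c("p", "p")),
               "duplicate gene")
})

test_that("GMT parsing deduplicates members, keeps file order, rejects bad lines", {
  gp <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("SET_A\tdesc\tg1\tg2\tg2",
               "SET_B\tother\tg3"), gp)
  gs <- read_gmt(gp)
  expect_identical(names(gs$sets), c("SET_A", "SET_B"))
  expect_identical(gs$sets$SET_A, c("g1", "g2"))
  expect_identical(unname(gs$description["SET_A"]), "desc")
  expect_length(gs, 2L)

  writeLines("SET_B\tdesc", gp)
  expect_error(read_gmt(gp), "no members")
  writeLines(c("SET_A\td\tg1", "SET_A\td\tg2"), gp)
  expect_error(read_gmt(gp), "duplicate gene-set name")
})

test_that("GMT write/read round trip is lossless", {
  gs <- gene_set_collection(list(PATH_ONE = c("g1", "g5", "g2"),
                                 PATH_TWO = c("g9")),
                            description = c(PATH_ONE = "first",
                                            PATH_TWO = "second"))
  gp <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(gs, gp)
  gs2 <- read_gmt(gp)
  expect_identical(gs2$sets, gs$sets)
  expect_identical(gs2$description, gs$description)
})

test_that("a 1x1 matrix writes as two lines and enrichment TSVs round trip", {
  vals <- matrix(pi, 1, 1, dimnames = list("SET_X", "s1"))
  em <- cuporigin:::new_annotated_matrix(vals, platform = "p1",
                                         origin_class = "lung",
                                         class = "enrichment_matrix",
                                         what = "gene_set")
  mp <- withr::local_tempfile(fileext = ".tsv")
  dp <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(em, mp)
  expect_length(readLines(mp), 2L)
  expect_match(readLines(mp)[1], "^gene_set\t")
  write_metadata(em, dp)
  em2 <- read_enrichment(mp, dp)
  expect_equal(em2$values, em$values, tolerance = 1e-12)
})

test_that("origin vocabulary validates its classes", {
  expect_identical(as.character(origin_vocabulary(c("lung", "breast"))),
                   c("lung", "breast"))
  expect_error(origin_vocabulary(c("lung", "lung")), "duplicate")
  expect_error(origin_vocabulary(c("lung", "")), "non-empty")
})
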