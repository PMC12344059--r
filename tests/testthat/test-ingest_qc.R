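make_cm <- function(m, age = NULL, condition = NULL) {
  cd <- data.frame(barcode = colnames(m))
  if (!is.null(age)) cd$age <- age
  if (!is.null(condition)) cd$condition <- condition
  count_matrix(m, cd)
}

test_that("10x triplet write/read round-trips counts, gene ids and barcodes", {
  m <- matrix(c(0, 1, 5, 0, 2, 0, 7, 3, 0, 0, 0, 4), nrow = 3,
              dimnames = list(c("mt:CoI", "gA", "gB"), paste0("bc", 1:4)))
  cm <- make_cm(m, age = rep("old", 4), condition = rep("axenic", 4))
  dir <- withr::local_tempdir()
  write_counts_10x(cm, dir)
  back <- read_counts_10x(dir)
  expect_identical(as.matrix(back$counts), as.matrix(cm$counts))
  expect_identical(rownames(back$counts), rownames(m))
  expect_identical(back$cell_data$barcode, colnames(m))
  expect_identical(back$cell_data$age, rep("old", 4))
  # mt: prefix flags mitochondrial genes
  expect_identical(back$gene_data$is_mitochondrial, c(TRUE, FALSE, FALSE))
})

test_that("dimension mismatches and non-integer entries are format errors", {
  m <- matrix(1:12, nrow = 3, dimnames = list(paste0("g", 1:3), paste0("b", 1:4)))
  dir <- withr::local_tempdir()
  write_counts_10x(make_cm(m), dir)
  writeLines(paste0("b", 1:3), file.path(dir, "barcodes.tsv"))
  expect_error(read_counts_10x(dir), "format error")
  expect_error(count_matrix(matrix(c(0.5, 1), 1, 2,
                                   dimnames = list("g", c("a", "b"))),
                            data.frame(barcode = c("a", "b"))),
               "non-negative integers")
})

test_that("qc_filter applies inclusive feature bounds and a strict mito rule", {
  # three cells: too few genes, acceptable, too mitochondrial
  n_genes <- 600
  m <- matrix(0L, nrow = n_genes, ncol = 3,
              dimnames = list(c("mt:g1", paste0("g", 2:n_genes)), paste0("c", 1:3)))
  m[2:151, 1] <- 1L                      # 150 genes detected
  m[2:501, 2] <- 1L; m[1, 2] <- 5L       # 501 genes, mito 5/505 ~ 1%
  m[2:501, 3] <- 1L; m[1, 3] <- 215L     # mito 215/715 ~ 30%
  res <- qc_filter(make_cm(m), min_features = 200, max_features = 2500,
                   max_mito_fraction = 0.20)
  expect_identical(colnames(res$counts$counts), "c2")
  expect_equal(res$report$n_low_features, 1)
  expect_equal(res$report$n_high_mito, 1)

  # boundary: exactly 200 detected genes is retained (closed interval)
  mb <- matrix(0L, nrow = 300, ncol = 1,
               dimnames = list(paste0("g", 1:300), "cell1"))
  mb[1:200, 1] <- 1L
  expect_equal(qc_filter(make_cm(mb))$report$n_retained, 1)

  # no mitochondrial genes: mito criterion removes nothing
  expect_equal(qc_filter(make_cm(mb))$report$n_high_mito, 0)

  # idempotence
  once <- qc_filter(make_cm(m))
  twice <- qc_filter(once$counts)
  expect_identical(as.matrix(twice$counts$counts), as.matrix(once$counts$counts))

  # removing every cell warns rather than failing silently
  expect_warning(qc_filter(make_cm(m), min_features = 550, max_features = 600),
                 "every cell")
})

test_that("normalization evaluates log2(1 + scale * count / total) exactly", {
  m <- matrix(c(1L, 3L), nrow = 2, dimnames = list(c("g1", "g2"), "c1"))
  nm <- normalize_log(make_cm(m), scale = 1e4)
  v <- as.numeric(as.matrix(nm$values))
  expect_equal(v, c(log2(1 + 1e4 * 1 / 4), log2(1 + 1e4 * 3 / 4)))
  expect_equal(round(v, 3), c(11.288, 12.873))

  # zeros stay exactly zero; equal counts give equal values
  m2 <- matrix(c(2L, 2L, 0L, 2L), nrow = 2,
               dimnames = list(c("g1", "g2"), c("c1", "c2")))
  v2 <- as.matrix(normalize_log(make_cm(m2))$values)
  expect_identical(v2["g1", "c1"], v2["g2", "c1"])
  expect_identical(v2["g1", "c2"], 0)

  # zero-total cell errors with its barcode
  m3 <- matrix(c(1L, 0L), nrow = 1, dimnames = list("g1", c("ok", "empty")))
  expect_error(normalize_log(make_cm(m3)), "empty")
})
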