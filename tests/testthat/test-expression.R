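make_em <- function(v) {
  rownames(v) <- paste0("g", seq_len(nrow(v)))
  colnames(v) <- paste0("o", seq_len(ncol(v)))
  expr_matrix(v)
}

test_that("log2 transform maps powers of two and sentinels correctly", {
  m <- make_em(matrix(c(8, 1, -1, 0, 2, 16), 2, 3))
  out <- log2_transform(m)
  expect_equal(out$values[1, 1], 3)
  expect_equal(out$values[2, 1], 0)     # log2(1)
  expect_true(is.na(out$values[1, 2]))  # negative sentinel
  expect_true(is.na(out$values[2, 2]))  # zero under plain log2
  # pseudocount alternative keeps zeros, still drops the sentinel
  out2 <- log2_transform(m, pseudocount = 1)
  expect_equal(out2$values[2, 2], 0)
  expect_true(is.na(out2$values[1, 2]))
})

test_that("replicate experiments average per voxel, ignoring missing", {
  values <- rbind(c(2, 2, NA), c(4, NA, NA), c(7, 7, 7))
  info <- data.frame(experiment_id = c("e1", "e2", "e3"),
                     gene = c("gA", "gA", "gB"),
                     plane = "coronal")
  out <- average_replicate_experiments(experiment_set(values, info))
  expect_equal(unname(out$values["gA", ]), c(3, 2, NA))
  # single-experiment gene passes through identically
  expect_equal(unname(out$values["gB", ]), c(7, 7, 7))
  expect_error(average_replicate_experiments(
    experiment_set(values[0, , drop = FALSE], info[0, ])), "empty")
})

test_that("missingness filter is strictly greater-than", {
  v <- matrix(0, 3, 100)
  v[1, 1:21] <- NA    # 21% missing: removed
  v[2, 1:20] <- NA    # exactly 20%: retained
  out <- filter_genes_by_missingness(make_em(v), 0.2)
  expect_identical(rownames(out$values), c("g2", "g3"))
  complete <- make_em(matrix(rnorm(30), 3, 10))
  expect_identical(filter_genes_by_missingness(complete)$values,
                   complete$values)
  # idempotence
  expect_identical(filter_genes_by_missingness(out, 0.2)$values, out$values)
})

test_that("KNN imputation equals the brute-force oracle", {
  # four-observation toy, one missing cell, k = 2
  v <- rbind(c(1, 1.1, 5, NA), c(2, 2.1, 9, 2.05), c(3, 3.1, 1, 3.05))
  out <- knn_impute(make_em(v), k = 2)
  # nearest two observations carrying g1 are o1 and o2 (o3 is far)
  expect_equal(out$values[1, 4], mean(c(1, 1.1)))
  expect_equal(out$values, oracle_knn(v, 2), ignore_attr = TRUE)
  # exhaustive small random instances
  set.seed(41)
  for (rep in 1:30) {
    nr <- sample(2:6, 1); nc <- sample(3:6, 1)
    v <- matrix(rnorm(nr * nc), nr, nc)
    v[sample(length(v), max(1, floor(length(v) * 0.15)))] <- NA
    if (any(rowSums(!is.na(v)) < 2) || any(colSums(!is.na(v)) == 0)) next
    k <- min(2, min(rowSums(!is.na(v))))
    expect_equal(knn_impute(v, k), oracle_knn(v, k))
  }
  # observed entries never change; imputation is idempotent
  v <- matrix(rnorm(24), 4, 6); v[2, 3] <- NA
  out <- knn_impute(v, k = 3)
  expect_identical(out[-2, ], v[-2, ])
  expect_identical(knn_impute(out, k = 3), out)
  # degenerate inputs
  all_na <- make_em(rbind(c(NA, NA, NA), c(1, 2, 3)))
  expect_error(knn_impute(all_na, 1), "g1")
  expect_identical(knn_impute(make_em(matrix(1:4 + 0, 2)), 1)$values,
                   make_em(matrix(1:4 + 0, 2))$values)
})

test_that("homolog intersection aligns rows one-to-one", {
  tab <- data.frame(group_id = c(1, 2, 3, 3),
                    mouse_symbol = c("a", "b", "c", "c2"),
                    human_symbol = c("A", "B", "C", "C"))
  # many-to-many group 3 is dropped entirely
  expect_identical(resolve_homologs(tab)$mouse_symbol, c("a", "b"))
  mouse <- make_em(matrix(rnorm(9), 3, 3)); rownames(mouse$values) <- c("a", "b", "z")
  human <- make_em(matrix(rnorm(9), 3, 3)); rownames(human$values) <- c("B", "A", "Q")
  out <- intersect_homologous_genes(mouse, human, tab)
  expect_identical(rownames(out$mouse$values), c("a", "b"))
  expect_identical(rownames(out$human$values), c("A", "B"))
  expect_equal(out$human$values["B", ], human$values["B", ])
  disjoint <- tab; disjoint$mouse_symbol <- c("x1", "x2", "x3", "x4")
  expect_error(intersect_homologous_genes(mouse, human, disjoint),
               "no homologous genes")
  # identity table on identical symbol sets leaves matrices aligned
  idt <- data.frame(group_id = 1:3, mouse_symbol = c("a", "b", "z"),
                    human_symbol = c("a", "b", "z"))
  human2 <- make_em(matrix(rnorm(9), 3, 3))
  rownames(human2$values) <- c("a", "b", "z")
  out2 <- intersect_homologous_genes(mouse, human2, idt)
  expect_identical(out2$mouse$values, mouse$values)
  expect_identical(out2$human$values, human2$values)
})

test_that("two-step normalization satisfies its exact identities", {
  set.seed(11)
  v <- matrix(rnorm(60, sd = 3), 6, 10)
  out <- normalize_expression(make_em(v))$values
  # step 2 forces every gene's mean over observations to exactly 0
  expect_lt(max(abs(rowMeans(out))), 1e-12)
  # hand computation on a 3x2 matrix (genes x observations)
  m <- matrix(c(0, 1, 4, 2, 3, 7), 3, 2)
  z <- apply(m, 2, function(col) (col - mean(col)) / sd(col))
  z <- z - rowMeans(z)
  expect_equal(normalize_expression(make_em(m))$values, z,
               ignore_attr = TRUE)
  # constant observation signature is an error naming the observation
  bad <- make_em(cbind(c(1, 1, 1), c(1, 2, 3)))
  expect_error(normalize_expression(bad), "o1")
  expect_error(normalize_expression(make_em(cbind(c(NA, 1), c(1, 2)))),
               "complete")
})

test_that("regional aggregation averages member observations", {
  v <- matrix(c(1, 10, 3, 30, 5, 50), 2, 3)
  rownames(v) <- c("g1", "g2")
  colnames(v) <- paste0("o", 1:3)
  regions <- c("A", "A", "B")
  out <- aggregate_by_region(v, regions)
  expect_equal(out["A", ], c(g1 = 2, g2 = 20))
  expect_equal(out["B", ], c(g1 = 5, g2 = 50))
  # permutation of observations leaves the result unchanged
  perm <- c(3, 1, 2)
  expect_equal(aggregate_by_region(v[, perm], regions[perm])[c("A", "B"), ],
               out[c("A", "B"), ])
  expect_error(aggregate_by_region(v, regions, expected = c("A", "B", "C")),
               "C")
  # annotated expr_matrix route and single-observation regions
  em <- expr_matrix(v, data.frame(id = colnames(v),
                                  region = c("A", "B", "C")))
  expect_equal(aggregate_by_region(em)["C", ], v[, 3])
})

test_that("expression matrices round-trip through TSV", {
  em <- expr_matrix(matrix(rnorm(12), 3, 4,
                           dimnames = list(paste0("g", 1:3),
                                           paste0("o", 1:4))),
                    data.frame(id = paste0("o", 1:4),
                               region = c("A", "A", "B", "B")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression(em, path)
  back <- read_expression(path)
  expect_equal(back$values, em$values)
  expect_equal(back$obs$region, em$obs$region)
})

test_that("homolog tables parse from long HomoloGene-style TSV", {
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(
    data.frame(group_id = c(1, 1, 2, 2), taxon_id = c(10090, 9606, 10090, 9606),
               symbol = c("Gfap", "GFAP", "Mbp", "MBP")),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  tab <- read_homolog_table(path)
  expect_identical(tab$mouse_symbol, c("Gfap", "Mbp"))
  expect_identical(tab$human_symbol, c("GFAP", "MBP"))
})
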