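# IO round trips, QC filtering, window aggregation, size factors.

test_that("write_dataset / read_dataset round-trips a simulated dataset", {
  ds <- generate_dataset(sim_config(n_cells = 15, n_features = 5, seed = 8,
                                    s = c(rep(1.2, 7), rep(0.8, 8))))
  dir <- file.path(tempdir(), "roundtrip")
  write_dataset(ds, dir)
  back <- read_dataset(file.path(dir, "expression.tsv"),
                       file.path(dir, "methylation.tsv"),
                       file.path(dir, "factors.tsv"))
  expect_length(back, 5L)
  for (j in 1:5) {
    expect_equal(back[[j]]$y1, ds$features[[j]]$y1)
    expect_equal(back[[j]]$y2, ds$features[[j]]$y2)
    expect_equal(back[[j]]$n, ds$features[[j]]$n)
    expect_equal(back[[j]]$s, ds$features[[j]]$s)
    expect_equal(back[[j]]$feature_id, ds$features[[j]]$feature_id)
  }
})

test_that("cells missing from the epigenome table get zero coverage", {
  dir <- file.path(tempdir(), "partial")
  dir.create(dir, showWarnings = FALSE)
  writeLines(c("cell_id\tgeneA\tgeneB", "c1\t5\t0", "c2\t2\t1", "c3\t7\t3"),
             file.path(dir, "expression.tsv"))
  writeLines(c("feature_id\tcell_id\tmet_reads\ttotal_reads",
               "geneA\tc1\t2\t10", "geneA\tc3\t1\t4", "geneB\tc2\t0\t6"),
             file.path(dir, "methylation.tsv"))
  ds <- read_dataset(file.path(dir, "expression.tsv"), file.path(dir, "methylation.tsv"))
  a <- ds[[which(vapply(ds, `[[`, character(1), "feature_id") == "geneA")]]
  expect_equal(a$n, c(10, 0, 4))  # c2 missing -> vacuous coverage
  expect_equal(a$y2, c(2, 0, 1))
  expect_equal(a$y1, c(5, 2, 7))
})

test_that("malformed epigenome rows are rejected with their location", {
  dir <- file.path(tempdir(), "broken")
  dir.create(dir, showWarnings = FALSE)
  writeLines(c("cell_id\tgeneA", "c1\t5", "c2\t2"), file.path(dir, "expression.tsv"))
  writeLines(c("feature_id\tcell_id\tmet_reads\ttotal_reads",
               "geneA\tc1\t2\t10", "geneA\tc2\tbroken\t4"),
             file.path(dir, "methylation.tsv"))
  expect_error(read_dataset(file.path(dir, "expression.tsv"),
                            file.path(dir, "methylation.tsv")),
               "line 3")
  writeLines(c("feature_id\tcell_id\tmet_reads\ttotal_reads",
               "geneA\tc1\t12\t10"), file.path(dir, "methylation.tsv"))
  expect_error(read_dataset(file.path(dir, "expression.tsv"),
                            file.path(dir, "methylation.tsv")),
               "exceeds total_reads")
  writeLines(c("feature_id\tcell_id\tmet_reads\ttotal_reads",
               "geneA\tother\t1\t10"), file.path(dir, "methylation.tsv"))
  expect_error(read_dataset(file.path(dir, "expression.tsv"),
                            file.path(dir, "methylation.tsv")),
               "no overlapping cells")
})

test_that("MatrixMarket expression input is supported", {
  dir <- file.path(tempdir(), "mtx")
  dir.create(dir, showWarnings = FALSE)
  m <- Matrix::Matrix(matrix(c(0, 3, 2, 0, 1, 5), nrow = 3), sparse = TRUE)
  path <- file.path(dir, "expr.mtx")
  Matrix::writeMM(m, path)
  writeLines(c("c1", "c2", "c3"), paste0(path, ".rows"))
  writeLines(c("geneA", "geneB"), paste0(path, ".cols"))
  writeLines(c("feature_id\tcell_id\tmet_reads\ttotal_reads",
               "geneA\tc1\t1\t3", "geneB\tc2\t2\t2"),
             file.path(dir, "methylation.tsv"))
  ds <- read_dataset(path, file.path(dir, "methylation.tsv"))
  expect_length(ds, 2L)
  expect_equal(ds[[1]]$y1, c(0, 3, 2))
})

test_that("qc_filter applies the variance and zero-fraction rules", {
  cells <- 20
  clean <- feature_data("clean", y1 = rpois(cells, 5) + rep(c(0, 1), 10),
                        y2 = rep(c(1, 3), 10), n = rep(5, cells))
  constant <- feature_data("const", y1 = rep(4, cells),
                           y2 = rep(c(1, 2), 10), n = rep(5, cells))
  sparse <- feature_data("sparse", y1 = c(rep(0, 17), 1, 2, 3),
                         y2 = rep(c(1, 2), 10), n = rep(5, cells))
  kept <- qc_filter(list(clean, constant, sparse))
  expect_length(kept, 1L)
  expect_equal(kept[[1]]$feature_id, "clean")
  log <- attr(kept, "drop_log")
  expect_setequal(log$feature_id, c("const", "sparse"))
  expect_equal(log$reason[log$feature_id == "const"], "zero_variance_expression")
  expect_equal(log$reason[log$feature_id == "sparse"], "zero_fraction_expression")
  # idempotent
  again <- qc_filter(kept)
  expect_equal(vapply(again, `[[`, character(1), "feature_id"),
               vapply(kept, `[[`, character(1), "feature_id"))
  expect_equal(nrow(attr(again, "drop_log")), 0L)
  # permissive threshold keeps everything nonconstant
  expect_length(qc_filter(list(clean, sparse), max_zero_frac = 1), 2L)
  expect_error(qc_filter(list(constant)), "all features removed")
})

test_that("aggregate_windows respects strand-aware TSS windows", {
  ann <- data.frame(gene_id = c("plus", "minus"), chrom = "chr1",
                    start = c(10000, 30000), end = c(15000, 36000),
                    strand = c("+", "-"))
  # TSS: plus -> 10000, minus -> 36000
  sites <- data.frame(
    chrom = "chr1",
    pos = c(10000, 13000, 7000, 36000, 33000, 38501),
    cell_id = "c1",
    met_reads = c(1, 2, 4, 8, 16, 32),
    total_reads = c(2, 3, 5, 9, 17, 33))
  # window 2500: site at TSS included, sites 3000 away excluded
  w <- aggregate_windows(sites, ann, window_bp = 2500, anchor = "promoter")
  expect_equal(w$met_reads[w$feature_id == "plus"], 1)
  expect_equal(w$met_reads[w$feature_id == "minus"], 8)
  # window 12500 pulls in the distal sites; hand-summed totals
  w2 <- aggregate_windows(sites, ann, window_bp = 12500, anchor = "promoter")
  expect_equal(w2$met_reads[w2$feature_id == "plus"], 1 + 2 + 4)
  expect_equal(w2$total_reads[w2$feature_id == "plus"], 2 + 3 + 5)
  expect_equal(w2$met_reads[w2$feature_id == "minus"], 8 + 16 + 32)
  # exact boundary: |pos - TSS| == window is included
  w3 <- aggregate_windows(sites, ann, window_bp = 3000, anchor = "promoter")
  expect_equal(w3$met_reads[w3$feature_id == "plus"], 1 + 2 + 4)
  w4 <- aggregate_windows(sites, ann, window_bp = 2999, anchor = "promoter")
  expect_equal(w4$met_reads[w4$feature_id == "plus"], 1)  # both distal sites out
  # gene-body anchoring covers the interval plus flanks
  wb <- aggregate_windows(sites, ann, window_bp = 0, anchor = "gene_body")
  expect_equal(wb$met_reads[wb$feature_id == "plus"], 1 + 2)
  # missing strand is fatal for promoter anchoring only
  ann$strand <- "*"
  expect_error(aggregate_windows(sites, ann, 2500, "promoter"), "strand")
  expect_silent(aggregate_windows(sites, ann, 0, "gene_body"))
})

test_that("BED annotation is converted from 0-based half-open coordinates", {
  dir <- tempdir()
  bed <- file.path(dir, "genes.bed")
  # BED start 9999 half-open == 1-based start 10000
  writeLines("chr1\t9999\t15000\tgeneX\t0\t+", bed)
  sites <- data.frame(chrom = "chr1", pos = 10000, cell_id = "c1",
                      met_reads = 3, total_reads = 4)
  w <- aggregate_windows(sites, bed, window_bp = 0, anchor = "promoter")
  expect_equal(w$met_reads, 3)  # site exactly at the TSS
})

test_that("size factors normalise to mean one under both estimators", {
  m <- rbind(c(60, 40), c(120, 80))
  expect_equal(estimate_size_factors(m, "libsize"), c(2 / 3, 4 / 3))
  same <- rbind(c(5, 7, 1), c(5, 7, 1), c(5, 7, 1))
  expect_equal(estimate_size_factors(same, "libsize"), rep(1, 3))
  expect_equal(estimate_size_factors(same, "median_ratio"), rep(1, 3))
  # scale invariance: multiplying all counts by 5 changes nothing
  set.seed(2)
  counts <- matrix(rpois(60, 20) + 1, nrow = 6)
  expect_equal(estimate_size_factors(counts * 5, "libsize"),
               estimate_size_factors(counts, "libsize"))
  expect_equal(estimate_size_factors(counts * 5, "median_ratio"),
               estimate_size_factors(counts, "median_ratio"))
  expect_equal(mean(estimate_size_factors(counts, "median_ratio")), 1)
  # zero-count cells
  z <- rbind(c(0, 0), c(10, 10))
  expect_warning(f <- estimate_size_factors(z, "libsize"), "floored")
  expect_true(all(f > 0))
  expect_error(estimate_size_factors(z, "median_ratio"), "zero total")
})
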