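test_that("median-of-ratios size factors match hand computation", {
  m <- matrix(c(10, 20, 30, 10, 20, 30), ncol = 2,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  expect_equal(unname(size_factors(m)), c(1, 1))
  # sample2 = 2x sample1: geometric-mean-centered factors (1/sqrt(2), sqrt(2))
  m2 <- m; m2[, 2] <- 2 * m2[, 1]
  expect_equal(unname(size_factors(m2)), c(1 / sqrt(2), sqrt(2)))
  # no gene positive everywhere -> error mentioning the fallback
  m3 <- matrix(c(0, 5, 5, 0), ncol = 2,
               dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(size_factors(m3), "pseudocount")
  expect_length(size_factors(m3, pseudocount = 0.5), 2)
})

test_that("size factors agree with the reference median-of-ratios estimator", {
  set.seed(77)
  m <- matrix(rnbinom(600, mu = 80, size = 5), nrow = 60,
              dimnames = list(paste0("g", 1:60), paste0("s", 1:10)))
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(size_factors(m)), unname(ref), tolerance = 1e-10)
})

test_that("per-sample scaling shifts size factors by c_j / geomean(c)", {
  set.seed(11)
  m <- matrix(rnbinom(200, mu = 50, size = 10) + 1, nrow = 20,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  f0 <- size_factors(m)
  cj <- runif(10, 0.5, 2)
  f1 <- size_factors(sweep(m, 2, cj, "*"))
  expect_equal(unname(f1), unname(f0 * cj / exp(mean(log(cj)))),
               tolerance = 1e-9)
})

test_that("pca screening flags a planted distorted sample and only it", {
  cfg <- sim_config(seed = 1, time_points = 120, n_replicates = 6,
                    outlier = list(group = "treatment", time_h = 120,
                                   replicate = 3, factor = 20,
                                   gene_frac = 0.3))
  st <- simulate_study(cfg)
  res <- pca_outliers(st$counts, st$metadata)
  bad <- res$sample[res$flagged]
  expect_equal(bad, "tre_120h_r3")
})

test_that("pca screening is quiet on replicate noise and skips tiny strata", {
  cfg <- sim_config(seed = 5, time_points = 120, n_replicates = 6)
  st <- simulate_study(cfg)
  res <- pca_outliers(st$counts, st$metadata)
  expect_false(any(res$flagged))
  # stratum of 3 -> skipped with warning, no flags
  keep <- st$metadata$sample[st$metadata$group == "control"][1:3]
  expect_warning(
    res3 <- pca_outliers(st$counts[, keep],
                         st$metadata[st$metadata$sample %in% keep, ]),
    "fewer than 4")
  expect_equal(nrow(res3), 0)
})

test_that("pca screening is invariant to gene and sample ordering", {
  cfg <- sim_config(seed = 1, time_points = 120, n_replicates = 6,
                    outlier = list(group = "treatment", time_h = 120,
                                   replicate = 3, factor = 20,
                                   gene_frac = 0.3))
  st <- simulate_study(cfg)
  res <- pca_outliers(st$counts, st$metadata)
  set.seed(2)
  cnt2 <- st$counts[sample(nrow(st$counts)), sample(ncol(st$counts))]
  res2 <- pca_outliers(cnt2, st$metadata)
  res2 <- res2[match(res$sample, res2$sample), ]
  expect_equal(res2$flagged, res$flagged)
  expect_equal(res2$distance, res$distance, tolerance = 1e-8)
})

test_that("planted 4-fold genes are recovered by the DE stand-in", {
  hits <- 0; errs <- numeric()
  for (seed in 1:20) {
    cfg <- sim_config(seed = seed, n_genes = 40, n_phenotypes = 1,
                      module_size = 5, module_log2fc = 2,
                      n_planted_motifs = 0, nb_dispersion = 0.02,
                      n_replicates = 5, time_points = 120)
    st <- simulate_study(cfg)
    deg <- simple_de(st$counts, st$metadata, "trt_vs_ctl", 120)
    planted <- st$truth$modules$gene
    rows <- deg[match(planted, deg$gene), ]
    errs <- c(errs, rows$log2FC - 2)
    hits <- hits + sum(rows$padj < 0.05)
  }
  # estimates center on the planted value; the error tail is dominated by
  # low-baseline genes where Poisson noise adds to the NB dispersion
  expect_lt(abs(mean(errs)), 0.1)
  expect_lt(mean(abs(errs)), 0.3)
  expect_lt(quantile(abs(errs), 0.75), 0.3)
  expect_gte(hits / (20 * 5), 0.95)
})

test_that("DE conventions: all-zero genes and identical groups give p = 1", {
  cnt <- matrix(c(rep(0, 8), rep(5, 8)), nrow = 2, byrow = TRUE,
                dimnames = list(c("gz", "gc"), paste0("s", 1:8)))
  md <- data.frame(sample = paste0("s", 1:8), contrast = "c",
                   group = rep(c("treatment", "control"), each = 4),
                   time_h = 12, replicate = rep(1:4, 2))
  deg <- simple_de(cnt, md, "c", 12)
  expect_equal(deg$log2FC[deg$gene == "gz"], 0)
  expect_equal(deg$padj[deg$gene == "gz"], 1)
  expect_equal(deg$padj[deg$gene == "gc"], 1)
})

test_that("false discovery rate on planted-null mixtures stays controlled", {
  fdrs <- numeric()
  for (seed in 1:8) {
    cfg <- sim_config(seed = seed, n_genes = 200, n_phenotypes = 1,
                      module_size = 20, module_log2fc = 2,
                      n_planted_motifs = 0, time_points = 120,
                      n_cell_types = 1, markers_per_type = 1,
                      marker_shift = 0)
    st <- simulate_study(cfg)
    deg <- simple_de(st$counts, st$metadata, "trt_vs_ctl", 120)
    called <- deg$gene[deg$padj < 0.05]
    if (!length(called)) next
    fdrs <- c(fdrs, mean(!(called %in% st$truth$modules$gene)))
  }
  expect_lte(median(fdrs), 0.1)
})

test_that("removing a flagged outlier does not shrink the median DEG count", {
  delta <- numeric()
  for (seed in 1:7) {
    cfg <- sim_config(seed = seed, time_points = 120, n_replicates = 7,
                      outlier = list(group = "treatment", time_h = 120,
                                     replicate = 2, factor = 15,
                                     gene_frac = 0.3))
    st <- simulate_study(cfg)
    flagged <- pca_outliers(st$counts, st$metadata)
    flagged <- flagged$sample[flagged$flagged]
    before <- sum(simple_de(st$counts, st$metadata, "trt_vs_ctl",
                            120)$padj < 0.05)
    after <- sum(simple_de(st$counts, st$metadata, "trt_vs_ctl", 120,
                           exclude_samples = flagged)$padj < 0.05)
    delta <- c(delta, after - before)
  }
  expect_gte(median(delta), 0)
})

test_that("DE tables round-trip through TSV", {
  deg <- deg_rows("c", 120, c("A", "B"), c(1.5, -2), c(0.01, 0.2))
  f <- tempfile(fileext = ".tsv")
  write_deg_table(deg, f)
  expect_equal(read_deg_table(f), deg)
  writeLines("gene\tlog2FC", f)
  expect_error(read_deg_table(f), "lacks column")
})
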