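test_that("environment clustering recovers well-separated covariate groups", {
  envs <- default_environments()
  cl <- cluster_environments(envs, k = 4)
  ## perfect recovery up to label permutation
  expect_equal(length(unique(paste(cl, envs$cluster_true))), 4L)
  ## identical environments always co-cluster
  dup <- envs[c(1, 1, 2, 3, 4, 5), ]
  dup$env <- sprintf("D%d", 1:6)
  cld <- cluster_environments(dup, k = 3)
  expect_equal(cld[[1]], cld[[2]])
  ## k equal to the number of environments isolates each one
  expect_equal(length(unique(cluster_environments(envs, k = 12))), 12L)
  envs$Tmin <- 5
  expect_warning(cluster_environments(envs, k = 4), "constant")
})

mini_catalog <- function() {
  data.frame(trait = "fw",
             category = c("mean", "slope", "scv", "qei", "var"),
             chrom = c("1", "1", "1", "2", "2"),
             ci_lo_bp = c(1e6, 5e6, 18e6, 1e6, 40e6),
             ci_hi_bp = c(10e6, 20e6, 30e6, 2e6, 43e6),
             stringsAsFactors = FALSE)
}

test_that("co-localization uses CI overlap with transitive closure", {
  ov <- overlap_qtls(mini_catalog())
  ## peaks 1-2 overlap, 2-3 overlap, 1-3 do not: one component of three
  expect_equal(nrow(ov$unique_qtls), 3L)
  first <- ov$unique_qtls[ov$unique_qtls$chrom == "1", ]
  expect_equal(first$n_peaks, 3L)
  expect_equal(first$categories, "mean+scv+slope")
  expect_equal(ov$components[1], ov$components[3])
  expect_false(ov$components[4] == ov$components[5])
  ## sum of category-combination counts equals the unique-QTL count
  expect_equal(sum(ov$counts), nrow(ov$unique_qtls))
})

test_that("co-localization is invariant to peak input order", {
  cat0 <- mini_catalog()
  set.seed(2)
  for (r in 1:5) {
    shuf <- cat0[sample(nrow(cat0)), ]
    ov <- overlap_qtls(shuf)
    expect_equal(nrow(ov$unique_qtls), 3L)
    expect_setequal(ov$unique_qtls$categories,
                    c("mean+scv+slope", "qei", "var"))
  }
})

test_that("same-chromosome different-trait peaks never merge", {
  cat2 <- mini_catalog()
  cat2$trait <- c("fw", "flw", "fw", "fw", "fw")
  ov <- overlap_qtls(cat2)
  ## the flw peak no longer bridges peaks 1 and 3: five separate QTLs
  expect_equal(nrow(ov$unique_qtls), 5L)
})

eq_map <- function() data.frame(marker = sprintf("M%03d", 1:120),
                                chrom = rep(sprintf("%d", 1:12), each = 10),
                                cM = rep(1:10, 12),
                                bp = rep(1:10, 12) * 1e6)

test_that("chromosome enrichment reproduces hand-computed chi-square values", {
  map <- eq_map()
  ## proportional counts: statistic exactly zero
  even <- rep(sprintf("%d", 1:12), each = 2)
  res <- chisq_chromosome_enrichment(even, map)
  expect_equal(res$statistic, 0)
  ## all 24 QTLs on one of 12 equal chromosomes:
  ## (24-2)^2/2 + 11 * (0-2)^2/2 = 242 + 22 = 264
  allone <- rep("1", 24)
  res2 <- chisq_chromosome_enrichment(allone, map)
  expect_equal(res2$statistic, 264)
  expect_lt(res2$p, 0.001)
  expect_equal(res2$table$std_residual[1], (24 - 2) / sqrt(2))
  ## cross-check against the base chisq test
  obs <- table(factor(allone, levels = sprintf("%d", 1:12)))
  expect_equal(res2$statistic,
               unname(suppressWarnings(
                 chisq.test(obs, p = rep(1 / 12, 12))$statistic)))
  expect_warning(chisq_chromosome_enrichment("1", map), "fewer than 2")
})

test_that("exact Spearman concordance matches enumeration and cor.test", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3, 5.8)
  same <- allelic_effect_concordance(x, x)
  expect_equal(same$rho, 1)
  expect_equal(same$p, 2 / factorial(8))
  rev_ <- allelic_effect_concordance(x, -x)
  expect_equal(rev_$rho, -1)
  expect_equal(rev_$p, 2 / factorial(8))
  set.seed(6)
  for (r in 1:3) {
    a <- sample(seq(1, 8) + runif(8, 0, 0.1))
    b <- rnorm(8)
    ours <- allelic_effect_concordance(a, b)
    ref <- cor.test(a, b, method = "spearman", exact = TRUE)
    expect_equal(ours$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
  }
  expect_warning(out <- allelic_effect_concordance(rep(1, 8), x),
                 "constant")
  expect_true(is.na(out$rho))
})

test_that("tied effects are handled by mid-ranks", {
  a <- c(1, 1, 2, 3, 4, 5, 6, 7)
  b <- c(2, 1, 3, 4, 5, 6, 7, 8)
  out <- allelic_effect_concordance(a, b)
  expect_equal(out$rho, cor(rank(a), rank(b)), tolerance = 1e-12)
  expect_true(out$p > 0 && out$p <= 1)
})

test_that("interval overlap agrees with a brute-force all-pairs check", {
  set.seed(31)
  n <- 300
  cat3 <- data.frame(trait = "t", category = "mean",
                     chrom = sample(c("1", "2"), n, TRUE),
                     stringsAsFactors = FALSE)
  cat3$ci_lo_bp <- sample.int(1e6, n)
  cat3$ci_hi_bp <- cat3$ci_lo_bp + sample.int(5e4, n)
  ov <- overlap_qtls(cat3)
  brute <- outer(seq_len(n), seq_len(n), function(i, j)
    cat3$chrom[i] == cat3$chrom[j] &
      cat3$ci_lo_bp[i] <= cat3$ci_hi_bp[j] &
      cat3$ci_lo_bp[j] <= cat3$ci_hi_bp[i])
  g <- igraph::graph_from_adjacency_matrix(brute, mode = "undirected")
  expect_equal(nrow(ov$unique_qtls),
               igraph::components(g)$no)
})

test_that("sweep intersection applies the CI-width filter and finds known overlaps", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("3\t64759999\t65010000\tSW75",
               "11\t53809999\t55620000\tSW254"), bed)
  sweeps <- read_sweeps_bed(bed)
  expect_equal(sweeps$start_bp, c(64760000, 53810000))
  expect_equal(sweeps$end_bp, c(65010000, 55620000))
  cat4 <- data.frame(
    trait = "fw",
    category = c("slope", "mean", "qei", "mean"),
    chrom = c("3", "5", "7", "3"),
    ci_lo_bp = c(64.8e6, 1e6, 10e6, 60e6),
    ci_hi_bp = c(65.0e6, 1.5e6, 14e6, 63.5e6),  # last is 3.5 Mbp wide
    stringsAsFactors = FALSE)
  res <- intersect_sweeps(cat4, sweeps)
  expect_equal(nrow(res$table), 3L)              # wide non-QEI excluded
  hit <- res$table[res$table$chrom == "3", ]
  expect_true(hit$inside)
  expect_equal(hit$sweeps, "SW75")
  expect_false(res$table$inside[res$table$chrom == "5"])
  expect_true("7" %in% res$table$chrom)          # QEI kept despite width
  expect_equal(res$fraction_inside, 1 / 3)
})

test_that("catalogs merge peak tables with category tags", {
  peaks <- data.frame(marker = "M1", chrom = "1", cM = 5, bp = 5e6,
                      lod = 6, ci_lo_cM = 4, ci_hi_cM = 6,
                      ci_lo_bp = 4e6, ci_hi_bp = 6e6,
                      stringsAsFactors = FALSE)
  cat5 <- qtl_catalog(list(mean = peaks, slope = peaks[0, ]), trait = "fw")
  expect_equal(nrow(cat5), 1L)
  expect_equal(cat5$category, "mean")
  expect_equal(cat5$trait, "fw")
})
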