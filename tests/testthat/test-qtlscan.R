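test_that("the scan matches a brute-force two-model computation", {
  o <- experiment_scan_oracle(seed = 7, n_lines = 60, n_markers = 10)
  expect_lt(o$max_abs_diff, 1e-6)
})

test_that("LOD is invariant to affine rescaling of the phenotype", {
  sim <- shared_sim()
  cm <- cell_means(sim$phenotypes, "trait")
  y <- rowMeans(cm)
  a <- hk_scan(sim$tensor, y)
  b <- hk_scan(sim$tensor, -2.5 * y + 17)
  expect_lt(max(abs(a$lod - b$lod)), 1e-8)
})

test_that("degenerate phenotypes follow the scan contracts", {
  sim <- shared_sim()
  lines <- dimnames(sim$tensor)[[1]]
  const <- setNames(rep(3, length(lines)), lines)
  expect_true(all(hk_scan(sim$tensor, const)$lod == 0))
  ## perfect fit: phenotype an exact function of founder probabilities
  y <- as.numeric(sim$tensor[, 5, ] %*% c(4, -4, 2, -2, 1, -1, 0, 0))
  names(y) <- lines
  sc <- hk_scan(sim$tensor, y)
  expect_true(is.infinite(sc$lod[5]))
  tab <- scan_to_table(sc, sim$map)
  expect_equal(tab$lod[5], 1e4)
  expect_true(tab$infinite[5])
})

test_that("allelic effects are reported on the sum-to-zero scale", {
  sim <- shared_sim()
  cm <- cell_means(sim$phenotypes, "trait")
  sc <- hk_scan(sim$tensor, rowMeans(cm))
  sums <- rowSums(sc$effects[!sc$flagged, , drop = FALSE])
  expect_lt(max(abs(sums)), 1e-8)
})

test_that("the genome-wide threshold evaluates its formula", {
  expect_equal(lod_threshold(1, 1), 0)
  expect_equal(lod_threshold(0.05, 1), 1.3010, tolerance = 1e-4)
  expect_equal(lod_threshold(0.05, 1345), -log10(0.05 / 1345),
               tolerance = 1e-12)
  expect_error(lod_threshold(0, 10))
})

peak_map <- function(n) data.frame(marker = sprintf("M%03d", 1:n),
                                   chrom = "1", cM = seq_len(n),
                                   bp = seq_len(n) * 1e6)

test_that("peak calling applies the 2-LOD separation and 1-LOD interval rules", {
  ## single smooth peak
  lod <- c(0.5, 1, 2.5, 5.2, 6, 5.5, 2, 1, 0.5, 0.2)
  pk <- find_peaks(list(lod = lod), peak_map(10), threshold = 3)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$marker, "M005")
  expect_equal(c(pk$ci_lo_cM, pk$ci_hi_cM), c(4, 6))   # LOD >= 5 region
  ## two maxima with a 1.5-LOD dip merge into the higher one
  lod2 <- c(0.1, 4.0, 2.6, 4.5, 0.3, 0.1, 0.1, 0.1, 0.1, 0.1)
  pk2 <- find_peaks(list(lod = lod2), peak_map(10), threshold = 3)
  expect_equal(nrow(pk2), 1L)
  expect_equal(pk2$marker, "M004")
  ## a 2-LOD dip separates them
  lod3 <- c(0.1, 4.0, 1.9, 4.5, 0.3, 0.1, 0.1, 0.1, 0.1, 0.1)
  pk3 <- find_peaks(list(lod = lod3), peak_map(10), threshold = 3)
  expect_equal(pk3$marker, c("M002", "M004"))
  ## equal-height tie keeps the leftmost
  lod4 <- c(0.1, 4.5, 3.0, 4.5, 0.3, 0.1, 0.1, 0.1, 0.1, 0.1)
  pk4 <- find_peaks(list(lod = lod4), peak_map(10), threshold = 3)
  expect_equal(pk4$marker, "M002")
  ## nothing above threshold
  expect_equal(nrow(find_peaks(list(lod = rep(1, 10)), peak_map(10), 3)), 0L)
})

test_that("peak confidence intervals contain the peak and respect map order", {
  lod <- c(1, 2, 3.5, 5, 3.9, 3.2, 1.5, 1, 6, 2)
  pk <- find_peaks(list(lod = lod), peak_map(10), threshold = 3)
  expect_true(all(pk$ci_lo_cM <= pk$cM & pk$cM <= pk$ci_hi_cM))
  expect_true(all(pk$ci_lo_bp <= pk$bp & pk$bp <= pk$ci_hi_bp))
})

test_that("all four plasticity phenotypes are scanned with shared threshold", {
  sim <- shared_sim()
  cm <- cell_means(sim$phenotypes, "trait")
  pt <- plasticity_table(cm, default_environments()[1:4, ])
  scans <- scan_all_phenotypes(sim$tensor, pt, sim$map, alpha = 0.05)
  expect_setequal(names(scans), c("mean", "slope", "var", "scv"))
  thr <- lod_threshold(0.05, dim(sim$tensor)[2])
  for (sc in scans) {
    expect_equal(sc$threshold, thr)
    if (nrow(sc$peaks)) expect_true(all(sc$peaks$lod > thr))
  }
  few <- pt[1:10, ]
  w <- capture_warnings(scan_all_phenotypes(sim$tensor, few, sim$map))
  expect_length(w, 4L)                       # every phenotype skipped
  expect_true(all(grepl("non-missing", w)))
})

test_that("a planted mean-effect QTL is found by the mean scan at its locus", {
  env <- default_environments()[1:4, ]
  q <- qtl_spec("1", 50, main_effects = c(2, 2, -2, -2, 1, -1, 1, -1))
  cfg <- two_chrom_config(n_lines = 200, markers = 20, seed = 314,
                          qtl_specs = list(q), sigma2_L = 0.2,
                          sigma2_LxE = 0.1)
  sim <- simulate_magic_met(cfg)
  cm <- cell_means(sim$phenotypes, "trait")
  sc <- hk_scan(sim$tensor, rowMeans(cm))
  pk <- find_peaks(sc, sim$map, lod_threshold(0.05, 40))
  expect_gt(nrow(pk), 0)
  best <- pk[which.max(pk$lod), ]
  expect_equal(best$chrom, "1")
  expect_lt(abs(best$cM - 50), 15)
})
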