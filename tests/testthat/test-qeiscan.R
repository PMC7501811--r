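qei_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- magicmet:::power_genomes(100, 2, 15, seed = 777)
      cache <<- g
    }
    cache
  }
})

null_cells_for <- function(g, n_envs = 4, seed = 1) {
  set.seed(seed)
  magicmet:::qei_null_cells(dimnames(g$tensor)[[1]],
                            sprintf("E%02d", seq_len(n_envs)))
}

test_that("null variance components are recovered on cell means", {
  g <- qei_fixture()
  set.seed(15)
  lines <- dimnames(g$tensor)[[1]]
  n <- length(lines)
  cells <- outer(rnorm(n, 0, sqrt(2)), rnorm(6), "+") +
    matrix(rnorm(n * 6, 0, rep(c(0.5, 1.5), each = 3 * n)), n, 6)
  dimnames(cells) <- list(lines, sprintf("E%02d", 1:6))
  vc <- qei_null_varcomp(cells)
  expect_lt(abs(vc$sigma2_G - 2), 0.8)
  expect_lt(mean(vc$resid_var[1:3]) , 1)   # sd 0.5 block
  expect_gt(mean(vc$resid_var[4:6]), 1)    # sd 1.5 block
  holes <- cells; holes[1, 2] <- NA
  expect_warning(qei_null_varcomp(holes), "incomplete")
})

test_that("a pure-main marker shows a main effect, not an interaction", {
  g <- qei_fixture()
  qm <- magicmet:::nearest_marker(g$map, "1", 50)
  cells <- null_cells_for(g, seed = 21)
  a <- c(1, 1, 1, 1, -1, -1, -1, -1) * 0.8
  cells <- cells + outer(as.numeric(g$tensor[, qm, ] %*% a), rep(1, 4))
  vc <- qei_null_varcomp(cells)
  rec <- fit_marker_env_model(g$tensor, g$map$marker[qm], vc = vc)
  expect_lt(rec$p_main, 1e-6)
  expect_gt(rec$p_int, 0.01)
  expect_lt(rec$p_global, 1e-6)
})

test_that("a pure-interaction marker shows an interaction, and its effects are recovered", {
  g <- qei_fixture()
  qm <- magicmet:::nearest_marker(g$map, "1", 50)
  cells <- null_cells_for(g, seed = 22)
  B <- 0.9 * outer(c(1, 1, 1, 1, -1, -1, -1, -1), c(1, -1, 1, -1))
  cells <- cells + g$tensor[, qm, ] %*% B
  vc <- qei_null_varcomp(cells)
  rec <- fit_marker_env_model(g$tensor, g$map$marker[qm], vc = vc)
  expect_lt(rec$p_int, 1e-6)
  expect_gt(rec$p_main, 0.001)
  expect_equal(colSums(rec$effects), rep(0, 4), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_gt(cor(as.vector(rec$effects), as.vector(B)), 0.9)
})

test_that("marker tests are calibrated under a phenotypic null", {
  g <- qei_fixture()
  qm <- magicmet:::nearest_marker(g$map, "2", 30)
  set.seed(33)
  n_rep <- 150L
  ps <- matrix(NA_real_, n_rep, 3)
  for (r in seq_len(n_rep)) {
    cells <- null_cells_for(g, n_envs = 3, seed = 3000 + r)
    vc <- qei_null_varcomp(cells)
    rec <- fit_marker_env_model(g$tensor, g$map$marker[qm], vc = vc)
    ps[r, ] <- c(rec$p_main, rec$p_int, rec$p_global)
  }
  for (k in 1:3)
    expect_gt(stats::ks.test(ps[, k], "punif")$p.value, 0.01)
})

test_that("the scan is invariant to environment relabeling", {
  g <- qei_fixture()
  cells <- null_cells_for(g, seed = 44)
  vc <- qei_null_varcomp(cells)
  sc <- qei_scan(g$tensor, vc, markers = g$map$marker[1:8])
  perm <- c(3, 1, 4, 2)
  cells2 <- cells[, perm]
  vc2 <- vc
  vc2$Y <- cells2
  vc2$resid_var <- vc$resid_var[perm]
  vc2$V <- matrix(vc$sigma2_G, 4, 4) + diag(vc2$resid_var, 4)
  vc2$U <- solve(vc2$V)
  sc2 <- qei_scan(g$tensor, vc2, markers = g$map$marker[1:8])
  expect_equal(sc$F_int, sc2$F_int, tolerance = 1e-8)
  expect_equal(sc$F_main, sc2$F_main, tolerance = 1e-8)
  expect_equal(sc$F_global, sc2$F_global, tolerance = 1e-8)
})

test_that("permutation thresholds are deterministic and use the type-7 quantile", {
  g <- qei_fixture()
  cells <- null_cells_for(g, seed = 55)
  vc <- qei_null_varcomp(cells)
  expect_warning(t1 <- permutation_threshold(g$tensor, vc, n_perm = 15L,
                                             alpha = 0.05, seed = 99),
                 "poorly estimated")
  t2 <- suppressWarnings(permutation_threshold(g$tensor, vc, n_perm = 15L,
                                               alpha = 0.05, seed = 99))
  expect_identical(t1$interaction, t2$interaction)
  expect_equal(t1$main,
               unname(quantile(t1$max_stats[, "main"], 0.95, type = 7)))
  expect_equal(t1$global,
               unname(quantile(t1$max_stats[, "global"], 0.95, type = 7)))
})

test_that("forward selection finds a planted interaction and backward keeps it", {
  g <- qei_fixture()
  qm <- magicmet:::nearest_marker(g$map, "1", 50)
  cells <- null_cells_for(g, seed = 66)
  B <- 1.2 * outer(c(1, 1, 1, 1, -1, -1, -1, -1), c(1, -1, 1, -1))
  cells <- cells + g$tensor[, qm, ] %*% B
  vc <- qei_null_varcomp(cells)
  thr <- permutation_threshold(g$tensor, vc, n_perm = 100L, seed = 5)
  cof <- forward_selection(g$tensor, vc, thr, g$map)
  expect_gt(length(cof), 0)
  i <- match(cof, g$map$marker)
  expect_true(any(g$map$chrom[i] == "1" & abs(g$map$cM[i] - 50) <= 10))
  rec <- backward_elimination(g$tensor, vc, cof, thr)
  expect_true(any(rec$significant))
  ## no record is ever flagged without a significant interaction
  expect_true(all(-log10(pmax(rec$p_int[rec$significant], 1e-300)) >
                    thr$interaction))
  ## empty cofactor set gives an empty record set
  expect_equal(nrow(backward_elimination(g$tensor, vc, character(0), thr)),
               0L)
})

test_that("the global pass adds jointly-strong markers and never duplicates", {
  g <- qei_fixture()
  qm <- magicmet:::nearest_marker(g$map, "2", 30)
  cells <- null_cells_for(g, seed = 88)
  ## moderate main + moderate interaction: individually weak, jointly strong
  a <- 0.45 * c(1, 1, 1, 1, -1, -1, -1, -1)
  B <- outer(a, rep(1, 4)) + 0.45 * outer(c(1, -1, 1, -1, 1, -1, 1, -1),
                                          c(1, -1, 1, -1))
  cells <- cells + g$tensor[, qm, ] %*% B
  vc <- qei_null_varcomp(cells)
  rec <- fit_marker_env_model(g$tensor, g$map$marker[qm], vc = vc)
  expect_lt(rec$p_global, min(rec$p_main, rec$p_int) + 1e-12)
  thr <- permutation_threshold(g$tensor, vc, n_perm = 100L, seed = 6)
  glob <- global_effect_pass(g$tensor, vc, selected = character(0),
                             thresholds = thr, map = g$map)
  expect_false(any(duplicated(glob$marker)))
  glob2 <- global_effect_pass(g$tensor, vc,
                              selected = g$map$marker[qm],
                              thresholds = thr, map = g$map)
  expect_false(g$map$marker[qm] %in% glob2$marker)
})
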