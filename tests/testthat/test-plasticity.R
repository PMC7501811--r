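test_that("the environment index is the centred environment mean", {
  cells <- rbind(c(1, 2, 3), c(3, 4, 5))
  dimnames(cells) <- list(c("A", "B"), c("E1", "E2", "E3"))
  expect_equal(unname(environment_index(cells)), c(-1, 0, 1))
  same <- matrix(2, 3, 4, dimnames = list(letters[1:3], LETTERS[1:4]))
  expect_equal(unname(environment_index(same)), rep(0, 4))
  one <- matrix(1:3, 3, 1, dimnames = list(letters[1:3], "E1"))
  expect_equal(unname(environment_index(one)), 0)
})

test_that("noise-free joint regression recovers slopes and means exactly", {
  fw <- experiment_fw_exact(seed = 4)
  expect_lt(fw$max_slope_err, 1e-10)
  expect_lt(fw$max_var_nl, 1e-10)
  expect_lt(fw$max_mean_err, 1e-10)
  expect_equal(fw$mean_slope, 1, tolerance = 1e-10)
})

test_that("a line constant across environments has slope zero", {
  cells <- toy_cells(20, 5, seed = 3, noise = 0.5)
  cells["L001", ] <- 7
  fw <- fit_finlay_wilkinson(cells)
  expect_equal(fw$slope[fw$line == "L001"], 0, tolerance = 1e-10)
  expect_equal(fw$genotypic_mean[fw$line == "L001"], 7, tolerance = 1e-10)
})

test_that("joint regression demands a variable index and enough environments", {
  same <- matrix(rnorm(12), 4, 3,
                 dimnames = list(letters[1:4], LETTERS[1:3]))
  same <- same - rep(colMeans(same), each = 4) + 5   # identical env means
  expect_error(fit_finlay_wilkinson(same), "zero variance")
  cells <- toy_cells(10, 5, seed = 6, noise = 0.3)
  cells[1, 3:5] <- NA
  fw <- fit_finlay_wilkinson(cells)
  expect_true(is.na(fw$slope[1]))
  expect_false(is.na(fw$genotypic_mean[1]))
  expect_equal(fw$n_envs[1], 2L)
})

test_that("a single planted covariate explains all interaction sum of squares", {
  envs <- magicmet:::recovery_environments(6, seed = 8)
  z <- as.vector(scale(envs$Vpd))
  set.seed(9)
  lam <- rnorm(40); lam <- lam - mean(lam)
  cells <- outer(rnorm(40), rnorm(6), "+") + outer(lam, z)
  dimnames(cells) <- list(sprintf("L%03d", 1:40), envs$env)
  sel <- select_covariate(cells, envs)
  expect_identical(sel$best, "Vpd")
  expect_equal(sel$table$ss_share[sel$table$covariate == "Vpd"], 1,
               tolerance = 1e-10)
  scv <- fit_factorial_regression(cells, envs, "Vpd")
  expect_equal(unname(scv), lam, tolerance = 1e-10)
  expect_equal(sum(scv), 0, tolerance = 1e-10)
})

test_that("a shared sensitivity is absorbed by the environment effects", {
  envs <- magicmet:::recovery_environments(6, seed = 18)
  z <- as.vector(scale(envs$Tmin))
  cells <- outer(rnorm(30), rnorm(6), "+") + outer(rep(2, 30), z)
  dimnames(cells) <- list(sprintf("L%03d", 1:30), envs$env)
  scv <- fit_factorial_regression(cells, envs, "Tmin")
  expect_lt(max(abs(scv)), 1e-10)
})

test_that("the lm path for incomplete cells matches the planted truth", {
  envs <- magicmet:::recovery_environments(6, seed = 28)
  z <- as.vector(scale(envs$RH))
  set.seed(29)
  lam <- rnorm(25); lam <- lam - mean(lam)
  cells <- outer(rnorm(25), rnorm(6), "+") + outer(lam, z)
  dimnames(cells) <- list(sprintf("L%03d", 1:25), envs$env)
  cells[2, 5] <- NA                      # forces the lm code path
  scv <- fit_factorial_regression(cells, envs, "RH")
  expect_gt(cor(scv, lam), 0.999)
})

test_that("per-covariate false declarations stay near the nominal level", {
  envs <- magicmet:::recovery_environments(8, seed = 55)
  set.seed(56)
  n_rep <- 100L
  declared <- matrix(FALSE, n_rep, 7)
  for (r in seq_len(n_rep)) {
    cells <- toy_cells(60, 8, seed = NULL, noise = 1)
    sel <- select_covariate(cells, envs)
    declared[r, ] <- sel$table$p <= 0.05
  }
  rates <- colMeans(declared)
  expect_true(all(rates <= 0.13))
})

test_that("the scan transform handles logs, roots, and zeros", {
  expect_equal(transform_for_scan(1, "height"), 0)
  expect_equal(transform_for_scan(4, "fset"), 2)
  val <- transform_for_scan(0, "height", offset = 1e-4)
  expect_true(is.finite(val))
  expect_equal(val, log(1e-4))
  expect_error(transform_for_scan(-1, "height"))
})

test_that("slope and covariate sensitivity are positively related when one covariate drives the index", {
  envs <- magicmet:::recovery_environments(8, seed = 91)
  z <- as.vector(scale(envs$Tmax))
  set.seed(92)
  b <- 1 + rnorm(80, 0, 0.4)
  cells <- outer(rnorm(80, 10, 1), rep(1, 8)) + outer(b, 3 * z) +
    matrix(rnorm(640, 0, 0.3), 80)
  dimnames(cells) <- list(sprintf("L%03d", 1:80), envs$env)
  pt <- plasticity_table(cells, envs)
  expect_gt(cor(pt$slope, pt$scv, use = "complete.obs"), 0)
})

test_that("the plasticity table combines all parameters coherently", {
  sim <- shared_sim()
  cm <- cell_means(sim$phenotypes, "trait")
  pt <- plasticity_table(cm, default_environments()[1:4, ])
  expect_true(all(c("line", "genotypic_mean", "slope", "var_nl", "scv",
                    "n_envs", "best_covariate") %in% names(pt)))
  expect_true(all(pt$var_nl >= 0, na.rm = TRUE))
  bal <- rowSums(!is.na(cm)) == ncol(cm)
  expect_equal(pt$genotypic_mean[bal], unname(rowMeans(cm)[bal]),
               tolerance = 1e-10)
  expect_equal(mean(pt$slope, na.rm = TRUE), 1, tolerance = 1e-8)
})
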