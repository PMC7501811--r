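test_that("a chromosome of zero genetic length never recombines", {
  chrs <- data.frame(chrom = "1", length_morgan = 0, length_bp = 5e7)
  cfg <- sim_config(n_lines = 20, chromosomes = chrs,
                    markers_per_chromosome = 5,
                    env_specs = default_environments()[1:2, ], seed = 5)
  g <- simulate_magic_pedigree(cfg)
  for (line in g) {
    expect_length(line[[1]]$h1$founder, 1L)
    expect_length(line[[1]]$h2$founder, 1L)
  }
})

test_that("funnel symmetry gives balanced founder contributions", {
  chrs <- data.frame(chrom = "1", length_morgan = 1, length_bp = 9e7)
  cfg <- sim_config(n_lines = 2000, chromosomes = chrs,
                    markers_per_chromosome = 11,
                    env_specs = default_environments()[1:2, ], seed = 77)
  g <- simulate_magic_pedigree(cfg)
  map <- make_genetic_map(cfg)
  tens <- mosaics_to_probabilities(g, map, 0)
  truth <- attr(tens, "true_founder")
  props <- prop.table(table(factor(truth, levels = 1:8)))
  se <- sqrt(0.125 * 0.875 / 2000)
  expect_true(all(abs(props - 1 / 8) < 2 * se + 1e-12))
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- two_chrom_config(n_lines = 15, markers = 6, seed = 31,
                          sigma2_L = 0.5, sigma2_LxE = 0.2,
                          prob_softening = 0.05)
  a <- simulate_magic_met(cfg)
  b <- simulate_magic_met(cfg)
  expect_identical(a$tensor, b$tensor)
  expect_identical(a$phenotypes, b$phenotypes)
})

test_that("probability emission spreads epsilon and keeps unit mass", {
  cfg <- two_chrom_config(n_lines = 12, markers = 6, seed = 9)
  g <- simulate_magic_pedigree(cfg)
  map <- make_genetic_map(cfg)
  one_hot <- mosaics_to_probabilities(g, map, 0)
  expect_true(all(one_hot %in% c(0, 1)))
  soft <- mosaics_to_probabilities(g, map, 0.07)
  expect_true(all(abs(soft - 0.93) < 1e-12 | abs(soft - 0.01) < 1e-12))
  expect_true(max(abs(apply(soft, c(1, 2), sum) - 1)) < 1e-12)
})

test_that("degenerate probability inputs behave per contract", {
  cfg <- two_chrom_config(n_lines = 5, markers = 4, seed = 3)
  g <- simulate_magic_pedigree(cfg)
  map <- make_genetic_map(cfg)
  empty <- mosaics_to_probabilities(g, map[0, ], 0)
  expect_equal(dim(empty), c(5L, 0L, 8L))
  bad <- map
  bad$cM[1] <- 1e4
  expect_error(mosaics_to_probabilities(g, bad, 0), "beyond")
  expect_error(mosaics_to_probabilities(g, map, 1), "epsilon")
})

test_that("configuration invariants are enforced", {
  chrs <- data.frame(chrom = "1", length_morgan = 1, length_bp = 9e7)
  env <- default_environments()[1:2, ]
  expect_error(sim_config(10, chrs[0, ], 5, env), "chromosome")
  expect_error(sim_config(10, chrs, 5, env, prob_softening = 1),
               "prob_softening")
  q <- qtl_spec("1", 10, covariate = "Tmax")
  q$covariate <- "NotACovariate"
  expect_error(sim_config(10, chrs, 5, env, qtl_specs = list(q)),
               "covariate")
})

test_that("phenotypes reduce to mu plus environment effects when all noise is off", {
  env <- default_environments()[1:3, ]
  env$sigma_R <- 0
  env$row_sd <- 0
  env$pos_sd <- 0
  chrs <- data.frame(chrom = "1", length_morgan = 1, length_bp = 9e7)
  cfg <- sim_config(n_lines = 10, chromosomes = chrs,
                    markers_per_chromosome = 4, env_specs = env,
                    n_controls = 0, mu = 5, seed = 12)
  sim <- simulate_magic_met(cfg)
  truth <- attr(sim$phenotypes, "truth")
  expected <- 5 + truth$env_effects[sim$phenotypes$env]
  expect_equal(sim$phenotypes$trait, unname(expected), tolerance = 1e-12)
})

test_that("noise-free QTL phenotypes equal founder-effect contrasts", {
  env <- default_environments()[1, ]
  env$sigma_R <- 0; env$row_sd <- 0; env$pos_sd <- 0
  chrs <- data.frame(chrom = "1", length_morgan = 1, length_bp = 9e7)
  q <- qtl_spec("1", 50, main_effects = c(3, -3, 1, -1, 2, -2, 0, 0))
  cfg <- sim_config(n_lines = 30, chromosomes = chrs,
                    markers_per_chromosome = 9, env_specs = env,
                    qtl_specs = list(q), n_controls = 0, seed = 8)
  sim <- simulate_magic_met(cfg)
  truth <- attr(sim$phenotypes, "truth")
  mk <- truth$qtl[[1]]$marker
  contrib <- as.numeric(sim$tensor[, mk, ] %*% q$main_effects)
  names(contrib) <- dimnames(sim$tensor)[[1]]
  d <- sim$phenotypes[sim$phenotypes$rep == 1, ]
  expect_equal(unname(d$trait - mean(d$trait)),
               unname(contrib[d$line] - mean(contrib[d$line])),
               tolerance = 1e-10)
})

test_that("simulated datasets round-trip through the plain-text writers", {
  sim <- simulate_magic_met(two_chrom_config(n_lines = 8, markers = 4,
                                             seed = 21))
  dir <- withr::local_tempdir()
  files <- write_simulated_data(sim, dir)
  expect_true(all(file.exists(files)))
  map2 <- read.csv(file.path(dir, "map.csv"))
  expect_equal(map2$cM, sim$map$cM)
  tl <- read.delim(file.path(dir, "probabilities.tsv"))
  expect_equal(nrow(tl), prod(dim(sim$tensor)))
})
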