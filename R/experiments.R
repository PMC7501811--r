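## Recovery and calibration experiments on synthetic data.
##
## Each experiment regenerates its inputs from scratch under the given
## seed, runs the relevant pipeline stage, and measures how well known
## ground truth is recovered (or how well a null is calibrated). They are
## the package's validation surface: the analysis drivers run them and the
## test suite asserts on their summaries.

#' Compare the Haley-Knott scan with a brute-force least-squares oracle
#'
#' Simulates a MAGIC genome, draws a random phenotype, and recomputes the
#' LOD at every marker by explicitly fitting the intercept-only and the
#' founder-probability regression models with [stats::lm()], independent of
#' the scan's own linear algebra.
#'
#' @param seed Integer seed.
#' @param n_lines,n_markers Problem size (defaults 200 lines, 50 markers).
#' @return List with `max_abs_diff` (largest |LOD difference| over markers)
#'   and `n` sizes.
#' @export
experiment_scan_oracle <- function(seed = 1L, n_lines = 200L,
                                   n_markers = 50L) {
  chrs <- data.frame(chrom = c("1", "2"), length_morgan = c(1, 1),
                     length_bp = c(9e7, 8e7))
  cfg <- sim_config(n_lines = n_lines, chromosomes = chrs,
                    markers_per_chromosome = ceiling(n_markers / 2),
                    env_specs = default_environments()[1:2, ],
                    prob_softening = 0.05, seed = seed)
  genomes <- simulate_magic_pedigree(cfg)
  map <- make_genetic_map(cfg)[seq_len(n_markers), ]
  tensor <- mosaics_to_probabilities(genomes, map, cfg$prob_softening)
  y <- stats::rnorm(n_lines)
  names(y) <- dimnames(tensor)[[1]]
  sc <- hk_scan(tensor, y)
  oracle <- vapply(seq_len(n_markers), function(m) {
    d <- as.data.frame(tensor[, m, 1:7])
    d$y <- unname(y)
    full <- stats::lm(y ~ ., data = d)
    null <- stats::lm(y ~ 1, data = d)
    (length(y) / 2) * log10(sum(stats::residuals(null)^2) /
                              sum(stats::residuals(full)^2))
  }, 0)
  list(max_abs_diff = max(abs(sc$lod - oracle)),
       n_lines = n_lines, n_markers = n_markers)
}

#' Noise-free Finlay-Wilkinson recovery
#'
#' Builds cell means exactly as `a_i + b_i * e_j` with mean slope 1 and a
#' centred environment score, runs the joint regression, and reports the
#' worst-case recovery errors plus the balanced-case mean slope.
#'
#' @param seed Integer seed.
#' @param n_lines,n_envs Problem size.
#' @return List with `max_slope_err`, `max_var_nl`, `max_mean_err`,
#'   `mean_slope`.
#' @export
experiment_fw_exact <- function(seed = 1L, n_lines = 100L, n_envs = 8L) {
  set.seed(seed)
  a <- stats::rnorm(n_lines, 10, 2)
  b <- 1 + stats::rnorm(n_lines, 0, 0.3)
  b <- b - mean(b) + 1                      # population mean slope exactly 1
  e <- stats::rnorm(n_envs, 0, 3)
  e <- e - mean(e)
  cells <- outer(a, rep(1, n_envs)) + outer(b, e)
  dimnames(cells) <- list(sprintf("L%03d", seq_len(n_lines)),
                          sprintf("E%02d", seq_len(n_envs)))
  fw <- fit_finlay_wilkinson(cells)
  list(max_slope_err = max(abs(fw$slope - b)),
       max_var_nl = max(fw$var_nl),
       max_mean_err = max(abs(fw$genotypic_mean - a)),
       mean_slope = mean(fw$slope))
}

## Environment table for factorial-regression recovery: covariates drawn
## independently so the driving covariate is identifiable (the
## identifiability condition of the recovery design; the realistic default
## table has strongly confounded covariates).
recovery_environments <- function(n_envs, seed) {
  set.seed(seed)
  out <- data.frame(env = sprintf("E%02d", seq_len(n_envs)))
  base <- c(Tmin = 12, Tmax = 30, Tmean = 20, ThAmp = 16, SDD = 1000,
            Vpd = 1.2, RH = 60)
  sds <- c(3, 4, 3, 3, 200, 0.4, 10)
  for (i in seq_along(base))
    out[[names(base)[i]]] <- stats::rnorm(n_envs, base[i], sds[i])
  out
}

#' Factorial-regression sensitivity recovery
#'
#' Plants per-line sensitivities to one covariate (lambda_i ~ N(0, 1),
#' centred) on cell means with additive line and environment effects and
#' Gaussian noise, then checks that covariate selection finds the driving
#' covariate and that the estimated sensitivities track the truth.
#'
#' @param n_rep Number of replicates.
#' @param seed Integer seed.
#' @param n_lines,n_envs Problem size (defaults 300 x 8).
#' @param noise_sd Cell-level noise SD (default 0.5).
#' @param covariate Driving covariate (default `"Tmax"`).
#' @return List with `selection_rate`, `mean_cor`, `min_cor`, and the
#'   per-replicate values.
#' @export
experiment_factorial_recovery <- function(n_rep = 100L, seed = 1L,
                                          n_lines = 300L, n_envs = 8L,
                                          noise_sd = 0.5,
                                          covariate = "Tmax") {
  envs <- recovery_environments(n_envs, seed)
  z <- as.vector(scale(envs[[covariate]]))
  set.seed(seed + 1L)
  sel_ok <- logical(n_rep)
  cors <- numeric(n_rep)
  lines <- sprintf("L%03d", seq_len(n_lines))
  for (r in seq_len(n_rep)) {
    lambda <- stats::rnorm(n_lines)
    lambda <- lambda - mean(lambda)
    G <- stats::rnorm(n_lines, 0, 1)
    E <- stats::rnorm(n_envs, 0, 2)
    cells <- outer(G, E, "+") + outer(lambda, z) +
      matrix(stats::rnorm(n_lines * n_envs, 0, noise_sd), n_lines)
    dimnames(cells) <- list(lines, envs$env)
    sel <- select_covariate(cells, envs)
    sel_ok[r] <- identical(sel$best, covariate)
    scv <- fit_factorial_regression(cells, envs, covariate)
    cors[r] <- stats::cor(scv, lambda)
  }
  list(selection_rate = mean(sel_ok), mean_cor = mean(cors),
       min_cor = min(cors), cors = cors, selected = sel_ok)
}

#' Variance-component recovery for the multi-environment model
#'
#' Simulates the whole-design model directly (fixed environment effects,
#' random line and line-by-environment effects, heterogeneous residuals),
#' fits it by REML, and summarises the relative bias of every component
#' over replicates.
#'
#' @param n_rep Number of replicates.
#' @param seed Integer seed.
#' @param n_lines,n_envs,n_reps Design size (defaults 300 x 6 x 2).
#' @param sigma2_L,sigma2_LxE True variances (defaults 1 and 0.5).
#' @param resid_var True per-environment residual variances, recycled
#'   across environments (default `c(0.5, 1, 2)`).
#' @return List with `rel_bias` (named: line, line-by-env, each residual),
#'   `mean_prop_gxe`, `true_prop_gxe`, and the per-replicate estimates.
#' @export
experiment_varcomp_recovery <- function(n_rep = 100L, seed = 1L,
                                        n_lines = 300L, n_envs = 6L,
                                        n_reps = 2L, sigma2_L = 1,
                                        sigma2_LxE = 0.5,
                                        resid_var = c(0.5, 1, 2)) {
  set.seed(seed)
  s2e <- rep_len(resid_var, n_envs)
  lines <- sprintf("L%03d", seq_len(n_lines))
  envs <- sprintf("E%02d", seq_len(n_envs))
  base <- data.frame(line = rep(lines, each = n_envs * n_reps),
                     env = rep(rep(envs, each = n_reps), n_lines),
                     is_control = 0L, stringsAsFactors = FALSE)
  est <- matrix(NA_real_, n_rep, 2L + n_envs,
                dimnames = list(NULL, c("sigma2_L", "sigma2_LxE", envs)))
  props <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    L <- stats::setNames(stats::rnorm(n_lines, 0, sqrt(sigma2_L)), lines)
    LE <- matrix(stats::rnorm(n_lines * n_envs, 0, sqrt(sigma2_LxE)),
                 n_lines, n_envs, dimnames = list(lines, envs))
    Ej <- stats::setNames(stats::rnorm(n_envs, 0, 1), envs)
    d <- base
    d$trait <- L[d$line] + LE[cbind(d$line, d$env)] + Ej[d$env] +
      stats::rnorm(nrow(d), 0, sqrt(s2e[match(d$env, envs)]))
    v <- suppressMessages(fit_gxe_model(d, "trait"))
    est[r, ] <- c(v$sigma2_L, v$sigma2_LxE, v$resid_var[envs])
    props[r] <- v$prop_gxe
  }
  truth <- c(sigma2_L, sigma2_LxE, s2e)
  list(rel_bias = stats::setNames(colMeans(est) / truth - 1,
                                  colnames(est)),
       mean_prop_gxe = mean(props),
       true_prop_gxe = sigma2_LxE / (sigma2_L + sigma2_LxE),
       estimates = est, props = props)
}

## shared genome builder for the scan experiments
power_genomes <- function(n_lines, n_chrom, markers_per_chrom, seed,
                          epsilon = 0.02) {
  chrs <- data.frame(chrom = as.character(seq_len(n_chrom)),
                     length_morgan = rep(1, n_chrom),
                     length_bp = rep(9e7, n_chrom))
  cfg <- sim_config(n_lines = n_lines, chromosomes = chrs,
                    markers_per_chromosome = markers_per_chrom,
                    env_specs = default_environments()[1:2, ],
                    prob_softening = epsilon, seed = seed)
  genomes <- simulate_magic_pedigree(cfg)
  map <- make_genetic_map(cfg)
  list(tensor = mosaics_to_probabilities(genomes, map, epsilon), map = map)
}

#' Power and type-I error of the single-phenotype QTL scan
#'
#' Power: a QTL with founder effects explaining ~20% of the phenotypic
#' variance is planted mid-chromosome; a scan detects it when a peak above
#' the genome-wide threshold lands on the QTL chromosome, and covers it
#' when a peak's confidence interval contains the true position. Type I:
#' scans of pure-noise phenotypes on the same genomes; a false positive is
#' any peak anywhere.
#'
#' @param n_rep Power replicates (fresh phenotype noise; genomes are
#'   redrawn every `reps_per_genome` replicates).
#' @param n_null Null-scan replicates.
#' @param seed Integer seed.
#' @param n_lines Lines per genome (default 300).
#' @param n_chrom,markers_per_chrom Genome size (default 5 x 40).
#' @param effect_frac Variance fraction explained by the QTL (default 0.2).
#' @param alpha Genome-wide level.
#' @param reps_per_genome Phenotype replicates per genome draw (default 5).
#' @return List with `power`, `coverage` (CI covers truth, among detected),
#'   `fp_rate`, and the per-replicate outcomes.
#' @export
experiment_qtl_power <- function(n_rep = 100L, n_null = 200L, seed = 1L,
                                 n_lines = 300L, n_chrom = 5L,
                                 markers_per_chrom = 40L,
                                 effect_frac = 0.2, alpha = 0.05,
                                 reps_per_genome = 5L) {
  n_markers <- n_chrom * markers_per_chrom
  thr <- lod_threshold(alpha, n_markers)
  delta <- sqrt(effect_frac / (1 - effect_frac))   # noise SD 1
  eff <- delta * c(1, 1, 1, 1, -1, -1, -1, -1)
  qtl_chrom <- "3"
  detected <- covered <- logical(n_rep)
  fp <- logical(n_null)
  g <- NULL
  set.seed(seed)
  for (r in seq_len(n_rep)) {
    if (is.null(g) || (r - 1L) %% reps_per_genome == 0L)
      g <- power_genomes(n_lines, n_chrom, markers_per_chrom,
                         seed = seed + r)
    qm <- nearest_marker(g$map, qtl_chrom, 50)
    X <- g$tensor[, qm, ]
    y <- as.numeric(X %*% eff) + stats::rnorm(n_lines)
    names(y) <- dimnames(g$tensor)[[1]]
    sc <- hk_scan(g$tensor, y)
    pk <- find_peaks(sc, g$map, thr)
    on_chrom <- pk[pk$chrom == qtl_chrom, , drop = FALSE]
    detected[r] <- nrow(on_chrom) > 0L
    covered[r] <- any(on_chrom$ci_lo_bp <= g$map$bp[qm] &
                        on_chrom$ci_hi_bp >= g$map$bp[qm])
  }
  for (r in seq_len(n_null)) {
    if ((r - 1L) %% 20L == 0L)
      g <- power_genomes(n_lines, n_chrom, markers_per_chrom,
                         seed = seed + 1000L + r)
    y <- stats::rnorm(n_lines)
    names(y) <- dimnames(g$tensor)[[1]]
    pk <- find_peaks(hk_scan(g$tensor, y), g$map, thr)
    fp[r] <- nrow(pk) > 0L
  }
  list(power = mean(detected),
       coverage = if (any(detected)) mean(covered[detected]) else NA_real_,
       fp_rate = mean(fp), detected = detected, covered = covered, fp = fp)
}

## null cell means for the QEI experiments
qei_null_cells <- function(lines, envs, sigma2_G = 0.3,
                           resid_sd = c(0.8, 1, 1.2, 1)) {
  n <- length(lines); J <- length(envs)
  sds <- rep_len(resid_sd, J)
  cells <- outer(stats::rnorm(n, 0, sqrt(sigma2_G)),
                 stats::rnorm(J, 0, 1), "+") +
    matrix(stats::rnorm(n * J, 0, rep(sds, each = n)), n, J)
  dimnames(cells) <- list(lines, envs)
  cells
}

#' Genome-wide calibration of the QEI permutation threshold
#'
#' Repeatedly simulates a null genome and null phenotypes, computes each
#' replicate's own permutation threshold, scans, and records whether any
#' marker's interaction (and main, global) statistic exceeds it. The
#' genome-wide false-positive rate should match the nominal level.
#'
#' @param n_null Null replicates (default 200).
#' @param n_perm Permutations per replicate (default 200; study scale 1000).
#' @param seed Integer seed.
#' @param n_lines,n_envs Problem size (defaults 120 x 4).
#' @param n_chrom,markers_per_chrom Genome size (default 2 x 50).
#' @param alpha Level (default 0.05).
#' @return List with `fp_int`, `fp_main`, `fp_global` rates and the
#'   per-replicate outcomes.
#' @export
experiment_qei_calibration <- function(n_null = 200L, n_perm = 200L,
                                       seed = 1L, n_lines = 120L,
                                       n_envs = 4L, n_chrom = 2L,
                                       markers_per_chrom = 50L,
                                       alpha = 0.05) {
  fpm <- matrix(NA, n_null, 3,
                dimnames = list(NULL, c("main", "interaction", "global")))
  for (r in seq_len(n_null)) {
    g <- power_genomes(n_lines, n_chrom, markers_per_chrom, seed = seed + r)
    set.seed(seed + 10000L + r)
    cells <- qei_null_cells(dimnames(g$tensor)[[1]],
                            sprintf("E%02d", seq_len(n_envs)))
    vc <- qei_null_varcomp(cells)
    thr <- permutation_threshold(g$tensor, vc, n_perm = n_perm,
                                 alpha = alpha, seed = seed + 20000L + r)
    sc <- qei_scan(g$tensor, vc)
    lp <- function(p) -log10(pmax(p, 1e-300))
    fpm[r, ] <- c(max(lp(sc$p_main), na.rm = TRUE) > thr$main,
                  max(lp(sc$p_int), na.rm = TRUE) > thr$interaction,
                  max(lp(sc$p_global), na.rm = TRUE) > thr$global)
  }
  list(fp_main = mean(fpm[, "main"]), fp_int = mean(fpm[, "interaction"]),
       fp_global = mean(fpm[, "global"]), outcomes = fpm)
}

#' Detection of a pure-interaction (zero-marginal) QTL by the QEI procedure
#'
#' Plants a marker whose founder effects average to zero in every
#' environment and across environments (pure QTL-by-environment
#' interaction), runs the full forward-backward procedure with a
#' permutation threshold, and records whether the marker (or a neighbour
#' within the exclusion window) is reported with a significant interaction
#' — and whether any record is ever flagged on its main effect alone
#' (structurally impossible; asserted).
#'
#' @param n_rep Replicates (default 100).
#' @param n_perm Permutations per replicate (default 200).
#' @param seed Integer seed.
#' @param n_lines,n_envs Problem size (defaults 200 x 4).
#' @param n_chrom,markers_per_chrom Genome size (default 2 x 50).
#' @param delta Interaction effect half-range (default 0.5).
#' @param window_cM Match window around the true marker (default 10).
#' @return List with `detection_rate`, `main_only_rate` (share of
#'   replicates reporting any record without a significant interaction),
#'   and per-replicate outcomes.
#' @export
experiment_qei_power <- function(n_rep = 100L, n_perm = 200L, seed = 1L,
                                 n_lines = 200L, n_envs = 4L,
                                 n_chrom = 2L, markers_per_chrom = 50L,
                                 delta = 0.5, window_cM = 10) {
  s <- c(1, 1, 1, 1, -1, -1, -1, -1)
  tt <- rep_len(c(1, -1), n_envs)
  tt <- tt - mean(tt)
  B <- delta * outer(s, tt)                # founder x env, both margins zero
  hit <- logical(n_rep)
  main_only <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    g <- power_genomes(n_lines, n_chrom, markers_per_chrom, seed = seed + r)
    qm <- nearest_marker(g$map, "1", 50)
    set.seed(seed + 10000L + r)
    cells <- qei_null_cells(dimnames(g$tensor)[[1]],
                            sprintf("E%02d", seq_len(n_envs)))
    cells <- cells + g$tensor[, qm, ] %*% B
    vc <- qei_null_varcomp(cells)
    thr <- permutation_threshold(g$tensor, vc, n_perm = n_perm,
                                 alpha = 0.05, seed = seed + 20000L + r)
    cof <- forward_selection(g$tensor, vc, thr, g$map, window_cM)
    rec <- backward_elimination(g$tensor, vc, cof, thr)
    sig <- rec[rec$significant, , drop = FALSE]
    near <- function(m) {
      i <- match(m, g$map$marker)
      g$map$chrom[i] == g$map$chrom[qm] &
        abs(g$map$cM[i] - g$map$cM[qm]) <= window_cM
    }
    hit[r] <- nrow(sig) > 0L && any(vapply(sig$marker, near, TRUE))
    main_only[r] <- any(rec$significant &
                          -log10(pmax(rec$p_int, 1e-300)) <= thr$interaction)
  }
  list(detection_rate = mean(hit), main_only_rate = mean(main_only),
       hit = hit)
}

#' Spatial-correction recovery
#'
#' Injects a strong greenhouse row effect (SD four times the residual SD),
#' fits the within-environment spatial model, and measures whether the row
#' component is declared significant, how well the row BLUPs track the
#' injected effects, and how much row variance the corrected data retain.
#'
#' @param seed Integer seed.
#' @param n_lines Lines (default 150).
#' @param row_sd,resid_sd Injected row-effect and residual SDs
#'   (defaults 2 and 0.5).
#' @return List with `sig_row`, `blup_cor`, `row_var_ratio`
#'   (corrected/raw row sum of squares after removing line means).
#' @export
experiment_spatial <- function(seed = 1L, n_lines = 150L, row_sd = 2,
                               resid_sd = 0.5) {
  chrs <- data.frame(chrom = "1", length_morgan = 1, length_bp = 9e7)
  env <- default_environments()[1, ]
  env$sigma_R <- resid_sd
  env$row_sd <- row_sd
  env$pos_sd <- 0.2
  env$n_rows <- 8L
  env$n_positions <- 12L
  cfg <- sim_config(n_lines = n_lines, chromosomes = chrs,
                    markers_per_chromosome = 2L, env_specs = env,
                    n_replicates = 2L, sigma2_L = 0.5, seed = seed)
  sim <- simulate_magic_met(cfg)
  tab <- sim$phenotypes
  fit <- fit_spatial_model(tab, "trait", env$env)
  truth <- attr(tab, "truth")$row_effects[[env$env]]
  blup_cor <- stats::cor(fit$blup_row[as.character(seq_along(truth))], truth)
  corrected <- correct_spatial(tab, stats::setNames(list(fit), env$env),
                               "trait")
  row_ss <- function(d) {
    r <- stats::residuals(stats::lm(d$trait ~ factor(d$line)))
    stats::anova(stats::lm(r ~ factor(d$row)))[1, "Sum Sq"]
  }
  list(sig_row = fit$sig_row, p_row = fit$p_row, blup_cor = blup_cor,
       row_var_ratio = row_ss(corrected) / row_ss(tab))
}
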