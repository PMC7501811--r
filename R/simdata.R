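#' Simulation configuration for a synthetic MAGIC multi-environment trial
#'
#' Bundles every parameter of the synthetic MAGIC-MET generator: the genome
#' (chromosome genetic/physical lengths and marker density), the population
#' design (number of 8-way MAGIC lines, selfing generations, control lines),
#' the trial design (environments with their seven climatic covariates,
#' per-environment residual SDs and greenhouse row/position effect SDs,
#' replicates), and the genetic architecture (QTLs via [qtl_spec()],
#' polygenic and line-by-environment variances).
#'
#' @param n_lines Number of MAGIC lines to simulate.
#' @param chromosomes Data frame with columns `chrom`, `length_morgan`
#'   (genetic length in Morgans) and `length_bp` (physical length).
#' @param markers_per_chromosome Number of equally spaced markers placed on
#'   each chromosome.
#' @param env_specs Data frame with one row per environment: column `env`,
#'   the seven covariate columns `Tmin`, `Tmax`, `Tmean`, `ThAmp`, `SDD`,
#'   `Vpd`, `RH`, and columns `sigma_R` (residual SD), `row_sd`, `pos_sd`,
#'   `n_rows`, `n_positions`. Missing design columns get defaults.
#' @param qtl_specs List of QTL specifications from [qtl_spec()].
#' @param selfing_generations Selfing generations after the 8-way cross
#'   (default 3, the MAGIC standard).
#' @param prob_softening Probability mass spread to the seven wrong founders
#'   when emitting haplotype probabilities (`epsilon`, in `[0, 1)`).
#' @param n_replicates Plants per line per environment.
#' @param n_controls Number of control (parental/hybrid stand-in) lines with
#'   fixed effects, replicated `2 * n_replicates` times.
#' @param mu Grand mean of the trait.
#' @param sigma2_L Polygenic (line) variance.
#' @param sigma2_LxE Line-by-environment interaction variance.
#' @param seed Integer seed; the whole dataset is reproducible given the
#'   configuration and this seed.
#' @return An object of class `sim_config` (a list).
#' @export
sim_config <- function(n_lines,
                       chromosomes,
                       markers_per_chromosome,
                       env_specs,
                       qtl_specs = list(),
                       selfing_generations = 3L,
                       prob_softening = 0,
                       n_replicates = 2L,
                       n_controls = 4L,
                       mu = 0,
                       sigma2_L = 0,
                       sigma2_LxE = 0,
                       seed = 1L) {
  stopifnot(is.data.frame(chromosomes),
            all(c("chrom", "length_morgan", "length_bp") %in% names(chromosomes)))
  if (nrow(chromosomes) == 0L)
    stop("at least one chromosome is required")
  if (any(chromosomes$length_morgan < 0) || any(chromosomes$length_bp <= 0))
    stop("chromosome lengths must be positive")
  if (prob_softening < 0 || prob_softening >= 1)
    stop("prob_softening must lie in [0, 1)")
  if (sigma2_L < 0 || sigma2_LxE < 0)
    stop("variance parameters must be non-negative")
  stopifnot(is.data.frame(env_specs), "env" %in% names(env_specs))
  covs <- covariate_names()
  missing_cov <- setdiff(covs, names(env_specs))
  if (length(missing_cov))
    stop("env_specs lacks covariate columns: ", paste(missing_cov, collapse = ", "))
  env_specs$env <- as.character(env_specs$env)
  defaults <- list(sigma_R = 1, row_sd = 0, pos_sd = 0,
                   n_rows = 6L, n_positions = 10L)
  for (nm in names(defaults))
    if (!nm %in% names(env_specs)) env_specs[[nm]] <- defaults[[nm]]
  if (any(env_specs$sigma_R < 0) || any(env_specs$row_sd < 0) ||
      any(env_specs$pos_sd < 0))
    stop("environment SDs must be non-negative")
  for (q in qtl_specs) {
    stopifnot(inherits(q, "qtl_spec"))
    if (!q$chrom %in% chromosomes$chrom)
      stop("QTL references unknown chromosome: ", q$chrom)
    if (!is.null(q$covariate) && !q$covariate %in% covs)
      stop("QTL references unknown covariate: ", q$covariate)
  }
  structure(list(n_founders = 8L,
                 n_lines = as.integer(n_lines),
                 chromosomes = chromosomes,
                 markers_per_chromosome = as.integer(markers_per_chromosome),
                 selfing_generations = as.integer(selfing_generations),
                 prob_softening = prob_softening,
                 qtl_specs = qtl_specs,
                 env_specs = env_specs,
                 n_replicates = as.integer(n_replicates),
                 n_controls = as.integer(n_controls),
                 mu = mu,
                 sigma2_L = sigma2_L,
                 sigma2_LxE = sigma2_LxE,
                 seed = as.integer(seed)),
            class = "sim_config")
}

covariate_names <- function() c("Tmin", "Tmax", "Tmean", "ThAmp", "SDD", "Vpd", "RH")

#' Specify a planted QTL
#'
#' Defines the generative counterpart of a locus with main founder effects,
#' optional per-environment deviations (QTL-by-environment interaction) and
#' an optional founder-specific sensitivity to one environmental covariate.
#' Main effects and each environment column of the deviation matrix are
#' centred to sum to zero (the identifiable scale).
#'
#' @param chrom Chromosome id (must exist in the configuration).
#' @param pos_cM Genetic position in centiMorgans.
#' @param main_effects Numeric length-8 vector of founder main effects.
#' @param env_effects Optional 8 x n_env matrix of founder-by-environment
#'   deviations (columns centred).
#' @param covariate Optional name of the covariate driving founder-specific
#'   sensitivity.
#' @param sensitivity Numeric length-8 vector of founder slopes on the
#'   (z-scored) covariate; centred.
#' @return An object of class `qtl_spec`.
#' @export
qtl_spec <- function(chrom, pos_cM, main_effects = rep(0, 8),
                     env_effects = NULL, covariate = NULL,
                     sensitivity = rep(0, 8)) {
  stopifnot(length(main_effects) == 8L, length(sensitivity) == 8L)
  main_effects <- main_effects - mean(main_effects)
  sensitivity <- sensitivity - mean(sensitivity)
  if (!is.null(env_effects)) {
    env_effects <- as.matrix(env_effects)
    stopifnot(nrow(env_effects) == 8L)
    env_effects <- sweep(env_effects, 2L, colMeans(env_effects))
  }
  structure(list(chrom = chrom, pos_cM = pos_cM,
                 main_effects = main_effects, env_effects = env_effects,
                 covariate = covariate, sensitivity = sensitivity),
            class = "qtl_spec")
}

## One meiotic product from a diploid parent. Haplotypes are lists with
## `end` (segment right endpoints in cM, last = chromosome length) and
## `founder` (integer labels). Crossover count is Poisson with mean equal to
## the genetic length in Morgans, positions uniform (Haldane, no
## interference).
meiosis <- function(hap1, hap2, length_cM) {
  n_xo <- stats::rpois(1L, length_cM / 100)
  if (n_xo == 0L) {
    if (stats::runif(1) < 0.5) return(hap1) else return(hap2)
  }
  xo <- sort(stats::runif(n_xo, 0, length_cM))
  haps <- list(hap1, hap2)
  cur <- if (stats::runif(1) < 0.5) 1L else 2L
  bounds <- c(0, xo, length_cM)
  out_end <- numeric(0)
  out_f <- integer(0)
  for (s in seq_len(length(bounds) - 1L)) {
    lo <- bounds[s]; hi <- bounds[s + 1L]
    if (hi <= lo) { cur <- 3L - cur; next }
    h <- haps[[cur]]
    keep <- which(h$end > lo & c(0, h$end[-length(h$end)]) < hi)
    for (k in keep) {
      out_end <- c(out_end, min(h$end[k], hi))
      out_f <- c(out_f, h$founder[k])
    }
    cur <- 3L - cur
  }
  ## merge adjacent segments with equal founder
  if (length(out_f) > 1L) {
    same <- c(FALSE, out_f[-1L] == out_f[-length(out_f)])
    out_end <- out_end[!c(same[-1L], FALSE)]
    out_f <- out_f[!c(same[-1L], FALSE)]
  }
  out_end[length(out_end)] <- length_cM
  list(end = out_end, founder = out_f)
}

founder_hap <- function(f, length_cM) list(end = length_cM, founder = as.integer(f))

## gamete across all chromosomes from a diploid individual
## individual: list per chromosome of list(h1, h2)
gamete <- function(ind, lengths_cM) {
  lapply(seq_along(ind), function(c)
    meiosis(ind[[c]]$h1, ind[[c]]$h2, lengths_cM[c]))
}

cross <- function(a, b, lengths_cM) {
  ga <- gamete(a, lengths_cM)
  gb <- gamete(b, lengths_cM)
  lapply(seq_along(ga), function(c) list(h1 = ga[[c]], h2 = gb[[c]]))
}

#' Simulate the genomes of an 8-way MAGIC population
#'
#' Each line descends from its own funnel: four 2-way hybrids of the eight
#' founders, two 4-way crosses, one 8-way cross, followed by
#' `selfing_generations` generations of single-seed-descent selfing.
#' Crossovers per meiosis are Poisson with mean equal to the chromosome
#' length in Morgans, positions uniform (no interference). Residual
#' heterozygosity is retained: both homologues are kept per chromosome.
#'
#' @param config A [sim_config()].
#' @return A list of class `magic_genomes`: one element per line, each a
#'   per-chromosome list of `h1`/`h2` founder-mosaic haplotypes, with the
#'   chromosome table attached as an attribute.
#' @export
simulate_magic_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chr <- config$chromosomes
  len <- chr$length_morgan * 100  # cM
  founders <- lapply(1:8, function(f)
    lapply(len, function(L) list(h1 = founder_hap(f, L), h2 = founder_hap(f, L))))
  genomes <- vector("list", config$n_lines)
  for (i in seq_len(config$n_lines)) {
    ab <- cross(founders[[1]], founders[[2]], len)
    cd <- cross(founders[[3]], founders[[4]], len)
    ef <- cross(founders[[5]], founders[[6]], len)
    gh <- cross(founders[[7]], founders[[8]], len)
    abcd <- cross(ab, cd, len)
    efgh <- cross(ef, gh, len)
    ind <- cross(abcd, efgh, len)
    for (g in seq_len(config$selfing_generations))
      ind <- cross(ind, ind, len)
    genomes[[i]] <- ind
  }
  names(genomes) <- sprintf("L%03d", seq_len(config$n_lines))
  structure(genomes, chromosomes = chr, class = "magic_genomes")
}

#' Build an equally spaced genetic map from a configuration
#'
#' Markers are placed uniformly along each chromosome's genetic length;
#' physical positions follow a monotone piecewise-linear (here linear)
#' cM-to-bp map scaled to the chromosome's physical length.
#'
#' @param config A [sim_config()].
#' @return Data frame with columns `marker`, `chrom`, `cM`, `bp`.
#' @export
make_genetic_map <- function(config) {
  chr <- config$chromosomes
  m <- config$markers_per_chromosome
  out <- do.call(rbind, lapply(seq_len(nrow(chr)), function(c) {
    L <- chr$length_morgan[c] * 100
    cm <- if (m == 1L) L / 2 else seq(0, L, length.out = m)
    bp <- if (L > 0) round(1 + (cm / L) * (chr$length_bp[c] - 1)) else
      round(seq(1, chr$length_bp[c], length.out = m))
    data.frame(marker = sprintf("M%s_%03d", chr$chrom[c], seq_len(m)),
               chrom = chr$chrom[c], cM = cm, bp = bp,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

hap_founder_at <- function(hap, pos) {
  hap$founder[findInterval(pos, c(0, hap$end), rightmost.closed = TRUE,
                           left.open = TRUE)]
}

#' Emit founder haplotype probabilities from true mosaics
#'
#' Mimics the output of a founder-probability step on inbred lines: at each
#' marker one homologue of the line is sampled (collapsing residual
#' heterozygosity), the true founder receives probability `1 - epsilon` and
#' every other founder `epsilon / 7`, so each (line, marker) slice sums to 1.
#'
#' @param genomes A `magic_genomes` object.
#' @param map Genetic map data frame (`marker`, `chrom`, `cM`, `bp`).
#' @param epsilon Softening mass in `[0, 1)`.
#' @return A 3-d array `lines x markers x 8` of class `founder_prob` with the
#'   map and the sampled true founder matrix attached as attributes.
#' @export
mosaics_to_probabilities <- function(genomes, map, epsilon = 0) {
  stopifnot(inherits(genomes, "magic_genomes"))
  if (epsilon < 0 || epsilon >= 1) stop("epsilon must lie in [0, 1)")
  chr <- attr(genomes, "chromosomes")
  n <- length(genomes)
  if (nrow(map) == 0L) {
    tens <- array(numeric(0), dim = c(n, 0L, 8L),
                  dimnames = list(names(genomes), NULL, founder_labels()))
    attr(tens, "map") <- map
    class(tens) <- "founder_prob"
    return(tens)
  }
  lens <- stats::setNames(chr$length_morgan * 100, chr$chrom)
  if (any(map$cM > lens[as.character(map$chrom)] + 1e-9))
    stop("marker position beyond chromosome end")
  chr_index <- stats::setNames(seq_len(nrow(chr)), chr$chrom)
  truth <- matrix(NA_integer_, n, nrow(map),
                  dimnames = list(names(genomes), map$marker))
  for (i in seq_len(n)) {
    g <- genomes[[i]]
    for (c in seq_len(nrow(chr))) {
      idx <- which(map$chrom == chr$chrom[c])
      if (!length(idx)) next
      pos <- map$cM[idx]
      f1 <- hap_founder_at(g[[c]]$h1, pos)
      f2 <- hap_founder_at(g[[c]]$h2, pos)
      pick <- stats::runif(length(idx)) < 0.5
      truth[i, idx] <- ifelse(pick, f1, f2)
    }
  }
  tens <- array(epsilon / 7, dim = c(n, nrow(map), 8L),
                dimnames = list(names(genomes), map$marker, founder_labels()))
  for (p in 1:8) tens[, , p][truth == p] <- 1 - epsilon
  attr(tens, "map") <- map
  attr(tens, "true_founder") <- truth
  class(tens) <- "founder_prob"
  tens
}

founder_labels <- function() sprintf("F%d", 1:8)

nearest_marker <- function(map, chrom, pos_cM) {
  idx <- which(map$chrom == chrom)
  if (!length(idx)) stop("no markers on chromosome ", chrom)
  idx[which.min(abs(map$cM[idx] - pos_cM))]
}

#' Simulate replicate-level MET phenotypes from founder probabilities
#'
#' Generates one trait as the sum of a grand mean, fixed environment
#' effects, planted QTL contributions (main, per-environment deviation, and
#' covariate-sensitivity components weighted by the founder probabilities at
#' the marker nearest each QTL), a polygenic line effect, a
#' line-by-environment deviation, shared greenhouse row and position
#' effects, and heteroscedastic plant-level noise. Control lines carry fixed
#' effects and no random line terms, mirroring the role of parental/hybrid
#' checks. Every generated component is recorded in the `truth` attribute.
#'
#' @param tensor A `founder_prob` array (with its map attribute).
#' @param config The [sim_config()] used to generate it.
#' @param trait Trait name used in the output.
#' @return A `PhenotypeTable` data frame (`line`, `env`, `rep`, `row`,
#'   `position`, `is_control`, `value`) with attribute `truth`.
#' @export
simulate_met_phenotypes <- function(tensor, config, trait = "trait") {
  stopifnot(inherits(tensor, "founder_prob"), inherits(config, "sim_config"))
  es <- config$env_specs
  if (nrow(es) == 0L) stop("env_specs must be non-empty")
  if (config$n_replicates < 1L) stop("n_replicates must be >= 1")
  map <- attr(tensor, "map")
  lines <- dimnames(tensor)[[1]]
  n <- length(lines)
  J <- nrow(es)
  covz <- scale(as.matrix(es[covariate_names()]))
  covz[is.nan(covz)] <- 0
  qtl_cell <- matrix(0, n, J, dimnames = list(lines, es$env))
  qtl_truth <- list()
  for (qi in seq_along(config$qtl_specs)) {
    q <- config$qtl_specs[[qi]]
    if (!is.null(q$covariate) && !q$covariate %in% covariate_names())
      stop("QTL references unknown covariate: ", q$covariate)
    mk <- nearest_marker(map, q$chrom, q$pos_cM)
    X <- tensor[, mk, , drop = TRUE]          # n x 8
    if (is.null(dim(X))) X <- matrix(X, nrow = n)
    eff <- matrix(q$main_effects, 8L, J)
    if (!is.null(q$env_effects)) eff <- eff + q$env_effects
    if (!is.null(q$covariate))
      eff <- eff + outer(q$sensitivity, covz[, q$covariate])
    qtl_cell <- qtl_cell + X %*% eff
    qtl_truth[[qi]] <- list(marker = map$marker[mk], chrom = q$chrom,
                            pos_cM = q$pos_cM, bp = map$bp[mk],
                            main_effects = q$main_effects,
                            env_effects = q$env_effects,
                            covariate = q$covariate,
                            sensitivity = q$sensitivity)
  }
  env_eff <- stats::rnorm(J, 0, 1)
  names(env_eff) <- es$env
  polygenic <- stats::rnorm(n, 0, sqrt(config$sigma2_L))
  names(polygenic) <- lines
  gxe <- matrix(stats::rnorm(n * J, 0, sqrt(config$sigma2_LxE)), n, J,
                dimnames = list(lines, es$env))
  n_ctrl <- config$n_controls
  ctrl_eff <- if (n_ctrl > 0) stats::rnorm(n_ctrl, 0, sqrt(max(config$sigma2_L, 1))) else numeric(0)
  if (n_ctrl > 0) names(ctrl_eff) <- sprintf("C%02d", seq_len(n_ctrl))

  rows_list <- list()
  truth_rows <- list()
  truth_pos <- list()
  for (j in seq_len(J)) {
    nr <- es$n_rows[j]; np <- es$n_positions[j]
    row_eff <- stats::rnorm(nr, 0, es$row_sd[j])
    pos_eff <- stats::rnorm(np, 0, es$pos_sd[j])
    truth_rows[[as.character(es$env[j])]] <- row_eff
    truth_pos[[as.character(es$env[j])]] <- pos_eff
    ids <- c(rep(lines, each = config$n_replicates),
             rep(names(ctrl_eff), each = 2L * config$n_replicates))
    isc <- c(rep(0L, n * config$n_replicates),
             rep(1L, n_ctrl * 2L * config$n_replicates))
    reps <- c(rep(seq_len(config$n_replicates), times = n),
              rep(seq_len(2L * config$n_replicates), times = n_ctrl))
    nplants <- length(ids)
    cell_idx <- rep_len(sample.int(nr * np), nplants)
    plot_row <- (cell_idx - 1L) %/% np + 1L
    plot_pos <- (cell_idx - 1L) %% np + 1L
    envj <- as.character(es$env[j])
    gen <- numeric(nplants)
    im <- which(isc == 0L)
    gen[im] <- polygenic[ids[im]] + gxe[cbind(ids[im], rep(envj, length(im)))] +
      qtl_cell[cbind(ids[im], rep(envj, length(im)))]
    ic <- which(isc == 1L)
    if (length(ic)) gen[ic] <- ctrl_eff[ids[ic]]
    y <- config$mu + env_eff[j] + gen +
      row_eff[plot_row] + pos_eff[plot_pos] +
      stats::rnorm(nplants, 0, es$sigma_R[j])
    rows_list[[j]] <- data.frame(line = ids, env = as.character(es$env[j]),
                                 rep = reps, row = plot_row,
                                 position = plot_pos, is_control = isc,
                                 value = as.numeric(y),
                                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows_list)
  names(out)[names(out) == "value"] <- trait
  attr(out, "truth") <- list(mu = config$mu, env_effects = env_eff,
                             polygenic = polygenic, gxe = gxe,
                             qtl = qtl_truth, control_effects = ctrl_eff,
                             row_effects = truth_rows,
                             pos_effects = truth_pos,
                             covariates_z = covz)
  attr(out, "trait") <- trait
  out
}

#' Run the full synthetic generator
#'
#' Convenience wrapper chaining pedigree simulation, map construction,
#' probability emission and phenotype generation under a single seed.
#'
#' @param config A [sim_config()].
#' @param trait Trait name.
#' @return List with `genomes`, `map`, `tensor`, `phenotypes`, `env_specs`.
#' @export
simulate_magic_met <- function(config, trait = "trait") {
  genomes <- simulate_magic_pedigree(config)  # seeds the RNG
  map <- make_genetic_map(config)
  tensor <- mosaics_to_probabilities(genomes, map, config$prob_softening)
  phen <- simulate_met_phenotypes(tensor, config, trait = trait)
  list(genomes = genomes, map = map, tensor = tensor, phenotypes = phen,
       env_specs = config$env_specs)
}

#' Write a simulated dataset to plain-text files
#'
#' Emits the genetic map and covariates as CSV, the probability tensor in
#' long format TSV, the phenotype table as CSV, and the ground truth as JSON.
#'
#' @param sim Result of [simulate_magic_met()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_simulated_data <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(sim$map, file.path(dir, "map.csv"), row.names = FALSE)
  utils::write.csv(sim$env_specs, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$phenotypes, file.path(dir, "phenotypes.csv"),
                   row.names = FALSE)
  tl <- as.data.frame.table(sim$tensor, responseName = "prob")
  names(tl) <- c("line", "marker", "founder", "prob")
  utils::write.table(tl, file.path(dir, "probabilities.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  truth <- attr(sim$phenotypes, "truth")
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(file.path(dir, c("map.csv", "covariates.csv", "phenotypes.csv",
                             "probabilities.tsv", "truth.json")))
}

#' Default 12-environment covariate table
#'
#' A synthetic stand-in for a 12-environment greenhouse trial across three
#' regions with control, water-deficit, salinity and heat treatments: four
#' covariate clusters (Mediterranean high-amplitude, temperate-control,
#' mixed-stress, extreme-heat) generate the seven climatic covariates.
#'
#' @param seed Seed for the small covariate jitter.
#' @return Data frame usable as `env_specs` (with design defaults).
#' @export
default_environments <- function(seed = 42L) {
  set.seed(seed)
  centers <- rbind(
    c(12, 30, 21, 18, 900, 1.1, 55),   # high amplitude, low Vpd region
    c(10, 24, 17, 14, 700, 0.7, 80),   # temperate control
    c(14, 32, 23, 18, 1100, 1.6, 60),  # mixed stress
    c(22, 44, 33, 22, 1600, 2.8, 30))  # extreme heat
  assign_k <- c(1, 1, 1, 1, 2, 2, 3, 3, 3, 3, 3, 4)
  covs <- centers[assign_k, ] +
    matrix(stats::rnorm(12 * 7, 0, c(0.5, 0.8, 0.5, 0.5, 30, 0.08, 2)[col(matrix(0, 12, 7))]),
           12, 7)
  out <- data.frame(env = sprintf("E%02d", 1:12), covs)
  names(out)[2:8] <- covariate_names()
  out$cluster_true <- assign_k
  out$sigma_R <- stats::runif(12, 0.6, 1.4)
  out$row_sd <- 0.3
  out$pos_sd <- 0.2
  out$n_rows <- 6L
  out$n_positions <- 12L
  out
}
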