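#' Line-by-environment cell means
#'
#' Mean phenotype per MAGIC line and environment (control lines excluded),
#' the input scale of the joint-regression, factorial-regression and
#' multi-environment QTL models.
#'
#' @param table Phenotype data frame (`line`, `env`, `is_control`, trait).
#' @param trait Trait column name.
#' @return Numeric matrix lines x environments (NA for empty cells).
#' @export
cell_means <- function(table, trait) {
  d <- table[table$is_control == 0L & !is.na(table[[trait]]), , drop = FALSE]
  tapply(d[[trait]], list(factor(d$line), factor(d$env)), mean)
}

#' Environmental quality index
#'
#' The index of an environment is the mean performance of all genotypes
#' observed in it; indices are returned centred to mean zero across
#' environments.
#'
#' @param cells Cell-means matrix from [cell_means()].
#' @return Named numeric vector, one centred index per environment.
#' @export
environment_index <- function(cells) {
  idx <- colMeans(cells, na.rm = TRUE)
  if (any(!is.finite(idx))) stop("every environment needs >= 1 observed line")
  idx - mean(idx)
}

#' Finlay-Wilkinson joint regression per line
#'
#' Ordinary least squares of each line's cell means on the centred
#' environmental index: the intercept is the genotypic mean, the
#' coefficient is the slope (population mean response plus the
#' genotype-specific deviation), and the residual variance (denominator
#' `n - 2`) is the non-linear plasticity VAR. Lines observed in fewer than
#' `min_envs` environments get the mean only.
#'
#' @param cells Cell-means matrix.
#' @param min_envs Minimum environments for slope/VAR (default 3).
#' @return Data frame `line`, `genotypic_mean`, `slope`, `var_nl`, `n_envs`.
#' @export
fit_finlay_wilkinson <- function(cells, min_envs = 3L) {
  idx <- environment_index(cells)
  if (stats::var(idx) <= 0) stop("environmental index has zero variance")
  out <- data.frame(line = rownames(cells),
                    genotypic_mean = NA_real_, slope = NA_real_,
                    var_nl = NA_real_, n_envs = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cells))) {
    obs <- which(!is.na(cells[i, ]))
    out$n_envs[i] <- length(obs)
    if (length(obs) == 0L) next
    y <- cells[i, obs]
    x <- idx[obs]
    if (length(obs) < min_envs || stats::var(x) <= 0) {
      out$genotypic_mean[i] <- mean(y)
      next
    }
    xc <- x - mean(x)
    b <- sum(xc * y) / sum(xc^2)
    a <- mean(y) - b * mean(x)
    r <- y - a - b * x
    out$genotypic_mean[i] <- a
    out$slope[i] <- b
    out$var_nl[i] <- sum(r^2) / (length(obs) - 2L)
  }
  out
}

## Factorial-regression OLS for one (z-scored) covariate. For complete
## cells the fit has a closed form: double-centre the cell means (the
## interaction residuals of the additive two-way model) and regress each
## line's residual profile on the centred covariate; the sensitivities sum
## to zero automatically. With missing cells the model is fitted by lm().
## Returns sensitivities (sum-to-zero), the F test of the sensitivity term
## and its share of the interaction sum of squares.
factorial_fit <- function(cells, cvz) {
  n <- nrow(cells); J <- ncol(cells)
  if (!anyNA(cells)) {
    zt <- cvz - mean(cvz)
    resid <- sweep(sweep(cells, 1L, rowMeans(cells)), 2L,
                   colMeans(cells) - mean(cells))
    zz <- sum(zt^2)
    alpha <- as.numeric(resid %*% zt) / zz
    ss_gxe <- sum(resid^2)
    ss_cv <- sum(alpha^2) * zz
    df1 <- n - 1L
    df2 <- (n - 1L) * (J - 2L)
    Fstat <- if (df2 > 0 && ss_gxe > ss_cv)
      (ss_cv / df1) / ((ss_gxe - ss_cv) / df2) else Inf
    p <- if (is.finite(Fstat))
      stats::pf(Fstat, df1, df2, lower.tail = FALSE) else 0
    return(list(alpha = stats::setNames(alpha, rownames(cells)),
                F = Fstat, p = p, ss_gxe = ss_gxe, ss_cv = ss_cv))
  }
  long <- data.frame(y = as.vector(cells),
                     line = factor(rep(rownames(cells), ncol(cells))),
                     env = factor(rep(colnames(cells), each = nrow(cells))),
                     cv = rep(cvz, each = nrow(cells)))
  long <- long[!is.na(long$y), , drop = FALSE]
  add <- stats::lm(y ~ line + env, data = long)
  full <- stats::lm(y ~ line + env + line:cv, data = long)
  a <- stats::anova(add, full)
  ss_gxe <- sum(stats::residuals(add)^2)
  ss_cv <- ss_gxe - sum(stats::residuals(full)^2)
  cf <- stats::coef(full)
  raw <- stats::setNames(rep(0, nrow(cells)), rownames(cells))
  sel <- grep("^line(.+):cv$", names(cf))
  vals <- cf[sel]
  vals[is.na(vals)] <- 0   # aliased level: fixed at zero by the fit
  raw[sub("^line(.+):cv$", "\\1", names(cf)[sel])] <- vals
  list(alpha = raw - mean(raw), F = a$F[2], p = a$`Pr(>F)`[2],
       ss_gxe = ss_gxe, ss_cv = ss_cv)
}

#' Select the most impactful environmental covariate
#'
#' Tests each of the seven covariates singly in the factorial-regression
#' model: the covariate-sensitivity term is F-tested against the additive
#' line + environment model, and its share of the interaction sum of
#' squares (the residual SS of the additive two-way model) is recorded. The
#' covariate with the smallest p-value is declared best when p <= alpha.
#'
#' @param cells Cell-means matrix.
#' @param envs Environment covariate table (column `env` plus the seven
#'   covariates); covariates are z-scored across environments before
#'   fitting.
#' @param alpha Declaration level (default 0.05).
#' @return List with `best` (covariate name or NA), and `table` (covariate,
#'   F, p, ss_share).
#' @export
select_covariate <- function(cells, envs, alpha = 0.05) {
  if (ncol(cells) < 3L) stop("covariate selection needs >= 3 environments")
  envs <- envs[match(colnames(cells), envs$env), , drop = FALSE]
  res <- list()
  for (cv in intersect(covariate_names(), names(envs))) {
    v <- envs[[cv]]
    if (stats::sd(v) == 0 || any(!is.finite(v))) {
      warning("covariate ", cv, " constant across environments; skipped")
      next
    }
    ff <- factorial_fit(cells, as.vector(scale(v)))
    res[[cv]] <- data.frame(covariate = cv, F = ff$F, p = ff$p,
                            ss_share = ff$ss_cv / ff$ss_gxe,
                            stringsAsFactors = FALSE)
  }
  if (!length(res)) stop("no usable covariate")
  tab <- do.call(rbind, res)
  rownames(tab) <- NULL
  best <- tab$covariate[which.min(tab$p)]
  if (min(tab$p) > alpha) best <- NA_character_
  list(best = best, table = tab)
}

#' Genotypic sensitivity to one environmental covariate
#'
#' Fits the factorial-regression model with the chosen (z-scored) covariate
#' by OLS and extracts the per-line sensitivity under a sum-to-zero
#' constraint: sensitivities are expressed relative to the population mean
#' response, which is absorbed by the environment effects.
#'
#' @param cells Cell-means matrix.
#' @param envs Environment covariate table.
#' @param covariate Covariate name.
#' @param min_envs Minimum observed environments per line (default 3);
#'   lines below it get NA.
#' @return Named numeric vector of sensitivities (one per line).
#' @export
fit_factorial_regression <- function(cells, envs, covariate,
                                     min_envs = 3L) {
  envs <- envs[match(colnames(cells), envs$env), , drop = FALSE]
  v <- envs[[covariate]]
  if (is.null(v) || stats::sd(v) == 0)
    stop("covariate must vary across environments")
  ff <- factorial_fit(cells, as.vector(scale(v)))
  scv <- ff$alpha[rownames(cells)]
  scv[rowSums(!is.na(cells)) < min_envs] <- NA
  scv
}

#' Transform non-linear plasticity for scanning
#'
#' Natural log of VAR for all traits (zeros floored at `offset`); square
#' root for the fruit-set style trait tagged `fset`, matching its
#' normalising transform.
#'
#' @param var_nl Non-negative VAR values.
#' @param trait Trait name; `"fset"` selects the square-root transform.
#' @param offset Floor applied before the log (default 1e-6).
#' @return Transformed values.
#' @export
transform_for_scan <- function(var_nl, trait, offset = 1e-6) {
  stopifnot(all(var_nl >= 0, na.rm = TRUE))
  if (identical(trait, "fset")) sqrt(var_nl) else log(pmax(var_nl, offset))
}

#' Full plasticity table for one trait
#'
#' Combines the genotypic mean, Finlay-Wilkinson slope and VAR, and the
#' sensitivity to the selected covariate into one table per line.
#'
#' @param cells Cell-means matrix.
#' @param envs Environment covariate table.
#' @param min_envs Minimum environments for slope/VAR/SCv.
#' @param alpha Covariate declaration level.
#' @return Data frame `line`, `genotypic_mean`, `slope`, `var_nl`, `scv`,
#'   `n_envs`, `best_covariate`; attribute `covariate_selection` holds the
#'   per-covariate table.
#' @export
plasticity_table <- function(cells, envs, min_envs = 3L, alpha = 0.05) {
  fw <- fit_finlay_wilkinson(cells, min_envs)
  sel <- select_covariate(cells, envs, alpha)
  if (!is.na(sel$best)) {
    scv <- fit_factorial_regression(cells, envs, sel$best, min_envs)
    fw$scv <- unname(scv[fw$line])
  } else {
    fw$scv <- NA_real_
  }
  fw$best_covariate <- sel$best
  attr(fw, "covariate_selection") <- sel$table
  fw
}
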