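#' Flag outliers within environments by robust z-score
#'
#' An observation is flagged when its absolute deviation from the
#' environment median exceeds `k` times the MAD-based robust SD (MAD scaled
#' by 1.4826). Environments with fewer than 5 observations are left
#' unflagged with a warning.
#'
#' @param table Phenotype data frame with columns `line`, `env` and the trait.
#' @param trait Trait column name.
#' @param k Robust z-score cutoff (> 0), default 3.5.
#' @return Logical vector, `TRUE` for flagged observations (NA values are
#'   never flagged).
#' @export
flag_outliers <- function(table, trait, k = 3.5) {
  stopifnot(k > 0, trait %in% names(table))
  v <- table[[trait]]
  flag <- rep(FALSE, nrow(table))
  for (e in unique(table$env)) {
    idx <- which(table$env == e & !is.na(v))
    if (length(idx) < 5L) {
      if (length(idx) > 0L)
        warning("environment ", e, " has < 5 observations; no outlier flagging")
      next
    }
    med <- stats::median(v[idx])
    s <- stats::mad(v[idx])
    flag[idx] <- abs(v[idx] - med) > k * s
  }
  flag
}

#' Fit the within-environment spatial mixed model
#'
#' Fits, for one environment and trait, a mixed model with a fixed overall
#' mean and fixed control-line effects, a random MAGIC-line effect, and
#' random greenhouse row and position effects, by REML (lme4). The
#' significance of the row and position variance components is assessed by
#' REML likelihood-ratio tests against the reduced model, referred to the
#' boundary mixture 0.5*chisq(0) + 0.5*chisq(1).
#'
#' @param table Phenotype data frame (`line`, `env`, `row`, `position`,
#'   `is_control`, trait).
#' @param trait Trait column name.
#' @param env Environment id to fit.
#' @param alpha Significance level for the row/position tests (default 0.05).
#' @return A `spatial_fit` list: variance components, row/position BLUPs,
#'   LRT p-values and significance flags.
#' @export
fit_spatial_model <- function(table, trait, env, alpha = 0.05) {
  d <- table[table$env == env & !is.na(table[[trait]]), , drop = FALSE]
  if (nrow(d) == 0L) stop("no data for environment ", env)
  n_rows <- length(unique(d$row))
  n_pos <- length(unique(d$position))
  if (n_rows < 2L && n_pos < 2L)
    stop("environment ", env, " needs >= 2 rows or >= 2 positions")
  d$y <- d[[trait]]
  d$line <- factor(d$line)
  d$rowf <- factor(d$row)
  d$posf <- factor(d$position)
  d$m <- 1 - d$is_control
  has_controls <- any(d$is_control == 1L)
  if (has_controls) {
    d$ctrl <- factor(ifelse(d$is_control == 1L, as.character(d$line), ".magic"))
    fixed <- "y ~ ctrl"
  } else {
    message("no control lines in environment ", env,
            "; fitting without the control term")
    fixed <- "y ~ 1"
  }
  terms <- c(line = "(0 + m | line)",
             row = if (n_rows >= 2L) "(1 | rowf)",
             pos = if (n_pos >= 2L) "(1 | posf)")
  fit_with <- function(drop = NULL) {
    tt <- terms[setdiff(names(terms), drop)]
    f <- stats::as.formula(paste(fixed, "+", paste(tt, collapse = " + ")))
    suppressMessages(suppressWarnings(
      lme4::lmer(f, data = d, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore",
                                             calc.derivs = FALSE))))
  }
  full <- fit_with()
  vc <- as.data.frame(lme4::VarCorr(full))
  getvar <- function(grp) {
    i <- which(vc$grp == grp)
    if (length(i)) vc$vcov[i[1]] else NA_real_
  }
  boundary_lrt <- function(which) {
    if (!which %in% names(terms)) return(list(stat = NA_real_, p = NA_real_))
    red <- fit_with(drop = which)
    stat <- max(0, 2 * (as.numeric(stats::logLik(full)) -
                          as.numeric(stats::logLik(red))))
    p <- if (stat <= 0) 1 else 0.5 * stats::pchisq(stat, 1, lower.tail = FALSE)
    list(stat = stat, p = p)
  }
  lrt_row <- boundary_lrt("row")
  lrt_pos <- boundary_lrt("pos")
  re <- lme4::ranef(full)
  blup_row <- if ("rowf" %in% names(re))
    stats::setNames(re$rowf[[1]], rownames(re$rowf)) else NULL
  blup_pos <- if ("posf" %in% names(re))
    stats::setNames(re$posf[[1]], rownames(re$posf)) else NULL
  structure(list(env = env, trait = trait,
                 varcomp = c(line = getvar("line"), row = getvar("rowf"),
                             position = getvar("posf"),
                             residual = stats::sigma(full)^2),
                 blup_row = blup_row, blup_pos = blup_pos,
                 p_row = lrt_row$p, p_pos = lrt_pos$p,
                 sig_row = isTRUE(lrt_row$p <= alpha),
                 sig_pos = isTRUE(lrt_pos$p <= alpha),
                 has_controls = has_controls),
            class = "spatial_fit")
}

#' Fit the spatial model in every environment
#'
#' @param table Phenotype data frame.
#' @param trait Trait column name.
#' @param alpha Significance level passed to [fit_spatial_model()].
#' @return Named list of `spatial_fit`, one per environment.
#' @export
fit_spatial_all <- function(table, trait, alpha = 0.05) {
  envs <- unique(table$env)
  fits <- lapply(envs, function(e) fit_spatial_model(table, trait, e, alpha))
  stats::setNames(fits, envs)
}

#' Remove significant row/position BLUPs from the raw data
#'
#' Subtracts the BLUP of the row and/or position effect from each raw
#' observation, in each environment where the corresponding variance
#' component was significant. Record count and ordering are unchanged.
#'
#' @param table Phenotype data frame.
#' @param fits Named list of `spatial_fit` (one per environment) for one trait.
#' @param trait Trait column name.
#' @return The table with the trait column corrected.
#' @export
correct_spatial <- function(table, fits, trait) {
  envs <- unique(table$env)
  missing_fit <- setdiff(envs, names(fits))
  if (length(missing_fit))
    stop("fits missing for environments: ", paste(missing_fit, collapse = ", "))
  v <- table[[trait]]
  for (e in envs) {
    f <- fits[[e]]
    idx <- which(table$env == e)
    if (isTRUE(f$sig_row) && !is.null(f$blup_row)) {
      b <- f$blup_row[as.character(table$row[idx])]
      b[is.na(b)] <- 0
      v[idx] <- v[idx] - b
    }
    if (isTRUE(f$sig_pos) && !is.null(f$blup_pos)) {
      b <- f$blup_pos[as.character(table$position[idx])]
      b[is.na(b)] <- 0
      v[idx] <- v[idx] - b
    }
  }
  table[[trait]] <- v
  table
}

#' Outlier-flag and spatially correct one trait across all environments
#'
#' Convenience wrapper: flags outliers (set to NA), fits the spatial model
#' per environment, and removes significant row/position BLUPs.
#'
#' @inheritParams flag_outliers
#' @param alpha Significance level for the spatial tests.
#' @return List with the corrected `table` and the per-environment `fits`.
#' @export
preprocess_trait <- function(table, trait, k = 3.5, alpha = 0.05) {
  fl <- flag_outliers(table, trait, k)
  table[[trait]][fl] <- NA
  fits <- fit_spatial_all(table, trait, alpha)
  list(table = correct_spatial(table, fits, trait), fits = fits,
       n_flagged = sum(fl))
}
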