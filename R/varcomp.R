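#' Multi-environment variance decomposition for one trait
#'
#' REML fit of the whole-design model with fixed environment and
#' control-line (and control-by-environment) effects, random MAGIC-line and
#' line-by-environment effects, and a residual variance specific to each
#' environment. The significance of the line-by-environment component is
#' assessed by a REML likelihood-ratio test against the model without it,
#' referred to the boundary mixture 0.5*chisq(0) + 0.5*chisq(1).
#'
#' @param corrected Spatially corrected phenotype data frame (`line`, `env`,
#'   `is_control`, trait column).
#' @param trait Trait column name.
#' @return A `variance_decomposition` list: `sigma2_L`, `sigma2_LxE`,
#'   per-environment residual variances, `nb_E`, `nb_R` (mean replicate
#'   count over the design), mean residual variance, `prop_gxe`, `H2`, and
#'   the G-by-E LRT statistic and p-value.
#' @export
fit_gxe_model <- function(corrected, trait) {
  stopifnot(trait %in% names(corrected))
  d <- corrected[!is.na(corrected[[trait]]), , drop = FALSE]
  envs <- unique(d$env)
  if (length(envs) < 2L)
    stop("variance decomposition needs >= 2 environments with data")
  magic <- d$is_control == 0L
  cells <- table(d$line[magic], d$env[magic])
  if (max(cells) < 2L && length(envs) < 2L)
    stop("interaction variance inestimable: single replicate, one environment")
  y <- d[[trait]]
  envf <- factor(d$env)
  has_controls <- any(!magic)
  if (has_controls) {
    ctrl <- factor(ifelse(magic, ".magic", as.character(d$line)))
    X <- stats::model.matrix(~ envf * ctrl)
  } else {
    message("no control lines present; dropping the control terms")
    X <- stats::model.matrix(~ envf)
  }
  linef <- ifelse(magic, as.character(d$line), NA)
  cellf <- ifelse(magic, paste(d$line, d$env, sep = ":"), NA)
  full <- reml_fit(y, X, block = ifelse(magic, as.character(d$line),
                                        paste0(".ctrl", d$line)),
                   random = list(line = linef, cell = cellf),
                   resid_group = envf)
  red <- reml_fit(y, X, block = ifelse(magic, as.character(d$line),
                                       paste0(".ctrl", d$line)),
                  random = list(line = linef),
                  resid_group = envf)
  stat <- max(0, 2 * (full$loglik - red$loglik))
  p <- if (stat <= 0) 1 else 0.5 * stats::pchisq(stat, 1, lower.tail = FALSE)
  nb_E <- length(envs)
  nb_R <- mean(cells[cells > 0])
  out <- list(trait = trait,
              sigma2_L = unname(full$varcomp["line"]),
              sigma2_LxE = unname(full$varcomp["cell"]),
              resid_var = full$resid_var,
              nb_E = nb_E, nb_R = nb_R,
              mean_resid = mean(full$resid_var),
              lrt_stat = stat, lrt_p = p,
              loglik = full$loglik)
  out$prop_gxe <- prop_gxe(out)
  out$H2 <- heritability(out)
  class(out) <- "variance_decomposition"
  out
}

#' Proportion of genotypic plus interaction variance due to G-by-E
#'
#' `sigma2_LxE / (sigma2_L + sigma2_LxE)`.
#'
#' @param d A `variance_decomposition` (or any list with `sigma2_L`,
#'   `sigma2_LxE`).
#' @return Fraction in `[0, 1]`, or `NA` when both components are zero.
#' @export
prop_gxe <- function(d) {
  tot <- d$sigma2_L + d$sigma2_LxE
  if (!is.finite(tot) || tot <= 0) return(NA_real_)
  d$sigma2_LxE / tot
}

#' Broad-sense heritability at the whole-design level
#'
#' `H2 = sigma2_L / (sigma2_L + sigma2_LxE / nb.E + mean(sigma2_Ej) / nb.R)`
#' where `nb.E` is the number of environments and `nb.R` the mean replicate
#' count over the whole design.
#'
#' @param d A `variance_decomposition` (or any list with `sigma2_L`,
#'   `sigma2_LxE`, `mean_resid`, `nb_E`, `nb_R`).
#' @return Fraction in `[0, 1]`, or `NA` when the denominator is zero.
#' @export
heritability <- function(d) {
  stopifnot(d$nb_E >= 1, d$nb_R >= 1)
  den <- d$sigma2_L + d$sigma2_LxE / d$nb_E + d$mean_resid / d$nb_R
  if (!is.finite(den) || den <= 0) return(NA_real_)
  d$sigma2_L / den
}

#' Variance decomposition for several traits
#'
#' @param corrected Corrected phenotype data frame.
#' @param traits Character vector of trait columns.
#' @return Data frame, one row per trait, with the fields of
#'   [fit_gxe_model()].
#' @export
varcomp_table <- function(corrected, traits) {
  rows <- lapply(traits, function(tr) {
    v <- fit_gxe_model(corrected, tr)
    data.frame(trait = tr, sigma2_L = v$sigma2_L, sigma2_LxE = v$sigma2_LxE,
               mean_resid = v$mean_resid, nb_E = v$nb_E, nb_R = v$nb_R,
               prop_gxe = v$prop_gxe, H2 = v$H2,
               lrt_stat = v$lrt_stat, lrt_p = v$lrt_p)
  })
  do.call(rbind, rows)
}
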