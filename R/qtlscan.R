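#' Haley-Knott regression scan on founder probabilities
#'
#' At every marker, regresses the phenotype on the eight founder-origin
#' probability columns by least squares (intercept plus seven founder
#' columns; the eighth is the reference since probabilities sum to one) and
#' reports `LOD = (n/2) * log10(RSS0 / RSS1)` against the intercept-only
#' model. Allelic effects are re-expressed on the sum-to-zero scale. A
#' rank-deficient (monomorphic) marker gets LOD 0 with undefined effects
#' and is flagged.
#'
#' @param tensor `founder_prob` array (lines x markers x 8).
#' @param phenotype Named numeric vector indexed by line; lines with
#'   missing phenotype are dropped.
#' @return List of class `hk_scan`: `lod` (named per marker; `Inf` for a
#'   perfect fit), `effects` (markers x 8, sum-to-zero), `flagged`
#'   (logical), `n` (lines used).
#' @export
hk_scan <- function(tensor, phenotype) {
  lines <- dimnames(tensor)[[1]]
  ph <- phenotype[lines]
  keep <- which(!is.na(ph))
  if (length(keep) < 10L) stop("fewer than 10 lines with phenotype")
  y <- as.numeric(ph[keep])
  n <- length(y)
  rss0 <- sum((y - mean(y))^2)
  nm <- dim(tensor)[2]
  lod <- stats::setNames(numeric(nm), dimnames(tensor)[[2]])
  eff <- matrix(NA_real_, nm, 8, dimnames = list(dimnames(tensor)[[2]],
                                                 founder_labels()))
  flagged <- stats::setNames(logical(nm), dimnames(tensor)[[2]])
  for (m in seq_len(nm)) {
    P <- tensor[keep, m, , drop = TRUE]
    if (is.null(dim(P))) P <- matrix(P, nrow = n)
    X <- cbind(1, P[, 1:7, drop = FALSE])
    fit <- stats::lm.fit(X, y)
    rank_full <- fit$rank
    rss1 <- sum(fit$residuals^2)
    if (rank_full < ncol(X)) flagged[m] <- TRUE
    if (rss0 <= 0) { lod[m] <- 0; next }
    lod[m] <- if (rss1 <= max(1e-12 * rss0, 0)) Inf else
      (n / 2) * log10(rss0 / rss1)
    if (!flagged[m]) {
      e <- c(fit$coefficients[-1], 0)
      eff[m, ] <- e - mean(e)
    }
  }
  structure(list(lod = lod, effects = eff, flagged = flagged, n = n),
            class = "hk_scan")
}

#' Genome-wide LOD threshold
#'
#' Bonferroni-style threshold `-log10(alpha / n_markers)`.
#'
#' @param alpha Genome-wide type-I error level (0 < alpha <= 1).
#' @param n_markers Number of markers scanned.
#' @return LOD threshold.
#' @export
lod_threshold <- function(alpha, n_markers) {
  stopifnot(alpha > 0, alpha <= 1, n_markers >= 1)
  -log10(alpha / n_markers)
}

#' Call QTL peaks with 2-LOD separation and 1-LOD confidence intervals
#'
#' Within each chromosome, local maxima above the threshold are distinct
#' QTLs only when the LOD profile dips by at least `drop_sep` (default 2)
#' below the lower of two adjacent maxima; otherwise they are merged
#' (higher peak kept, leftmost on ties). Each peak's confidence interval is
#' the contiguous marker region where LOD >= peak - `drop_ci` (default 1);
#' endpoints are marker positions, no interpolation.
#'
#' @param scan An `hk_scan` result (or a list with `lod` and optional
#'   `effects`).
#' @param map Genetic map data frame aligned with the scan markers.
#' @param threshold LOD threshold.
#' @param drop_sep LOD fall required to separate two peaks.
#' @param drop_ci LOD drop defining the confidence interval.
#' @return Data frame of peaks: `marker`, `chrom`, `cM`, `bp`, `lod`,
#'   `ci_lo_cM`, `ci_hi_cM`, `ci_lo_bp`, `ci_hi_bp` and effect columns
#'   `F1`..`F8`.
#' @export
find_peaks <- function(scan, map, threshold, drop_sep = 2, drop_ci = 1) {
  lod <- scan$lod
  stopifnot(length(lod) == nrow(map))
  out <- list()
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    l <- lod[idx]
    lf <- ifelse(is.infinite(l), 1e4, l)   # order-preserving for rule checks
    cand <- integer(0)
    for (i in seq_along(l)) {
      left <- if (i == 1L) -Inf else lf[i - 1L]
      right <- if (i == length(l)) -Inf else lf[i + 1L]
      ## leftmost element of an equal-height plateau is the candidate
      if (lf[i] > threshold && lf[i] > left && lf[i] >= right)
        cand <- c(cand, i)
    }
    ## merge maxima not separated by a >= drop_sep dip
    while (length(cand) > 1L) {
      merged <- FALSE
      for (k in seq_len(length(cand) - 1L)) {
        a <- cand[k]; b <- cand[k + 1L]
        dip <- min(lf[a:b])
        if (min(lf[a], lf[b]) - dip < drop_sep) {
          keep <- if (lf[a] >= lf[b]) a else b   # ties keep leftmost
          cand <- cand[-(if (keep == a) k + 1L else k)]
          merged <- TRUE
          break
        }
      }
      if (!merged) break
    }
    for (pk in cand) {
      lo <- pk
      while (lo > 1L && lf[lo - 1L] >= lf[pk] - drop_ci) lo <- lo - 1L
      hi <- pk
      while (hi < length(l) && lf[hi + 1L] >= lf[pk] - drop_ci) hi <- hi + 1L
      g <- idx[pk]
      effs <- if (!is.null(scan$effects)) scan$effects[g, ] else rep(NA_real_, 8)
      out[[length(out) + 1L]] <- data.frame(
        marker = map$marker[g], chrom = ch, cM = map$cM[g], bp = map$bp[g],
        lod = unname(l[pk]),
        ci_lo_cM = map$cM[idx[lo]], ci_hi_cM = map$cM[idx[hi]],
        ci_lo_bp = map$bp[idx[lo]], ci_hi_bp = map$bp[idx[hi]],
        t(stats::setNames(as.numeric(effs), founder_labels())),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(marker = character(0), chrom = character(0),
                      cM = numeric(0), bp = numeric(0), lod = numeric(0),
                      ci_lo_cM = numeric(0), ci_hi_cM = numeric(0),
                      ci_lo_bp = numeric(0), ci_hi_bp = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Scan all phenotypes of a plasticity table
#'
#' Runs one Haley-Knott scan per phenotype in {genotypic mean, slope,
#' VAR (transformed via [transform_for_scan()]), SCv} and calls peaks at
#' the Bonferroni-style genome-wide threshold.
#'
#' @param tensor `founder_prob` array.
#' @param plasticity Plasticity table from [plasticity_table()].
#' @param map Genetic map aligned with the tensor markers.
#' @param alpha Genome-wide level (default 0.05).
#' @param trait Trait name (for the VAR transform and labels).
#' @param min_lines Minimum non-missing lines per phenotype (default 30).
#' @return Named list of scan results, each with `lod`, `effects`,
#'   `threshold` and `peaks`.
#' @export
scan_all_phenotypes <- function(tensor, plasticity, map, alpha = 0.05,
                                trait = "trait", min_lines = 30L) {
  phen <- list(
    mean = stats::setNames(plasticity$genotypic_mean, plasticity$line),
    slope = stats::setNames(plasticity$slope, plasticity$line),
    var = stats::setNames(
      transform_for_scan(ifelse(is.na(plasticity$var_nl), NA,
                                plasticity$var_nl), trait),
      plasticity$line),
    scv = stats::setNames(plasticity$scv, plasticity$line))
  thr <- lod_threshold(alpha, dim(tensor)[2])
  out <- list()
  for (nmp in names(phen)) {
    if (sum(!is.na(phen[[nmp]])) < min_lines) {
      warning("phenotype ", nmp, " has < ", min_lines,
              " non-missing lines; skipped")
      next
    }
    sc <- hk_scan(tensor, phen[[nmp]])
    sc$threshold <- thr
    sc$phenotype <- nmp
    sc$trait <- trait
    sc$peaks <- find_peaks(sc, map, thr)
    out[[nmp]] <- sc
  }
  out
}

#' Serialize a scan's LOD profile with capped infinities
#'
#' @param scan An `hk_scan` result.
#' @param map Genetic map.
#' @param cap Value replacing infinite LOD in output (default 1e4).
#' @return Data frame `marker`, `chrom`, `cM`, `bp`, `lod`, `infinite`.
#' @export
scan_to_table <- function(scan, map, cap = 1e4) {
  data.frame(marker = map$marker, chrom = map$chrom, cM = map$cM,
             bp = map$bp,
             lod = ifelse(is.infinite(scan$lod), cap, scan$lod),
             infinite = is.infinite(scan$lod),
             stringsAsFactors = FALSE)
}
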