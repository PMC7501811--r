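## QTL-by-environment interaction (QEI) scans.
##
## Model, on line x environment cell means: y_ij = mu + E_j +
## sum_p alpha_kp x_ikp + sum_p beta_kpj x_ikp + G_i + e_ij with random
## genotype G_i ~ N(0, s2_G) and per-environment residuals
## e_ij ~ N(0, s2_Rj). The variance components are estimated once under
## the no-marker null and held fixed while scanning (two-stage), so every
## per-marker fit is generalised least squares. The marker is parametrised
## by its full per-environment founder effects (the "global" form); the
## main effect (average over environments) and the interaction (deviations
## across environments) are Wald-F tested through contrasts of that block,
## with sum-to-zero environment contrasts. Because each line contributes J
## cells with the same J x J covariance V, all normal-equation blocks are
## Kronecker products of V^-1 with small founder cross-products, which is
## what makes 200-permutation genome-wide thresholds affordable.

#' Null variance components for the QEI model
#'
#' REML fit of cell means on fixed environment effects with a random
#' genotype intercept and heterogeneous per-environment residual variances.
#'
#' @param cellmeans Complete lines x environments matrix (lines with any
#'   missing cell are dropped with a warning).
#' @return List with `sigma2_G`, `resid_var`, the per-line covariance `V`
#'   and its inverse `U`, and the completed cell-means matrix `Y`.
#' @export
qei_null_varcomp <- function(cellmeans) {
  keep <- rowSums(is.na(cellmeans)) == 0L
  if (!all(keep)) {
    warning(sum(!keep), " lines with incomplete cells dropped from QEI")
    cellmeans <- cellmeans[keep, , drop = FALSE]
  }
  n <- nrow(cellmeans); J <- ncol(cellmeans)
  long <- data.frame(y = as.vector(cellmeans),
                     line = rep(rownames(cellmeans), J),
                     env = factor(rep(colnames(cellmeans), each = n)))
  fit <- reml_fit(long$y, stats::model.matrix(~ env, long),
                  block = long$line, random = list(g = long$line),
                  resid_group = long$env)
  s2g <- unname(fit$varcomp["g"])
  s2e <- fit$resid_var[colnames(cellmeans)]
  V <- matrix(s2g, J, J) + diag(s2e, J)
  list(sigma2_G = s2g, resid_var = s2e, V = V, U = solve(V),
       Y = cellmeans)
}

## marker design pieces: founder probabilities with founder 8 as reference
marker_Q <- function(tensor, marker, lines) {
  P <- tensor[lines, marker, , drop = TRUE]
  if (is.null(dim(P))) P <- matrix(P, nrow = length(lines), ncol = 8)
  P[, 1:7, drop = FALSE]
}

## Assemble and factor the GLS normal equations for env + marker blocks
## (the tested marker last). Returns NULL if singular.
qei_system <- function(U, n, Qs) {
  J <- nrow(U)
  nb <- length(Qs)
  dim_b <- 7L * J
  d <- J + nb * dim_b
  A <- matrix(0, d, d)
  A[1:J, 1:J] <- n * U
  for (a in seq_len(nb)) {
    ia <- J + (a - 1L) * dim_b + seq_len(dim_b)
    sa <- colSums(Qs[[a]])
    A[1:J, ia] <- kronecker(U, t(sa))
    A[ia, 1:J] <- t(A[1:J, ia])
    for (b in a:nb) {
      ib <- J + (b - 1L) * dim_b + seq_len(dim_b)
      A[ia, ib] <- kronecker(U, crossprod(Qs[[a]], Qs[[b]]))
      if (b > a) A[ib, ia] <- t(A[ia, ib])
    }
  }
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  list(chol = ch, d = d, J = J, nb = nb, dim_b = dim_b)
}

## Wald machinery for the tested marker (last block)
qei_tests_setup <- function(sys) {
  J <- sys$J
  ii <- sys$d - sys$dim_b + seq_len(sys$dim_b)
  Ainv <- chol2inv(sys$chol)
  Sigma <- Ainv[ii, ii, drop = FALSE]
  C <- stats::contr.helmert(J)                    # J x (J-1), sum-zero
  L_main <- kronecker(t(rep(1 / J, J)), diag(7))
  L_int <- kronecker(t(C), diag(7))
  mid <- function(L) {
    M <- L %*% Sigma %*% t(L)
    tryCatch(solve(M), error = function(e) NULL)
  }
  list(ii = ii, L_main = L_main, L_int = L_int,
       M_main = mid(L_main), M_int = mid(L_int),
       M_global = tryCatch(solve(Sigma), error = function(e) NULL))
}

qei_wald <- function(beta_blk, setup, ddf) {
  one <- function(L, M, q) {
    if (is.null(M)) return(c(NA_real_, NA_real_))
    v <- if (is.null(L)) beta_blk else as.numeric(L %*% beta_blk)
    Fstat <- as.numeric(t(v) %*% M %*% v) / q
    c(Fstat, stats::pf(Fstat, q, ddf, lower.tail = FALSE))
  }
  q_main <- nrow(setup$L_main)
  q_int <- nrow(setup$L_int)
  q_glob <- length(beta_blk)
  m <- one(setup$L_main, setup$M_main, q_main)
  i <- one(setup$L_int, setup$M_int, q_int)
  g <- one(NULL, setup$M_global, q_glob)
  c(F_main = m[1], p_main = m[2], F_int = i[1], p_int = i[2],
    F_global = g[1], p_global = g[2])
}

#' Scan all markers for main, interaction and global marker effects
#'
#' For every marker (optionally conditioning on cofactor markers), performs
#' the GLS fit of the multi-environment marker model with variance
#' components fixed at their null estimates, and Wald-F tests of the main
#' (7 df), interaction (7 x (nE - 1) df) and global (7 x nE df) marker
#' effects.
#'
#' @param tensor `founder_prob` array.
#' @param vc Null variance components from [qei_null_varcomp()].
#' @param cofactors Character vector of cofactor marker ids.
#' @param markers Markers to test (default: all except cofactors).
#' @return Data frame with one row per tested marker and columns `marker`,
#'   `F_main`, `p_main`, `F_int`, `p_int`, `F_global`, `p_global`.
#' @export
qei_scan <- function(tensor, vc, cofactors = character(0), markers = NULL) {
  Y <- vc$Y; U <- vc$U
  lines <- rownames(Y)
  n <- nrow(Y); J <- ncol(Y)
  all_m <- dimnames(tensor)[[2]]
  if (is.null(markers)) markers <- setdiff(all_m, cofactors)
  Qc <- lapply(cofactors, function(m) marker_Q(tensor, m, lines))
  Tm <- Y %*% t(U)                      # row i = (U y_i)'
  bE <- as.numeric(U %*% colSums(Y))
  b_cof <- lapply(Qc, function(Qa) as.numeric(crossprod(Qa, Tm)))
  res <- matrix(NA_real_, length(markers), 6,
                dimnames = list(markers,
                                c("F_main", "p_main", "F_int", "p_int",
                                  "F_global", "p_global")))
  for (m in markers) {
    Qm <- marker_Q(tensor, m, lines)
    sys <- qei_system(U, n, c(Qc, list(Qm)))
    if (is.null(sys)) next                       # collinear marker: skipped
    ddf <- n * J - sys$d
    if (ddf <= 0) next
    b <- c(bE, unlist(b_cof), as.numeric(crossprod(Qm, Tm)))
    beta <- backsolve(sys$chol, backsolve(sys$chol, b, transpose = TRUE))
    setup <- qei_tests_setup(sys)
    res[m, ] <- qei_wald(beta[sys$d - sys$dim_b + seq_len(sys$dim_b)],
                         setup, ddf)
  }
  out <- data.frame(marker = markers, res, row.names = NULL,
                    stringsAsFactors = FALSE)
  out
}

#' Fit the multi-environment model at one marker
#'
#' Single-marker version of [qei_scan()] that also returns the estimated
#' per-environment founder effects (sum-to-zero within each environment).
#'
#' @param tensor `founder_prob` array.
#' @param marker Marker id.
#' @param cellmeans Cell-means matrix (or a `vc` from
#'   [qei_null_varcomp()] via `vc`).
#' @param vc Optional precomputed null variance components.
#' @param cofactors Cofactor marker ids.
#' @return List: the test row (`F_main`, `p_main`, ...) plus `effects`
#'   (8 x nE matrix) and `ddf`.
#' @export
fit_marker_env_model <- function(tensor, marker, cellmeans = NULL,
                                 vc = NULL, cofactors = character(0)) {
  if (is.null(vc)) vc <- qei_null_varcomp(cellmeans)
  Y <- vc$Y; U <- vc$U
  lines <- rownames(Y)
  n <- nrow(Y); J <- ncol(Y)
  Qc <- lapply(cofactors, function(m) marker_Q(tensor, m, lines))
  Qm <- marker_Q(tensor, marker, lines)
  sys <- qei_system(U, n, c(Qc, list(Qm)))
  if (is.null(sys)) stop("marker ", marker, " collinear with cofactors")
  Tm <- Y %*% t(U)
  b <- c(as.numeric(U %*% colSums(Y)),
         unlist(lapply(Qc, function(Qa) as.numeric(crossprod(Qa, Tm)))),
         as.numeric(crossprod(Qm, Tm)))
  beta <- backsolve(sys$chol, backsolve(sys$chol, b, transpose = TRUE))
  blk <- beta[sys$d - sys$dim_b + seq_len(sys$dim_b)]
  ddf <- n * J - sys$d
  tests <- qei_wald(blk, qei_tests_setup(sys), ddf)
  B <- rbind(matrix(blk, 7, J), 0)               # founder x env, F8 ref
  B <- sweep(B, 2L, colMeans(B))
  dimnames(B) <- list(founder_labels(), colnames(Y))
  c(as.list(tests), list(marker = marker, effects = B, ddf = ddf))
}

#' Permutation thresholds for the QEI scan
#'
#' Shuffles line identity between the genotype tensor and the phenotype
#' cell means (preserving each line's environment profile and all
#' phenotypic structure), rescans, and records the per-permutation maximum
#' over markers of -log10(p) for the main, interaction and global tests.
#' Thresholds are the empirical `1 - alpha` quantiles (type 7).
#'
#' @param tensor `founder_prob` array.
#' @param vc Null variance components from [qei_null_varcomp()].
#' @param n_perm Number of permutations (>= 100 recommended; the study
#'   scale is 1000).
#' @param alpha Genome-wide level.
#' @param seed Integer seed (thresholds are deterministic given it).
#' @return List with `main`, `interaction`, `global` thresholds on the
#'   -log10(p) scale and the three max-statistic distributions.
#' @export
permutation_threshold <- function(tensor, vc, n_perm = 1000L, alpha = 0.05,
                                  seed = 1L) {
  if (n_perm < 1 / alpha)
    warning("n_perm < 1/alpha: threshold quantile is poorly estimated")
  Y <- vc$Y; U <- vc$U
  lines <- rownames(Y)
  n <- nrow(Y); J <- ncol(Y)
  markers <- dimnames(tensor)[[2]]
  Tm <- Y %*% t(U)
  bE <- as.numeric(U %*% colSums(Y))
  ## cache per-marker factorisations (permutation-invariant)
  cache <- vector("list", length(markers))
  for (k in seq_along(markers)) {
    Qm <- marker_Q(tensor, markers[k], lines)
    sys <- qei_system(U, n, list(Qm))
    if (is.null(sys)) next
    cache[[k]] <- list(Q = Qm, sys = sys, setup = qei_tests_setup(sys),
                       ddf = n * J - sys$d)
  }
  set.seed(seed)
  mx <- matrix(NA_real_, n_perm, 3,
               dimnames = list(NULL, c("main", "interaction", "global")))
  for (r in seq_len(n_perm)) {
    Tp <- Tm[sample.int(n), , drop = FALSE]
    best <- c(0, 0, 0)
    for (k in seq_along(markers)) {
      ca <- cache[[k]]
      if (is.null(ca) || ca$ddf <= 0) next
      b <- c(bE, as.numeric(crossprod(ca$Q, Tp)))
      beta <- backsolve(ca$sys$chol,
                        backsolve(ca$sys$chol, b, transpose = TRUE))
      w <- qei_wald(beta[ca$sys$d - ca$sys$dim_b + seq_len(ca$sys$dim_b)],
                    ca$setup, ca$ddf)
      lp <- -log10(pmax(w[c("p_main", "p_int", "p_global")], 1e-300))
      best <- pmax(best, unname(lp), na.rm = TRUE)
    }
    mx[r, ] <- best
  }
  q <- apply(mx, 2, stats::quantile, probs = 1 - alpha, type = 7,
             na.rm = TRUE)
  list(main = unname(q["main"]), interaction = unname(q["interaction"]),
       global = unname(q["global"]), max_stats = mx, alpha = alpha,
       n_perm = n_perm)
}

#' Forward inclusion of markers with significant main or interaction effects
#'
#' Iteratively scans all markers (conditioning on the cofactors selected so
#' far), adds the most significant marker whose main or interaction
#' component exceeds its permutation threshold, and excludes markers within
#' `window_cM` of a selected cofactor from entry. Stops when no marker
#' qualifies.
#'
#' @param tensor `founder_prob` array.
#' @param vc Null variance components.
#' @param thresholds Thresholds from [permutation_threshold()].
#' @param map Genetic map aligned with the tensor markers.
#' @param window_cM Exclusion window around cofactors (default 10).
#' @param max_cofactors Safety cap on the cofactor count (default 12).
#' @return Character vector of selected cofactor markers.
#' @export
forward_selection <- function(tensor, vc, thresholds, map, window_cM = 10,
                              max_cofactors = 12L) {
  cof <- character(0)
  repeat {
    excl <- excluded_markers(map, cof, window_cM)
    cand <- setdiff(dimnames(tensor)[[2]], c(cof, excl))
    if (!length(cand) || length(cof) >= max_cofactors) break
    sc <- qei_scan(tensor, vc, cofactors = cof, markers = cand)
    lp_main <- -log10(pmax(sc$p_main, 1e-300))
    lp_int <- -log10(pmax(sc$p_int, 1e-300))
    qual <- (lp_main > thresholds$main) | (lp_int > thresholds$interaction)
    qual[is.na(qual)] <- FALSE
    if (!any(qual)) break
    score <- pmax(lp_main, lp_int)
    score[!qual] <- -Inf
    cof <- c(cof, sc$marker[which.max(score)])
  }
  cof
}

excluded_markers <- function(map, cofactors, window_cM) {
  if (!length(cofactors)) return(character(0))
  ex <- character(0)
  for (m in cofactors) {
    i <- match(m, map$marker)
    near <- map$marker[map$chrom == map$chrom[i] &
                         abs(map$cM - map$cM[i]) <= window_cM]
    ex <- union(ex, near)
  }
  setdiff(ex, cofactors)
}

#' Backward joint elimination of the forward cofactor set
#'
#' Fits all selected markers jointly and removes the weakest marker (the
#' one whose best of main/interaction -log10(p), relative to its
#' threshold, is smallest and below it) until every remaining marker keeps
#' a significant main or interaction component. Records are flagged
#' `significant` only when the interaction component passes its threshold.
#'
#' @param tensor `founder_prob` array.
#' @param vc Null variance components.
#' @param cofactors Markers from [forward_selection()].
#' @param thresholds Thresholds from [permutation_threshold()].
#' @return Data frame of `QEIRecord` rows (marker, stage, statistics,
#'   p-values, `significant` interaction flag), with per-environment
#'   effects in the `effects` attribute (list of 8 x nE matrices).
#' @export
backward_elimination <- function(tensor, vc, cofactors, thresholds) {
  empty <- data.frame(marker = character(0), stage = character(0),
                      F_main = numeric(0), p_main = numeric(0),
                      F_int = numeric(0), p_int = numeric(0),
                      F_global = numeric(0), p_global = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE)
  cur <- cofactors
  while (length(cur)) {
    rows <- lapply(seq_along(cur), function(k)
      fit_marker_env_model(tensor, cur[k], vc = vc, cofactors = cur[-k]))
    lp_main <- vapply(rows, function(r) -log10(max(r$p_main, 1e-300)), 0)
    lp_int <- vapply(rows, function(r) -log10(max(r$p_int, 1e-300)), 0)
    rel <- pmax(lp_main / thresholds$main, lp_int / thresholds$interaction)
    rel[is.na(rel)] <- 0
    if (all(rel >= 1)) {
      out <- do.call(rbind, lapply(rows, function(r)
        data.frame(marker = r$marker, stage = "backward",
                   F_main = r$F_main, p_main = r$p_main,
                   F_int = r$F_int, p_int = r$p_int,
                   F_global = r$F_global, p_global = r$p_global,
                   significant = -log10(max(r$p_int, 1e-300)) >
                     thresholds$interaction,
                   stringsAsFactors = FALSE)))
      attr(out, "effects") <- stats::setNames(
        lapply(rows, function(r) r$effects), cur)
      return(out)
    }
    cur <- cur[-which.min(rel)]
  }
  empty
}

#' Global-effect pass for markers missed by the separate tests
#'
#' Scans with the global parametrisation (per-environment founder effects
#' tested jointly, 7 x nE df), conditioning on the markers already
#' selected, and adds markers whose global test exceeds its permutation
#' threshold, forward-style with the same exclusion window. Added records
#' are stage-tagged `global`; already selected markers are never
#' duplicated.
#'
#' @param tensor `founder_prob` array.
#' @param vc Null variance components.
#' @param selected Markers already reported by the first procedure.
#' @param thresholds Thresholds from [permutation_threshold()].
#' @param map Genetic map.
#' @param window_cM Exclusion window (default 10).
#' @param max_add Cap on added markers (default 12).
#' @return Data frame of `QEIRecord` rows, stage `global`.
#' @export
global_effect_pass <- function(tensor, vc, selected, thresholds, map,
                               window_cM = 10, max_add = 12L) {
  added <- character(0)
  repeat {
    base <- c(selected, added)
    excl <- excluded_markers(map, base, window_cM)
    cand <- setdiff(dimnames(tensor)[[2]], c(base, excl))
    if (!length(cand) || length(added) >= max_add) break
    sc <- qei_scan(tensor, vc, cofactors = base, markers = cand)
    lp <- -log10(pmax(sc$p_global, 1e-300))
    lp[is.na(lp)] <- 0
    if (max(lp) <= thresholds$global) break
    added <- c(added, sc$marker[which.max(lp)])
  }
  if (!length(added))
    return(data.frame(marker = character(0), stage = character(0),
                      F_main = numeric(0), p_main = numeric(0),
                      F_int = numeric(0), p_int = numeric(0),
                      F_global = numeric(0), p_global = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE))
  rows <- lapply(added, function(m)
    fit_marker_env_model(tensor, m, vc = vc,
                         cofactors = setdiff(c(selected, added), m)))
  out <- do.call(rbind, lapply(rows, function(r)
    data.frame(marker = r$marker, stage = "global",
               F_main = r$F_main, p_main = r$p_main,
               F_int = r$F_int, p_int = r$p_int,
               F_global = r$F_global, p_global = r$p_global,
               significant = -log10(max(r$p_int, 1e-300)) >
                 thresholds$interaction,
               stringsAsFactors = FALSE)))
  attr(out, "effects") <- stats::setNames(lapply(rows, function(r) r$effects),
                                          added)
  out
}

#' Run the complete two-step QEI procedure for one trait
#'
#' Estimates the null variance components, computes permutation thresholds,
#' runs forward selection on the separate main/interaction tests, backward
#' joint elimination, and the global-effect pass.
#'
#' @param tensor `founder_prob` array.
#' @param cellmeans Cell-means matrix for the trait.
#' @param map Genetic map aligned with the tensor.
#' @param n_perm Permutations for the thresholds (study scale 1000).
#' @param alpha Genome-wide level.
#' @param seed Seed for the permutations.
#' @param window_cM Cofactor exclusion window.
#' @return List: `records` (QEI records from both stages), `cofactors`,
#'   `thresholds`, `vc`.
#' @export
run_qei <- function(tensor, cellmeans, map, n_perm = 1000L, alpha = 0.05,
                    seed = 1L, window_cM = 10) {
  vc <- qei_null_varcomp(cellmeans)
  thr <- permutation_threshold(tensor, vc, n_perm, alpha, seed)
  cof <- forward_selection(tensor, vc, thr, map, window_cM)
  back <- backward_elimination(tensor, vc, cof, thr)
  glob <- global_effect_pass(tensor, vc, back$marker, thr, map, window_cM)
  records <- rbind(back, glob)
  effects <- c(attr(back, "effects"), attr(glob, "effects"))
  attr(records, "effects") <- effects
  list(records = records, cofactors = cof, thresholds = thr, vc = vc)
}
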