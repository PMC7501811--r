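## Block-diagonal REML engine.
##
## Handles Gaussian mixed models whose random-effect factors are nested
## within a blocking factor (here: MAGIC line), with one variance per random
## term and heterogeneous residual variances by group (here: environment).
## The marginal covariance is then block-diagonal by line, so the REML
## log-likelihood is assembled from small dense per-line blocks:
##   V_i = sum_k s2_k Z_ik Z_ik' + diag(s2_resid[group]),
##   llR = -0.5 * (sum_i log|V_i| + log|X'V^-1 X| + y'Py).
## Observations whose random-factor value is NA (control lines) carry no
## random effect. Optimisation is L-BFGS-B on log-variances, which keeps
## every variance non-negative (the boundary is approached, never crossed).

reml_loglik <- function(par, dat) {
  nr <- dat$n_random
  s2r <- exp(par[seq_len(nr)])
  s2e <- exp(par[nr + seq_len(dat$n_groups)])
  p <- ncol(dat$X)
  A <- matrix(0, p, p); b <- numeric(p); q <- 0; ld <- 0
  for (sg in dat$sig_groups) {
    m <- sg$m; nb <- sg$nb
    V <- diag(s2e[sg$group], m)
    for (k in seq_len(nr)) {
      zk <- sg$rand[[k]]          # integer codes, 0 = no effect
      if (is.null(zk)) next
      for (u in unique(zk[zk > 0L])) {
        sel <- which(zk == u)
        V[sel, sel] <- V[sel, sel] + s2r[k]
      }
    }
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(-1e10)
    ## all member blocks share V: solve them in one triangular sweep
    Xarr <- matrix(array(dat$X[sg$rows, , drop = FALSE], c(m, nb, p)),
                   m, nb * p)
    Wv <- matrix(backsolve(ch, Xarr, transpose = TRUE), m * nb, p)
    wy <- backsolve(ch, matrix(dat$y[sg$rows], m, nb), transpose = TRUE)
    A <- A + crossprod(Wv)
    b <- b + as.numeric(crossprod(Wv, as.vector(wy)))
    q <- q + sum(wy^2)
    ld <- ld + nb * 2 * sum(log(diag(ch)))
  }
  chA <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(chA)) return(-1e10)
  beta <- backsolve(chA, backsolve(chA, b, transpose = TRUE))
  yPy <- q - sum(b * beta)
  ll <- -0.5 * (ld + 2 * sum(log(diag(chA))) + yPy)
  attr(ll, "beta") <- beta
  ll
}

## Precompute per-block structures, grouped by structural signature so
## balanced designs share one Cholesky per likelihood evaluation.
## random: named list of factors (NA = no effect); resid_group, block:
## factors.
reml_data <- function(y, X, block, random, resid_group) {
  stopifnot(length(y) == nrow(X), length(block) == length(y))
  block <- factor(block)
  gcode <- as.integer(resid_group <- factor(resid_group))
  blocks <- lapply(levels(block), function(lv) {
    idx <- which(block == lv)
    idx <- idx[order(gcode[idx])]        # canonical within-block order
    rand <- lapply(random, function(f) {
      codes <- as.integer(factor(as.character(f[idx]),
                                 levels = unique(as.character(f[idx]))))
      codes[is.na(codes)] <- 0L
      codes
    })
    key <- paste(paste(gcode[idx], collapse = ","),
                 paste(vapply(rand, paste, "", collapse = ","),
                       collapse = "|"), sep = "||")
    list(idx = idx, group = gcode[idx], rand = rand, key = key)
  })
  keys <- vapply(blocks, function(b) b$key, "")
  sig_groups <- lapply(split(seq_along(blocks), keys), function(members) {
    first <- blocks[[members[1]]]
    list(m = length(first$idx), nb = length(members),
         group = first$group, rand = first$rand,
         rows = unlist(lapply(blocks[members], function(b) b$idx)))
  })
  list(y = y, X = X, sig_groups = sig_groups, n_random = length(random),
       n_groups = nlevels(resid_group), group_levels = levels(resid_group),
       random_names = names(random))
}

#' Fit a nested-random-effects model with heterogeneous residuals by REML
#'
#' Fits `y = X beta + (random intercepts) + e` where every random factor is
#' nested within `block` and the residual variance differs by
#' `resid_group`. Returns REML variance components, fixed effects and the
#' REML log-likelihood. Used for the multi-environment variance
#' decomposition and for the QTL-by-environment null model.
#'
#' @param y Numeric response.
#' @param X Fixed-effects design matrix (full column rank enforced
#'   internally by dropping aliased columns).
#' @param block Blocking factor (independent units, e.g. line).
#' @param random Named list of grouping factors for random intercepts; NA
#'   entries contribute no random effect.
#' @param resid_group Factor defining residual variance groups.
#' @param start Optional named start values for the variances.
#' @param n_restarts Restarts from perturbed starts on failure.
#' @return List with `varcomp` (random-term variances), `resid_var`
#'   (per-group residual variances), `beta`, `loglik`, `convergence`.
#' @export
reml_fit <- function(y, X, block, random, resid_group, start = NULL,
                     n_restarts = 3L) {
  keep <- !is.na(y)
  X <- drop_aliased(X[keep, , drop = FALSE])
  dat <- reml_data(y[keep], X, droplevels(factor(block)[keep]),
                   lapply(random, function(f) f[keep]),
                   droplevels(factor(resid_group)[keep]))
  vy <- stats::var(dat$y)
  if (!is.finite(vy) || vy <= 0) vy <- 1
  npar <- dat$n_random + dat$n_groups
  p0 <- log(rep(vy / (dat$n_random + 1), npar))
  if (!is.null(start)) p0 <- log(pmax(start, 1e-8))
  obj <- function(par) -as.numeric(reml_loglik(par, dat))
  best <- NULL
  for (r in 0:n_restarts) {
    par_init <- if (r == 0) p0 else p0 + stats::rnorm(npar, 0, 0.5)
    opt <- tryCatch(
      stats::optim(par_init, obj, method = "L-BFGS-B",
                   lower = log(vy) - 25, upper = log(vy) + 12,
                   control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(opt) && opt$value < 1e9 &&
        (is.null(best) || opt$value < best$value)) best <- opt
    if (!is.null(best) && r == 0) break
  }
  if (is.null(best))
    stop("REML optimisation failed after ", n_restarts, " restarts")
  ll <- reml_loglik(best$par, dat)
  s2 <- exp(best$par)
  varcomp <- stats::setNames(s2[seq_len(dat$n_random)], dat$random_names)
  ## variances within a factor 1e-8 of the boundary are reported as 0
  floor0 <- function(v) ifelse(v < exp(log(vy) - 20), 0, v)
  list(varcomp = floor0(varcomp),
       resid_var = stats::setNames(floor0(s2[dat$n_random + seq_len(dat$n_groups)]),
                                   dat$group_levels),
       beta = stats::setNames(attr(ll, "beta"), colnames(X)),
       loglik = as.numeric(ll),
       convergence = best$convergence)
}

## Drop linearly dependent columns (keeps the pivoted leading set).
drop_aliased <- function(X) {
  qr_ <- qr(X)
  if (qr_$rank == ncol(X)) return(X)
  X[, qr_$pivot[seq_len(qr_$rank)], drop = FALSE]
}
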