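#' Cluster environments by their climatic covariates
#'
#' Z-scores the seven covariates across environments (constant covariates
#' are dropped with a warning), computes Euclidean distances and Ward
#' linkage (`ward.D2`), and cuts the tree at `k` clusters.
#'
#' @param envs Environment covariate table (column `env` plus covariates).
#' @param k Number of clusters (default 4).
#' @return Named integer vector of cluster labels; the `hclust` tree is
#'   attached as attribute `tree`.
#' @export
cluster_environments <- function(envs, k = 4L) {
  stopifnot(nrow(envs) >= k)
  covs <- intersect(covariate_names(), names(envs))
  X <- as.matrix(envs[covs])
  keep <- apply(X, 2, function(v) stats::sd(v) > 0)
  if (!all(keep)) {
    warning("constant covariates dropped: ",
            paste(covs[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  Z <- scale(X)
  rownames(Z) <- envs$env
  tree <- stats::hclust(stats::dist(Z), method = "ward.D2")
  cl <- stats::cutree(tree, k = k)
  attr(cl, "tree") <- tree
  cl
}

#' Merge scan and QEI peaks into a tagged QTL catalog
#'
#' @param peaks_by_category Named list of peak data frames (as returned by
#'   [find_peaks()]); names are category tags such as `mean`, `slope`,
#'   `var`, `scv`, `qei`. Each needs `chrom`, `ci_lo_bp`, `ci_hi_bp` (QEI
#'   entries may carry a point position expanded to a 1-bp interval) and
#'   optionally `trait` and the effect columns.
#' @param trait Trait the peaks belong to (recycled into the catalog when
#'   absent from the inputs).
#' @return Data frame catalog with one row per peak and a `category`
#'   column.
#' @export
qtl_catalog <- function(peaks_by_category, trait = "trait") {
  rows <- list()
  for (cat in names(peaks_by_category)) {
    p <- peaks_by_category[[cat]]
    if (is.null(p) || nrow(p) == 0L) next
    p$category <- cat
    if (is.null(p$trait)) p$trait <- trait
    rows[[length(rows) + 1L]] <-
      p[, intersect(c("trait", "category", "marker", "chrom", "bp", "lod",
                      "ci_lo_bp", "ci_hi_bp", founder_labels()), names(p)),
        drop = FALSE]
  }
  if (!length(rows)) return(data.frame())
  out <- do.call(rbind, lapply(rows, function(r) {
    for (col in setdiff(c("marker", "bp", "lod", founder_labels()),
                        names(r))) r[[col]] <- NA
    r
  }))
  rownames(out) <- NULL
  out
}

#' Co-localize QTLs of one trait by confidence-interval overlap
#'
#' Two peaks of the same trait co-localize when their physical confidence
#' intervals intersect on the same chromosome; co-localization is closed
#' transitively (connected components), and each resulting unique QTL is
#' labelled by the union of the category tags of its members.
#'
#' @param catalog Catalog from [qtl_catalog()] (may span several traits;
#'   components never join across traits).
#' @return List with `components` (per-peak component id), `unique_qtls`
#'   (one row per component: trait, chrom, span, categories), and `counts`
#'   (table over category combinations).
#' @export
overlap_qtls <- function(catalog) {
  if (nrow(catalog) == 0L)
    return(list(components = integer(0),
                unique_qtls = data.frame(), counts = table(character(0))))
  key <- paste(catalog$trait, catalog$chrom)
  comp <- seq_len(nrow(catalog))
  ir <- IRanges::IRanges(start = catalog$ci_lo_bp, end = catalog$ci_hi_bp)
  ov <- as.data.frame(IRanges::findOverlaps(ir, ir))
  ov <- ov[ov$queryHits < ov$subjectHits &
             key[ov$queryHits] == key[ov$subjectHits], , drop = FALSE]
  find <- function(i) { while (comp[i] != i) { comp[i] <<- comp[comp[i]]; i <- comp[i] }; i }
  for (r in seq_len(nrow(ov))) {
    a <- find(ov$queryHits[r]); b <- find(ov$subjectHits[r])
    if (a != b) comp[max(a, b)] <- min(a, b)
  }
  comp <- vapply(seq_along(comp), find, 0L)
  ids <- match(comp, sort(unique(comp)))
  uq <- do.call(rbind, lapply(sort(unique(ids)), function(u) {
    sel <- which(ids == u)
    data.frame(qtl = u, trait = catalog$trait[sel[1]],
               chrom = catalog$chrom[sel[1]],
               start_bp = min(catalog$ci_lo_bp[sel]),
               end_bp = max(catalog$ci_hi_bp[sel]),
               categories = paste(sort(unique(catalog$category[sel])),
                                  collapse = "+"),
               n_peaks = length(sel), stringsAsFactors = FALSE)
  }))
  list(components = ids, unique_qtls = uq,
       counts = table(uq$categories))
}

#' Chi-square enrichment of plasticity QTLs across chromosomes
#'
#' Tests observed QTL counts per chromosome against expectations
#' proportional to marker counts (or physical lengths).
#'
#' @param qtl_chroms Chromosome of each QTL (vector).
#' @param map Genetic map (for marker counts per chromosome).
#' @param weight `"markers"` (default) or `"length"` for bp-weighted
#'   expectations.
#' @return List with `statistic`, `df`, `p`, and a per-chromosome table of
#'   observed/expected counts and standardized residuals; NULL with a
#'   warning when there are fewer than 2 QTLs.
#' @export
chisq_chromosome_enrichment <- function(qtl_chroms, map,
                                        weight = c("markers", "length")) {
  weight <- match.arg(weight)
  chroms <- unique(map$chrom)
  if (length(qtl_chroms) < 2L) {
    warning("fewer than 2 QTLs; enrichment test skipped")
    return(NULL)
  }
  w <- if (weight == "markers") table(factor(map$chrom, levels = chroms))
  else tapply(map$bp, factor(map$chrom, levels = chroms), max)
  pr <- as.numeric(w) / sum(w)
  obs <- table(factor(qtl_chroms, levels = chroms))
  n <- sum(obs)
  expd <- n * pr
  if (any(expd < 1))
    warning("expected count < 1 on some chromosome; test unreliable")
  stat <- sum((as.numeric(obs) - expd)^2 / expd)
  df <- length(chroms) - 1L
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE),
       table = data.frame(chrom = chroms, observed = as.numeric(obs),
                          expected = expd,
                          std_residual = (as.numeric(obs) - expd) / sqrt(expd),
                          stringsAsFactors = FALSE))
}

## all permutations of 1..n (n <= 8 here: 40320 rows)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Exact Spearman concordance of two founder allelic-effect vectors
#'
#' Spearman rank correlation of two length-8 effect vectors with mid-rank
#' tie handling and an exact two-sided permutation p-value enumerated over
#' all 8! orderings.
#'
#' @param effects_a,effects_b Numeric length-8 founder effect vectors.
#' @return List with `rho` and `p` (NA with a warning for a constant
#'   vector).
#' @export
allelic_effect_concordance <- function(effects_a, effects_b) {
  stopifnot(length(effects_a) == length(effects_b))
  n <- length(effects_a)
  if (stats::sd(effects_a) == 0 || stats::sd(effects_b) == 0) {
    warning("constant effect vector; concordance undefined")
    return(list(rho = NA_real_, p = NA_real_))
  }
  ra <- rank(effects_a); rb <- rank(effects_b)
  rho_of <- function(x, y) stats::cor(x, y)
  rho <- rho_of(ra, rb)
  perms <- all_perms(n)
  null_rho <- apply(perms, 1, function(pm) rho_of(ra[pm], rb))
  p <- mean(abs(null_rho) >= abs(rho) - 1e-12)
  list(rho = rho, p = p)
}

#' Read selective-sweep intervals from a BED file
#'
#' BED is 0-based half-open; intervals are returned 1-based inclusive.
#'
#' @param path BED file (columns chrom, start, end, name).
#' @return Data frame `chrom`, `start_bp`, `end_bp`, `label`.
#' @export
read_sweeps_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start_bp = GenomicRanges::start(gr),
             end_bp = GenomicRanges::end(gr),
             label = if (!is.null(gr$name)) gr$name else
               paste0("SW", seq_along(gr)),
             stringsAsFactors = FALSE)
}

#' Intersect QTLs with selective-sweep regions
#'
#' QTLs whose confidence interval is narrower than `max_ci` (QEI entries
#' are always included) are tested for any overlap with the sweep
#' intervals.
#'
#' @param catalog QTL catalog (needs `chrom`, `ci_lo_bp`, `ci_hi_bp`,
#'   `category`).
#' @param sweeps Sweep data frame from [read_sweeps_bed()] (or with the
#'   same columns).
#' @param max_ci Maximum CI width in bp for non-QEI entries (default 2e6).
#' @return List with `table` (per selected QTL: sweep labels hit) and
#'   `fraction_inside`.
#' @export
intersect_sweeps <- function(catalog, sweeps, max_ci = 2e6) {
  width <- catalog$ci_hi_bp - catalog$ci_lo_bp + 1
  sel <- which(width < max_ci | catalog$category == "qei")
  if (!length(sel))
    return(list(table = data.frame(), fraction_inside = NA_real_))
  levs <- union(catalog$chrom[sel], sweeps$chrom)
  qgr <- GenomicRanges::GRanges(factor(catalog$chrom[sel], levs),
                                IRanges::IRanges(catalog$ci_lo_bp[sel],
                                                 catalog$ci_hi_bp[sel]))
  sgr <- GenomicRanges::GRanges(factor(sweeps$chrom, levs),
                                IRanges::IRanges(sweeps$start_bp,
                                                 sweeps$end_bp))
  ov <- GenomicRanges::findOverlaps(qgr, sgr)
  hits <- split(sweeps$label[S4Vectors::subjectHits(ov)],
                S4Vectors::queryHits(ov))
  lab <- vapply(seq_along(sel), function(i) {
    h <- hits[[as.character(i)]]
    if (is.null(h)) "" else paste(sort(unique(h)), collapse = ",")
  }, "")
  tab <- data.frame(catalog[sel, c("trait", "category", "chrom",
                                   "ci_lo_bp", "ci_hi_bp")],
                    sweeps = lab, inside = lab != "",
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  list(table = tab, fraction_inside = mean(tab$inside))
}
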