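#' Region-of-interest set
#'
#' Named voxel masks for the five right-lateralized inhibition-network
#' regions (IFG pars triangularis, caudate, putamen, thalamus, STN) plus the
#' right calcarine control region. In the synthetic voxel space the masks
#' are the generator's labeled regions; for real-space use the conventional
#' MNI centers of mass (mm) are carried along — caudate (15, 11, 8),
#' putamen (28, 4, 1), thalamus (13, -19, 7), IFG (51, 28, 8),
#' STN (9, -13, -7) — with spheres of `sphere_radius_mm`.
#'
#' @param labels a labeled grid from [synthetic_brain_labels()].
#' @param sphere_radius_mm sphere radius used when the centers define ROIs
#'   in millimeter space.
#' @return an `roi_set`: list of `masks` (named list of voxel indices),
#'   `network` (the five inhibition ROI names), `control`, `centers_mm`.
#' @export
roi_set <- function(labels = synthetic_brain_labels(),
                    sphere_radius_mm = 6) {
  regions <- attr(labels, "regions")
  masks <- lapply(seq_along(regions), function(i) which(labels == i))
  names(masks) <- regions
  if (any(lengths(masks) == 0)) stop("empty ROI mask", call. = FALSE)
  centers <- rbind(rIFG = c(51, 28, 8), rCaudate = c(15, 11, 8),
                   rPutamen = c(28, 4, 1), rThalamus = c(13, -19, 7),
                   rSTN = c(9, -13, -7), rCalcarine = c(14, -73, 9))
  structure(list(masks = masks, network = .inhibition_network,
                 control = "rCalcarine", centers_mm = centers,
                 sphere_radius_mm = sphere_radius_mm),
            class = "roi_set")
}

#' Extract per-ROI and network means from a voxel map
#'
#' ROI value = arithmetic mean of the map over the mask's voxels; the
#' network value pools the voxels of the five inhibition ROIs before
#' averaging.
#'
#' @param map a `dor_map`, `ssr_map`, or numeric vector over voxels.
#' @param rois an [roi_set()].
#' @return named numeric vector: one mean per ROI plus `network`.
#' @export
extract_roi_values <- function(map, rois = roi_set()) {
  stopifnot(inherits(rois, "roi_set"))
  v <- if (inherits(map, "dor_map")) map$dor
       else if (inherits(map, "ssr_map")) map$ssr
       else as.numeric(map)
  if (max(unlist(rois$masks)) > length(v))
    stop("map grid does not match the ROI masks", call. = FALSE)
  out <- vapply(rois$masks, function(m) mean(v[m]), numeric(1))
  net_vox <- unlist(rois$masks[rois$network], use.names = FALSE)
  c(out, network = mean(v[net_vox]))
}

#' One-way ANOVA with eta squared
#'
#' Standard one-way fixed-effects ANOVA across groups, reporting F, degrees
#' of freedom, p and the effect size eta^2 = SS_between / SS_total.
#'
#' @param values numeric outcome.
#' @param group group labels (coerced to factor).
#' @return a `group_test` list: `F`, `df1`, `df2`, `p`, `eta_squared`.
#' @examples
#' one_way_anova(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
#' @export
one_way_anova <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(group) < 1) || length(values) - nlevels(group) < 1)
    stop("too few observations for ANOVA", call. = FALSE)
  fit <- aov(values ~ group)
  tab <- anova(fit)
  ssb <- tab$`Sum Sq`[1]; ssw <- tab$`Sum Sq`[2]
  structure(list(F = tab$`F value`[1], df1 = tab$Df[1], df2 = tab$Df[2],
                 p = tab$`Pr(>F)`[1], eta_squared = ssb / (ssb + ssw)),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("F(%d, %d) = %.3f, p = %.4g, eta^2 = %.3f\n",
              x$df1, x$df2, x$F, x$p, x$eta_squared))
  invisible(x)
}

#' Pearson or partial correlation
#'
#' Pearson's r with a two-sided t test. With covariates, the partial
#' correlation is computed as the correlation of the two variables'
#' residuals after regressing each on the covariates, with `n - 2 - k`
#' degrees of freedom for `k` covariates.
#'
#' @param x,y numeric vectors.
#' @param covariates optional numeric vector/matrix of control variables.
#' @return a `correlation_result`: `r`, `n`, `df`, `p`, `n_covariates`.
#' @export
correlations <- function(x, y, covariates = NULL) {
  keep <- complete.cases(x, y, covariates)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  k <- 0L
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)[keep, , drop = FALSE]
    k <- ncol(covariates)
    x <- resid(lm(x ~ covariates))
    y <- resid(lm(y ~ covariates))
  }
  if (n < 3 + k) stop("need at least 3 + #covariates paired observations",
                      call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  r <- cor(x, y)
  df <- n - 2L - k
  tval <- r * sqrt(df / (1 - r^2))
  structure(list(r = r, n = n, df = df, p = 2 * pt(-abs(tval), df),
                 n_covariates = k),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  lab <- if (x$n_covariates > 0)
    sprintf("partial r (k=%d)", x$n_covariates) else "r"
  cat(sprintf("%s = %.3f, n = %d, df = %d, p = %.4g\n", lab, x$r, x$n,
              x$df, x$p))
  invisible(x)
}

#' Compare two independent correlations (Fisher r-to-z)
#'
#' z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3)), with a two-sided
#' normal p value.
#'
#' @param r1,r2 sample correlations (|r| < 1).
#' @param n1,n2 sample sizes (>= 4).
#' @return list with `z` and `p`.
#' @export
fisher_z_compare <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1)
    stop("|r| must be < 1 for the Fisher transform", call. = FALSE)
  if (n1 < 4 || n2 < 4) stop("need n >= 4 in each group", call. = FALSE)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Sample size for a two-sample t test
#'
#' Smallest equal per-group n for which a two-sided two-sample t test at
#' level `alpha` reaches the requested power against standardized effect
#' size `d`, computed exactly under the noncentral t distribution.
#'
#' @param effect_size_d Cohen's d (> 0).
#' @param alpha two-sided significance level.
#' @param power target power.
#' @param n_max search limit.
#' @return list with `n_per_group`, `n_total`, `achieved_power`.
#' @examples
#' power_sample_size(1.2)   # 12 per group, 24 in total
#' @export
power_sample_size <- function(effect_size_d, alpha = 0.05, power = 0.80,
                              n_max = 1e5) {
  if (effect_size_d <= 0) stop("effect size must be > 0", call. = FALSE)
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop("alpha and power must lie in (0, 1)", call. = FALSE)
  pow <- function(n) {
    df <- 2 * n - 2
    ncp <- effect_size_d * sqrt(n / 2)
    crit <- qt(1 - alpha / 2, df)
    1 - pt(crit, df, ncp) + pt(-crit, df, ncp)
  }
  for (n in 2:n_max) {
    p <- pow(n)
    if (p >= power)
      return(list(n_per_group = n, n_total = 2L * n, achieved_power = p))
  }
  stop("requested power not attainable within n_max per group",
       call. = FALSE)
}

#' Voxel-wise two-sample group comparison with cluster-extent filtering
#'
#' Two-sample pooled-variance t test per voxel between two groups of voxel
#' maps, thresholded at a Bonferroni-corrected voxel-level alpha over the
#' in-mask voxels, followed by removal of suprathreshold clusters (6-
#' connectivity, faces only) smaller than `min_cluster_voxels` (default 10).
#'
#' @param maps1,maps2 subjects x voxels matrices (one row per subject's
#'   map), e.g. stacked DoR maps per group.
#' @param dims voxel-grid dimensions.
#' @param alpha family-wise alpha; the voxel threshold is `alpha / #voxels`
#'   within the mask.
#' @param min_cluster_voxels cluster-extent threshold.
#' @param mask optional logical/integer vector restricting the tested
#'   voxels.
#' @return list with `t` (voxel-wise t map), `df`, `threshold_t`,
#'   `thresholded` (t map zeroed below threshold / outside surviving
#'   clusters) and `clusters` (data frame: cluster id, size, peak t, peak
#'   voxel coordinates).
#' @export
voxelwise_group_map <- function(maps1, maps2, dims, alpha = 0.05,
                                min_cluster_voxels = 10, mask = NULL) {
  maps1 <- as.matrix(maps1); maps2 <- as.matrix(maps2)
  if (ncol(maps1) != ncol(maps2))
    stop("groups' maps have different voxel counts", call. = FALSE)
  n1 <- nrow(maps1); n2 <- nrow(maps2)
  if (n1 < 2 || n2 < 2) stop("need >= 2 subjects per group", call. = FALSE)
  nvox <- ncol(maps1)
  if (is.null(mask)) mask <- rep(TRUE, nvox)
  mask <- as.logical(mask)

  m1 <- colMeans(maps1); m2 <- colMeans(maps2)
  v1 <- apply(maps1, 2, var); v2 <- apply(maps2, 2, var)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tmap <- (m1 - m2) / se
  degenerate <- se == 0 | !is.finite(tmap)
  tmap[degenerate] <- 0

  n_test <- sum(mask)
  thr <- qt(1 - (alpha / n_test) / 2, df)
  supra <- abs(tmap) > thr & mask & !degenerate

  lab <- label_clusters_6conn(supra & tmap > 0, dims)
  lab_neg <- label_clusters_6conn(supra & tmap < 0, dims)
  if (max(lab_neg) > 0) lab[lab_neg > 0] <- lab_neg[lab_neg > 0] + max(lab)

  keep <- integer(0)
  clusters <- list()
  for (cl in setdiff(unique(lab), 0L)) {
    vox <- which(lab == cl)
    if (length(vox) < min_cluster_voxels) next
    pk <- vox[which.max(abs(tmap[vox]))]
    clusters[[length(clusters) + 1]] <- data.frame(
      cluster = length(clusters) + 1L, n_voxels = length(vox),
      peak_t = tmap[pk],
      peak_x = ((pk - 1) %% dims[1]) + 1,
      peak_y = (((pk - 1) %/% dims[1]) %% dims[2]) + 1,
      peak_z = ((pk - 1) %/% (dims[1] * dims[2])) + 1)
    keep <- c(keep, vox)
  }
  thresholded <- numeric(nvox)
  thresholded[keep] <- tmap[keep]
  clusters <- if (length(clusters)) do.call(rbind, clusters) else
    data.frame(cluster = integer(0), n_voxels = integer(0),
               peak_t = numeric(0), peak_x = integer(0),
               peak_y = integer(0), peak_z = integer(0))
  list(t = tmap, df = df, threshold_t = thr, thresholded = thresholded,
       clusters = clusters, degenerate = which(degenerate & mask))
}

# connected components over a logical voxel vector, 6-neighborhood
label_clusters_6conn <- function(flag, dims) {
  lab <- integer(length(flag))
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  idx2xyz <- function(i) {
    i0 <- i - 1L
    c(i0 %% nx, (i0 %/% nx) %% ny, i0 %/% (nx * ny))
  }
  cur <- 0L
  for (start in which(flag & lab == 0L)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      xyz <- idx2xyz(i)
      for (d in 1:3) {
        for (s in c(-1L, 1L)) {
          nb <- xyz; nb[d] <- nb[d] + s
          if (nb[d] < 0 || nb[d] >= dims[d]) next
          j <- nb[1] + nx * (nb[2] + ny * nb[3]) + 1L
          if (flag[j] && lab[j] == 0L) {
            lab[j] <- cur
            queue <- c(queue, j)
          }
        }
      }
    }
  }
  lab
}
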