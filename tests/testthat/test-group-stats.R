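test_that("ROI extraction averages masks and pools the network", {
  labels <- synthetic_brain_labels()
  rois <- roi_set(labels)
  const <- rep(3.5, length(labels))
  vals <- extract_roi_values(const, rois)
  expect_true(all(abs(vals - 3.5) < 1e-12))
  # equal-sized ROIs: network mean = mean of the five ROI means
  set.seed(1)
  m <- rnorm(length(labels))
  vals2 <- extract_roi_values(m, rois)
  expect_equal(unname(vals2["network"]),
               mean(vals2[rois$network]), tolerance = 1e-12)
  # toy arithmetic on a 3-voxel mask
  toy_rois <- structure(list(masks = list(a = 1:3), network = "a",
                             control = "a",
                             centers_mm = matrix(0, 1, 3)),
                        class = "roi_set")
  expect_equal(unname(extract_roi_values(c(1, 2, 3), toy_rois)["a"]), 2)
  expect_error(extract_roi_values(c(1, 2), rois), "does not match")
})

test_that("one-way ANOVA matches the pooled t test and hand arithmetic", {
  g <- rep(c("a", "b"), each = 3)
  same <- one_way_anova(c(1, 2, 3, 1, 2, 3), g)
  expect_equal(same$F, 0)
  r <- one_way_anova(c(1, 2, 3, 4, 5, 6), g)
  expect_equal(r$F, 13.5)
  expect_equal(r$eta_squared, 13.5 / 17.5)
  expect_equal(r$df1, 1)
  expect_equal(r$df2, 4)
  set.seed(8)
  x <- rnorm(25); gg <- rep(c("a", "b"), c(12, 13))
  tt <- t.test(x ~ gg, var.equal = TRUE)
  expect_equal(one_way_anova(x, gg)$F, unname(tt$statistic)^2,
               tolerance = 1e-10)
  expect_equal(one_way_anova(x, gg)$p, tt$p.value, tolerance = 1e-10)
  expect_error(one_way_anova(1:3, rep("a", 3)), "2 groups")
})

test_that("Pearson and partial correlations behave as defined", {
  perfect <- correlations(1:10, 2 * (1:10) + 3)
  expect_equal(perfect$r, 1)
  # toy 4-point set, hand-computed
  x <- c(1, 2, 3, 4); y <- c(2, 1, 4, 3)
  hand <- sum((x - 2.5) * (y - 2.5)) /
    sqrt(sum((x - 2.5)^2) * sum((y - 2.5)^2))
  r4 <- correlations(x, y)
  expect_equal(r4$r, hand)
  expect_equal(r4$p, cor.test(x, y)$p.value, tolerance = 1e-10)
  # a covariate independent of both variables barely changes r
  set.seed(9)
  a <- rnorm(400); b <- 0.5 * a + rnorm(400); z <- rnorm(400)
  raw <- correlations(a, b)
  part <- correlations(a, b, covariates = z)
  expect_equal(part$r, raw$r, tolerance = 0.05)
  expect_equal(part$df, raw$df - 1)
  expect_error(correlations(rep(1, 10), rnorm(10)), "zero variance")
  expect_error(correlations(1:3, 1:3 + 0.1, covariates = cbind(1:3, 3:1)),
               "covariates")
})

test_that("partial correlation removes a shared confounder", {
  set.seed(12)
  z <- rnorm(500)
  a <- z + rnorm(500, sd = 0.3)
  b <- z + rnorm(500, sd = 0.3)
  expect_gt(correlations(a, b)$r, 0.8)
  expect_lt(abs(correlations(a, b, covariates = z)$r), 0.15)
})

test_that("Fisher r-to-z comparison follows the stated formula", {
  expect_equal(fisher_z_compare(0.4, 30, 0.4, 40)$z, 0)
  out <- fisher_z_compare(0.5, 30, 0, 30)
  expect_equal(out$z, atanh(0.5) / sqrt(2 / 27), tolerance = 1e-12)
  expect_equal(out$p, 2 * pnorm(-abs(out$z)), tolerance = 1e-12)
  swapped <- fisher_z_compare(0, 30, 0.5, 30)
  expect_equal(swapped$z, -out$z)
  expect_error(fisher_z_compare(1, 30, 0, 30), "Fisher")
  expect_error(fisher_z_compare(0.2, 3, 0, 30), "n >= 4")
})

test_that("power analysis inverts the noncentral-t power function", {
  big <- power_sample_size(10)
  expect_equal(big$n_per_group, 2L)
  expect_error(power_sample_size(0), "> 0")
  expect_error(power_sample_size(0.5, alpha = 1.2), "alpha")
  # Monte-Carlo power oracle at the returned n, d = 0.5 and 0.8
  for (d in c(0.5, 0.8)) {
    res <- power_sample_size(d)
    n <- res$n_per_group
    set.seed(100 + 10 * d)
    rej <- replicate(4000, {
      t.test(rnorm(n, d), rnorm(n), var.equal = TRUE)$p.value < 0.05
    })
    expect_equal(mean(rej), 0.80, tolerance = 0.035)
    # n - 1 per group must fall short of the target power
    pw <- function(nn) {
      df <- 2 * nn - 2; ncp <- d * sqrt(nn / 2)
      crit <- qt(0.975, df)
      1 - pt(crit, df, ncp) + pt(-crit, df, ncp)
    }
    expect_lt(pw(n - 1), 0.80)
    expect_gte(res$achieved_power, 0.80)
  }
})

test_that("voxel-wise maps threshold, cluster and stay empty under the null", {
  dims <- c(10, 10, 10)
  set.seed(3)
  g1 <- matrix(rnorm(8 * 1000), 8, 1000)
  g2 <- matrix(rnorm(8 * 1000), 8, 1000)
  null_map <- voxelwise_group_map(g1, g2, dims)
  expect_equal(nrow(null_map$clusters), 0)
  expect_true(all(null_map$thresholded == 0))
  expect_equal(formals(voxelwise_group_map)$min_cluster_voxels, 10)
  # planted 27-voxel effect in the synthetic thalamus is one cluster
  labels <- synthetic_brain_labels(dims)
  thal <- which(labels == 4)
  g1[, thal] <- g1[, thal] + 8
  planted <- voxelwise_group_map(g1, g2, dims)
  expect_equal(nrow(planted$clusters), 1)
  expect_equal(planted$clusters$n_voxels, 27)
  expect_setequal(which(planted$thresholded != 0), thal)
  # clusters below the extent threshold are removed
  small <- voxelwise_group_map(g1, g2, dims, min_cluster_voxels = 28)
  expect_equal(nrow(small$clusters), 0)
})

test_that("degenerate-variance voxels are flagged, not propagated", {
  g1 <- matrix(1, 5, 10); g2 <- matrix(1, 5, 10)
  g1[, 2] <- 2
  out <- voxelwise_group_map(g1, g2, c(10, 1, 1), min_cluster_voxels = 1)
  expect_true(2 %in% out$degenerate || out$t[2] == 0)
  expect_true(all(is.finite(out$t)))
})
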