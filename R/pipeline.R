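#' Pipeline configuration
#'
#' Assembles (and optionally reads from YAML) the configuration driving
#' [run_pipeline()]: task design, cohort structure, MCMC settings, BOLD
#' simulation options, QC threshold, analysis options, output directory and
#' the master seed from which all stage seeds are derived.
#'
#' @param path optional YAML file whose keys override the defaults.
#' @param ... named overrides applied last (nested lists merged).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(path = NULL, ...) {
  cfg <- list(
    seed = 1L,
    out_dir = "stopvar-output",
    design = list(),                    # task_design() arguments
    cohort = NULL,                      # NULL = default_group_specs()
    qc = list(min_stop_success_pct = 30),
    mcmc = list(n_chains = 3, n_samples = 3000, n_burn_in = 1000,
                thinning = 2, n_predictions = 1000,
                estimate_trigger_failure = FALSE),
    bold = list(stop_sd = c(child = 0.9, adult = 2.1), coupling = 0.5,
                calcarine_sd = 0.8, noise_sd = 1, ar1 = 0.3, drift_amp = 1,
                runs_per_subject = 2, fd_outlier_mm = 0.9,
                motion_scale = c(child = 1.15, adult = 1.0)),
    analysis = list(alpha = 0.05, min_cluster_voxels = 10))
  if (!is.null(path)) cfg <- modifyList(cfg, yaml::read_yaml(path))
  dots <- list(...)
  if (length(dots)) cfg <- modifyList(cfg, dots)
  structure(cfg, class = "pipeline_config")
}

# subject-level stop-success amplitude SD, optionally coupled to stopping
# consistency: subjects with larger true tau_stop (less consistent stopping)
# get smaller trial-amplitude SD, exp(-coupling * z(tau)) around the group
# base value
couple_stop_sd <- function(truth, base_sd_by_group, coupling, group_specs) {
  vapply(seq_len(nrow(truth)), function(i) {
    g <- truth$group[i]
    base <- base_sd_by_group[[g]]
    if (is.null(base) || is.na(base)) base <- mean(unlist(base_sd_by_group))
    if (coupling == 0) return(base)
    gs <- group_specs[[g]]
    z <- (truth$tau_stop[i] - gs$loc$tau_stop) / gs$scale[["tau_stop"]]
    base * exp(-coupling * z)
  }, numeric(1))
}

# simulate, denoise and model one subject's runs; returns summed DoR over
# runs plus the mean framewise displacement
subject_bold_dor <- function(session, stop_sd, bold_cfg, seed) {
  dor_sum <- NULL
  fd <- numeric(0)
  set.seed(seed)
  # subject-specific motion level: group scale times a lognormal factor,
  # giving realistic between-subject spread in framewise displacement
  msub <- exp(rnorm(1, 0, 0.3))
  spec <- bold_sim_spec(
    amp = default_amp_table(stop_sd = stop_sd,
                            calcarine_sd = bold_cfg$calcarine_sd),
    noise_sd = bold_cfg$noise_sd, ar1 = bold_cfg$ar1,
    drift_amp = bold_cfg$drift_amp,
    motion_sd = c(0.055, 4.8e-4) * msub *
      (bold_cfg$motion_scale[[session$group]] %||% 1))
  n_runs <- min(bold_cfg$runs_per_subject, session$design$n_blocks)
  for (b in seq_len(n_runs)) {
    ev <- session_events(session, block = b)
    if (sum(ev$trial_type == "stop-success") < 2) next
    run <- simulate_bold_run(ev, spec, seed = seed + b)
    fd_run <- mean_framewise_displacement(run$motion)
    outliers <- which(c(0, rowSums(abs(cbind(
      diff(run$motion[, 1:3]), diff(run$motion[, 4:6]) * 50)))) >
      bold_cfg$fd_outlier_mm)
    run <- denoise(run, confounds = run$motion, outliers = outliers)
    ds <- build_design(ev, run$n_volumes, run$tr, mode = "standard",
                       conditions = c("go-success", "stop-success"))
    dt <- build_design(ev, run$n_volumes, run$tr, mode = "trialwise",
                       conditions = c("go-success", "stop-success"))
    dor <- difference_of_residuals(fit_glm_ssr(run, ds),
                                   fit_glm_ssr(run, dt))
    dor_sum <- if (is.null(dor_sum)) dor$dor else dor_sum + dor$dor
    fd <- c(fd, fd_run)
  }
  if (is.null(dor_sum))
    stop("no run with enough successful stops for subject ",
         session$subject_id, call. = FALSE)
  list(dor = dor_sum, fd = mean(fd), dims = spec$dims)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# BOLD stage over a whole cohort: subjects x voxels DoR matrix + FD vector
cohort_bold_dor <- function(cohort, bold_cfg, seed) {
  sds <- couple_stop_sd(cohort$truth, as.list(bold_cfg$stop_sd),
                        bold_cfg$coupling, cohort$group_specs)
  n <- length(cohort$sessions)
  dor <- NULL
  fd <- numeric(n)
  for (i in seq_len(n)) {
    res <- subject_bold_dor(cohort$sessions[[i]], sds[i], bold_cfg,
                            seed = seed + 100L * i)
    if (is.null(dor)) dor <- matrix(NA_real_, n, length(res$dor))
    dor[i, ] <- res$dor
    fd[i] <- res$fd
  }
  rownames(dor) <- names(cohort$sessions)
  list(dor = dor, fd = fd, dims = res$dims)
}

# group-level inferential statistics shared by run_pipeline and callers
cohort_statistics <- function(behavior, race_est, dor, fd, dims,
                              alpha = 0.05, min_cluster_voxels = 10) {
  rois <- roi_set(synthetic_brain_labels(dims))
  roi_vals <- t(apply(dor, 1, extract_roi_values, rois = rois))
  grp <- behavior$group

  anova_rows <- list()
  add_anova <- function(measure, values) {
    gt <- one_way_anova(values, grp)
    anova_rows[[length(anova_rows) + 1]] <<- data.frame(
      measure = measure, F = gt$F, df1 = gt$df1, df2 = gt$df2, p = gt$p,
      eta_squared = gt$eta_squared, stringsAsFactors = FALSE)
  }
  add_anova("ssrt_integration", behavior$ssrt_integration)
  add_anova("pct_stop_success", behavior$pct_stop_success)
  for (p in c("mu_stop", "sigma_stop", "tau_stop"))
    add_anova(paste0("bpa_", p), race_est[[p]])
  for (r in c(rois$network, rois$control, "network"))
    add_anova(paste0("dor_", r), roi_vals[, r])
  anova_tab <- do.call(rbind, anova_rows)

  g1 <- unique(grp)[1]; g2 <- unique(grp)[2]
  tmap <- voxelwise_group_map(dor[grp == g1, , drop = FALSE],
                              dor[grp == g2, , drop = FALSE],
                              dims, alpha = alpha,
                              min_cluster_voxels = min_cluster_voxels)

  cor_rows <- list()
  for (g in unique(grp)) {
    sel <- grp == g
    go_cov <- as.matrix(race_est[sel, c("mu_go", "sigma_go", "tau_go")])
    for (p in c("tau_stop", "sigma_stop", "mu_stop")) {
      for (region in c("network", rois$control)) {
        cr <- correlations(roi_vals[sel, region], race_est[[p]][sel])
        # partial correlations need n > 2 + #covariates; NA on tiny groups
        pr <- tryCatch(correlations(roi_vals[sel, region],
                                    race_est[[p]][sel],
                                    covariates = go_cov),
                       error = function(e) list(r = NA_real_, p = NA_real_))
        cor_rows[[length(cor_rows) + 1]] <- data.frame(
          group = g, region = region, parameter = p, r = cr$r, p_value = cr$p,
          partial_r = pr$r, partial_p = pr$p, n = cr$n,
          stringsAsFactors = FALSE)
      }
    }
  }
  cor_tab <- do.call(rbind, cor_rows)

  zcmp <- lapply(c("tau_stop", "sigma_stop", "mu_stop"), function(p) {
    a <- cor_tab[cor_tab$parameter == p & cor_tab$region == "network", ]
    z <- fisher_z_compare(a$r[1], a$n[1], a$r[2], a$n[2])
    data.frame(parameter = p, group1 = a$group[1], group2 = a$group[2],
               z = z$z, p_value = z$p, stringsAsFactors = FALSE)
  })
  zcmp <- do.call(rbind, zcmp)

  fd_test <- one_way_anova(fd, grp)
  fd_cor <- correlations(fd, roi_vals[, "network"])

  list(roi_values = roi_vals, anova = anova_tab, tmap = tmap,
       correlations = cor_tab, fisher_z = zcmp,
       fd = list(by_group = tapply(fd, grp, mean), test = fd_test,
                 cor_network = fd_cor))
}

#' Run the full simulation-to-statistics pipeline
#'
#' Executes, with one master seed and a single configuration: cohort
#' simulation, behavioral QC and summaries, the hierarchical Bayesian race
#' fit per group, BOLD simulation and difference-of-residuals maps per
#' subject, and the group/correlation statistics. Every intermediate
#' artifact is written under `config$out_dir` (sessions, truth, behavior
#' summaries and posterior draws as TSV; DoR maps as NIfTI; statistics as
#' TSV) together with a markdown report with behavioral, BOLD-variability
#' and correlation sections. Identical configurations and seeds produce
#' identical outputs; stage failures abort with a stage-tagged error,
#' retaining prior artifacts.
#'
#' @param config a [pipeline_config()].
#' @param verbose print stage progress.
#' @return (invisibly) a list with the in-memory results of every stage.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = TRUE) {
  stage <- function(name, expr) {
    if (verbose) message("[stopvar] stage: ", name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  out <- config$out_dir
  stage("setup", {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out)) stop("cannot create output directory ", out)
  })

  cohort <- stage("simulate", {
    specs <- config$cohort %||% default_group_specs()
    design <- do.call(task_design, config$design)
    coh <- simulate_cohort(specs, design, seed = config$seed)
    write_sessions_tsv(coh, file.path(out, "sessions.tsv"))
    write.table(coh$truth, file.path(out, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    coh
  })

  behavior <- stage("behavior", {
    keep <- vapply(cohort$sessions, qc_filter,
                   min_stop_success_pct = config$qc$min_stop_success_pct,
                   logical(1))
    if (any(!keep) && verbose)
      message("  excluded by QC: ",
              paste(names(keep)[!keep], collapse = ", "))
    sessions <- cohort$sessions[keep]
    beh <- do.call(rbind, lapply(sessions, summarize_stopping))
    rownames(beh) <- NULL
    write.table(beh, file.path(out, "behavior.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    cohort$sessions <- sessions
    cohort$truth <- cohort$truth[keep, ]
    beh
  })

  fits <- stage("fit-race", {
    groups <- unique(cohort$truth$group)
    fits <- list()
    for (g in groups) {
      sess <- cohort$sessions[cohort$truth$group == g]
      st <- do.call(mcmc_settings,
                    c(config$mcmc, list(seed = config$seed + 7L)))
      fits[[g]] <- fit_race(sess, st)
      write_posterior_tsv(fits[[g]],
                          file.path(out, sprintf("posterior_%s.tsv", g)))
    }
    est <- do.call(rbind, lapply(groups, function(g) {
      cf <- coef(fits[[g]])$subjects
      data.frame(subject_id = rownames(cf), group = g, cf,
                 stringsAsFactors = FALSE)
    }))
    rownames(est) <- NULL
    write.table(est, file.path(out, "race_estimates.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(fits = fits, est = est)
  })

  boldres <- stage("bold-dor", {
    res <- cohort_bold_dor(cohort, config$bold, seed = config$seed + 50L)
    dir.create(file.path(out, "dor"), showWarnings = FALSE)
    for (i in seq_len(nrow(res$dor)))
      write_nifti(res$dor[i, ],
                  file.path(out, "dor",
                            paste0(rownames(res$dor)[i], "_dor.nii.gz")),
                  dims = res$dims)
    res
  })

  stats <- stage("analyze", {
    est <- fits$est[match(behavior$subject_id, fits$est$subject_id), ]
    st <- cohort_statistics(behavior, est, boldres$dor, boldres$fd,
                            boldres$dims, alpha = config$analysis$alpha,
                            min_cluster_voxels =
                              config$analysis$min_cluster_voxels)
    write.table(st$anova, file.path(out, "anova.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(st$correlations, file.path(out, "correlations.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(st$fisher_z, file.path(out, "fisher_z.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(st$tmap$clusters, file.path(out, "clusters.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    st
  })

  stage("report", {
    writeLines(pipeline_report(behavior, fits$est, stats),
               file.path(out, "report.md"))
  })

  invisible(list(cohort = cohort, behavior = behavior, fits = fits$fits,
                 race_estimates = fits$est, bold = boldres, stats = stats,
                 out_dir = out))
}

pipeline_report <- function(behavior, est, stats) {
  fmt_aov <- function(m) {
    r <- stats$anova[stats$anova$measure == m, ]
    sprintf("F(%d, %d) = %.3f, p = %.3g, eta^2 = %.2f", r$df1, r$df2, r$F,
            r$p, r$eta_squared)
  }
  by_grp <- function(v) tapply(v, behavior$group, mean, na.rm = TRUE)
  ssrt <- by_grp(behavior$ssrt_integration)
  pss <- by_grp(behavior$pct_stop_success)
  c("# Stop-signal variability report",
    "",
    "## Behavior",
    sprintf("- Subjects analyzed: %d (%s)", nrow(behavior),
            paste(sprintf("%s n=%d", names(table(behavior$group)),
                          table(behavior$group)), collapse = ", ")),
    sprintf("- Mean integration SSRT: %s ms; group ANOVA %s",
            paste(sprintf("%s %.0f", names(ssrt), ssrt), collapse = ", "),
            fmt_aov("ssrt_integration")),
    sprintf("- Percent successful stops: %s; group ANOVA %s",
            paste(sprintf("%s %.1f%%", names(pss), pss), collapse = ", "),
            fmt_aov("pct_stop_success")),
    sprintf("- SSRT distribution parameters (hierarchical Bayesian): mu %s; sigma %s; tau %s",
            fmt_aov("bpa_mu_stop"), fmt_aov("bpa_sigma_stop"),
            fmt_aov("bpa_tau_stop")),
    "",
    "## BOLD variability",
    sprintf("- Network DoR group ANOVA: %s", fmt_aov("dor_network")),
    sprintf("- Voxel-wise group map: %d suprathreshold cluster(s)%s",
            nrow(stats$tmap$clusters),
            if (nrow(stats$tmap$clusters))
              sprintf(" (sizes: %s voxels)",
                      paste(stats$tmap$clusters$n_voxels, collapse = ", "))
            else ""),
    sprintf("- Mean framewise displacement by group: %s; ANOVA p = %.3g; correlation with network DoR r = %.3f (p = %.3g)",
            paste(sprintf("%s %.3f mm", names(stats$fd$by_group),
                          stats$fd$by_group), collapse = ", "),
            stats$fd$test$p, stats$fd$cor_network$r, stats$fd$cor_network$p),
    "",
    "## Correlations",
    unlist(lapply(seq_len(nrow(stats$correlations)), function(i) {
      r <- stats$correlations[i, ]
      sprintf("- %s, %s ~ %s: r = %.3f (p = %.3g); partial r = %.3f (p = %.3g)",
              r$group, r$region, r$parameter, r$r, r$p_value, r$partial_r,
              r$partial_p)
    })),
    "",
    sprintf("- Fisher z group comparisons (network): %s",
            paste(sprintf("%s z = %.2f (p = %.3g)", stats$fisher_z$parameter,
                          stats$fisher_z$z, stats$fisher_z$p_value),
                  collapse = "; ")))
}
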