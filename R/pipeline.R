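# Pipeline orchestration and the routine companion statistics reported
# alongside the core model.

#' Companion tests for a migration dataset
#'
#' The standard statistics reported next to the central model, as thin
#' wrappers over the usual routines: Levene's test (median-centred, via
#' \pkg{car}) for equality of the group variances of 48-week subsidence,
#' total translation and total rotation; the Fisher exact test on the
#' outlier-count 2x2 table; and Pearson correlations (with CIs) between
#' z-axis rotation change and y-axis translation change - and, when a
#' column `gruen1_bmd_change` is supplied in the observations, between
#' z-rotation and that periprosthetic BMD change - over the first-visit
#' records.
#'
#' @param dataset Trial dataset (`roster` + `observations`).
#' @param rules Outlier rules for the 2x2 table (default
#'   [trial_outlier_rules()]).
#' @param week_late Visit used for the variance tests (default the last
#'   available week).
#' @param week_early Visit used for the correlations (default the first).
#' @return List with `levene` (data frame), `fisher_outliers` (htest),
#'   `outlier_table` and `pearson` (list of htest objects).
#' @export
companion_tests <- function(dataset, rules = trial_outlier_rules(),
                            week_late = NULL, week_early = NULL) {
  obs <- dataset$observations
  roster <- dataset$roster
  if (is.null(week_late)) week_late <- max(obs$week)
  if (is.null(week_early)) week_early <- min(obs$week)
  grp <- factor(roster$group[match(as.character(obs$subject),
                                   as.character(roster$subject))])

  late <- obs$week == week_late
  lev <- lapply(c(subsidence = "ty", total_translation = "tt",
                  total_rotation = "tr"), function(metric) {
    v <- switch(metric,
                ty = obs$ty[late],
                tt = sqrt(obs$tx[late]^2 + obs$ty[late]^2 + obs$tz[late]^2),
                tr = sqrt(obs$rx[late]^2 + obs$ry[late]^2 + obs$rz[late]^2))
    g <- droplevels(grp[late])
    ok <- !is.na(v)
    lt <- car::leveneTest(v[ok], g[ok])
    c(F = lt[1, "F value"], p = lt[1, "Pr(>F)"])
  })
  levene <- data.frame(metric = names(lev),
                       F = vapply(lev, `[`, 0, "F"),
                       p = vapply(lev, `[`, 0, "p"),
                       week = week_late, row.names = NULL)

  fl <- flag_outliers(obs, rules)
  is_out <- as.character(roster$subject) %in% fl$subjects
  tab <- table(group = roster$group, outlier = factor(is_out, c(TRUE, FALSE)))
  fisher <- stats::fisher.test(tab)

  early <- obs[obs$week == week_early, , drop = FALSE]
  pearson <- list(
    rz_vs_ty = stats::cor.test(early$rz, early$ty, method = "pearson")
  )
  if ("gruen1_bmd_change" %in% names(early)) {
    pearson$rz_vs_gruen1_bmd <-
      stats::cor.test(early$rz, early$gruen1_bmd_change, method = "pearson")
  }
  list(levene = levene, fisher_outliers = fisher, outlier_table = tab,
       pearson = pearson)
}

.config_hash <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(obj, f, version = 2)
  unname(tools::md5sum(f))
}

#' Run the full migration analysis pipeline
#'
#' Executes the complete reanalysis on a dataset: outlier flagging, the
#' multivariate LMM on both cohorts (original and without outliers) with
#' backward simplification, the joint 3D group test, per-axis effect slices
#' and LS-means (raw per axis, plus the axis-standardised blended "3D
#' migration" trajectory), and the companion tests. Deterministic given its
#' inputs; every stage logs its in/out counts when `verbose = TRUE`.
#'
#' @param dataset Trial dataset (`roster` + `observations`), e.g. from
#'   [generate_trial()] or [read_migration_csv()].
#' @param config List of options: `rules` (outlier rules, default
#'   [trial_outlier_rules()]), `cov_structure` (default `"kronecker_un"`),
#'   `fixed` (fixed-effects formula, default group x week x axis),
#'   `simplify` (backward-eliminate interactions, default TRUE),
#'   `alpha_keep` (default 0.05), `exclude` (extra subject ids to drop,
#'   e.g. QC failures), `seed` (recorded in provenance only).
#' @param verbose Print one log line per stage.
#' @return List of class `analysis_report`; see Details. Each cohort entry
#'   carries the joint test (`joint`), the per-axis slices (`slices`), the
#'   LS-means tables, and the dropped interaction terms.
#' @export
run_pipeline <- function(dataset, config = list(), verbose = FALSE) {
  cfg <- utils::modifyList(list(
    rules = trial_outlier_rules(),
    cov_structure = "kronecker_un",
    fixed = NULL,
    simplify = TRUE,
    alpha_keep = 0.05,
    exclude = character(),
    seed = NA
  ), config)
  say <- function(...) if (verbose) message(sprintf(...))
  stopifnot(is.list(dataset), all(c("roster", "observations") %in% names(dataset)))
  if (!all(RSA_AXES %in% names(dataset$observations))) {
    stop("run_pipeline: observations lack axis column(s): ",
         paste(setdiff(RSA_AXES, names(dataset$observations)), collapse = ", "))
  }
  say("input: %d subjects, %d observations",
      nrow(dataset$roster), nrow(dataset$observations))

  fl <- flag_outliers(dataset$observations, cfg$rules)
  say("outlier flagging: %d subjects flagged", length(fl$subjects))

  analyse_cohort <- function(cohort) {
    frame <- build_model_frame(dataset, cohort = cohort, rules = cfg$rules,
                               exclude = cfg$exclude)
    say("cohort %s: %d subjects, %d rows", cohort,
        nlevels(frame$subject), nrow(frame))
    fit <- fit_mv_lmm(frame, fixed = cfg$fixed,
                      cov_structure = cfg$cov_structure)
    dropped <- data.frame(term = character(), p = numeric())
    if (isTRUE(cfg$simplify)) {
      fit <- simplify_model(fit, alpha_keep = cfg$alpha_keep)
      dropped <- attr(fit, "dropped")
      say("cohort %s: dropped %d interaction term(s)", cohort, nrow(dropped))
    }
    joint <- test_3d_group_effect(fit)
    slices <- slice_by_axis(fit)
    lsm_axis <- lsmeans(fit, c("group", "axis", "week"))
    frame_std <- build_model_frame(dataset, cohort = cohort,
                                   rules = cfg$rules, exclude = cfg$exclude,
                                   standardize = TRUE)
    fit_std <- fit_mv_lmm(frame_std, fixed = cfg$fixed,
                          cov_structure = cfg$cov_structure)
    lsm_3d <- lsmeans(fit_std, c("group", "week"))
    say("cohort %s: joint 3D p = %.3f", cohort, joint$p)
    list(cohort = cohort,
         n_subjects = nlevels(frame$subject),
         n_rows = nrow(frame),
         excluded = attr(frame, "excluded"),
         fit = fit,
         joint = list(F = joint$F, num_df = joint$num_df,
                      denom_df = joint$denom_df, p = joint$p,
                      terms = joint$terms),
         slices = slices,
         lsmeans_axis = lsm_axis,
         lsmeans_3d_standardized = lsm_3d,
         axis_scale = attr(frame_std, "axis_scale"),
         dropped = dropped)
  }

  res_orig <- analyse_cohort("original")
  res_noout <- analyse_cohort("without_outliers")
  comp <- companion_tests(dataset, cfg$rules)
  say("companion tests done")

  report <- list(
    outliers = fl,
    original = res_orig,
    without_outliers = res_noout,
    companion = comp,
    provenance = list(
      seed = cfg$seed,
      config_hash = .config_hash(cfg[setdiff(names(cfg), "seed")]),
      data_hash = .config_hash(dataset),
      package_version = as.character(utils::packageVersion("stemrsa")),
      timestamp = NA # deliberately constant so identical inputs hash alike
    )
  )
  class(report) <- "analysis_report"
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("RSA migration analysis report\n")
  cat(sprintf("  outliers flagged: %d (%s)\n", length(x$outliers$subjects),
              paste(x$outliers$subjects, collapse = ", ")))
  for (c in c("original", "without_outliers")) {
    r <- x[[c]]
    cat(sprintf("  cohort %-17s n=%2d  joint 3D F=%.3f (df %d, %.1f) p=%.3f\n",
                c, r$n_subjects, r$joint$F, r$joint$num_df,
                r$joint$denom_df, r$joint$p))
    sig <- r$slices[r$slices$p < 0.05, , drop = FALSE]
    if (nrow(sig)) {
      for (i in seq_len(nrow(sig))) {
        cat(sprintf("    slice %s: diff %.3f [%.3f, %.3f], p=%.3f\n",
                    sig$axis[i], sig$estimate[i], sig$lower[i],
                    sig$upper[i], sig$p[i]))
      }
    }
  }
  invisible(x)
}
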