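# Long-format model frame for the doubly repeated-measures LMM.

#' Build the axis-by-visit model frame
#'
#' Converts a trial dataset (roster + wide per-axis observations) into the
#' long model frame consumed by [fit_mv_lmm()]: one row per observed
#' subject x visit x axis cell, with the change-from-baseline migration as
#' the response. Missing RSA visits are simply absent (case-wise missing
#' cells are handled by the likelihood, never imputed), and cohort exclusion
#' is a view: the underlying dataset is not modified.
#'
#' @param dataset A list with elements `roster` (subject, group, optionally
#'   bmd_class) and `observations` (subject, week, and the six axis columns
#'   [RSA_AXES]), as produced by [generate_trial()] or [read_migration_csv()].
#' @param cohort `"original"` (all subjects) or `"without_outliers"`.
#' @param rules Outlier rules used when `cohort = "without_outliers"`;
#'   default the frozen trial cutoffs [trial_outlier_rules()].
#' @param exclude Additional subject ids to drop (e.g. QC failures).
#' @param axes Axes to keep (default all six).
#' @param standardize If TRUE, each axis is divided by its pooled SD across
#'   the frame (the scale used for the blended "3D migration" display where
#'   mm and degrees must be mixed); the scales are kept in
#'   `attr(frame, "axis_scale")`.
#' @return Data frame with columns `subject`, `group`, `week`, `axis`,
#'   `value` and, when present in the roster, `bmd_class`; class
#'   `stemrsa_frame`.
#' @export
build_model_frame <- function(dataset,
                              cohort = c("original", "without_outliers"),
                              rules = trial_outlier_rules(),
                              exclude = character(),
                              axes = RSA_AXES,
                              standardize = FALSE) {
  cohort <- match.arg(cohort)
  roster <- dataset$roster
  obs <- dataset$observations
  stopifnot(all(c("subject", "group") %in% names(roster)),
            all(c("subject", "week") %in% names(obs)))
  axes <- intersect(RSA_AXES, axes)
  if (!all(axes %in% names(obs))) {
    stop("build_model_frame: observation table lacks axis column(s): ",
         paste(setdiff(axes, names(obs)), collapse = ", "))
  }
  drop <- as.character(exclude)
  if (cohort == "without_outliers") {
    drop <- union(drop, flag_outliers(obs, rules)$subjects)
  }
  keep <- !(as.character(obs$subject) %in% drop)
  obs <- obs[keep, , drop = FALSE]
  roster <- roster[!(as.character(roster$subject) %in% drop), , drop = FALSE]

  long <- do.call(rbind, lapply(axes, function(ax) {
    data.frame(subject = as.character(obs$subject),
               week = obs$week,
               axis = ax,
               value = obs[[ax]],
               stringsAsFactors = FALSE)
  }))
  long <- long[!is.na(long$value), , drop = FALSE]
  ri <- match(long$subject, as.character(roster$subject))
  if (anyNA(ri)) {
    stop("build_model_frame: observations reference unknown subjects: ",
         paste(unique(long$subject[is.na(ri)]), collapse = ", "))
  }
  long$group <- factor(roster$group[ri])
  if ("bmd_class" %in% names(roster)) long$bmd_class <- factor(roster$bmd_class[ri])
  if (anyDuplicated(long[c("subject", "week", "axis")])) {
    stop("build_model_frame: more than one row per (subject, week, axis)")
  }
  long$week <- factor(long$week, levels = sort(unique(long$week)))
  long$axis <- factor(long$axis, levels = axes)
  long$subject <- factor(long$subject)

  axis_scale <- stats::setNames(rep(1, length(axes)), axes)
  if (standardize) {
    for (ax in axes) {
      s <- stats::sd(long$value[long$axis == ax], na.rm = TRUE)
      if (!is.finite(s) || s == 0) s <- 1
      axis_scale[ax] <- s
      long$value[long$axis == ax] <- long$value[long$axis == ax] / s
    }
  }
  long <- long[order(long$subject, long$week, long$axis),
               c("subject", "group", "week", "axis", "value",
                 intersect("bmd_class", names(long)))]
  rownames(long) <- NULL
  attr(long, "axis_scale") <- axis_scale
  attr(long, "cohort") <- cohort
  attr(long, "excluded") <- sort(unique(drop))
  class(long) <- c("stemrsa_frame", "data.frame")
  long
}
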