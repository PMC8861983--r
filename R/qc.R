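# Marker-based quality control and the IQR outlier rule.

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the rotation and translation that best superimpose `markers_ref`
#' onto `markers_obs` in the least-squares sense, via SVD of the
#' cross-covariance of the centered configurations, with the usual reflection
#' guard.
#'
#' @param markers_ref,markers_obs [marker_set()]s with identical labels
#'   (order may differ), n >= 3, not all collinear.
#' @return List with `transform` (a [rigid_transform()]), `residuals`
#'   (per-marker residual distances, mm, named) and `me` (mean error of
#'   rigid-body fitting, see [rigid_fit_error()]).
#' @export
rigid_fit <- function(markers_ref, markers_obs) {
  P <- as.matrix(unclass(markers_ref))
  Q <- as.matrix(unclass(markers_obs))
  if (is.null(rownames(P)) || is.null(rownames(Q)) ||
      !setequal(rownames(P), rownames(Q)) || nrow(P) != nrow(Q)) {
    stop("rigid_fit: marker labels must match between the two sets")
  }
  Q <- Q[rownames(P), , drop = FALSE]
  n <- nrow(P)
  if (n < 3) stop("rigid_fit: need at least 3 markers")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  s <- svd(crossprod(Pc, Qc)) # 3x3: t(Pc) %*% Qc
  if (s$d[2] < 1e-9 * max(s$d[1], 1)) {
    stop("rigid_fit: marker configuration is (near-)collinear")
  }
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- cq - as.numeric(R %*% cp)
  fitted <- P %*% t(R) + matrix(t, n, 3, byrow = TRUE)
  res <- sqrt(rowSums((fitted - Q)^2))
  names(res) <- rownames(P)
  list(transform = rigid_transform(R, t),
       residuals = res,
       me = sqrt(sum(res^2) / (n - 1)))
}

#' Mean error of rigid-body fitting (ME)
#'
#' Residual of the least-squares rigid superposition of a marker set across
#' two examinations, summarised in the RSA convention as
#' `sqrt(sum(d_i^2) / (n - 1))` where `d_i` is the residual distance of
#' marker i after the fit. ME is 0 (within tolerance) iff the observed
#' markers are an exactly rigid motion of the reference; high ME indicates
#' unstable markers.
#'
#' @inheritParams rigid_fit
#' @return ME in mm.
#' @export
rigid_fit_error <- function(markers_ref, markers_obs) {
  rigid_fit(markers_ref, markers_obs)$me
}

#' Condition number (CN) of a marker configuration
#'
#' Scatter metric of the marker cloud: `scale / sigma_min`, the reciprocal of
#' the smallest singular value of the centered n x 3 coordinate matrix (mm),
#' times a scale constant. The smallest singular value measures the spread of
#' the configuration along its weakest principal direction, which governs the
#' sensitivity of the rigid-body rotation estimate; near-collinear and
#' near-coplanar marker clouds therefore get a large CN. With the default
#' `scale = 1000` mm, typical trochanteric bead clouds (40-80 mm span, a few
#' mm out-of-plane scatter) land in the 30-150 range, so the conventional
#' acceptability threshold of 150 is meaningful. CN conventions differ across
#' RSA platforms; treat `scale` and the threshold as a pair.
#'
#' @param markers A [marker_set()] (n >= 3).
#' @param scale Scale constant in mm (default 1000).
#' @return CN (dimensionless given the fixed scale); `Inf` for a collinear
#'   configuration.
#' @export
condition_number <- function(markers, scale = 1000) {
  P <- as.matrix(unclass(markers))
  if (nrow(P) < 3) stop("condition_number: need at least 3 markers")
  Pc <- sweep(P, 2, colMeans(P))
  sv <- svd(Pc, nu = 0, nv = 0)$d
  smin <- sv[3]
  if (smin < 1e-9 * max(sv[1], 1)) return(Inf)
  scale / smin
}

#' QC metric pair
#'
#' @param me Mean error of rigid-body fitting (mm), >= 0.
#' @param cn Condition number, >= 1.
#' @return Named list of class `qc_metrics`.
#' @export
qc_metrics <- function(me, cn) {
  if (!is.finite(me) || me < 0) stop("qc_metrics: me must be finite and >= 0")
  if (is.na(cn) || cn < 1) stop("qc_metrics: cn must be >= 1")
  structure(list(me = me, cn = cn), class = "qc_metrics")
}

#' Flag an examination as unacceptable on QC grounds
#'
#' An RSA examination is considered unacceptable when ME exceeds 0.35 mm or
#' CN exceeds 150 (both configurable).
#'
#' @param q A [qc_metrics()] object, or a list with `me` and `cn`.
#' @param thresholds Named vector with elements `me` and `cn`;
#'   default [QC_THRESHOLDS].
#' @return TRUE if the examination should be excluded.
#' @export
flag_unacceptable <- function(q, thresholds = QC_THRESHOLDS) {
  isTRUE(q$me > thresholds[["me"]]) || isTRUE(q$cn > thresholds[["cn"]])
}

#' Per-axis outlier rules
#'
#' A set of per-axis lower/upper cutoffs. A value is an outlier when it is
#' strictly below the lower or strictly above the upper cutoff (the strict
#' inequality matches how the trial cutoffs are phrased, e.g. subsidence
#' "> 5.44 mm").
#'
#' @param ... Named arguments, one per axis (names from [RSA_AXES]), each a
#'   numeric `c(lower, upper)` with lower <= upper (`-Inf`/`Inf` allowed for
#'   one-sided rules).
#' @return Object of class `outlier_rules`: a named list of
#'   `c(lower, upper)` vectors.
#' @export
outlier_rules <- function(...) {
  rules <- list(...)
  if (length(rules) == 1 && is.null(names(rules)) && is.list(rules[[1]])) {
    rules <- rules[[1]]
  }
  if (is.null(names(rules)) || !all(names(rules) %in% RSA_AXES)) {
    stop("outlier_rules: rules must be named by axis (", paste(RSA_AXES, collapse = ", "), ")")
  }
  rules <- lapply(rules, function(r) {
    r <- as.numeric(r)
    if (length(r) != 2 || anyNA(r) || r[1] > r[2]) {
      stop("outlier_rules: each rule is c(lower, upper) with lower <= upper")
    }
    c(lower = r[1], upper = r[2])
  })
  structure(rules, class = "outlier_rules")
}

#' @export
print.outlier_rules <- function(x, ...) {
  cat("Outlier rules (flag if value < lower or > upper):\n")
  for (ax in names(x)) {
    cat(sprintf("  %s: lower %s, upper %s\n", ax,
                format(x[[ax]]["lower"]), format(x[[ax]]["upper"])))
  }
  invisible(x)
}

#' Tukey fence cutoffs for one migration axis
#'
#' Computes `(Q1 - 1.5*IQR, Q3 + 1.5*IQR)` from a sample of one axis, with
#' quartiles from the linear-interpolation estimator
#' (`stats::quantile(..., type = 7)`).
#'
#' @param values Numeric sample, n >= 4 (NAs dropped).
#' @param k Fence multiplier (default 1.5).
#' @return Named numeric `c(lower, upper)`.
#' @export
iqr_cutoffs <- function(values, k = 1.5) {
  values <- values[!is.na(values)]
  if (length(values) < 4) stop("iqr_cutoffs: need at least 4 values")
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  c(lower = q[1] - k * iqr, upper = q[2] + k * iqr)
}

#' Flag outlier subjects in a migration dataset
#'
#' A subject is an outlier if any of the selected axes at any visit falls
#' strictly outside its rule's cutoffs. Flagging is a view on the data: it
#' returns the offending cells and the subject set, but never modifies the
#' dataset (use the `cohort` argument of [build_model_frame()] to exclude).
#'
#' @param observations Data frame with columns `subject`, `week` and the axis
#'   columns named in `rules` (e.g. the `observations` element of a
#'   [generate_trial()] dataset).
#' @param rules An [outlier_rules()] object; default the frozen trial
#'   cutoffs [trial_outlier_rules()].
#' @param axes Axes to scan; default all axes with a rule.
#' @return List with `subjects` (character vector of flagged subject ids) and
#'   `report` (data frame: subject, axis, week, value, lower, upper).
#' @export
flag_outliers <- function(observations,
                          rules = trial_outlier_rules(),
                          axes = names(rules)) {
  stopifnot(all(c("subject", "week") %in% names(observations)))
  missing_ax <- setdiff(axes, names(observations))
  if (length(missing_ax)) {
    stop("flag_outliers: unknown axis column(s): ", paste(missing_ax, collapse = ", "))
  }
  hits <- list()
  for (ax in axes) {
    r <- rules[[ax]]
    if (is.null(r)) stop("flag_outliers: no rule for axis ", ax)
    v <- observations[[ax]]
    bad <- !is.na(v) & (v < r["lower"] | v > r["upper"])
    if (any(bad)) {
      hits[[ax]] <- data.frame(
        subject = as.character(observations$subject[bad]),
        axis = ax,
        week = observations$week[bad],
        value = v[bad],
        lower = unname(r["lower"]),
        upper = unname(r["upper"]),
        stringsAsFactors = FALSE
      )
    }
  }
  report <- if (length(hits)) do.call(rbind, hits) else
    data.frame(subject = character(), axis = character(), week = numeric(),
               value = numeric(), lower = numeric(), upper = numeric(),
               stringsAsFactors = FALSE)
  rownames(report) <- NULL
  report <- report[order(report$subject, report$axis, report$week), , drop = FALSE]
  list(subjects = sort(unique(report$subject)), report = report)
}

#' Serialize outlier rules to/from YAML
#'
#' @param rules An [outlier_rules()] object.
#' @param path File path.
#' @return `write_outlier_rules` returns `path` invisibly;
#'   `read_outlier_rules` returns an [outlier_rules()].
#' @export
write_outlier_rules <- function(rules, path) {
  yaml::write_yaml(lapply(unclass(rules), as.list), path)
  invisible(path)
}

#' @rdname write_outlier_rules
#' @export
read_outlier_rules <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(outlier_rules, lapply(raw, function(r) c(r$lower, r$upper)))
}
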