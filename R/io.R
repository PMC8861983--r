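# File interfaces: long-format migration CSV, roster CSV, marker CSV,
# JSON report and power-curve CSV.

#' Read and write trial migration data as CSV
#'
#' The on-disk contract is a pair of plain CSV files: a roster
#' (`subject, group[, bmd_class]`) and a wide observation table
#' (`subject, week, tx, ty, tz, rx, ry, rz`, translations in mm, rotations
#' in degrees, empty cells for missing values).
#'
#' @param observations_csv,roster_csv Paths.
#' @return `read_migration_csv`: a `trial_dataset`-shaped list.
#' @export
read_migration_csv <- function(observations_csv, roster_csv) {
  obs <- utils::read.csv(observations_csv, stringsAsFactors = FALSE)
  roster <- utils::read.csv(roster_csv, stringsAsFactors = FALSE)
  need <- c("subject", "week", RSA_AXES)
  if (!all(need %in% names(obs))) {
    stop("migration CSV lacks column(s): ",
         paste(setdiff(need, names(obs)), collapse = ", "))
  }
  if (!all(c("subject", "group") %in% names(roster))) {
    stop("roster CSV needs columns subject, group")
  }
  bad <- setdiff(as.character(obs$subject), as.character(roster$subject))
  if (length(bad)) {
    stop("observations reference unrostered subjects: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  structure(list(roster = roster, observations = obs),
            class = "trial_dataset")
}

#' @rdname read_migration_csv
#' @param dataset A trial dataset (`roster` + `observations`).
#' @export
write_migration_csv <- function(dataset, observations_csv, roster_csv) {
  utils::write.csv(dataset$observations, observations_csv, row.names = FALSE)
  utils::write.csv(dataset$roster, roster_csv, row.names = FALSE)
  invisible(c(observations_csv, roster_csv))
}

#' Read and write marker coordinates as CSV
#'
#' Columns: `label, x, y, z` in mm.
#'
#' @param path File path.
#' @return `read_marker_csv`: a [marker_set()].
#' @export
read_marker_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("label", "x", "y", "z") %in% names(d))) {
    stop("marker CSV needs columns label, x, y, z")
  }
  marker_set(as.matrix(d[c("x", "y", "z")]), labels = d$label)
}

#' @rdname read_marker_csv
#' @param markers A [marker_set()].
#' @export
write_marker_csv <- function(markers, path) {
  P <- as.matrix(unclass(markers))
  utils::write.csv(data.frame(label = rownames(P), x = P[, 1], y = P[, 2],
                              z = P[, 3]),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write an analysis report to JSON
#'
#' Serialises the numeric content of a [run_pipeline()] report (joint
#' tests, slices, LS-means, companion tests, outlier report, provenance) to
#' a JSON file; model fit objects themselves are not serialised.
#'
#' @param report An `analysis_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  cohort_out <- function(r) {
    list(cohort = r$cohort, n_subjects = r$n_subjects, n_rows = r$n_rows,
         excluded = r$excluded, joint = r$joint,
         slices = r$slices,
         lsmeans_axis = r$lsmeans_axis,
         lsmeans_3d_standardized = r$lsmeans_3d_standardized,
         axis_scale = as.list(r$axis_scale),
         dropped_terms = r$dropped)
  }
  out <- list(
    outliers = list(subjects = report$outliers$subjects,
                    report = report$outliers$report),
    original = cohort_out(report$original),
    without_outliers = cohort_out(report$without_outliers),
    companion = list(
      levene = report$companion$levene,
      fisher_outliers = list(
        p = report$companion$fisher_outliers$p.value,
        odds_ratio = unname(report$companion$fisher_outliers$estimate),
        table = as.data.frame(report$companion$outlier_table)),
      pearson = lapply(report$companion$pearson, function(h) {
        list(r = unname(h$estimate), p = h$p.value,
             ci = as.numeric(h$conf.int))
      })
    ),
    provenance = report$provenance
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}

#' Write a power curve to CSV
#'
#' @param curve A [power_sweep()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_power_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
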