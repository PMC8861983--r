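# Synthetic two-arm RSA trial generator. Emulates the statistical structure
# the analysis pipeline assumes - early settling trajectories, BMD-dependent
# subsidence, measurement noise at the clinical precision limits, sporadic
# missing visits and a small fraction of grossly migrating outlier subjects -
# without claiming the source trial's actual effect magnitudes.

#' Configuration of the synthetic RSA trial
#'
#' Defaults emulate a 65-subject two-arm trial: 33 treated / 32 placebo
#' subjects, RSA visits at 12, 22 and 48 weeks, saturating mean migration
#' `A * (1 - exp(-week / tau))`, a BMD-class mixture of roughly 50% normal /
#' 46% osteopenia / 4% osteoporosis with larger subsidence for the low-BMD
#' classes, per-axis measurement noise with SD = precision limit / 1.96,
#' 12% outlier contamination and 2.1% missing observations, and a
#' between-subject variance reduction in the treated arm.
#'
#' @param n_treated,n_placebo Arm sizes (default 33 / 32).
#' @param weeks Visit weeks (default 12, 22, 48).
#' @param asymptote Named list of per-axis asymptote means `A` (mm/deg);
#'   the `ty` entry is the normal-BMD subsidence asymptote.
#' @param bmd_subsidence_penalty Additional (more negative) ty asymptote for
#'   osteopenia/osteoporosis subjects (default -0.8 mm).
#' @param tau Settling time constant in weeks (default 8: most migration
#'   happens before the first RSA visit).
#' @param between_sd Named per-axis between-subject SD of the asymptote.
#' @param variance_reduction Multiplier on the treated arm's between-subject
#'   variance (default 0.4; 1 disables the effect).
#' @param precision Per-axis 95% precision limits; noise SD is
#'   `precision / 1.96` (interpreting the limit as the 95% bound of a single
#'   examination's error; set `precision_interpretation = "difference"` to
#'   read it as the limit of a difference of two examinations, which divides
#'   the SD by a further sqrt(2)).
#' @param precision_interpretation `"single"` (default) or `"difference"`.
#' @param bmd_mixture Probabilities of normal/osteopenia/osteoporosis.
#' @param outlier_rate Per-subject contamination probability (default 0.12).
#' @param missing_rate Per-observation missingness probability (default
#'   0.021).
#' @return List of class `trial_config`.
#' @export
trial_config <- function(n_treated = 33, n_placebo = 32,
                         weeks = c(12, 22, 48),
                         asymptote = list(tx = 0.10, ty = -0.80, tz = 0.10,
                                          rx = 0.40, ry = 1.20, rz = -0.30),
                         bmd_subsidence_penalty = -0.80,
                         tau = 8,
                         between_sd = list(tx = 0.15, ty = 0.80, tz = 0.20,
                                           rx = 0.40, ry = 1.20, rz = 0.25),
                         variance_reduction = 0.4,
                         precision = RSA_PRECISION_LIMITS,
                         precision_interpretation = c("single", "difference"),
                         bmd_mixture = c(normal = 0.50, osteopenia = 0.46,
                                         osteoporosis = 0.04),
                         outlier_rate = 0.12,
                         missing_rate = 0.021) {
  precision_interpretation <- match.arg(precision_interpretation)
  stopifnot(n_treated >= 2, n_placebo >= 2, tau > 0,
            outlier_rate >= 0, outlier_rate <= 1,
            missing_rate >= 0, missing_rate <= 1,
            all(RSA_AXES %in% names(asymptote)),
            all(RSA_AXES %in% names(between_sd)),
            abs(sum(bmd_mixture) - 1) < 1e-8)
  structure(list(
    n_treated = n_treated, n_placebo = n_placebo, weeks = sort(weeks),
    asymptote = asymptote, bmd_subsidence_penalty = bmd_subsidence_penalty,
    tau = tau, between_sd = between_sd,
    variance_reduction = variance_reduction,
    precision = precision,
    precision_interpretation = precision_interpretation,
    bmd_mixture = bmd_mixture, outlier_rate = outlier_rate,
    missing_rate = missing_rate
  ), class = "trial_config")
}

.noise_sd <- function(cfg) {
  sd <- cfg$precision[RSA_AXES] / 1.96
  if (cfg$precision_interpretation == "difference") sd <- sd / sqrt(2)
  sd
}

#' Expected change from baseline on one axis
#'
#' The saturating mean trajectory `A * (1 - exp(-week / tau))`: rapid early
#' settling followed by a plateau at the asymptote `A`. Low-BMD subjects get
#' the configured subsidence penalty added to the `ty` asymptote.
#'
#' @param axis One of [RSA_AXES].
#' @param group `"treated"` or `"placebo"` (treatment has no mean effect in
#'   the default configuration; kept as an argument so alternative
#'   configurations can introduce one through `cfg$asymptote`).
#' @param bmd_class `"normal"`, `"osteopenia"` or `"osteoporosis"`.
#' @param week Weeks since surgery (>= 0).
#' @param cfg A [trial_config()].
#' @return Expected change from baseline (mm or degrees).
#' @export
mean_trajectory <- function(axis, group = "placebo", bmd_class = "normal",
                            week, cfg = trial_config()) {
  stopifnot(axis %in% RSA_AXES, all(week >= 0))
  A <- cfg$asymptote[[axis]]
  if (axis == "ty" && bmd_class != "normal") {
    A <- A + cfg$bmd_subsidence_penalty
  }
  A * (1 - exp(-week / cfg$tau))
}

#' Generate a synthetic RSA trial dataset
#'
#' Simulates the full trial: subject-level random asymptotes around the
#' configured means (between-subject SD shrunk by `variance_reduction` in
#' the treated arm), visit-level measurement noise at the precision-derived
#' SDs, outlier subjects whose subsidence or y-rotation asymptote is
#' inflated beyond the shipped trial cutoffs (a two-component mixture, so
#' injected outliers are individually identifiable), and observations
#' deleted completely at random at the missingness rate. Reproducible via
#' [set.seed()].
#'
#' @param cfg A [trial_config()].
#' @return List of class `trial_dataset` with `roster` (subject, group,
#'   bmd_class, outlier flag and type) and `observations` (subject, week,
#'   six axis columns), plus the config in `attr(, "config")`.
#' @export
generate_trial <- function(cfg = trial_config()) {
  stopifnot(inherits(cfg, "trial_config"))
  n <- cfg$n_treated + cfg$n_placebo
  roster <- data.frame(
    subject = sprintf("S%03d", seq_len(n)),
    group = rep(c("treated", "placebo"), c(cfg$n_treated, cfg$n_placebo)),
    bmd_class = sample(names(cfg$bmd_mixture), n, replace = TRUE,
                       prob = cfg$bmd_mixture),
    stringsAsFactors = FALSE
  )
  roster$outlier <- stats::runif(n) < cfg$outlier_rate
  roster$outlier_type <- ifelse(
    roster$outlier,
    sample(c("subsidence", "internal_rotation", "external_rotation"), n,
           replace = TRUE, prob = c(0.6, 0.25, 0.15)),
    NA_character_)

  noise_sd <- .noise_sd(cfg)
  cutoffs <- trial_outlier_rules()
  obs <- vector("list", n)
  for (i in seq_len(n)) {
    vr <- if (roster$group[i] == "treated") sqrt(cfg$variance_reduction) else 1
    A <- vapply(RSA_AXES, function(ax) {
      mean_trajectory(ax, roster$group[i], roster$bmd_class[i], Inf, cfg) +
        stats::rnorm(1, 0, cfg$between_sd[[ax]] * vr)
    }, 0)
    if (roster$outlier[i]) {
      mult <- stats::runif(1, 1.3, 2.2)
      A <- switch(roster$outlier_type[i],
        subsidence = { A["ty"] <- cutoffs$ty["lower"] * mult; A },
        internal_rotation = { A["ry"] <- cutoffs$ry["upper"] * mult; A },
        external_rotation = { A["ry"] <- cutoffs$ry["lower"] * mult; A })
    }
    settle <- 1 - exp(-cfg$weeks / cfg$tau)
    M <- outer(settle, A) # visits x axes
    M <- M + matrix(stats::rnorm(length(M), 0, rep(noise_sd, each = length(cfg$weeks))),
                    nrow = length(cfg$weeks))
    colnames(M) <- RSA_AXES
    obs[[i]] <- data.frame(subject = roster$subject[i], week = cfg$weeks,
                           M, stringsAsFactors = FALSE)
  }
  obs <- do.call(rbind, obs)
  rownames(obs) <- NULL
  keep <- stats::runif(nrow(obs)) >= cfg$missing_rate
  obs <- obs[keep, , drop = FALSE]
  structure(list(roster = roster, observations = obs),
            class = "trial_dataset") -> ds
  attr(ds, "config") <- cfg
  ds
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat(sprintf("Synthetic RSA trial: %d subjects (%s), %d observations\n",
              nrow(x$roster),
              paste(names(table(x$roster$group)), table(x$roster$group),
                    sep = "=", collapse = ", "),
              nrow(x$observations)))
  invisible(x)
}

#' Generate a marker fixture with a known rigid motion
#'
#' Builds a trochanteric-scale marker configuration (>= 4 markers inside a
#' 50 mm sphere, guaranteed non-collinear) plus a known baseline/follow-up
#' rigid transform pair, optionally with per-marker isotropic jitter added
#' to the follow-up positions - the ground-truth fixture for testing rigid
#' fitting and QC metrics.
#'
#' @param n_markers Number of markers (default 6, minimum 4).
#' @param jitter_sd Isotropic per-coordinate jitter SD in mm (default 0).
#' @param max_rotation_deg Upper bound for each Euler angle of the true
#'   motion (default 3 degrees).
#' @return List: `markers` ([marker_set()]), `baseline`, `followup`
#'   ([rigid_transform()]s), `observed` (markers moved by the relative
#'   motion, jittered), `truth` (the relative motion as a
#'   [rigid_transform()]).
#' @export
generate_marker_fixture <- function(n_markers = 6, jitter_sd = 0,
                                    max_rotation_deg = 3) {
  stopifnot(n_markers >= 4)
  repeat {
    P <- matrix(stats::runif(n_markers * 3, -25, 25), ncol = 3)
    sv <- svd(sweep(P, 2, colMeans(P)), nu = 0, nv = 0)$d
    if (sv[2] > 5) break # comfortably non-collinear
  }
  markers <- marker_set(P)
  base <- dof6_to_transform(dof6(
    stats::runif(1, -1, 1), stats::runif(1, -1, 1), stats::runif(1, -1, 1),
    stats::runif(1, -max_rotation_deg, max_rotation_deg),
    stats::runif(1, -max_rotation_deg, max_rotation_deg),
    stats::runif(1, -max_rotation_deg, max_rotation_deg)))
  foll <- dof6_to_transform(dof6(
    stats::runif(1, -2, 2), stats::runif(1, -2, 2), stats::runif(1, -2, 2),
    stats::runif(1, -max_rotation_deg, max_rotation_deg),
    stats::runif(1, -max_rotation_deg, max_rotation_deg),
    stats::runif(1, -max_rotation_deg, max_rotation_deg)))
  R <- foll$R %*% t(base$R)
  t <- foll$t - as.numeric(R %*% base$t)
  moved <- P %*% t(R) + matrix(t, n_markers, 3, byrow = TRUE)
  if (jitter_sd > 0) {
    moved <- moved + matrix(stats::rnorm(length(moved), 0, jitter_sd),
                            ncol = 3)
  }
  list(markers = markers, baseline = base, followup = foll,
       observed = marker_set(moved, labels = rownames(markers)),
       truth = rigid_transform(R, t))
}
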