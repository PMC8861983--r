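# Monte Carlo power study: multivariate joint test versus univariate and
# surrogate t-tests under rotation of the measurement frame, plus the
# two-proportion sample-size calculator.

#' Default 6x6 migration covariance for simulations
#'
#' A documented stand-in for the (unpublished) 12-week trial covariance,
#' used when no pilot data are supplied. Variances start from the clinical
#' precision profile (SD = limit / 1.96 per axis, see
#' [RSA_PRECISION_LIMITS]), and the two dominant migration axes - y
#' translation (subsidence) and y rotation - get a biological SD multiplier
#' on top of the measurement component. Correlations are 0.3 between
#' translations and 0.2 between rotations, plus the kinematic coupling of
#' subsidence with stem rotation that real RSA data show: 0.6 between ty
#' and ry (a subsiding stem rotates about its long axis) and -0.45 between
#' ty and rz (subsidence accompanies varus/valgus tilt; the magnitude
#' follows the correlation reported between those changes in clinical
#' cohorts). This is NOT any trial's covariance: absolute simulated power
#' values depend on it, while the calibration anchors (80% at 0 degrees,
#' alpha at 90 degrees) and the qualitative method ordering do not.
#'
#' @param bio_sd_mult Numeric of length 6 (order [RSA_AXES]): multiplier on
#'   each axis SD; default `c(2, 18, 2, 2, 3, 2)` puts subsidence SD near
#'   1 mm and y-rotation SD near 1.6 degrees.
#' @param cor_translation,cor_rotation Within-block correlations.
#' @param cor_ty_ry,cor_ty_rz Cross-block couplings of subsidence with
#'   internal/external rotation and with varus/valgus tilt.
#' @return Symmetric positive-definite 6x6 matrix (mm/degree units).
#' @export
default_migration_covariance <- function(bio_sd_mult = c(2, 18, 2, 2, 3, 2),
                                         cor_translation = 0.3,
                                         cor_rotation = 0.2,
                                         cor_ty_ry = 0.6,
                                         cor_ty_rz = -0.45) {
  sds <- (RSA_PRECISION_LIMITS / 1.96) * bio_sd_mult
  C <- diag(6)
  C[1:3, 1:3][upper.tri(diag(3))] <- cor_translation
  C[1:3, 1:3][lower.tri(diag(3))] <- cor_translation
  C[4:6, 4:6][upper.tri(diag(3))] <- cor_rotation
  C[4:6, 4:6][lower.tri(diag(3))] <- cor_rotation
  C[2, 5] <- C[5, 2] <- cor_ty_ry
  C[2, 6] <- C[6, 2] <- cor_ty_rz
  if (min(eigen(C, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("default_migration_covariance: correlation matrix not positive definite")
  }
  S <- diag(sds) %*% C %*% diag(sds)
  dimnames(S) <- list(RSA_AXES, RSA_AXES)
  S
}

#' Pooled within-group covariance of the six migration axes at one week
#'
#' Models the simulation covariance from pilot RSA results: the
#' within-group sample covariance of the six migration values at the given
#' week, pooled over groups.
#'
#' @param dataset Trial dataset (`roster` + `observations`), e.g. from
#'   [generate_trial()].
#' @param week Visit week (default 12).
#' @return 6x6 pooled sample covariance (axes in [RSA_AXES] order).
#' @export
estimate_pilot_covariance <- function(dataset, week = 12) {
  obs <- dataset$observations
  obs <- obs[obs$week == week, , drop = FALSE]
  obs <- obs[stats::complete.cases(obs[RSA_AXES]), , drop = FALSE]
  if (nrow(obs) < 7) stop("estimate_pilot_covariance: need >= 7 complete subjects")
  grp <- dataset$roster$group[match(as.character(obs$subject),
                                    as.character(dataset$roster$subject))]
  grp <- factor(grp)
  S <- matrix(0, 6, 6)
  dfree <- 0
  for (g in levels(grp)) {
    Y <- as.matrix(obs[grp == g, RSA_AXES])
    if (nrow(Y) < 2) next
    S <- S + stats::cov(Y) * (nrow(Y) - 1)
    dfree <- dfree + nrow(Y) - 1
  }
  S <- S / dfree
  dimnames(S) <- list(RSA_AXES, RSA_AXES)
  S
}

#' Calibrate the subsidence mean difference to a target t-test power
#'
#' Solves the two-sample noncentral-t power equation for the mean shift in
#' y-axis translation such that a univariate t-test with `n` subjects per
#' group attains `target_power` at level `alpha`. Monotone in
#' `target_power`; doubling the SD doubles the returned shift.
#'
#' @param sigma_y Variance of y-translation (mm^2).
#' @param n Subjects per group.
#' @param alpha Two-sided significance level (default 0.05).
#' @param target_power Target power in `(alpha, 1)` (default 0.80).
#' @return Mean shift delta in mm.
#' @export
calibrate_delta <- function(sigma_y, n = 30, alpha = 0.05,
                            target_power = 0.80) {
  if (sigma_y <= 0) stop("calibrate_delta: sigma_y must be positive")
  if (target_power <= alpha || target_power >= 1) {
    stop("calibrate_delta: target_power must lie in (alpha, 1)")
  }
  stats::power.t.test(n = n, sd = sqrt(sigma_y), sig.level = alpha,
                      power = target_power, type = "two.sample",
                      alternative = "two.sided")$delta
}

# Welch two-sample t-test p-value, direct formula (hot loop; equals
# stats::t.test(x, y)$p.value, checked in the test suite)
.welch_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x) / nx; vy <- stats::var(y) / ny
  tt <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (nx - 1) + vy^2 / (ny - 1))
  2 * stats::pt(-abs(tt), df)
}

#' Joint multivariate group test for a balanced complete single-visit draw
#'
#' The closed-form path used inside the power sweep: for two complete
#' groups observed at one time point, the multivariate LMM with unstructured
#' covariance and a group x axis mean model collapses to two-sample
#' multivariate regression, and the Kenward-Roger joint test of all
#' group-involving terms is exact and equal to Hotelling's T-squared:
#' `F = (N - q - 1) / ((N - 2) q) * T^2 ~ F(q, N - q - 1)`. The equality
#' with the iterative [fit_mv_lmm()] + [kenward_roger_test()] route is part
#' of the test suite.
#'
#' @param y1,y2 Numeric matrices (subjects x axes) for the two groups.
#' @return List with `T2`, `F`, `num_df`, `denom_df`, `p`.
#' @export
mv_joint_test <- function(y1, y2) {
  y1 <- as.matrix(y1); y2 <- as.matrix(y2)
  q <- ncol(y1)
  n1 <- nrow(y1); n2 <- nrow(y2); N <- n1 + n2
  if (N - q - 1 <= 0) stop("mv_joint_test: too few subjects for ", q, " axes")
  d <- colMeans(y1) - colMeans(y2)
  S <- (crossprod(sweep(y1, 2, colMeans(y1))) +
        crossprod(sweep(y2, 2, colMeans(y2)))) / (N - 2)
  T2 <- (n1 * n2 / N) * sum(d * solve(S, d))
  Fs <- (N - q - 1) / ((N - 2) * q) * T2
  list(T2 = T2, F = Fs, num_df = q, denom_df = N - q - 1,
       p = stats::pf(Fs, q, N - q - 1, lower.tail = FALSE))
}

#' Monte Carlo configuration for the offset-angle power study
#'
#' @param n_per_group Subjects per simulated group (default 30).
#' @param alpha Significance level (default 0.05).
#' @param target_power Calibration target for the y-axis t-test at 0 degrees
#'   (default 0.80).
#' @param sigma 6x6 covariance of the migration axes; default
#'   [default_migration_covariance()].
#' @param n_iter Monte Carlo iterations per angle (default 3000).
#' @param angle_grid Offset angles in degrees (default 0 to 90 by 5).
#' @param zero_covariance If TRUE, all off-diagonal covariance entries are
#'   set to zero (the worst case for the multivariate test).
#' @return List of class `sim_config` with the calibrated `delta` included.
#' @export
sim_config <- function(n_per_group = 30, alpha = 0.05, target_power = 0.80,
                       sigma = default_migration_covariance(),
                       n_iter = 3000, angle_grid = seq(0, 90, by = 5),
                       zero_covariance = FALSE) {
  sigma <- as.matrix(sigma)
  stopifnot(all(dim(sigma) == c(6, 6)),
            max(abs(sigma - t(sigma))) < 1e-8,
            all(angle_grid >= 0 & angle_grid <= 90),
            n_per_group >= 2, n_iter >= 1)
  if (zero_covariance) sigma <- diag(diag(sigma))
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("sim_config: sigma must be positive definite")
  delta <- calibrate_delta(sigma[2, 2], n = n_per_group, alpha = alpha,
                           target_power = target_power)
  structure(list(n_per_group = n_per_group, alpha = alpha,
                 target_power = target_power, sigma = sigma,
                 n_iter = n_iter, angle_grid = angle_grid,
                 zero_covariance = zero_covariance, delta = delta),
            class = "sim_config")
}

#' One Monte Carlo iteration of the offset-angle study
#'
#' Draws the two groups from the 6-dimensional normal (group 2 shifted by
#' the calibrated delta on y-translation), rotates both groups' translation
#' and rotation triples by `angle` degrees about a fresh random unit vector
#' in the x-z plane, and records the rejection (at `cfg$alpha`) of each
#' analysis method: the Welch t-test on y-translation, the Welch t-tests on
#' total translation and total rotation (also combined as either-rejects),
#' and the joint multivariate test on all six axes.
#'
#' @param cfg A [sim_config()].
#' @param angle Offset angle in degrees.
#' @return Named logical vector: `ty_t`, `total_translation_t`,
#'   `total_rotation_t`, `surrogate_either`, `lmm_joint`.
#' @export
simulate_iteration <- function(cfg, angle) {
  n <- cfg$n_per_group
  y1 <- MASS::mvrnorm(n, mu = rep(0, 6), Sigma = cfg$sigma)
  y2 <- MASS::mvrnorm(n, mu = c(0, cfg$delta, 0, 0, 0, 0), Sigma = cfg$sigma)
  u <- random_xz_unit()
  .analyse_iteration(y1, y2, u, angle, cfg$alpha)
}

.analyse_iteration <- function(y1, y2, u, angle, alpha) {
  if (angle != 0) {
    y1 <- rotate_dof6(y1, u, angle)
    y2 <- rotate_dof6(y2, u, angle)
  }
  p_ty <- .welch_p(y1[, 2], y2[, 2])
  tt1 <- sqrt(rowSums(y1[, 1:3]^2)); tt2 <- sqrt(rowSums(y2[, 1:3]^2))
  rr1 <- sqrt(rowSums(y1[, 4:6]^2)); rr2 <- sqrt(rowSums(y2[, 4:6]^2))
  p_tt <- .welch_p(tt1, tt2)
  p_rr <- .welch_p(rr1, rr2)
  p_mv <- mv_joint_test(y1, y2)$p
  c(ty_t = p_ty < alpha,
    total_translation_t = p_tt < alpha,
    total_rotation_t = p_rr < alpha,
    surrogate_either = p_tt < alpha || p_rr < alpha,
    lmm_joint = p_mv < alpha)
}

#' Empirical power over the offset-angle grid
#'
#' Runs the full Monte Carlo study: `cfg$n_iter` iterations per angle in
#' `cfg$angle_grid`, recording each method's empirical rejection rate with
#' its binomial Monte Carlo standard error. Iterations share their random
#' draws (data and rotation axis) across the angle grid - a common-random-
#' numbers design that makes the curves directly comparable across angles -
#' so results are deterministic given the RNG state (use [set.seed()]).
#'
#' @param cfg A [sim_config()].
#' @return Object of class `power_curve`: a data frame with columns
#'   `method`, `angle`, `power`, `se`, `n_iter`; the angle-averaged power
#'   per method is in `attr(, "angle_average")`.
#' @export
power_sweep <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  methods <- c("ty_t", "total_translation_t", "total_rotation_t",
               "surrogate_either", "lmm_joint")
  ang <- cfg$angle_grid
  hits <- matrix(0, length(methods), length(ang),
                 dimnames = list(methods, ang))
  n <- cfg$n_per_group
  for (it in seq_len(cfg$n_iter)) {
    y1 <- MASS::mvrnorm(n, mu = rep(0, 6), Sigma = cfg$sigma)
    y2 <- MASS::mvrnorm(n, mu = c(0, cfg$delta, 0, 0, 0, 0),
                        Sigma = cfg$sigma)
    u <- random_xz_unit()
    for (j in seq_along(ang)) {
      hits[, j] <- hits[, j] + .analyse_iteration(y1, y2, u, ang[j], cfg$alpha)
    }
  }
  pw <- hits / cfg$n_iter
  out <- data.frame(
    method = rep(methods, times = length(ang)),
    angle = rep(ang, each = length(methods)),
    power = as.numeric(pw),
    se = as.numeric(sqrt(pw * (1 - pw) / cfg$n_iter)),
    n_iter = cfg$n_iter,
    stringsAsFactors = FALSE
  )
  class(out) <- c("power_curve", "data.frame")
  attr(out, "angle_average") <- rowMeans(pw)
  attr(out, "config") <- cfg
  out
}

#' @export
print.power_curve <- function(x, ...) {
  cat("Monte Carlo power curve (", unique(x$n_iter), " iterations/angle)\n",
      sep = "")
  cat("angle-averaged power:\n")
  print(round(attr(x, "angle_average"), 3))
  invisible(x)
}

#' Sample size for comparing two proportions
#'
#' Per-group sample size from the pooled-variance normal approximation for a
#' two-sided comparison of two independent proportions (e.g. outlier rates),
#' rounded up to an integer. Symmetric in `p1` and `p2`.
#'
#' @param p1,p2 The two proportions, distinct, in (0, 1).
#' @param alpha Two-sided significance level (default 0.05).
#' @param power Target power (default 0.80).
#' @return Integer subjects per group.
#' @examples
#' sample_size_two_proportions(6 / 32, 2 / 33) # 105
#' @export
sample_size_two_proportions <- function(p1, p2, alpha = 0.05, power = 0.80) {
  if (any(c(p1, p2) <= 0) || any(c(p1, p2) >= 1)) {
    stop("sample_size_two_proportions: proportions must lie in (0, 1)")
  }
  if (p1 == p2) stop("sample_size_two_proportions: p1 and p2 must differ")
  pbar <- (p1 + p2) / 2
  za <- stats::qnorm(1 - alpha / 2)
  zb <- stats::qnorm(power)
  n <- (za * sqrt(2 * pbar * (1 - pbar)) +
        zb * sqrt(p1 * (1 - p1) + p2 * (1 - p2)))^2 / (p1 - p2)^2
  as.integer(ceiling(n - 1e-12))
}
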