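# The multivariate REML LMM and its Kenward-Roger inference.

test_that("model frame has one row per observed subject x visit x axis cell", {
  ds <- local({ set.seed(301); complete_trial() })
  fr <- build_model_frame(ds)
  expect_equal(nrow(fr), 65 * 3 * 6) # 1170
  # removing three visit records removes 18 rows
  ds2 <- ds
  ds2$observations <- ds2$observations[-c(1, 50, 100), ]
  expect_equal(nrow(build_model_frame(ds2)), 1170 - 18)
  # the without-outliers cohort drops whole subjects
  ds3 <- local({
    set.seed(302)
    complete_trial(outlier_subjects = sprintf("S%03d", c(2, 9, 17, 23, 31, 44, 51, 60)))
  })
  fr3 <- build_model_frame(ds3, cohort = "without_outliers")
  expect_equal(nrow(fr3), 57 * 3 * 6) # 1026
  expect_length(attr(fr3, "excluded"), 8)
})

test_that("single-axis single-visit fit reproduces the pooled two-sample t-test", {
  set.seed(303)
  n1 <- 12; n2 <- 15
  y1 <- rnorm(n1); y2 <- rnorm(n2, 0.6)
  fr <- frame_from_groups(matrix(y1), matrix(y2), axes = "ty")
  tt <- t.test(y1, y2, var.equal = TRUE)
  for (cs in c("diagonal", "full_un")) {
    fit <- fit_mv_lmm(fr, cov_structure = cs,
                      control = list(gtol = 1e-10))
    kt <- kenward_roger_test(fit, "group")
    expect_equal(kt$F, unname(tt$statistic)^2, tolerance = 1e-9)
    expect_equal(kt$denom_df, n1 + n2 - 2, tolerance = 1e-9)
    expect_equal(kt$p, tt$p.value, tolerance = 1e-9)
  }
})

test_that("balanced complete 6-axis joint KR test equals Hotelling T-squared", {
  set.seed(304)
  S <- default_migration_covariance()
  y1 <- MASS::mvrnorm(16, rep(0, 6), S)
  y2 <- MASS::mvrnorm(16, c(0, 0.5, 0, 0, 0, 0), S)
  fit <- fit_mv_lmm(frame_from_groups(y1, y2), cov_structure = "full_un")
  kt <- test_3d_group_effect(fit)
  ho <- mv_joint_test(y1, y2)
  expect_equal(kt$F, ho$F, tolerance = 1e-6)
  expect_equal(kt$denom_df, ho$denom_df, tolerance = 1e-6)
  expect_equal(kt$p, ho$p, tolerance = 1e-6)
})

test_that("REML fit agrees with a gls oracle on complete single-visit data", {
  skip_if_not_installed("nlme")
  set.seed(305)
  S <- crossprod(matrix(rnorm(9), 3)) + diag(3) * 0.4
  y1 <- MASS::mvrnorm(11, rep(0, 3), S)
  y2 <- MASS::mvrnorm(13, c(0.4, 0, -0.2), S)
  fr <- frame_from_groups(y1, y2, axes = c("tx", "ty", "tz"))
  fit <- fit_mv_lmm(fr, cov_structure = "full_un",
                    control = list(gtol = 1e-10))
  fr$axis <- factor(fr$axis, levels = c("tx", "ty", "tz"))
  fr$axis_pos <- as.integer(fr$axis)
  g <- nlme::gls(value ~ group * axis, data = fr,
                 correlation = nlme::corSymm(form = ~ axis_pos | subject),
                 weights = nlme::varIdent(form = ~ 1 | axis), method = "REML")
  # same estimated within-subject covariance
  expect_equal(unname(as.matrix(nlme::getVarCov(g))), unname(fit$Sigma),
               tolerance = 1e-3)
  # same REML likelihood-ratio separation from the independence model
  # (differences cancel the parameterization-dependent constants)
  fit_d <- fit_mv_lmm(fr, cov_structure = "diagonal",
                      control = list(gtol = 1e-10))
  g_d <- nlme::gls(value ~ group * axis, data = fr,
                   weights = nlme::varIdent(form = ~ 1 | axis),
                   method = "REML")
  expect_equal(fit_d$neg2remll - fit$neg2remll,
               2 * (as.numeric(logLik(g)) - as.numeric(logLik(g_d))),
               tolerance = 1e-4)
  # same fixed-effect estimates in the cell-mean basis
  rg <- expand.grid(group = factor(c("a", "b")),
                    axis = factor(c("tx", "ty", "tz")))
  ours <- as.numeric(lsmeans(fit, c("group", "axis"))$estimate)
  theirs <- as.numeric(predict(g, rg))
  expect_equal(sort(ours), sort(theirs), tolerance = 1e-5)
})

test_that("Kronecker covariance is recovered within 10% at n = 200", {
  set.seed(306)
  nv <- 3; na <- 6
  Tm <- matrix(c(1, 0.7, 0.5, 0.7, 1.3, 0.8, 0.5, 0.8, 1.6), 3, 3)
  A <- default_migration_covariance()
  Sig <- kronecker(Tm, A)
  Y <- MASS::mvrnorm(200, rep(0, nv * na), Sig)
  fr <- frame_from_matrix(Y, c(12, 22, 48), RSA_AXES,
                          rep(c("a", "b"), each = 100))
  fit <- fit_mv_lmm(fr, cov_structure = "kronecker_un")
  expect_equal(fit$T[1, 1], 1, tolerance = 1e-9) # identifiability constraint
  rel <- norm(kronecker(fit$T, fit$A) - Sig, "F") / norm(Sig, "F")
  expect_lt(rel, 0.10)
})

test_that("the Kronecker model is nested in the full unstructured model", {
  set.seed(307)
  Y <- MASS::mvrnorm(40, rep(0, 4),
                     crossprod(matrix(rnorm(16), 4)) + diag(4) * 0.5)
  fr <- frame_from_matrix(Y, c(12, 48), c("ty", "ry"),
                          rep(c("a", "b"), each = 20))
  f_kron <- fit_mv_lmm(fr, cov_structure = "kronecker_un")
  f_full <- fit_mv_lmm(fr, cov_structure = "full_un")
  expect_lte(f_full$neg2remll, f_kron$neg2remll + 1e-6)
  # optimizer monotonicity: the accepted-objective trace never increases
  expect_true(all(diff(f_kron$trace) <= 0))
  expect_lte(f_kron$neg2remll, f_kron$trace[1])
})

test_that("the joint group test is invariant to linear maps of the axis block", {
  set.seed(308)
  y1 <- MASS::mvrnorm(14, rep(0, 4), diag(4) + 0.4)
  y2 <- MASS::mvrnorm(14, c(0.4, 0.2, 0, 0), diag(4) + 0.4)
  M <- matrix(rnorm(16), 4) + diag(4) # invertible map
  axes <- c("tx", "ty", "tz", "rx")
  p1 <- test_3d_group_effect(
    fit_mv_lmm(frame_from_groups(y1, y2, axes), cov_structure = "full_un"))$p
  p2 <- test_3d_group_effect(
    fit_mv_lmm(frame_from_groups(y1 %*% t(M), y2 %*% t(M), axes),
               cov_structure = "full_un"))$p
  expect_lt(abs(p1 - p2), 1e-8)
})

test_that("joint-test p-values are uniform under group-label permutation", {
  set.seed(309)
  n <- 30
  Y <- MASS::mvrnorm(2 * n, rep(0, 6), default_migration_covariance())
  # closed-form joint-test path (equality with the iterative fit is
  # established above at 1e-6)
  ps <- replicate(400, {
    pm <- sample(2 * n)
    mv_joint_test(Y[pm[1:n], ], Y[pm[(n + 1):(2 * n)], ])$p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("effect slices isolate the axis carrying the signal", {
  set.seed(310)
  hits <- 0; others_sig <- 0
  n_sim <- 25
  S <- diag(6) * 0.3
  for (i in seq_len(n_sim)) {
    y1 <- MASS::mvrnorm(20, rep(0, 6), S)
    y2 <- MASS::mvrnorm(20, c(0, 0, 0, 0, 0, 0.8), S) # rz only
    fit <- fit_mv_lmm(frame_from_groups(y1, y2), cov_structure = "diagonal")
    sl <- slice_by_axis(fit)
    hits <- hits + (sl$p[sl$axis == "rz"] < 0.05)
    others_sig <- others_sig + sum(sl$p[sl$axis != "rz"] < 0.05)
  }
  expect_gte(hits / n_sim, 0.9)
  # the five null axes keep roughly nominal size (binomial, 125 tries)
  expect_lte(others_sig, 18)
})

test_that("slice estimates equal raw group mean differences in balanced data", {
  set.seed(311)
  y1 <- MASS::mvrnorm(10, rep(0, 3), diag(3))
  y2 <- MASS::mvrnorm(10, rep(0.3, 3), diag(3))
  fit <- fit_mv_lmm(frame_from_groups(y1, y2, c("tx", "ty", "tz")),
                    cov_structure = "full_un")
  sl <- slice_by_axis(fit)
  expect_close(sl$estimate, colMeans(y1) - colMeans(y2), 1e-8)
  # LS-means equal cell means
  lm_ <- lsmeans(fit, c("group", "axis"))
  cm <- c(colMeans(y1), colMeans(y2))
  expect_close(sort(lm_$estimate), sort(cm), 1e-8)
})

test_that("LS-mean interval width shrinks like 1/sqrt(n)", {
  set.seed(312)
  width_at <- function(n) {
    y1 <- MASS::mvrnorm(n, rep(0, 2), diag(2))
    y2 <- MASS::mvrnorm(n, rep(0, 2), diag(2))
    fit <- fit_mv_lmm(frame_from_groups(y1, y2, c("tx", "ty")),
                      cov_structure = "full_un")
    lm_ <- lsmeans(fit, c("group", "axis"))
    mean(lm_$upper - lm_$lower)
  }
  w <- vapply(c(20, 80, 320), width_at, 0)
  expect_equal(w[1] / w[2], 2, tolerance = 0.35)
  expect_equal(w[2] / w[3], 2, tolerance = 0.35)
})

test_that("Satterthwaite df tracks the KR df on balanced slices", {
  set.seed(313)
  y1 <- MASS::mvrnorm(15, rep(0, 3), diag(3) * 0.5)
  y2 <- MASS::mvrnorm(15, rep(0.2, 3), diag(3) * 0.5)
  fit <- fit_mv_lmm(frame_from_groups(y1, y2, c("tx", "ty", "tz")),
                    cov_structure = "full_un")
  ml <- stemrsa:::.margin_L(fit, c("group", "axis"))
  l <- ml$L[1, , drop = FALSE] - ml$L[2, , drop = FALSE]
  kr_df <- kenward_roger_test(fit, l)$denom_df
  sat_df <- satterthwaite_df(fit, l)
  expect_lt(abs(kr_df - sat_df) / kr_df, 0.05)
})

test_that("backward elimination drops null interactions and keeps real ones", {
  set.seed(314)
  # strong group x axis interaction: signal on one axis only
  y1 <- MASS::mvrnorm(18, rep(0, 3), diag(3) * 0.3)
  y2 <- MASS::mvrnorm(18, c(1.2, 0, 0), diag(3) * 0.3)
  fit <- fit_mv_lmm(frame_from_groups(y1, y2, c("tx", "ty", "tz")),
                    cov_structure = "diagonal")
  simp <- simplify_model(fit)
  tl <- attr(simp$prep$terms, "term.labels")
  expect_true("group:axis" %in% tl)

  # all-null interactions collapse to main effects most of the time
  kept <- 0
  for (i in 1:10) {
    Y <- MASS::mvrnorm(30, rep(0, 4), diag(4))
    fr <- frame_from_matrix(Y, c(12, 48), c("ty", "ry"),
                            rep(c("a", "b"), each = 15))
    s <- simplify_model(fit_mv_lmm(fr, cov_structure = "diagonal"))
    tl <- attr(s$prep$terms, "term.labels")
    kept <- kept + any(grepl(":", tl))
  }
  expect_lte(kept, 3) # interactions retained in at most ~alpha-level fraction

  # main-effects-only model is returned unchanged
  fr <- frame_from_groups(matrix(rnorm(20)), matrix(rnorm(20)), axes = "ty")
  f0 <- fit_mv_lmm(fr, fixed = value ~ group, cov_structure = "diagonal")
  s0 <- simplify_model(f0)
  expect_identical(attr(s0$prep$terms, "term.labels"), "group")
  expect_equal(nrow(attr(s0, "dropped")), 0)
})

test_that("rank-deficient contrasts and degenerate frames are rejected", {
  set.seed(315)
  fr <- frame_from_groups(matrix(rnorm(10)), matrix(rnorm(10)), axes = "ty")
  fit <- fit_mv_lmm(fr, cov_structure = "diagonal")
  L <- rbind(c(0, 1), c(0, 2)) # second row redundant
  expect_error(kenward_roger_test(fit, L), "rank")
  expect_error(fit_mv_lmm(fr[fr$subject %in% c("s001", "s011"), ]),
               "2 subjects")
  bad <- fr; bad$value[1] <- NA
  expect_error(fit_mv_lmm(bad), "finite")
})
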