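# Marker QC metrics and the IQR outlier machinery.

test_that("rigid fit error is zero for exactly rigid motion and label-order invariant", {
  set.seed(201)
  for (i in 1:10) {
    fx <- generate_marker_fixture(jitter_sd = 0)
    expect_lt(rigid_fit_error(fx$markers, fx$observed), 1e-9)
    # shuffle observed rows: labels must be honoured
    perm <- sample(nrow(fx$observed))
    shuffled <- marker_set(unclass(fx$observed)[perm, ],
                           labels = rownames(fx$observed)[perm])
    expect_lt(rigid_fit_error(fx$markers, shuffled), 1e-9)
  }
  bad <- marker_set(unclass(generate_marker_fixture()$markers),
                    labels = paste0("x", 1:6))
  expect_error(rigid_fit(generate_marker_fixture()$markers, bad), "label")
})

test_that("rigid fit error matches a direct 6-parameter optimisation oracle", {
  set.seed(202)
  deg <- pi / 180
  oracle_me <- function(P, Q) {
    # brute force over rotation (Euler angles) + translation
    obj <- function(par) {
      Rx <- rbind(c(1, 0, 0), c(0, cos(par[4]), -sin(par[4])),
                  c(0, sin(par[4]), cos(par[4])))
      Ry <- rbind(c(cos(par[5]), 0, sin(par[5])), c(0, 1, 0),
                  c(-sin(par[5]), 0, cos(par[5])))
      Rz <- rbind(c(cos(par[6]), -sin(par[6]), 0),
                  c(sin(par[6]), cos(par[6]), 0), c(0, 0, 1))
      fitted <- P %*% t(Rx %*% Ry %*% Rz) +
        matrix(par[1:3], nrow(P), 3, byrow = TRUE)
      sum((fitted - Q)^2)
    }
    o <- optim(rep(0, 6), obj, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
    sqrt(o$value / (nrow(P) - 1))
  }
  for (i in 1:5) {
    fx <- generate_marker_fixture(jitter_sd = 0)
    P <- unclass(fx$markers)
    Q <- unclass(fx$observed)
    Q[1, ] <- Q[1, ] + runif(3, -0.3, 0.3) # displace one marker
    expect_equal(rigid_fit_error(fx$markers,
                                 marker_set(Q, labels = rownames(P))),
                 oracle_me(P, Q), tolerance = 1e-6)
  }
  expect_error(
    rigid_fit(marker_set(cbind(1:5, 2 * (1:5), 3 * (1:5))),
              marker_set(cbind(1:5, 2 * (1:5), 3 * (1:5)))),
    "collinear")
})

test_that("condition number follows the smallest-singular-value convention", {
  # planar circle of radius 50 plus one out-of-plane point at 50 mm
  ang <- seq(0, 2 * pi, length.out = 7)[-7]
  P <- rbind(cbind(50 * cos(ang), 50 * sin(ang), 0), c(0, 0, 50))
  m <- marker_set(P)
  # independent oracle: eigen of the centred scatter matrix
  Pc <- sweep(P, 2, colMeans(P))
  smin <- sqrt(min(eigen(crossprod(Pc), symmetric = TRUE)$values))
  expect_equal(condition_number(m), 1000 / smin, tolerance = 1e-9)
  expect_true(is.finite(condition_number(m)))
  # scaling all coordinates x2 halves CN
  expect_equal(condition_number(marker_set(2 * P)),
               condition_number(m) / 2, tolerance = 1e-9)
  # collinear -> infinite
  lin <- marker_set(cbind(1:4, 2 * (1:4), -1 * (1:4)))
  expect_identical(condition_number(lin), Inf)
})

test_that("acceptability thresholds are applied as configured", {
  expect_false(flag_unacceptable(qc_metrics(me = 0.10, cn = 80)))
  expect_true(flag_unacceptable(qc_metrics(me = 0.36, cn = 80)))
  expect_true(flag_unacceptable(qc_metrics(me = 0.10, cn = 151)))
  expect_false(flag_unacceptable(qc_metrics(me = 0.35, cn = 150))) # strict >
  expect_false(flag_unacceptable(qc_metrics(me = 0, cn = 1)))
  expect_true(flag_unacceptable(qc_metrics(me = 0.10, cn = 80),
                                thresholds = c(me = 0.05, cn = 150)))
})

test_that("IQR cutoffs use type-7 quartiles and handle degenerate samples", {
  cc <- iqr_cutoffs(1:8)
  # type-7: Q1 = 2.75, Q3 = 6.25, IQR = 3.5
  expect_equal(unname(cc), c(2.75 - 1.5 * 3.5, 6.25 + 1.5 * 3.5))
  cc2 <- iqr_cutoffs(rep(4, 10))
  expect_equal(unname(cc2), c(4, 4))
  expect_error(iqr_cutoffs(1:3), "at least 4")
})

test_that("shipped trial cutoffs flag exactly the injected outliers", {
  ds <- local({ set.seed(203); complete_trial(outlier_subjects = "S010") })
  fl <- flag_outliers(ds$observations)
  expect_identical(fl$subjects, "S010")
  expect_true(all(fl$report$axis == "ty"))
  expect_true(all(fl$report$value < -5.44))
  # nothing flagged when all values sit inside the cutoffs
  ds2 <- ds
  ds2$observations$ty <- pmax(ds2$observations$ty, -5)
  expect_length(flag_outliers(ds2$observations)$subjects, 0)
})

test_that("flag_outliers agrees with a brute-force cell scan", {
  set.seed(204)
  for (rep in 1:5) {
    n <- 20
    obs <- data.frame(subject = rep(sprintf("p%02d", 1:n), each = 3),
                      week = rep(c(12, 22, 48), n))
    for (ax in RSA_AXES) obs[[ax]] <- rnorm(3 * n, 0, 3)
    obs$ty[sample(3 * n, 3)] <- NA # missing cells must not flag
    rules <- outlier_rules(ty = c(-5.44, Inf), ry = c(-4.32, 5.52),
                           tz = c(-4, 4))
    got <- flag_outliers(obs, rules)$subjects
    want <- character()
    for (i in seq_len(nrow(obs))) {
      for (ax in names(rules)) {
        v <- obs[[ax]][i]
        if (!is.na(v) && (v < rules[[ax]]["lower"] || v > rules[[ax]]["upper"]))
          want <- c(want, obs$subject[i])
      }
    }
    expect_identical(got, sort(unique(want)))
  }
})

test_that("outlier rules survive a YAML round trip", {
  rules <- outlier_rules(ty = c(-5.44, Inf), ry = c(-4.32, 5.52))
  f <- withr::local_tempfile(fileext = ".yaml")
  write_outlier_rules(rules, f)
  back <- read_outlier_rules(f)
  expect_equal(unclass(back), unclass(rules))
})
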