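# REML engine for the hierarchical LMM with time point and migration axis as
# the two repeated measures.
#
# Marginal model: y_i ~ N(X_i beta, Sigma[idx_i, idx_i]) per subject i, where
# Sigma is the within-subject covariance over the visit x axis cells,
# structured as
#   kronecker_un : Sigma = T (x) A, T and A unstructured, T[1,1] = 1,
#   full_un      : Sigma fully unstructured,
#   diagonal     : independent cells (one variance per visit x axis cell).
# Covariance parameters are estimated by REML with a quasi-Newton (BFGS)
# search on a log-Cholesky parameterization and analytic gradients; the
# likelihood of each subject is evaluated on that subject's observed cells
# only, so case-wise missing data need no imputation.

# ---- preparation -----------------------------------------------------------

.lmm_factor_vars <- c("group", "week", "axis", "bmd_class")

.lmm_prepare <- function(frame, fixed = NULL) {
  stopifnot(is.data.frame(frame),
            all(c("subject", "group", "week", "axis", "value") %in% names(frame)))
  frame <- as.data.frame(frame)
  if (!is.factor(frame$week)) {
    wk <- frame$week
    lev <- if (is.numeric(wk)) sort(unique(wk)) else unique(wk)
    frame$week <- factor(wk, levels = lev)
  }
  if (!is.factor(frame$axis)) {
    ax <- unique(as.character(frame$axis))
    lev <- if (all(ax %in% RSA_AXES)) intersect(RSA_AXES, ax) else sort(ax)
    frame$axis <- factor(frame$axis, levels = lev)
  }
  for (v in intersect(.lmm_factor_vars, names(frame))) {
    frame[[v]] <- droplevels(factor(frame[[v]]))
  }
  frame$subject <- droplevels(factor(frame$subject))
  if (!all(is.finite(frame$value))) stop("fit_mv_lmm: non-finite responses")
  if (anyDuplicated(frame[c("subject", "week", "axis")])) {
    stop("fit_mv_lmm: more than one row per (subject, week, axis)")
  }
  if (nlevels(frame$group) < 1) stop("fit_mv_lmm: no groups")
  if (any(table(unique(frame[c("subject", "group")])$group) < 2)) {
    stop("fit_mv_lmm: need at least 2 subjects per group")
  }

  if (is.null(fixed)) fixed <- value ~ group * week * axis
  # drop variables that are constant in this frame (e.g. a single visit)
  avail <- names(frame)[vapply(frame, function(x)
    !is.factor(x) || nlevels(x) >= 2, TRUE)]
  tl <- attr(stats::terms(fixed), "term.labels")
  keep <- vapply(tl, function(t) {
    all(all.vars(stats::reformulate(t)) %in% avail)
  }, TRUE)
  tl <- tl[keep]
  fixed <- if (length(tl)) stats::reformulate(tl, response = "value")
           else value ~ 1
  trm <- stats::terms(fixed)

  contr <- lapply(intersect(all.vars(fixed), .lmm_factor_vars), function(v) "contr.sum")
  names(contr) <- intersect(all.vars(fixed), .lmm_factor_vars)
  contr <- contr[vapply(names(contr), function(v) is.factor(frame[[v]]), TRUE)]
  X <- stats::model.matrix(trm, frame,
                           contrasts.arg = if (length(contr)) contr else NULL)
  Xassign <- attr(X, "assign")
  Xnames <- colnames(X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("fit_mv_lmm: fixed-effect design is rank deficient; aliased: ",
         paste(aliased, collapse = ", "))
  }

  nv <- nlevels(frame$week); na <- nlevels(frame$axis)
  cell <- (as.integer(frame$week) - 1L) * na + as.integer(frame$axis)
  ncell <- nv * na
  cell_labels <- as.vector(t(outer(levels(frame$week), levels(frame$axis),
                                   paste, sep = ":")))

  sid <- levels(frame$subject)
  ord <- order(frame$subject, cell)
  frame_o <- frame[ord, , drop = FALSE]
  X <- X[ord, , drop = FALSE]
  cell <- cell[ord]
  y <- frame_o$value
  rows <- split(seq_along(y), frame_o$subject)

  subj <- lapply(sid, function(s) {
    r <- rows[[s]]
    list(idx = cell[r], X = X[r, , drop = FALSE], y = y[r])
  })
  names(subj) <- sid

  # collapse by missingness pattern, and within pattern by identical X
  pat_key <- vapply(subj, function(s) paste(s$idx, collapse = ","), "")
  patterns <- lapply(split(seq_along(subj), pat_key), function(is) {
    list(idx = subj[[is[1]]]$idx, members = is)
  })
  xt_key <- vapply(seq_along(subj), function(i) {
    paste(pat_key[i], paste(signif(subj[[i]]$X, 12), collapse = ","), sep = "|")
  }, "")
  xtypes <- lapply(split(seq_along(subj), xt_key), function(is) {
    list(idx = subj[[is[1]]]$idx, X = subj[[is[1]]]$X, n = length(is))
  })

  list(frame = frame_o, terms = trm, fixed = fixed, X = X, y = y,
       assign = Xassign, xnames = Xnames,
       contrasts = contr, subj = subj, patterns = patterns, xtypes = xtypes,
       nv = nv, na = na, ncell = ncell, cell_labels = cell_labels,
       n_subjects = length(sid), n_obs = length(y), p = ncol(X))
}

# moment starting covariance: cell-wise residual covariance, PD-clipped
.lmm_start_sigma <- function(prep) {
  b0 <- qr.coef(qr(prep$X), prep$y)
  r0 <- prep$y - as.numeric(prep$X %*% b0)
  Rmat <- matrix(NA_real_, prep$n_subjects, prep$ncell)
  pos <- 0L
  for (i in seq_along(prep$subj)) {
    m <- length(prep$subj[[i]]$idx)
    Rmat[i, prep$subj[[i]]$idx] <- r0[(pos + 1L):(pos + m)]
    pos <- pos + m
  }
  S <- stats::cov(Rmat, use = "pairwise.complete.obs")
  S[!is.finite(S)] <- 0
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  lo <- max(e$values[1], 1e-8) * 1e-4
  e$values[e$values < lo] <- lo
  e$vectors %*% (e$values * t(e$vectors))
}

# ---- covariance structures -------------------------------------------------

# Each structure provides: npar, init(S0), make(theta) -> Sigma,
# dmake(theta) -> list of dSigma/dtheta (log-Cholesky parameterization), and
# linear_basis(Sigma_hat) -> list(Vdot = list of ncell x ncell first
# derivatives in the linear covariance-entry basis, Vddot = list of
# list(i, j, M) second-derivative entries, or empty).

.ltri_index <- function(n) which(lower.tri(diag(n), diag = TRUE), arr.ind = TRUE)

.chol_from_theta <- function(theta, n) {
  idx <- .ltri_index(n)
  L <- matrix(0, n, n)
  v <- theta
  diag_pos <- idx[, 1] == idx[, 2]
  v[diag_pos] <- exp(v[diag_pos])
  L[idx] <- v
  L
}

.theta_from_chol <- function(L) {
  n <- nrow(L)
  idx <- .ltri_index(n)
  v <- L[idx]
  diag_pos <- idx[, 1] == idx[, 2]
  v[diag_pos] <- log(pmax(v[diag_pos], 1e-10))
  v
}

.sym_elem <- function(n, a, b) {
  E <- matrix(0, n, n)
  E[a, b] <- E[b, a] <- 1
  E
}

.structure_full_un <- function(prep) {
  n <- prep$ncell
  idx <- .ltri_index(n)
  list(
    name = "full_un",
    npar = nrow(idx),
    init = function(S0) .theta_from_chol(t(chol(S0))),
    make = function(theta) {
      L <- .chol_from_theta(theta, n)
      tcrossprod(L)
    },
    dmake = function(theta) {
      L <- .chol_from_theta(theta, n)
      lapply(seq_len(nrow(idx)), function(k) {
        a <- idx[k, 1]; b <- idx[k, 2]
        D <- matrix(0, n, n)
        D[a, b] <- if (a == b) L[a, b] else 1 # chain rule through exp on diag
        D %*% t(L) + L %*% t(D)
      })
    },
    linear_basis = function(Sigma) {
      list(Vdot = lapply(seq_len(nrow(idx)), function(k)
        .sym_elem(n, idx[k, 1], idx[k, 2])),
        Vddot = list())
    }
  )
}

.structure_diagonal <- function(prep) {
  n <- prep$ncell
  list(
    name = "diagonal",
    npar = n,
    init = function(S0) 0.5 * log(pmax(diag(S0), 1e-8)),
    make = function(theta) diag(exp(2 * theta), n),
    dmake = function(theta) {
      lapply(seq_len(n), function(k) {
        D <- matrix(0, n, n); D[k, k] <- 2 * exp(2 * theta[k]); D
      })
    },
    linear_basis = function(Sigma) {
      list(Vdot = lapply(seq_len(n), function(k) {
        E <- matrix(0, n, n); E[k, k] <- 1; E
      }), Vddot = list())
    }
  )
}

.structure_kronecker <- function(prep) {
  nv <- prep$nv; na <- prep$na
  idxT <- .ltri_index(nv); idxA <- .ltri_index(na)
  freeT <- which(!(idxT[, 1] == 1 & idxT[, 2] == 1)) # L_T[1,1] fixed at 1
  npT <- length(freeT); npA <- nrow(idxA)
  thetaT_to_L <- function(thT) {
    v <- numeric(nrow(idxT))
    v[-which(idxT[, 1] == 1 & idxT[, 2] == 1)] <- thT
    L <- matrix(0, nv, nv)
    diag_pos <- idxT[, 1] == idxT[, 2]
    v[diag_pos & seq_len(nrow(idxT)) != 1] <-
      exp(v[diag_pos & seq_len(nrow(idxT)) != 1])
    v[1] <- 1
    L[idxT] <- v
    L
  }
  list(
    name = "kronecker_un",
    npar = npT + npA,
    nv = nv, na = na, npT = npT, npA = npA,
    init = function(S0) {
      # moment split: A from averaged per-visit diagonal blocks, T from
      # block traces against A, then rescale so T[1,1] = 1
      A0 <- matrix(0, na, na)
      for (t in seq_len(nv)) {
        b <- ((t - 1) * na + 1):(t * na)
        A0 <- A0 + S0[b, b]
      }
      A0 <- A0 / nv
      Ai <- solve(A0 + diag(1e-8 * mean(diag(A0)), na))
      T0 <- matrix(0, nv, nv)
      for (t in seq_len(nv)) for (u in seq_len(nv)) {
        bt <- ((t - 1) * na + 1):(t * na); bu <- ((u - 1) * na + 1):(u * na)
        T0[t, u] <- sum(diag(Ai %*% S0[bt, bu])) / na
      }
      T0 <- (T0 + t(T0)) / 2
      eT <- eigen(T0, symmetric = TRUE)
      eT$values <- pmax(eT$values, max(eT$values) * 1e-3)
      T0 <- eT$vectors %*% (eT$values * t(eT$vectors))
      cc <- T0[1, 1]
      T0 <- T0 / cc; A0 <- A0 * cc
      LT <- t(chol(T0)); LA <- t(chol(A0))
      # renormalise so LT[1,1] = 1 exactly (chol of T0 with T0[1,1]=1 already is)
      thT_full <- numeric(nrow(idxT))
      vT <- LT[idxT]
      diag_pos <- idxT[, 1] == idxT[, 2]
      vT[diag_pos] <- log(pmax(vT[diag_pos], 1e-8))
      thT_full <- vT
      c(thT_full[freeT], .theta_from_chol(LA))
    },
    make = function(theta) {
      LT <- thetaT_to_L(theta[seq_len(npT)])
      LA <- .chol_from_theta(theta[npT + seq_len(npA)], na)
      kronecker(tcrossprod(LT), tcrossprod(LA))
    },
    make_factors = function(theta) {
      LT <- thetaT_to_L(theta[seq_len(npT)])
      LA <- .chol_from_theta(theta[npT + seq_len(npA)], na)
      list(T = tcrossprod(LT), A = tcrossprod(LA))
    },
    dmake = function(theta) {
      LT <- thetaT_to_L(theta[seq_len(npT)])
      LA <- .chol_from_theta(theta[npT + seq_len(npA)], na)
      TT <- tcrossprod(LT); AA <- tcrossprod(LA)
      out <- vector("list", npT + npA)
      for (k in seq_len(npT)) {
        a <- idxT[freeT[k], 1]; b <- idxT[freeT[k], 2]
        D <- matrix(0, nv, nv)
        D[a, b] <- if (a == b) LT[a, b] else 1
        out[[k]] <- kronecker(D %*% t(LT) + LT %*% t(D), AA)
      }
      for (k in seq_len(npA)) {
        a <- idxA[k, 1]; b <- idxA[k, 2]
        D <- matrix(0, na, na)
        D[a, b] <- if (a == b) LA[a, b] else 1
        out[[npT + k]] <- kronecker(TT, D %*% t(LA) + LA %*% t(D))
      }
      out
    },
    linear_basis = function(Sigma, theta) {
      f <- list(T = NULL, A = NULL)
      LT <- thetaT_to_L(theta[seq_len(npT)])
      LA <- .chol_from_theta(theta[npT + seq_len(npA)], na)
      f$T <- tcrossprod(LT); f$A <- tcrossprod(LA)
      # linear basis: distinct entries of T (excluding T[1,1]) and of A;
      # V is bilinear, so cross second derivatives are nonzero
      Tb <- lapply(freeT, function(k) .sym_elem(nv, idxT[k, 1], idxT[k, 2]))
      Ab <- lapply(seq_len(npA), function(k) .sym_elem(na, idxA[k, 1], idxA[k, 2]))
      Vdot <- c(lapply(Tb, function(D) kronecker(D, f$A)),
                lapply(Ab, function(D) kronecker(f$T, D)))
      Vddot <- list()
      for (i in seq_along(Tb)) for (j in seq_along(Ab)) {
        Vddot[[length(Vddot) + 1]] <-
          list(i = i, j = length(Tb) + j, M = kronecker(Tb[[i]], Ab[[j]]))
      }
      list(Vdot = Vdot, Vddot = Vddot)
    }
  )
}

.cov_structure <- function(name, prep) {
  switch(name,
         full_un = .structure_full_un(prep),
         diagonal = .structure_diagonal(prep),
         kronecker_un = .structure_kronecker(prep),
         stop("unknown covariance structure: ", name))
}

# ---- REML objective --------------------------------------------------------

# Returns -2 * restricted log-likelihood (constants dropped) and, with
# gradient = TRUE, its analytic gradient in the structural parameterization.
.reml_eval <- function(theta, prep, struct, gradient = FALSE) {
  Sigma <- struct$make(theta)
  p <- prep$p
  XtVX <- matrix(0, p, p)
  XtVy <- numeric(p)
  ldet <- 0
  ytVy <- 0
  pat <- prep$patterns
  Winv <- vector("list", length(pat))
  for (pi in seq_along(pat)) {
    idx <- pat[[pi]]$idx
    Sp <- Sigma[idx, idx, drop = FALSE]
    ch <- tryCatch(chol(Sp), error = function(e) NULL)
    if (is.null(ch)) return(list(value = 1e10, bad = TRUE))
    Wp <- chol2inv(ch)
    Winv[[pi]] <- Wp
    ld <- 2 * sum(log(diag(ch)))
    for (i in pat[[pi]]$members) {
      s <- prep$subj[[i]]
      WX <- Wp %*% s$X
      XtVX <- XtVX + crossprod(s$X, WX)
      wy <- Wp %*% s$y
      XtVy <- XtVy + as.numeric(crossprod(s$X, wy))
      ytVy <- ytVy + sum(s$y * wy)
      ldet <- ldet + ld
    }
  }
  chX <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(chX)) return(list(value = 1e10, bad = TRUE))
  beta <- backsolve(chX, forwardsolve(t(chX), XtVy))
  rss <- ytVy - sum(beta * XtVy)
  val <- ldet + 2 * sum(log(diag(chX))) + rss
  out <- list(value = val, beta = beta, Phi = chol2inv(chX),
              Sigma = Sigma, Winv = Winv, bad = FALSE)
  if (!gradient) return(out)

  Phi <- out$Phi
  dS <- struct$dmake(theta)
  K <- length(dS)
  grad <- numeric(K)
  # residual vectors u_i = Sigma_p^-1 r_i, grouped by pattern
  for (pi in seq_along(pat)) {
    idx <- pat[[pi]]$idx
    Wp <- Winv[[pi]]
    mem <- pat[[pi]]$members
    Rres <- t(vapply(mem, function(i) {
      s <- prep$subj[[i]]
      as.numeric(s$y - s$X %*% beta)
    }, numeric(length(idx))))
    if (length(idx) == 1) Rres <- matrix(Rres, ncol = 1)
    U <- Rres %*% Wp # rows u_i'
    for (k in seq_len(K)) {
      Sd <- dS[[k]][idx, idx, drop = FALSE]
      WSd <- Wp %*% Sd
      grad[k] <- grad[k] + length(mem) * sum(diag(WSd)) -
        sum((U %*% Sd) * U)
    }
  }
  # - tr(Phi * sum_i X_i' W Sd W X_i), collapsed over identical-X types
  xt_w <- vapply(prep$xtypes, function(xt) {
    for (pi in seq_along(pat)) {
      if (identical(pat[[pi]]$idx, xt$idx)) return(pi)
    }
    stop("internal: pattern not found")
  }, 0L)
  xt_U <- lapply(seq_along(prep$xtypes), function(j)
    Winv[[xt_w[j]]] %*% prep$xtypes[[j]]$X)
  for (k in seq_len(K)) {
    Gk <- matrix(0, p, p)
    for (j in seq_along(prep$xtypes)) {
      xt <- prep$xtypes[[j]]
      Gk <- Gk + xt$n *
        crossprod(xt_U[[j]], dS[[k]][xt$idx, xt$idx, drop = FALSE] %*% xt_U[[j]])
    }
    grad[k] <- grad[k] - sum(Phi * Gk)
  }
  out$gradient <- grad
  out
}

# expected Hessian of -2 restricted log-likelihood:
# H[k,l] = tr(P Vd_k P Vd_l) in the structural parameterization
.reml_expected_hessian <- function(theta, prep, struct, ev) {
  dS <- struct$dmake(theta)
  K <- length(dS)
  pat <- prep$patterns
  Winv <- ev$Winv
  Phi <- ev$Phi
  p <- prep$p
  xt_w <- vapply(prep$xtypes, function(xt) {
    for (pi in seq_along(pat)) if (identical(pat[[pi]]$idx, xt$idx)) return(pi)
    stop("internal: pattern not found")
  }, 0L)
  xt_U <- lapply(seq_along(prep$xtypes), function(j)
    Winv[[xt_w[j]]] %*% prep$xtypes[[j]]$X)
  WS <- lapply(seq_len(K), function(k) {
    lapply(seq_along(pat), function(pi) {
      idx <- pat[[pi]]$idx
      Winv[[pi]] %*% dS[[k]][idx, idx, drop = FALSE]
    })
  })
  SU <- lapply(seq_len(K), function(k) {
    lapply(seq_along(prep$xtypes), function(j) {
      idx <- prep$xtypes[[j]]$idx
      dS[[k]][idx, idx, drop = FALSE] %*% xt_U[[j]]
    })
  })
  G <- lapply(seq_len(K), function(k) {
    Gk <- matrix(0, p, p)
    for (j in seq_along(prep$xtypes)) {
      Gk <- Gk + prep$xtypes[[j]]$n * crossprod(xt_U[[j]], SU[[k]][[j]])
    }
    Gk
  })
  nmem <- vapply(pat, function(pp) length(pp$members), 0L)
  H <- matrix(0, K, K)
  for (l in seq_len(K)) for (k in seq_len(l)) {
    t1 <- 0
    for (pi in seq_along(pat)) {
      t1 <- t1 + nmem[pi] * sum(WS[[k]][[pi]] * t(WS[[l]][[pi]]))
    }
    Qkl <- matrix(0, p, p)
    for (j in seq_along(prep$xtypes)) {
      Qkl <- Qkl + prep$xtypes[[j]]$n *
        crossprod(SU[[k]][[j]], Winv[[xt_w[j]]] %*% SU[[l]][[j]])
    }
    H[k, l] <- H[l, k] <-
      t1 - 2 * sum(Phi * Qkl) + sum((Phi %*% G[[k]]) * t(Phi %*% G[[l]]))
  }
  H
}

#' Fit the multivariate migration LMM by REML
#'
#' Fits the hierarchical linear mixed model in which both the follow-up time
#' point and the migration axis are repeated measures. The within-subject
#' covariance over the visit x axis cells is estimated by REML under one of
#' three structures: a Kronecker product of an unstructured visit factor T
#' (identified by T[1,1] = 1) and an unstructured axis factor A (the
#' default, matching "unstructured for both repeated measures"), a single
#' fully unstructured matrix, or independent cells. Fixed effects default to
#' group, visit, axis and all their interactions; factors that are constant
#' in the supplied frame are dropped automatically, and factor contrasts are
#' sum-to-zero so that joint tests of a term's coefficients are Type-III
#' style. Each subject contributes the marginal likelihood of its observed
#' cells only, so missing visits need no imputation. Mixed units (mm vs
#' degrees) are absorbed by the unstructured covariance.
#'
#' @param frame Long model frame from [build_model_frame()] (or any data
#'   frame with columns subject, group, week, axis, value).
#' @param fixed Fixed-effects formula (response must be `value`); default
#'   `value ~ group * week * axis`.
#' @param cov_structure `"kronecker_un"`, `"full_un"` or `"diagonal"`.
#' @param control List: `maxit` (default 500 BFGS iterations per restart),
#'   `gtol` (gradient tolerance, default 1e-6 relative to `1 + |objective|`),
#'   `restarts` (default 3), `on_nonconvergence` (`"error"` or `"warn"`).
#' @return Object of class `stemrsa_lmm`: REML estimates (`beta`, `Sigma`,
#'   for the Kronecker structure also `T` and `A`), the naive and
#'   Kenward-Roger-adjusted fixed-effect covariances (`Phi`, `Phi_adj`), the
#'   REML criterion (`neg2remll`, the trace of accepted evaluations in
#'   `trace`), and the ingredients used by [kenward_roger_test()].
#' @seealso [kenward_roger_test()], [test_3d_group_effect()],
#'   [slice_by_axis()], [lsmeans()], [simplify_model()]
#' @export
fit_mv_lmm <- function(frame,
                       fixed = NULL,
                       cov_structure = c("kronecker_un", "full_un", "diagonal"),
                       control = list()) {
  cov_structure <- match.arg(cov_structure)
  ctl <- utils::modifyList(
    list(maxit = 500, gtol = 1e-6, restarts = 3, on_nonconvergence = "error"),
    control)
  prep <- .lmm_prepare(frame, fixed)
  struct <- .cov_structure(cov_structure, prep)
  S0 <- .lmm_start_sigma(prep)
  theta <- struct$init(S0)

  trace_env <- new.env()
  trace_env$vals <- numeric()
  fn <- function(th) {
    v <- .reml_eval(th, prep, struct)$value
    trace_env$vals <- c(trace_env$vals, v)
    v
  }
  gr <- function(th) .reml_eval(th, prep, struct, gradient = TRUE)$gradient

  conv <- FALSE; gnorm <- NA_real_; value <- Inf
  for (r in seq_len(ctl$restarts)) {
    opt <- stats::optim(theta, fn, gr, method = "BFGS",
                        control = list(maxit = ctl$maxit, reltol = 1e-14))
    theta <- opt$par
    # Fisher-scoring polish: Newton steps on the expected information to
    # drive the gradient to the tolerance (BFGS alone stalls earlier)
    for (it in seq_len(25)) {
      ev <- .reml_eval(theta, prep, struct, gradient = TRUE)
      value <- ev$value
      gnorm <- max(abs(ev$gradient))
      trace_env$vals <- c(trace_env$vals, value)
      if (gnorm < ctl$gtol * (1 + abs(value))) { conv <- TRUE; break }
      H <- .reml_expected_hessian(theta, prep, struct, ev)
      step <- tryCatch(solve(H + diag(1e-10, nrow(H)), ev$gradient),
                       error = function(e) NULL)
      if (is.null(step)) break
      ok <- FALSE
      for (h in 2^-(0:10)) {
        cand <- theta - h * step
        vc <- .reml_eval(cand, prep, struct)
        if (!vc$bad && vc$value <= value + 1e-10) {
          theta <- cand; ok <- TRUE; break
        }
      }
      if (!ok) break
    }
    if (conv) break
  }
  if (!conv) {
    msg <- sprintf(
      "fit_mv_lmm: REML did not converge (max |gradient| %.3e after %d restarts of %d iterations)",
      gnorm, ctl$restarts, ctl$maxit)
    if (ctl$on_nonconvergence == "error") stop(msg) else warning(msg)
  }

  ev <- .reml_eval(theta, prep, struct, gradient = TRUE)
  Sigma <- ev$Sigma
  dimnames(Sigma) <- list(prep$cell_labels, prep$cell_labels)
  fit <- list(
    beta = stats::setNames(ev$beta, prep$xnames),
    Phi = ev$Phi,
    Sigma = Sigma,
    theta = theta,
    structure = cov_structure,
    neg2remll = ev$value,
    converged = conv,
    grad_norm = gnorm,
    trace = cummin(trace_env$vals),
    prep = prep,
    control = ctl
  )
  if (cov_structure == "kronecker_un") {
    f <- struct$make_factors(theta)
    dimnames(f$T) <- list(levels(prep$frame$week), levels(prep$frame$week))
    dimnames(f$A) <- list(levels(prep$frame$axis), levels(prep$frame$axis))
    fit$T <- f$T; fit$A <- f$A
  }
  basis <- if (cov_structure == "kronecker_un") {
    struct$linear_basis(Sigma, theta)
  } else {
    struct$linear_basis(Sigma)
  }
  fit$kr <- .kr_ingredients(prep, ev, basis)
  fit$Phi_adj <- fit$kr$Phi_adj
  class(fit) <- "stemrsa_lmm"
  fit
}

#' @export
print.stemrsa_lmm <- function(x, ...) {
  cat("Multivariate migration LMM (REML, ", x$structure, ")\n", sep = "")
  cat(sprintf("  subjects: %d, observations: %d, cells: %d (%d visits x %d axes)\n",
              x$prep$n_subjects, x$prep$n_obs, x$prep$ncell, x$prep$nv, x$prep$na))
  cat(sprintf("  -2 restricted log-likelihood: %.3f (max |grad| %.2e)\n",
              x$neg2remll, x$grad_norm))
  cat("  fixed effects:\n")
  se <- sqrt(diag(x$Phi_adj))
  print(round(cbind(estimate = unname(x$beta), se = se), 4))
  invisible(x)
}
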