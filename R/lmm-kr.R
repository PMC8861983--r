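# Kenward-Roger small-sample adjustment.
#
# Derivatives of the marginal covariance V are taken in the linear basis of
# distinct covariance entries (for the Kronecker structure: the entries of
# the visit factor T, excluding the fixed T[1,1], and of the axis factor A;
# V = T (x) A is bilinear there, so the cross second-derivative term is kept).
# W is the inverse expected REML information of those entries at the REML
# estimate. The adjusted fixed-effect covariance and the scaled-F
# denominator degrees of freedom follow Kenward & Roger (1997).

.kr_ingredients <- function(prep, ev, basis) {
  Vdot <- basis$Vdot
  K <- length(Vdot)
  p <- prep$p
  Phi <- ev$Phi
  pat <- prep$patterns
  Winv <- ev$Winv

  # map each xtype to its pattern inverse
  xt_w <- vapply(prep$xtypes, function(xt) {
    for (pi in seq_along(pat)) if (identical(pat[[pi]]$idx, xt$idx)) return(pi)
    stop("internal: pattern not found")
  }, 0L)
  xt_U <- lapply(seq_along(prep$xtypes), function(j)
    Winv[[xt_w[j]]] %*% prep$xtypes[[j]]$X)

  # per-param, per-pattern W Sd; per-param, per-xtype Sd U
  WS <- vector("list", K)     # WS[[k]][[pi]] = W_p Sd_p
  SU <- vector("list", K)     # SU[[k]][[j]]  = Sd U_j
  G <- vector("list", K)      # G[[k]] = sum_i X' W Sd W X
  for (k in seq_len(K)) {
    WS[[k]] <- lapply(seq_along(pat), function(pi) {
      idx <- pat[[pi]]$idx
      Winv[[pi]] %*% Vdot[[k]][idx, idx, drop = FALSE]
    })
    SU[[k]] <- lapply(seq_along(prep$xtypes), function(j) {
      idx <- prep$xtypes[[j]]$idx
      Vdot[[k]][idx, idx, drop = FALSE] %*% xt_U[[j]]
    })
    Gk <- matrix(0, p, p)
    for (j in seq_along(prep$xtypes)) {
      Gk <- Gk + prep$xtypes[[j]]$n * crossprod(xt_U[[j]], SU[[k]][[j]])
    }
    G[[k]] <- Gk
  }
  npat_members <- vapply(pat, function(pp) length(pp$members), 0L)

  # expected REML information: I[k,l] = 0.5 tr(P Vd_k P Vd_l)
  # tr(P Vd P Vd) = sum_i tr(W Sd_k W Sd_l) - 2 tr(Phi Q_kl) + tr(Phi G_k Phi G_l)
  Q <- array(0, c(p, p, K * (K + 1) / 2))
  info <- matrix(0, K, K)
  pair_index <- function(k, l) { # k <= l
    (l - 1) * l / 2 + k
  }
  for (l in seq_len(K)) for (k in seq_len(l)) {
    t1 <- 0
    for (pi in seq_along(pat)) {
      t1 <- t1 + npat_members[pi] * sum(WS[[k]][[pi]] * t(WS[[l]][[pi]]))
    }
    Qkl <- matrix(0, p, p)
    for (j in seq_along(prep$xtypes)) {
      idx <- prep$xtypes[[j]]$idx
      Qkl <- Qkl + prep$xtypes[[j]]$n *
        crossprod(SU[[k]][[j]], Winv[[xt_w[j]]] %*% SU[[l]][[j]])
    }
    Q[, , pair_index(k, l)] <- Qkl
    info[k, l] <- info[l, k] <-
      0.5 * (t1 - 2 * sum(Phi * Qkl) + sum((Phi %*% G[[k]]) * t(Phi %*% G[[l]])))
  }
  Wmat <- tryCatch(solve(info), error = function(e) MASS::ginv(info))

  # second-derivative (R) term, nonzero only for Kronecker cross pairs
  Rterm <- matrix(0, p, p)
  for (dd in basis$Vddot) {
    Rij <- matrix(0, p, p)
    for (j in seq_along(prep$xtypes)) {
      idx <- prep$xtypes[[j]]$idx
      Rij <- Rij + prep$xtypes[[j]]$n *
        crossprod(xt_U[[j]], dd$M[idx, idx, drop = FALSE] %*% xt_U[[j]])
    }
    # pairs enter the double sum twice (W symmetric, R_ij = R_ji)
    Rterm <- Rterm + 2 * Wmat[dd$i, dd$j] * Rij
  }

  # adjusted covariance
  Lam <- matrix(0, p, p)
  for (l in seq_len(K)) for (k in seq_len(K)) {
    Qkl <- Q[, , pair_index(min(k, l), max(k, l))]
    if (k > l) Qkl <- t(Qkl)
    Lam <- Lam + Wmat[k, l] * (Qkl - G[[k]] %*% Phi %*% G[[l]])
  }
  Lam <- Lam - 0.25 * Rterm
  Phi_adj <- Phi + 2 * Phi %*% Lam %*% Phi
  Phi_adj <- (Phi_adj + t(Phi_adj)) / 2

  # precompute Phi G_k Phi for the degrees-of-freedom formulas
  PhiGPhi <- lapply(G, function(Gk) Phi %*% Gk %*% Phi)

  list(Phi_adj = Phi_adj, W = Wmat, PhiGPhi = PhiGPhi, Phi = Phi,
       n_covpar = K)
}

#' Kenward-Roger adjusted F-test of a fixed-effect contrast
#'
#' Tests `L beta = 0` with the small-sample adjusted Wald F-statistic: the
#' fixed-effect covariance is inflated for the uncertainty of the estimated
#' within-subject covariance, and the denominator degrees of freedom and the
#' F scale factor are obtained by matching the first two moments of the
#' statistic. In classical balanced cases the test is exact: a single
#' response and a two-group mean model give denominator df n1 + n2 - 2, and
#' the balanced complete multi-axis single-visit case reproduces the
#' two-sample Hotelling T-squared test.
#'
#' @param fit A [fit_mv_lmm()] result.
#' @param contrast Numeric contrast matrix L (q x p, p = number of fixed
#'   effect columns, see `names(fit$beta)`), or a character vector of fixed
#'   effect names (tests those coefficients jointly), or a character vector
#'   of model variable names such as `"group"` (tests all terms involving
#'   them, see [test_3d_group_effect()]).
#' @return List with `F` (scaled statistic), `num_df`, `denom_df`, `p`,
#'   `F_unscaled` and `scale`.
#' @export
kenward_roger_test <- function(fit, contrast) {
  stopifnot(inherits(fit, "stemrsa_lmm"))
  L <- .resolve_contrast(fit, contrast)
  q <- nrow(L)
  qr_ <- qr(L)
  if (qr_$rank < q) {
    stop("kenward_roger_test: rank-deficient contrast; redundant rows: ",
         paste(which(duplicated(round(t(qr.Q(qr_)), 10)))[1], collapse = ", "),
         " (rank ", qr_$rank, " < ", q, ")")
  }
  .kr_F(fit, L)
}

.kr_F <- function(fit, L) {
  kr <- fit$kr
  Phi <- kr$Phi
  q <- nrow(L)
  LPL <- L %*% Phi %*% t(L)
  Theta <- t(L) %*% solve(LPL, L)
  K <- kr$n_covpar
  Tmats <- lapply(kr$PhiGPhi, function(M) Theta %*% M)
  tvec <- vapply(Tmats, function(M) sum(diag(M)), 0)
  A1 <- as.numeric(t(tvec) %*% kr$W %*% tvec)
  # A2 = sum_kl W_kl tr(T_k T_l)
  TT <- t(vapply(Tmats, function(M) as.numeric(M), numeric(length(Phi))))
  TTt <- t(vapply(Tmats, function(M) as.numeric(t(M)), numeric(length(Phi))))
  A2 <- sum(kr$W * (TT %*% t(TTt)))

  Fraw <- as.numeric(t(fit$beta) %*% Theta_adj_stat(fit, L)) / q

  B <- (A1 + 6 * A2) / (2 * q)
  g <- ((q + 1) * A1 - (q + 4) * A2) / ((q + 2) * A2)
  if (!is.finite(g) || A2 < 1e-12) {
    # no covariance-parameter uncertainty reaches this contrast
    m <- 1e7; lambda <- 1
  } else {
    c1 <- g / (3 * q + 2 * (1 - g))
    c2 <- (q - g) / (3 * q + 2 * (1 - g))
    c3 <- (q + 2 - g) / (3 * q + 2 * (1 - g))
    Estar <- 1 / (1 - A2 / q)
    Vstar <- (2 / q) * (1 + c1 * B) / ((1 - c2 * B)^2 * (1 - c3 * B))
    rho <- Vstar / (2 * Estar^2)
    m <- 4 + (q + 2) / (q * rho - 1)
    if (!is.finite(m) || m <= 2) m <- 1e7
    lambda <- m / (Estar * (m - 2))
    if (!is.finite(lambda) || lambda <= 0) lambda <- 1
  }
  Fstat <- lambda * Fraw
  list(F = Fstat, num_df = q, denom_df = m,
       p = stats::pf(Fstat, q, m, lower.tail = FALSE),
       F_unscaled = Fraw, scale = lambda)
}

# beta' L' (L Phi_adj L')^-1 L beta, returned as the quadratic-form vector
Theta_adj_stat <- function(fit, L) {
  LPL <- L %*% fit$Phi_adj %*% t(L)
  t(L) %*% solve(LPL, L %*% fit$beta)
}

.resolve_contrast <- function(fit, contrast) {
  p <- fit$prep$p
  xnames <- fit$prep$xnames
  if (is.matrix(contrast)) {
    if (ncol(contrast) != p) stop("contrast must have ", p, " columns")
    return(contrast)
  }
  if (is.character(contrast)) {
    cols <- if (all(contrast %in% xnames)) {
      match(contrast, xnames)
    } else {
      # variable names: all columns of terms involving any of them
      tl <- attr(fit$prep$terms, "term.labels")
      hit_terms <- which(vapply(tl, function(t)
        any(all.vars(stats::reformulate(t)) %in% contrast), TRUE))
      which(fit$prep$assign %in% hit_terms)
    }
    if (!length(cols)) stop("contrast matches no fixed-effect columns")
    L <- matrix(0, length(cols), p)
    L[cbind(seq_along(cols), cols)] <- 1
    rownames(L) <- xnames[cols]
    return(L)
  }
  stop("contrast must be a matrix or character vector")
}

#' Satterthwaite denominator degrees of freedom for a 1-df contrast
#'
#' Companion approximation to [kenward_roger_test()] for single-degree
#' contrasts: `df = 2 (l' Phi l)^2 / Var(l' Phi l)` with the variance from
#' the delta method over the covariance parameters.
#'
#' @param fit A [fit_mv_lmm()] result.
#' @param l Numeric contrast vector (length p).
#' @return Denominator degrees of freedom.
#' @export
satterthwaite_df <- function(fit, l) {
  kr <- fit$kr
  l <- as.numeric(l)
  v <- as.numeric(t(l) %*% kr$Phi %*% l)
  gvec <- vapply(kr$PhiGPhi, function(M) as.numeric(t(l) %*% M %*% l), 0)
  denom <- as.numeric(t(gvec) %*% kr$W %*% gvec)
  if (denom <= 0) return(Inf)
  2 * v^2 / denom
}
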