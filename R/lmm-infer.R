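# Inference on the fitted multivariate LMM: joint 3D group comparison,
# per-axis effect slices, least-squares means, and backward model
# simplification.

# full reference grid over the model's factor variables, with one L row per
# grid point (model matrix row on the estimation contrasts)
.reference_grid <- function(fit) {
  frame <- fit$prep$frame
  vars <- intersect(all.vars(fit$prep$fixed)[-1], names(frame))
  levs <- lapply(vars, function(v) levels(frame[[v]]))
  names(levs) <- vars
  grid <- expand.grid(levs, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  for (v in vars) grid[[v]] <- factor(grid[[v]], levels = levs[[v]])
  trm <- stats::delete.response(fit$prep$terms)
  L <- stats::model.matrix(trm, grid,
                           contrasts.arg = if (length(fit$prep$contrasts))
                             fit$prep$contrasts else NULL)
  list(grid = grid, L = L, vars = vars)
}

# average the grid L rows within margin combinations (equal weights over the
# levels of the remaining factors)
.margin_L <- function(fit, margins) {
  rg <- .reference_grid(fit)
  margins <- intersect(margins, rg$vars)
  if (!length(margins)) {
    return(list(keys = data.frame(.overall = "overall"),
                L = matrix(colMeans(rg$L), 1)))
  }
  key <- do.call(paste, c(rg$grid[margins], list(sep = "\r")))
  ukeys <- unique(key)
  Lm <- t(vapply(ukeys, function(k)
    colMeans(rg$L[key == k, , drop = FALSE]), numeric(ncol(rg$L))))
  keys <- rg$grid[match(ukeys, key), margins, drop = FALSE]
  rownames(keys) <- NULL
  list(keys = keys, L = Lm)
}

#' Least-squares means with Kenward-Roger confidence intervals
#'
#' Estimated marginal means over the requested factor margins: the model
#' prediction at each margin level combination, averaged with equal weights
#' over the levels of the remaining factors. Standard errors use the
#' Kenward-Roger adjusted fixed-effect covariance, and interval degrees of
#' freedom come from the 1-df adjusted F-test of each mean. In complete
#' balanced data LS-means equal arithmetic cell means.
#'
#' @param fit A [fit_mv_lmm()] result.
#' @param margins Character vector of model factor names, e.g.
#'   `c("group", "week")` or `c("group", "axis", "week")`.
#' @param level Confidence level (default 0.95).
#' @return Data frame: margin columns, `estimate`, `se`, `df`, `lower`,
#'   `upper`.
#' @export
lsmeans <- function(fit, margins = c("group", "week"), level = 0.95) {
  stopifnot(inherits(fit, "stemrsa_lmm"))
  ml <- .margin_L(fit, margins)
  out <- ml$keys
  n <- nrow(ml$L)
  est <- as.numeric(ml$L %*% fit$beta)
  se <- df <- numeric(n)
  for (i in seq_len(n)) {
    l <- ml$L[i, , drop = FALSE]
    se[i] <- sqrt(as.numeric(l %*% fit$Phi_adj %*% t(l)))
    df[i] <- .kr_F(fit, l)$denom_df
  }
  tq <- stats::qt(1 - (1 - level) / 2, df)
  out$estimate <- est
  out$se <- se
  out$df <- df
  out$lower <- est - tq * se
  out$upper <- est + tq * se
  out
}

#' Joint Kenward-Roger test of the 3D group effect
#'
#' The "3D migration" comparison: a joint adjusted F-test that all fixed
#' effect terms involving the treatment group (main effect and any retained
#' interactions with visit and axis) are zero. Run it on the full model or
#' on the output of [simplify_model()].
#'
#' @param fit A [fit_mv_lmm()] result.
#' @return As [kenward_roger_test()], plus `terms` (the group-involving
#'   terms tested).
#' @export
test_3d_group_effect <- function(fit) {
  stopifnot(inherits(fit, "stemrsa_lmm"))
  tl <- attr(fit$prep$terms, "term.labels")
  gterms <- tl[vapply(tl, function(t)
    "group" %in% all.vars(stats::reformulate(t)), TRUE)]
  if (!length(gterms)) stop("test_3d_group_effect: model has no group terms")
  res <- kenward_roger_test(fit, "group")
  res$terms <- gterms
  res
}

#' Per-axis effect slices of the group difference
#'
#' For each migration axis, tests the between-group difference within that
#' axis (averaged with equal weights over visits and any other factors) with
#' a 1-df Kenward-Roger F-test, and reports the LS-mean difference with its
#' confidence interval. In the default group ordering the difference is
#' `first level - second level`.
#'
#' @param fit A [fit_mv_lmm()] result.
#' @param level Confidence level (default 0.95).
#' @return Data frame: `axis`, `estimate` (LS-mean difference), `se`,
#'   `num_df`, `denom_df`, `F`, `p`, `lower`, `upper`, plus the comparison
#'   label in `attr(, "comparison")`.
#' @export
slice_by_axis <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "stemrsa_lmm"))
  frame <- fit$prep$frame
  glev <- levels(frame$group)
  if (length(glev) != 2) stop("slice_by_axis: needs exactly two groups")
  ml <- .margin_L(fit, c("group", "axis"))
  axes <- levels(frame$axis)
  out <- data.frame(axis = axes, estimate = NA_real_, se = NA_real_,
                    num_df = 1, denom_df = NA_real_, F = NA_real_,
                    p = NA_real_, lower = NA_real_, upper = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(axes)) {
    r1 <- which(ml$keys$group == glev[1] & ml$keys$axis == axes[i])
    r2 <- which(ml$keys$group == glev[2] & ml$keys$axis == axes[i])
    l <- ml$L[r1, , drop = FALSE] - ml$L[r2, , drop = FALSE]
    kt <- .kr_F(fit, l)
    est <- as.numeric(l %*% fit$beta)
    se <- sqrt(as.numeric(l %*% fit$Phi_adj %*% t(l)))
    tq <- stats::qt(1 - (1 - level) / 2, kt$denom_df)
    out$estimate[i] <- est
    out$se[i] <- se
    out$denom_df[i] <- kt$denom_df
    out$F[i] <- kt$F
    out$p[i] <- kt$p
    out$lower[i] <- est - tq * se
    out$upper[i] <- est + tq * se
  }
  attr(out, "comparison") <- paste(glev[1], "-", glev[2])
  out
}

#' Backward elimination of non-significant interactions
#'
#' Simplifies the fixed-effects model by repeatedly dropping the interaction
#' term with the largest Kenward-Roger p-value at or above `alpha_keep`,
#' highest order first and preserving marginality: a term is only eligible
#' when no retained higher-order interaction contains it, and main effects
#' are never dropped. Ties in p-value are broken by term name, so the
#' procedure is deterministic.
#'
#' @param fit A [fit_mv_lmm()] result.
#' @param alpha_keep Retention threshold (default 0.05): terms with
#'   p < alpha_keep are kept.
#' @return A refitted `stemrsa_lmm` with attribute `dropped`: a data frame
#'   of eliminated terms and their p-values at removal (empty if none).
#' @export
simplify_model <- function(fit, alpha_keep = 0.05) {
  stopifnot(inherits(fit, "stemrsa_lmm"))
  frame <- fit$prep$frame
  dropped <- data.frame(term = character(), p = numeric(),
                        stringsAsFactors = FALSE)
  repeat {
    tl <- attr(fit$prep$terms, "term.labels")
    orders <- vapply(strsplit(tl, ":", fixed = TRUE), length, 0L)
    if (!any(orders > 1)) break
    contains <- function(a, b) { # is a strictly contained in b
      va <- strsplit(a, ":", fixed = TRUE)[[1]]
      vb <- strsplit(b, ":", fixed = TRUE)[[1]]
      length(va) < length(vb) && all(va %in% vb)
    }
    eligible <- vapply(seq_along(tl), function(i) {
      orders[i] > 1 && !any(vapply(tl[-i], function(b)
        contains(tl[i], b), TRUE))
    }, TRUE)
    if (!any(eligible)) break
    cand <- tl[eligible]
    pv <- vapply(cand, function(t) {
      cols <- which(fit$prep$assign == match(t, tl))
      L <- matrix(0, length(cols), fit$prep$p)
      L[cbind(seq_along(cols), cols)] <- 1
      .kr_F(fit, L)$p
    }, 0)
    ord <- order(-pv, cand)
    if (pv[ord[1]] < alpha_keep) break
    worst <- cand[ord[1]]
    dropped <- rbind(dropped,
                     data.frame(term = worst, p = pv[ord[1]],
                                stringsAsFactors = FALSE))
    newtl <- setdiff(tl, worst)
    newfixed <- if (length(newtl)) stats::reformulate(newtl, response = "value")
                else value ~ 1
    fit <- fit_mv_lmm(frame, fixed = newfixed,
                      cov_structure = fit$structure, control = fit$control)
  }
  attr(fit, "dropped") <- dropped
  fit
}
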