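# Shared helpers: small frames and datasets built in code.

# long frame for two complete groups observed at one visit (cols = axes)
frame_from_groups <- function(y1, y2, axes = RSA_AXES[seq_len(ncol(y1))],
                              week = 12) {
  n1 <- nrow(y1); n2 <- nrow(y2)
  Y <- rbind(y1, y2)
  do.call(rbind, lapply(seq_len(n1 + n2), function(i) {
    data.frame(subject = sprintf("s%03d", i),
               group = if (i <= n1) "a" else "b",
               week = week, axis = axes, value = as.numeric(Y[i, ]),
               stringsAsFactors = FALSE)
  }))
}

# complete multi-visit frame from a subjects x (visits*axes) matrix
# (visit-major column order)
frame_from_matrix <- function(Y, weeks, axes, groups) {
  n <- nrow(Y)
  do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(subject = sprintf("s%03d", i), group = groups[i],
               week = rep(weeks, each = length(axes)),
               axis = rep(axes, length(weeks)),
               value = as.numeric(Y[i, ]), stringsAsFactors = FALSE)
  }))
}

# a complete trial dataset with no randomness in structure: optional
# injected outlier subsidence values
complete_trial <- function(n_treated = 33, n_placebo = 32,
                           outlier_subjects = character()) {
  cfg <- trial_config(n_treated = n_treated, n_placebo = n_placebo,
                      outlier_rate = 0, missing_rate = 0)
  ds <- generate_trial(cfg)
  if (length(outlier_subjects)) {
    sel <- ds$observations$subject %in% outlier_subjects &
      ds$observations$week == 48
    ds$observations$ty[sel] <- -6.5
  }
  ds
}

expect_close <- function(x, y, tol) {
  expect_lt(max(abs(x - y)), tol)
}
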