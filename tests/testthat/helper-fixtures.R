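# Shared small fixtures, built in code at test time.

small_calcium_params <- function(...) {
  defaults <- list(n_neurons = 10, seed = 42L, n_frames = 80,
                   stimulus_window = c(15, 20), field_shape_px = c(96, 96))
  args <- utils::modifyList(defaults, list(...))
  do.call(calcium_sim_params, args)
}

small_mito_params <- function(...) {
  defaults <- list(n_mito = 10, seed = 42L, shape_vox = c(10, 16, 96, 96),
                   min_separation_um = 3)
  args <- utils::modifyList(defaults, list(...))
  do.call(mito_sim_params, args)
}

stack_frame_for_test <- function(st, t) calmito:::stack_frame(st, t)

# Independent brute-force oracle for the exact paired Wilcoxon p-value:
# enumerate every sign assignment explicitly and apply the two-sided
# doubling rule to the positive-rank sum.
wilcoxon_enum_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_le <- mean(w_all <= w_obs + 1e-9)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Rank-then-Pearson oracle for Spearman rho, written out long-hand.
spearman_rank_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}
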