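# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# flood-fill 8-connected labelling of a logical mask (slow, queue-based)
flood_label <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (mask[i, j] && lab[i, j] == 0L) {
      nxt <- nxt + 1L
      queue <- list(c(i, j)); lab[i, j] <- nxt
      while (length(queue)) {
        cur <- queue[[1]]; queue <- queue[-1]
        for (di in -1:1) for (dj in -1:1) {
          ii <- cur[1] + di; jj <- cur[2] + dj
          if (ii >= 1 && ii <= h && jj >= 1 && jj <= w &&
              mask[ii, jj] && lab[ii, jj] == 0L) {
            lab[ii, jj] <- nxt
            queue[[length(queue) + 1L]] <- c(ii, jj)
          }
        }
      }
    }
  }
  lab
}

# exhaustive ROI-offset search: foreground pixels inside all ROI discs for
# every integer offset in [-max_shift, max_shift]^2; returns scores + the
# set of maximizing offsets
exhaustive_roi_scores <- function(mask, layout, max_shift) {
  ctr <- eyescreen::pattern_centers(layout)
  r <- layout$pattern_diameter_px / 2
  h <- nrow(mask); w <- ncol(mask)
  xg <- matrix(rep(0:(w - 1), each = h), h, w)
  yg <- matrix(rep(0:(h - 1), times = w), h, w)
  shifts <- expand.grid(dx = -max_shift:max_shift, dy = -max_shift:max_shift)
  shifts$score <- vapply(seq_len(nrow(shifts)), function(k) {
    inside <- matrix(FALSE, h, w)
    for (p in seq_len(nrow(ctr))) {
      inside <- inside |
        ((xg - ctr$cx[p] - shifts$dx[k])^2 +
           (yg - ctr$cy[p] - shifts$dy[k])^2 <= r^2)
    }
    sum(mask & inside)
  }, numeric(1))
  shifts
}

# dense grid search of the Bernoulli-logistic log-likelihood
loglik_logistic <- function(beta0, beta1, C, y) {
  eta <- beta0 + beta1 * C
  sum(y * eta - log1p(exp(eta)))
}

grid_search_logistic <- function(C, y, beta0_grid, beta1_grid) {
  best <- c(NA, NA); best_ll <- -Inf
  for (b0 in beta0_grid) for (b1 in beta1_grid) {
    ll <- loglik_logistic(b0, b1, C, y)
    if (ll > best_ll) { best_ll <- ll; best <- c(b0, b1) }
  }
  list(beta0 = best[1], beta1 = best[2], loglik = best_ll)
}

# expected value of the rounded, truncated-below-at-1 normal cell-count law
expected_truncated_count <- function(mean, sd, kmax = 50) {
  k <- 1:kmax
  p <- pnorm(k + 0.5, mean, sd) - pnorm(k - 0.5, mean, sd)
  p[1] <- pnorm(1.5, mean, sd)         # everything below 1.5 rounds/truncates to 1
  sum(k * p) / sum(p)
}
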