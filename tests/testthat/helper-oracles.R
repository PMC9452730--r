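# Shared fixtures and independent oracles used across test files.

# One-repetition paradigm: 20 R + 40 H + 40 M + 20 R = 120 s (60 volumes
# at TR 2 s). Small enough for per-test simulation.
small_scheme <- function() {
  data.frame(condition = c("REST", "HAPPY", "MOTOR", "REST"),
             duration = c(20, 40, 40, 20))
}

small_paradigm <- function(tr = 2) build_paradigm(tr = tr, scheme = small_scheme())

small_template <- function(dim = c(10L, 12L, 10L)) tutor_template(sim_grid(dim))

# Brute-force exact Wilcoxon signed-rank p-value: explicit loop over all
# 2^n sign assignments of the observed absolute ranks. Independent of the
# package's convolution-based implementation.
wilcoxon_bruteforce <- function(differences,
                                alternative = c("two.sided", "greater",
                                                "less")) {
  alternative <- match.arg(alternative)
  d <- differences[differences != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  # every sign assignment as one row of a 2^n x n 0/1 matrix
  signs <- as.matrix(expand.grid(rep(list(0:1), n)))
  w_all <- as.vector(signs %*% r)
  hits <- switch(alternative,
                 greater = w_all >= w_obs - 1e-9,
                 less = w_all <= w_obs + 1e-9,
                 two.sided = abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
  mean(hits)
}

# Direct time-domain convolution oracle for the HRF response: convolve a
# fine-grid boxcar with the sampled double-gamma kernel by explicit
# double loop (O(n^2) sum), then sample at volume onsets.
convolution_oracle <- function(indicator, tr, dt = 0.1, hrf_duration = 32) {
  up <- round(tr / dt)
  box <- rep(indicator, each = up)
  tk <- seq(0, hrf_duration, by = dt)
  kern <- hrf_double_gamma(tk)
  kern <- kern / (sum(kern) * dt)
  n <- length(box)
  out <- numeric(n)
  for (i in seq_len(n)) {
    jmax <- min(i, length(kern))
    out[i] <- sum(box[i - seq_len(jmax) + 1] * kern[seq_len(jmax)]) * dt
  }
  out[1 + (seq_along(indicator) - 1) * up]
}

# Per-voxel brute-force effect map: explicit loop over voxels.
effect_map_oracle <- function(weights, x, y) {
  e <- numeric(ncol(x))
  for (j in seq_len(ncol(x))) {
    e[j] <- weights[j] * (mean(x[y == "HAPPY", j]) - mean(x[y == "MOTOR", j]))
  }
  e
}

# A trained tutor model on the small grid, cached per test session.
small_trained <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- experiment_config(seed = 42, grid_dim = c(10L, 12L, 10L),
                               tutor = list(n_runs = 4))
      cache <<- train_tutor_classifier(cfg)
    }
    cache
  }
})
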