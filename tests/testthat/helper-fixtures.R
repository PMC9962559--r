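# Shared fixtures: everything is generated in code at test time.

quick_acq <- function(n_echoes = 256L, noise_sigma = 0, tau = 4e-4,
                      n_scans = 1L) {
  acquisition_config(tau = tau, n_echoes = n_echoes,
                     noise_sigma = noise_sigma, n_scans = n_scans)
}

# small network that still has the 4-layer dilated shape but trains in seconds
quick_cfg <- function(epochs = 30L, target_len = 128L,
                      filters = c(8L, 8L, 16L, 16L), kernel_size = 5L,
                      ...) {
  model_config(filters = filters, kernel_size = kernel_size,
               target_len = target_len, epochs = epochs, ...)
}

# n noiseless (or low-noise) curves per class from the default generator
make_curve_set <- function(n_per_class, acq = quick_acq(), jitter = 0.02,
                           seed = 1) {
  set.seed(seed)
  prm <- default_oxidation_params(component_jitter = jitter)
  xs <- list()
  ys <- character(0)
  for (cl in oxidation_levels) {
    for (i in seq_len(n_per_class)) {
      st <- sample_oxidation_state(cl, prm[[cl]])
      xs[[length(xs) + 1]] <- simulate_cpmg_curve(st$components, acq)
      ys <- c(ys, cl)
    }
  }
  list(x = xs, y = ys)
}

# Independent brute-force oracle for the penalized non-negative inversion:
# enumerate every support set on a small grid, solve the stationarity system
# on the support, keep feasible candidates, return the best objective value
# and its solution. Deliberately naive; usable for p <= 12.
ilt_oracle <- function(K, s, a1, a2) {
  p <- ncol(K)
  A <- 2 * crossprod(K) + diag(2 * a2, p)
  b <- as.vector(2 * crossprod(K, s)) - a1
  best_obj <- sum(s^2)  # empty support
  best_f <- numeric(p)
  for (mask in seq_len(2^p - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
    fs <- tryCatch(solve(A[S, S, drop = FALSE], b[S]),
                   error = function(e) NULL)
    if (is.null(fs) || any(fs < 0)) next
    f <- numeric(p)
    f[S] <- fs
    obj <- sum((K %*% f - s)^2) + a1 * sum(f) + a2 * sum(f^2)
    if (obj < best_obj) {
      best_obj <- obj
      best_f <- f
    }
  }
  list(objective = best_obj, f = best_f)
}

expect_oxi_error <- function(expr, class = "oxirelax_invalid_input") {
  expect_error(expr, class = class)
}
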