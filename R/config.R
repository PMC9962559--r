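#' CPMG acquisition settings
#'
#' Parameters of the simulated Carr--Purcell--Meiboom--Gill echo train.
#' The k-th echo is recorded at time `2 * tau * k`, k = 1..`n_echoes`.
#'
#' @param tau Echo half-spacing in seconds. Benchtop instruments typically use
#'   200--550 microseconds; the default is 400 microseconds.
#' @param n_echoes Number of echoes in the train. Default 2048, a desk-scale
#'   setting; full-resolution acquisitions of 16384 echoes are supported and
#'   handled downstream by pooling.
#' @param noise_sigma Standard deviation of additive Gaussian noise, relative
#'   to the initial amplitude, before scan averaging.
#' @param n_scans Number of averaged scans; the effective noise standard
#'   deviation is `noise_sigma / sqrt(n_scans)`.
#' @return An object of class `"acquisition_config"`.
#' @export
acquisition_config <- function(tau = 4e-4, n_echoes = 2048L,
                               noise_sigma = 0.01, n_scans = 1L) {
  if (!is.numeric(tau) || length(tau) != 1 || !is.finite(tau) || tau <= 0)
    stop_invalid("tau must be a single positive number (seconds)")
  n_echoes <- as.integer(n_echoes)
  if (is.na(n_echoes) || n_echoes < 1L)
    stop_invalid("n_echoes must be a positive integer")
  if (!is.numeric(noise_sigma) || noise_sigma < 0)
    stop_invalid("noise_sigma must be >= 0")
  n_scans <- as.integer(n_scans)
  if (is.na(n_scans) || n_scans < 1L)
    stop_invalid("n_scans must be a positive integer")
  structure(list(tau = tau, n_echoes = n_echoes, noise_sigma = noise_sigma,
                 n_scans = n_scans),
            class = "acquisition_config")
}

#' Echo time grid of an acquisition
#'
#' @param acq An [acquisition_config()].
#' @return Numeric vector of echo times `2 * tau * (1:n_echoes)` in seconds.
#' @export
echo_times <- function(acq) 2 * acq$tau * seq_len(acq$n_echoes)

#' Relaxation component specification
#'
#' One proton population contributing `amplitude * exp(-t / t2)` to the decay.
#'
#' @param amplitude Non-negative signal fraction.
#' @param t2 Transverse relaxation time constant in seconds, positive.
#' @return An object of class `"component_spec"`.
#' @export
component_spec <- function(amplitude, t2) {
  if (!is.numeric(amplitude) || length(amplitude) != 1 || amplitude < 0)
    stop_invalid("amplitude must be a single non-negative number")
  if (!is.numeric(t2) || length(t2) != 1 || !is.finite(t2) || t2 <= 0)
    stop_invalid("t2 must be a single positive number (seconds)")
  structure(list(amplitude = amplitude, t2 = t2), class = "component_spec")
}

# Coerce a list of component_spec / 2-column data.frame into a data.frame
# with columns amplitude, t2 and validate it.
as_components <- function(components) {
  if (inherits(components, "component_spec")) components <- list(components)
  if (is.data.frame(components)) {
    df <- components[, c("amplitude", "t2")]
  } else if (is.list(components) && length(components) > 0) {
    df <- data.frame(
      amplitude = vapply(components, function(c) c$amplitude, numeric(1)),
      t2 = vapply(components, function(c) c$t2, numeric(1)))
  } else {
    stop_invalid("components must be a non-empty list of component_spec ",
                 "or a data.frame with columns amplitude, t2")
  }
  if (nrow(df) == 0) stop_invalid("component list is empty")
  if (any(df$amplitude < 0)) stop_invalid("component amplitudes must be >= 0")
  if (any(df$t2 <= 0)) stop_invalid("component t2 values must be > 0")
  df
}

#' Class-conditional oxidation state parameters
#'
#' Describes how samples of one oxidation class are drawn: the mean relaxation
#' components of the class, the per-sample relative jitter applied to them,
#' and the (closed) intervals the companion chemistry is drawn from. The
#' chemistry intervals must lie inside the diffusion/peroxide bin of the class
#' (see [classify_oxidation()]), so that generated samples re-classify to
#' their own class by construction.
#'
#' @param class_label One of `"Good"`, `"Fair"`, `"Bad"`.
#' @param component_means Mean components, as for [simulate_cpmg_curve()].
#' @param component_jitter Relative standard deviation of the per-sample
#'   multiplicative jitter applied to every component amplitude and t2.
#' @param d_range Interval for the self-diffusion coefficient D, m^2/s.
#' @param pv_range Interval for the peroxide value, mmol/kg.
#' @param pav_range Interval for the p-anisidine value (dimensionless).
#' @param cutoffs Classification cutoffs the ranges are validated against.
#' @return An object of class `"oxidation_state_params"`.
#' @export
oxidation_state_params <- function(class_label, component_means,
                                   component_jitter = 0.05,
                                   d_range, pv_range, pav_range,
                                   cutoffs = oxidation_cutoffs()) {
  class_label <- match.arg(class_label, oxidation_levels)
  component_means <- as_components(component_means)
  chk_range <- function(r, nm) {
    if (!is.numeric(r) || length(r) != 2 || any(!is.finite(r)) || r[1] > r[2])
      stop_invalid(nm, " must be a non-empty numeric interval c(lo, hi)")
  }
  chk_range(d_range, "d_range"); chk_range(pv_range, "pv_range")
  chk_range(pav_range, "pav_range")
  if (component_jitter < 0) stop_invalid("component_jitter must be >= 0")
  # both interval endpoints must classify (per criterion) to class_label
  dcl <- d_class(d_range, cutoffs)
  pcl <- pv_class(pv_range, cutoffs)
  if (any(dcl != class_label))
    stop_invalid("d_range [", d_range[1], ", ", d_range[2],
                 "] is not inside the D bin of class ", class_label)
  if (any(pcl != class_label))
    stop_invalid("pv_range [", pv_range[1], ", ", pv_range[2],
                 "] is not inside the PV bin of class ", class_label)
  structure(list(class_label = class_label,
                 component_means = component_means,
                 component_jitter = component_jitter,
                 d_range = d_range, pv_range = pv_range,
                 pav_range = pav_range, cutoffs = cutoffs),
            class = "oxidation_state_params")
}

#' Default class-conditional simulation parameters
#'
#' Default component sets for the three oxidation classes. The non-oxidized
#' class carries the four segmental-mobility components typical of a
#' triacylglycerol oil, with T2 means 0.08, 0.13, 0.19 and 0.26 s. Partial
#' oxidation shortens every T2 by 20%; high oxidation shortens them by 40% and
#' adds a short (0.02 s) oxidation-product component, with amplitudes
#' renormalized to unit total so curves remain comparable. Chemistry ranges sit
#' strictly inside the classification bins of each class.
#'
#' @param component_jitter Relative per-sample jitter, default 0.05.
#' @param cutoffs Classification cutoffs, default [oxidation_cutoffs()].
#' @return Named list of [oxidation_state_params()], one per class.
#' @export
default_oxidation_params <- function(component_jitter = 0.05,
                                     cutoffs = oxidation_cutoffs()) {
  base_t2 <- c(0.08, 0.13, 0.19, 0.26)
  base_a <- c(0.15, 0.25, 0.30, 0.30)
  comp <- function(a, t2) data.frame(amplitude = a / sum(a), t2 = t2)
  list(
    Good = oxidation_state_params(
      "Good", comp(base_a, base_t2), component_jitter,
      d_range = c(0.031e-9, 0.040e-9), pv_range = c(2, 18),
      pav_range = c(2, 10), cutoffs = cutoffs),
    Fair = oxidation_state_params(
      "Fair", comp(base_a, 0.8 * base_t2), component_jitter,
      d_range = c(0.0205e-9, 0.0295e-9), pv_range = c(22, 48),
      pav_range = c(10, 25), cutoffs = cutoffs),
    Bad = oxidation_state_params(
      "Bad", comp(c(base_a, 0.15), c(0.6 * base_t2, 0.02)), component_jitter,
      d_range = c(0.012e-9, 0.0195e-9), pv_range = c(52, 110),
      pav_range = c(25, 60), cutoffs = cutoffs))
}

#' PFGSE acquisition settings
#'
#' Pulse parameters of the pulsed-field gradient spin-echo diffusion
#' experiment. The diffusion weighting of a gradient step G is
#' `b = gamma^2 G^2 delta^2 (Delta - delta/3)`.
#'
#' @param big_delta Gradient pulse separation Delta, seconds (default 7.5 ms).
#' @param small_delta Gradient pulse duration delta, seconds (default 0.5 ms).
#' @param gradient_steps Gradient strengths G in T/m; a zero-gradient point is
#'   always included. Default 9 steps from 0 to 1.6 T/m.
#' @param gamma 1H gyromagnetic ratio, rad s^-1 T^-1 (fixed constant).
#' @return An object of class `"pfgse_config"`.
#' @export
pfgse_config <- function(big_delta = 7.5e-3, small_delta = 5e-4,
                         gradient_steps = seq(0, 1.6, length.out = 9),
                         gamma = 2.675e8) {
  if (!(big_delta > small_delta / 3) || small_delta <= 0)
    stop_invalid("requires big_delta > small_delta/3 > 0")
  if (any(gradient_steps < 0))
    stop_invalid("gradient_steps must be >= 0")
  structure(list(big_delta = big_delta, small_delta = small_delta,
                 gradient_steps = sort(unique(c(0, gradient_steps))),
                 gamma = gamma),
            class = "pfgse_config")
}

#' Diffusion weighting of a gradient strength
#'
#' @param g Gradient strength(s), T/m.
#' @param cfg A [pfgse_config()].
#' @return b-values in s/m^2, `gamma^2 g^2 delta^2 (Delta - delta/3)`.
#' @export
b_value <- function(g, cfg = pfgse_config()) {
  cfg$gamma^2 * g^2 * cfg$small_delta^2 * (cfg$big_delta - cfg$small_delta / 3)
}
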