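#' Simulate a CPMG transverse-relaxation curve
#'
#' Generates the echo-train amplitudes of a discrete multi-exponential decay,
#' `S(t_k) = sum_i a_i exp(-t_k / T2_i) + e_k`, at echo times
#' `t_k = 2 * tau * k`, with additive Gaussian noise of standard deviation
#' `noise_sigma / sqrt(n_scans)`.
#'
#' @param components Components as for [component_spec()]: a list of such
#'   objects or a data.frame with columns `amplitude` and `t2`.
#' @param acq An [acquisition_config()].
#' @param seed Optional integer seed; when `NULL` the current RNG state is
#'   used. Given a seed the curve is fully reproducible.
#' @return An object of class `"relaxation_curve"`: a data.frame with columns
#'   `time_s` and `amplitude` and the acquisition settings attached as
#'   attribute `"acq"`.
#' @examples
#' acq <- acquisition_config(n_echoes = 64, noise_sigma = 0)
#' crv <- simulate_cpmg_curve(component_spec(1, 0.1), acq)
#' @export
simulate_cpmg_curve <- function(components, acq = acquisition_config(),
                                seed = NULL) {
  comp <- as_components(components)
  if (!inherits(acq, "acquisition_config"))
    stop_invalid("acq must be an acquisition_config")
  if (!is.null(seed)) set.seed(seed)
  t <- echo_times(acq)
  s <- as.vector(exp(-outer(t, 1 / comp$t2)) %*% comp$amplitude)
  if (acq$noise_sigma > 0)
    s <- s + rnorm(length(t), 0, acq$noise_sigma / sqrt(acq$n_scans))
  structure(data.frame(time_s = t, amplitude = s),
            acq = acq, class = c("relaxation_curve", "data.frame"))
}

#' @export
print.relaxation_curve <- function(x, ...) {
  acq <- attr(x, "acq")
  cat(sprintf("CPMG relaxation curve: %d echoes, tau = %.3g s, t in [%.3g, %.3g] s\n",
              nrow(x), acq$tau, x$time_s[1], x$time_s[nrow(x)]))
  invisible(x)
}

#' @export
plot.relaxation_curve <- function(x, ..., log = "") {
  graphics::plot(x$time_s, x$amplitude, type = "l", log = log,
                 xlab = "time (s)", ylab = "amplitude", ...)
  invisible(x)
}

#' Simulate a PFGSE attenuation series
#'
#' Stejskal--Tanner attenuation of the spin-echo signal by diffusion under a
#' stepped pulsed field gradient: for each gradient strength G the relative
#' signal is `exp(-b * d)` with `b = gamma^2 G^2 delta^2 (Delta - delta/3)`,
#' plus optional additive Gaussian noise. The zero-gradient (b = 0) reference
#' point is always included with noiseless value 1.
#'
#' @param d Self-diffusion coefficient, m^2/s, positive.
#' @param cfg A [pfgse_config()].
#' @param noise_sigma Additive Gaussian noise standard deviation (relative
#'   signal units) applied to the non-reference points.
#' @param seed Optional integer seed.
#' @return A data.frame with columns `g_T_per_m`, `b_s_per_m2`, `signal`.
#' @export
simulate_pfgse <- function(d, cfg = pfgse_config(), noise_sigma = 0,
                           seed = NULL) {
  if (!is.numeric(d) || length(d) != 1 || !is.finite(d) || d <= 0)
    stop_invalid("d must be a single positive number (m^2/s)")
  if (!inherits(cfg, "pfgse_config"))
    stop_invalid("cfg must be a pfgse_config")
  if (!is.null(seed)) set.seed(seed)
  g <- cfg$gradient_steps
  b <- b_value(g, cfg)
  s <- exp(-b * d)
  if (noise_sigma > 0) {
    eps <- rnorm(length(s), 0, noise_sigma)
    eps[b == 0] <- 0  # reference point kept exact
    s <- s + eps
  }
  data.frame(g_T_per_m = g, b_s_per_m2 = b, signal = s)
}

#' Draw one oxidation state: relaxation components plus chemistry
#'
#' Samples the per-sample realization of a class: component amplitudes and T2
#' values jittered multiplicatively around the class means
#' (`x * (1 + N(0, jitter))`, truncated to stay positive), and chemistry (PV,
#' p-AV, D) drawn uniformly within the class intervals. Because the intervals
#' lie inside the classification bins, the returned chemistry always
#' re-classifies to `class_label`.
#'
#' @param class_label One of `"Good"`, `"Fair"`, `"Bad"`; must equal
#'   `params$class_label`.
#' @param params An [oxidation_state_params()].
#' @param seed Optional integer seed.
#' @return List with `components` (data.frame) and `chem` ([chem_assay()]).
#' @export
sample_oxidation_state <- function(class_label, params, seed = NULL) {
  class_label <- match.arg(class_label, oxidation_levels)
  if (!inherits(params, "oxidation_state_params"))
    stop_invalid("params must be an oxidation_state_params")
  if (params$class_label != class_label)
    stop_invalid("params are for class ", params$class_label,
                 ", not ", class_label)
  if (!is.null(seed)) set.seed(seed)
  cm <- params$component_means
  jit <- function(x) {
    f <- 1 + rnorm(length(x), 0, params$component_jitter)
    x * pmax(f, 0.05)  # keep amplitudes/T2 positive under extreme draws
  }
  comp <- data.frame(amplitude = jit(cm$amplitude), t2 = jit(cm$t2))
  chem <- chem_assay(pv = runif(1, params$pv_range[1], params$pv_range[2]),
                     pav = runif(1, params$pav_range[1], params$pav_range[2]),
                     d = runif(1, params$d_range[1], params$d_range[2]))
  list(components = comp, chem = chem)
}

# Largest-remainder apportionment of n samples to class proportions.
class_counts <- function(n, mix) {
  raw <- n * mix / sum(mix)
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

#' Generate a labeled synthetic dataset
#'
#' Produces `n` labeled samples with the requested class mixture. Each sample
#' gets its own seed (derived from `seed`), a CPMG curve, a PFGSE attenuation
#' series and a chemistry assay; its stored class is verified to re-derive
#' from the chemistry via [classify_oxidation()].
#'
#' @param n Number of samples, at least the number of represented classes.
#' @param class_mix Proportions over (Good, Fair, Bad); normalized internally.
#'   The default mirrors a 126/77/187 class balance.
#' @param acq An [acquisition_config()].
#' @param pfgse_cfg A [pfgse_config()].
#' @param params Per-class [oxidation_state_params()], as returned by
#'   [default_oxidation_params()].
#' @param pfgse_noise Noise sd of the attenuation series (default 0.005).
#' @param policy Labeling policy used for the consistency audit.
#' @param seed Integer master seed; the dataset is reproducible from it.
#' @return An object of class `"oxi_dataset"`: list with `records` (a list of
#'   sample records, each holding `sample_id`, `curve`, `pfgse`, `chem`,
#'   `true_class`, `seed`) and `manifest` (a data.frame, one row per sample).
#' @export
generate_dataset <- function(n, class_mix = c(Good = 126, Fair = 77,
                                              Bad = 187),
                             acq = acquisition_config(),
                             pfgse_cfg = pfgse_config(),
                             params = default_oxidation_params(),
                             pfgse_noise = 0.005,
                             policy = "worst_case", seed = 1L) {
  if (length(class_mix) != 3)
    stop_invalid("class_mix must have 3 entries (Good, Fair, Bad)")
  if (any(class_mix < 0) || sum(class_mix) <= 0)
    stop_invalid("class_mix must be non-negative with positive sum")
  if (abs(sum(class_mix / sum(class_mix)) - 1) > 1e-8)
    stop_invalid("class_mix does not normalize")
  counts <- class_counts(n, class_mix)
  if (n < sum(class_mix > 0) || any(counts == 0 & class_mix > 0))
    stop_invalid("n = ", n, " is too small for ", sum(class_mix > 0),
                 " classes with nonzero proportion")
  classes <- rep(oxidation_levels, counts)
  set.seed(seed)
  sample_seeds <- sample.int(.Machine$integer.max - 1L, n)
  cutoffs <- params[[1]]$cutoffs
  records <- vector("list", n)
  for (i in seq_len(n)) {
    cl <- classes[i]
    set.seed(sample_seeds[i])
    st <- sample_oxidation_state(cl, params[[cl]])
    curve <- simulate_cpmg_curve(st$components, acq)
    pf <- simulate_pfgse(st$chem$d, pfgse_cfg, noise_sigma = pfgse_noise)
    relabel <- classify_oxidation(st$chem$d, st$chem$pv, policy = policy,
                                  cutoffs = cutoffs)
    if (as.character(relabel) != cl)
      stop("internal error: generated chemistry re-classifies to ", relabel,
           " instead of ", cl)
    records[[i]] <- list(sample_id = sprintf("S%05d", i), curve = curve,
                         pfgse = pf, chem = st$chem, true_class = cl,
                         seed = sample_seeds[i])
  }
  manifest <- data.frame(
    sample_id = vapply(records, `[[`, character(1), "sample_id"),
    curve_path = NA_character_,
    class = classes,
    pv_mmol_per_kg = vapply(records, function(r) r$chem$pv, numeric(1)),
    pav = vapply(records, function(r) r$chem$pav, numeric(1)),
    totox = vapply(records, function(r) r$chem$totox, numeric(1)),
    d_m2_per_s = vapply(records, function(r) r$chem$d, numeric(1)),
    tau_s = acq$tau, n_echoes = acq$n_echoes, n_scans = acq$n_scans,
    seed = sample_seeds, stringsAsFactors = FALSE)
  structure(list(records = records, manifest = manifest, seed = seed),
            class = "oxi_dataset")
}

#' @export
print.oxi_dataset <- function(x, ...) {
  cat(sprintf("oxi_dataset: %d samples (%s)\n", nrow(x$manifest),
              paste(sprintf("%s=%d", oxidation_levels,
                            tabulate(factor(x$manifest$class,
                                            oxidation_levels), 3)),
                    collapse = ", ")))
  invisible(x)
}

#' Write a dataset to disk
#'
#' Writes one two-column CSV per curve (`time_s,amplitude`) and a JSON
#' manifest with one object per sample.
#'
#' @param dataset An [generate_dataset()] result.
#' @param dir Output directory, created if missing.
#' @return Invisibly, the manifest path.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "curves"), recursive = TRUE, showWarnings = FALSE)
  man <- dataset$manifest
  for (i in seq_along(dataset$records)) {
    r <- dataset$records[[i]]
    path <- file.path("curves", paste0(r$sample_id, ".csv"))
    write.csv(as.data.frame(r$curve)[, c("time_s", "amplitude")],
              file.path(dir, path), row.names = FALSE, quote = FALSE)
    man$curve_path[i] <- path
  }
  man_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, man_path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(man_path)
}

#' Read a relaxation curve file
#'
#' Reads a two-column delimited text file with header `time_s,amplitude`.
#'
#' @param path File path.
#' @param tau Echo half-spacing recorded in the returned acquisition metadata;
#'   inferred from the first echo time when `NULL`.
#' @return A `"relaxation_curve"` object.
#' @export
read_curve <- function(path, tau = NULL) {
  if (!file.exists(path)) stop_invalid("curve file not found: ", path)
  df <- tryCatch(read.csv(path, strip.white = TRUE),
                 error = function(e) stop_invalid(
                   "cannot parse curve file ", path, ": ", conditionMessage(e)))
  if (nrow(df) == 0 || !all(c("time_s", "amplitude") %in% names(df)))
    stop_invalid("curve file ", path,
                 " must have header 'time_s,amplitude' and at least one row")
  bad <- which(!is.finite(df$time_s) | !is.finite(df$amplitude))
  if (length(bad) > 0)
    stop_invalid("curve file ", path, ": non-numeric value at data line ",
                 bad[1])
  if (is.null(tau)) tau <- df$time_s[1] / 2
  acq <- acquisition_config(tau = tau, n_echoes = nrow(df),
                            noise_sigma = 0, n_scans = 1L)
  structure(df[, c("time_s", "amplitude")], acq = acq,
            class = c("relaxation_curve", "data.frame"))
}

#' Read a dataset manifest
#'
#' @param path Path to a `manifest.json` written by [write_dataset()].
#' @return The manifest as a data.frame.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_invalid("manifest not found: ", path)
  jsonlite::fromJSON(path)
}
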