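#' Classification cutoffs for oxidation labeling
#'
#' Bin boundaries mapping the self-diffusion coefficient D and the peroxide
#' value PV to the three ordinal classes. The default boundaries are:
#' D above 0.03e-9 m^2/s is `"Good"`, 0.02e-9 < D <= 0.03e-9 is `"Fair"`,
#' D <= 0.02e-9 is `"Bad"`; PV below 20 mmol/kg is `"Good"`, 20 <= PV < 50 is
#' `"Fair"`, PV >= 50 is `"Bad"`. Bins are half-open so every (D, PV) point
#' belongs to exactly one class per criterion. The `"prose"` preset raises the
#' Good/Fair PV boundary to 30 mmol/kg, an alternative cutoff reported for
#' linseed oil.
#'
#' @param d_good,d_bad D boundaries in m^2/s: `Good` requires `d > d_good`,
#'   `Bad` requires `d <= d_bad`.
#' @param pv_good,pv_bad PV boundaries in mmol/kg: `Good` requires
#'   `pv < pv_good`, `Bad` requires `pv >= pv_bad`.
#' @param preset `"table1"` (default) or `"prose"`.
#' @return An object of class `"oxidation_cutoffs"`.
#' @export
oxidation_cutoffs <- function(d_good = 0.03e-9, d_bad = 0.02e-9,
                              pv_good = 20, pv_bad = 50,
                              preset = c("table1", "prose")) {
  preset <- match.arg(preset)
  if (preset == "prose") pv_good <- 30
  if (!(d_bad < d_good) || !(pv_good < pv_bad))
    stop_invalid("cutoffs must satisfy d_bad < d_good and pv_good < pv_bad")
  structure(list(d_good = d_good, d_bad = d_bad,
                 pv_good = pv_good, pv_bad = pv_bad, preset = preset),
            class = "oxidation_cutoffs")
}

# Single-criterion classes (vectorized, half-open bins).
d_class <- function(d, cutoffs) {
  ifelse(d > cutoffs$d_good, "Good",
         ifelse(d > cutoffs$d_bad, "Fair", "Bad"))
}
pv_class <- function(pv, cutoffs) {
  ifelse(pv < cutoffs$pv_good, "Good",
         ifelse(pv < cutoffs$pv_bad, "Fair", "Bad"))
}

#' Total oxidation value
#'
#' TOTOX combines primary (hydroperoxide) and secondary (aldehyde) oxidation
#' products: `totox = pav + 2 * pv`. Lower is better.
#'
#' @param pv Peroxide value(s), mmol/kg, non-negative.
#' @param pav p-anisidine value(s), dimensionless, non-negative.
#' @return `pav + 2 * pv`, vectorized.
#' @export
totox <- function(pv, pav) {
  if (any(!is.finite(pv)) || any(!is.finite(pav)) ||
      any(pv < 0) || any(pav < 0))
    stop_invalid("pv and pav must be finite and non-negative")
  pav + 2 * pv
}

#' Chemistry assay record
#'
#' Bundles the wet-chemistry and diffusion measurements of one oil sample.
#' TOTOX is always recomputed from PV and p-AV, never stored independently.
#'
#' @param pv Peroxide value, mmol/kg.
#' @param pav p-anisidine value.
#' @param d Self-diffusion coefficient, m^2/s, positive.
#' @return An object of class `"chem_assay"` with fields `pv`, `pav`,
#'   `totox`, `d`.
#' @export
chem_assay <- function(pv, pav, d) {
  if (!is.numeric(d) || length(d) != 1 || !is.finite(d) || d <= 0)
    stop_invalid("d must be a single positive number (m^2/s)")
  structure(list(pv = pv, pav = pav, totox = totox(pv, pav), d = d),
            class = "chem_assay")
}

#' Classify oxidation status from diffusion and peroxide value
#'
#' Maps (D, PV) to the ordinal class. When the two criteria
#' fall in the same bin the common class is returned. When they disagree,
#' `policy` decides: `"worst_case"` (default) returns the more-oxidized of the
#' two single-criterion classes (conservative for food safety), `"d_priority"`
#' returns the class implied by D alone, and `"strict"` raises an error that
#' names both implied classes.
#'
#' @param d Self-diffusion coefficient(s), m^2/s, positive.
#' @param pv Peroxide value(s), mmol/kg, non-negative.
#' @param policy Conflict policy, see above.
#' @param cutoffs An [oxidation_cutoffs()] object.
#' @return Ordered factor with levels `Good < Fair < Bad`, same length as the
#'   (recycled) inputs.
#' @examples
#' classify_oxidation(0.035e-9, 10)  # Good
#' classify_oxidation(0.015e-9, 60)  # Bad
#' classify_oxidation(0.025e-9, 35)  # Fair
#' @export
classify_oxidation <- function(d, pv,
                               policy = c("worst_case", "d_priority",
                                          "strict"),
                               cutoffs = oxidation_cutoffs()) {
  policy <- match.arg(policy)
  if (any(!is.finite(d)) || any(d <= 0))
    stop_invalid("d must be positive and finite")
  if (any(!is.finite(pv)) || any(pv < 0))
    stop_invalid("pv must be non-negative and finite")
  n <- max(length(d), length(pv))
  d <- rep_len(d, n); pv <- rep_len(pv, n)
  dc <- as_oxidation_factor(d_class(d, cutoffs))
  pc <- as_oxidation_factor(pv_class(pv, cutoffs))
  conflict <- dc != pc
  if (policy == "strict" && any(conflict)) {
    i <- which(conflict)[1]
    stop(errorCondition(
      sprintf(paste0("conflicting criteria for sample %d: D implies '%s' ",
                     "but PV implies '%s'"), i, dc[i], pc[i]),
      class = c("oxirelax_label_conflict", "error", "condition")))
  }
  # strict reaches here only without conflicts, where dc == pc
  if (policy == "worst_case") pmax(dc, pc) else dc
}

#' Estimate the self-diffusion coefficient from PFGSE attenuation
#'
#' Fits the Stejskal--Tanner relation `log(S/S0) = -b * D` by ordinary least
#' squares of `log(signal)` on the b-value; D is the negated slope. With a
#' list of replicate series, each is fit separately and the reported D is the
#' mean of the per-replicate estimates (instrument practice is to average
#' several, typically 10, repeated measurements).
#'
#' @param series A data.frame with columns `b_s_per_m2` and `signal` (as
#'   returned by [simulate_pfgse()]), or a list of such data.frames
#'   (replicate mode).
#' @return An object of class `"d_fit"`: list with `d` (m^2/s), `r_squared`,
#'   `residual_sd`, `n_points`, `out_of_model` (TRUE when the fitted slope is
#'   non-negative, i.e. no attenuation), and in replicate mode `d_replicates`.
#' @export
estimate_d <- function(series) {
  if (is.list(series) && !is.data.frame(series)) {
    fits <- lapply(series, estimate_d)
    d_rep <- vapply(fits, function(f) f$d, numeric(1))
    out <- fits[[1]]
    out$d <- mean(d_rep)
    out$d_replicates <- d_rep
    out$r_squared <- mean(vapply(fits, function(f) f$r_squared, numeric(1)))
    out$residual_sd <- mean(vapply(fits,
                                   function(f) f$residual_sd, numeric(1)))
    out$out_of_model <- out$d <= 0
    return(out)
  }
  if (!all(c("b_s_per_m2", "signal") %in% names(series)))
    stop_invalid("series must have columns b_s_per_m2 and signal")
  b <- series$b_s_per_m2
  s <- series$signal
  if (length(unique(b)) < 2)
    stop_invalid("need at least 2 distinct b-values")
  if (any(s <= 0))
    stop_invalid("all signals must be positive to take logarithms")
  fit <- lm(log(s) ~ b)
  d <- -unname(coef(fit)[2])
  # noiseless series fit perfectly; summary.lm's reliability warning is moot
  sm <- suppressWarnings(summary(fit))
  r2 <- sm$r.squared
  oom <- d <= 0
  if (oom)
    warning("fitted slope is non-negative: no measurable attenuation, ",
            "estimate is out of model (D must be > 0)")
  structure(list(d = d, r_squared = r2,
                 residual_sd = sm$sigma,
                 n_points = length(b), out_of_model = oom),
            class = "d_fit")
}

#' @export
print.d_fit <- function(x, ...) {
  cat(sprintf("PFGSE diffusion fit: D = %.4g m^2/s (R^2 = %.4f, n = %d)\n",
              x$d, x$r_squared, x$n_points))
  if (!is.null(x$d_replicates))
    cat(sprintf("  mean of %d replicate fits\n", length(x$d_replicates)))
  if (x$out_of_model) cat("  WARNING: out of model (slope >= 0)\n")
  invisible(x)
}
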