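test_that("noiseless CPMG curves follow the analytic multi-exponential decay", {
  acq <- quick_acq(n_echoes = 10L, tau = 0.05)
  crv <- simulate_cpmg_curve(component_spec(1, 0.1), acq)
  expect_equal(crv$time_s, 2 * 0.05 * (1:10))
  # value at t = 0.1 s is exp(-1); extrapolating to t = 0 gives the total
  # amplitude sum(a_i) = 1
  expect_equal(crv$amplitude[1], exp(-1), tolerance = 1e-12)
  comps <- data.frame(amplitude = c(0.5, 0.5), t2 = c(0.05, 0.2))
  crv2 <- simulate_cpmg_curve(comps, quick_acq(n_echoes = 200L))
  mono_fast <- exp(-crv2$time_s / 0.05)
  mono_slow <- exp(-crv2$time_s / 0.2)
  # a two-component mixture lies pointwise between the pure monoexponentials
  expect_true(all(crv2$amplitude >= mono_fast - 1e-12))
  expect_true(all(crv2$amplitude <= mono_slow + 1e-12))
})

test_that("noiseless curves are positive, strictly decreasing, and bounded by the total amplitude", {
  prm <- default_oxidation_params()
  for (cl in oxidation_levels) {
    crv <- simulate_cpmg_curve(prm[[cl]]$component_means,
                               quick_acq(n_echoes = 2048L))
    expect_true(all(crv$amplitude > 0))
    expect_true(all(diff(crv$amplitude) < 0))
    expect_lte(crv$amplitude[1], sum(prm[[cl]]$component_means$amplitude))
    expect_lt(crv$amplitude[length(crv$amplitude)], 0.01)
  }
})

test_that("simulate_cpmg_curve validates inputs and is seed-deterministic", {
  expect_oxi_error(simulate_cpmg_curve(list(), quick_acq()))
  expect_oxi_error(acquisition_config(tau = 0))
  expect_oxi_error(acquisition_config(tau = -1e-4))
  a <- simulate_cpmg_curve(component_spec(1, 0.1),
                           quick_acq(noise_sigma = 0.05), seed = 9)
  b <- simulate_cpmg_curve(component_spec(1, 0.1),
                           quick_acq(noise_sigma = 0.05), seed = 9)
  expect_identical(a, b)
})

test_that("scan averaging shrinks noise like 1/sqrt(n_scans)", {
  sd_of <- function(n_scans) {
    acq <- quick_acq(n_echoes = 2048L, noise_sigma = 0.05,
                     n_scans = n_scans)
    crv <- simulate_cpmg_curve(component_spec(1, 0.1), acq, seed = 11)
    ref <- exp(-crv$time_s / 0.1)
    sd(crv$amplitude - ref)
  }
  ratio <- sd_of(1L) / sd_of(25L)
  expect_equal(ratio, 5, tolerance = 0.1)
})

test_that("PFGSE attenuation follows the Stejskal-Tanner form", {
  cfg <- pfgse_config()
  s <- simulate_pfgse(3e-11, cfg)
  expect_equal(s$signal[s$b_s_per_m2 == 0], 1)
  pos <- s$b_s_per_m2 > 0
  expect_equal(log(s$signal[pos]), -s$b_s_per_m2[pos] * 3e-11,
               tolerance = 1e-12)
  s2 <- simulate_pfgse(6e-11, cfg)
  expect_equal(log(s2$signal[pos]), 2 * log(s$signal[pos]),
               tolerance = 1e-9)
  expect_oxi_error(simulate_pfgse(-1e-11, cfg))
  expect_oxi_error(simulate_pfgse(0, cfg))
  expect_oxi_error(pfgse_config(big_delta = 1e-4, small_delta = 5e-4))
})

test_that("sampled oxidation states stay inside their class chemistry bins", {
  prm <- default_oxidation_params()
  for (seed in 1:25) {
    bad <- sample_oxidation_state("Bad", prm$Bad, seed = seed)
    expect_lte(bad$chem$d, 0.02e-9)
    expect_gte(bad$chem$pv, 50)
    good <- sample_oxidation_state("Good", prm$Good, seed = seed)
    expect_gt(good$chem$d, 0.03e-9)
    expect_lt(good$chem$pv, 20)
  }
  expect_oxi_error(sample_oxidation_state("Good", prm$Bad))
})

test_that("zero jitter reproduces the class component means exactly", {
  prm <- default_oxidation_params(component_jitter = 0)
  st <- sample_oxidation_state("Fair", prm$Fair, seed = 4)
  expect_equal(st$components, prm$Fair$component_means)
})

test_that("mean class T2 shortens with oxidation and the Bad curve lies below Good", {
  prm <- default_oxidation_params()
  mean_t2 <- vapply(prm, function(p) mean(p$component_means$t2), numeric(1))
  expect_true(mean_t2["Good"] > mean_t2["Fair"])
  expect_true(mean_t2["Fair"] > mean_t2["Bad"])
  acq <- quick_acq(n_echoes = 2048L)
  curves <- lapply(prm, function(p)
    simulate_cpmg_curve(p$component_means, acq)$amplitude)
  beyond <- 11:2048  # every echo beyond the first decade
  expect_true(all(curves$Bad[beyond] < curves$Good[beyond]))
  expect_true(all(curves$Bad[beyond] < curves$Fair[beyond]))
  expect_true(all(curves$Fair[beyond] < curves$Good[beyond]))
})

test_that("generated datasets match requested class counts and stay label-consistent", {
  ds <- generate_dataset(390, class_mix = c(126, 77, 187),
                         acq = quick_acq(n_echoes = 64L, noise_sigma = 0.01),
                         seed = 5)
  counts <- table(factor(ds$manifest$class, oxidation_levels))
  expect_equal(as.integer(counts), c(126L, 77L, 187L))
  relabel <- classify_oxidation(ds$manifest$d_m2_per_s,
                                ds$manifest$pv_mmol_per_kg)
  expect_equal(as.character(relabel), ds$manifest$class)
  expect_equal(ds$manifest$totox,
               ds$manifest$pav + 2 * ds$manifest$pv_mmol_per_kg)
  ds3 <- generate_dataset(3, class_mix = c(1, 1, 1) / 3,
                          acq = quick_acq(n_echoes = 16L), seed = 5)
  expect_equal(sort(ds3$manifest$class), sort(oxidation_levels))
  expect_oxi_error(generate_dataset(2, class_mix = c(1, 1, 1) / 3,
                                    acq = quick_acq(n_echoes = 16L)))
})

test_that("dataset generation and manifests are byte-identical under a fixed seed", {
  gen <- function() {
    ds <- generate_dataset(12, acq = quick_acq(n_echoes = 32L,
                                               noise_sigma = 0.01),
                           seed = 77)
    dir <- tempfile()
    write_dataset(ds, dir)
    paste(readLines(file.path(dir, "manifest.json")), collapse = "\n")
  }
  expect_identical(gen(), gen())
})

test_that("curve round-trip through disk preserves data and bad files raise parse errors", {
  ds <- generate_dataset(3, class_mix = c(1, 1, 1) / 3,
                         acq = quick_acq(n_echoes = 32L), seed = 2)
  dir <- tempfile()
  write_dataset(ds, dir)
  man <- read_manifest(file.path(dir, "manifest.json"))
  crv <- read_curve(file.path(dir, man$curve_path[1]))
  expect_equal(crv$amplitude, ds$records[[1]]$curve$amplitude,
               tolerance = 1e-12)
  empty <- tempfile(fileext = ".csv")
  file.create(empty)
  expect_oxi_error(read_curve(empty))
  bad <- tempfile(fileext = ".csv")
  writeLines(c("time_s,amplitude", "0.001,0.9", "0.002,oops"), bad)
  expect_oxi_error(read_curve(bad))
})
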