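# Sweep engine: grids, overrides, summaries, caching, surface IO.

short_base <- function() {
  simulation_config(t_end = 1600, burn_in = 1000, sample_dt = 0.05,
                    stimulus = field_stimulus(A = 100, f = 10))
}

fake_result <- function(rate, axes, freq = NULL) {
  lock <- if (!is.null(freq)) sweep(rate, 2, freq, "/") else rate * NA
  structure(list(axes = axes, fixed = list(),
                 rate_hz = rate, locking_ratio = lock,
                 n_spikes = round(rate * 4), n_simulated = length(rate),
                 failures = list(), base_hash = "x", timestamp = "t"),
            class = "sweep_result")
}

test_that("sweep specs validate axes and overrides", {
  expect_error(sweep_spec(list()), "1 or 2")
  expect_error(sweep_spec(list(bogus = 1:3)), "axis names")
  expect_error(sweep_spec(list(Rout = c(2, 1))), "sorted")
  expect_error(sweep_spec(list(Rout = 1:3), fixed = list(Rout = 1)),
               "not already swept")
})

test_that("overrides reach the right model components", {
  base <- short_base()
  cfg <- apply_overrides(base, list(VK = -70, Rout = 9, amplitude = 50,
                                    frequency = 25, Id = 0.5))
  expect_equal(cfg$params$VK, -70)
  expect_equal(cfg$params$Id, 0.5)
  expect_equal(cfg$circuit$RDSout, 9)
  expect_equal(cfg$stimulus$A, 50)
  expect_equal(cfg$stimulus$f, 25)
  # potassium route sets the ratio
  cfg2 <- apply_overrides(base, list(Ko = 8.5))
  expect_equal(cfg2$circuit$r, 0.15)
  # a stimulus is synthesized with conventional defaults when absent
  nostim <- simulation_config(t_end = 100, burn_in = 0)
  cfg3 <- apply_overrides(nostim, list(amplitude = 30))
  expect_equal(cfg3$stimulus$f, 10)
})

test_that("a 1x1 sweep equals the corresponding single run", {
  base <- short_base()
  sp <- sweep_spec(axes = list(Rout = 10), base = base)
  res <- run_sweep(sp)
  single <- simulate_and_analyze(apply_overrides(base, list(Rout = 10)))
  expect_equal(unname(res$rate_hz[1, 1]), single$rate_hz)
  expect_equal(unname(res$locking_ratio[1, 1]), single$locking_ratio)
})

test_that("zero amplitude is equivalent to no applied field", {
  base <- short_base()
  sp <- sweep_spec(axes = list(amplitude = 0), base = base)
  res <- run_sweep(sp)
  nofield <- simulation_config(t_end = 1600, burn_in = 1000, sample_dt = 0.05)
  expect_equal(unname(res$rate_hz[1, 1]),
               simulate_and_analyze(nofield)$rate_hz)
})

test_that("cached sweeps resume with zero new simulations", {
  base <- short_base()
  cache <- withr::local_tempdir()
  sp <- sweep_spec(axes = list(Rout = c(8, 12)), base = base,
                   cache_dir = cache)
  res1 <- run_sweep(sp)
  expect_equal(res1$n_simulated, 2L)
  res2 <- run_sweep(sp)
  expect_equal(res2$n_simulated, 0L)
  expect_identical(res2$rate_hz, res1$rate_hz)
  expect_identical(res2$locking_ratio, res1$locking_ratio)
})

test_that("axis means average over the named axis excluding missing cells", {
  m <- matrix(c(10, 30, 20, 40), 2, 2,
              dimnames = list(c("-90", "-20"), c("5", "10")))
  res <- fake_result(m, axes = list(VK = c(-90, -20), frequency = c(5, 10)),
                     freq = c(5, 10))
  expect_equal(unname(mean_rate_over_axis(res, "frequency")), c(15, 35))
  expect_equal(unname(mean_rate_over_axis(res, "VK")), c(20, 30))
  const <- fake_result(matrix(7, 2, 2), axes = list(VK = 1:2, frequency = 1:2))
  expect_equal(unname(mean_rate_over_axis(const, "frequency")), c(7, 7))
  m[1, 2] <- NA
  res$rate_hz <- m
  expect_equal(unname(mean_rate_over_axis(res, "frequency")), c(10, 35))
  expect_error(mean_rate_over_axis(res, "Rout"), "no such sweep axis")
})

test_that("locking jump threshold is the first exceedance on the amplitude axis", {
  amps <- c(0, 40, 80, 120)
  res <- fake_result(matrix(c(1, 1, 2.5, 3) * 10, 4, 1),
                     axes = list(amplitude = amps), freq = 10)
  expect_equal(locking_jump_threshold(res, level = 2), 80)
  res$locking_ratio[] <- 1
  expect_true(is.na(locking_jump_threshold(res, level = 2)))
  noamp <- fake_result(matrix(1, 1, 1), axes = list(Rout = 10))
  expect_error(locking_jump_threshold(noamp), "not a swept axis")
})

test_that("surfaces round trip through long CSV with missing cells", {
  m <- matrix(c(10, NA, 20, 40), 2, 2,
              dimnames = list(c("8", "12"), c("5", "10")))
  res <- fake_result(m, axes = list(Rout = c(8, 12), frequency = c(5, 10)),
                     freq = c(5, 10))
  res$n_spikes[is.na(m)] <- NA
  f <- withr::local_tempfile(fileext = ".csv")
  export_surface(res, f)
  expect_true(file.exists(paste0(f, ".manifest.json")))
  back <- load_surface(f)
  expect_equal(back$rate_hz, res$rate_hz)
  expect_equal(back$locking_ratio, res$locking_ratio)
  expect_true(is.na(back$rate_hz["12", "5"]))
  # schema violations are named
  g <- data.table::fread(f)
  g$rate_hz <- NULL
  data.table::fwrite(g, f)
  expect_error(load_surface(f), "rate_hz")
})
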