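test_that("noiseless isotherms invert exactly", {
  cv <- simulate_titration(25, noise_sd = 0)
  fit <- fit_kd(cv)
  expect_lt(abs(fit$kd - 25), 1e-6)
  expect_equal(fit$hill, 1)
  expect_lt(fit$rss, 1e-12)
  # half-saturation identity: f = 0.5 exactly at [P] = Kd
  cv2 <- simulate_titration(25, concentrations = c(0, 1, 10, 25, 100))
  expect_equal(cv2$fraction_bound[4], 0.5)
})

test_that("titration simulation is seeded and clipped", {
  a <- simulate_titration(25, noise_sd = 0.05, seed = 12)
  b <- simulate_titration(25, noise_sd = 0.05, seed = 12)
  expect_identical(a, b)
  expect_true(all(a$fraction_bound >= 0 & a$fraction_bound <= 1))
  c1 <- simulate_titration(25, noise_sd = 0.05, seed = 13)
  expect_false(identical(a$fraction_bound, c1$fraction_bound))
  expect_error(simulate_titration(-1), "positive")
})

test_that("curve validation rejects malformed titrations", {
  expect_error(binding_curve(c(0, 1, 2), c(0, 0.1, 0.2)), "at least 4")
  expect_error(binding_curve(c(0, 2, 1, 3), rep(0.1, 4)), "increasing")
  expect_error(binding_curve(c(0, 1, 2, 3), c(0, 0.1, 0.2, 1.2)), "\\[0, 1\\]")
  expect_error(fit_kd(binding_curve(c(0, 1, 2, 3), rep(0, 4))), "no binding")
})

test_that("Kd recovery bias vanishes as noise shrinks", {
  errs <- vapply(c(0.08, 0.02, 0.005, 0), function(sd) {
    kds <- vapply(1:40, function(r) {
      fit_kd(simulate_titration(25, noise_sd = sd, seed = 7000 + r))$kd
    }, numeric(1))
    abs(stats::median(kds) - 25) / 25
  }, numeric(1))
  expect_lt(errs[4], 1e-7)
  expect_lt(errs[3], errs[1] + 0.02)  # monotone trend, loose stochastic slack
  expect_lt(errs[2], 0.05)
})

test_that("the noiseless isotherm is monotone in [P] and in Kd", {
  P <- emsa_lane_series()
  f25 <- simulate_titration(25, P)$fraction_bound
  f75 <- simulate_titration(75, P)$fraction_bound
  expect_true(all(diff(f25) > 0))
  expect_true(all(f75[-1] < f25[-1]))  # larger Kd binds less at every [P]
})

test_that("free-Hill fitting and the exact-probe model work", {
  cv <- simulate_titration(30, noise_sd = 0, hill = 2)
  fit <- fit_kd(cv, fix_hill = FALSE)
  expect_lt(abs(fit$kd - 30) / 30, 1e-3)
  expect_lt(abs(fit$hill - 2), 1e-2)
  # exact quadratic solution reduces to the excess approximation for
  # probe << Kd, and the fit recovers the generator Kd
  cv3 <- binding_curve(emsa_lane_series(),
                       pprkit:::.isotherm_exact(emsa_lane_series(), 25, 2),
                       probe_nM = 2)
  expect_lt(abs(fit_kd(cv3, exact_probe = TRUE)$kd - 25), 1e-6)
})

test_that("bootstrap intervals bracket the point estimate and cover truth", {
  cv <- simulate_titration(25, noise_sd = 0.05, seed = 2)
  fit <- fit_kd(cv, bootstrap = 200, seed = 3)
  expect_true(fit$ci[1] <= fit$kd && fit$kd <= fit$ci[2])
  # coverage check, scaled down from the nominal 200 x 1000 design to
  # 100 replicates x 250 resamples to keep the suite fast; the criterion
  # (>= 85% coverage at sigma = 0.05) is unchanged
  covered <- vapply(1:100, function(r) {
    cvr <- simulate_titration(25, noise_sd = 0.05, seed = r)
    f <- fit_kd(cvr, bootstrap = 250, seed = r + 10000)
    f$ci[1] <= 25 && 25 <= f$ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.85)
})

test_that("titrations round-trip through TSV", {
  cv <- simulate_titration(40, noise_sd = 0.03, seed = 8)
  path <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(conc_nM = cv$conc_nM,
                                fraction_bound = cv$fraction_bound),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  cv2 <- read_binding_curve(path)
  expect_equal(cv2$conc_nM, cv$conc_nM)
  expect_equal(cv2$fraction_bound, cv$fraction_bound)
  writeLines("a\tb\n1\t2", path)
  expect_error(read_binding_curve(path), "conc_nM")
})
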