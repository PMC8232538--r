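test_that("log likelihood is exact and overflow-safe", {
  expect_equal(log_likelihood(0, 1), -log(2))
  expect_equal(log_likelihood(c(0, 0), c(1, 0)), -2 * log(2))
  # large |eta| must not overflow
  expect_equal(log_likelihood(700, 1), 0, tolerance = 1e-10)
  expect_equal(log_likelihood(-700, 0), 0, tolerance = 1e-10)
  expect_equal(log_likelihood(700, 0), -700)
  # random instance against a direct per-term evaluation at modest eta
  set.seed(81)
  eta <- rnorm(50); y <- rbinom(50, 1, 0.5)
  direct <- sum(ifelse(y == 1, log(plogis(eta)), log(1 - plogis(eta))))
  expect_equal(log_likelihood(eta, y), direct, tolerance = 1e-12)
  expect_error(log_likelihood(c(0, 0), 1), "lengths")
  expect_error(log_likelihood(0, 2), "binary")
})

test_that("Polya-Gamma draws match closed-form moments", {
  set.seed(82)
  for (z in c(0, 1.5, 4)) {
    x <- sarlogit:::rpg_vec(rep(z, 50000))
    m_true <- if (z == 0) 0.25 else tanh(z / 2) / (2 * z)
    expect_lt(abs(mean(x) - m_true), 4 * sd(x) / sqrt(50000))
  }
  x0 <- sarlogit:::rpg_vec(rep(0, 50000))
  expect_equal(var(x0), 1 / 24, tolerance = 0.03)
})

test_that("intercept-only fit on balanced data centres at zero", {
  set.seed(83)
  y <- rep(c(0, 1), 500)
  m <- sar_model("M2", fixed = list(), smooths = list(), spatial = FALSE)
  fit <- fit_sar(data.frame(sufficient = y), NULL, m,
                 sar_engine(1500, 500, seed = 84))
  s <- fit$summaries$fixed
  expect_lt(abs(s$mean), 3 * s$sd)
  expect_true(s$q2.5 <= s$mean && s$mean <= s$q97.5)
})

test_that("two regions with opposite prevalences get opposite spatial signs", {
  set.seed(85)
  n <- 800
  reg <- rep(c("a", "b"), each = n / 2)
  y <- rbinom(n, 1, ifelse(reg == "a", 0.75, 0.25))
  g <- region_graph(list(a = "b", b = "a"))
  fit <- fit_sar(data.frame(sufficient = y, region = reg), g,
                 sar_model("M1"), sar_engine(1200, 400, seed = 86))
  sp <- fit$summaries$spatial
  expect_gt(sp["a", "mean"], 0)
  expect_lt(sp["b", "mean"], 0)
  expect_equal(sp["a", "mean"], -sp["b", "mean"], tolerance = 1e-10)
  expect_equal(sum(colMeans(fit$draws$spatial)), 0, tolerance = 1e-10)
})

test_that("identical seed and settings reproduce summaries exactly", {
  sim <- simulate_dataset(sim_config(n_women = 400), seed = 87)
  m <- sar_model("M2", fixed = default_fixed_levels()["residence"],
                 smooths = list(sar_smooth("age", k = 8)))
  # 400 iterations suffice for a determinism check; ESS warnings expected
  f1 <- suppressWarnings(
    fit_sar(sim$records, sim$graph, m, sar_engine(400, 100, seed = 88)))
  f2 <- suppressWarnings(
    fit_sar(sim$records, sim$graph, m, sar_engine(400, 100, seed = 88)))
  expect_identical(f1$summaries, f2$summaries)
  expect_identical(f1$draws$deviance, f2$draws$deviance)
})

test_that("posterior summaries respect quantile ordering in every block", {
  sim <- simulate_dataset(sim_config(n_women = 600), seed = 89)
  m <- sar_model("M3", fixed = default_fixed_levels()["wealth"],
                 smooths = list(sar_smooth("age", k = 8)))
  fit <- fit_sar(sim$records, sim$graph, m, sar_engine(500, 150, seed = 90))
  for (blk in fit$summaries) {
    if (is.null(blk)) next
    expect_true(all(blk$q2.5 <= blk$mean + 1e-12))
    expect_true(all(blk$mean <= blk$q97.5 + 1e-12))
  }
})

test_that("fixed-effect posteriors are insensitive to the vague prior scale", {
  sim <- simulate_dataset(sim_config(
    n_women = 5000, smooths = list(), tau2_spatial = 0.2,
    sd_household = 0, sd_community = 0), seed = 91)
  base <- default_fixed_levels()[c("residence", "education")]
  m1 <- sar_model("M2", fixed = base, smooths = list(),
                  priors = sar_priors(fixed_prec = 1e-6))
  m2 <- sar_model("M2", fixed = base, smooths = list(),
                  priors = sar_priors(fixed_prec = 5e-7))  # doubled variance
  f1 <- fit_sar(sim$records, sim$graph, m1, sar_engine(700, 200, seed = 92))
  f2 <- fit_sar(sim$records, sim$graph, m2, sar_engine(700, 200, seed = 92))
  expect_lt(max(abs(f1$summaries$fixed$mean - f2$summaries$fixed$mean)), 0.01)
})

test_that("odds-ratio transform treats draws and summaries correctly", {
  z <- posterior_transform_or(draws = rep(0, 100))
  expect_equal(z$mean, 1)
  expect_equal(c(z$q2.5, z$q97.5), c(1, 1))
  expect_false(z$approximate_mean)
  # lognormal closed form: draws from N(0.2, 0.05^2)
  set.seed(93)
  d <- rnorm(200000, 0.2, 0.05)
  o <- posterior_transform_or(draws = d)
  expect_equal(o$q2.5, exp(qnorm(0.025, 0.2, 0.05)), tolerance = 0.002)
  expect_equal(o$q97.5, exp(qnorm(0.975, 0.2, 0.05)), tolerance = 0.002)
  expect_equal(o$mean, exp(0.2 + 0.05^2 / 2), tolerance = 0.002)
  # summary-only route flags the approximate mean
  a <- posterior_transform_or(summary = c(mean = 0.2, q2.5 = 0.1, q97.5 = 0.3))
  expect_true(a$approximate_mean)
  expect_equal(a$q2.5, exp(0.1))
  expect_error(posterior_transform_or(), "draws or summary")
})

test_that("validation errors are raised before sampling", {
  sim <- simulate_dataset(sim_config(n_women = 100), seed = 94)
  m <- sar_model("M1")
  expect_error(fit_sar(sim$records, NULL, m, sar_engine(10, 5, seed = 1)),
               "region_graph")
  small_g <- region_graph(list(a = "b", b = "a"))
  expect_error(fit_sar(sim$records, small_g, m, sar_engine(10, 5, seed = 1)),
               "absent from the graph")
  bad <- sim$records
  bad$sufficient[1] <- NA
  expect_error(fit_sar(bad, sim$graph, m, sar_engine(10, 5, seed = 1)),
               "complete")
  expect_error(sar_engine(100, 50), "seed")
})
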