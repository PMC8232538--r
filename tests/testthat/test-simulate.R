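test_that("ICAR field draws satisfy the sum-to-zero constraint", {
  g <- make_lattice_graph(3, 3)
  f <- sample_icar_field(g, tau2 = 1, seed = 51)
  expect_equal(sum(f), 0, tolerance = 1e-10)
  # two regions: the values are negatives of each other
  g2 <- region_graph(list(a = "b", b = "a"))
  f2 <- sample_icar_field(g2, tau2 = 2, seed = 52)
  expect_equal(f2[["a"]], -f2[["b"]])
})

test_that("ICAR draw covariance matches the pseudo-inverse oracle", {
  g <- make_lattice_graph(2, 3)
  Q <- icar_precision(g)
  tau2 <- 0.8
  # constrained generalized inverse of Q / tau2
  eg <- eigen(Q, symmetric = TRUE)
  V <- eg$vectors[, 1:5]
  Sigma <- tau2 * V %*% diag(1 / eg$values[1:5]) %*% t(V)
  set.seed(53)
  draws <- t(replicate(10000, sample_icar_field(g, tau2)))
  emp <- cov(draws)
  expect_lt(max(abs(emp - Sigma)), 0.05)
  expect_lt(max(abs(colMeans(draws))), 0.03)
})

test_that("disconnected graphs are rejected with guidance", {
  g <- region_graph(list(a = "b", b = "a", c = "d", d = "c"))
  expect_error(sample_icar_field(g, 1), "component")
})

test_that("default age truth peaks at 35 with the documented shape", {
  grid <- 15:49
  f <- default_smooth_age(grid)
  expect_equal(grid[which.max(f)], 35)
  expect_lt(f[grid == 20], f[grid == 35])
  expect_lt(f[grid == 45], f[grid == 35])
  # centering over an arbitrary age sample
  set.seed(54)
  ages <- sample(15:49, 300, TRUE)
  expect_equal(mean(default_smooth_age(ages, center_on = ages)), 0,
               tolerance = 1e-12)
  expect_error(default_smooth_age(c(20, 55)), "range")
})

test_that("age-at-first-birth truth is flat below 20 then increasing", {
  expect_equal(default_smooth_afb(c(12, 15, 19.9)), rep(0, 3))
  v <- default_smooth_afb(c(22, 28, 34))
  expect_true(all(diff(v) > 0))
})

test_that("datasets are bitwise reproducible under config + seed", {
  cfg <- sim_config(n_women = 300)
  s1 <- simulate_dataset(cfg, seed = 55)
  s2 <- simulate_dataset(cfg, seed = 55)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$truth$spatial, s2$truth$spatial)
  s3 <- simulate_dataset(cfg, seed = 56)
  expect_false(identical(s1$records$sufficient, s3$records$sufficient))
})

test_that("marginals failing to sum to one are rejected", {
  bad <- sim_config(marginals = list(residence = c(rural = 0.5, urban = 0.4)))
  expect_error(simulate_dataset(bad, seed = 57), "sum to")
})

test_that("null truth gives 50% prevalence; intercept-only matches its logit", {
  null_cfg <- sim_config(n_women = 20000, gamma = list(), smooths = list(),
                         beta0 = 0, tau2_spatial = 0,
                         sd_household = 0, sd_community = 0)
  sim <- simulate_dataset(null_cfg, seed = 58)
  se <- sqrt(0.25 / 20000)
  expect_lt(abs(mean(sim$records$sufficient) - 0.5), 3 * se)

  prev_cfg <- sim_config(n_women = 20000, gamma = list(), smooths = list(),
                         beta0 = qlogis(0.592), tau2_spatial = 0,
                         sd_household = 0, sd_community = 0)
  sim2 <- simulate_dataset(prev_cfg, seed = 59)
  expect_lt(abs(mean(sim2$records$sufficient) - 0.592),
            3 * sqrt(0.592 * 0.408 / 20000))
})

test_that("empirical covariate shares match the configured marginals", {
  sim <- simulate_dataset(sim_config(n_women = 20000), seed = 60)
  rural <- mean(sim$records$residence == "rural")
  expect_lt(abs(rural - 0.580), 3 * sqrt(0.58 * 0.42 / 20000))
})

test_that("nesting is strict: household -> cluster -> region", {
  sim <- simulate_dataset(sim_config(n_women = 1000), seed = 61)
  r <- sim$records
  expect_true(all(tapply(r$cluster, r$household,
                         function(x) length(unique(x))) == 1L))
  expect_true(all(tapply(r$region, r$cluster,
                         function(x) length(unique(x))) == 1L))
  expect_true(all(r$region %in% sim$graph$ids))
  # outcome consistent with the five generated responses
  resp <- as.matrix(r[knowledge_questions()])
  expect_equal(r$sufficient, as.integer(rowSums(resp) == 5L))
})

test_that("a larger positive effect raises prevalence in its stratum", {
  base <- sim_config(n_women = 20000, smooths = list(), tau2_spatial = 0,
                     sd_household = 0, sd_community = 0, beta0 = 0,
                     gamma = list(education = c(primary = 0, secondary = 0,
                                                higher = 0.2)))
  up <- base
  up$gamma$education["higher"] <- 1.0
  p_base <- with(simulate_dataset(base, seed = 62)$records,
                 mean(sufficient[education == "higher"]))
  p_up <- with(simulate_dataset(up, seed = 62)$records,
               mean(sufficient[education == "higher"]))
  expect_gt(p_up, p_base + 0.05)
})

test_that("written datasets round-trip through the plain-text formats", {
  sim <- simulate_dataset(sim_config(n_women = 120), seed = 63)
  dir <- tempfile()
  paths <- write_dataset(sim, dir)
  back <- read_women_csv(paths[["women"]])
  expect_equal(nrow(back), 120L)
  expect_equal(back$sufficient, sim$records$sufficient)
  g <- read_neighbor_list(paths[["neighbors"]])
  expect_equal(g$nb, sim$graph$nb)
  truth <- yaml::read_yaml(paths[["truth"]])
  expect_equal(truth$seed, 63)
  expect_equal(unlist(truth$spatial), sim$truth$spatial, tolerance = 1e-6)
})
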