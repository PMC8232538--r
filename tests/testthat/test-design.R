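test_that("dummy coding produces one column per non-reference level", {
  df <- data.frame(wealth = c("poorest", "poorer", "middle", "richer",
                              "richest", "poorest"))
  X <- encode_fixed(df, list(wealth = c("poorest", "poorer", "middle",
                                        "richer", "richest")))
  expect_equal(ncol(X), 5L)  # intercept + 4 indicators
  expect_equal(colnames(X)[1], "(Intercept)")
  expect_false("wealth:poorest" %in% colnames(X))
  # all records at reference -> intercept only columns of zeros
  ref <- data.frame(wealth = rep("poorest", 3))
  Xr <- encode_fixed(ref, list(wealth = c("poorest", "poorer")))
  expect_equal(unname(Xr[, "wealth:poorer"]), rep(0, 3))
  expect_error(
    encode_fixed(data.frame(wealth = "gold"), list(wealth = "poorest")),
    "record 1.*wealth.*gold")
})

test_that("design column sums equal tabulated level counts", {
  sim <- simulate_dataset(sim_config(n_women = 500), seed = 41)
  spec <- default_fixed_levels()["education"]
  X <- encode_fixed(sim$records, spec)
  tab <- tabulate_covariates(sim$records, "education",
                             levels = list(education = spec$education))
  for (l in spec$education[-1]) {
    expect_equal(sum(X[, paste0("education:", l)]),
                 tab$count[tab$level == l])
  }
})

test_that("B-spline bases are a partition of unity", {
  set.seed(42)
  z <- runif(200, 15, 49)
  B <- build_spline_basis(z, k = 12, degree = 3)
  expect_equal(rowSums(B), rep(1, 200), tolerance = 1e-10)
  expect_equal(ncol(B), 12L)
  # integer-valued covariates evaluate at their own range ends
  zi <- rep(0:14, 3)
  Bi <- build_spline_basis(zi, k = 8)
  expect_equal(rowSums(Bi), rep(1, length(zi)), tolerance = 1e-10)
})

test_that("degree-0 basis is the histogram indicator matrix", {
  z <- c(0.1, 0.4, 0.6, 0.9, 0)
  B <- build_spline_basis(z, k = 2, degree = 0)
  expect_true(all(B %in% c(0, 1)))
  expect_equal(rowSums(B), rep(1, 5))
  expect_equal(B[, 1] == 1, z < 0.45)
})

test_that("basis values match a de Boor recursion oracle", {
  # direct Cox-de Boor recursion, written independently of splineDesign
  deboor <- function(x, knots, j, d) {
    if (d == 0) {
      return(as.numeric(knots[j] <= x & x < knots[j + 1]))
    }
    a <- if (knots[j + d] > knots[j]) {
      (x - knots[j]) / (knots[j + d] - knots[j]) * deboor(x, knots, j, d - 1)
    } else 0
    b <- if (knots[j + d + 1] > knots[j + 1]) {
      (knots[j + d + 1] - x) / (knots[j + d + 1] - knots[j + 1]) *
        deboor(x, knots, j + 1, d - 1)
    } else 0
    a + b
  }
  z <- seq(0, 1, length.out = 11)
  B <- build_spline_basis(z, k = 7, degree = 3)
  kn <- attr(B, "knots")
  mids <- (kn[4:10] + kn[5:11]) / 2   # knot midpoints inside the range
  mids <- mids[mids >= 0 & mids <= 1]
  Bm <- splines::splineDesign(kn, mids, ord = 4)
  for (j in seq_len(7)) {
    expect_equal(Bm[, j], vapply(mids, deboor, 0, kn, j, 3), tolerance = 1e-12)
  }
})

test_that("spline preconditions are enforced", {
  expect_error(build_spline_basis(rep(1, 10)), "distinct")
  expect_error(build_spline_basis(1:10, k = 4, degree = 3), "k >= degree")
})

test_that("RW2 penalty has its exact closed form at k = 3", {
  K <- rw2_penalty(3)
  expect_equal(K, matrix(c(1, -2, 1, -2, 4, -2, 1, -2, 1), 3))
  expect_error(rw2_penalty(2), "at least 3")
})

test_that("RW2 penalty annihilates linear trends and penalizes curvature", {
  for (k in c(5, 12, 30)) {
    K <- rw2_penalty(k)
    expect_equal(as.numeric(K %*% rep(1, k)), rep(0, k), tolerance = 1e-12)
    expect_equal(as.numeric(K %*% seq_len(k)), rep(0, k), tolerance = 1e-12)
    quad <- (seq_len(k) - 1)^2
    expect_gt(sum(quad * (K %*% quad)), 0)
    expect_equal(qr(K)$rank, k - 2L)  # numerical rank oracle
  }
})

test_that("adding a constant to a smooth and removing it from the intercept
           leaves the predictor unchanged", {
  set.seed(44)
  z <- runif(50)
  B <- build_spline_basis(z, k = 6)
  theta <- rnorm(6)
  beta0 <- 0.3
  shift <- 0.7
  eta1 <- beta0 + as.numeric(B %*% theta)
  eta2 <- (beta0 - shift) + as.numeric(B %*% (theta + shift))
  expect_equal(eta1, eta2, tolerance = 1e-10)  # partition of unity
})
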