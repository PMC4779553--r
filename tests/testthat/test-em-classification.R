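test_that("extent-based initialization reproduces class-wise sample statistics", {
  # separated constant groups: exact means, SDs clamped to the floor
  x <- c(rep(100, 40), rep(140, 20))
  inside <- c(rep(FALSE, 40), rep(TRUE, 20))
  w <- capture_warnings(init <- initialize_from_extent(x, inside))
  expect_match(w, "sigma floor", all = TRUE)
  expect_length(w, 2)  # both constant classes clamp
  expect_equal(init$mu_normal, 100)
  expect_equal(init$mu_mar, 140)
  expect_equal(init$w_mar, 1 / 3)
  expect_error(initialize_from_extent(x, rep(TRUE, 60)), "non-empty")
  # overlapping Gaussian samples: init equals direct sample mean/SD
  set.seed(21)
  x <- c(rnorm(200, 1, 0.1), rnorm(100, 1.3, 0.1))
  inside <- rep(c(FALSE, TRUE), c(200, 100))
  init <- initialize_from_extent(x, inside)
  expect_equal(init$mu_normal, mean(x[1:200]), tolerance = 1e-12)
  expect_equal(init$sigma_mar, sd(x[201:300]), tolerance = 1e-12)
})

test_that("EM recovers the parameters of a planted two-Gaussian mixture", {
  set.seed(101)
  n <- 5000
  z <- runif(n) < 0.4
  x <- ifelse(z, rnorm(n, 1.4, 0.1), rnorm(n, 1.0, 0.1))
  init <- gaussian_mixture_fit(0.9, 0.2, 1.5, 0.2, 0.5)
  fit <- em_fit(x, init)
  expect_lt(abs(fit$mu_normal - 1.0), 0.02)
  expect_lt(abs(fit$mu_mar - 1.4), 0.02)
  expect_lt(abs(fit$w_mar - 0.4), 0.03)
})

test_that("EM log-likelihood is non-decreasing and labels stay ordered across seeds", {
  for (seed in 1:50) {
    set.seed(seed)
    mu2 <- runif(1, 1.2, 1.6)
    w <- runif(1, 0.2, 0.6)
    n <- 600
    z <- runif(n) < w
    x <- ifelse(z, rnorm(n, mu2, 0.12), rnorm(n, 1.0, 0.1))
    init <- gaussian_mixture_fit(runif(1, 0.8, 1.0), 0.3,
                                 runif(1, 1.3, 1.7), 0.3, 0.5)
    fit <- em_fit(x, init)
    ll <- attr(fit, "loglik")
    expect_true(all(diff(ll) >= -1e-8 * abs(ll[-length(ll)])))
    expect_gte(fit$mu_mar, fit$mu_normal)
  }
})

test_that("parameter recovery holds on average over 50 seeded simulations", {
  errs <- vapply(1:50, function(seed) {
    set.seed(seed + 500)
    n <- 3000
    z <- runif(n) < 0.35
    x <- ifelse(z, rnorm(n, 1.4, 0.1), rnorm(n, 1.0, 0.1))
    fit <- em_fit(x, gaussian_mixture_fit(0.95, 0.2, 1.45, 0.2, 0.5))
    (abs(fit$mu_normal - 1.0) + abs(fit$mu_mar - 1.4)) / 2
  }, numeric(1))
  expect_lt(mean(errs), 0.02)
})

test_that("EM started at the truth of a well-specified mixture is at a fixed point", {
  set.seed(7)
  n <- 20000
  z <- runif(n) < 0.4
  x <- ifelse(z, rnorm(n, 1.4, 0.1), rnorm(n, 1.0, 0.1))
  truth <- gaussian_mixture_fit(1.0, 0.1, 1.4, 0.1, 0.4)
  fit <- em_fit(x, truth, em_config(tol = 1e-4))
  expect_lte(attr(fit, "iterations"), 2)
  expect_error(em_fit(rep(1, 100), truth), "degenerate")
})

test_that("decision threshold sits at posterior 0.5 and responds to the weight", {
  fit <- gaussian_mixture_fit(1.0, 0.1, 1.4, 0.1, 0.5)
  expect_equal(decision_threshold(fit), 1.2)  # symmetric case: midpoint
  for (fit in list(fit,
                   gaussian_mixture_fit(1.0, 0.08, 1.5, 0.2, 0.3),
                   gaussian_mixture_fit(0.9, 0.15, 1.3, 0.1, 0.6))) {
    thr <- decision_threshold(fit)
    expect_equal(mar_posterior(thr, fit), 0.5, tolerance = 1e-6)
  }
  # decreasing the MaR weight strictly raises the threshold
  thr <- vapply(seq(0.6, 0.1, by = -0.1), function(w)
    decision_threshold(gaussian_mixture_fit(1.0, 0.1, 1.4, 0.12, w)),
    numeric(1))
  expect_true(all(diff(thr) > 0))
  expect_error(decision_threshold(gaussian_mixture_fit(1, 0.1, 1, 0.1, 0.5)),
               "identical")
})
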