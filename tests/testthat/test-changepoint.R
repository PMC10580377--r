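test_that("exponential segment cost matches its closed form", {
  expect_equal(exp_segment_cost(c(1, 1), 1, 2), 0)
  expect_equal(exp_segment_cost(rep(100, 4), 1, 4), 8 * log(100))
  # splitting at the true rate change never increases the raw cost
  x <- c(rep(1000, 6), rep(5, 6))
  whole <- exp_segment_cost(x, 1, 12)
  split <- exp_segment_cost(x, 1, 6) + exp_segment_cost(x, 7, 12)
  expect_true(split <= whole)
})

test_that("the BIC-style penalty is 2 log n and monotone", {
  expect_equal(bic_penalty(20), 2 * log(20))
  expect_equal(bic_penalty(exp(2)), 4)
  expect_true(bic_penalty(100) > bic_penalty(50))
  expect_error(bic_penalty(1), ">= 2")
})

test_that("PELT finds no changepoint in a constant-rate sequence", {
  r <- cpt_exponential(rep(10, 20))
  expect_equal(r$changepoints, 20L)
})

test_that("PELT recovers a clean rate shift with the expected objective", {
  x <- c(rep(1000, 10), rep(10, 10))
  r <- cpt_exponential(x)
  expect_equal(r$changepoints, c(10L, 20L))
  expect_equal(r$objective,
               20 * log(1000) + 20 * log(10) + bic_penalty(20))
  # unsplit fit is strictly worse
  expect_true(r$objective < exp_segment_cost(x, 1, 20))
})

test_that("PELT equals brute-force optimal partitioning on random sequences", {
  set.seed(101)
  for (i in 1:60) {
    n1 <- sample(3:15, 1)
    n2 <- sample(0:15, 1)
    x <- c(rexp(n1, 1 / sample(c(10, 1000), 1)),
           if (n2 > 0) rexp(n2, 1 / sample(c(10, 1000), 1)))
    beta <- runif(1, 0.3, 3) * log(length(x))
    p <- cpt_exponential(x, penalty = beta)
    b <- cpt_brute_force(x, penalty = beta)
    expect_identical(p$changepoints, b$changepoints)
    expect_equal(p$objective, b$objective, tolerance = 1e-10)
  }
})

test_that("SegNeigh with an unbounded budget matches PELT; a budget of one forces one segment", {
  set.seed(5)
  for (i in 1:20) {
    x <- c(rexp(sample(4:12, 1), 1 / 20), rexp(sample(4:12, 1), 1 / 2000))
    s <- cpt_exponential(x, method = "segneigh")
    p <- cpt_exponential(x)
    expect_equal(s$objective, p$objective, tolerance = 1e-10)
    expect_identical(s$changepoints, p$changepoints)
  }
  x <- c(rep(1000, 10), rep(10, 10))
  expect_equal(cpt_exponential(x, method = "segneigh",
                               max_segments = 1)$changepoints, 20L)
})

test_that("BinSeg agrees with PELT on a single clean shift and never beats it", {
  x <- c(rep(1000, 10), rep(10, 10))
  expect_identical(cpt_exponential(x, method = "binseg")$changepoints,
                   cpt_exponential(x)$changepoints)
  expect_equal(cpt_exponential(rep(7, 12), method = "binseg")$changepoints,
               12L)
  set.seed(31)
  for (i in 1:25) {
    x <- rexp(sample(10:40, 1), 1 / sample(c(5, 50, 500), 1))
    if (runif(1) < 0.7) x <- c(x, rexp(sample(5:20, 1), 1 / 5),
                               rexp(sample(5:20, 1), 1 / 800))
    bs <- cpt_exponential(x, method = "binseg")
    p <- cpt_exponential(x)
    expect_true(bs$objective >= p$objective - 1e-9)
  }
})

test_that("AMOC returns at most one changepoint and matches an exhaustive scan", {
  expect_equal(cpt_exponential(rep(3, 16), method = "amoc")$changepoints, 16L)
  x <- c(rep(1000, 10), rep(10, 10))
  a <- cpt_exponential(x, method = "amoc")
  expect_equal(a$changepoints, c(10L, 20L))
  set.seed(77)
  for (i in 1:20) {
    x <- c(rexp(sample(5:15, 1), 1 / 10), rexp(sample(5:15, 1), 1 / 1500))
    n <- length(x)
    beta <- bic_penalty(n)
    a <- cpt_exponential(x, method = "amoc", penalty = beta)
    expect_lte(length(a$changepoints), 2)
    # exhaustive single-split scan
    splits <- 2:(n - 2)
    costs <- vapply(splits, function(tau) {
      exp_segment_cost(x, 1, tau) + exp_segment_cost(x, tau + 1, n) + beta
    }, numeric(1))
    whole <- exp_segment_cost(x, 1, n)
    if (min(costs) < whole) {
      expect_equal(a$changepoints[1], splits[which.min(costs)])
      expect_equal(a$objective, min(costs))
    } else {
      expect_equal(a$changepoints, n)
    }
  }
})

test_that("all search algorithms honour the minimal segment length", {
  set.seed(13)
  for (i in 1:15) {
    x <- c(rexp(sample(8:20, 1), 1 / sample(c(10, 1000), 1)),
           rexp(sample(8:20, 1), 1 / sample(c(10, 1000), 1))) + 1
    msl <- sample(2:4, 1)
    for (m in c("pelt", "binseg", "segneigh", "amoc")) {
      r <- cpt_exponential(x, method = m, min_seg_len = msl)
      expect_true(all(diff(c(0L, r$changepoints)) >= msl),
                  label = sprintf("method %s, min_seg_len %d", m, msl))
      expect_equal(r$changepoints[length(r$changepoints)], length(x))
    }
  }
})

test_that("the optimal objective is nondecreasing in the penalty", {
  set.seed(19)
  x <- c(rexp(15, 1 / 10), rexp(15, 1 / 1000), rexp(10, 1 / 10))
  betas <- c(0.5, 2, 5, 10, 40)
  objs <- vapply(betas, function(b) {
    cpt_exponential(x, penalty = b)$objective
  }, numeric(1))
  expect_true(all(diff(objs) >= -1e-9))
  # and the number of changepoints is nonincreasing
  ncps <- vapply(betas, function(b) {
    length(cpt_exponential(x, penalty = b)$changepoints) - 1L
  }, integer(1))
  expect_true(all(diff(ncps) <= 0))
})

test_that("degenerate and invalid inputs are handled", {
  expect_equal(cpt_exponential(c(5, 5, 5))$changepoints, 3L)  # n < 2*minseg
  expect_error(cpt_exponential(c(1, -1, 2)), "positive")
  expect_error(cpt_exponential(numeric(0)), "empty")
  expect_error(cpt_exponential(c(1, 2), penalty = -1), "positive")
})
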