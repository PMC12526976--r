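cfg2d <- function(...) {
  defaults <- list(pop_size = 10, max_iter = 100, lower = c(-10, -10),
                   upper = c(10, 10))
  do.call(aoa_config, utils::modifyList(defaults, list(...)))
}

test_that("tent map steps match hand evaluation on both branches", {
  expect_equal(tent_step(0.3, 0.5), 0.6)
  expect_equal(tent_step(0.8, 0.5), 0.4)
  expect_error(tent_stream(10, 1.2, 0.5), "a_tent")
})

test_that("tent-chaos initialization fills the bounds deterministically", {
  cfg <- aoa_config(pop_size = 40, max_iter = 10, lower = c(-2, 100),
                    upper = c(3, 200), seed = 6L)
  p1 <- tent_init(cfg)
  p2 <- tent_init(cfg)
  expect_identical(p1, p2)
  expect_true(all(p1[, 1] >= -2 & p1[, 1] <= 3))
  expect_true(all(p1[, 2] >= 100 & p1[, 2] <= 200))
})

test_that("accelerated schedules hit their endpoints and interior values", {
  lin <- cfg2d(schedule = "linear", moa_min = 0.2, moa_max = 1)
  expect_equal(accel_schedule(0, lin), 0.2)
  expect_equal(accel_schedule(lin$max_iter, lin), 1)

  nl <- cfg2d(schedule = "nonlinear")
  expect_equal(accel_schedule(0, nl), 0)
  expect_equal(accel_schedule(nl$max_iter, nl), 1)
  expect_equal(accel_schedule(nl$max_iter / 2, nl), 0.25 * exp(0.5),
               tolerance = 1e-12)
  expect_error(accel_schedule(nl$max_iter + 1, nl), "max_iter")
})

test_that("nonlinear schedule stays below the linear one in the interior", {
  nl <- aoa_config(pop_size = 5, max_iter = 1000, lower = 0, upper = 1,
                   schedule = "nonlinear", moa_min = 0, moa_max = 1)
  t <- 1:999
  omoa <- accel_schedule(t, nl)
  moa_lin <- t / 1000 # linear with Min = 0, Max = 1
  expect_true(all(omoa < moa_lin))
  expect_true(all(diff(accel_schedule(0:1000, nl)) > 0))
})

test_that("math optimizer probability decays from 1 to 0", {
  cfg <- cfg2d(a_mop = 5)
  expect_equal(math_optimizer_probability(0, cfg), 1)
  expect_equal(math_optimizer_probability(cfg$max_iter, cfg), 0)
  expect_equal(math_optimizer_probability(cfg$max_iter / 2, cfg),
               1 - 0.5^0.2, tolerance = 1e-12)
})

test_that("position updates follow the arithmetic operators and stay in bounds", {
  cfg <- cfg2d(mu = 0.5)
  xb <- c(1, -2)
  # exploit with MOP = 0: both branches collapse onto the incumbent best
  expect_equal(position_update(xb, "exploit", mop = 0, cfg, r = c(0.1, 0.9)), xb)
  # symmetric bounds make the scaled span zero, so the additive step is zero
  expect_equal(position_update(c(0, 0), "exploit", mop = 0.5, cfg,
                               r = c(0.9, 0.9)), c(0, 0))
  set.seed(3)
  for (i in 1:20) {
    p <- position_update(runif(2, -10, 10), sample(c("explore", "exploit"), 1),
                         mop = runif(1), cfg)
    expect_true(all(p >= cfg$lower & p <= cfg$upper))
  }
})

test_that("mutation blends the pulls toward best and random members", {
  cfg <- cfg2d()
  x <- c(1, 2); xb <- c(3, -1); xr <- c(-2, 5)
  expect_equal(mutate_position(x, xb, xr, r1 = 1, cfg), xb - x)
  expect_equal(mutate_position(x, xb, xr, r1 = 0, cfg), xr - x)
  expect_equal(mutate_position(x, x, x, r1 = 0.4, cfg), c(0, 0))
})

test_that("optimizer converges on smooth and shifted objectives", {
  sphere <- function(x) sum(x^2)
  fits <- vapply(1:10, function(s) {
    aoa_optimize(sphere, aoa_config(pop_size = 30, max_iter = 200,
                                    lower = c(-10, -10), upper = c(10, 10),
                                    seed = s))$best_fitness
  }, numeric(1))
  expect_lt(median(fits), 1e-2)

  hits <- vapply(1:10, function(s) {
    fit <- aoa_optimize(function(x) (x - 3)^2,
                        aoa_config(pop_size = 20, max_iter = 100,
                                   lower = 0, upper = 10, seed = s))
    abs(fit$best_position - 3) < 0.1
  }, logical(1))
  expect_gte(sum(hits), 9L)
})

test_that("best-so-far history is non-increasing and bounded by evaluations", {
  fit <- aoa_optimize(function(x) sum((x - c(2, -5))^2),
                      cfg2d(seed = 17L, max_iter = 50))
  expect_true(all(diff(fit$history$best_fitness) <= 0))
  expect_true(all(fit$history$best_x1 >= -10 & fit$history$best_x1 <= 10))
})

test_that("a constant objective returns the constant", {
  fit <- aoa_optimize(function(x) 1.5, cfg2d(max_iter = 5))
  expect_equal(fit$best_fitness, 1.5)
})

test_that("non-finite objective values trigger resampling, not failure", {
  bad <- function(x) if (x[1] > 0) Inf else sum(x^2)
  expect_warning(
    fit <- aoa_optimize(bad, aoa_config(pop_size = 6, max_iter = 5,
                                        lower = c(-1, -1), upper = c(1, 1),
                                        seed = 2L)),
    "non-finite"
  )
  expect_true(is.finite(fit$best_fitness))
})

test_that("integer dimensions are rounded at evaluation and reporting time", {
  seen <- new.env(); seen$k <- numeric()
  obj <- function(x) { seen$k <- c(seen$k, x[1]); (x[1] - 3.4)^2 + x[2]^2 }
  fit <- aoa_optimize(obj, aoa_config(pop_size = 8, max_iter = 10,
                                      lower = c(1, -2), upper = c(8, 2),
                                      integer_dims = 1L, seed = 4L))
  expect_true(all(seen$k == round(seen$k)))
  expect_true(fit$best_position[1] == round(fit$best_position[1]))
})

test_that("tent stream is uniform on (0,1) by a KS check", {
  u <- tent_stream(1e4, a_tent = 0.7, x0 = 0.2026)
  expect_true(all(u > 0 & u < 1))
  ks <- suppressWarnings(stats::ks.test(u, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("improvements at least match vanilla AOA on a multimodal objective", {
  rastrigin <- function(x) sum(x^2 - 10 * cos(2 * pi * x) + 10)
  success <- function(improved) {
    vapply(1:20, function(s) {
      cfg <- aoa_config(pop_size = 20, max_iter = 100,
                        lower = c(-4, -4), upper = c(6, 6), seed = s,
                        tent_init = improved, mutation_on = improved,
                        schedule = if (improved) "nonlinear" else "linear")
      aoa_optimize(rastrigin, cfg)$best_fitness < 1
    }, logical(1))
  }
  expect_gte(sum(success(TRUE)), sum(success(FALSE)))
})
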