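# Entropy production, second-law bounds and the fluctuation theorem on
# exactly enumerated delayed bipartite models.

test_that("the backward kernel is the argument-swapped forward kernel", {
  m <- symmetric_kernel_model()
  expect_equal(backward_kernel(m), m$w)
  m2 <- make_coupled_binary()
  pb <- backward_kernel(m2)
  expect_equal(apply(pb, c(2, 3), sum), matrix(1, 2, 2), tolerance = 1e-12)
})

test_that("bath entropy: symmetric kernels give 0, single steps match by hand", {
  m <- symmetric_kernel_model()
  for (i in 1:5) {
    tr <- simulate_series(m, 6, seed = i, init = "p1")
    expect_equal(bath_entropy(tr, m), 0, tolerance = 1e-12)
  }
  # one transition 1 -> 2 with w(2|1,y) = 0.3, w(1|2,y) = 0.1
  w <- array(0, c(2, 2, 2))
  w[, 1, ] <- c(0.7, 0.3); w[, 2, ] <- c(0.1, 0.9)
  q <- array(0.5, c(2, 2, 2))
  m2 <- bipartite_model(w, q, matrix(0.25, 2, 2))
  expect_equal(bath_entropy(data.frame(x = c(1, 2), y = c(1, 1)), m2),
               log(0.3 / 0.1), tolerance = 1e-12)
  # a static path accumulates nothing
  expect_equal(bath_entropy(data.frame(x = c(2, 2, 2), y = c(1, 2, 1)), m2),
               log(0.9) - log(0.9) + log(0.9) - log(0.9), tolerance = 1e-12)
})

test_that("stochastic TE/BTE integrands average to the ensemble quantities", {
  m <- make_coupled_binary()
  N <- 4
  pf <- path_functionals(m, N)
  pd <- enumerate_paths(m, N)
  di <- directed_information(pd)$value
  bdi <- backward_directed_information(pd)$value
  expect_equal(sum(pf$p * (pf$i_tr + pf$i1)), di, tolerance = 1e-10)
  expect_equal(sum(pf$p * (pf$i_bt + pf$iN)), bdi, tolerance = 1e-10)
})

test_that("sigma equals the log ratio of path measure to reference measure", {
  for (i in 1:6) {
    m <- random_bipartite_model(n = (i - 1) %% 3, seed = 400 + i)
    pf <- path_functionals(m, 4)
    expect_lt(max(abs(pf$sigma - (log(pf$p) - pf$log_pb))), 1e-10)
    expect_lt(max(abs(pf$sigma_weak - (log(pf$p) - pf$log_pw))), 1e-10)
    expect_equal(sum(exp(pf$log_pb)), 1, tolerance = 1e-10)
    expect_equal(sum(exp(pf$log_pw)), 1, tolerance = 1e-10)
  }
})

test_that("mean entropy production is the Methods KL divergence", {
  m <- make_demon(n = 0)
  ep <- entropy_production(m, 4)
  expect_equal(ep$mean_sigma, ep$kl$value, tolerance = 1e-10)
  expect_gte(ep$mean_sigma, -1e-12)
})

test_that("a non-interacting pair obeys the conventional second law", {
  m <- non_interacting_model(seed = 31)
  pf <- path_functionals(m, 4)
  # informational terms vanish pointwise in expectation
  expect_lt(abs(sum(pf$p * (pf$i_tr + pf$i1))), 1e-10)
  expect_lt(abs(sum(pf$p * (pf$i_bt + pf$iN))), 1e-10)
  cb <- check_bounds(m, 4)
  expect_equal(cb$weak_rhs, 0, tolerance = 1e-10)
  expect_equal(cb$tight_rhs, 0, tolerance = 1e-10)
  expect_gte(cb$mean_ds, -1e-10)
})

test_that("an equilibrium symmetric non-interacting model has zero sigma", {
  # symmetric source kernel, autonomous uniform-stationary target,
  # started from the uniform joint: every sigma component vanishes
  w <- array(0, c(2, 2, 2))
  for (y in 1:2) w[, , y] <- matrix(c(0.7, 0.3, 0.3, 0.7), 2, 2)
  q <- array(0, c(2, 2, 2))
  for (x in 1:2) q[, , x] <- matrix(c(0.6, 0.4, 0.4, 0.6), 2, 2)
  m <- bipartite_model(w, q, matrix(0.25, 2, 2))
  ep <- entropy_production(m, 4)
  expect_equal(ep$mean_sigma, 0, tolerance = 1e-10)
  ift <- integrated_fluctuation_theorem(m, 4)
  expect_equal(ift$value, 1, tolerance = 1e-12)
  expect_lt(max(abs(ep$functionals$sigma)), 1e-10)
})

test_that("IFT holds exactly and Monte Carlo agrees within 3 SE", {
  d1 <- make_demon(n = 0)
  expect_equal(integrated_fluctuation_theorem(d1, 4)$value, 1,
               tolerance = 1e-10)
  d2 <- make_demon(n = 1)
  mc <- integrated_fluctuation_theorem(d2, 4, mode = "montecarlo",
                                       n_samples = 1e5, seed = 99)
  expect_lt(abs(mc$value - 1), 3 * mc$se)
})

test_that("demon fixture extracts work within the tight bound", {
  d2 <- make_demon(n = 1)
  cb <- check_bounds(d2, 4)
  expect_lt(cb$mean_ds, 0)
  expect_gte(cb$tight_gap, -1e-10)
  expect_gte(cb$weak_gap, -1e-10)
  expect_lte(cb$tight_gap, cb$weak_gap + 1e-10)
})

test_that("stepwise tight bounds telescope to the total at n = 0", {
  for (m in list(make_demon(n = 0), make_coupled_binary())) {
    sb <- stepwise_tight_bound(m, 4)
    cb <- check_bounds(m, 4)
    expect_equal(sb$total, cb$tight_rhs, tolerance = 1e-10)
    expect_equal(cb$mean_xi, 0)
    # N = 2: the single step is the whole bound
    sb2 <- stepwise_tight_bound(m, 2)
    cb2 <- check_bounds(m, 2)
    expect_equal(sb2$total, cb2$tight_rhs, tolerance = 1e-10)
  }
  expect_error(stepwise_tight_bound(make_demon(n = 1), 4), "n = 0")
})

test_that("stationary stepwise bounds reduce to BTE minus TE per step", {
  m <- make_coupled_binary(p1 = stationary_joint(make_coupled_binary()))
  sb <- stepwise_tight_bound(m, 4)
  expect_lt(max(abs(sb$steps$mi_k1 - sb$steps$mi_k)), 1e-10)
  expect_equal(sb$steps$bound, sb$steps$bte - sb$steps$te,
               tolerance = 1e-10)
})

test_that("locally reversible dynamics flip the bound quantity under reversal", {
  m <- symmetric_kernel_model()
  pf <- path_functionals(m, 3)
  expect_lt(max(abs(pf$ds_bath)), 1e-12)
  pd <- enumerate_paths(m, 3)
  quantity <- function(pd) {
    fd <- as_finite_dist(pd)
    hx1 <- entropy(marginal(fd, "x1"))$value
    hxN <- entropy(marginal(fd, "x3"))$value
    (hxN - hx1) + directed_information(pd)$value -
      backward_directed_information(pd)$value
  }
  expect_equal(quantity(reverse_paths(pd)), -quantity(pd),
               tolerance = 1e-10)
})
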