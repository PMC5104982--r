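# Transfer entropy, backward transfer entropy, directed information,
# learning rate and sensory capacity on exactly enumerated path tables.

test_that("transfer entropy vanishes when the target kernel ignores the source", {
  for (i in 1:50) {
    m <- y_autonomous_model(seed = 200 + i)
    pd <- enumerate_paths(m, 3)
    for (k in 1:2) {
      expect_lt(transfer_entropy(pd, k)$value, 1e-12)
    }
  }
})

test_that("transfer entropy of a (noisy) copy channel matches closed forms", {
  pd <- enumerate_paths(copy_model(0), 3)
  expect_equal(transfer_entropy(pd, 1)$value, log(2), tolerance = 1e-12)
  pd2 <- enumerate_paths(copy_model(0.1), 3)
  hb <- -(0.9 * log(0.9) + 0.1 * log(0.1))
  expect_equal(transfer_entropy(pd2, 2)$value, log(2) - hb,
               tolerance = 1e-12)
  expect_equal(transfer_entropy(pd2, 2)$value, 0.368064, tolerance = 1e-6)
})

test_that("insufficient history raises an informative error", {
  pd <- enumerate_paths(make_coupled_binary(), 3)
  expect_error(transfer_entropy(pd, 1, l = 2), "admissible")
  expect_error(transfer_entropy(pd, 3, l = 1), "admissible")
})

test_that("path reversal is an involution and reverses per-time marginals", {
  m <- make_coupled_binary()
  pd <- enumerate_paths(m, 3)
  rr <- reverse_paths(reverse_paths(pd))
  expect_equal(rr$tab, pd$tab)
  expect_equal(rr$probs, pd$probs)
  rv <- reverse_paths(pd)
  for (k in 1:3) {
    a <- marginal(as_finite_dist(pd), paste0("x", k))
    b <- marginal(as_finite_dist(rv), paste0("x", 4 - k))
    expect_equal(a$probs[order(a$outcomes[[1]])],
                 b$probs[order(b$outcomes[[1]])], tolerance = 1e-12)
  }
  pd1 <- enumerate_paths(m, 1)
  r1 <- reverse_paths(pd1)
  expect_equal(r1$probs, pd1$probs)
})

test_that("BTE equals TE of the reversed paths for all steps and histories", {
  set.seed(33)
  for (i in 1:10) {
    m <- random_bipartite_model(seed = 300 + i)
    pd <- enumerate_paths(m, 4)
    for (l in 1:2) for (mm in 1:(4 - l)) {
      bte <- backward_transfer_entropy(pd, mm, l)$value
      te_rev <- transfer_entropy(reverse_paths(pd), 4 - mm, l)$value
      expect_lt(abs(bte - te_rev), 1e-12)
      # general-l forward-index form I(X_{m+1:m+l}; Y_m | Y_{m+1:m+l})
      fd <- as_finite_dist(pd)
      direct <- bteflow:::.cmi(fd, paste0("x", (mm + 1):(mm + l)),
                               paste0("y", mm), paste0("y", (mm + 1):(mm + l)))
      expect_lt(abs(bte - direct), 1e-12)
    }
  }
})

test_that("BTE vanishes exactly on hidden-Markov sensor models", {
  pd <- enumerate_paths(make_hmm_sensor(0.3, 0.25), 4)
  for (l in 1:2) for (mm in 1:(4 - l)) {
    expect_lt(backward_transfer_entropy(pd, mm, l)$value, 1e-12)
  }
})

test_that("one-step BTE vanishes iff the three-variable marginal factorizes", {
  # factorized direction: hidden-Markov sensor
  pd <- enumerate_paths(make_hmm_sensor(), 3)
  fd <- marginal(as_finite_dist(pd), c("y1", "y2", "x2"))
  key <- bteflow:::.pkey
  p_y1 <- marginal(fd, "y1")
  lhs <- fd$probs
  # p(y1) p(y2|y1) p(x2|y2)
  p_y1y2 <- marginal(fd, c("y1", "y2"))
  p_y2x2 <- marginal(fd, c("y2", "x2"))
  p_y2 <- marginal(fd, "y2")
  look <- function(m, cols) {
    m$probs[match(key(fd$outcomes, cols), key(m$outcomes, cols))]
  }
  rhs <- look(p_y1y2, c("y1", "y2")) * look(p_y2x2, c("y2", "x2")) /
    look(p_y2, "y2")
  expect_equal(lhs, rhs, tolerance = 1e-12)
  expect_lt(backward_transfer_entropy(pd, 1)$value, 1e-12)
  # non-factorized direction: generic coupled model has positive BTE
  pd2 <- enumerate_paths(make_coupled_binary(), 3)
  expect_gt(backward_transfer_entropy(pd2, 1)$value, 1e-6)
})

test_that("directed information sums stepwise terms plus the initial MI", {
  m <- make_coupled_binary()
  pd <- enumerate_paths(m, 4)
  fd <- as_finite_dist(pd)
  terms <- sapply(1:3, function(k) {
    bteflow:::.cmi(fd, paste0("x", 1:k), paste0("y", k + 1), paste0("y", 1:k))
  })
  i1 <- mutual_information(marginal(fd, c("x1", "y1")))$value
  expect_equal(directed_information(pd)$value, sum(terms) + i1,
               tolerance = 1e-12)
  # N = 1 reduces to the initial MI; independent processes give 0
  pd1 <- enumerate_paths(m, 1)
  expect_equal(directed_information(pd1)$value,
               mutual_information(marginal(as_finite_dist(pd1),
                                           c("x1", "y1")))$value,
               tolerance = 1e-12)
  pd0 <- enumerate_paths(non_interacting_model(seed = 9), 3)
  expect_lt(directed_information(pd0)$value, 1e-12)
  expect_lt(backward_directed_information(pd0)$value, 1e-12)
})

test_that("backward DI reduces to the final-time MI for sensor models", {
  pd <- enumerate_paths(make_hmm_sensor(), 4)
  iN <- mutual_information(marginal(as_finite_dist(pd),
                                    c("x4", "y4")))$value
  expect_equal(backward_directed_information(pd)$value, iN,
               tolerance = 1e-12)
  # and equals forward DI of the reversed table in general
  pd2 <- enumerate_paths(make_coupled_binary(), 4)
  expect_equal(backward_directed_information(pd2)$value,
               directed_information(reverse_paths(pd2))$value,
               tolerance = 1e-12)
})

test_that("learning rate obeys the alternating-update identity", {
  # Y updates while X is frozen: nu_k = TE_k - BTE_k exactly
  m <- frozen_x_model()
  pd <- enumerate_paths(m, 3)
  for (k in 1:2) {
    nu <- learning_rate(pd, k)$value
    te <- transfer_entropy(pd, k)$value
    bte <- backward_transfer_entropy(pd, k)$value
    expect_lt(abs(nu - (te - bte)), 1e-12)
  }
  # an uninformative target update cannot raise the learning rate above 0
  m2 <- iid_race_model()
  pd2 <- enumerate_paths(m2, 3)
  expect_lte(learning_rate(pd2, 1)$value, 1e-12)
})

test_that("sensory capacity is 1 for sensors, inside (0,1) generically", {
  sc <- sensory_capacity(make_hmm_sensor(0.2, 0.1))
  expect_equal(sc$capacity, 1, tolerance = 1e-12)
  expect_gt(sc$te$value, 0)
  sc2 <- sensory_capacity(make_coupled_binary())
  expect_gt(sc2$capacity, 0)
  expect_lt(sc2$capacity, 1)
  expect_equal(sc2$capacity, 1 - sc2$bte$value / sc2$te$value,
               tolerance = 1e-12)
  # undefined when the stationary TE vanishes
  expect_error(sensory_capacity(non_interacting_model(seed = 4)),
               "undefined")
})
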