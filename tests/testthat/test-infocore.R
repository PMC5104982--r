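# Shannon primitives on finite joint distributions.

bern <- function(p) finite_dist(data.frame(a = 1:2), c(p, 1 - p))

test_that("entropy matches hand-evaluated values", {
  expect_equal(entropy(bern(0.5))$value, log(2), tolerance = 1e-12)
  expect_equal(entropy(bern(1))$value, 0)
  # direct evaluation of -sum p ln p for (0.9, 0.1)
  expect_equal(entropy(bern(0.9))$value, 0.325083, tolerance = 1e-6)
})

test_that("distribution validation rejects bad inputs", {
  expect_error(finite_dist(data.frame(a = 1:2), c(0.6, 0.6)), "sum")
  expect_error(finite_dist(data.frame(a = 1:2), c(1.2, -0.2)), "negative")
  expect_error(finite_dist(data.frame(a = c(1, 1)), c(0.5, 0.5)),
               "duplicated")
})

test_that("mutual information: independence, identity and noisy coupling", {
  g <- expand.grid(a = 1:2, b = 1:2)
  prod_fd <- finite_dist(g, c(0.18, 0.42, 0.12, 0.28))  # p(a)=(.3,.7), p(b)=(.6,.4)
  expect_equal(mutual_information(prod_fd)$value, 0, tolerance = 1e-12)
  corr <- finite_dist(data.frame(a = 1:2, b = 1:2), c(0.5, 0.5))
  expect_equal(mutual_information(corr)$value, log(2), tolerance = 1e-12)
  # binary symmetric channel, uniform input, flip probability 0.1:
  # closed form ln 2 - H_b(0.1)
  bsc <- finite_dist(g, c(0.45, 0.05, 0.05, 0.45))
  expect_equal(mutual_information(bsc)$value, 0.368064, tolerance = 1e-6)
  expect_equal(mutual_information(bsc)$value,
               log(2) - entropy(bern(0.9))$value, tolerance = 1e-12)
})

test_that("conditional MI: degenerate conditioning and chain rule", {
  g <- expand.grid(a = 1:2, b = 1:2, c = 1)
  bsc <- finite_dist(g, c(0.45, 0.05, 0.05, 0.45))
  expect_equal(conditional_mutual_information(bsc)$value,
               mutual_information(marginal(bsc, c("a", "b")))$value,
               tolerance = 1e-12)
  # conditional independence given c
  g3 <- expand.grid(a = 1:2, b = 1:2, c = 1:2)
  p_ci <- with(g3, ifelse(c == 1, 0.5, 0.5) *
                 ifelse(a == c, 0.8, 0.2) * ifelse(b == c, 0.7, 0.3))
  fd_ci <- finite_dist(g3, p_ci)
  expect_equal(conditional_mutual_information(fd_ci)$value, 0,
               tolerance = 1e-12)
})

test_that("KL divergence: identity, support failure, direct value", {
  p <- bern(0.7); q <- bern(0.5)
  expect_equal(kl_divergence(p, p)$value, 0)
  expect_equal(kl_divergence(bern(1), q)$value, log(2), tolerance = 1e-12)
  expect_true(is.infinite(kl_divergence(q, bern(1))$value))
  expect_equal(kl_divergence(p, q)$value, 0.0822829, tolerance = 1e-6)
  expect_error(kl_divergence(p, finite_dist(data.frame(b = 1:2), c(0.5, 0.5))),
               "outcome spaces")
})

test_that("nonnegativity and exact identities hold on random distributions", {
  set.seed(101)
  for (i in 1:200) {
    p <- stats::rgamma(8, 1); p <- p / sum(p)
    fd <- finite_dist(expand.grid(a = 1:2, b = 1:2, c = 1:2), p)
    mi <- mutual_information(fd, "a", "b")$value
    cmi <- conditional_mutual_information(fd, "a", "b", "c")$value
    expect_gte(entropy(fd)$value, 0)
    expect_gte(mi, 0)
    expect_gte(cmi, 0)
    # chain rule I(A; B, C) = I(A; C) + I(A; B | C)
    iabc <- mutual_information(fd, "a", c("b", "c"))$value
    iac <- mutual_information(fd, "a", "c")$value
    expect_equal(iabc, iac + cmi, tolerance = 1e-10)
    # MI equals KL(joint || product of marginals)
    ma <- marginal(fd, "a"); mb <- marginal(fd, "b")
    pr <- outer(ma$probs, mb$probs)
    prod_fd <- finite_dist(expand.grid(a = 1:2, b = 1:2),
                           as.vector(pr))
    expect_equal(mutual_information(marginal(fd, c("a", "b")))$value,
                 kl_divergence(marginal(fd, c("a", "b")), prod_fd)$value,
                 tolerance = 1e-10)
  }
})

test_that("empirical joints are ML frequency tables that converge", {
  expect_error(empirical_joint(data.frame(a = integer(0))), "no samples")
  one <- empirical_joint(data.frame(a = c(1, 1, 1)))
  expect_equal(one$probs, 1)
  two <- empirical_joint(data.frame(a = c(1, 2, 2, 1)))
  expect_equal(sort(two$probs), c(0.5, 0.5))
  # convergence to a known 2x2 joint
  truth <- c(0.4, 0.1, 0.2, 0.3)
  err <- sapply(c(1e3, 1e4, 1e5), function(n) {
    set.seed(7)
    s <- sample(1:4, n, replace = TRUE, prob = truth)
    fd <- empirical_joint(data.frame(a = (s - 1) %% 2, b = (s - 1) %/% 2))
    key <- paste(fd$outcomes$a, fd$outcomes$b)
    ref <- truth[match(key, c("0 0", "1 0", "0 1", "1 1"))]
    max(abs(fd$probs - ref))
  })
  expect_lt(err[3], 0.01)
  expect_lt(err[3], err[1])
})
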