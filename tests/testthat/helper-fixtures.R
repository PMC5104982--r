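# Model builders shared across test files.  Everything is generated in
# code; no stored fixtures.

# binary model: y' copies x_k with flip probability eps, x i.i.d. uniform
copy_model <- function(eps = 0) {
  q <- array(0, c(2, 2, 2))
  q[, , 1] <- matrix(c(1 - eps, eps, 1 - eps, eps), 2, 2)   # q[y', y, x=1]
  q[, , 2] <- matrix(c(eps, 1 - eps, eps, 1 - eps), 2, 2)   # q[y', y, x=2]
  w <- array(0.5, c(2, 2, 2))                               # x i.i.d. uniform
  bipartite_model(w, q, matrix(0.25, 2, 2))
}

# model whose target kernel ignores the source (zero transfer entropy)
y_autonomous_model <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- random_bipartite_model()
  q <- m$q
  q[, , 2] <- q[, , 1]   # y-update ignores x
  bipartite_model(m$w, q, m$p1, n = m$n)
}

# source frozen during the step (alternating update): x' = x
frozen_x_model <- function(q = make_coupled_binary()$q,
                           p1 = matrix(0.25, 2, 2)) {
  w <- array(0, c(2, 2, 2))
  w[1, 1, ] <- 1
  w[2, 2, ] <- 1
  bipartite_model(w, q, p1)
}

# locally reversible source kernel: w(x'|x, y) symmetric in (x, x')
symmetric_kernel_model <- function(flip = c(0.3, 0.45),
                                   q = make_coupled_binary()$q,
                                   p1 = matrix(0.25, 2, 2)) {
  w <- array(0, c(2, 2, 2))
  for (y in 1:2) {
    w[, , y] <- matrix(c(1 - flip[y], flip[y], flip[y], 1 - flip[y]), 2, 2)
  }
  bipartite_model(w, q, p1)
}

# i.i.d. winners with probabilities p, independent uniform side info
iid_race_model <- function(p = c(0.7, 0.3)) {
  q <- array(0, c(2, 2, 2))
  q[1, , ] <- p[1]
  q[2, , ] <- p[2]
  w <- array(0.5, c(2, 2, 2))
  bipartite_model(w, q, matrix(0.25, 2, 2))
}

# non-interacting pair: both kernels ignore the other variable
non_interacting_model <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- random_bipartite_model()
  q <- m$q; q[, , 2] <- q[, , 1]
  w <- m$w; w[, , 2] <- w[, , 1]
  px <- rowSums(m$p1); py <- colSums(m$p1)
  bipartite_model(w, q, outer(px, py), n = m$n)
}
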