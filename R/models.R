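# Model constructors, exact path enumeration and seeded simulation for
# delayed bipartite Markov pair processes.  Every fixture used elsewhere
# in the package (sensor models, feedback demons, coupled binary chains)
# is built here, so all tests run on programmatically generated inputs.

.ROW_TOL <- 1e-12

# draw one symbol per row from a matrix of row-wise probabilities
.rcat <- function(pmat) {
  cs <- pmat
  for (j in seq_len(ncol(pmat))[-1]) cs[, j] <- cs[, j] + cs[, j - 1L]
  u <- stats::runif(nrow(pmat))
  rowSums(u > cs) + 1L
}

#' Delayed bipartite Markov model
#'
#' A discrete-time pair process in which, at each step `k`, the target
#' updates as \eqn{y_{k+1} \sim q(\cdot | y_k, x_k)} (measurement) and the
#' source updates as \eqn{x_{k+1} \sim w(\cdot | x_k, y_{c})} (feedback),
#' where the conditioning state is the delayed value
#' \eqn{y_c = y_{\max(k-n, 1)}} (`x_cond = "lagged"`, the default) or the
#' freshly updated \eqn{y_{k+1}} (`x_cond = "fresh"`, as in instantaneous
#' sensor models).  `n = 0` gives Markovian interacting dynamics.
#'
#' @param w array `w[x', x, y]`: probability of the new source state
#'   given the old source state and the conditioning target state.
#' @param q array `q[y', y, x]`: probability of the new target state
#'   given the old target state and the old source state.
#' @param p1 matrix `p1[x, y]`: initial joint distribution.
#' @param n nonnegative integer time delay (only with `x_cond = "lagged"`).
#' @param x_cond `"lagged"` or `"fresh"` (see above).
#' @return An object of class `bipartite_model`.
#' @export
bipartite_model <- function(w, q, p1, n = 0L, x_cond = c("lagged", "fresh")) {
  x_cond <- match.arg(x_cond)
  n <- as.integer(n)
  stopifnot(length(dim(w)) == 3L, length(dim(q)) == 3L, is.matrix(p1),
            n >= 0L)
  Sx <- dim(w)[1L]; Sy <- dim(q)[1L]
  stopifnot(dim(w)[2L] == Sx, dim(w)[3L] == Sy,
            dim(q)[2L] == Sy, dim(q)[3L] == Sx,
            nrow(p1) == Sx, ncol(p1) == Sy)
  if (any(w < 0) || any(q < 0) || any(p1 < 0)) stop("negative probabilities")
  if (max(abs(apply(w, c(2, 3), sum) - 1)) > .ROW_TOL ||
      max(abs(apply(q, c(2, 3), sum) - 1)) > .ROW_TOL) {
    stop("kernels are not row-stochastic")
  }
  if (abs(sum(p1) - 1) > .ROW_TOL) stop("initial distribution not normalized")
  if (n > 0L && x_cond == "fresh") stop("delay requires x_cond = \"lagged\"")
  structure(list(w = w, q = q, p1 = p1, n = n, x_cond = x_cond,
                 Sx = Sx, Sy = Sy),
            class = "bipartite_model")
}

#' @export
print.bipartite_model <- function(x, ...) {
  cat(sprintf("<bipartite_model> |X| = %d, |Y| = %d, delay n = %d, x_cond = %s\n",
              x$Sx, x$Sy, x$n, x$x_cond))
  invisible(x)
}

# index of the target state conditioning the source update at step k
.ycond_index <- function(k, n) max(k - n, 1L)

#' Exact enumeration of the joint path distribution
#'
#' Builds the exact probability table over all length-`N` paths of the
#' model by forward recursion over the declared update order and delay.
#'
#' @param model a [bipartite_model()].
#' @param N horizon (number of time steps).
#' @param budget maximum number of paths to enumerate (default `1e7`).
#' @return A [path_dist()].
#' @export
enumerate_paths <- function(model, N, budget = 1e7) {
  stopifnot(inherits(model, "bipartite_model"), N >= 1L)
  Sx <- model$Sx; Sy <- model$Sy
  if ((Sx * Sy)^N > budget) {
    stop(sprintf("enumeration of %g paths exceeds the budget of %g; %s",
                 (Sx * Sy)^N, budget,
                 "use seeded Monte Carlo (simulate) instead"))
  }
  g <- expand.grid(x = 1:Sx, y = 1:Sy)
  tab <- data.frame(x1 = g$x, y1 = g$y)
  p <- model$p1[cbind(g$x, g$y)]
  if (N > 1L) {
    blk <- expand.grid(xn = 1:Sx, yn = 1:Sy)
    m <- nrow(blk)
    for (k in 1:(N - 1L)) {
      idx <- rep(seq_len(nrow(tab)), each = m)
      bi <- rep(seq_len(m), times = nrow(tab))
      new <- tab[idx, , drop = FALSE]
      xn <- blk$xn[bi]; yn <- blk$yn[bi]
      xk <- new[[.xcols(k)]]; yk <- new[[.ycols(k)]]
      yc <- if (model$x_cond == "fresh") yn
            else new[[.ycols(.ycond_index(k, model$n))]]
      p <- p[idx] * model$q[cbind(yn, yk, xk)] * model$w[cbind(xn, xk, yc)]
      new[[.xcols(k + 1L)]] <- xn
      new[[.ycols(k + 1L)]] <- yn
      tab <- new
    }
  }
  path_dist(tab, p, Sx, Sy)
}

# one-step joint transition matrix over composite states s = (x, y),
# with s = (y - 1) * Sx + x
.joint_kernel <- function(model) {
  Sx <- model$Sx; Sy <- model$Sy
  S <- Sx * Sy
  T1 <- matrix(0, S, S)
  for (x in 1:Sx) for (y in 1:Sy) for (xn in 1:Sx) for (yn in 1:Sy) {
    yc <- if (model$x_cond == "fresh") yn else y
    T1[(y - 1L) * Sx + x, (yn - 1L) * Sx + xn] <-
      model$q[yn, y, x] * model$w[xn, x, yc]
  }
  T1
}

#' Stationary joint distribution of a Markovian bipartite model
#'
#' Solves \eqn{\pi T = \pi} for the one-step composite kernel.  The chain
#' must be irreducible (checked on the transition graph); the leading
#' eigenvector is validated to residual `1e-12`.
#'
#' @param model a [bipartite_model()] with `n = 0`.
#' @return Matrix `pi[x, y]` of stationary probabilities.
#' @export
stationary_joint <- function(model) {
  stopifnot(inherits(model, "bipartite_model"))
  if (model$n != 0L) stop("stationary distribution requires n = 0")
  T1 <- .joint_kernel(model)
  S <- nrow(T1)
  A <- (T1 > .ZERO_TOL) + diag(S)
  R <- diag(S)
  for (i in 1:S) R <- (R %*% A > 0) + 0
  if (any(R == 0)) stop("kernel is not ergodic (transition graph not irreducible)")
  e <- eigen(t(T1))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  if (max(abs(as.vector(v %*% T1) - v)) > 1e-12) {
    stop("stationary solve did not converge to tolerance 1e-12")
  }
  v[v < 0] <- 0
  matrix(v / sum(v), model$Sx, model$Sy)
}

#' Stationary one-step path distribution
#'
#' The exact joint distribution of `(x_k, y_k, x_{k+1}, y_{k+1})` with
#' the model started in its stationary state, as a two-step
#' [path_dist()].  This is the object on which stationary per-step
#' transfer entropy and backward transfer entropy are evaluated.
#'
#' @param model a [bipartite_model()] with `n = 0`.
#' @return A [path_dist()] with `N = 2`.
#' @export
stationary_step_dist <- function(model) {
  pi1 <- stationary_joint(model)
  m2 <- bipartite_model(model$w, model$q, pi1, n = model$n,
                        x_cond = model$x_cond)
  enumerate_paths(m2, 2L)
}

#' Simulate trajectories of a bipartite model
#'
#' Draws `n_traj` independent length-`N` trajectories.  Reproducible for
#' a fixed seed.
#'
#' @param model a [bipartite_model()].
#' @param N horizon.
#' @param n_traj number of trajectories.
#' @param seed optional integer seed.
#' @return Data frame with columns `x1..xN`, `y1..yN`, one row per
#'   trajectory.
#' @export
simulate_paths <- function(model, N, n_traj, seed = NULL) {
  stopifnot(inherits(model, "bipartite_model"), N >= 1L, n_traj >= 0L)
  if (!is.null(seed)) set.seed(seed)
  Sx <- model$Sx; Sy <- model$Sy
  cols <- stats::setNames(
    rep(list(integer(n_traj)), 2L * N), c(.xcols(1:N), .ycols(1:N)))
  out <- as.data.frame(cols)
  if (n_traj == 0L) return(out)
  g <- expand.grid(x = 1:Sx, y = 1:Sy)
  s <- .rcat(matrix(model$p1[cbind(g$x, g$y)], n_traj, Sx * Sy,
                    byrow = TRUE))
  out$x1 <- g$x[s]; out$y1 <- g$y[s]
  if (N > 1L) {
    for (k in 1:(N - 1L)) {
      xk <- out[[.xcols(k)]]; yk <- out[[.ycols(k)]]
      qm <- matrix(model$q[cbind(rep(1:Sy, each = n_traj), yk, xk)],
                   n_traj, Sy)
      yn <- .rcat(qm)
      yc <- if (model$x_cond == "fresh") yn
            else out[[.ycols(.ycond_index(k, model$n))]]
      wm <- matrix(model$w[cbind(rep(1:Sx, each = n_traj), xk, yc)],
                   n_traj, Sx)
      out[[.xcols(k + 1L)]] <- .rcat(wm)
      out[[.ycols(k + 1L)]] <- yn
    }
  }
  out
}

#' Simulate one long stationary series
#'
#' Draws a single trajectory of length `steps`, started from the
#' stationary distribution (`n = 0` models) or from `p1`.  Intended for
#' plug-in estimation of stationary information measures.
#'
#' @param model a [bipartite_model()].
#' @param steps series length.
#' @param seed optional integer seed.
#' @param init `"stationary"` (default; requires `n = 0`) or `"p1"`.
#' @return Data frame with columns `x`, `y` and `steps` rows.
#' @export
simulate_series <- function(model, steps, seed = NULL,
                            init = c("stationary", "p1")) {
  stopifnot(inherits(model, "bipartite_model"), steps >= 1L)
  init <- match.arg(init)
  if (!is.null(seed)) set.seed(seed)
  Sx <- model$Sx; Sy <- model$Sy
  p0 <- if (init == "stationary") stationary_joint(model) else model$p1
  x <- integer(steps); y <- integer(steps)
  s <- sample.int(Sx * Sy, 1L, prob = as.vector(p0))
  x[1L] <- (s - 1L) %% Sx + 1L
  y[1L] <- (s - 1L) %/% Sx + 1L
  if (steps > 1L) {
    for (k in 1:(steps - 1L)) {
      yn <- sample.int(Sy, 1L, prob = model$q[, y[k], x[k]])
      yc <- if (model$x_cond == "fresh") yn else y[.ycond_index(k, model$n)]
      x[k + 1L] <- sample.int(Sx, 1L, prob = model$w[, x[k], yc])
      y[k + 1L] <- yn
    }
  }
  data.frame(x = x, y = y)
}

# binary copy kernel: state 1/2 copied with flip probability eps
.copy_kernel <- function(eps) {
  matrix(c(1 - eps, eps, eps, 1 - eps), 2L, 2L)
}

#' Hidden-Markov sensor model
#'
#' Binary instantaneous-sensor model: the signal `Y` copies the previous
#' sensor state with flip probability `p_meas`
#' (\eqn{q(y_{k+1}|y_k,x_k)} ignores \eqn{y_k}), and the sensor `X` is
#' redrawn from the *current* signal with flip probability `p_obs`
#' (\eqn{x_{k+1}} depends only on \eqn{y_{k+1}}).  By construction the
#' backward transfer entropy from X to Y vanishes at every step, and the
#' stationary sensory capacity is 1.
#'
#' @param p_meas,p_obs flip probabilities in `(0, 0.5]`.
#' @return A [bipartite_model()] with `x_cond = "fresh"`.
#' @export
make_hmm_sensor <- function(p_meas = 0.2, p_obs = 0.1) {
  stopifnot(p_meas > 0, p_meas <= 0.5, p_obs > 0, p_obs <= 0.5)
  cm <- .copy_kernel(p_meas)
  co <- .copy_kernel(p_obs)
  q <- array(0, c(2, 2, 2))
  w <- array(0, c(2, 2, 2))
  for (y in 1:2) q[, y, ] <- cm           # y' copies x, ignores y
  for (x in 1:2) w[, x, ] <- co           # x' copies fresh y', ignores x
  bipartite_model(w, q, matrix(0.25, 2, 2), n = 0L, x_cond = "fresh")
}

#' Generic coupled binary model (fixture with TE > 0 and BTE > 0)
#'
#' A Markovian (`n = 0`) binary bipartite model parameterized by the 8
#' kernel probabilities `q(y' = 2 | y, x)` and `w(x' = 2 | x, y)`.  The
#' defaults give strictly positive transfer entropy and backward transfer
#' entropy in both directions.
#'
#' @param q2 length-4 vector `q(y' = 2 | y, x)` in order
#'   `(y,x) = (1,1), (2,1), (1,2), (2,2)`.
#' @param w2 length-4 vector `w(x' = 2 | x, y)` in the order
#'   `(x,y) = (1,1), (2,1), (1,2), (2,2)`.
#' @param p1 initial joint matrix (default uniform).
#' @return A [bipartite_model()].
#' @export
make_coupled_binary <- function(q2 = c(0.11, 0.27, 0.83, 0.14),
                                w2 = c(0.80, 0.62, 0.28, 0.11),
                                p1 = matrix(0.25, 2, 2)) {
  stopifnot(length(q2) == 4L, length(w2) == 4L,
            all(q2 > 0 & q2 < 1), all(w2 > 0 & w2 < 1))
  q <- array(0, c(2, 2, 2))
  w <- array(0, c(2, 2, 2))
  q[2, , ] <- matrix(q2, 2, 2)  # q[2, y, x]
  q[1, , ] <- 1 - q[2, , ]
  w[2, , ] <- matrix(w2, 2, 2)  # w[2, x, y]
  w[1, , ] <- 1 - w[2, , ]
  bipartite_model(w, q, p1, n = 0L)
}

#' Measurement-feedback demon model
#'
#' Binary Maxwell-demon fixture: the memory `Y` measures the system `X`
#' (`y_{k+1}` copies `x_k` with error `err_meas`) and `X` relaxes under a
#' detailed-balance kernel whose equilibrium puts mass `1 - delta` on the
#' delayed measured value `y_{k-n}`, with attempt rate `r`.  The initial
#' joint is correlated (`P(x_1 != y_1) = rho`): when the actual alignment
#' between the system and the measurement record exceeds the kernel's
#' equilibrium bias `1 - delta`, the system escapes its preferred state
#' more often than it would at equilibrium, absorbing heat, and the mean
#' entropy change of system plus bath is negative (work extraction
#' steered by the measurement).  The defaults are validated for this at
#' construction by exact enumeration.
#'
#' @param n nonnegative delay.
#' @param err_meas measurement error in `(0, 0.5)`.
#' @param delta bias of the feedback equilibrium in `(0, 0.5)`.
#' @param r attempt rate in `(0, 1]`.
#' @param rho initial misalignment probability `P(x_1 != y_1)`.
#' @param check_negative_entropy verify \eqn{\langle \Delta S_{x+bath}
#'   \rangle < 0} at horizon `N = 4` (default `TRUE`).
#' @return A [bipartite_model()].
#' @export
make_demon <- function(n = 0L, err_meas = 0.05, delta = 0.35, r = 0.5,
                       rho = 0.1, check_negative_entropy = TRUE) {
  stopifnot(err_meas > 0, err_meas < 0.5, delta > 0, delta < 0.5,
            r > 0, r <= 1, rho > 0, rho < 0.5)
  cm <- .copy_kernel(err_meas)
  q <- array(0, c(2, 2, 2))
  for (y in 1:2) q[, y, ] <- cm           # y' measures x, ignores y
  # x-kernel: detailed balance w.r.t. (1 - delta) on the measured state y
  w <- array(0, c(2, 2, 2))
  for (y in 1:2) {
    other <- 3L - y
    w[y, other, y] <- r                    # move into preferred state
    w[other, other, y] <- 1 - r
    w[other, y, y] <- r * delta / (1 - delta)  # escape, suppressed
    w[y, y, y] <- 1 - w[other, y, y]
  }
  p1 <- matrix(c((1 - rho) / 2, rho / 2, rho / 2, (1 - rho) / 2), 2, 2)
  m <- bipartite_model(w, q, p1, n = n)
  if (check_negative_entropy) {
    pf <- path_functionals(m, 4L)
    if (sum(pf$p * (pf$ds_bath + pf$ds_x)) >= 0) {
      stop("demon parameters do not yield negative mean entropy change")
    }
  }
  m
}

#' Random bipartite model (Dirichlet kernels)
#'
#' Draws kernel rows and the initial joint from a symmetric Dirichlet
#' distribution; all probabilities are strictly positive, so every path
#' has positive probability.
#'
#' @param n delay.
#' @param Sx,Sy alphabet sizes.
#' @param alpha Dirichlet concentration (default 1, i.e. uniform).
#' @param seed optional integer seed.
#' @param x_cond passed to [bipartite_model()].
#' @return A [bipartite_model()].
#' @export
random_bipartite_model <- function(n = 0L, Sx = 2L, Sy = 2L, alpha = 1,
                                   seed = NULL, x_cond = "lagged") {
  if (!is.null(seed)) set.seed(seed)
  rdir <- function(k) { g <- stats::rgamma(k, alpha) + 1e-6; g / sum(g) }
  w <- array(0, c(Sx, Sx, Sy))
  q <- array(0, c(Sy, Sy, Sx))
  for (x in 1:Sx) for (y in 1:Sy) w[, x, y] <- rdir(Sx)
  for (y in 1:Sy) for (x in 1:Sx) q[, y, x] <- rdir(Sy)
  p1 <- matrix(rdir(Sx * Sy), Sx, Sy)
  bipartite_model(w, q, p1, n = n, x_cond = x_cond)
}
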