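# Closed-form Gaussian information measures for a stationary bivariate
# first-order linear process, and ordinary-least-squares Granger
# causality / anti-causality, establishing the factor-of-two
# equivalences GC = 2 TE and anti-GC = 2 BTE.

#' Stationary bivariate VAR(1) model
#'
#' The linear recursion
#' \deqn{x_{k+1} = a x_k + \xi_k, \qquad
#'       y_{k+1} = b y_k + c x_k + \eta_k,}
#' with independent zero-mean Gaussian noises of variances `var_xi`,
#' `var_eta`.  Stability (spectral radius of the coefficient matrix < 1)
#' is enforced.
#'
#' @param a,b,c recursion coefficients.
#' @param var_xi,var_eta noise variances (> 0).
#' @return An object of class `var1_model`.
#' @export
var1_model <- function(a = 0.5, b = 0.3, c = 0.4, var_xi = 1, var_eta = 1) {
  stopifnot(var_xi > 0, var_eta > 0)
  A <- rbind(c(a, 0), c(c, b))
  if (max(abs(eigen(A, only.values = TRUE)$values)) >= 1) {
    stop("unstable coefficients: spectral radius must be < 1")
  }
  structure(list(a = a, b = b, c = c, var_xi = var_xi, var_eta = var_eta,
                 A = A, Q = diag(c(var_xi, var_eta))),
            class = "var1_model")
}

#' @export
print.var1_model <- function(x, ...) {
  cat(sprintf("<var1_model> a = %g, b = %g, c = %g, noise vars = (%g, %g)\n",
              x$a, x$b, x$c, x$var_xi, x$var_eta))
  invisible(x)
}

#' Stationary covariance over a window of consecutive times
#'
#' Solves the discrete Lyapunov equation
#' \eqn{\Sigma_0 = A \Sigma_0 A' + Q} for the single-time stationary
#' covariance and propagates cross-covariances
#' \eqn{Cov(z_{k+h}, z_k) = A^h \Sigma_0} to assemble the covariance of
#' the stacked vector \eqn{(x_k, y_k, \ldots, x_{k+W-1}, y_{k+W-1})}.
#'
#' @param model a [var1_model()].
#' @param W window length (number of consecutive time steps).
#' @return A `2W x 2W` symmetric positive-definite covariance matrix.
#' @export
stationary_covariance <- function(model, W = 2L) {
  stopifnot(inherits(model, "var1_model"), W >= 1L)
  A <- model$A
  S0 <- matrix(solve(diag(4) - A %x% A, as.vector(model$Q)), 2, 2)
  S0 <- (S0 + t(S0)) / 2
  if (max(abs(S0 - A %*% S0 %*% t(A) - model$Q)) > 1e-10) {
    stop("Lyapunov solve failed to reach tolerance 1e-10")
  }
  G <- matrix(0, 2 * W, 2 * W)
  Ah <- diag(2)
  blocks <- vector("list", W)
  for (h in 0:(W - 1L)) {
    blocks[[h + 1L]] <- Ah %*% S0
    Ah <- A %*% Ah
  }
  for (i in 1:W) for (j in 1:W) {
    B <- if (i >= j) blocks[[i - j + 1L]] else t(blocks[[j - i + 1L]])
    G[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)] <- B
  }
  (G + t(G)) / 2
}

.logdet <- function(S, idx) {
  if (!length(idx)) return(0)
  d <- determinant(S[idx, idx, drop = FALSE], logarithm = TRUE)
  if (d$sign <= 0) stop("singular or non-positive-definite submatrix")
  as.numeric(d$modulus)
}

#' Gaussian conditional mutual information from a covariance matrix
#'
#' \deqn{I(A;B|C) = \tfrac12 \ln \frac{\det\Sigma_{A\cup C}\,
#'   \det\Sigma_{B\cup C}}{\det\Sigma_C\, \det\Sigma_{A\cup B\cup C}},}
#' with \eqn{\det\Sigma_\emptyset \equiv 1}.  In nats.
#'
#' @param cov covariance matrix.
#' @param a,b,c integer index sets (`c` may be empty).
#' @return An [info_value()] of kind `"CMI"` (or `"MI"` when `c` is
#'   empty).
#' @export
gaussian_cmi <- function(cov, a, b, c = integer(0)) {
  stopifnot(is.matrix(cov), nrow(cov) == ncol(cov))
  v <- 0.5 * (.logdet(cov, c(a, c)) + .logdet(cov, c(b, c)) -
                .logdet(cov, c) - .logdet(cov, c(a, b, c)))
  info_value(max(v, 0), if (length(c)) "CMI" else "MI", estimator = "gaussian")
}

# stacked-window index helpers: variables ordered (x_1, y_1, ..., x_W, y_W)
.ix <- function(t) 2L * t - 1L
.iy <- function(t) 2L * t

#' Gaussian transfer entropy of a VAR(1) model
#'
#' Exact stationary transfer entropy
#' \eqn{I(X_{k-l+1:k}; Y_{k+1} | Y_{k-l+1:k})} from the stationary
#' covariance, in nats.
#'
#' @param model a [var1_model()].
#' @param l history length.
#' @return An [info_value()] of kind `"TE"`.
#' @export
gaussian_te <- function(model, l = 1L) {
  G <- stationary_covariance(model, l + 1L)
  v <- gaussian_cmi(G, .ix(1:l), .iy(l + 1L), .iy(1:l))
  info_value(v$value, "TE", history = l, estimator = "gaussian")
}

#' Gaussian backward transfer entropy of a VAR(1) model
#'
#' Exact stationary backward transfer entropy
#' \eqn{I(X_{m+1:m+l}; Y_m | Y_{m+1:m+l})}, in nats.
#'
#' @inheritParams gaussian_te
#' @return An [info_value()] of kind `"BTE"`.
#' @export
gaussian_bte <- function(model, l = 1L) {
  G <- stationary_covariance(model, l + 1L)
  v <- gaussian_cmi(G, .ix(2:(l + 1L)), .iy(1L), .iy(2:(l + 1L)))
  info_value(v$value, "BTE", history = l, estimator = "gaussian")
}

# conditional variance of one target given predictor indices
.cond_var <- function(G, target, given) {
  if (!length(given)) return(G[target, target])
  Gg <- G[given, given, drop = FALSE]
  cr <- G[target, given, drop = FALSE]
  as.numeric(G[target, target] - cr %*% solve(Gg, t(cr)))
}

# OLS residual variance (maximum-likelihood convention: divisor = n),
# intercept always included; rank-deficient designs fall back to the
# pseudo-inverse with a warning
.ols_resvar <- function(y, X) {
  X <- cbind(1, X)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    warning("collinear design: using pseudo-inverse solution")
    beta <- qr.coef(qx, y)
    beta[is.na(beta)] <- 0
    r <- y - X %*% beta
  } else {
    r <- qr.resid(qx, y)
  }
  mean(r^2)
}

# build the lagged design for the causal regressions on data
.gc_frames <- function(x, y, l) {
  T <- length(x)
  stopifnot(length(y) == T, T > 3L * l + 2L)
  k <- (l):(T - 1L)               # target index k+1
  tgt <- y[k + 1L]
  lagmat <- function(v) sapply(1:l, function(j) v[k - j + 1L])
  list(target = tgt, ylags = lagmat(y), xlags = lagmat(x))
}

#' Granger causality (log variance-ratio measure)
#'
#' The standard Granger-causality measure of X on Y at lag `l`:
#' \deqn{GC = \ln\frac{var(\epsilon')}{var(\epsilon)},}
#' where \eqn{\epsilon'} is the residual of the restricted regression of
#' \eqn{y_{k+1}} on \eqn{y_{k-l+1:k}} and \eqn{\epsilon} that of the full
#' regression that adds \eqn{x_{k-l+1:k}}.  From a model the measure is
#' computed exactly from the stationary covariance (conditional-variance
#' algebra); from data, by ordinary least squares with residual-variance
#' divisor `n` (maximum-likelihood convention) and intercepts included.
#' For Gaussian processes GC equals twice the transfer entropy.
#'
#' @param obj a [var1_model()], or a data frame / matrix with columns
#'   `x`, `y` (one row per time step).
#' @param l lag (history length).
#' @return The GC measure in nats (numeric scalar).
#' @export
granger_causality <- function(obj, l = 1L) {
  if (inherits(obj, "var1_model")) {
    G <- stationary_covariance(obj, l + 1L)
    v_r <- .cond_var(G, .iy(l + 1L), .iy(1:l))
    v_f <- .cond_var(G, .iy(l + 1L), c(.iy(1:l), .ix(1:l)))
    return(log(v_r / v_f))
  }
  obj <- as.data.frame(obj)
  fr <- .gc_frames(obj$x, obj$y, l)
  log(.ols_resvar(fr$target, fr$ylags) /
        .ols_resvar(fr$target, cbind(fr$ylags, fr$xlags)))
}

#' Granger anti-causality (backward prediction)
#'
#' The Granger-style measure for predicting the *past* state of Y from
#' future values: the restricted regression predicts \eqn{y_m} from
#' \eqn{y_{m+1:m+l}}, the full regression adds \eqn{x_{m+1:m+l}}, and
#' \deqn{GC^{\dagger} = \ln\frac{var(\epsilon'^{\dagger})}
#'   {var(\epsilon^{\dagger})}.}
#' For Gaussian processes it equals twice the backward transfer entropy.
#'
#' @inheritParams granger_causality
#' @return The anti-causality measure in nats (numeric scalar).
#' @export
granger_anticausality <- function(obj, l = 1L) {
  if (inherits(obj, "var1_model")) {
    G <- stationary_covariance(obj, l + 1L)
    v_r <- .cond_var(G, .iy(1L), .iy(2:(l + 1L)))
    v_f <- .cond_var(G, .iy(1L), c(.iy(2:(l + 1L)), .ix(2:(l + 1L))))
    return(log(v_r / v_f))
  }
  obj <- as.data.frame(obj)
  rev_obj <- data.frame(x = rev(obj$x), y = rev(obj$y))
  granger_causality(rev_obj, l)
}

#' Gaussian plug-in transfer entropy from data
#'
#' Estimates the stationary Gaussian transfer entropy by applying the
#' log-determinant formula to the sample covariance of the delay-embedded
#' series (window of `l + 1` consecutive times).  This is the
#' information-theoretic counterpart of the OLS Granger regressions
#' computed on the same records: for any sample the two satisfy the
#' factor-2 identity exactly.
#'
#' @param data data frame or matrix with numeric columns `x`, `y`.
#' @param l history length.
#' @return An [info_value()] of kind `"TE"`.
#' @export
gaussian_te_plugin <- function(data, l = 1L) {
  Z <- .window_embed(as.data.frame(data), l)
  v <- gaussian_cmi(stats::cov(Z), .ix(1:l), .iy(l + 1L), .iy(1:l))
  info_value(v$value, "TE", history = l, estimator = "gaussian-plugin")
}

#' Gaussian plug-in backward transfer entropy from data
#'
#' @inheritParams gaussian_te_plugin
#' @return An [info_value()] of kind `"BTE"`.
#' @export
gaussian_bte_plugin <- function(data, l = 1L) {
  Z <- .window_embed(as.data.frame(data), l)
  v <- gaussian_cmi(stats::cov(Z), .ix(2:(l + 1L)), .iy(1L),
                    .iy(2:(l + 1L)))
  info_value(v$value, "BTE", history = l, estimator = "gaussian-plugin")
}

# stack l + 1 consecutive (x, y) pairs per row
.window_embed <- function(data, l) {
  T <- nrow(data)
  stopifnot(T > 3L * l + 2L)
  t0 <- 1:(T - l)
  Z <- matrix(0, length(t0), 2L * (l + 1L))
  for (h in 0:l) {
    Z[, 2L * h + 1L] <- data$x[t0 + h]
    Z[, 2L * h + 2L] <- data$y[t0 + h]
  }
  Z
}

#' Simulate a stationary VAR(1) series
#'
#' Seeded simulation of the bivariate recursion, started from the
#' stationary distribution (via a discarded burn-in).
#'
#' @param model a [var1_model()].
#' @param steps series length.
#' @param seed optional integer seed.
#' @param burnin number of initial steps to discard.
#' @return Data frame with numeric columns `x`, `y`.
#' @export
simulate_var1 <- function(model, steps, seed = NULL, burnin = 200L) {
  stopifnot(inherits(model, "var1_model"), steps >= 1L)
  if (!is.null(seed)) set.seed(seed)
  n <- steps + burnin
  xi <- stats::rnorm(n, sd = sqrt(model$var_xi))
  eta <- stats::rnorm(n, sd = sqrt(model$var_eta))
  x <- as.numeric(stats::filter(xi, model$a, method = "recursive"))
  drive <- model$c * c(0, x[-n]) + eta
  y <- as.numeric(stats::filter(drive, model$b, method = "recursive"))
  data.frame(x = x[(burnin + 1L):n], y = y[(burnin + 1L):n])
}
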