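# Directed information-flow measures computed exactly from a joint path
# distribution: transfer entropy, backward transfer entropy, directed
# information (forward and backward), the discrete learning rate, and the
# sensory capacity of stationary bipartite sensor models.

.flow_paths <- function(paths, direction = c("xy", "yx")) {
  direction <- match.arg(direction)
  if (direction == "yx") swap_processes(paths) else paths
}

#' Transfer entropy at a single step
#'
#' The transfer entropy from the source process to the target process at
#' step `k` with history length `l`,
#' \deqn{I_{tr}(k, l) = I(X_{k-l+1:k} ; Y_{k+1} \mid Y_{k-l+1:k}),}
#' i.e. the information the source's recent path carries about the
#' target's next state beyond the target's own history.  Nonnegative;
#' zero if and only if the target's transition probability ignores the
#' source path.
#'
#' @param paths a [path_dist()].
#' @param k step index (`l <= k <= N-1`).
#' @param l history length (`>= 1`).
#' @param direction `"xy"` (source X, target Y; default) or `"yx"`.
#' @return An [info_value()] of kind `"TE"`.
#' @export
transfer_entropy <- function(paths, k, l = 1L, direction = c("xy", "yx")) {
  stopifnot(inherits(paths, "path_dist"), l >= 1L)
  paths <- .flow_paths(paths, direction)
  N <- paths$N
  if (k - l + 1L < 1L || k + 1L > N) {
    stop(sprintf(
      "insufficient history for step k = %d with l = %d (admissible k: %d..%d)",
      k, l, l, N - 1L))
  }
  fd <- as_finite_dist(paths)
  v <- .cmi(fd, .xcols((k - l + 1L):k), .ycols(k + 1L),
            .ycols((k - l + 1L):k))
  info_value(v, "TE", step = k, history = l,
             direction = match.arg(direction), estimator = "exact")
}

#' Backward transfer entropy at a single step
#'
#' The transfer entropy of the time-reversed pair process, indexed by the
#' backward step `m` (forward time): with history length `l`,
#' \deqn{I_{BT}(m, l) = I(X_{m+1:m+l} ; Y_m \mid Y_{m+1:m+l}).}
#' Equivalently `transfer_entropy(reverse_paths(paths), N - m, l)`.
#' Nonnegative; for `l = 1` it vanishes if and only if the Markov chain
#' \eqn{Y_m \to Y_{m+1} \to X_{m+1}} holds, i.e. the source is an
#' instantaneous (hidden-Markov) observation of the target.
#'
#' @param paths a [path_dist()].
#' @param m backward step index in forward time (`1 <= m <= N-l`).
#' @inheritParams transfer_entropy
#' @return An [info_value()] of kind `"BTE"`.
#' @export
backward_transfer_entropy <- function(paths, m, l = 1L,
                                      direction = c("xy", "yx")) {
  stopifnot(inherits(paths, "path_dist"))
  paths <- .flow_paths(paths, direction)
  v <- transfer_entropy(reverse_paths(paths), paths$N - m, l)
  info_value(v$value, "BTE", step = m, history = l,
             direction = match.arg(direction), estimator = "exact")
}

#' Directed information
#'
#' The cumulative directed information from the source to the target over
#' the horizon,
#' \deqn{DI = I(X_1;Y_1) + \sum_{k=1}^{N-1} I(X_{1:k} ; Y_{k+1} \mid Y_{1:k}),}
#' i.e. the sum of transfer entropies with maximal history plus the
#' initial mutual information.  Nonnegative.
#'
#' @inheritParams transfer_entropy
#' @return An [info_value()] of kind `"DI"`.
#' @export
directed_information <- function(paths, direction = c("xy", "yx")) {
  stopifnot(inherits(paths, "path_dist"))
  paths <- .flow_paths(paths, direction)
  fd <- as_finite_dist(paths)
  v <- .cmi(fd, .xcols(1L), .ycols(1L))
  if (paths$N > 1L) {
    for (k in 1:(paths$N - 1L)) {
      v <- v + .cmi(fd, .xcols(1:k), .ycols(k + 1L), .ycols(1:k))
    }
  }
  info_value(v, "DI", direction = match.arg(direction), estimator = "exact")
}

#' Backward directed information
#'
#' Directed information of the time-reversed pair process: the sum of
#' backward transfer entropies with maximal history plus the mutual
#' information between the two processes at the final time.
#'
#' @inheritParams transfer_entropy
#' @return An [info_value()] of kind `"DI"` (metadata marks it backward).
#' @export
backward_directed_information <- function(paths,
                                          direction = c("xy", "yx")) {
  stopifnot(inherits(paths, "path_dist"))
  paths <- .flow_paths(paths, direction)
  v <- directed_information(reverse_paths(paths))
  info_value(v$value, "DI", direction = match.arg(direction),
             time = "backward", estimator = "exact")
}

#' Discrete learning rate (dynamic information flow)
#'
#' The discrete-time learning rate of the source about the target at step
#' `k`,
#' \deqn{\nu_k = I(X_k ; Y_{k+1}) - I(X_k ; Y_k),}
#' the rate at which the target's update changes its mutual information
#' with the (held) source state.  May be negative.
#'
#' @inheritParams transfer_entropy
#' @return An [info_value()] of kind `"learning_rate"`.
#' @export
learning_rate <- function(paths, k, direction = c("xy", "yx")) {
  stopifnot(inherits(paths, "path_dist"))
  paths <- .flow_paths(paths, direction)
  stopifnot(k >= 1L, k + 1L <= paths$N)
  fd <- as_finite_dist(paths)
  v <- .cmi(fd, .xcols(k), .ycols(k + 1L)) - .cmi(fd, .xcols(k), .ycols(k))
  info_value(v, "learning_rate", step = k, direction = match.arg(direction))
}

#' Sensory capacity of a stationary bipartite sensor model
#'
#' For a Markovian (`n = 0`) bipartite model in its stationary state the
#' sensory capacity is the ratio of the learning rate to the transfer
#' entropy, which reduces to
#' \deqn{C = 1 - I_{BT} / I_{tr}}
#' with the single-step stationary transfer entropy
#' \eqn{I_{tr} = I(X_k; Y_{k+1} | Y_k)} and backward transfer entropy
#' \eqn{I_{BT} = I(X_{k+1}; Y_k | Y_{k+1})} (stationarity makes
#' \eqn{I(X_{k+1};Y_{k+1}) = I(X_k;Y_k)}).  `C` lies in `[0, 1]` and
#' attains 1 exactly for hidden-Markov (instantaneous) sensors.
#'
#' @param model a [bipartite_model()] with `n = 0` admitting a unique
#'   stationary distribution.
#' @return A list with components `capacity`, `te`, `bte` (the latter two
#'   are [info_value()]s evaluated in the stationary state).
#' @export
sensory_capacity <- function(model) {
  stopifnot(inherits(model, "bipartite_model"))
  if (model$n != 0L) stop("sensory capacity requires a Markovian model (n = 0)")
  sd <- stationary_step_dist(model)
  te <- transfer_entropy(sd, 1L)
  bte <- backward_transfer_entropy(sd, 1L)
  if (te$value <= 1e-14) {
    stop("stationary transfer entropy is zero: sensory capacity undefined")
  }
  list(capacity = 1 - bte$value / te$value, te = te, bte = bte)
}
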