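# Horse-race gambling with side information: fair odds (causal or
# anti-causal "cheating bookmaker"), Kelly and alternative bet policies,
# expected log-wealth growth, and the information bounds mirroring the
# thermodynamic second-law bounds.

#' Horse-race game on a joint (side-information, winner) process
#'
#' The target process Y is the sequence of race winners and the source
#' process X the side information.  Before race `k` the gambler can
#' access the side information \eqn{x_{1:k-1}} and the past winners
#' \eqn{y_{1:k-1}} (for the first race, \eqn{x_1}).  Bets are normalized
#' per context (the gambler stakes all wealth each race).  Fair odds
#' satisfy \eqn{\sum_{y_k} 1/o_k(y_k) = 1}:
#' * `odds = "causal"`: \eqn{1/o_k(y_k) = p(y_k | y_{1:k-1})};
#' * `odds = "anticausal"` (cheating bookmaker): \eqn{1/o_k(y_k) =
#'   p(y_k | x_{k+1:N}, y_{k+1:N})} for \eqn{k \le N-1} and
#'   \eqn{1/o_N(y_N) = p(y_N | x_N)}.
#'
#' @param paths a [path_dist()] for the joint (X, Y) process.
#' @param odds `"causal"` or `"anticausal"`.
#' @param bets `"kelly"` (bet the conditional winner probabilities given
#'   the accessible history), `"uniform"`, or a function
#'   `f(paths, k)` returning the per-path log bet fraction placed on the
#'   realized winner of race `k`.
#' @return An object of class `horse_race` carrying per-path, per-race
#'   log bet fractions and log inverse odds.
#' @export
horse_race <- function(paths, odds = c("causal", "anticausal"),
                       bets = "kelly") {
  stopifnot(inherits(paths, "path_dist"))
  odds <- match.arg(odds)
  N <- paths$N
  log_inv_odds <- matrix(0, nrow(paths$tab), N)
  for (k in 1:N) {
    log_inv_odds[, k] <- if (odds == "causal") {
      if (k == 1L) .cond_logp(paths, .ycols(1L))
      else .cond_logp(paths, .ycols(k), .ycols(1:(k - 1L)))
    } else {
      if (k == N) .cond_logp(paths, .ycols(N), .xcols(N))
      else .cond_logp(paths, .ycols(k),
                      c(.xcols((k + 1L):N), .ycols((k + 1L):N)))
    }
  }
  log_bets <- matrix(0, nrow(paths$tab), N)
  for (k in 1:N) {
    log_bets[, k] <- if (is.function(bets)) {
      bets(paths, k)
    } else if (identical(bets, "kelly")) {
      kelly_log_bets(paths, k)
    } else if (identical(bets, "uniform")) {
      rep(-log(paths$y_alphabet), nrow(paths$tab))
    } else stop("unknown bet policy")
  }
  structure(list(paths = paths, odds = odds,
                 bets = if (is.function(bets)) "custom" else bets,
                 log_bets = log_bets, log_inv_odds = log_inv_odds),
            class = "horse_race")
}

#' @export
print.horse_race <- function(x, ...) {
  cat(sprintf("<horse_race> N = %d races, odds = %s, bets = %s\n",
              x$paths$N, x$odds, x$bets))
  invisible(x)
}

#' Kelly bet fractions (log scale, per path and race)
#'
#' The equality-achieving causal policy: bet on each horse its
#' conditional winning probability given the accessible history,
#' \eqn{f_k(y_k) = p(y_k | x_{1:k-1}, y_{1:k-1})} for \eqn{k \ge 2} and
#' \eqn{f_1(y_1) = p(y_1 | x_1)}.
#'
#' @param paths a [path_dist()].
#' @param k race index.
#' @return Numeric vector: per-path log bet fraction on the realized
#'   winner.
#' @export
kelly_log_bets <- function(paths, k) {
  stopifnot(inherits(paths, "path_dist"))
  if (k == 1L) {
    .cond_logp(paths, .ycols(1L), .xcols(1L))
  } else {
    .cond_logp(paths, .ycols(k),
               c(.xcols(1:(k - 1L)), .ycols(1:(k - 1L))))
  }
}

#' Fair odds tables
#'
#' Enumerates the fair inverse-odds \eqn{1/o_k(y_k)} for every
#' positive-probability context, in causal or anti-causal mode.  Inverse
#' odds sum to 1 over the winner within each context.
#'
#' @inheritParams horse_race
#' @param k race index.
#' @return Data frame with the context columns, the winner column and
#'   `inv_odds`.
#' @export
fair_odds <- function(paths, k, odds = c("causal", "anticausal")) {
  stopifnot(inherits(paths, "path_dist"))
  odds <- match.arg(odds)
  N <- paths$N
  ctx <- if (odds == "causal") {
    if (k == 1L) character(0) else .ycols(1:(k - 1L))
  } else {
    if (k == N) .xcols(N) else c(.xcols((k + 1L):N), .ycols((k + 1L):N))
  }
  lio <- if (odds == "causal") {
    if (k == 1L) .cond_logp(paths, .ycols(1L))
    else .cond_logp(paths, .ycols(k), ctx)
  } else {
    .cond_logp(paths, .ycols(k), ctx)
  }
  cols <- c(ctx, .ycols(k))
  keep <- !duplicated(.pkey(paths$tab, cols)) & paths$probs > .ZERO_TOL
  out <- paths$tab[keep, cols, drop = FALSE]
  out$inv_odds <- exp(lio[keep])
  rownames(out) <- NULL
  out
}

#' Expected wealth growth of a game
#'
#' The ensemble average of the total log wealth growth
#' \eqn{G = \sum_k \ln(f_k(y_k)\, o_k(y_k))}, by exact enumeration.
#'
#' @param game a [horse_race()].
#' @return List with `expected_growth`, per-race means `per_race`, and
#'   the per-path growth `per_path`.
#' @export
expected_growth <- function(game) {
  stopifnot(inherits(game, "horse_race"))
  g <- game$log_bets - game$log_inv_odds
  p <- game$paths$probs
  pos <- p > .ZERO_TOL
  if (any(!is.finite(g[pos, ]))) {
    warning("zero bet on a positive-probability winner: growth is -Inf")
  }
  per_race <- colSums(p[pos] * g[pos, , drop = FALSE])
  list(expected_growth = sum(per_race), per_race = per_race,
       per_path = rowSums(g))
}

#' Information bound on the gambler's wealth growth
#'
#' For causal fair odds the expected growth is bounded by the directed
#' information from the side information to the winners,
#' \eqn{\langle G \rangle \le DI = \sum I_{tr} + I(X_1;Y_1)}.  For the
#' anti-causal (cheating) bookmaker the bound is reduced by the sum of
#' backward transfer entropies,
#' \eqn{\langle G \rangle \le \sum I_{tr} - \sum I_{BT} + I(X_1;Y_1) -
#' I(X_N;Y_N)}, the same form as the tight thermodynamic second-law
#' bound for Markovian interacting dynamics.  The gap is a
#' Kullback-Leibler divergence: nonnegative, and zero exactly for Kelly
#' bets.
#'
#' @param game a [horse_race()].
#' @return List with `expected_growth`, `bound`, `gap` and the
#'   informational terms `di`, `sum_bte_plus_iN`.
#' @export
growth_bound <- function(game) {
  stopifnot(inherits(game, "horse_race"))
  paths <- game$paths
  eg <- expected_growth(game)
  di <- directed_information(paths)$value
  if (game$odds == "causal") {
    bound <- di
    terms <- list(di = di, sum_bte_plus_iN = NA_real_)
  } else {
    bdi <- backward_directed_information(paths)$value
    bound <- di - bdi
    terms <- list(di = di, sum_bte_plus_iN = bdi)
  }
  c(list(expected_growth = eg$expected_growth, bound = bound,
         gap = bound - eg$expected_growth), terms)
}

#' Two-horse race fixture
#'
#' A Markov winner process with a side-information channel: winners
#' persist (`q`-kernel) and are influenced by the side-information
#' process, which evolves autonomously with its own persistence.  Built
#' as a coupled binary bipartite model and enumerated over `N` races;
#' the directed information from side information to winners is strictly
#' positive.
#'
#' @param N number of races.
#' @param q2,w2 kernel parameters passed to [make_coupled_binary()];
#'   the defaults couple the side information into the winners and keep
#'   the side information autonomous.
#' @return A [path_dist()] over (side information, winners).
#' @export
make_race <- function(N = 4L,
                      q2 = c(0.25, 0.65, 0.40, 0.80),
                      w2 = c(0.20, 0.80, 0.20, 0.80)) {
  model <- make_coupled_binary(q2 = q2, w2 = w2)
  enumerate_paths(model, N)
}
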