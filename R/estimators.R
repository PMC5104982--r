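# Plug-in (maximum-likelihood) estimation of stationary transfer entropy
# and backward transfer entropy from a single discrete series, and a
# surrogate-data test for hidden-Markov structure based on the backward
# transfer entropy.

# delay-embed a pair series into the (source history, target next,
# target history) frame used by the stationary TE estimator
.embed_frame <- function(x, y, l) {
  T <- length(x)
  stopifnot(length(y) == T)
  if (T < l + 2L) stop(sprintf("series too short for history length l = %d", l))
  k <- l:(T - 1L)
  tab <- data.frame(row.names = seq_along(k))
  for (j in 1:l) {
    tab[[paste0("xh", j)]] <- x[k - l + j]
    tab[[paste0("yh", j)]] <- y[k - l + j]
  }
  tab$ynext <- y[k + 1L]
  tab
}

#' Plug-in transfer entropy from a discrete series
#'
#' Stationary transfer entropy \eqn{I(X_{k-l+1:k}; Y_{k+1} |
#' Y_{k-l+1:k})} estimated by applying the exact conditional
#' mutual-information functional to the empirical frequency table of the
#' delay-embedded series.  No bias correction is applied.
#'
#' @param x,y discrete series (integer or character vectors of equal
#'   length); `x` is the source.
#' @param l history length.
#' @return An [info_value()] of kind `"TE"` with estimator tag
#'   `"plugin"`.
#' @export
te_plugin <- function(x, y, l = 1L) {
  tab <- .embed_frame(x, y, l)
  fd <- empirical_joint(tab)
  v <- .cmi(fd, paste0("xh", 1:l), "ynext", paste0("yh", 1:l))
  info_value(v, "TE", history = l, estimator = "plugin", n = length(x))
}

#' Plug-in backward transfer entropy from a discrete series
#'
#' The transfer entropy of the reversed series: the series pair is
#' time-reversed and [te_plugin()] applied, estimating the stationary
#' \eqn{I(X_{m+1:m+l}; Y_m | Y_{m+1:m+l})}.
#'
#' @inheritParams te_plugin
#' @return An [info_value()] of kind `"BTE"` with estimator tag
#'   `"plugin"`.
#' @export
bte_plugin <- function(x, y, l = 1L) {
  v <- te_plugin(rev(x), rev(y), l)
  info_value(v$value, "BTE", history = l, estimator = "plugin",
             n = length(x))
}

#' Surrogate-data test for hidden-Markov structure
#'
#' Tests whether a pair series is consistent with the source being an
#' instantaneous (hidden-Markov) observation of the target, i.e. with
#' the Markov chain \eqn{Y_m \to Y_{m+1} \to X_{m+1}}.  The test
#' statistic is the one-step plug-in backward transfer entropy
#' \eqn{\hat I(X_{m+1}; Y_m | Y_{m+1})}.  The null distribution is built
#' by conditional resampling: for every record the source state
#' \eqn{x_{m+1}} is redrawn from the empirical conditional
#' \eqn{\hat p(x | y_{m+1})}, which enforces the Markov chain while
#' preserving the instantaneous source-target coupling.  The null
#' hypothesis is rejected (decision "not hidden-Markov") when the
#' observed statistic exceeds the empirical \eqn{1 - \alpha} null
#' quantile (type-7 quantiles).
#'
#' @inheritParams te_plugin
#' @param n_surrogates number of surrogate resamples (at least 19).
#' @param alpha test level (default 0.05).
#' @param seed optional integer seed.
#' @return List with `bte` (observed [info_value()]), `null_quantile`,
#'   `null_values`, `p_value`, `decision` and a `warning` field (set
#'   when the alphabet is large relative to the sample size).
#' @export
hmm_detection <- function(x, y, n_surrogates = 199L, alpha = 0.05,
                          seed = NULL) {
  if (n_surrogates < 19L) stop("n_surrogates must be at least 19")
  stopifnot(alpha > 0, alpha < 1, length(x) == length(y), length(x) >= 3L)
  if (!is.null(seed)) set.seed(seed)
  obs <- bte_plugin(x, y, 1L)
  T <- length(x)
  m <- 1:(T - 1L)
  rec <- data.frame(ym = y[m], y1 = y[m + 1L], x1 = x[m + 1L])
  groups <- split(seq_len(nrow(rec)), rec$y1)
  xpool <- lapply(groups, function(i) rec$x1[i])
  stat <- function(x1) {
    fd <- empirical_joint(data.frame(x1 = x1, ym = rec$ym, y1 = rec$y1))
    .cmi(fd, "x1", "ym", "y1")
  }
  null_values <- vapply(seq_len(n_surrogates), function(s) {
    xs <- rec$x1
    for (g in seq_along(groups)) {
      i <- groups[[g]]
      xs[i] <- xpool[[g]][sample.int(length(i), length(i), replace = TRUE)]
    }
    stat(xs)
  }, numeric(1))
  qn <- stats::quantile(null_values, 1 - alpha, type = 7, names = FALSE)
  pv <- (sum(null_values >= obs$value) + 1) / (n_surrogates + 1)
  warn <- NULL
  n_cells <- length(unique(x)) * length(unique(y))^2
  if (n_cells > T / 10) {
    warn <- "alphabet large relative to sample size; estimates may be biased"
  }
  list(bte = obs, null_quantile = qn, null_values = null_values,
       p_value = pv,
       decision = if (obs$value > qn) "not hidden-Markov"
                  else "consistent with hidden Markov model",
       alpha = alpha, n_surrogates = n_surrogates, warning = warn)
}
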