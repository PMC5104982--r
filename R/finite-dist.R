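# Finite joint distributions over tuples of symbols, and the Shannon
# primitives evaluated exactly on them.  These are the work-horses behind
# every path-space computation in the package.

.ZERO_TOL <- 1e-15  # probabilities below this are treated as exact zeros

# collapse selected columns of a data frame into a single key per row
.pkey <- function(tab, cols) {
  if (!length(cols)) return(rep.int("", nrow(tab)))
  do.call(paste, c(tab[cols], list(sep = "\r")))
}

# sum probabilities by key; returns a named vector
.psum <- function(key, p) {
  s <- rowsum(p, key, reorder = FALSE)
  stats::setNames(as.vector(s), rownames(s))
}

#' Finite joint distribution
#'
#' A probability distribution over a finite set of outcome tuples.  Each
#' column of `outcomes` is one variable (or one time slice of a variable);
#' each row is one joint outcome.
#'
#' @param outcomes data frame (or matrix) of outcome tuples, one row per
#'   outcome; rows must be unique.
#' @param probs numeric vector of probabilities, same length as
#'   `nrow(outcomes)`; must be nonnegative and sum to 1 within `1e-12`.
#'
#' @return An object of class `finite_dist` with fields `outcomes` and
#'   `probs`.
#' @export
finite_dist <- function(outcomes, probs) {
  if (is.matrix(outcomes)) outcomes <- as.data.frame(outcomes)
  stopifnot(is.data.frame(outcomes), nrow(outcomes) == length(probs))
  probs <- as.numeric(probs)
  if (any(probs < -.ZERO_TOL)) stop("negative probabilities")
  probs[probs < 0] <- 0
  if (abs(sum(probs) - 1) > 1e-12) {
    stop(sprintf("probabilities sum to %.15f, not 1", sum(probs)))
  }
  if (anyDuplicated(.pkey(outcomes, names(outcomes)))) {
    stop("duplicated outcomes")
  }
  rownames(outcomes) <- NULL
  structure(list(outcomes = outcomes, probs = probs), class = "finite_dist")
}

#' @export
print.finite_dist <- function(x, ...) {
  cat(sprintf("<finite_dist> %d outcomes over %d variable(s): %s\n",
              nrow(x$outcomes), ncol(x$outcomes),
              paste(names(x$outcomes), collapse = ", ")))
  invisible(x)
}

#' Marginal distribution over selected variables
#'
#' @param dist a [finite_dist()].
#' @param cols column names (or indices) of the variables to keep.
#' @return A [finite_dist()] over the selected variables.
#' @export
marginal <- function(dist, cols) {
  stopifnot(inherits(dist, "finite_dist"))
  if (is.numeric(cols)) cols <- names(dist$outcomes)[cols]
  key <- .pkey(dist$outcomes, cols)
  keep <- !duplicated(key)
  p <- .psum(key, dist$probs)
  finite_dist(dist$outcomes[keep, cols, drop = FALSE], unname(p[key[keep]]))
}

#' Shannon entropy of a finite distribution
#'
#' Computes \eqn{-\sum_i p_i \ln p_i} with the convention
#' \eqn{0 \ln 0 = 0}.  Result in nats.
#'
#' @param dist a [finite_dist()].
#' @return An [info_value()] of kind `"entropy"`.
#' @export
entropy <- function(dist) {
  stopifnot(inherits(dist, "finite_dist"))
  p <- dist$probs[dist$probs > .ZERO_TOL]
  info_value(-sum(p * log(p)), "entropy")
}

# core conditional-mutual-information evaluator; a, b, c are column-name
# vectors of dist$outcomes (c may be empty -> plain mutual information)
.cmi <- function(dist, a, b, c = character(0)) {
  tab <- dist$outcomes
  p <- dist$probs
  kabc <- .pkey(tab, c(a, b, c))
  pabc <- .psum(kabc, p)
  keep <- !duplicated(kabc)
  cells <- tab[keep, , drop = FALSE]
  pc_abc <- unname(pabc[kabc[keep]])
  pac <- .psum(.pkey(cells, c(a, c)), pc_abc)
  pbc <- .psum(.pkey(cells, c(b, c)), pc_abc)
  p_ac <- unname(pac[.pkey(cells, c(a, c))])
  p_bc <- unname(pbc[.pkey(cells, c(b, c))])
  if (length(c)) {
    pcc <- .psum(.pkey(cells, c), pc_abc)
    p_c <- unname(pcc[.pkey(cells, c)])
  } else {
    p_c <- rep.int(1, nrow(cells))
  }
  pos <- pc_abc > .ZERO_TOL
  sum(pc_abc[pos] *
        (log(pc_abc[pos]) + log(p_c[pos]) - log(p_ac[pos]) - log(p_bc[pos])))
}

#' Mutual information between two variable groups
#'
#' \eqn{I(A;B) = \sum p(a,b) \ln[p(a,b) / (p(a) p(b))]}, in nats.
#' Nonnegative; zero if and only if the joint factorizes.
#'
#' @param dist a [finite_dist()] whose columns cover both groups.
#' @param a,b column names of the two groups.  When `dist` has exactly two
#'   columns they default to the first and second column.
#' @return An [info_value()] of kind `"MI"`.
#' @export
mutual_information <- function(dist, a = NULL, b = NULL) {
  stopifnot(inherits(dist, "finite_dist"))
  nm <- names(dist$outcomes)
  if (is.null(a) && is.null(b)) {
    if (length(nm) != 2L) stop("specify variable groups `a` and `b`")
    a <- nm[1L]; b <- nm[2L]
  }
  info_value(.cmi(dist, a, b), "MI")
}

#' Conditional mutual information I(A;B|C)
#'
#' \eqn{I(A;B|C) = \sum p(a,b,c) \ln[p(a,b|c) / (p(a|c) p(b|c))]}, in
#' nats.  Nonnegative; zero if and only if A and B are conditionally
#' independent given C.
#'
#' @param dist a [finite_dist()].
#' @param a,b,c column names of the three groups.  When `dist` has exactly
#'   three columns they default to columns 1, 2 and 3.
#' @return An [info_value()] of kind `"CMI"`.
#' @export
conditional_mutual_information <- function(dist, a = NULL, b = NULL,
                                           c = NULL) {
  stopifnot(inherits(dist, "finite_dist"))
  nm <- names(dist$outcomes)
  if (is.null(a) && is.null(b) && is.null(c)) {
    if (length(nm) != 3L) stop("specify variable groups `a`, `b`, `c`")
    a <- nm[1L]; b <- nm[2L]; c <- nm[3L]
  }
  info_value(.cmi(dist, a, b, c), "CMI")
}

#' Kullback-Leibler divergence between two finite distributions
#'
#' \eqn{D_{KL}(p \| q) = \sum_i p_i \ln(p_i / q_i)}, in nats.  The two
#' distributions must live on the same outcome space.  When `p` puts mass
#' where `q` has none the divergence is `Inf` (absolute continuity fails);
#' this is returned as an explicit infinite value, not an error.
#'
#' @param p,q [finite_dist()] objects on the same outcome space.
#' @return An [info_value()] of kind `"KL"`.
#' @export
kl_divergence <- function(p, q) {
  stopifnot(inherits(p, "finite_dist"), inherits(q, "finite_dist"))
  if (!identical(sort(names(p$outcomes)), sort(names(q$outcomes)))) {
    stop("outcome spaces differ (variable names do not match)")
  }
  kp <- .pkey(p$outcomes, names(p$outcomes))
  kq <- .pkey(q$outcomes, names(p$outcomes))
  if (!setequal(kp, kq)) stop("outcome spaces differ (outcome sets differ)")
  qp <- q$probs[match(kp, kq)]
  pos <- p$probs > .ZERO_TOL
  if (any(pos & qp <= .ZERO_TOL)) {
    return(info_value(Inf, "KL"))
  }
  info_value(sum(p$probs[pos] * (log(p$probs[pos]) - log(qp[pos]))), "KL")
}

#' Empirical (maximum-likelihood) joint distribution from samples
#'
#' Builds the plug-in frequency table over selected coordinates of a set
#' of sampled tuples.  No bias correction is applied: the estimator is the
#' exact information functional applied to the empirical measure.
#'
#' @param samples data frame or matrix, one sampled tuple per row.
#' @param cols columns to retain (names or indices); defaults to all.
#' @return A [finite_dist()].
#' @export
empirical_joint <- function(samples, cols = NULL) {
  if (is.matrix(samples)) samples <- as.data.frame(samples)
  stopifnot(is.data.frame(samples))
  if (nrow(samples) == 0L) stop("no samples")
  if (is.null(cols)) cols <- names(samples)
  if (is.numeric(cols)) cols <- names(samples)[cols]
  tab <- samples[cols]
  key <- .pkey(tab, cols)
  keep <- !duplicated(key)
  counts <- .psum(key, rep.int(1, nrow(tab)))
  finite_dist(tab[keep, , drop = FALSE],
              unname(counts[key[keep]]) / nrow(tab))
}
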