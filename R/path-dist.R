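# Exact joint distributions over length-N paths of a pair process
# (x_{1:N}, y_{1:N}).  The table representation (columns x1..xN, y1..yN
# plus a probability vector) is the universal oracle input for every
# information measure in the package.

.xcols <- function(k) paste0("x", k)
.ycols <- function(k) paste0("y", k)

#' Joint path distribution
#'
#' Exact probability table over all length-`N` paths of a finite-alphabet
#' pair process.  Columns `x1..xN` and `y1..yN` of `tab` hold the symbols
#' (coded `1..S`); `probs` holds the path probabilities.
#'
#' @param tab data frame with integer columns `x1..xN`, `y1..yN`.
#' @param probs numeric path probabilities (sum to 1 within `1e-12`).
#' @param x_alphabet,y_alphabet number of symbols of each process.
#' @return An object of class `path_dist`.
#' @export
path_dist <- function(tab, probs, x_alphabet, y_alphabet) {
  N <- ncol(tab) / 2L
  stopifnot(N == round(N),
            all(c(.xcols(1:N), .ycols(1:N)) %in% names(tab)))
  fd <- finite_dist(tab[c(.xcols(1:N), .ycols(1:N))], probs)
  structure(list(N = as.integer(N), tab = fd$outcomes, probs = fd$probs,
                 x_alphabet = as.integer(x_alphabet),
                 y_alphabet = as.integer(y_alphabet)),
            class = "path_dist")
}

#' @export
print.path_dist <- function(x, ...) {
  cat(sprintf("<path_dist> N = %d, |X| = %d, |Y| = %d, %d paths\n",
              x$N, x$x_alphabet, x$y_alphabet, nrow(x$tab)))
  invisible(x)
}

# view a path distribution as a finite_dist (optionally marginalized)
as_finite_dist <- function(paths, cols = NULL) {
  fd <- finite_dist(paths$tab, paths$probs)
  if (is.null(cols)) fd else marginal(fd, cols)
}

# per-path log conditional probability ln p(target | given), evaluated at
# each row of the path table; rows with zero path probability yield NaN
# and must be masked by the caller.
.cond_logp <- function(paths, target, given = character(0)) {
  tab <- paths$tab
  p <- paths$probs
  ktg <- .pkey(tab, c(target, given))
  ptg <- .psum(ktg, p)
  lt <- log(unname(ptg[ktg]))
  if (!length(given)) return(lt)
  kg <- .pkey(tab, given)
  pg <- .psum(kg, p)
  lt - log(unname(pg[kg]))
}

#' Time-reverse a joint path distribution
#'
#' Returns the distribution of the time-reversed trajectories
#' \eqn{\bar{x}_j = x_{N-j+1}}, \eqn{\bar{y}_j = y_{N-j+1}}.  Applying
#' the reversal twice is the identity.
#'
#' @param paths a [path_dist()].
#' @return A [path_dist()] of the reversed pair process.
#' @export
reverse_paths <- function(paths) {
  stopifnot(inherits(paths, "path_dist"))
  N <- paths$N
  tab <- paths$tab[c(.xcols(N:1), .ycols(N:1))]
  names(tab) <- c(.xcols(1:N), .ycols(1:N))
  path_dist(tab, paths$probs, paths$x_alphabet, paths$y_alphabet)
}

# swap the roles of the two processes (X <-> Y)
swap_processes <- function(paths) {
  N <- paths$N
  tab <- paths$tab[c(.ycols(1:N), .xcols(1:N))]
  names(tab) <- c(.xcols(1:N), .ycols(1:N))
  path_dist(tab, paths$probs, paths$y_alphabet, paths$x_alphabet)
}
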