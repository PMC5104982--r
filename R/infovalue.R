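#' Information values
#'
#' All information quantities in bteflow are returned as `info_value`
#' objects: a numeric value in nats together with metadata describing what
#' was computed (kind of quantity, direction, time index, history length,
#' estimator).  Natural logarithms are used throughout so that information
#' terms are commensurable with entropy-production terms (Boltzmann
#' constant set to 1).
#'
#' @param value numeric scalar, in nats.  May be `Inf` for a
#'   Kullback-Leibler divergence whose absolute continuity fails.
#' @param kind one of `"entropy"`, `"MI"`, `"CMI"`, `"TE"`, `"BTE"`,
#'   `"DI"`, `"learning_rate"`, `"KL"`.
#' @param ... named metadata fields (e.g. `step`, `history`, `direction`,
#'   `estimator`).
#'
#' @return An object of class `info_value`.
#' @export
info_value <- function(value, kind, ...) {
  kinds <- c("entropy", "MI", "CMI", "TE", "BTE", "DI", "learning_rate", "KL")
  kind <- match.arg(kind, kinds)
  value <- as.numeric(value)
  stopifnot(length(value) == 1L)
  # clip tiny negative round-off; learning rates are genuinely signed
  if (kind != "learning_rate" && !is.infinite(value)) {
    if (value < -1e-9) {
      stop(sprintf("negative %s (%.3g nats): invalid distribution input?",
                   kind, value))
    }
    if (value < 0) value <- 0
  }
  structure(list(value = value, kind = kind, meta = list(...)),
            class = "info_value")
}

#' @export
as.double.info_value <- function(x, ...) x$value

#' @export
print.info_value <- function(x, ...) {
  m <- x$meta[lengths(x$meta) > 0]
  tag <- if (length(m)) {
    paste0(" [", paste(names(m), unlist(lapply(m, paste, collapse = ":")),
                       sep = "=", collapse = ", "), "]")
  } else ""
  cat(sprintf("<%s> %.6f nats%s\n", x$kind, x$value, tag))
  invisible(x)
}

#' Convert nats to bits (display helper)
#'
#' @param x an `info_value` or numeric value in nats.
#' @return numeric value in bits.
#' @export
in_bits <- function(x) as.numeric(x) / log(2)
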