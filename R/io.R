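# Reading paired time series (TSV/CSV), model configurations (JSON/YAML)
# and writing JSON reports.

#' Read a paired time series
#'
#' Reads a delimited table (tab- or comma-separated, chosen by file
#' extension) with a header row of variable names and one row per time
#' step.  Discrete series are read as character symbols unless
#' `discretize` is given; real-valued series must be discretized
#' explicitly (equal-frequency binning) before information estimation —
#' binning is never silent.
#'
#' @param path file path (`.tsv`/`.txt` tab-separated, `.csv`
#'   comma-separated).
#' @param discretize optional integer: number of equal-frequency bins to
#'   apply to numeric columns.
#' @return Data frame of symbol series.
#' @export
read_series <- function(path, discretize = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("empty series file: ", path)
  if (any(is.na(tab) | tab == "")) stop("missing values are not allowed")
  num <- vapply(tab, function(v) !anyNA(suppressWarnings(as.numeric(v))),
                logical(1))
  if (!is.null(discretize)) {
    stopifnot(discretize >= 2)
    for (j in which(num)) {
      v <- as.numeric(tab[[j]])
      br <- stats::quantile(v, probs = seq(0, 1, length.out = discretize + 1))
      tab[[j]] <- as.integer(cut(v, unique(br), include.lowest = TRUE))
    }
  } else if (any(num)) {
    # numeric-looking columns with few levels are treated as symbols
    for (j in which(num)) {
      if (length(unique(tab[[j]])) > 50L) {
        stop("column '", names(tab)[j], "' looks real-valued; ",
             "pass `discretize` to bin it explicitly")
      }
    }
  }
  tab
}

#' Read a bipartite model configuration
#'
#' Accepts JSON or YAML with fields `w`, `q` (kernel tables, nested
#' lists indexed `[new][old][cond]`), `p1`, and optional `n`, `x_cond`.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return A [bipartite_model()].
#' @export
read_model_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  to_array <- function(a) {
    # stored nesting [new][old][cond]; jsonlite may pre-simplify to an array
    if (is.array(a) && length(dim(a)) == 3L) return(a)
    S1 <- length(a); S2 <- length(a[[1L]]); S3 <- length(a[[1L]][[1L]])
    arr <- array(0, c(S1, S2, S3))
    for (i in 1:S1) for (j in 1:S2) arr[i, j, ] <- unlist(a[[i]][[j]])
    arr
  }
  w <- to_array(cfg$w)
  q <- to_array(cfg$q)
  p1 <- if (is.matrix(cfg$p1)) cfg$p1 else
    matrix(unlist(cfg$p1), nrow = dim(w)[1L], byrow = TRUE)
  bipartite_model(w, q, p1,
                  n = if (is.null(cfg$n)) 0L else cfg$n,
                  x_cond = if (is.null(cfg$x_cond)) "lagged" else cfg$x_cond)
}

#' Write a bipartite model configuration
#'
#' @param model a [bipartite_model()].
#' @param path output path (`.json` or `.yaml`).
#' @return `path`, invisibly.
#' @export
write_model_config <- function(model, path) {
  stopifnot(inherits(model, "bipartite_model"))
  from_array <- function(a) {
    a <- aperm(a, c(3, 2, 1))  # internal [new, old, cond] -> [new][old][cond]
    lapply(seq_len(dim(a)[3L]), function(i)
      lapply(seq_len(dim(a)[2L]), function(j) unname(a[, j, i])))
  }
  cfg <- list(w = from_array(model$w), q = from_array(model$q),
              p1 = lapply(seq_len(nrow(model$p1)),
                          function(i) unname(model$p1[i, ])),
              n = model$n, x_cond = model$x_cond)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(cfg, path)
  } else {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Write a JSON report
#'
#' Reports carry a reproducibility block (package version, seed, and a
#' hash of the settings) alongside the results; numbers are written at
#' full precision so a re-parsed report reproduces all values bitwise.
#'
#' @param results named list of results.
#' @param path output path, or `""` for stdout.
#' @param seed seed used for the run (may be `NULL`).
#' @param settings named list echoed into the report.
#' @return The report list, invisibly.
#' @export
write_report <- function(results, path = "", seed = NULL, settings = list()) {
  rep <- list(
    schema = "bteflow-report/1",
    reproducibility = list(
      package = "bteflow",
      version = as.character(utils::packageVersion("bteflow")),
      seed = seed,
      config_hash = sum(utf8ToInt(paste(
        names(settings), vapply(settings, function(s)
          paste(format(s, digits = 17), collapse = ","), ""),
        collapse = ";")))
    ),
    settings = settings,
    results = results
  )
  js <- jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  if (nzchar(path)) writeLines(js, path) else cat(js, "\n")
  invisible(rep)
}
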