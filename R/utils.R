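#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

## Structured conditions: config errors map to CLI exit code 2,
## data/format errors to exit code 3.
stop_config <- function(msg) {
  stop(structure(class = c("caburst_config_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_data <- function(msg) {
  stop(structure(class = c("caburst_data_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

assert_that <- function(cond, msg, kind = c("config", "data")) {
  if (!isTRUE(cond)) {
    if (match.arg(kind) == "config") stop_config(msg) else stop_data(msg)
  }
  invisible(TRUE)
}

#' Significance stars for a p-value
#'
#' Standard annotation: `***` for p < 0.001, `**` for p < 0.01, `*` for
#' p < 0.05, `"ns"` otherwise.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return character vector of the same length.
#' @export
#' @examples
#' significance_stars(c(0.2, 0.04, 0.004, 2e-4))
significance_stars <- function(p) {
  assert_that(all(is.finite(p) & p >= 0 & p <= 1), "p-values must lie in [0, 1]")
  out <- rep("ns", length(p))
  out[p < 0.05]  <- "*"
  out[p < 0.01]  <- "**"
  out[p < 0.001] <- "***"
  out
}

## trapezoidal integral of y over x; single point integrates to 0
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-n] + y[-1]) / 2)
}

## homogeneous Poisson event times on [t0, t1)
rpois_times <- function(rate, t0, t1) {
  if (rate <= 0 || t1 <= t0) return(numeric(0))
  n <- stats::rpois(1L, rate * (t1 - t0))
  sort(stats::runif(n, t0, t1))
}

## standard error of the mean
sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

## deterministic md5 of an R object (via canonical JSON) for provenance
object_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f), add = TRUE)
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(f))
}

## derive a child RNG seed stream from a master seed (kept below 2^31)
derive_seeds <- function(seed, n) {
  seed <- as.integer(abs(as.numeric(seed)) %% 2147483646)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
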