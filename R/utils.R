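# Error, logging and RNG plumbing shared across modules.

#' @noRd
phytoStop <- function(msg, class = "phytoValidationError") {
  stop(errorCondition(msg, class = unique(c(class, "phytoValidationError"))))
}

#' @noRd
qcWarn <- function(msg, class = "phytoQC") {
  warning(warningCondition(msg, class = c(class, "phytoQC")))
}

# Log levels in increasing severity.
.logLevels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)

#' Set or query the logging threshold
#'
#' Messages below the threshold are suppressed. Log lines go to standard
#' error with a timestamp, as is conventional for pipeline tools.
#'
#' @param level one of `"debug"`, `"info"`, `"warn"`, `"error"`.
#' @return the previous level, invisibly.
#' @export
logLevel <- function(level = c("info", "debug", "warn", "error")) {
  level <- match.arg(level)
  old <- getOption("phytoRSI.log_level", "info")
  options(phytoRSI.log_level = level)
  invisible(old)
}

#' @noRd
logMsg <- function(msg, level = "info") {
  threshold <- getOption("phytoRSI.log_level", "info")
  if (.logLevels[[level]] >= .logLevels[[threshold]]) {
    message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"),
                    toupper(level), msg))
  }
  invisible(NULL)
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Seeds the generator, evaluates `expr`, and restores the caller's RNG
#' state so that library code never clobbers the global random stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' @noRd
stopifnotScalarNumeric <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    phytoStop(sprintf("'%s' must be a single finite number", name))
  }
  invisible(x)
}

# Linear interpolation that errors (rather than returning NA) outside the
# sampled range; profile lookups must never silently extrapolate.
#' @noRd
interpAt <- function(x, y, x0, what = "value") {
  if (x0 < min(x) || x0 > max(x)) {
    phytoStop(sprintf("%s requested at %.3f m, outside sampled range [%.3f, %.3f] m",
                      what, x0, min(x), max(x)),
              class = "phytoCoverageError")
  }
  approx(x, y, xout = x0, ties = "ordered")$y
}
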