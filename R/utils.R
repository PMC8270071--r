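#' Run code with a temporary RNG seed
#'
#' Saves and restores \code{.Random.seed} so that seeded helpers never
#' disturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of \code{code}.
#' @keywords internal
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Merge possibly overlapping half-open intervals
#'
#' Intervals are treated as half-open \code{[start, end)}; touching
#' intervals (end of one equals start of the next) are merged, because a
#' shared endpoint leaves no uncovered gap.
#'
#' @param starts,ends numeric vectors of equal length.
#' @return a two-column matrix (\code{start}, \code{end}) of disjoint,
#'   sorted intervals; zero rows if the input is empty or all degenerate.
#' @export
merge_intervals <- function(starts, ends) {
  stopifnot(length(starts) == length(ends))
  keep <- is.finite(starts) & is.finite(ends) & ends > starts
  starts <- starts[keep]; ends <- ends[keep]
  if (length(starts) == 0L) {
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1]; me <- ends[1]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= me) {
      me <- max(me, ends[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- starts[i]; me <- ends[i]
    }
  }
  out_s <- c(out_s, ms); out_e <- c(out_e, me)
  cbind(start = out_s, end = out_e)
}

#' Total length of an interval union
#' @param intervals matrix from [merge_intervals()].
#' @return numeric scalar.
#' @export
interval_union_length <- function(intervals) {
  if (nrow(intervals) == 0L) return(0)
  sum(intervals[, "end"] - intervals[, "start"])
}

#' Clip intervals to a range and drop empty pieces
#' @keywords internal
clip_intervals <- function(intervals, lo, hi) {
  if (nrow(intervals) == 0L) return(intervals)
  s <- pmax(intervals[, "start"], lo)
  e <- pmin(intervals[, "end"], hi)
  keep <- e > s
  cbind(start = s[keep], end = e[keep])
}

# Rounding half away from zero (base round() is round-half-even).
round_half_away <- function(x) trunc(x + 0.5 * sign(x))

#' Structured log message
#'
#' Writes "LEVEL timestamp message" lines to stderr and, optionally, to a
#' log file. Levels below the package option `aacscore.log_level`
#' ("INFO" by default) are suppressed.
#' @keywords internal
aac_log <- function(level = "INFO", ..., file = NULL) {
  levels <- c(DEBUG = 1L, INFO = 2L, WARN = 3L, ERROR = 4L)
  threshold <- getOption("aacscore.log_level", "INFO")
  if (levels[[level]] < levels[[threshold]]) return(invisible(NULL))
  line <- sprintf("%-5s %s %s", level,
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  paste0(..., collapse = ""))
  cat(line, "\n", file = stderr(), sep = "")
  if (!is.null(file)) cat(line, "\n", file = file, append = TRUE, sep = "")
  invisible(NULL)
}

# Validation helper: stop with the name of the violated invariant.
check_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
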