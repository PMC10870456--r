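#' @title Internal validation and condition helpers
#' @noRd
ls_abort <- function(message, class, ...) {
  stop(structure(
    class = c(class, "leansim_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         closed_lower = TRUE, closed_upper = TRUE,
                         finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    ls_abort(sprintf("`%s` must be a single numeric value", name),
             "leansim_error_validation", field = name)
  }
  if (finite && !is.finite(x)) {
    ls_abort(sprintf("`%s` must be finite", name),
             "leansim_error_validation", field = name)
  }
  lo_ok <- if (closed_lower) x >= lower else x > lower
  hi_ok <- if (closed_upper) x <= upper else x < upper
  if (!lo_ok || !hi_ok) {
    ls_abort(sprintf(
      "`%s` = %g is outside %s%g, %g%s", name, x,
      if (closed_lower) "[" else "(", lower, upper,
      if (closed_upper) "]" else ")"
    ), "leansim_error_validation", field = name)
  }
  invisible(x)
}

#' Draw from a truncated normal by rejection, clamping after max_tries
#'
#' Used by the cohort generator so that physiologic bounds are respected
#' without distorting the bulk of the distribution.
#' @noRd
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf,
                        max_tries = 1000L) {
  if (any(lower > mean - 6 * sd & upper < mean + 6 * sd &
          (upper - lower) <= 0)) {
    ls_abort("truncation bounds exclude the distribution",
             "leansim_error_spec")
  }
  if (any(lower >= upper)) {
    ls_abort("truncation bounds exclude the distribution",
             "leansim_error_spec")
  }
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  tries <- 0L
  while (length(bad) > 0L && tries < max_tries) {
    out[bad] <- rnorm(length(bad), if (length(mean) > 1L) mean[bad] else mean,
                      if (length(sd) > 1L) sd[bad] else sd)
    bad <- which(out < lower | out > upper)
    tries <- tries + 1L
  }
  if (length(bad) > 0L) out[bad] <- pmin(pmax(out[bad], lower), upper)
  out
}

#' Run code with a temporarily seeded RNG, restoring the caller's state
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(code)
}
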