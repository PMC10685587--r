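# Logging and error helpers shared by all modules.

.log_levels <- c(debug = 10L, info = 20L, warning = 30L)

#' Set the package log level
#'
#' @param level one of "debug", "info", "warning"
#' @return the previous level, invisibly
#' @export
lam_log_level <- function(level = c("info", "debug", "warning")) {
  level <- match.arg(level)
  old <- getOption("lamellar.log_level", "info")
  options(lamellar.log_level = level)
  invisible(old)
}

# Log lines follow "LEVEL | module | message".
lam_log <- function(level, module, msg, ...) {
  thr <- .log_levels[[getOption("lamellar.log_level", "info")]]
  if (.log_levels[[level]] >= thr) {
    message(sprintf("%s | %s | %s", toupper(level), module, sprintf(msg, ...)))
  }
  invisible(NULL)
}

# Classed conditions: validation errors map to CLI exit status 2, state
# errors signal misuse of the API (e.g. synthesis before phasing).
lam_abort <- function(msg, ..., class = "lamellar_validation_error") {
  stop(structure(
    class = c(class, "lamellar_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

lam_abort_state <- function(msg, ...) {
  lam_abort(msg, class = "lamellar_state_error", ...)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    lam_abort("%s must be a finite number", name)
  }
  bad_lo <- if (strict_lower) x <= lower else x < lower
  bad_hi <- if (strict_upper) x >= upper else x > upper
  if (bad_lo || bad_hi) {
    lam_abort("%s = %g outside the allowed range %s%g, %g%s", name, x,
              if (strict_lower) "(" else "[", lower, upper,
              if (strict_upper) ")" else "]")
  }
  invisible(x)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Next odd integer >= n, used for symmetric z grids that include z = 0.
odd_at_least <- function(n) {
  n <- as.integer(ceiling(n))
  if (n %% 2L == 0L) n + 1L else n
}
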