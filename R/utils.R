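#' Round half away from zero
#'
#' Decimal rounding that maps 0.5 up (towards +Inf for positive values),
#' matching how percentages are conventionally printed in tables, rather
#' than R's round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(19.25, 1) # 19.3
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Standard error of the mean
#'
#' @param x Numeric vector; NAs removed.
#' @return sd(x)/sqrt(n); NA when fewer than 2 values remain.
#' @export
sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's .Random.seed afterwards. NULL seed = use the
# current RNG stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Parameter validation helper: abort naming the offending field.
check_that <- function(ok, field, msg) {
  if (!isTRUE(ok)) {
    rlang::abort(sprintf("invalid parameter `%s`: %s", field, msg),
                 class = "regenexpr_param_error", field = field)
  }
  invisible(TRUE)
}
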