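# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so library code never perturbs the user's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Round half away from zero
#'
#' The presentation convention for report tables (base `round()` is
#' half-even): 0.95779 renders as 0.958, 0.0005 as 0.001. A small epsilon
#' guards against binary doubles that represent 0.0005 as 0.000499....
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 3L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Tokens embedded in pipe/colon-delimited codes must not contain the
# delimiters themselves, or the encoding becomes unparseable.
check_token <- function(x, what, allow_colon = FALSE) {
  if (!is_string(x) || !nzchar(x))
    stop(what, " must be a non-empty string", call. = FALSE)
  if (grepl("|", x, fixed = TRUE))
    stop(what, " must not contain '|': ", x, call. = FALSE)
  if (!allow_colon && grepl(":", x, fixed = TRUE))
    stop(what, " must not contain ':': ", x, call. = FALSE)
  invisible(x)
}

new_issue <- function(severity, location, message) {
  data.frame(severity = severity, location = location, message = message,
             stringsAsFactors = FALSE)
}

no_issues <- function() {
  data.frame(severity = character(), location = character(),
             message = character(), stringsAsFactors = FALSE)
}
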