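#' Round half away from zero at a fixed number of decimals
#'
#' Reporting convention for tables: values are rounded half-up (0.5 always
#' rounds away from zero), unlike base \code{round}'s banker's rounding.
#' Internal arithmetic is always carried at full precision; this is applied
#' only when formatting reported values.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (may be 0).
#' @return numeric vector rounded half-up.
#' @examples
#' round_half_up(2.5, 0)   # 3, not 2
#' round_half_up(94.125, 2)
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-12) / scale
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`;
# global .Random.seed is restored afterwards. seed = NULL runs as-is.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

stop_if_not_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}

# nm^3 -> um^3
nm3_to_um3 <- function(v) v / 1e9
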