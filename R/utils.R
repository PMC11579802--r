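#' @importFrom rlang %||% abort warn .data
#' @importFrom dplyr mutate filter select arrange summarise group_by ungroup
#'   across left_join bind_rows bind_cols n row_number all_of rename count
#'   distinct pull
#' @importFrom tibble tibble as_tibble
#' @importFrom stats pnorm qnorm dnorm rnorm runif rbinom median quantile
#'   setNames uniroot
NULL

#' Round half away from zero
#'
#' Fixed-point rounding with halves rounded up (away from zero), the
#' convention used for the 2-decimal display of diagnostic metrics and for
#' reconstructing integer confusion counts from published rates. Base
#' `round()` rounds half to even, which disagrees on exact halves.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector rounded to `digits` places.
#' @examples
#' round_half_up(0.5)        # 1, where round(0.5) is 0
#' round_half_up(0.715, 2)   # 0.72
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  # small guard against representation error (e.g. 0.715 * 100 = 71.49999...)
  sign(x) * floor(abs(x) * f + 0.5 + 1e-9) / f
}

# shared constant: the four assessment ages (months)
hine_ages <- function() c(3L, 6L, 9L, 12L)

assert_ages <- function(age_months, arg = "age_months") {
  bad <- setdiff(unique(age_months), hine_ages())
  if (length(bad) > 0) {
    abort(sprintf(
      "`%s` must be one of %s; got: %s",
      arg, paste(hine_ages(), collapse = ", "), paste(bad, collapse = ", ")
    ))
  }
  invisible(age_months)
}
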