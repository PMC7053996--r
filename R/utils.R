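#' Geometric mean
#'
#' Geometric mean of strictly positive values, the per-dendrite summary used
#' for spine-change timecourses. `NA` values are dropped when `na.rm = TRUE`.
#'
#' @param x Numeric vector of positive values.
#' @param na.rm Drop missing values first.
#' @return A single numeric value, or `NA` if no values remain.
#' @export
#' @examples
#' geom_mean(c(1, 4))   # 2
#' geom_mean(c(2, 0.5)) # 1
geom_mean <- function(x, na.rm = TRUE) {
  if (na.rm) x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  if (any(x <= 0)) abort("geom_mean() requires strictly positive values")
  exp(mean(log(x)))
}

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the arithmetic
#' mean. Used as the day-to-day dynamics metric for spine fluorescence.
#'
#' @param x Numeric vector.
#' @param na.rm Drop missing values first.
#' @return sd(x) / mean(x), or `NA` if fewer than 2 values remain.
#' @export
coef_variation <- function(x, na.rm = TRUE) {
  if (na.rm) x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  sd(x) / mean(x)
}

# round half away from zero; base round() rounds half to even
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# standard error of the mean
sem <- function(x, na.rm = TRUE) {
  if (na.rm) x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  sd(x) / sqrt(length(x))
}
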