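#' @importFrom rlang abort .data
#' @importFrom stats pt sd var setNames
NULL

# genotype roles of the trio design, in canonical order
.roles <- c("female_parent", "male_parent", "hybrid")

.abort_design <- function(msg) abort(msg, class = "heteroprot_design_error")
.abort_format <- function(msg) abort(msg, class = "heteroprot_format_error")
.abort_value  <- function(msg) abort(msg, class = "heteroprot_value_error")
.abort_config <- function(msg) abort(msg, class = "heteroprot_config_error")

#' Round half away from zero
#'
#' Base [round()] rounds half to even; count-to-percentage tables in this
#' field round half away from zero (so 15.855 prints as 15.86). Used by
#' [percentage()] and the summary builders.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @keywords internal
round_half_away <- function(x, digits = 0) {
  pow <- 10^digits
  sign(x) * floor(abs(x) * pow + 0.5) / pow
}

#' Convert a count to a rounded percentage
#'
#' `count / total * 100`, rounded half away from zero to `decimals` places.
#' This is the rounding convention used throughout the package's summary
#' tables (e.g. `percentage(697, 4395, 2)` is `15.86`).
#'
#' @param count non-negative count, at most `total`.
#' @param total positive total.
#' @param decimals decimal places to keep (default 2).
#' @return numeric percentage.
#' @examples
#' percentage(697, 4395, 2)
#' percentage(195, 299, 1)
#' @export
percentage <- function(count, total, decimals = 2) {
  if (any(total <= 0)) .abort_value("`total` must be > 0")
  if (any(count < 0 | count > total)) {
    .abort_value("`count` must satisfy 0 <= count <= total")
  }
  round_half_away(count / total * 100, decimals)
}

# pooled-variance two-sided t on vectors of group means/vars/sizes.
# Degenerate pooled variance: zero spread with zero difference gives t = 0,
# p = 1; zero spread with a difference gives t = +/-Inf, p = 0.
.pooled_t_vec <- function(mean_a, mean_b, var_a, var_b, n_a, n_b) {
  df <- n_a + n_b - 2
  sp2 <- ((n_a - 1) * var_a + (n_b - 1) * var_b) / df
  se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
  diff <- mean_a - mean_b
  t <- ifelse(se > 0, diff / se,
              ifelse(diff == 0, 0, sign(diff) * Inf))
  p <- 2 * pt(-abs(t), df)
  list(t_stat = t, df = df, p_value = p)
}
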