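#' Required sample size per group for a rare-carrier association
#'
#' Normal-approximation sample size for detecting an odds ratio `or`
#' when the control carrier frequency is `p0`, with equal numbers of
#' cases and controls. The case frequency comes from exact odds
#' conversion `p1 = p0 * or / (1 - p0 + p0 * or)`, and the log-OR
#' variance uses the uncorrected Woolf form:
#' `n = (z_alpha + z_power)^2 * [1/(p0 q0) + 1/(p1 q1)] / (ln or)^2`,
#' rounded up to the nearest `roundTo` (default 100, reporting
#' granularity).
#'
#' @param p0 control carrier frequency, in (0,1).
#' @param or odds ratio to detect (not 1).
#' @param alpha type-I error rate.
#' @param sided `"one"` (default) or `"two"`.
#' @param power target power, in (0,1).
#' @param roundTo round the result up to this multiple (1 = exact).
#' @return Required n per group.
#' @examples
#' nPerGroup(p0 = 0.0038, or = 3, alpha = 1e-4)  # about 6,100
#' @export
nPerGroup <- function(p0, or, alpha = 1e-4, sided = c("one", "two"),
                      power = 0.80, roundTo = 100) {
  sided <- match.arg(sided)
  stopifnot(p0 > 0, p0 < 1, or > 0, alpha > 0, alpha < 1,
            power > 0, power < 1)
  if (or == 1) stop("or = 1 requires infinite n")
  p1 <- p0 * or / (1 - p0 + p0 * or)
  za <- stats::qnorm(1 - if (sided == "one") alpha else alpha / 2)
  zb <- stats::qnorm(power)
  n <- (za + zb)^2 * (1 / (p0 * (1 - p0)) + 1 / (p1 * (1 - p1))) /
    log(or)^2
  roundTo * ceiling(n / roundTo)
}

#' Power at a given per-group sample size
#'
#' Inverts the normal approximation of [nPerGroup()]:
#' `power = pnorm(sqrt(n * (ln or)^2 / [1/(p0 q0) + 1/(p1 q1)]) - z_alpha)`.
#'
#' @param p0 control carrier frequency.
#' @param or odds ratio.
#' @param n per-group sample size (cases = controls).
#' @param alpha type-I error rate.
#' @param sided `"one"` or `"two"`.
#' @return Power in (0,1).
#' @examples
#' powerAtN(0.0038, 3, n = 6100, alpha = 1e-4)
#' @export
powerAtN <- function(p0, or, n, alpha = 1e-4, sided = c("one", "two")) {
  sided <- match.arg(sided)
  stopifnot(p0 > 0, p0 < 1, or > 0, n >= 1, alpha > 0, alpha < 1)
  p1 <- p0 * or / (1 - p0 + p0 * or)
  za <- stats::qnorm(1 - if (sided == "one") alpha else alpha / 2)
  v <- 1 / (p0 * (1 - p0)) + 1 / (p1 * (1 - p1))
  stats::pnorm(sqrt(n * log(or)^2 / v) - za)
}
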