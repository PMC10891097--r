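#' Exact Clopper-Pearson binomial confidence interval
#'
#' @param k number of successes.
#' @param n number of trials.
#' @param level confidence level (default 0.95).
#' @return Tibble: `k`, `n`, `proportion`, `lower`, `upper`.
#' @examples
#' clopper_pearson(9, 15)
#' @export
clopper_pearson <- function(k, n, level = 0.95) {
  stopifnot(length(k) == 1, length(n) == 1, n >= 1)
  if (k < 0 || k > n) stop("k must lie in [0, n]", call. = FALSE)
  alpha <- (1 - level) / 2
  lower <- if (k == 0) 0 else stats::qbeta(alpha, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - alpha, k + 1, n - k)
  tibble::tibble(k = k, n = n, proportion = k / n, lower = lower,
                 upper = upper)
}

#' Single-arm exact binomial design against an objective performance
#' criterion
#'
#' The phase-2 BBB-opening analysis tests the proportion of successful
#' sonication sessions against a fixed objective performance criterion
#' (OPC): success is declared when the lower limit of the exact 95% CI
#' exceeds the OPC, equivalent to a one-sided exact binomial test at level
#' `alpha`.
#'
#' @param n sample size (default 15).
#' @param p0 OPC, the benchmark proportion under the null (default 0.30).
#' @param p1 design true success proportion (default 0.70).
#' @param alpha one-sided significance level (default 0.025).
#' @return A `binomial_design` list.
#' @export
binomial_design <- function(n = 15, p0 = 0.30, p1 = 0.70, alpha = 0.025) {
  stopifnot(n >= 1, p0 > 0, p1 > p0, p1 < 1, alpha > 0, alpha < 0.5)
  structure(list(n = as.integer(n), p0 = p0, p1 = p1, alpha = alpha),
            class = "binomial_design")
}

#' Critical value, achieved alpha and power of the exact design
#'
#' Enumerates k = 0..n: the critical value is the smallest k whose exact
#' Clopper-Pearson lower bound (at level `1 - 2 alpha`) exceeds `p0` —
#' identical to the smallest k with upper-tail probability
#' `P(X >= k | p0) <= alpha`. Power is the exact upper-tail probability of
#' the critical region under `p1`.
#'
#' @param design a [binomial_design()].
#' @return One-row tibble: `critical_k`, `exact_alpha`, `power`
#'   (`critical_k = NA`, power 0 when no rejection region exists).
#' @examples
#' exact_power(binomial_design(n = 15, p0 = 0.30, p1 = 0.70))
#' @export
exact_power <- function(design) {
  stopifnot(inherits(design, "binomial_design"))
  n <- design$n
  level <- 1 - 2 * design$alpha
  lowers <- vapply(0:n, function(k) clopper_pearson(k, n, level)$lower,
                   numeric(1))
  ok <- which(lowers > design$p0)
  if (length(ok) == 0) {
    warning("no achievable rejection region at this n")
    return(tibble::tibble(critical_k = NA_integer_, exact_alpha = 0,
                          power = 0))
  }
  crit <- min(ok) - 1L # back to 0-based k
  tibble::tibble(
    critical_k = crit,
    exact_alpha = stats::pbinom(crit - 1, n, design$p0, lower.tail = FALSE),
    power = stats::pbinom(crit - 1, n, design$p1, lower.tail = FALSE)
  )
}

#' Evaluate observed session successes against the OPC
#'
#' Effectiveness is demonstrated when the lower limit of the exact CI on
#' the success proportion exceeds the OPC.
#'
#' @param successes logical (or 0/1) vector of per-session success flags.
#' @param level confidence level (default 0.95).
#' @param opc objective performance criterion (default 0.30).
#' @return One-row tibble: `k`, `n`, `proportion`, `lower`, `upper`,
#'   `effective`.
#' @export
success_proportion_evaluation <- function(successes, level = 0.95,
                                          opc = 0.30) {
  successes <- as.logical(successes)
  if (length(successes) < 1) stop("need at least one observation",
                                  call. = FALSE)
  ci <- clopper_pearson(sum(successes), length(successes), level)
  dplyr::mutate(ci, effective = .data$lower > opc)
}

#' Carboplatin dose by the Calvert formula
#'
#' `dose (mg) = target AUC x (GFR + 25)`.
#'
#' @param target_auc target area under the concentration curve in
#'   mg/mL*min; the protocol range is 4-6 (a value outside it warns).
#' @param gfr glomerular filtration rate in mL/min.
#' @return Dose in mg.
#' @examples
#' carboplatin_dose(5, 100) # 625 mg
#' @export
carboplatin_dose <- function(target_auc, gfr) {
  if (any(target_auc <= 0) || any(gfr <= 0))
    stop("target_auc and gfr must be positive", call. = FALSE)
  if (any(target_auc < 4 | target_auc > 6))
    warning("target AUC outside the protocol range 4-6 mg/mL*min")
  target_auc * (gfr + 25)
}
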