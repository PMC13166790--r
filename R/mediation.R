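# Two-step mediation MR: decompose the effect of a modifiable risk factor on
# the outcome into the component running through a protein mediator
# (beta1 * beta2) and the remainder, with a Sobel test and a delta-method
# interval for the proportion mediated.

#' Two-step mediation decomposition with Sobel test
#'
#' Combines three MR legs: `step1` (risk factor -> mediator, effect `beta1`),
#' `step2` (mediator -> outcome, `beta2`) and `total` (risk factor ->
#' outcome, `c_prime`). The mediated effect is `beta1 * beta2` with Sobel
#' standard error `sqrt(beta2^2 se1^2 + beta1^2 se2^2)` and a two-sided
#' normal p-value. The proportion mediated is `beta1 * beta2 / c_prime`; its
#' variance comes from a first-order delta expansion treating the three
#' estimates as independent, either over all three (`prop_var = "three"`,
#' the default) or holding the total effect fixed (`"two"`).
#'
#' A combination is flagged `reliable` only when the Sobel p-value is below
#' 0.05, the mediated and total effects agree in sign, and the total-effect
#' analysis shows no pleiotropy (`total_pleiotropy_p >= 0.05`; a missing
#' pleiotropy p-value, e.g. too few instruments to test, counts as a pass).
#'
#' @param step1,step2,total One-row MR-estimate data frames (see [ivw()]).
#' @param total_pleiotropy_p Egger intercept p-value of the total-effect
#'   analysis, or `NA` when not testable.
#' @param prop_var `"three"` or `"two"`: delta-variance terms used for the
#'   proportion interval.
#' @return One-row data frame with the decomposition, Sobel p-value,
#'   proportion mediated (with 95% CI) and the `reliable` flag.
#' @export
mediate <- function(step1, step2, total, total_pleiotropy_p = NA_real_,
                    prop_var = c("three", "two")) {
  prop_var <- match.arg(prop_var)
  b1 <- step1$beta; s1 <- step1$se
  b2 <- step2$beta; s2 <- step2$se
  cp <- total$beta; sc <- total$se
  if (cp == 0) stop("total effect is zero: proportion mediated undefined", call. = FALSE)

  med <- b1 * b2
  se_med <- sqrt(b2^2 * s1^2 + b1^2 * s2^2)
  sobel_p <- if (se_med == 0) {
    if (med == 0) 1 else .Machine$double.xmin
  } else {
    2 * stats::pnorm(-abs(med / se_med))
  }

  prop <- med / cp
  if (b1 != 0 && b2 != 0) {
    rel_var <- s1^2 / b1^2 + s2^2 / b2^2
    if (prop_var == "three") rel_var <- rel_var + sc^2 / cp^2
    se_prop <- abs(prop) * sqrt(rel_var)
    ci_low <- prop - Z975 * se_prop
    ci_high <- prop + Z975 * se_prop
  } else {
    se_prop <- NA_real_; ci_low <- NA_real_; ci_high <- NA_real_
  }

  pleio_pass <- is.na(total_pleiotropy_p) || total_pleiotropy_p >= 0.05
  data.frame(
    risk_factor_id = total$exposure_id,
    mediator_id = step2$exposure_id,
    beta1 = b1, se1 = s1, beta2 = b2, se2 = s2,
    c_prime = cp, se_c = sc,
    mediated = med, se_mediated = se_med, sobel_p = sobel_p,
    proportion = prop, se_proportion = se_prop,
    prop_ci_low = ci_low, prop_ci_high = ci_high,
    total_pleiotropy_p = total_pleiotropy_p,
    reliable = sobel_p < 0.05 & sign(med) == sign(cp) & pleio_pass,
    stringsAsFactors = FALSE
  )
}
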