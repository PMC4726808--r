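#' Quantum Prospect Decision Theory quarter-law prediction
#'
#' QPDT fixes the magnitude of the interference term at 1/4 (the interference
#' quarter law) with opposite signs on the two prospects (interference
#' alternation). Operationally, for the two-condition scenarios modeled here
#' the focal action's prediction is the classical law-of-total-probability
#' value minus 0.25 when the focal action is uncertainty-averse (destructive
#' interference, the default), and the complement gains 0.25, so the pair
#' still sums to 1.
#'
#' @param p_given_cond1,p_given_cond2 Conditional probabilities of the focal
#'   action under the two known conditions.
#' @param prior1 Prior probability of the first condition (default 0.5).
#' @param focal_destructive If `TRUE` (default) the focal action takes the
#'   destructive (-0.25) interference; set `FALSE` to flip the signs.
#' @return A one-row tibble with columns `classical`, `interference`,
#'   `predicted` (focal), `predicted_complement`, and `clamped` (TRUE when
#'   the raw value fell outside `[0, 1]` and was clamped).
#' @export
qpdt_predict <- function(p_given_cond1, p_given_cond2, prior1 = 0.5,
                         focal_destructive = TRUE) {
  classical <- ltp_predict(p_given_cond1, p_given_cond2, prior1)
  q <- if (focal_destructive) -0.25 else 0.25
  raw <- classical + q
  clamped <- raw < 0 | raw > 1
  if (any(clamped)) {
    warn("QPDT prediction fell outside [0, 1]; clamped.")
  }
  predicted <- pmin(1, pmax(0, raw))
  tibble(
    classical = classical, interference = q, predicted = predicted,
    predicted_complement = 1 - predicted, clamped = clamped
  )
}
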