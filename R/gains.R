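#' Gain curves: resource-to-fitness maps
#'
#' A gain curve wraps a scalar map together with its first (and optionally
#' second) derivative. Four curves define the model: adult survival `Pa(E)`,
#' female gain `f(F)`, male gain `m(M)` and the selfed-adult fraction `S(s)`.
#'
#' @param value Function of one numeric argument returning the curve value.
#' @param deriv Optional first-derivative function. Solvers fall back to
#'   finite differences of the total fitness when it is absent.
#' @param deriv2 Optional second-derivative function.
#' @param label Short description used in printing.
#' @return Object of class `"gain_curve"`.
#' @export
gain_curve <- function(value, deriv = NULL, deriv2 = NULL, label = "custom") {
  stopifnot(is.function(value))
  if (!is.null(deriv)) stopifnot(is.function(deriv))
  if (!is.null(deriv2)) stopifnot(is.function(deriv2))
  structure(list(value = value, deriv = deriv, deriv2 = deriv2, label = label),
            class = "gain_curve")
}

#' @export
print.gain_curve <- function(x, ...) {
  cat("Gain curve:", x$label,
      if (is.null(x$deriv)) "(no analytic derivative)" else "", "\n")
  invisible(x)
}

#' Constant curve
#'
#' A curve with a fixed value and zero derivatives. Used to evaluate the
#' selfing threshold `tau` and the selfing selection gradient at fixed
#' numeric `Pa` and `f` instead of at a full allocation strategy. Constant
#' female/male curves violate `f(0) = 0` / `m(0) = 0`, so gain sets built
#' from them must skip validation; they are for threshold evaluation, not for
#' allocation solving.
#'
#' @param value The constant.
#' @return A [gain_curve()].
#' @export
constant_curve <- function(value) {
  force(value)
  gain_curve(function(x) value, function(x) 0, function(x) 0,
             label = sprintf("constant %g", value))
}

power_survival_curve <- function(Pa_max, beta) {
  force(Pa_max); force(beta)
  gain_curve(
    value  = function(E) Pa_max * (1 - E)^beta,
    deriv  = function(E) -Pa_max * beta * (1 - E)^(beta - 1),
    deriv2 = function(E) -Pa_max * beta * (1 - beta) * (1 - E)^(beta - 2),
    label  = sprintf("Pa(E) = %g * (1 - E)^%g", Pa_max, beta))
}

linear_female_curve <- function(f_max) {
  force(f_max)
  gain_curve(
    value  = function(F) f_max * F,
    deriv  = function(F) f_max,
    deriv2 = function(F) 0,
    label  = sprintf("f(F) = %g * F", f_max))
}

power_male_curve <- function(m_max, eta) {
  force(m_max); force(eta)
  gain_curve(
    value  = function(M) m_max * M^eta,
    deriv  = function(M) m_max * eta * M^(eta - 1),
    deriv2 = function(M) m_max * eta * (eta - 1) * M^(eta - 2),
    label  = sprintf("m(M) = %g * M^%g", m_max, eta))
}

linear_selfing_curve <- function(gamma) {
  force(gamma)
  gain_curve(
    value  = function(s) gamma * s,
    deriv  = function(s) gamma,
    deriv2 = function(s) 0,
    label  = sprintf("S(s) = %g * s", gamma))
}

#' Bundle of the model's four gain curves
#'
#' @param survival `Pa(E)`: adult survivorship as a function of reproductive
#'   allocation; must be strictly decreasing on \[0, 1\].
#' @param female `f(F)`: seed number; `f(0) = 0`, nondecreasing.
#' @param male `m(M)`: pollen number; `m(0) = 0`, nondecreasing.
#' @param selfed `S(s)`: fraction of selfed adults; `S(0) = 0`, nondecreasing.
#' @param validate Check the `f(0) = m(0) = S(0) = 0`, monotonicity and
#'   `Pa` decrease conditions on a coarse grid. Disable for deliberately
#'   degenerate curves such as [constant_curve()].
#' @return Object of class `"gain_set"`.
#' @seealso [default_gains()] for the standard curves, [fixed_gains()] for
#'   constant-value threshold evaluation.
#' @export
gain_set <- function(survival, female, male, selfed, validate = TRUE) {
  for (g in list(survival, female, male, selfed))
    if (!inherits(g, "gain_curve"))
      stop("all four components must be 'gain_curve' objects", call. = FALSE)
  gs <- structure(list(survival = survival, female = female,
                       male = male, selfed = selfed),
                  class = "gain_set")
  if (validate) .validate_gain_set(gs)
  gs
}

.validate_gain_set <- function(gs, n = 9L) {
  grid <- seq(0, 1, length.out = n)
  if (abs(gs$female$value(0)) > 1e-12) stop("f(0) must be 0", call. = FALSE)
  if (abs(gs$male$value(0)) > 1e-12) stop("m(0) must be 0", call. = FALSE)
  if (abs(gs$selfed$value(0)) > 1e-12) stop("S(0) must be 0", call. = FALSE)
  fv <- vapply(grid, gs$female$value, 0)
  mv <- vapply(grid, gs$male$value, 0)
  sv <- vapply(grid, gs$selfed$value, 0)
  if (any(diff(fv) < -1e-12)) stop("f must be nondecreasing", call. = FALSE)
  if (any(diff(mv) < -1e-12)) stop("m must be nondecreasing", call. = FALSE)
  if (any(diff(sv) < -1e-12)) stop("S must be nondecreasing", call. = FALSE)
  pv <- vapply(grid[-n], gs$survival$value, 0)
  if (any(diff(pv) >= 0))
    stop("Pa must be strictly decreasing on [0, 1)", call. = FALSE)
  invisible(TRUE)
}

#' Default gain curves of the model
#'
#' `Pa(E) = Pa_max * (1 - E)^beta` (strictly decreasing, strictly concave),
#' linear female gain `f(F) = f_max * F`, power-law male gain
#' `m(M) = m_max * M^eta`, and linear selfed-adult fraction `S(s) = gamma * s`.
#'
#' @param params A [life_history()] object.
#' @return A [gain_set()].
#' @export
default_gains <- function(params) {
  params <- as_life_history(params)
  gain_set(
    survival = power_survival_curve(params$Pa_max, params$beta),
    female   = linear_female_curve(params$f_max),
    male     = power_male_curve(params$m_max, params$eta),
    selfed   = linear_selfing_curve(params$gamma),
    validate = FALSE)  # closed forms satisfy the conditions by construction
}

#' Gain set with fixed survival and female-gain values
#'
#' Replaces `Pa(E)` and `f(F)` by constants, as in the threshold
#' `tau = delta_a * Pa * gamma / (Pj * f)` where `Pa` and `f` appear as
#' numbers. The male curve is constant 1 (the siring ratio is then 1) and
#' `S(s) = gamma * s` is kept. Intended for mating-system threshold
#' evaluation only; do not solve allocation ESS against these curves.
#'
#' @param Pa Fixed adult survivorship value.
#' @param f Fixed seed number.
#' @param params A [life_history()] object supplying `gamma`.
#' @return A [gain_set()] (validation skipped).
#' @export
fixed_gains <- function(Pa, f, params) {
  params <- as_life_history(params)
  gain_set(
    survival = constant_curve(Pa),
    female   = constant_curve(f),
    male     = constant_curve(1),
    selfed   = linear_selfing_curve(params$gamma),
    validate = FALSE)
}

#' @export
print.gain_set <- function(x, ...) {
  cat("Gain functions:\n")
  cat("  survival:", x$survival$label, "\n")
  cat("  female:  ", x$female$label, "\n")
  cat("  male:    ", x$male$label, "\n")
  cat("  selfed:  ", x$selfed$label, "\n")
  invisible(x)
}

#' Adult survivorship at a given reproductive allocation
#'
#' Evaluates `Pa(E)`, the probability that an adult spending a fraction `E`
#' of its budget on reproduction survives to the next season. The default
#' curve is `Pa_max * (1 - E)^beta`.
#'
#' @param E Reproductive allocation in \[0, 1\] (vectorized).
#' @param params A [life_history()] object.
#' @param gains A [gain_set()]; defaults to [default_gains()].
#' @return Survival probabilities.
#' @examples
#' p <- life_history(Pa_max = 0.9, beta = 0.5)
#' adult_survival(c(0, 0.5, 1), p)
#' @export
adult_survival <- function(E, params, gains = default_gains(params)) {
  if (any(!is.finite(E)) || any(E < 0) || any(E > 1))
    stop("E must lie in [0, 1]", call. = FALSE)
  vapply(E, gains$survival$value, 0)
}

#' Seed number at a given female allocation
#'
#' Evaluates `f(F)`; the default is the linear curve `f_max * F`.
#'
#' @param F Female allocation in \[0, 1\] (vectorized).
#' @inheritParams adult_survival
#' @return Seed counts.
#' @export
female_gain <- function(F, params, gains = default_gains(params)) {
  if (any(!is.finite(F)) || any(F < 0) || any(F > 1))
    stop("F must lie in [0, 1]", call. = FALSE)
  vapply(F, gains$female$value, 0)
}

#' Pollen number at a given male allocation
#'
#' Evaluates `m(M)`; the default is the power curve `m_max * M^eta`. With
#' `eta < 1` the derivative is unbounded at `M = 0`; solvers never evaluate
#' the derivative there.
#'
#' @param M Male allocation in \[0, 1\] (vectorized).
#' @inheritParams adult_survival
#' @return Pollen counts.
#' @export
male_gain <- function(M, params, gains = default_gains(params)) {
  if (any(!is.finite(M)) || any(M < 0) || any(M > 1))
    stop("M must lie in [0, 1]", call. = FALSE)
  vapply(M, gains$male$value, 0)
}

#' Fraction of self-fertilized adults at a given selfing rate
#'
#' Evaluates `S(s)`; the default is `gamma * s`, with `gamma` the growth rate
#' of self-fertilized adults, so the value lies in \[0, 1).
#'
#' @param s Selfing rate in \[0, 1\] (vectorized).
#' @inheritParams adult_survival
#' @return Selfed-adult fractions.
#' @export
selfed_adult_fraction <- function(s, params, gains = default_gains(params)) {
  if (any(!is.finite(s)) || any(s < 0) || any(s > 1))
    stop("s must lie in [0, 1]", call. = FALSE)
  vapply(s, gains$selfed$value, 0)
}
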