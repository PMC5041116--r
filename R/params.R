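#' Life-history parameters for a hermaphroditic perennial
#'
#' Constructs and validates the constant parameters of the resource-allocation
#' model: an individual splits a unit resource budget among adult survival,
#' male function (pollen) and female function (seeds), and inbreeding
#' depression reduces the survivorship of selfed juveniles and selfed adults.
#'
#' The relative survivorships are always derived, never stored:
#' `w_j = 1 - delta_j` (selfed juvenile survivorship relative to outcrossed)
#' and `w_a = 1 - delta_a` (same for adults); see
#' [relative_survivorships()].
#'
#' @param Pj Baseline (outcrossed) juvenile survivorship, in (0, 1].
#' @param delta_j Fraction of juvenile inbreeding depression, in \[0, 1\].
#' @param delta_a Fraction of adult inbreeding depression, in \[0, 1\].
#' @param gamma Growth rate of self-fertilized adults, in (0, 1): the slope of
#'   the default selfed-adult fraction `S(s) = gamma * s`.
#' @param f_max Maximum seed number when all resources go to seed production
#'   (> 0).
#' @param m_max Maximum pollen number when all resources go to pollen
#'   production (> 0). Enters fitness only through the siring ratio
#'   `m(M')/m(M)`, so it never affects the ESS.
#' @param eta Exponent of the power-law male gain curve, in (0, 1];
#'   `eta = 1` is linear.
#' @param Pa_max Baseline adult survivorship at zero reproductive spending,
#'   in (0, 1].
#' @param beta Curvature of the adult survival curve
#'   `Pa(E) = Pa_max * (1 - E)^beta`, in (0, 1).
#' @param R Total resource budget. Fixed to 1 by normalization: `M`, `F` and
#'   `E` are proportions of the budget.
#'
#' @return An object of class `"life_history"`: a named list of validated
#'   parameters.
#' @seealso [strategy()], [default_gains()], [solve_ess()]
#' @examples
#' p <- life_history(Pj = 0.2, delta_j = 0.2, delta_a = 0.4, gamma = 0.5)
#' p
#' relative_survivorships(p)
#' @export
life_history <- function(Pj = 0.2, delta_j = 0.2, delta_a = 0.4, gamma = 0.5,
                         f_max = 10, m_max = 100, eta = 0.8,
                         Pa_max = 0.9, beta = 0.5, R = 1) {
  p <- list(Pj = Pj, delta_j = delta_j, delta_a = delta_a, gamma = gamma,
            f_max = f_max, m_max = m_max, eta = eta,
            Pa_max = Pa_max, beta = beta, R = R)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("parameter '%s' must be a single finite number", nm),
           call. = FALSE)
  }
  .check_range(Pj, "Pj", lower = 0, upper = 1, lower_open = TRUE)
  .check_range(delta_j, "delta_j", lower = 0, upper = 1)
  .check_range(delta_a, "delta_a", lower = 0, upper = 1)
  .check_range(gamma, "gamma", lower = 0, upper = 1,
               lower_open = TRUE, upper_open = TRUE)
  .check_range(eta, "eta", lower = 0, upper = 1, lower_open = TRUE)
  .check_range(Pa_max, "Pa_max", lower = 0, upper = 1, lower_open = TRUE)
  .check_range(beta, "beta", lower = 0, upper = 1,
               lower_open = TRUE, upper_open = TRUE)
  if (f_max <= 0) stop("parameter 'f_max' must be > 0", call. = FALSE)
  if (m_max <= 0) stop("parameter 'm_max' must be > 0", call. = FALSE)
  if (R != 1)
    stop("the resource budget R is normalized to 1; ",
         "M, F and E are proportions of the budget", call. = FALSE)
  structure(p, class = "life_history")
}

.check_range <- function(x, name, lower, upper,
                         lower_open = FALSE, upper_open = FALSE) {
  lo_bad <- if (lower_open) x <= lower else x < lower
  hi_bad <- if (upper_open) x >= upper else x > upper
  if (lo_bad || hi_bad) {
    lo <- if (lower_open) "(" else "["
    hi <- if (upper_open) ")" else "]"
    stop(sprintf("parameter '%s' = %g is outside %s%g, %g%s",
                 name, x, lo, lower, upper, hi), call. = FALSE)
  }
  invisible(TRUE)
}

#' Relative survivorships of selfed offspring
#'
#' Derived quantities `w_j = 1 - delta_j` and `w_a = 1 - delta_a`: the
#' survivorship of self-fertilized juveniles (adults) relative to outcrossed
#' juveniles (adults).
#'
#' @param params A [life_history()] object.
#' @return Named numeric vector `c(w_j = , w_a = )`.
#' @export
relative_survivorships <- function(params) {
  params <- as_life_history(params)
  c(w_j = 1 - params$delta_j, w_a = 1 - params$delta_a)
}

#' @export
print.life_history <- function(x, ...) {
  cat("Life-history parameters (hermaphroditic perennial)\n")
  cat(sprintf("  juvenile survivorship  Pj      = %g\n", x$Pj))
  cat(sprintf("  inbreeding depression  delta_j = %g  (w_j = %g)\n",
              x$delta_j, 1 - x$delta_j))
  cat(sprintf("                         delta_a = %g  (w_a = %g)\n",
              x$delta_a, 1 - x$delta_a))
  cat(sprintf("  selfed-adult growth    gamma   = %g\n", x$gamma))
  cat(sprintf("  gain curves: f_max = %g, m_max = %g, eta = %g\n",
              x$f_max, x$m_max, x$eta))
  cat(sprintf("  adult survival curve:  Pa_max = %g, beta = %g\n",
              x$Pa_max, x$beta))
  invisible(x)
}

#' @export
update.life_history <- function(object, ...) {
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(unclass(object)))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
  }
  do.call(life_history, utils::modifyList(unclass(object), dots))
}

as_life_history <- function(x) {
  if (inherits(x, "life_history")) return(x)
  if (is.list(x)) return(do.call(life_history, x))
  stop("expected a 'life_history' object", call. = FALSE)
}

#' Phenotypic strategy on the allocation simplex
#'
#' A strategy is the triplet (E, r, s): reproductive allocation `E` (share of
#' the unit budget spent on reproduction; `1 - E` goes to survival), sex
#' allocation `r` (share of reproductive resources spent on male function),
#' and selfing rate `s` (fraction of ovules self-fertilized). The absolute
#' allocations are `M = E * r` (pollen) and `F = E * (1 - r)` (seeds).
#'
#' @param E Reproductive allocation in \[0, 1\].
#' @param r Sex allocation in \[0, 1\].
#' @param s Selfing rate in \[0, 1\].
#' @return Object of class `"strategy"`: named numeric vector
#'   `c(E = , r = , s = )`.
#' @seealso [strategy_MF()] to construct from absolute allocations,
#'   [allocation()] to recover them.
#' @examples
#' st <- strategy(E = 0.5, r = 0.3, s = 0.5)
#' allocation(st)  # M = 0.15, F = 0.35
#' @export
strategy <- function(E, r, s = 0) {
  for (v in list(E = E, r = r, s = s)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("strategy components must be single finite numbers", call. = FALSE)
  }
  if (E < 0 || E > 1) stop("E = ", E, " is outside [0, 1]", call. = FALSE)
  if (r < 0 || r > 1) stop("r = ", r, " is outside [0, 1]", call. = FALSE)
  if (s < 0 || s > 1) stop("s = ", s, " is outside [0, 1]", call. = FALSE)
  structure(c(E = E, r = r, s = s), class = "strategy")
}

#' Construct a strategy from absolute allocations
#'
#' @param M Proportion of the budget allocated to male function, `M >= 0`.
#' @param F Proportion allocated to female function, `F >= 0`, with
#'   `M + F <= 1`.
#' @param s Selfing rate in \[0, 1\].
#' @details At `E = M + F = 0` the sex allocation is undefined; the
#'   convention `r = 0` is used (fitness does not depend on `r` there).
#' @return A [strategy()] object.
#' @export
strategy_MF <- function(M, F, s = 0) {
  if (M < 0 || F < 0 || M + F > 1 + 1e-12)
    stop("require M >= 0, F >= 0 and M + F <= 1", call. = FALSE)
  E <- min(M + F, 1)
  r <- if (E > 0) M / E else 0
  strategy(E = E, r = min(max(r, 0), 1), s = s)
}

#' Absolute male/female allocations of a strategy
#'
#' @param x A [strategy()] object.
#' @return Named numeric vector `c(M = , F = )`.
#' @export
allocation <- function(x) {
  x <- as_strategy(x)
  c(M = unname(x["E"] * x["r"]), F = unname(x["E"] * (1 - x["r"])))
}

as_strategy <- function(x) {
  if (inherits(x, "strategy")) return(x)
  if (is.numeric(x) && length(x) == 3L)
    return(strategy(x[[1]], x[[2]], x[[3]]))
  stop("expected a 'strategy' object or a numeric (E, r, s) triple",
       call. = FALSE)
}

#' @export
print.strategy <- function(x, ...) {
  a <- allocation(x)
  cat(sprintf(
    "Strategy: E = %g, r = %g, s = %g  (M = %g, F = %g, survival share = %g)\n",
    x["E"], x["r"], x["s"], a["M"], a["F"], 1 - x["E"]))
  invisible(x)
}
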