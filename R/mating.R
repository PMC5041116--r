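#' Selfed-adult mortality threshold tau
#'
#' The quantity `tau = delta_a * Pa * gamma / (Pj * f)` — the self-fertilized
#' adult mortality rate caused by inbreeding depression — shifts the
#' juvenile inbreeding-depression boundary between complete selfing and
#' complete outcrossing from 1/2 down to `1/2 - tau`.
#'
#' `Pa` and `f` enter as numbers. By default they are evaluated at the
#' allocation ESS for the given resident selfing rate (`Pa(E*)` and
#' `f(F*)`); alternatively pass an explicit evaluation strategy
#' (`E_eval`, `r_eval`) or fixed values (`Pa`, `f`).
#'
#' @param params A [life_history()] object.
#' @param E_eval,r_eval Optional evaluation allocation; defaults to the
#'   allocation ESS at `s`.
#' @param s Resident selfing rate used when solving the default evaluation
#'   allocation.
#' @param Pa,f Optional fixed numeric values overriding curve evaluation.
#' @param gains A [gain_set()] used to evaluate `Pa` and `f`.
#' @return The threshold value, `>= 0`; 0 whenever `delta_a = 0`.
#' @examples
#' p <- life_history(delta_a = 0.4, gamma = 0.5, Pj = 0.2)
#' mating_tau(p, Pa = 0.5, f = 5)  # 0.1
#' @export
mating_tau <- function(params, E_eval = NULL, r_eval = NULL, s = 0,
                       Pa = NULL, f = NULL, gains = default_gains(params)) {
  p <- as_life_history(params)
  if (is.null(Pa) || is.null(f)) {
    if (is.null(E_eval)) E_eval <- as.numeric(solve_ess_E(p, s))
    if (is.null(r_eval)) r_eval <- as.numeric(solve_ess_r(p, s))
    if (is.null(Pa)) Pa <- gains$survival$value(E_eval)
    if (is.null(f)) f <- gains$female$value(E_eval * (1 - r_eval))
  }
  if (f <= 0)
    stop("female gain f is zero at the evaluation strategy; ",
         "tau is undefined", call. = FALSE)
  p$delta_a * Pa * p$gamma / (p$Pj * f)
}

#' Selection gradient on the selfing rate
#'
#' Derivative of mutant total fitness with respect to the mutant's selfing
#' rate `s'`, at mutant = resident. Under the default (linear) curves the
#' closed form is
#' \deqn{\partial W / \partial s' = P_j f(F) (w_j - \tfrac12)
#'   - P_a(E) \gamma \delta_a,}
#' independent of `s'` itself, so selection on the selfing rate is
#' directional: complete selfing or complete outcrossing is the ESS
#' depending on its sign. (For a general selfed-adult curve `gamma` is
#' replaced by `S'(s)`.)
#'
#' @inheritParams selection_gradient
#' @param method `"analytic"` (curve derivatives) or `"numeric"` (finite
#'   differences of [total_fitness()] in `s'`; central in the interior,
#'   one-sided at `s = 0` or `s = 1` with the side recorded in attribute
#'   `"side"`).
#' @return Gradient value.
#' @export
selfing_selection_gradient <- function(resident, params,
                                       gains = default_gains(params),
                                       method = c("analytic", "numeric"),
                                       step = 1e-6) {
  method <- match.arg(method)
  res <- as_strategy(resident)
  p <- as_life_history(params)
  E <- unname(res["E"]); r <- unname(res["r"]); s <- unname(res["s"])
  F <- E * (1 - r)
  if (method == "analytic") {
    dS <- if (is.null(gains$selfed$deriv))
      stop("analytic selfing gradient requires the selfed-curve derivative",
           call. = FALSE)
    else gains$selfed$deriv(s)
    wj <- 1 - p$delta_j
    g <- p$Pj * gains$female$value(F) * (wj - 0.5) -
      gains$survival$value(E) * dS * p$delta_a
    return(g)
  }
  W <- function(sp) total_fitness(strategy(E, r, sp), res, p, gains)
  h <- step
  if (s - h >= 0 && s + h <= 1) {
    g <- (W(s + h) - W(s - h)) / (2 * h)
    side <- "central"
  } else if (s + h <= 1) {
    g <- (W(s + h) - W(s)) / h
    side <- "right"
  } else {
    g <- (W(s) - W(s - h)) / h
    side <- "left"
  }
  structure(g, side = side)
}

#' Classify the ESS mating system
#'
#' Compares the fraction of juvenile inbreeding depression `delta_j` to the
#' boundary `1/2 - tau`: selection on the selfing rate is directional under
#' the default curves, so the evolutionary endpoint is complete selfing when
#' `delta_j < 1/2 - tau` (the selfing gradient is positive), complete
#' outcrossing when `delta_j > 1/2 - tau` (gradient negative), and neutral
#' exactly at the boundary. The rule-based regime and the sign of the
#' numerically differentiated fitness are both computed and must agree; a
#' disagreement beyond tolerance raises an internal-consistency error.
#'
#' With a nonlinear user-supplied selfed-adult curve `S(s')` the gradient
#' can change sign in `s'`; the interior zero is then located and reported
#' with regime `"interior_singular"` (an extension beyond the linear model).
#'
#' @inheritParams mating_tau
#' @param tol Neutrality tolerance on the gradient (absolute).
#' @return Object of class `"mating_ess"`: list with `tau`,
#'   `delta_j_boundary` (`1/2 - tau`; negative values mean the whole
#'   `delta_j` range is in the selfing regime), `regime`, `gradient`,
#'   `gradient_fd`, `gradient_sign`, `strategy`, `s_singular` (or `NA`).
#' @examples
#' classify_mating_ess(life_history(delta_j = 0.2, delta_a = 0))
#' @export
classify_mating_ess <- function(params, s = 0, Pa = NULL, f = NULL,
                                gains = default_gains(params), tol = 1e-9) {
  p <- as_life_history(params)
  fixed <- !is.null(Pa) && !is.null(f)
  if (fixed) {
    gains_eval <- fixed_gains(Pa, f, p)
    st <- strategy(0.5, 0.5, s)   # arbitrary: curves ignore the allocation
    tau <- mating_tau(p, Pa = Pa, f = f)
  } else {
    gains_eval <- gains
    E <- as.numeric(solve_ess_E(p, s))
    r <- as.numeric(solve_ess_r(p, s))
    st <- strategy(E, r, s)
    tau <- mating_tau(p, E_eval = E, r_eval = r, gains = gains)
  }
  g <- selfing_selection_gradient(st, p, gains_eval, method = "analytic")
  g_fd <- as.numeric(selfing_selection_gradient(st, p, gains_eval,
                                                method = "numeric"))
  if (abs(g - g_fd) > 1e-6)
    stop(sprintf(paste0(
      "internal consistency failure: analytic selfing gradient (%.3g) and ",
      "finite-difference gradient (%.3g) disagree"), g, g_fd), call. = FALSE)

  # nonlinear S(s') can give an s'-dependent gradient with an interior zero
  s_singular <- NA_real_
  dgrad <- function(sp) {
    dS <- gains_eval$selfed$deriv(sp)
    p$Pj * gains_eval$female$value(unname(allocation(st)["F"])) *
      (0.5 - p$delta_j) - gains_eval$survival$value(unname(st["E"])) *
      dS * p$delta_a
  }
  g0 <- dgrad(0); g1 <- dgrad(1)
  if (is.finite(g0) && is.finite(g1) && sign(g0) * sign(g1) < 0 &&
      min(abs(g0), abs(g1)) > tol) {
    s_singular <- stats::uniroot(dgrad, c(0, 1), tol = 1e-10)$root
    regime <- "interior_singular"
    gsign <- 0L
  } else {
    gsign <- if (g > tol) 1L else if (g < -tol) -1L else 0L
    regime <- c("complete_outcrossing", "neutral", "complete_selfing")[gsign + 2L]
    # rule route: compare delta_j with 1/2 - tau on the gradient's own scale
    fval <- gains_eval$female$value(unname(allocation(st)["F"]))
    rule <- p$Pj * fval * (0.5 - tau - p$delta_j)
    rsign <- if (rule > tol) 1L else if (rule < -tol) -1L else 0L
    if (rsign != gsign)
      stop("internal consistency failure: the delta_j vs 1/2 - tau rule and ",
           "the selfing gradient sign disagree", call. = FALSE)
  }
  structure(list(tau = tau, delta_j_boundary = 0.5 - tau, regime = regime,
                 gradient = g, gradient_fd = g_fd, gradient_sign = gsign,
                 strategy = st, s_singular = s_singular, params = p),
            class = "mating_ess")
}

#' @export
print.mating_ess <- function(x, ...) {
  cat("ESS mating-system classification\n")
  cat(sprintf("  tau = %.6g, delta_j boundary 1/2 - tau = %.6g\n",
              x$tau, x$delta_j_boundary))
  cat(sprintf("  delta_j = %g; selfing gradient dW/ds' = %.6g\n",
              x$params$delta_j, x$gradient))
  cat("  regime:", x$regime, "\n")
  if (!is.na(x$s_singular))
    cat(sprintf("  interior singular selfing rate: s* = %.6g\n", x$s_singular))
  invisible(x)
}

#' Locate the juvenile inbreeding-depression boundary
#'
#' Bisects on `delta_j` for the zero of the selfing selection gradient, all
#' other parameters fixed. At each trial `delta_j` the gradient is evaluated
#' at the allocation ESS for that parameter set (or at fixed `Pa`, `f`), so
#' the recovered boundary equals `1/2 - tau` with `tau` evaluated
#' consistently. If the gradient has the same sign at `delta_j = 0` and
#' `delta_j = 1` there is no boundary and the uniform regime is returned
#' instead (not an error).
#'
#' @inheritParams classify_mating_ess
#' @param tol Absolute bisection tolerance on `delta_j`.
#' @return List with `delta_j` (the boundary, or `NA` if none), `found`,
#'   `regime` (uniform regime when no boundary), `tau_at_boundary`.
#' @examples
#' find_deltaj_boundary(life_history(delta_a = 0))$delta_j  # 0.5
#' @export
find_deltaj_boundary <- function(params, s = 0, Pa = NULL, f = NULL,
                                 gains = NULL, tol = 1e-8) {
  p <- as_life_history(params)
  fixed <- !is.null(Pa) && !is.null(f)
  grad_at <- function(dj) {
    pj <- update(p, delta_j = dj)
    gns <- if (fixed) fixed_gains(Pa, f, pj)
           else if (is.null(gains)) default_gains(pj) else gains
    st <- if (fixed) strategy(0.5, 0.5, s)
          else strategy(as.numeric(solve_ess_E(pj, s)),
                        as.numeric(solve_ess_r(pj, s)), s)
    as.numeric(selfing_selection_gradient(st, pj, gns, method = "analytic"))
  }
  g0 <- grad_at(0); g1 <- grad_at(1)
  if (sign(g0) == sign(g1) || g0 == 0 && g1 == 0) {
    regime <- if (g0 > 0) "complete_selfing" else "complete_outcrossing"
    return(list(delta_j = NA_real_, found = FALSE, regime = regime,
                tau_at_boundary = NA_real_))
  }
  lo <- 0; hi <- 1; glo <- g0
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    gm <- grad_at(mid)
    if (gm == 0) { lo <- mid; hi <- mid; break }
    if (sign(gm) == sign(glo)) { lo <- mid; glo <- gm } else hi <- mid
  }
  dj <- (lo + hi) / 2
  pj <- update(p, delta_j = dj)
  tau_b <- if (fixed) mating_tau(pj, Pa = Pa, f = f)
           else mating_tau(pj, s = s)
  list(delta_j = dj, found = TRUE, regime = "boundary",
       tau_at_boundary = tau_b)
}

#' Pairwise invasibility of mutant selfing rates
#'
#' For each resident selfing rate on a grid, solves the allocation ESS,
#' then scores the sign of the invasion fitness
#' `W(mutant s'; resident s) - W(resident; resident)` for every mutant
#' selfing rate, mutant and resident sharing the resident's ESS allocation.
#' Under the default curves fitness is linear in `s'`, so each row is a
#' single-signed half line on either side of the (exactly zero) diagonal.
#'
#' @param params A [life_history()] object.
#' @param grid_size Number of grid points on \[0, 1\] (`>= 2`).
#' @param s_grid Optional explicit grid (overrides `grid_size`).
#' @param gains A [gain_set()].
#' @param tol Absolute tolerance below which an invasion fitness difference
#'   counts as zero.
#' @return Object of class `"invasion_grid"`: list with `s_resident`,
#'   `s_mutant`, `sign` (matrix, rows = residents, columns = mutants),
#'   `params`.
#' @export
pairwise_invasibility <- function(params, grid_size = 21,
                                  s_grid = NULL,
                                  gains = default_gains(params),
                                  tol = 1e-12) {
  p <- as_life_history(params)
  if (is.null(s_grid)) {
    if (grid_size < 2) stop("grid_size must be >= 2", call. = FALSE)
    s_grid <- seq(0, 1, length.out = grid_size)
  }
  n <- length(s_grid)
  sgn <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    s <- s_grid[i]
    E <- as.numeric(solve_ess_E(p, s))
    r <- as.numeric(solve_ess_r(p, s))
    res <- strategy(E, r, s)
    W_res <- total_fitness(res, res, p, gains)
    for (j in seq_len(n)) {
      d <- total_fitness(strategy(E, r, s_grid[j]), res, p, gains) - W_res
      sgn[i, j] <- if (d > tol) 1L else if (d < -tol) -1L else 0L
    }
  }
  structure(list(s_resident = s_grid, s_mutant = s_grid, sign = sgn,
                 params = p),
            class = "invasion_grid")
}

#' @export
print.invasion_grid <- function(x, ...) {
  n <- length(x$s_resident)
  up <- x$sign[upper.tri(x$sign)]
  cat(sprintf("Pairwise invasibility grid (%d x %d residents x mutants)\n",
              n, n))
  cat(sprintf("  mutants with s' > s: %d invade, %d repelled, %d neutral\n",
              sum(up > 0), sum(up < 0), sum(up == 0)))
  invisible(x)
}

#' @export
as.data.frame.invasion_grid <- function(x, ...) {
  data.frame(s_resident = rep(x$s_resident, times = length(x$s_mutant)),
             s_mutant = rep(x$s_mutant, each = length(x$s_resident)),
             sign = as.vector(x$sign))
}

#' @export
plot.invasion_grid <- function(x, ...) {
  graphics::image(x$s_resident, x$s_mutant, x$sign,
                  col = c("#4575b4", "#ffffbf", "#d73027"),
                  breaks = c(-1.5, -0.5, 0.5, 1.5),
                  xlab = "resident selfing rate s",
                  ylab = "mutant selfing rate s'",
                  main = "pairwise invasibility (red: mutant invades)", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Write an invasion grid as a CSV matrix
#'
#' First row and first column carry the mutant and resident grid
#' coordinates; the top-left cell is empty.
#'
#' @param x An [pairwise_invasibility()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_invasion_grid <- function(x, path) {
  stopifnot(inherits(x, "invasion_grid"))
  header <- paste(c("", .fmt_num(x$s_mutant)), collapse = ",")
  rows <- vapply(seq_along(x$s_resident), function(i)
    paste(c(.fmt_num(x$s_resident[i]), x$sign[i, ]), collapse = ","), "")
  writeLines(c(header, rows), path)
  invisible(path)
}

.fmt_num <- function(x) sprintf("%.12g", x)
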