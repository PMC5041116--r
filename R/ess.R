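#' Selection gradient on the allocation traits
#'
#' Partial derivatives of mutant total fitness with respect to the mutant's
#' reproductive allocation `E'` and sex allocation `r'`, evaluated at
#' mutant = resident. Both components vanish at an interior ESS.
#'
#' The closed form (available whenever all curves carry analytic
#' derivatives) is obtained by the chain rule from the `(M', F')`
#' derivatives of the fitness; the finite-difference route differentiates
#' [total_fitness()] directly and works for any curves.
#'
#' @param resident Resident [strategy()]; must be interior
#'   (`0 < E < 1`, `0 < r < 1`).
#' @param params A [life_history()] object.
#' @param gains A [gain_set()].
#' @param method `"analytic"` (curve derivatives) or `"numeric"` (central
#'   finite differences on the fitness).
#' @param step Relative finite-difference step for the numeric route.
#' @return Named vector `c(dW_dE = , dW_dr = )`.
#' @export
selection_gradient <- function(resident, params,
                               gains = default_gains(params),
                               method = c("analytic", "numeric"),
                               step = 1e-5) {
  method <- match.arg(method)
  res <- as_strategy(resident)
  p <- as_life_history(params)
  E <- unname(res["E"]); r <- unname(res["r"]); s <- unname(res["s"])
  if (E <= 0 || E >= 1 || r <= 0 || r >= 1)
    stop("boundary resident: the selection gradient is defined for ",
         "interior strategies only (0 < E < 1, 0 < r < 1)", call. = FALSE)

  if (method == "analytic") {
    if (is.null(gains$survival$deriv) || is.null(gains$female$deriv) ||
        is.null(gains$male$deriv))
      stop("analytic gradient requires curve derivatives; use method = ",
           "\"numeric\"", call. = FALSE)
    wj <- 1 - p$delta_j
    M <- E * r; F <- E * (1 - r)
    Sdisc <- 1 - gains$selfed$value(s) * p$delta_a
    cf <- p$Pj * (s * wj + 0.5 * (1 - s)) * gains$female$deriv(F)
    cm <- if (s < 1) {
      mM <- gains$male$value(M)
      if (mM <= 0)
        stop("degenerate pollen pool: resident male gain m(M) = 0",
             call. = FALSE)
      0.5 * p$Pj * (1 - s) * gains$female$value(F) * gains$male$deriv(M) / mM
    } else 0
    dW_dE <- gains$survival$deriv(E) * Sdisc + cf * (1 - r) + cm * r
    dW_dr <- E * (cm - cf)
    return(c(dW_dE = dW_dE, dW_dr = dW_dr))
  }

  W <- function(Ep, rp) total_fitness(strategy(Ep, rp, s), res, p, gains)
  hE <- min(step * max(1, abs(E)), E / 2, (1 - E) / 2)
  hr <- min(step * max(1, abs(r)), r / 2, (1 - r) / 2)
  c(dW_dE = (W(E + hE, r) - W(E - hE, r)) / (2 * hE),
    dW_dr = (W(E, r + hr) - W(E, r - hr)) / (2 * hr))
}

#' Marginal male-minus-female balance
#'
#' The difference between the marginal male-fitness gain and the marginal
#' female-fitness gain per unit resource moved between pollen and seed
#' production, at mutant = resident:
#' \deqn{\tfrac12 P_j (1 - s) f(F) m'(M)/m(M)
#'   - P_j (s w_j + \tfrac12 (1 - s)) f'(F).}
#' The adult-survival marginals cancel (a unit moved between `M` and `F`
#' leaves `E` unchanged), so the residual is independent of `delta_a`. It is
#' zero at the ESS sex allocation, negative when male function is
#' overinvested (`r` above the ESS), positive when underinvested.
#'
#' @inheritParams selection_gradient
#' @return A single residual value (male minus female marginal gain).
#' @export
marginal_balance_residual <- function(resident, params,
                                      gains = default_gains(params)) {
  res <- as_strategy(resident)
  p <- as_life_history(params)
  E <- unname(res["E"]); r <- unname(res["r"]); s <- unname(res["s"])
  if (E <= 0 || E >= 1 || r <= 0 || r >= 1)
    stop("boundary resident: marginal balance requires an interior strategy",
         call. = FALSE)
  M <- E * r; F <- E * (1 - r)
  wj <- 1 - p$delta_j
  dm <- gains$male$deriv(M); mM <- gains$male$value(M)
  if (!is.finite(dm) || !is.finite(dm / mM))
    stop("unbounded marginal male gain at M = ", M, call. = FALSE)
  male_marg <- 0.5 * p$Pj * (1 - s) * gains$female$value(F) * dm / mM
  female_marg <- p$Pj * (s * wj + 0.5 * (1 - s)) * gains$female$deriv(F)
  male_marg - female_marg
}

#' ESS reproductive allocation (closed form)
#'
#' Under the linear female gain and the default concave survival curve, the
#' ESS reproductive allocation is independent of the sex allocation `r` and
#' solves the first-order condition
#' \deqn{-P_a'(E) (1 - s \gamma \delta_a)
#'   = \tfrac12 P_j f_{max} (1 + s (2 w_j - 1)).}
#' With `Pa(E) = Pa_max (1 - E)^beta` the root is
#' `E* = 1 - (Pa_max * beta / K)^(1/(1-beta))` where
#' `K = (Pj f_max / 2) (1 + s (2 w_j - 1)) / (1 - s gamma delta_a)`.
#' Roots outside \[0, 1\] are clipped, with the `"boundary"` attribute set.
#'
#' Whether `E*` increases or decreases with `s` is governed by the ratio
#' `w_j / (1 - gamma + gamma w_a)` relative to 1/2; see [classify_dE_ds()].
#'
#' @param params A [life_history()] object.
#' @param s Selfing rate in \[0, 1\].
#' @return `E*` with a logical attribute `"boundary"` (TRUE when clipped).
#' @examples
#' p <- life_history(Pa_max = 0.9, beta = 0.5, Pj = 0.2, f_max = 10,
#'                   delta_j = 0.2, delta_a = 0.4, gamma = 0.5)
#' solve_ess_E(p, s = 0.5)  # 0.902944
#' @export
solve_ess_E <- function(params, s = 0) {
  p <- as_life_history(params)
  if (!is.numeric(s) || any(s < 0) || any(s > 1))
    stop("s must lie in [0, 1]", call. = FALSE)
  wj <- 1 - p$delta_j
  K <- (p$Pj * p$f_max / 2) * (1 + s * (2 * wj - 1)) /
    (1 - s * p$gamma * p$delta_a)
  E <- 1 - (p$Pa_max * p$beta / K)^(1 / (1 - p$beta))
  boundary <- E < 0 | E > 1
  E <- pmin(pmax(E, 0), 1)
  attr(E, "boundary") <- boundary
  E
}

#' ESS sex allocation (closed form)
#'
#' Under linear female gain and power-law male gain `m = m_max M^eta`, the
#' ESS sex allocation is
#' \deqn{r^* = \frac{\eta (1 - s)}{\eta (1 - s) + 1 + s (2 w_j - 1)},}
#' independent of the reproductive allocation, of `f_max`, `m_max`, and of
#' the adult inbreeding depression `delta_a`; it decreases strictly with the
#' selfing rate whenever `w_j > 0`, reaching 0 at `s = 1`.
#'
#' @inheritParams solve_ess_E
#' @return `r*` with a logical attribute `"boundary"` (TRUE at `s = 1`).
#' @examples
#' p <- life_history(eta = 0.8, delta_j = 0.2)
#' solve_ess_r(p, s = 0.5)  # 0.235294
#' solve_ess_r(p, s = 0)    # eta / (eta + 1)
#' @export
solve_ess_r <- function(params, s = 0) {
  p <- as_life_history(params)
  if (!is.numeric(s) || any(s < 0) || any(s > 1))
    stop("s must lie in [0, 1]", call. = FALSE)
  wj <- 1 - p$delta_j
  a <- p$eta * (1 - s)
  r <- a / (a + 1 + s * (2 * wj - 1))
  attr(r, "boundary") <- s >= 1
  r
}

#' Slope of the ESS sex allocation in the selfing rate
#'
#' Closed-form derivative of [solve_ess_r()] with respect to `s`:
#' \deqn{\frac{dr^*}{ds} = \frac{-2 \eta w_j}
#'   {(\eta (1 - s) + 1 + s (2 w_j - 1))^2},}
#' strictly negative for `w_j > 0` and zero only in the degenerate case
#' `w_j = 0` (complete juvenile inbreeding mortality). The sign involves
#' neither `delta_a` nor `gamma`: the decrease of male investment with
#' selfing is universal.
#'
#' @inheritParams solve_ess_E
#' @return Derivative value(s).
#' @export
sex_allocation_slope <- function(params, s = 0) {
  p <- as_life_history(params)
  if (!is.numeric(s) || any(s < 0) || any(s > 1))
    stop("s must lie in [0, 1]", call. = FALSE)
  wj <- 1 - p$delta_j
  denom <- p$eta * (1 - s) + 1 + s * (2 * wj - 1)
  -2 * p$eta * wj / denom^2
}

#' Direction of the ESS reproductive allocation in the selfing rate
#'
#' The effect of the selfing rate on `E*` is governed by the ratio
#' `w_j / (1 - gamma + gamma * w_a)`: `E*` increases with `s` when the ratio
#' exceeds 1/2, decreases when it falls below 1/2, and is independent of `s`
#' exactly at 1/2. With no adult inbreeding depression (`w_a = 1`) this
#' reduces to the sign of `1/2 - delta_j`.
#'
#' @param params A [life_history()] object.
#' @param tol Absolute tolerance on the ratio for the `"independent"` label.
#' @return One of `"increasing"`, `"decreasing"`, `"independent"`, with the
#'   ratio attached as attribute `"ratio"`.
#' @export
classify_dE_ds <- function(params, tol = 1e-9) {
  p <- as_life_history(params)
  wj <- 1 - p$delta_j
  wa <- 1 - p$delta_a
  ratio <- wj / (1 - p$gamma + p$gamma * wa)
  lab <- if (ratio > 0.5 + tol) "increasing"
         else if (ratio < 0.5 - tol) "decreasing"
         else "independent"
  structure(lab, ratio = ratio)
}

#' Second-order (maximality) conditions at a strategy
#'
#' Finite-difference Hessian of the mutant total fitness with respect to the
#' mutant's absolute allocations `(M', F')`, evaluated at mutant = resident.
#' A genuine ESS requires this matrix to be negative definite (both leading
#' minor tests: `H[1,1] < 0` and `det(H) > 0`). With a linear male gain
#' (`eta = 1`) and linear female gain the matrix is singular (all entries
#' equal the survival curvature) and the check reports `indeterminate`
#' rather than failing.
#'
#' @inheritParams selection_gradient
#' @param step Relative finite-difference step for the second derivatives.
#' @return Object of class `"second_order_check"`: list with `hessian`,
#'   `negative_definite`, `indeterminate`, `minors`.
#' @export
check_second_order <- function(resident, params,
                               gains = default_gains(params),
                               step = 1e-4) {
  res <- as_strategy(resident)
  p <- as_life_history(params)
  E <- unname(res["E"]); r <- unname(res["r"]); s <- unname(res["s"])
  if (E <= 0 || E >= 1 || r <= 0 || r >= 1)
    stop("interior resident required for the second-order check",
         call. = FALSE)
  M <- E * r; F <- E * (1 - r)
  W <- function(Mp, Fp) total_fitness(strategy_MF(Mp, Fp, s), res, p, gains)
  # steps shrunk so that all stencil points stay on the simplex
  room <- (1 - E) / 4
  h <- min(step * max(1, M), M / 2, room)
  k <- min(step * max(1, F), F / 2, room)
  W0 <- W(M, F)
  H11 <- (W(M + h, F) - 2 * W0 + W(M - h, F)) / h^2
  H22 <- (W(M, F + k) - 2 * W0 + W(M, F - k)) / k^2
  H12 <- (W(M + h, F + k) - W(M + h, F - k) -
          W(M - h, F + k) + W(M - h, F - k)) / (4 * h * k)
  H <- matrix(c(H11, H12, H12, H22), 2, 2,
              dimnames = list(c("M", "F"), c("M", "F")))
  det2 <- H11 * H22 - H12^2
  scale <- max(1, max(abs(H)))
  tol1 <- 1e-6 * scale
  tol2 <- 1e-5 * scale^2
  indeterminate <- abs(H11) <= tol1 || abs(det2) <= tol2
  nd <- !indeterminate && H11 < -tol1 && det2 > tol2
  structure(list(hessian = H, negative_definite = nd,
                 indeterminate = indeterminate,
                 minors = c(H11 = H11, det = det2)),
            class = "second_order_check")
}

#' @export
print.second_order_check <- function(x, ...) {
  cat("Second-order conditions in (M', F') at mutant = resident\n")
  print(signif(x$hessian, 6))
  cat(sprintf("  leading minors: H11 = %.6g, det = %.6g\n",
              x$minors["H11"], x$minors["det"]))
  cat("  negative definite:", x$negative_definite,
      if (x$indeterminate) "(indeterminate: near-singular matrix)" else "",
      "\n")
  invisible(x)
}

#' Solve the allocation ESS
#'
#' The central solver: finds the evolutionarily stable reproductive
#' allocation `E*` and sex allocation `r*` at a fixed selfing rate `s`, by
#' the closed forms of [solve_ess_E()] and [solve_ess_r()]
#' (`method = "analytic"`, default gain curves only) or by best-response
#' iteration on the mutant fitness ([solve_ess_numeric()];
#' `method = "numeric"`, any gain curves). The returned object records the
#' selection gradient at the solution and the second-order (maximality)
#' check.
#'
#' @param params A [life_history()] object.
#' @param s Selfing rate in \[0, 1\], held fixed during allocation evolution.
#' @param method `"analytic"` or `"numeric"`.
#' @param gains A [gain_set()]; only used by the numeric method.
#' @param ... Passed on to [solve_ess_numeric()].
#' @return Object of class `"ess_fit"` with elements `E_star`, `r_star`,
#'   `s`, `gradient_at_ess`, `second_order`, `second_order_ok`, `boundary`,
#'   `method`, `params`.
#' @examples
#' p <- life_history()
#' fit <- solve_ess(p, s = 0.5)
#' fit
#' coef(fit)
#' @export
solve_ess <- function(params, s = 0, method = c("analytic", "numeric"),
                      gains = default_gains(params), ...) {
  method <- match.arg(method)
  p <- as_life_history(params)
  if (method == "analytic") {
    E <- solve_ess_E(p, s)
    r <- solve_ess_r(p, s)
    boundary <- attr(E, "boundary") || attr(r, "boundary")
    E <- as.numeric(E); r <- as.numeric(r)
  } else {
    nr <- solve_ess_numeric(p, s, gains = gains, ...)
    E <- nr$E_star; r <- nr$r_star; boundary <- nr$boundary
  }
  interior <- E > 1e-9 && E < 1 - 1e-9 && r > 1e-9 && r < 1 - 1e-9
  grad <- c(dW_dE = NA_real_, dW_dr = NA_real_)
  so <- NULL; so_ok <- NA
  if (interior) {
    st <- strategy(E, r, s)
    grad_method <- if (is.null(gains$survival$deriv)) "numeric" else "analytic"
    grad <- selection_gradient(st, p, gains, method = grad_method)
    so <- check_second_order(st, p, gains)
    so_ok <- so$negative_definite
  }
  structure(list(E_star = E, r_star = r, s = s,
                 gradient_at_ess = grad,
                 second_order = so, second_order_ok = so_ok,
                 boundary = boundary || !interior,
                 method = method, params = p, gains = gains),
            class = "ess_fit")
}

#' Numerical ESS by best-response iteration
#'
#' Independent of every closed form in the package: starting from
#' `(E, r) = start`, repeatedly computes the mutant best response to the
#' current resident by nested golden-section/Brent maximization of
#' [total_fitness()] over `(E', r')` on the unit square, replacing the
#' resident by the maximizer, until the resident moves less than `tol`.
#' Deterministic (no random numbers). Works for arbitrary gain curves.
#'
#' @inheritParams solve_ess
#' @param start Numeric `(E, r)` starting resident.
#' @param relax Initial relaxation factor in (0, 1\]: the resident moves
#'   this fraction of the way to the best response each step. Plain
#'   best-response updating (`relax = 1`) overshoots and cycles in the sex
#'   allocation — a resident with little male investment makes pollen cheap
#'   to monopolize, and the steeper the male gain curve (eta near 1) the
#'   harder the best response swings back — so each component's factor
#'   adapts independently: halved whenever that component's successive
#'   displacements reverse direction, grown gently while they agree. The
#'   fixed points are those of the undamped map.
#' @param tol Convergence tolerance on the best-response displacement
#'   (max-norm): iteration stops when the best response to the current
#'   resident is within `tol` of it, i.e., at a fixed point.
#' @param max_iter Iteration cap; exceeding it raises a condition of class
#'   `"essalloc_convergence_error"` carrying the iteration trajectory in its
#'   `trajectory` field.
#' @param optimize_tol Tolerance handed to [stats::optimize()].
#' @return List with `E_star`, `r_star`, `boundary`, `iterations`,
#'   `trajectory` (matrix of iterates).
#' @export
solve_ess_numeric <- function(params, s = 0, gains = default_gains(params),
                              start = c(0.5, 0.5), relax = 0.5, tol = 1e-8,
                              max_iter = 500, optimize_tol = 1e-9) {
  p <- as_life_history(params)
  if (!is.numeric(s) || length(s) != 1L || s < 0 || s > 1)
    stop("s must lie in [0, 1]", call. = FALSE)

  best_response <- function(E, r) {
    res <- c(E, r, s)
    Wfun <- function(Ep, rp)
      sum(.fitness_parts(c(Ep, rp, s), res, p, gains))
    inner <- function(Ep)
      stats::optimize(function(rp) Wfun(Ep, rp), c(0, 1),
                      maximum = TRUE, tol = optimize_tol)
    out <- stats::optimize(function(Ep) inner(Ep)$objective, c(0, 1),
                           maximum = TRUE, tol = optimize_tol)
    Ep <- out$maximum
    c(Ep, inner(Ep)$maximum)
  }

  cur <- c(min(max(start[1], 1e-3), 1 - 1e-3),
           min(max(start[2], 1e-3), 1 - 1e-3))
  relax <- rep(min(max(relax, 1e-3), 1), 2)  # per-component damping
  traj <- matrix(NA_real_, nrow = max_iter + 1L, ncol = 2,
                 dimnames = list(NULL, c("E", "r")))
  traj[1L, ] <- cur
  prev_disp <- NULL
  for (it in seq_len(max_iter)) {
    br <- best_response(cur[1], cur[2])
    disp <- br - cur
    # at E' ~ 0 the fitness is flat in r', so r carries no signal there;
    # judge convergence on E alone
    disp_norm <- if (br[1] < 1e-6) abs(disp[1]) else max(abs(disp))
    if (disp_norm < tol) {
      traj[it + 1L, ] <- br
      edge <- 2e-6  # golden-section cannot land exactly on 0 or 1
      boundary <- br[1] < edge || br[1] > 1 - edge ||
        br[2] < edge || br[2] > 1 - edge
      return(list(E_star = br[1], r_star = br[2], boundary = boundary,
                  iterations = it, trajectory = traj[seq_len(it + 1L), ,
                                                     drop = FALSE]))
    }
    if (!is.null(prev_disp)) {
      flip <- disp * prev_disp < 0
      relax[flip] <- pmax(relax[flip] / 2, 1e-3)
      relax[!flip] <- pmin(relax[!flip] * 1.2, 1)
    }
    prev_disp <- disp
    cur <- cur + relax * disp
    traj[it + 1L, ] <- cur
  }
  cond <- structure(
    class = c("essalloc_convergence_error", "error", "condition"),
    list(message = sprintf(
      "best-response iteration did not converge in %d iterations (last move %.3g)",
      max_iter, max(abs(traj[max_iter + 1L, ] - traj[max_iter, ]))),
      call = sys.call(-1),
      trajectory = traj))
  stop(cond)
}

#' @export
print.ess_fit <- function(x, ...) {
  cat(sprintf("ESS allocation (%s) at selfing rate s = %g\n", x$method, x$s))
  cat(sprintf("  E* = %.8f  (reproductive allocation)\n", x$E_star))
  cat(sprintf("  r* = %.8f  (sex allocation, male share)\n", x$r_star))
  if (x$boundary) cat("  [boundary solution]\n")
  if (!any(is.na(x$gradient_at_ess)))
    cat(sprintf("  gradient at ESS: dW/dE' = %.3g, dW/dr' = %.3g\n",
                x$gradient_at_ess["dW_dE"], x$gradient_at_ess["dW_dr"]))
  if (!is.na(x$second_order_ok))
    cat("  second-order conditions:",
        if (isTRUE(x$second_order_ok)) "negative definite (maximum)"
        else if (isTRUE(x$second_order$indeterminate)) "indeterminate"
        else "NOT satisfied", "\n")
  invisible(x)
}

#' @export
coef.ess_fit <- function(object, ...) {
  c(E_star = object$E_star, r_star = object$r_star)
}

#' @export
summary.ess_fit <- function(object, ...) {
  a <- allocation(strategy(object$E_star, object$r_star, object$s))
  cat("ESS allocation summary\n")
  print(object)
  cat(sprintf("  absolute allocations: M* = %.6f, F* = %.6f, survival = %.6f\n",
              a["M"], a["F"], 1 - object$E_star))
  cat(sprintf("  Pa(E*) = %.6f, f(F*) = %.6f\n",
              object$gains$survival$value(object$E_star),
              object$gains$female$value(a[["F"]])))
  cat(sprintf("  E*-vs-s direction: %s (ratio %.4f)\n",
              classify_dE_ds(object$params),
              attr(classify_dE_ds(object$params), "ratio")))
  invisible(object)
}

#' @export
plot.ess_fit <- function(x, n = 101, ...) {
  res <- strategy(x$E_star, x$r_star, x$s)
  Es <- seq(0.001, 0.999, length.out = n)
  WE <- vapply(Es, function(E)
    total_fitness(strategy(E, x$r_star, x$s), res, x$params, x$gains), 0)
  rs <- seq(0.001, 0.999, length.out = n)
  Wr <- vapply(rs, function(r)
    total_fitness(strategy(x$E_star, r, x$s), res, x$params, x$gains), 0)
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(Es, WE, type = "l", xlab = "mutant E'",
                 ylab = "mutant fitness W", main = "fitness vs E'", ...)
  graphics::abline(v = x$E_star, lty = 2)
  graphics::plot(rs, Wr, type = "l", xlab = "mutant r'",
                 ylab = "mutant fitness W", main = "fitness vs r'", ...)
  graphics::abline(v = x$r_star, lty = 2)
  invisible(x)
}
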