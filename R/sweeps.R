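#' Sweep the ESS reproductive allocation over the selfing rate
#'
#' Solves `E*` (and `r*`) along a grid of selfing rates. The direction of
#' the `E*` curve matches [classify_dE_ds()]: increasing when
#' `w_j / (1 - gamma + gamma w_a) > 1/2`, decreasing below, constant at
#' exactly 1/2.
#'
#' @param params A [life_history()] object.
#' @param s_grid Grid of selfing rates in \[0, 1\].
#' @return Object of class `"ess_sweep"`: list with `axis_name`,
#'   `axis_values`, `E_star`, `r_star`, `boundary`, `regime`,
#'   `params_snapshot`.
#' @export
sweep_E_vs_s <- function(params, s_grid = seq(0, 1, length.out = 21)) {
  p <- as_life_history(params)
  E <- solve_ess_E(p, s_grid)
  r <- solve_ess_r(p, s_grid)
  structure(list(axis_name = "s", axis_values = s_grid,
                 E_star = as.numeric(E), r_star = as.numeric(r),
                 boundary = attr(E, "boundary"),
                 regime = as.character(classify_dE_ds(p)),
                 params_snapshot = p),
            class = "ess_sweep")
}

#' Sweep the ESS sex allocation over the selfing rate, by w_j
#'
#' One `r*`-versus-`s` curve per juvenile relative survivorship `w_j`
#' (i.e., per `delta_j = 1 - w_j`). Every curve with `w_j > 0` decreases
#' strictly, from `eta / (eta + 1)` at `s = 0` (independent of `w_j`) to 0
#' at `s = 1`.
#'
#' @inheritParams sweep_E_vs_s
#' @param w_j_values Juvenile relative survivorships to sweep over.
#' @return Object of class `"ess_sweep_family"`: list with `axis_values`,
#'   `w_j_values`, `r_star` (matrix, rows = `s`, columns = `w_j`),
#'   `params_snapshot`.
#' @export
sweep_r_vs_s <- function(params, s_grid = seq(0, 1, length.out = 21),
                         w_j_values = c(0.3, 0.6, 0.9)) {
  p <- as_life_history(params)
  r <- vapply(w_j_values, function(wj)
    as.numeric(solve_ess_r(update(p, delta_j = 1 - wj), s_grid)),
    numeric(length(s_grid)))
  r <- matrix(r, nrow = length(s_grid),
              dimnames = list(NULL, paste0("w_j=", w_j_values)))
  structure(list(axis_name = "s", axis_values = s_grid,
                 w_j_values = w_j_values, r_star = r,
                 params_snapshot = p),
            class = "ess_sweep_family")
}

#' @export
as.data.frame.ess_sweep <- function(x, ...) {
  data.frame(s = x$axis_values, E_star = x$E_star, r_star = x$r_star,
             boundary = x$boundary)
}

#' @export
as.data.frame.ess_sweep_family <- function(x, ...) {
  data.frame(s = rep(x$axis_values, times = length(x$w_j_values)),
             w_j = rep(x$w_j_values, each = length(x$axis_values)),
             r_star = as.vector(x$r_star))
}

#' @export
print.ess_sweep <- function(x, ...) {
  cat(sprintf("ESS sweep over %s (%d points): E* in [%.4f, %.4f], %s in s\n",
              x$axis_name, length(x$axis_values),
              min(x$E_star), max(x$E_star), x$regime))
  invisible(x)
}

#' @export
print.ess_sweep_family <- function(x, ...) {
  cat(sprintf("ESS sex-allocation sweep over s (%d points) for w_j = %s\n",
              length(x$axis_values),
              paste(x$w_j_values, collapse = ", ")))
  invisible(x)
}

#' @export
plot.ess_sweep <- function(x, ...) {
  graphics::plot(x$axis_values, x$E_star, type = "l",
                 xlab = "selfing rate s", ylab = "ESS reproductive allocation E*",
                 main = sprintf("E* vs s (%s)", x$regime), ...)
  invisible(x)
}

#' @export
plot.ess_sweep_family <- function(x, ...) {
  graphics::matplot(x$axis_values, x$r_star, type = "l", lty = 1,
                    xlab = "selfing rate s", ylab = "ESS sex allocation r*",
                    main = "r* vs s by juvenile relative survivorship", ...)
  graphics::legend("topright", colnames(x$r_star), lty = 1,
                   col = seq_len(ncol(x$r_star)), bty = "n")
  invisible(x)
}

#' Mating-system phase diagram over (delta_j, tau)
#'
#' Regime label per cell of a grid of juvenile inbreeding-depression
#' fractions and threshold values: `"complete_selfing"` where
#' `delta_j < 1/2 - tau`, `"complete_outcrossing"` where
#' `delta_j > 1/2 - tau`, `"neutral"` on the boundary. When `tau_grid` is
#' `NULL` a single `tau` is computed from `params` at the allocation ESS.
#'
#' @param params A [life_history()] object.
#' @param delta_j_grid Grid of `delta_j` values in \[0, 1\].
#' @param tau_grid Grid of `tau` values (`>= 0`), or `NULL`.
#' @param tol Neutrality tolerance on `delta_j - (1/2 - tau)`.
#' @return Object of class `"phase_diagram"`: list with `delta_j`, `tau`,
#'   `regime` (matrix, rows = `delta_j`, columns = `tau`).
#' @export
phase_diagram <- function(params, delta_j_grid = seq(0, 1, length.out = 21),
                          tau_grid = NULL, tol = 1e-9) {
  p <- as_life_history(params)
  if (is.null(tau_grid)) tau_grid <- mating_tau(p)
  regime <- outer(delta_j_grid, tau_grid, function(dj, tau) {
    d <- 0.5 - tau - dj
    ifelse(d > tol, "complete_selfing",
           ifelse(d < -tol, "complete_outcrossing", "neutral"))
  })
  dimnames(regime) <- list(paste0("delta_j=", signif(delta_j_grid, 6)),
                           paste0("tau=", signif(tau_grid, 6)))
  structure(list(delta_j = delta_j_grid, tau = tau_grid, regime = regime,
                 params_snapshot = p),
            class = "phase_diagram")
}

#' @export
as.data.frame.phase_diagram <- function(x, ...) {
  data.frame(delta_j = rep(x$delta_j, times = length(x$tau)),
             tau = rep(x$tau, each = length(x$delta_j)),
             regime = as.vector(x$regime))
}

#' @export
print.phase_diagram <- function(x, ...) {
  tab <- table(x$regime)
  cat("Mating-system phase diagram:",
      paste(sprintf("%s: %d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
plot.phase_diagram <- function(x, ...) {
  z <- matrix(match(x$regime, c("complete_outcrossing", "neutral",
                                "complete_selfing")),
              nrow = length(x$delta_j))
  if (length(x$tau) < 2) {
    graphics::plot(x$delta_j, z[, 1], type = "s", yaxt = "n",
                   xlab = "delta_j", ylab = "regime", ...)
    graphics::axis(2, at = 1:3, labels = c("outcrossing", "neutral", "selfing"))
  } else {
    graphics::image(x$delta_j, x$tau, z,
                    col = c("#4575b4", "#ffffbf", "#d73027"),
                    breaks = c(0.5, 1.5, 2.5, 3.5),
                    xlab = "delta_j", ylab = "tau",
                    main = "selfing (red) vs outcrossing (blue) regimes", ...)
    graphics::abline(0.5, -1, lty = 2)  # delta_j = 1/2 - tau
  }
  invisible(x)
}

#' Bundled parameter scenarios
#'
#' Named parameter sets landing clearly inside each qualitative regime of
#' the model: the three directions of the `E*`-versus-`s` relationship
#' (ratio `w_j / (1 - gamma + gamma w_a)` above, below and exactly at 1/2),
#' a family of juvenile relative survivorships for the `r*`-versus-`s`
#' sweep, and the two mating-system regimes on either side of the
#' `delta_j = 1/2 - tau` boundary.
#'
#' @return Named list of objects of class `"scenario"`, each with `name`,
#'   `params`, `s`, `w_j_values` (where relevant) and `description`.
#' @export
scenarios <- function() {
  mk <- function(name, params, description, s = 0, w_j_values = NULL) {
    structure(list(name = name, params = params, s = s,
                   w_j_values = w_j_values, description = description),
              class = "scenario")
  }
  out <- list(
    mk("ea_increasing",
       life_history(delta_j = 0.2, delta_a = 0.4, gamma = 0.5),
       "E* increases with s: ratio w_j/(1 - gamma + gamma*w_a) = 0.8/0.8 > 1/2"),
    mk("ea_decreasing",
       life_history(delta_j = 0.7, delta_a = 0.4, gamma = 0.5),
       "E* decreases with s: ratio = 0.3/0.8 < 1/2"),
    mk("ea_independent",
       life_history(delta_j = 0.5, delta_a = 0, gamma = 0.5),
       "E* independent of s: ratio = 0.5/1 exactly 1/2"),
    mk("sex_allocation_family",
       life_history(delta_a = 0.4, gamma = 0.5),
       "r* vs s curves for a family of juvenile relative survivorships",
       w_j_values = c(0.3, 0.6, 0.9)),
    mk("selfing_ess",
       life_history(delta_j = 0.3, delta_a = 0.4, gamma = 0.5),
       "delta_j below 1/2 - tau: complete selfing is the ESS"),
    mk("outcrossing_ess",
       life_history(delta_j = 0.48, delta_a = 0.4, gamma = 0.5),
       "delta_j above 1/2 - tau at every selfing rate: complete outcrossing"))
  names(out) <- vapply(out, function(x) x$name, "")
  out
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("Scenario '%s': %s\n", x$name, x$description))
  print(x$params)
  invisible(x)
}
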