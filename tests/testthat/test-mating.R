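p_ex <- example_params()

test_that("tau follows the fixed-value arithmetic and vanishes with delta_a", {
  expect_equal(mating_tau(p_ex, Pa = 0.5, f = 5), 0.1)
  expect_equal(mating_tau(update(p_ex, delta_a = 0)), 0)
  expect_error(mating_tau(p_ex, Pa = 0.5, f = 0), "undefined")
  # default evaluation at the allocation ESS
  E <- as.numeric(solve_ess_E(p_ex, 0))
  r <- as.numeric(solve_ess_r(p_ex, 0))
  expect_equal(mating_tau(p_ex),
               0.4 * adult_survival(E, p_ex) * 0.5 /
                 (0.2 * female_gain(E * (1 - r), p_ex)),
               tolerance = 1e-12)
})

test_that("selfing gradient: closed form, finite differences, and signs", {
  # exact neutrality at delta_j = 1/2 with no adult cost
  p_neutral <- update(p_ex, delta_j = 0.5, delta_a = 0)
  expect_equal(selfing_selection_gradient(strategy(0.5, 0.4, 0.3), p_neutral), 0)

  # low juvenile inbreeding depression, no adult cost: selfing invades
  p_self <- update(p_ex, delta_j = 0.2, delta_a = 0)
  expect_gt(selfing_selection_gradient(strategy(0.5, 0.4, 0.3), p_self), 0)

  # fixed-value curves with tau = 0.1: delta_j = 0.45 is above the 0.4
  # boundary, so outcrossing is favored
  p_out <- update(p_ex, delta_j = 0.45)
  g_out <- selfing_selection_gradient(strategy(0.5, 0.5, 0.3), p_out,
                                      gains = fixed_gains(0.5, 5, p_out))
  expect_lt(g_out, 0)
  expect_equal(g_out, 0.2 * 5 * (0.55 - 0.5) - 0.5 * 0.5 * 0.4,
               tolerance = 1e-12)

  # two-route agreement, including one-sided differentiation at the edges
  set.seed(37)
  for (i in 1:25) {
    p <- random_params()
    st <- random_strategy(interior = TRUE)
    ga <- selfing_selection_gradient(st, p)
    gn <- selfing_selection_gradient(st, p, method = "numeric")
    expect_equal(ga, as.numeric(gn), tolerance = 1e-6)
  }
  g0 <- selfing_selection_gradient(strategy(0.5, 0.4, 0), p_self,
                                   method = "numeric")
  expect_equal(attr(g0, "side"), "right")
  g1 <- selfing_selection_gradient(strategy(0.5, 0.4, 1), p_self,
                                   method = "numeric")
  expect_equal(attr(g1, "side"), "left")
})

test_that("mating-system classification matches the delta_j vs 1/2 - tau rule", {
  # gradient positive <=> delta_j below the boundary <=> selfing evolves
  cls_self <- classify_mating_ess(update(p_ex, delta_j = 0.3), Pa = 0.5, f = 5)
  expect_equal(cls_self$tau, 0.1)
  expect_equal(cls_self$delta_j_boundary, 0.4)
  expect_equal(cls_self$regime, "complete_selfing")
  expect_equal(cls_self$gradient_sign, 1L)

  cls_out <- classify_mating_ess(update(p_ex, delta_j = 0.45), Pa = 0.5, f = 5)
  expect_equal(cls_out$regime, "complete_outcrossing")
  expect_equal(cls_out$gradient_sign, -1L)

  cls_neutral <- classify_mating_ess(update(p_ex, delta_j = 0.5, delta_a = 0))
  expect_equal(cls_neutral$regime, "neutral")
  expect_equal(cls_neutral$tau, 0)

  # default evaluation at the allocation ESS
  expect_equal(classify_mating_ess(life_history(delta_j = 0.2, delta_a = 0))$regime,
               "complete_selfing")
})

test_that("rule and gradient agree across random parameter sets", {
  set.seed(41)
  for (i in 1:50) {
    p <- random_params()
    # classification computes both routes and errors on disagreement
    cls <- classify_mating_ess(p)
    expect_true(cls$regime %in%
                  c("complete_selfing", "complete_outcrossing", "neutral"))
    g <- cls$gradient
    if (cls$regime == "complete_selfing") expect_gt(g, 0)
    if (cls$regime == "complete_outcrossing") expect_lt(g, 0)
  }
})

test_that("bisection recovers the delta_j boundary 1/2 - tau", {
  # no adult inbreeding depression: boundary at exactly 1/2
  b0 <- find_deltaj_boundary(update(p_ex, delta_a = 0))
  expect_true(b0$found)
  expect_equal(b0$delta_j, 0.5, tolerance = 1e-6)

  # fixed-value curves with tau = 0.1: boundary at 0.4
  bf <- find_deltaj_boundary(p_ex, Pa = 0.5, f = 5)
  expect_equal(bf$delta_j, 0.4, tolerance = 1e-6)

  # self-consistency: boundary equals 1/2 - tau(at the boundary)
  set.seed(43)
  for (i in 1:25) {
    p <- random_params()
    b <- find_deltaj_boundary(p)
    if (b$found)
      expect_equal(b$delta_j, 0.5 - b$tau_at_boundary, tolerance = 1e-6)
  }

  # tau too large for any boundary: uniform complete outcrossing
  p_big <- update(p_ex, Pj = 0.1, delta_a = 0.9, gamma = 0.9)
  expect_gt(mating_tau(p_big), 0.5)
  b_none <- find_deltaj_boundary(p_big)
  expect_false(b_none$found)
  expect_true(is.na(b_none$delta_j))
  expect_equal(b_none$regime, "complete_outcrossing")
})

test_that("nonlinear selfed-adult curves yield an interior singular rate", {
  p <- update(p_ex, delta_j = 0.45, delta_a = 0.8)
  g <- gain_set(
    survival = power_survival_curve(p$Pa_max, p$beta),
    female   = linear_female_curve(p$f_max),
    male     = power_male_curve(p$m_max, p$eta),
    selfed   = gain_curve(function(s) 0.5 * s^2, function(s) s,
                          function(s) 1, label = "quadratic S"))
  cls <- classify_mating_ess(p, gains = g)
  expect_equal(cls$regime, "interior_singular")
  # closed-form oracle: Pj f(F*) (w_j - 1/2) = Pa(E*) S'(s*) delta_a
  E <- as.numeric(solve_ess_E(p, 0)); r <- as.numeric(solve_ess_r(p, 0))
  s_expect <- p$Pj * female_gain(E * (1 - r), p) * 0.05 /
    (adult_survival(E, p) * p$delta_a)
  expect_equal(cls$s_singular, s_expect, tolerance = 1e-6)
})

test_that("pairwise invasibility: zero diagonal and regime-consistent half planes", {
  sc <- scenarios()

  pip_self <- pairwise_invasibility(sc$selfing_ess$params, grid_size = 9)
  expect_true(all(diag(pip_self$sign) == 0L))
  up <- upper.tri(pip_self$sign)
  expect_true(all(pip_self$sign[up] == 1L))    # higher selfing invades
  expect_true(all(t(pip_self$sign)[up] == -1L))

  pip_out <- pairwise_invasibility(sc$outcrossing_ess$params, grid_size = 9)
  expect_true(all(diag(pip_out$sign) == 0L))
  expect_true(all(pip_out$sign[upper.tri(pip_out$sign)] == -1L))

  expect_error(pairwise_invasibility(p_ex, grid_size = 1), "grid_size")
})

test_that("invasion grids serialize as coordinate-framed CSV", {
  pip <- pairwise_invasibility(p_ex, grid_size = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_invasion_grid(pip, path)
  lines <- readLines(path)
  expect_length(lines, 6)
  expect_match(lines[1], "^,0,")
  mat <- utils::read.csv(path, header = TRUE, row.names = 1, check.names = FALSE)
  expect_equal(unname(as.matrix(mat)), matrix(as.integer(pip$sign), 5, 5),
               ignore_attr = TRUE)
  df <- as.data.frame(pip)
  expect_equal(nrow(df), 25)
})
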