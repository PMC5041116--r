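p_ex <- example_params()

test_that("closed-form ESS allocations reproduce the worked example", {
  E <- solve_ess_E(p_ex, s = 0.5)
  expect_equal(as.numeric(E), 0.902944, tolerance = 1e-6)
  expect_false(attr(E, "boundary"))
  # independent arithmetic: root of -Pa'(E) (1 - s g da) = K
  K <- (0.2 * 10 / 2) * (1 + 0.5 * (2 * 0.8 - 1)) / (1 - 0.5 * 0.5 * 0.4)
  expect_equal(as.numeric(E), 1 - (0.9 * 0.5 / K)^2, tolerance = 1e-12)

  r <- solve_ess_r(p_ex, s = 0.5)
  expect_equal(as.numeric(r), 0.235294, tolerance = 1e-6)
  expect_equal(as.numeric(r), 0.4 / (0.4 + 1.3), tolerance = 1e-12)
})

test_that("sex-allocation limits: s = 1 gives r* = 0, s = 0 gives eta/(eta+1)", {
  expect_equal(as.numeric(solve_ess_r(p_ex, 1)), 0)
  expect_true(attr(solve_ess_r(p_ex, 1), "boundary"))
  expect_equal(as.numeric(solve_ess_r(update(p_ex, eta = 1), 0)), 0.5)
  expect_equal(as.numeric(solve_ess_r(p_ex, 0)), 0.8 / 1.8, tolerance = 1e-12)
})

test_that("E* is independent of s in the outcrossing limit and at ratio 1/2", {
  # s = 0: root of -Pa'(E) = Pj f_max / 2, untouched by delta_j, delta_a, gamma
  E0 <- as.numeric(solve_ess_E(p_ex, 0))
  for (p2 in list(update(p_ex, delta_j = 0.9), update(p_ex, delta_a = 0.9),
                  update(p_ex, gamma = 0.1)))
    expect_equal(as.numeric(solve_ess_E(p2, 0)), E0, tolerance = 1e-14)

  # w_j = 1/2, delta_a = 0: the s-dependent factor is constant
  p_half <- update(p_ex, delta_j = 0.5, delta_a = 0)
  Es <- vapply(c(0, 0.5, 1), function(s) as.numeric(solve_ess_E(p_half, s)), 0)
  expect_equal(max(Es) - min(Es), 0, tolerance = 1e-14)
})

test_that("selection gradient vanishes at the analytic ESS", {
  for (s in c(0.1, 0.5, 0.9)) {
    st <- strategy(as.numeric(solve_ess_E(p_ex, s)),
                   as.numeric(solve_ess_r(p_ex, s)), s)
    g <- selection_gradient(st, p_ex)
    expect_lt(max(abs(g)), 1e-9)
  }
})

test_that("analytic and finite-difference gradients agree on random interiors", {
  set.seed(23)
  worst <- 0
  for (i in 1:100) {
    p <- random_params()
    st <- random_strategy(interior = TRUE)
    ga <- selection_gradient(st, p, method = "analytic")
    gn <- selection_gradient(st, p, method = "numeric")
    worst <- max(worst, abs(ga - gn))
  }
  expect_lt(worst, 1e-6)
})

test_that("gradient refuses boundary residents", {
  expect_error(selection_gradient(strategy(0, 0.5, 0), p_ex), "boundary")
  expect_error(selection_gradient(strategy(0.5, 1, 0), p_ex), "boundary")
})

test_that("the s-dependent factor of the E condition is flat when delta_a = 0, w_j = 1/2", {
  # along strategies whose sex allocation satisfies the marginal balance at
  # each s, the E-direction gradient loses all s dependence: the factor
  # (1 + s (2 w_j - 1)) / (1 - s gamma delta_a) is identically 1
  p <- update(p_ex, delta_a = 0, delta_j = 0.5)
  g_at <- function(s) {
    r_bal <- stats::uniroot(
      function(r) marginal_balance_residual(strategy(0.6, r, s), p),
      c(0.01, 0.99), tol = 1e-14)$root
    unname(selection_gradient(strategy(0.6, r_bal, s), p)["dW_dE"])
  }
  expect_equal(g_at(0), g_at(0.8), tolerance = 1e-9)
  expect_equal(g_at(0.3), g_at(0.8), tolerance = 1e-9)
})

test_that("marginal balance is zero at r*, negative above, and delta_a-free", {
  s <- 0.4
  r_star <- as.numeric(solve_ess_r(p_ex, s))
  at <- function(r, p = p_ex) marginal_balance_residual(strategy(0.5, r, s), p)
  expect_lt(abs(at(r_star)), 1e-10)
  expect_lt(at(r_star + 0.2), 0)   # male overinvested
  expect_gt(at(r_star - 0.1), 0)
  expect_equal(at(0.3, update(p_ex, delta_a = 1)), at(0.3, update(p_ex, delta_a = 0)),
               tolerance = 1e-14)
})

test_that("best-response oracle matches the closed forms", {
  set.seed(101)
  worst <- 0
  for (i in 1:25) {
    case <- random_interior_case()
    nr <- solve_ess_numeric(case$params, case$s)
    worst <- max(worst, abs(nr$E_star - case$E_star),
                 abs(nr$r_star - case$r_star))
    expect_false(nr$boundary)
  }
  expect_lt(worst, 1e-6)
})

test_that("cost-free selfing still raises E* through the transmission advantage", {
  # delta_j = delta_a = 0 makes resident-total fitness s-independent, but
  # the ESS allocation is not: the ratio criterion gives ratio = 1 > 1/2,
  # so the doubled genetic share of selfed seeds pulls E* up with s
  p0 <- update(p_ex, delta_j = 0, delta_a = 0)
  expect_equal(as.character(classify_dE_ds(p0)), "increasing")
  a <- solve_ess_numeric(p0, 0)
  b <- solve_ess_numeric(p0, 0.5)
  expect_gt(b$E_star, a$E_star)
  expect_equal(a$E_star, as.numeric(solve_ess_E(p0, 0)), tolerance = 1e-6)
  expect_equal(b$E_star, as.numeric(solve_ess_E(p0, 0.5)), tolerance = 1e-6)
})

test_that("vanishing reproductive payoff drives E* to the zero boundary", {
  p_tiny <- update(p_ex, f_max = 1e-6)
  E <- solve_ess_E(p_tiny, 0.3)
  expect_equal(as.numeric(E), 0)
  expect_true(attr(E, "boundary"))
  nr <- solve_ess_numeric(p_tiny, 0.3)
  expect_lt(nr$E_star, 1e-4)
  expect_true(nr$boundary)
})

test_that("solve_ess returns a coherent fitted object", {
  fit <- solve_ess(p_ex, s = 0.5)
  expect_s3_class(fit, "ess_fit")
  expect_equal(unname(coef(fit)), c(0.9029438, 0.2352941), tolerance = 1e-6)
  expect_lt(max(abs(fit$gradient_at_ess)), 1e-9)
  expect_true(fit$second_order_ok)
  expect_false(fit$boundary)
  expect_output(print(fit), "E\\*")

  fit_n <- solve_ess(p_ex, s = 0.5, method = "numeric")
  expect_equal(coef(fit_n), coef(fit), tolerance = 1e-6)
})

test_that("second-order conditions: negative definite at the ESS, degenerate when linear", {
  st <- strategy(as.numeric(solve_ess_E(p_ex, 0.5)),
                 as.numeric(solve_ess_r(p_ex, 0.5)), 0.5)
  so <- check_second_order(st, p_ex)
  expect_true(so$negative_definite)
  expect_lt(so$minors["H11"], 0)
  expect_gt(so$minors["det"], 0)

  # the check is pointwise: it still reports away from the ESS
  far <- check_second_order(strategy(0.99, 0.5, 0.5), p_ex)
  expect_true(is.matrix(far$hessian))

  # linear male and female gains: singular matrix, flagged indeterminate
  p_lin <- update(p_ex, eta = 1)
  st_lin <- strategy(as.numeric(solve_ess_E(p_lin, 0)),
                     as.numeric(solve_ess_r(p_lin, 0)), 0)
  so_lin <- check_second_order(st_lin, p_lin)
  expect_true(so_lin$indeterminate)
  expect_false(so_lin$negative_definite)
})

test_that("dE*/ds direction is classified by the ratio criterion", {
  cl <- classify_dE_ds(p_ex)   # 0.8 / 0.8 = 1 > 1/2
  expect_equal(as.character(cl), "increasing")
  cl2 <- classify_dE_ds(life_history(delta_j = 0.2, delta_a = 0.4, gamma = 0.5))
  expect_equal(attr(cl2, "ratio"), 0.8 / 0.8)
  expect_equal(as.character(classify_dE_ds(life_history(delta_j = 0.5, delta_a = 0))),
               "independent")
  expect_equal(as.character(classify_dE_ds(life_history(delta_j = 0.7, delta_a = 0.4,
                                                        gamma = 0.5))),
               "decreasing")
  # no adult inbreeding depression: increasing whenever delta_j < 1/2
  expect_equal(as.character(classify_dE_ds(life_history(delta_j = 0.3, delta_a = 0))),
               "increasing")

  # label agrees with the measured sign of E*(0.9) - E*(0.1)
  set.seed(29)
  for (i in 1:20) {
    p <- random_params()
    d <- as.numeric(solve_ess_E(p, 0.9)) - as.numeric(solve_ess_E(p, 0.1))
    lab <- as.character(classify_dE_ds(p))
    if (abs(d) > 1e-10)
      expect_equal(lab, if (d > 0) "increasing" else "decreasing")
  }
})

test_that("r* decreases with s everywhere, matching the closed-form slope", {
  set.seed(31)
  slopes <- replicate(1000, {
    p <- random_params()   # delta_j <= 0.9 so w_j > 0
    sex_allocation_slope(p, runif(1, 0, 0.95))
  })
  expect_true(all(slopes < 0))

  # degenerate w_j = 0: r* constant in s
  p0 <- life_history(delta_j = 1)
  expect_equal(sex_allocation_slope(p0, 0.3), 0)
  expect_equal(as.numeric(solve_ess_r(p0, 0.2)), as.numeric(solve_ess_r(p0, 0.7)),
               tolerance = 1e-14)

  # central-difference slope of solve_ess_r agrees with the closed form
  h <- 1e-6
  fd <- (as.numeric(solve_ess_r(p_ex, 0.3 + h)) -
           as.numeric(solve_ess_r(p_ex, 0.3 - h))) / (2 * h)
  expect_equal(fd, sex_allocation_slope(p_ex, 0.3), tolerance = 1e-6)
})

test_that("r* is invariant to E, f_max, m_max and delta_a; E* to r", {
  s <- 0.35
  # r*: root of the marginal balance in r, under perturbed parameters
  root_r <- function(E, p) {
    stats::uniroot(function(r) marginal_balance_residual(strategy(E, r, s), p),
                   c(0.01, 0.99), tol = 1e-12)$root
  }
  base <- root_r(0.5, p_ex)
  expect_equal(root_r(0.2, p_ex), base, tolerance = 1e-8)
  expect_equal(root_r(0.9, p_ex), base, tolerance = 1e-8)
  expect_equal(root_r(0.5, update(p_ex, f_max = 3)), base, tolerance = 1e-8)
  expect_equal(root_r(0.5, update(p_ex, m_max = 1e4)), base, tolerance = 1e-8)
  expect_equal(root_r(0.5, update(p_ex, delta_a = 0.9)), base, tolerance = 1e-8)

  # E*: root of the survival-vs-female first-order condition, by finite
  # differences of the fitness in F' (no closed form involved), at several
  # resident sex allocations
  dW_dF <- function(E, r) {
    res <- strategy(E, r, s)
    M <- E * r; F <- E * (1 - r)
    h <- 1e-6
    (total_fitness(strategy_MF(M, F + h, s), res, p_ex) -
        total_fitness(strategy_MF(M, F - h, s), res, p_ex)) / (2 * h)
  }
  root_E <- function(r)
    stats::uniroot(function(E) dW_dF(E, r), c(0.2, 0.999), tol = 1e-12)$root
  E_base <- root_E(0.5)
  expect_equal(root_E(0.2), E_base, tolerance = 1e-8)
  expect_equal(root_E(0.8), E_base, tolerance = 1e-8)
  expect_equal(E_base, as.numeric(solve_ess_E(p_ex, s)), tolerance = 1e-6)
})

test_that("non-convergence raises a condition carrying the trajectory", {
  err <- tryCatch(solve_ess_numeric(p_ex, 0.5, max_iter = 2),
                  essalloc_convergence_error = function(e) e)
  expect_s3_class(err, "essalloc_convergence_error")
  expect_true(is.matrix(err$trajectory))
})
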