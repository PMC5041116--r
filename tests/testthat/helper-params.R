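# shared fixtures: the worked-example parameter set and a random generator
# for valid parameter sets with an interior allocation ESS

example_params <- function() {
  life_history(Pj = 0.2, delta_j = 0.2, delta_a = 0.4, gamma = 0.5,
               f_max = 10, m_max = 100, eta = 0.8, Pa_max = 0.9, beta = 0.5)
}

random_params <- function() {
  life_history(Pj = runif(1, 0.1, 0.9),
               delta_j = runif(1, 0, 0.9),
               delta_a = runif(1, 0, 0.9),
               gamma = runif(1, 0.05, 0.95),
               f_max = runif(1, 3, 20),
               m_max = runif(1, 10, 500),
               eta = runif(1, 0.3, 0.9),
               Pa_max = runif(1, 0.3, 1),
               beta = runif(1, 0.15, 0.85))
}

# rejection-sample a (params, s) pair whose analytic ESS is interior with
# some margin; margin keeps golden-section well away from the edges
random_interior_case <- function(margin = 0.02) {
  repeat {
    p <- random_params()
    s <- runif(1, 0.05, 0.95)
    E <- as.numeric(solve_ess_E(p, s))
    r <- as.numeric(solve_ess_r(p, s))
    if (E > margin && E < 1 - margin && r > margin && r < 1 - margin)
      return(list(params = p, s = s, E_star = E, r_star = r))
  }
}

random_strategy <- function(interior = FALSE) {
  if (interior)
    strategy(runif(1, 0.05, 0.95), runif(1, 0.05, 0.95), runif(1, 0, 1))
  else
    strategy(runif(1), runif(1), runif(1))
}
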