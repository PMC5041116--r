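#' Mutant fitness in a monomorphic resident population
#'
#' The fate of a rare mutant with strategy `(E', r', s')` in a resident
#' population fixed for `(E, r, s)` is scored by its expected genetic
#' contribution to the next generation. Writing `M = E r`, `F = E (1 - r)`,
#' `w_j = 1 - delta_j`, and `S(s)` for the selfed-adult fraction, the total
#' fitness is
#'
#' \deqn{W = P_a(E') (1 - S(s') \delta_a)
#'   + P_j [ s' w_j f(F') + \tfrac12 (1 - s') f(F')
#'   + \tfrac12 (1 - s) f(F) m(M') / m(M) ]}
#'
#' The three juvenile terms are: selfed seeds (two gene copies from the
#' mutant, hence full weight, discounted by juvenile inbreeding depression),
#' outcrossed seeds as seed parent (one copy, weight 1/2), and outcross
#' siring of the resident's outcrossed ovules in proportion to the mutant's
#' share of the pollen pool (weight 1/2). The adult term is the mutant's own
#' survival, discounted by adult inbreeding mortality of its selfed fraction.
#'
#' `female_fitness()` is the seed-parent part (adult survival as a seed
#' parent plus seed-parent gametic success) and `male_fitness()` the
#' pollen-parent part; a selfed offspring contributes 1/2 to each, and the
#' adult survival term is split half and half, so that
#' `female_fitness + male_fitness == total_fitness` exactly.
#'
#' @param mutant Mutant [strategy()] (or numeric `(E, r, s)` triple).
#' @param resident Resident strategy; defaults to the mutant (resident
#'   self-consistency).
#' @param params A [life_history()] object.
#' @param gains A [gain_set()]; defaults to [default_gains()].
#' @return A single fitness value.
#' @examples
#' p <- life_history(Pj = 0.2, f_max = 10, delta_j = 0.2, delta_a = 0.4,
#'                   gamma = 0.5, Pa_max = 0.9, beta = 0.5)
#' st <- strategy(0.5, 0.3, 0.5)
#' total_fitness(st, st, p)                      # 1.202756
#' female_fitness(st, st, p) + male_fitness(st, st, p)  # identical
#' @name fitness
NULL

# scalar kernel shared by all fitness entry points; mut/res are bare numeric
# (E, r, s) triples, already validated
.fitness_parts <- function(mut, res, p, g) {
  Ep <- mut[[1]]; rp <- mut[[2]]; sp <- mut[[3]]
  E  <- res[[1]]; r  <- res[[2]]; s  <- res[[3]]
  Fp <- Ep * (1 - rp); Mp <- Ep * rp
  Ff <- E * (1 - r);   Mm <- E * r
  wj <- 1 - p$delta_j

  adult <- g$survival$value(Ep) * (1 - g$selfed$value(sp) * p$delta_a)
  fFp <- g$female$value(Fp)
  self_term <- 0.5 * sp * wj * fFp        # selfed seeds, per-parent share
  outf_term <- 0.5 * (1 - sp) * fFp       # outcrossed seeds, seed parent

  fF <- g$female$value(Ff)
  if ((1 - s) * fF > 0) {
    mM <- g$male$value(Mm)
    if (mM <= 0)
      stop("degenerate pollen pool: resident male gain m(M) = 0 while ",
           "outcrossed ovules exist (s < 1, f(F) > 0)", call. = FALSE)
    sire <- 0.5 * (1 - s) * fF * g$male$value(Mp) / mM
  } else {
    sire <- 0
  }

  c(female = 0.5 * adult + p$Pj * (self_term + outf_term),
    male   = 0.5 * adult + p$Pj * (self_term + sire))
}

.fitness_args <- function(mutant, resident, params) {
  list(mut = unclass(as_strategy(mutant)),
       res = unclass(as_strategy(resident)),
       p = as_life_history(params))
}

#' @rdname fitness
#' @export
female_fitness <- function(mutant, resident = mutant, params,
                           gains = default_gains(params)) {
  a <- .fitness_args(mutant, resident, params)
  unname(.fitness_parts(a$mut, a$res, a$p, gains)["female"])
}

#' @rdname fitness
#' @export
male_fitness <- function(mutant, resident = mutant, params,
                         gains = default_gains(params)) {
  a <- .fitness_args(mutant, resident, params)
  unname(.fitness_parts(a$mut, a$res, a$p, gains)["male"])
}

#' @rdname fitness
#' @export
total_fitness <- function(mutant, resident = mutant, params,
                          gains = default_gains(params)) {
  a <- .fitness_args(mutant, resident, params)
  sum(.fitness_parts(a$mut, a$res, a$p, gains))
}
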