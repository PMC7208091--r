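# Random but valid parameter sets used by the property-style tests.
# All draws respect the domain constraints (alpha in (0,1), w in (0,1],
# h >= F, h > 2) so every generated set is admissible by construction.

random_param_set <- function() {
  R <- runif(1, 500, 10000)
  r_f <- runif(1, 2, 20)
  r_m <- runif(1, 0.5, 2)
  alpha <- runif(1, 0.05, 0.95)
  w <- runif(1, 0.1, 1)
  F <- alpha * R / r_f
  h <- max(3, F * runif(1, 1.5, 20))
  list(params = reproduction_params(R, r_f, r_m, alpha),
       disp = dispersal_params(h, w))
}

# like random_param_set() but with h >= R/r_f, so every allocation in (0,1)
# respects the capacity bound h >= F and the optimum is interior — the
# setting in which the ovule-bias and monotonicity propositions apply
random_interior_set <- function() {
  R <- runif(1, 500, 10000)
  r_f <- runif(1, 2, 20)
  r_m <- runif(1, 0.5, 2)
  alpha <- runif(1, 0.05, 0.95)
  w <- runif(1, 0.1, 1)
  h <- max(3, (R / r_f) * runif(1, 1.05, 25))
  list(params = reproduction_params(R, r_f, r_m, alpha),
       disp = dispersal_params(h, w))
}

# integer-valued set for the Monte Carlo simulator
random_sim_set <- function() {
  F <- sample(20:200, 1)
  M <- sample(100:2000, 1)
  h <- sample(max(F, 3):2000, 1)
  w <- runif(1, 0.3, 1)
  list(F = F, M = M, disp = dispersal_params(h, w))
}

# E(F*) as a plain function of alpha, for grid-search oracles
ef_of_alpha <- function(alpha, R, r_f, r_m, disp) {
  vapply(alpha, function(a) {
    expected_fertilized(reproduction_params(R, r_f, r_m, a), disp)$E_Fstar
  }, numeric(1))
}
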