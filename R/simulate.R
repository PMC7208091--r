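#' Monte Carlo simulation of pollen dispersal and ovule fertilization
#'
#' Empirical counterpart of the closed forms: in each replicate the retained
#' pollen scatter uniformly and independently over the `h` spatial units of
#' the dispersal range, and an ovule is fertilized when at least one pollen
#' lands on its unit. Because dispersal is uniform, which units hold the `F`
#' ovules is irrelevant (exchangeability); the simulator designates units
#' `1..F`.
#'
#' Retention can act stochastically — each of the `M` pollen stays in the
#' range independently with probability `w` (binomial thinning, mean exactly
#' `w M`) — or deterministically as a fixed `round(w M)` retained pollen.
#' The deterministic mode matches the closed forms' fixed exponent and is
#' the right comparator for `E(P) = 1 - (1 - 1/h)^round(wM)`.
#'
#' @param F integer ovule count, `1 <= F <= h`.
#' @param M integer pollen count, >= 0.
#' @param disp a [dispersal_params()] object; `h` must be a whole number.
#' @param reps number of replicates, >= 1.
#' @param seed random seed (integer); required for reproducibility — the
#'   same seed reproduces the samples bit-for-bit.
#' @param retention `"stochastic"` (binomial thinning, default) or
#'   `"deterministic"` (`round(w M)` pollen retained).
#' @return An object of class `"simulation_result"`: list with `samples_P`
#'   (per-replicate fertilized proportion), `samples_Fstar`, `mean_P`,
#'   `var_P`, `se_mean_P`, `mean_Fstar`, `reps`, `seed`, and the closed-form
#'   comparators `E_P`, `V_P` evaluated with the matching retained-pollen
#'   exponent.
#' @examples
#' sim <- simulate_dispersal(250, 1000, dispersal_params(1000), reps = 2000,
#'                           seed = 1)
#' c(sim$mean_P, sim$E_P)
#' @export
simulate_dispersal <- function(F, M, disp, reps = 10000, seed = 1,
                               retention = c("stochastic", "deterministic")) {
  stopifnot(inherits(disp, "dispersal_params"))
  retention <- match.arg(retention)
  for (nm in c("F", "M", "reps", "seed")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v != round(v)) {
      stop(sprintf("`%s` must be a whole number", nm), call. = FALSE)
    }
  }
  if (disp$h != round(disp$h)) {
    stop("the simulator requires an integer range size `h`", call. = FALSE)
  }
  if (F < 1 || M < 0 || reps < 1) {
    stop("need F >= 1, M >= 0, reps >= 1", call. = FALSE)
  }
  if (F > disp$h) {
    stop(sprintf("model assumption h >= F violated: F = %d > h = %d",
                 as.integer(F), as.integer(disp$h)), call. = FALSE)
  }
  set.seed(seed)
  fert <- dispersal_replicates_cpp(as.integer(F), as.integer(M),
                                   as.integer(disp$h), disp$w,
                                   as.integer(reps),
                                   retention == "stochastic")
  samples_P <- fert / F
  mean_P <- mean(samples_P)
  var_P <- stats::var(samples_P)
  # comparator exponent: wM for stochastic thinning, round(wM) when fixed
  M_eff <- if (retention == "stochastic") disp$w * M else round(disp$w * M)
  unit_disp <- dispersal_params(disp$h, 1)
  structure(list(reps = reps, seed = seed, retention = retention,
                 samples_P = samples_P, samples_Fstar = fert,
                 mean_P = mean_P, var_P = var_P,
                 se_mean_P = sqrt(var_P / reps),
                 mean_Fstar = F * mean_P,
                 E_P = expected_proportion(M_eff, unit_disp),
                 V_P = if (disp$h > 2)
                         variance_proportion(F, M_eff, unit_disp)
                       else NA_real_),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("Dispersal simulation: %g replicates (seed %g, %s retention)\n",
              x$reps, x$seed, x$retention))
  cat(sprintf("  mean P = %.5f (SE %.5f), closed form E(P) = %.5f\n",
              x$mean_P, x$se_mean_P, x$E_P))
  cat(sprintf("  var P  = %.3g, closed form V(P) = %.3g\n", x$var_P, x$V_P))
  cat(sprintf("  mean fertilized ovules = %.3f\n", x$mean_Fstar))
  invisible(x)
}

#' Simulated expected number of fertilized ovules from model parameters
#'
#' Wraps [gamete_counts()] and [simulate_dispersal()]: computes `F` and `M`
#' from the resource budget and allocation, rounds them to integers, and
#' simulates. The empirical `mean_Fstar` estimates `E(F*)`.
#'
#' @param params a [reproduction_params()] object.
#' @param disp a [dispersal_params()] object with whole-number `h`.
#' @inheritParams simulate_dispersal
#' @return A `"simulation_result"` (see [simulate_dispersal()]).
#' @export
simulate_expected_fertilized <- function(params, disp, reps = 10000,
                                         seed = 1,
                                         retention = c("stochastic",
                                                       "deterministic")) {
  stopifnot(inherits(params, "reproduction_params"))
  retention <- match.arg(retention)
  g <- gamete_counts(params)
  F <- round(g$F)
  if (F == 0) {  # allocation so small no whole ovule is produced
    zero <- rep(0, reps)
    return(structure(list(reps = reps, seed = seed, retention = retention,
                          samples_P = zero, samples_Fstar = zero,
                          mean_P = 0, var_P = 0, se_mean_P = 0,
                          mean_Fstar = 0, E_P = NA_real_, V_P = NA_real_),
                     class = "simulation_result"))
  }
  simulate_dispersal(F, round(g$M), disp, reps = reps, seed = seed,
                     retention = retention)
}
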