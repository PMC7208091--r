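#' Resource-decline scenario
#'
#' Describes a sudden reduction of the gametic resource budget from `R` to
#' `q * R` while all other parameters stay put. The baseline expectation
#' `E(F*)` under full resources is recorded; the compensation strategies ask
#' how (and whether) it can be restored under `q * R`.
#'
#' @param params baseline [reproduction_params()].
#' @param disp baseline [dispersal_params()].
#' @param q remaining fraction of resources, in (0, 1].
#' @return An object of class `"decline_scenario"`: list with `params`,
#'   `disp`, `q`, and `baseline_E_Fstar`.
#' @examples
#' sc <- decline_scenario(reproduction_params(5000, 10, 1, 0.5),
#'                        dispersal_params(1000, 0.4), q = 0.9)
#' @export
decline_scenario <- function(params, disp, q) {
  stopifnot(inherits(params, "reproduction_params"),
            inherits(disp, "dispersal_params"))
  check_scalar(q, "q", lower = 0, upper = 1, strict = c(TRUE, FALSE))
  baseline <- expected_fertilized(params, disp)
  structure(list(params = params, disp = disp, q = q,
                 baseline_E_Fstar = baseline$E_Fstar,
                 baseline_E_P = baseline$E_P),
            class = "decline_scenario")
}

#' Gamete production and fertilization after resource decline
#'
#' With unchanged allocation and dispersal, declined resources `q * R` scale
#' both gamete counts linearly (`F' = q F`, `M' = q M`), which depresses both
#' the expected proportion `E(P') = 1 - (1 - 1/h)^(w q M)` and the expected
#' number `E(F*') = F' E(P')` of fertilized ovules.
#'
#' @param scenario a [decline_scenario()].
#' @return A list with `F`, `M` (declined counts), `E_P`, `E_Fstar`, and the
#'   full `"fertilization_stats"` object as `stats`.
#' @export
apply_decline <- function(scenario) {
  stopifnot(inherits(scenario, "decline_scenario"))
  p <- scenario$params
  declined <- reproduction_params(scenario$q * p$R, p$r_f, p$r_m, p$alpha)
  st <- expected_fertilized(declined, scenario$disp)
  list(F = st$F, M = st$M, E_P = st$E_P, E_Fstar = st$E_Fstar, stats = st)
}

new_compensation_result <- function(strategy, feasible, adjusted_value,
                                    achieved_E_Fstar, scenario,
                                    infeasibility_reason = NA_character_) {
  structure(list(strategy = strategy, feasible = feasible,
                 adjusted_value = adjusted_value,
                 achieved_E_Fstar = achieved_E_Fstar,
                 baseline_E_Fstar = scenario$baseline_E_Fstar,
                 q = scenario$q,
                 infeasibility_reason = infeasibility_reason),
            class = "compensation_result")
}

#' @export
print.compensation_result <- function(x, ...) {
  cat(sprintf("Compensation by %s (q = %g): %s\n", x$strategy, x$q,
              if (x$feasible) "feasible" else
                sprintf("infeasible [%s]", x$infeasibility_reason)))
  if (x$feasible) {
    if (x$strategy == "allocation") {
      cat(sprintf("  dual allocations alpha_1 = %.6f, alpha_2 = %.6f\n",
                  x$adjusted_value[1], x$adjusted_value[2]))
    } else {
      cat(sprintf("  adjusted %s = %.6g\n",
                  if (x$strategy == "retention") "w'" else "h'",
                  x$adjusted_value))
    }
    cat(sprintf("  restores E(F*) = %.6g (baseline %.6g)\n",
                x$achieved_E_Fstar, x$baseline_E_Fstar))
  }
  invisible(x)
}

#' Compensation by re-allocating resources between the sexes
#'
#' Re-allocation can restore the baseline `E(F*)` under `q * R` exactly when
#' the baseline does not exceed the new maximum over all allocations,
#' `E(F*) <= max E(F*')`. When feasible there are two such allocations — the
#' dual pair bracketing the post-decline optimum — and both are returned,
#' labelled by the side of the new `alpha_hat` each lies on.
#'
#' @param scenario a [decline_scenario()].
#' @return A `"compensation_result"` with strategy `"allocation"`;
#'   `adjusted_value` is the named pair `c(alpha_1, alpha_2)` when feasible.
#'   Infeasibility is a result (reason `"exceeds_new_maximum"`), never an
#'   error.
#' @export
compensable_by_allocation <- function(scenario) {
  stopifnot(inherits(scenario, "decline_scenario"))
  p <- scenario$params
  opt <- optimal_allocation(scenario$q * p$R, p$r_f, p$r_m, scenario$disp)
  if (scenario$baseline_E_Fstar > opt$max_E_Fstar * (1 + 1e-12)) {
    return(new_compensation_result("allocation", FALSE, NA_real_, NA_real_,
                                   scenario, "exceeds_new_maximum"))
  }
  duals <- dual_allocations(scenario$baseline_E_Fstar,
                            scenario$q * p$R, p$r_f, p$r_m, scenario$disp)
  achieved <- expected_fertilized(
    reproduction_params(scenario$q * p$R, p$r_f, p$r_m, duals$alpha_1),
    scenario$disp)$E_Fstar
  new_compensation_result(
    "allocation", TRUE,
    c(alpha_1 = duals$alpha_1, alpha_2 = duals$alpha_2),
    achieved, scenario)
}

#' Compensation by raising pollen retention
#'
#' To keep `E(F*)` at its baseline despite the fewer ovules `q F`, the
#' expected proportion must rise to `E(P') = E(P) / q`. Solving
#' `1 - (1 - 1/h)^(w' q M) = E(P)/q` for the retention gives
#' \deqn{w' = \frac{\ln(1 - E(P)/q)}{q M \ln(1 - 1/h)}}
#' Feasible iff the decline is mild enough that `q > E(P)` (otherwise the
#' required proportion exceeds 1) and the solved retention fits under the
#' ceiling `w' <= 1`. The achieved expectation is re-verified by forward
#' evaluation at `(q R, w')`.
#'
#' @param scenario a [decline_scenario()].
#' @return A `"compensation_result"` with strategy `"retention"`; reason
#'   codes `"decline_too_severe"` (q <= E(P)) or `"retention_ceiling"`
#'   (w' > 1).
#' @export
compensate_retention <- function(scenario) {
  stopifnot(inherits(scenario, "decline_scenario"))
  p <- scenario$params; d <- scenario$disp; q <- scenario$q
  E_P <- scenario$baseline_E_P
  if (q <= E_P) {
    return(new_compensation_result("retention", FALSE, NA_real_, NA_real_,
                                   scenario, "decline_too_severe"))
  }
  M <- gamete_counts(p)$M
  w_prime <- log(1 - E_P / q) / (q * M * log1p(-1 / d$h))
  # round-off guard: at q = 1 the solution is exactly w' = w
  if (w_prime <= 1 + 1e-12) w_prime <- min(w_prime, 1)
  if (w_prime > 1) {
    return(new_compensation_result("retention", FALSE, w_prime, NA_real_,
                                   scenario, "retention_ceiling"))
  }
  achieved <- expected_fertilized(
    reproduction_params(q * p$R, p$r_f, p$r_m, p$alpha),
    dispersal_params(d$h, w_prime))$E_Fstar
  new_compensation_result("retention", TRUE, w_prime, achieved, scenario)
}

#' Compensation by shrinking the pollen dispersal range
#'
#' The alternative route to the required proportion `E(P') = E(P)/q` is a
#' smaller range `h'` over which the `w q M` retained pollen concentrate:
#' \deqn{h' = \frac{1}{1 - (1 - E(P)/q)^{1/(w q M)}}}
#' Feasible iff `q > E(P)` and the shrunken range still holds every ovule,
#' `h' >= q F`. The achieved expectation is re-verified by forward
#' evaluation at `(q R, h')`. `h'` is returned real-valued; set
#' `round_up = TRUE` to round up to the next integer for hand-off to the
#' simulator.
#'
#' @param scenario a [decline_scenario()].
#' @param round_up round `h'` up to an integer (default `FALSE`).
#' @return A `"compensation_result"` with strategy `"range"`; reason codes
#'   `"decline_too_severe"` or `"range_below_ovule_count"` (h' < q F).
#' @export
compensate_range <- function(scenario, round_up = FALSE) {
  stopifnot(inherits(scenario, "decline_scenario"))
  p <- scenario$params; d <- scenario$disp; q <- scenario$q
  E_P <- scenario$baseline_E_P
  if (q <= E_P) {
    return(new_compensation_result("range", FALSE, NA_real_, NA_real_,
                                   scenario, "decline_too_severe"))
  }
  g <- gamete_counts(p)
  h_prime <- 1 / (1 - (1 - E_P / q)^(1 / (d$w * q * g$M)))
  if (h_prime < q * g$F * (1 - 1e-12)) {
    return(new_compensation_result("range", FALSE, h_prime, NA_real_,
                                   scenario, "range_below_ovule_count"))
  }
  if (round_up) h_prime <- ceiling(h_prime)
  achieved <- expected_fertilized(
    reproduction_params(q * p$R, p$r_f, p$r_m, p$alpha),
    dispersal_params(h_prime, d$w))$E_Fstar
  new_compensation_result("range", TRUE, h_prime, achieved, scenario)
}

#' Feasibility map of the pollen-density strategies over a (w, h) grid
#'
#' Classifies every combination of baseline retention and range size by
#' whether a decline to `q * R` can be compensated by raising retention
#' and/or shrinking the range. Both strategies share the necessary condition
#' `q > E(P)`; milder declines (larger `q`) can only enlarge the feasible
#' region.
#'
#' @param params baseline [reproduction_params()].
#' @param w_grid,h_grid numeric vectors of baseline retentions and range
#'   sizes; every `(w, h)` cell must satisfy `h >= F`.
#' @param q remaining resource fraction, in (0, 1].
#' @return A data frame with one row per grid cell: `w`, `h`, `E_P`,
#'   `retention_feasible`, `w_prime`, `range_feasible`, `h_prime`.
#' @export
compensation_map <- function(params, w_grid, h_grid, q) {
  stopifnot(inherits(params, "reproduction_params"))
  cells <- expand.grid(w = w_grid, h = h_grid, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    d <- dispersal_params(cells$h[i], cells$w[i])
    sc <- decline_scenario(params, d, q)
    ret <- compensate_retention(sc)
    rng <- compensate_range(sc)
    data.frame(w = cells$w[i], h = cells$h[i], E_P = sc$baseline_E_P,
               retention_feasible = ret$feasible,
               w_prime = if (is.na(ret$adjusted_value[1])) NA_real_
                         else unname(ret$adjusted_value[1]),
               range_feasible = rng$feasible,
               h_prime = if (is.na(rng$adjusted_value[1])) NA_real_
                         else unname(rng$adjusted_value[1]))
  })
  do.call(rbind, rows)
}
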