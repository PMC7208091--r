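base_params <- function() reproduction_params(5000, 10, 1, 0.5)

test_that("resource decline scales gamete counts and depresses E(F*)", {
  sc1 <- decline_scenario(base_params(), dispersal_params(1000, 1), 1)
  out1 <- apply_decline(sc1)
  expect_equal(out1$E_Fstar, sc1$baseline_E_Fstar)

  sc <- decline_scenario(base_params(), dispersal_params(1000, 1), 0.5)
  out <- apply_decline(sc)
  expect_equal(out$F, 125)
  expect_equal(out$M, 1250)

  # strictly decreasing in decline severity
  efs <- vapply(c(1, 0.8, 0.6, 0.4, 0.2), function(q) {
    apply_decline(decline_scenario(base_params(),
                                   dispersal_params(1000, 1), q))$E_Fstar
  }, numeric(1))
  expect_true(all(diff(efs) < 0))

  expect_error(decline_scenario(base_params(), dispersal_params(1000, 1), 0),
               "q")
})

test_that("re-allocation compensates iff the baseline is under the new maximum", {
  d <- dispersal_params(10000, 1)

  # a population already at its optimum has no headroom after any decline
  opt <- optimal_allocation(5000, 10, 1, d)
  sc_opt <- decline_scenario(reproduction_params(5000, 10, 1, opt$alpha_hat),
                             d, 0.9)
  res_opt <- compensable_by_allocation(sc_opt)
  expect_false(res_opt$feasible)
  expect_equal(res_opt$infeasibility_reason, "exceeds_new_maximum")

  # a suboptimal baseline with a mild decline leaves two compensating
  # allocations bracketing the post-decline optimum
  sc <- decline_scenario(reproduction_params(5000, 10, 1, 0.15), d, 0.8)
  res <- compensable_by_allocation(sc)
  expect_true(res$feasible)
  a <- res$adjusted_value
  expect_lt(a[["alpha_1"]], a[["alpha_2"]])
  new_opt <- optimal_allocation(0.8 * 5000, 10, 1, d)
  expect_lte(a[["alpha_1"]], new_opt$alpha_hat)
  expect_gte(a[["alpha_2"]], new_opt$alpha_hat)
  for (ai in a) {
    got <- expected_fertilized(reproduction_params(0.8 * 5000, 10, 1, ai),
                               d)$E_Fstar
    expect_equal(got, sc$baseline_E_Fstar,
                 tolerance = 1e-8)
  }

  # verdict agrees with a brute-force grid maximum under qR
  for (q in c(0.95, 0.8, 0.5)) {
    sci <- decline_scenario(reproduction_params(5000, 10, 1, 0.35), d, q)
    grid_max <- max(ef_of_alpha(seq(0.001, 0.999, length.out = 4000),
                                q * 5000, 10, 1, d))
    expect_equal(compensable_by_allocation(sci)$feasible,
                 sci$baseline_E_Fstar <= grid_max)
  }
})

test_that("retention adjustment inverts the occupancy formula exactly", {
  params <- base_params()
  sc <- decline_scenario(params, dispersal_params(1000, 0.4), 0.9)
  expect_equal(sc$baseline_E_Fstar, 158.1, tolerance = 0.1 / 158.1)

  res <- compensate_retention(sc)
  expect_true(res$feasible)
  expect_equal(unname(res$adjusted_value), 0.5386, tolerance = 1e-3)
  expect_equal(res$achieved_E_Fstar, sc$baseline_E_Fstar, tolerance = 1e-8)

  # bisection oracle on w' reproduces the closed-form inversion
  target_EP <- sc$baseline_E_P / 0.9
  M <- gamete_counts(params)$M
  f <- function(w) expected_proportion(0.9 * M, dispersal_params(1000, w)) -
    target_EP
  w_bis <- uniroot(f, c(1e-6, 1), tol = 1e-12)$root
  expect_equal(unname(res$adjusted_value), w_bis, tolerance = 1e-9)

  # severe decline: q below E(P) rules retention out
  sc_sev <- decline_scenario(params, dispersal_params(1000, 0.4), 0.5)
  res_sev <- compensate_retention(sc_sev)
  expect_false(res_sev$feasible)
  expect_equal(res_sev$infeasibility_reason, "decline_too_severe")

  # retention already (near) full: no headroom above w' = 1
  sc_full <- decline_scenario(base_params(), dispersal_params(1000, 1), 0.95)
  res_full <- compensate_retention(sc_full)
  expect_false(res_full$feasible)
  expect_equal(res_full$infeasibility_reason, "retention_ceiling")
})

test_that("range shrinkage inverts the occupancy formula exactly", {
  params <- base_params()
  sc <- decline_scenario(params, dispersal_params(1000, 0.4), 0.9)
  res <- compensate_range(sc)
  expect_true(res$feasible)
  expect_equal(unname(res$adjusted_value), 742.8, tolerance = 0.5 / 742.8)
  expect_gte(unname(res$adjusted_value), 0.9 * 250)
  expect_equal(res$achieved_E_Fstar, sc$baseline_E_Fstar, tolerance = 1e-8)

  # bisection oracle on h'
  target_EP <- sc$baseline_E_P / 0.9
  M <- gamete_counts(params)$M
  f <- function(h) expected_proportion(0.9 * M, dispersal_params(h, 0.4)) -
    target_EP
  h_bis <- uniroot(f, c(2, 1000), tol = 1e-10)$root
  expect_equal(unname(res$adjusted_value), h_bis, tolerance = 1e-8)

  expect_false(compensate_range(
    decline_scenario(params, dispersal_params(1000, 0.4), 0.5))$feasible)

  # shrinking h along a grid eventually pushes h' below the ovule count
  reasons <- vapply(c(2000, 1000, 600, 450, 400), function(h) {
    r <- compensate_range(decline_scenario(params,
                                           dispersal_params(h, 0.4), 0.9))
    if (r$feasible) "feasible" else r$infeasibility_reason
  }, character(1))
  expect_equal(reasons[1], "feasible")
  expect_true("range_below_ovule_count" %in% reasons)

  # integer hand-off mode still compensates to within rounding
  res_int <- compensate_range(sc, round_up = TRUE)
  expect_equal(unname(res_int$adjusted_value) %% 1, 0)
  expect_equal(res_int$achieved_E_Fstar, sc$baseline_E_Fstar,
               tolerance = 1e-3)
})

test_that("every feasible compensation restores the baseline exactly", {
  set.seed(41)
  n_checked <- 0
  for (i in 1:200) {
    ps <- random_param_set()
    q <- runif(1, 0.3, 1)
    sc <- decline_scenario(ps$params, ps$disp, q)
    for (strat in list(compensate_retention, compensate_range,
                       compensable_by_allocation)) {
      res <- strat(sc)
      if (res$feasible) {
        expect_equal(res$achieved_E_Fstar, sc$baseline_E_Fstar,
                     tolerance = 1e-8)
        n_checked <- n_checked + 1
      }
    }
    # both density strategies share the necessary condition q > E(P)
    if (q <= sc$baseline_E_P) {
      expect_false(compensate_retention(sc)$feasible)
      expect_false(compensate_range(sc)$feasible)
    }
    # feasible density adjustments always raise the pollen density
    ret <- compensate_retention(sc)
    if (ret$feasible) expect_gte(unname(ret$adjusted_value), ps$disp$w)
    rng <- compensate_range(sc)
    if (rng$feasible) expect_lte(unname(rng$adjusted_value), ps$disp$h)
  }
  expect_gt(n_checked, 50)  # the scenario generator must exercise feasibility
})

test_that("decreasing q never turns an infeasible strategy feasible", {
  set.seed(43)
  for (i in 1:30) {
    ps <- random_param_set()
    qs <- sort(runif(2, 0.3, 1))  # qs[1] < qs[2]
    for (strat in list(compensate_retention, compensate_range)) {
      hi <- strat(decline_scenario(ps$params, ps$disp, qs[2]))
      lo <- strat(decline_scenario(ps$params, ps$disp, qs[1]))
      if (lo$feasible) expect_true(hi$feasible)
    }
  }
})

test_that("the (w, h) compensation map has the expected structure", {
  params <- base_params()
  w_grid <- seq(0.1, 1, by = 0.1)
  h_grid <- c(300, 500, 1000, 2000, 4000)

  # no decline: nothing to compensate, every cell trivially feasible
  map1 <- compensation_map(params, w_grid, h_grid, 1)
  expect_true(all(map1$retention_feasible))
  expect_true(all(map1$range_feasible))
  expect_equal(map1$w_prime, map1$w, tolerance = 1e-9)

  map9 <- compensation_map(params, w_grid, h_grid, 0.9)
  map4 <- compensation_map(params, w_grid, h_grid, 0.4)
  expect_gt(sum(map9$retention_feasible) + sum(map9$range_feasible),
            sum(map4$retention_feasible) + sum(map4$range_feasible))
  # shared necessary condition q > E(P), cell by cell
  blocked <- map4$E_P >= 0.4
  expect_true(all(!map4$retention_feasible[blocked]))
  expect_true(all(!map4$range_feasible[blocked]))
})
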