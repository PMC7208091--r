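# Implicit optimality function g(alpha) = b^(1-alpha) (alpha ln b - 1) + 1.
# Its unique root on (0,1) is the allocation maximizing E(F*); g(0+) = 1 - b
# > 0 and g(1-) = ln b < 0, so a bracketed root always exists.
implicit_optimality <- function(alpha, b) {
  exp((1 - alpha) * log(b)) * (alpha * log(b) - 1) + 1
}

#' Optimal sexual allocation
#'
#' Finds the unique allocation `alpha_hat` maximizing the expected number of
#' fertilized ovules `E(F*) = (alpha R / r_f) (1 - b^(1-alpha))`, as the root
#' of the implicit equation
#' \deqn{b^{1-\hat\alpha}(\hat\alpha \ln b - 1) + 1 = 0}
#' with `b = (1 - 1/h)^(w R / r_m)`. No closed form exists, so the root is
#' located by bracketed root finding on (0, 1) and always cross-checked
#' against direct bounded maximization of `E(F*)`; the two must agree to
#' 1e-8. The optimum allocates more than half the budget to ovules
#' (`alpha_hat > 0.5`) for every valid parameter set.
#'
#' The ovule-capacity assumption `F <= h` restricts the admissible range to
#' `alpha <= h r_f / R`; when the unconstrained root exceeds that bound the
#' boundary allocation is returned with `constrained = TRUE`.
#'
#' @param R,r_f,r_m resource budget and per-gamete investments (see
#'   [reproduction_params()]); `alpha` is what is being solved for.
#' @param disp a [dispersal_params()] object with `h > 1`.
#' @return An object of class `"optimum_result"`: list with `alpha_hat`,
#'   `max_E_Fstar`, `residual` (implicit-equation value at the root), `b`,
#'   and `constrained`.
#' @examples
#' optimal_allocation(R = 5000, r_f = 10, r_m = 1,
#'                    disp = dispersal_params(h = 1000, w = 1))
#' @export
optimal_allocation <- function(R, r_f, r_m, disp) {
  stopifnot(inherits(disp, "dispersal_params"))
  check_scalar(R, "R", lower = 0, strict = TRUE)
  check_scalar(r_f, "r_f", lower = 0, strict = TRUE)
  check_scalar(r_m, "r_m", lower = 0, strict = TRUE)
  b <- compound_b(reproduction_params(R, r_f, r_m, 0.5), disp)

  eps <- 1e-9
  lo <- eps; hi <- 1 - eps
  glo <- implicit_optimality(lo, b); ghi <- implicit_optimality(hi, b)
  if (glo * ghi > 0) {
    stop(sprintf(paste0("no sign change of the optimality equation on ",
                        "(%g, %g): g(lo) = %g, g(hi) = %g, b = %g"),
                 lo, hi, glo, ghi, b), call. = FALSE)
  }
  root <- stats::uniroot(implicit_optimality, c(lo, hi), b = b,
                         tol = 1e-12)$root

  ef <- function(a) (a * R / r_f) * -expm1((1 - a) * log(b))
  alpha_cap <- min(1 - eps, disp$h * r_f / R)  # F <= h bound
  constrained <- root > alpha_cap
  if (constrained) {
    alpha_hat <- alpha_cap
  } else {
    # cross-validation by direct bounded maximization of E(F*)
    opt <- stats::optimize(ef, c(eps, alpha_cap), maximum = TRUE,
                           tol = 1e-10)
    if (abs(opt$maximum - root) > 1e-8) {
      stop(sprintf(paste0("implicit-equation root (%0.12g) and direct ",
                          "maximizer (%0.12g) disagree beyond 1e-8"),
                   root, opt$maximum), call. = FALSE)
    }
    alpha_hat <- root
  }
  structure(list(alpha_hat = alpha_hat,
                 max_E_Fstar = ef(alpha_hat),
                 residual = implicit_optimality(alpha_hat, b),
                 b = b, constrained = constrained),
            class = "optimum_result")
}

#' @export
print.optimum_result <- function(x, ...) {
  cat(sprintf("Optimal sexual allocation: alpha_hat = %.6f%s\n",
              x$alpha_hat,
              if (x$constrained) " (capacity bound h >= F binding)" else ""))
  cat(sprintf("  max E(F*) = %.4f fertilized ovules\n", x$max_E_Fstar))
  cat(sprintf("  b = %.6g, residual of implicit equation = %.3g\n",
              x$b, x$residual))
  invisible(x)
}

#' Maximum expected number of fertilized ovules
#'
#' Convenience wrapper: `E(F*)` evaluated at the optimal allocation from
#' [optimal_allocation()].
#'
#' @inheritParams optimal_allocation
#' @return The maximum of `E(F*)` over the allocation.
#' @export
max_expected_fertilized <- function(R, r_f, r_m, disp) {
  optimal_allocation(R, r_f, r_m, disp)$max_E_Fstar
}

#' Dual allocations achieving a common fertilization level
#'
#' `E(F*)` is strictly concave in the allocation with a single interior
#' maximum, so every achievable level below the maximum is attained by
#' exactly two allocations, one on either side of `alpha_hat`. They are
#' located by bisection on each flank and verified by forward evaluation.
#' `target = max E(F*)` returns the degenerate pair
#' `alpha_1 = alpha_2 = alpha_hat`.
#'
#' @param target the common `E(F*)` level, in (0, max].
#' @inheritParams optimal_allocation
#' @return An object of class `"dual_pair"`: list with `alpha_1`, `alpha_2`,
#'   `target`, `alpha_hat`.
#' @examples
#' dual_allocations(150, R = 5000, r_f = 10, r_m = 1,
#'                  disp = dispersal_params(h = 1000, w = 1))
#' @export
dual_allocations <- function(target, R, r_f, r_m, disp) {
  check_scalar(target, "target", lower = 0, strict = TRUE)
  opt <- optimal_allocation(R, r_f, r_m, disp)
  if (target > opt$max_E_Fstar * (1 + 1e-12)) {
    stop(sprintf("target E(F*) = %g exceeds the maximum %g attainable here",
                 target, opt$max_E_Fstar), call. = FALSE)
  }
  ef <- function(a) (a * R / r_f) * -expm1((1 - a) * log(opt$b))
  g <- function(a) ef(a) - target
  eps <- 1e-12
  if (target >= opt$max_E_Fstar * (1 - 1e-12)) {
    a1 <- a2 <- opt$alpha_hat
  } else {
    bisect <- function(lo, hi) {  # monotone flank; 200-iteration cap
      flo <- g(lo)
      for (i in seq_len(200)) {
        mid <- (lo + hi) / 2
        if (sign(g(mid)) == sign(flo)) lo <- mid else hi <- mid
        if (hi - lo < 1e-14) break
      }
      (lo + hi) / 2
    }
    a1 <- bisect(eps, opt$alpha_hat)
    a2 <- bisect(opt$alpha_hat, 1 - eps)
  }
  structure(list(alpha_1 = a1, alpha_2 = a2, target = target,
                 alpha_hat = opt$alpha_hat),
            class = "dual_pair")
}

#' @export
print.dual_pair <- function(x, ...) {
  cat(sprintf(
    "Dual allocations for E(F*) = %g: alpha_1 = %.6f, alpha_2 = %.6f\n",
    x$target, x$alpha_1, x$alpha_2))
  cat(sprintf("  (optimum alpha_hat = %.6f lies between)\n", x$alpha_hat))
  invisible(x)
}

#' Sensitivity of the optimal allocation to a model parameter
#'
#' Recomputes `alpha_hat` over a grid of one parameter, holding the others
#' fixed. The optimum shifts further toward ovules when resources grow
#' (`R` up), pollen gets cheaper (`r_m` down), the range shrinks (`h` down),
#' or retention rises (`w` up); the returned table makes those monotone
#' trends directly checkable.
#'
#' @inheritParams optimal_allocation
#' @param parameter_name one of `"R"`, `"r_m"`, `"w"`, `"h"`.
#' @param grid numeric vector of values for that parameter; each must keep
#'   the parameter set valid.
#' @return A data frame with columns `param`, `value`, `alpha_hat`,
#'   `max_E_Fstar`, `residual`.
#' @export
optimum_sensitivity <- function(R, r_f, r_m, disp, parameter_name, grid) {
  parameter_name <- match.arg(parameter_name, c("R", "r_m", "w", "h"))
  rows <- lapply(grid, function(v) {
    Ri <- R; r_mi <- r_m; di <- disp
    switch(parameter_name,
           R = { Ri <- v }, r_m = { r_mi <- v },
           w = { di <- dispersal_params(disp$h, v) },
           h = { di <- dispersal_params(v, disp$w) })
    o <- optimal_allocation(Ri, r_f, r_mi, di)
    data.frame(param = parameter_name, value = v, alpha_hat = o$alpha_hat,
               max_E_Fstar = o$max_E_Fstar, residual = o$residual)
  })
  do.call(rbind, rows)
}
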