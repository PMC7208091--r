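#' Ovule and pollen numbers under the resource trade-off
#'
#' With a budget `R` split by the sexual allocation `alpha`, the population
#' produces `F = alpha * R / r_f` ovules and `M = (1 - alpha) * R / r_m`
#' pollen, so that `r_f * F + r_m * M = R` exactly. Counts are real-valued
#' here; integerization happens only in the simulator.
#'
#' @param params a [reproduction_params()] object.
#' @return An object of class `"gamete_counts"`: list with fields `F` (ovules)
#'   and `M` (pollen).
#' @examples
#' gamete_counts(reproduction_params(5000, 10, 1, 0.5))  # F = 250, M = 2500
#' @export
gamete_counts <- function(params) {
  stopifnot(inherits(params, "reproduction_params"))
  structure(list(F = params$alpha * params$R / params$r_f,
                 M = (1 - params$alpha) * params$R / params$r_m),
            class = "gamete_counts")
}

#' @export
print.gamete_counts <- function(x, ...) {
  cat(sprintf("Gamete counts: F = %g ovules, M = %g pollen\n", x$F, x$M))
  invisible(x)
}

#' Sexual allocation from the two pollen-ovule ratios
#'
#' The allocation to ovules is determined entirely by the numeric
#' pollen-ovule ratio `M/F` and the investment ratio `r_m/r_f`:
#' `alpha = 1 / (1 + (r_m/r_f) * (M/F))`. Feeding the result back through
#' [gamete_counts()] reproduces the ratio `M/F`.
#'
#' @param pollen_ovule_ratio the count ratio `M/F`, > 0.
#' @param cost_ratio the investment ratio `r_m/r_f`, > 0.
#' @return The allocation in (0, 1).
#' @examples
#' alpha_from_ratios(10, 0.1)  # 0.5: the two ratios cancel
#' @export
alpha_from_ratios <- function(pollen_ovule_ratio, cost_ratio) {
  check_scalar(pollen_ovule_ratio, "pollen_ovule_ratio", lower = 0, strict = TRUE)
  check_scalar(cost_ratio, "cost_ratio", lower = 0, strict = TRUE)
  1 / (1 + cost_ratio * pollen_ovule_ratio)
}

#' Mean pollen density within the dispersal range
#'
#' Under uniform dispersal, the mean number of retained pollen settling in
#' each of the `h` spatial units — and hence on any ovule's pollen-catching
#' surface — is `d = w * M / h`.
#'
#' @param M pollen count, >= 0.
#' @param disp a [dispersal_params()] object.
#' @return The density `d` (pollen per spatial unit).
#' @export
pollen_density <- function(M, disp) {
  stopifnot(inherits(disp, "dispersal_params"))
  check_scalar(M, "M", lower = 0, strict = FALSE)
  disp$w * M / disp$h
}

#' Compound emptiness probability b
#'
#' `b = (1 - 1/h)^(w R / r_m)` is the probability that a given spatial unit
#' receives no pollen if the whole budget went to pollen production (alpha =
#' 0) with retention `w`. It collapses the expected proportion of fertilized
#' ovules to `E(P) = 1 - b^(1 - alpha)` and is the variable in which the
#' optimal allocation is expressed.
#'
#' Computed as `exp((w R / r_m) * log1p(-1/h))` for numerical stability at
#' large `h`.
#'
#' @param params a [reproduction_params()] object (only `R` and `r_m` are
#'   used; `b` does not depend on `alpha`).
#' @param disp a [dispersal_params()] object with `h > 1`.
#' @return `b` in (0, 1).
#' @examples
#' compound_b(reproduction_params(5000, 10, 1, 0.5), dispersal_params(1000))
#' @export
compound_b <- function(params, disp) {
  stopifnot(inherits(params, "reproduction_params"),
            inherits(disp, "dispersal_params"))
  if (disp$h <= 1) {
    stop("`h` must exceed 1: at h = 1 the range is a single unit and b ",
         "degenerates to 0", call. = FALSE)
  }
  exp(disp$w * params$R / params$r_m * log1p(-1 / disp$h))
}

#' Expected proportion of fertilized ovules
#'
#' An ovule is fertilized when at least one of the `w*M` retained pollen
#' lands on its spatial unit, so
#' `E(P) = 1 - (1 - 1/h)^(w M)` — one minus the probability that every
#' retained pollen lands in the other `h - 1` units. Increasing in `M` and
#' `w`, decreasing in `h`. At `h = 1` the limit convention `E(P) = 1` for
#' `w M > 0` applies (all pollen land in the single unit).
#'
#' @param M pollen count, >= 0.
#' @param disp a [dispersal_params()] object.
#' @return `E(P)` in \[0, 1\].
#' @examples
#' expected_proportion(1000, dispersal_params(1000))  # 0.6323
#' @export
expected_proportion <- function(M, disp) {
  stopifnot(inherits(disp, "dispersal_params"))
  check_scalar(M, "M", lower = 0, strict = FALSE)
  if (M == 0) return(0)
  if (disp$h == 1) return(1)
  -expm1(disp$w * M * log1p(-1 / disp$h))
}

#' Variance of the proportion of fertilized ovules
#'
#' The occupancy variance of the fertilized proportion `P` among `F` ovules:
#' \deqn{V(P) = (1 - 1/F)(1 - 2/h)^{wM}
#'       - (1 - 1/h)^{wM}\left[(1 - 1/h)^{wM} - 1/F\right]}
#' For a single ovule (`F = 1`) this reduces to the Bernoulli variance
#' `x (1 - x)` with `x = (1 - 1/h)^(w M)`.
#'
#' @param F ovule count, >= 1 (real-valued allowed).
#' @param M pollen count, >= 0.
#' @param disp a [dispersal_params()] object with `h > 2`.
#' @return `V(P)` in \[0, 0.25\].
#' @export
variance_proportion <- function(F, M, disp) {
  stopifnot(inherits(disp, "dispersal_params"))
  check_scalar(F, "F", lower = 1, strict = FALSE)
  check_scalar(M, "M", lower = 0, strict = FALSE)
  if (disp$h <= 2) {
    stop("`h` must exceed 2 for the variance formula (the two-unit-empty ",
         "probability (1 - 2/h)^(wM) degenerates)", call. = FALSE)
  }
  if (M == 0) return(0)
  x1 <- exp(disp$w * M * log1p(-1 / disp$h))  # P(unit empty)
  x2 <- exp(disp$w * M * log1p(-2 / disp$h))  # P(two given units empty)
  v <- (1 - 1 / F) * x2 - x1 * (x1 - 1 / F)
  max(v, 0)  # guard tiny negative round-off
}

#' Closed-form fertilization statistics
#'
#' Evaluates the full model at one parameter set: gamete counts, pollen
#' density, the compound variable `b`, the expected proportion
#' `E(P) = 1 - b^(1 - alpha)`, its variance, the expected number of
#' fertilized ovules `E(F*) = F * E(P)`, and the standard-deviation band
#' `F * sqrt(V(P))` used to frame `E(F*)`.
#'
#' The model assumes each spatial unit holds at most one ovule and all
#' ovules lie within the range, hence `F <= h`; violating parameter sets are
#' rejected.
#'
#' @param params a [reproduction_params()] object.
#' @param disp a [dispersal_params()] object with `h > 2`.
#' @return An object of class `"fertilization_stats"`: list with fields
#'   `F`, `M`, `d`, `b`, `E_P`, `V_P`, `E_Fstar`, `SD_Fstar`.
#' @examples
#' expected_fertilized(reproduction_params(5000, 10, 1, 0.5),
#'                     dispersal_params(1000))
#' @export
expected_fertilized <- function(params, disp) {
  stopifnot(inherits(params, "reproduction_params"),
            inherits(disp, "dispersal_params"))
  g <- gamete_counts(params)
  if (g$F > disp$h) {
    stop(sprintf(paste0("model assumption h >= F violated: F = %g ovules ",
                        "but the dispersal range holds only h = %g units"),
                 g$F, disp$h), call. = FALSE)
  }
  b <- compound_b(params, disp)
  E_P <- -expm1((1 - params$alpha) * log(b))  # 1 - b^(1 - alpha)
  V_P <- if (g$F >= 1) variance_proportion(g$F, g$M, disp) else NA_real_
  structure(list(F = g$F, M = g$M,
                 d = pollen_density(g$M, disp),
                 b = b, E_P = E_P, V_P = V_P,
                 E_Fstar = g$F * E_P,
                 SD_Fstar = if (is.na(V_P)) NA_real_ else g$F * sqrt(V_P)),
            class = "fertilization_stats")
}

#' @export
print.fertilization_stats <- function(x, digits = 4, ...) {
  cat("Fertilization statistics\n")
  cat(sprintf("  F = %g ovules, M = %g pollen, density d = %s\n",
              x$F, x$M, format(x$d, digits = digits)))
  cat(sprintf("  b = %s, E(P) = %s, V(P) = %s\n",
              format(x$b, digits = digits), format(x$E_P, digits = digits),
              format(x$V_P, digits = digits)))
  cat(sprintf("  E(F*) = %s fertilized ovules (SD band %s)\n",
              format(x$E_Fstar, digits = digits),
              format(x$SD_Fstar, digits = digits)))
  invisible(x)
}
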