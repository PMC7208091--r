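#' Reproduction parameters
#'
#' Bundle the gamete-production side of the model: the total resource budget
#' `R` available for gamete production (abstract energy units), the per-gamete
#' investments `r_f` (one ovule) and `r_m` (one pollen), and the sexual
#' allocation `alpha`, the proportion of `R` invested in ovules. The remainder
#' `(1 - alpha) * R` is invested in pollen.
#'
#' @param R total gametic production resources, > 0.
#' @param r_f resource investment per ovule, > 0, same units as `R`.
#' @param r_m resource investment per pollen, > 0, same units as `R`.
#' @param alpha proportion of `R` allocated to ovules, strictly in (0, 1).
#'
#' @return An object of class `"reproduction_params"`: a named list with
#'   fields `R`, `r_f`, `r_m`, `alpha`.
#' @examples
#' reproduction_params(R = 5000, r_f = 10, r_m = 1, alpha = 0.5)
#' @export
reproduction_params <- function(R, r_f, r_m, alpha) {
  check_scalar(R, "R", lower = 0, strict = TRUE)
  check_scalar(r_f, "r_f", lower = 0, strict = TRUE)
  check_scalar(r_m, "r_m", lower = 0, strict = TRUE)
  check_scalar(alpha, "alpha", lower = 0, upper = 1, strict = TRUE)
  structure(list(R = R, r_f = r_f, r_m = r_m, alpha = alpha),
            class = "reproduction_params")
}

#' Pollen dispersal parameters
#'
#' The dispersal range is measured in `h` spatial units, each the size of one
#' ovule's pollen-catching surface (so a unit covers the fraction `1/h` of the
#' range). A proportion `w` of the produced pollen is retained within the
#' range; the rest is lost to fertilization. `w = 1` (all pollen retained) is
#' admitted; `w = 0` is rejected as it leaves nothing to model.
#'
#' `h` may be real-valued in the analytic functions; the Monte Carlo simulator
#' requires an integer `h`.
#'
#' @param h size of the pollen dispersal range in pollen-catching-surface
#'   units, >= 1.
#' @param w pollen retention, the proportion of produced pollen remaining in
#'   the range, in (0, 1].
#'
#' @return An object of class `"dispersal_params"` with fields `h`, `w`.
#' @examples
#' dispersal_params(h = 1000, w = 1)
#' @export
dispersal_params <- function(h, w = 1) {
  check_scalar(h, "h", lower = 1, strict = FALSE)
  check_scalar(w, "w", lower = 0, upper = 1, strict = c(TRUE, FALSE))
  structure(list(h = h, w = w), class = "dispersal_params")
}

#' @export
print.reproduction_params <- function(x, ...) {
  cat("Reproduction parameters\n")
  cat(sprintf("  R  = %g (resource budget)\n", x$R))
  cat(sprintf("  r_f= %g per ovule, r_m = %g per pollen\n", x$r_f, x$r_m))
  cat(sprintf("  alpha = %g (proportion of R to ovules)\n", x$alpha))
  invisible(x)
}

#' @export
print.dispersal_params <- function(x, ...) {
  cat(sprintf("Dispersal range: h = %g units, retention w = %g\n", x$h, x$w))
  invisible(x)
}

# scalar validator shared by every constructor; strict may be length 2
# (lower bound strictness, upper bound strictness)
check_scalar <- function(x, name, lower = -Inf, upper = Inf, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  strict <- rep_len(strict, 2L)
  lo_ok <- if (strict[1L]) x > lower else x >= lower
  hi_ok <- if (strict[2L]) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    lob <- if (strict[1L]) "(" else "["
    hib <- if (strict[2L]) ")" else "]"
    stop(sprintf("`%s` must lie in %s%g, %g%s, got %g",
                 name, lob, lower, upper, hib, x), call. = FALSE)
  }
  invisible(TRUE)
}
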