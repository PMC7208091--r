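#' Evaluate the model over a grid of allocations
#'
#' Tabulates every closed-form quantity — gamete counts, pollen density,
#' compound `b`, `E(P)`, `V(P)`, `E(F*)` and its SD band — over an `alpha`
#' grid, restricted to allocations satisfying the capacity bound `F <= h`.
#'
#' @param R,r_f,r_m resource budget and per-gamete investments.
#' @param disp a [dispersal_params()] object.
#' @param alpha numeric vector of allocations in (0, 1); defaults to a
#'   401-point grid.
#' @return A data frame with columns `alpha`, `F`, `M`, `d`, `b`, `E_P`,
#'   `V_P`, `E_Fstar`, `SD_Fstar`.
#' @export
evaluate_table <- function(R, r_f, r_m, disp,
                           alpha = seq(0.0025, 0.9975, length.out = 401)) {
  alpha <- alpha[alpha > 0 & alpha < 1 & alpha * R / r_f <= disp$h]
  rows <- lapply(alpha, function(a) {
    st <- expected_fertilized(reproduction_params(R, r_f, r_m, a), disp)
    data.frame(alpha = a, F = st$F, M = st$M, d = st$d, b = st$b,
               E_P = st$E_P, V_P = st$V_P, E_Fstar = st$E_Fstar,
               SD_Fstar = st$SD_Fstar)
  })
  do.call(rbind, rows)
}

# built-in parameter sets for the first four standard figures; the last two
# depend on choices their captions leave open, so overrides are mandatory
figure_defaults <- list(
  `1` = list(R = 5000, r_m = 1, w = 1, h = 1000),
  `2` = list(R = 5000, r_f = 10, r_m = 1, w = 1, h = 1000),
  `3` = list(R = 5000, r_f = 10, r_m = 1, w = 1, h = 1000,
             q = c(1.0, 0.8, 0.6, 0.4, 0.2)),
  `4` = list(R = 5000, r_f = 10, r_m = 1, w = 1, h = 10000,
             q = c(0.8, 0.6, 0.4)),
  `5` = NULL,
  `6` = NULL
)

#' Data tables underlying the six standard model figures
#'
#' Recomputes the curve data behind the package's six canonical
#' illustrations:
#' \describe{
#'   \item{1}{`E(P)` as a function of the pollen number `M` from 0 to
#'     `R/r_m` (R = 5000, r_m = 1, w = 1, h = 1000).}
#'   \item{2}{`E(P)`, `E(F*)` and its SD band over the allocation grid
#'     (R = 5000, r_f = 10, r_m = 1, w = 1, h = 1000).}
#'   \item{3}{The same curves for declined resources, one family per
#'     `q` in 1.0, 0.8, 0.6, 0.4, 0.2.}
#'   \item{4}{Feasibility of compensation by re-allocation over a grid of
#'     baseline allocations, per `q` in 0.8, 0.6, 0.4 (h = 10000).}
#'   \item{5}{Retention (`w'`) and range (`h'`) compensation curves at a
#'     given decline; no complete built-in parameter set exists, so
#'     `overrides` must supply R, r_f, r_m, alpha, w, h (and optionally q).}
#'   \item{6}{Feasibility map of both pollen-density strategies over a
#'     (w, h) grid; `overrides` must supply R, r_f, r_m, alpha and q.}
#' }
#'
#' @param figure_id integer 1-6.
#' @param overrides named list overriding (or, for figures 5-6, supplying)
#'   parameters; entries `alpha_grid`, `w_grid`, `h_grid` control grids.
#' @return A data frame of curve data; the shape depends on `figure_id`.
#' @examples
#' head(run_figure_table(2))
#' @export
run_figure_table <- function(figure_id, overrides = list()) {
  figure_id <- as.character(figure_id)
  if (!figure_id %in% names(figure_defaults)) {
    stop("figure_id must be 1..6", call. = FALSE)
  }
  p <- figure_defaults[[figure_id]]
  if (is.null(p) && !length(overrides)) {
    stop(sprintf(paste0("figure %s has no complete built-in parameter set; ",
                        "supply `overrides` (R, r_f, r_m, alpha, w, h, q ",
                        "as applicable)"), figure_id), call. = FALSE)
  }
  p <- utils::modifyList(if (is.null(p)) list() else p, overrides)

  switch(figure_id,
    `1` = {
      M <- if (!is.null(p$M_grid)) p$M_grid else
        seq(0, p$R / p$r_m, length.out = 501)
      d <- dispersal_params(p$h, p$w)
      data.frame(M = M,
                 E_P = vapply(M, expected_proportion, numeric(1), disp = d))
    },
    `2` = {
      evaluate_table(p$R, p$r_f, p$r_m, dispersal_params(p$h, p$w),
                     alpha = p$alpha_grid %||%
                       seq(0.0025, 0.9975, length.out = 401))
    },
    `3` = {
      do.call(rbind, lapply(p$q, function(qi) {
        tab <- evaluate_table(qi * p$R, p$r_f, p$r_m,
                              dispersal_params(p$h, p$w),
                              alpha = p$alpha_grid %||%
                                seq(0.0025, 0.9975, length.out = 401))
        cbind(q = qi, tab)
      }))
    },
    `4` = {
      agrid <- p$alpha_grid %||% seq(0.01, 0.99, by = 0.01)
      do.call(rbind, lapply(p$q, function(qi) {
        do.call(rbind, lapply(agrid, function(a) {
          sc <- decline_scenario(
            reproduction_params(p$R, p$r_f, p$r_m, a),
            dispersal_params(p$h, p$w), qi)
          res <- compensable_by_allocation(sc)
          data.frame(q = qi, alpha_baseline = a,
                     baseline_E_Fstar = sc$baseline_E_Fstar,
                     feasible = res$feasible,
                     alpha_1 = if (res$feasible) res$adjusted_value[[1]]
                               else NA_real_,
                     alpha_2 = if (res$feasible) res$adjusted_value[[2]]
                               else NA_real_)
        }))
      }))
    },
    `5` = {
      need <- c("R", "r_f", "r_m", "alpha")
      if (!all(need %in% names(p))) {
        stop("figure 5 overrides must include R, r_f, r_m, alpha",
             call. = FALSE)
      }
      q <- p$q %||% 0.9
      params <- reproduction_params(p$R, p$r_f, p$r_m, p$alpha)
      wg <- p$w_grid %||% seq(0.05, 1, by = 0.05)
      hg <- p$h_grid %||% round(seq(p$alpha * p$R / p$r_f, 2000,
                                    length.out = 40))
      hfix <- p$h %||% max(hg)
      wfix <- p$w %||% 1
      left <- do.call(rbind, lapply(wg, function(wi) {
        res <- compensate_retention(decline_scenario(
          params, dispersal_params(hfix, wi), q))
        data.frame(panel = "retention", x = wi,
                   adjusted = unname(res$adjusted_value)[1],
                   feasible = res$feasible,
                   reason = res$infeasibility_reason)
      }))
      right <- do.call(rbind, lapply(hg, function(hi) {
        res <- compensate_range(decline_scenario(
          params, dispersal_params(hi, wfix), q))
        data.frame(panel = "range", x = hi,
                   adjusted = unname(res$adjusted_value)[1],
                   feasible = res$feasible,
                   reason = res$infeasibility_reason)
      }))
      rbind(left, right)
    },
    `6` = {
      need <- c("R", "r_f", "r_m", "alpha", "q")
      if (!all(need %in% names(p))) {
        stop("figure 6 overrides must include R, r_f, r_m, alpha, q",
             call. = FALSE)
      }
      params <- reproduction_params(p$R, p$r_f, p$r_m, p$alpha)
      Fo <- p$alpha * p$R / p$r_f
      wg <- p$w_grid %||% seq(0.05, 1, by = 0.05)
      hg <- p$h_grid %||% round(seq(max(1, Fo), 5000, length.out = 40))
      hg <- hg[hg >= Fo]
      compensation_map(params, wg, hg, p$q)
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
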