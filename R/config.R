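#' Read a flat key-value configuration file
#'
#' The configuration format is plain text, one `key = value` (or
#' `key: value`) pair per line; blank lines and `#` comments are ignored.
#' Recognised keys: `R`, `r_f`, `r_m`, `alpha`, `w`, `h`, `q`, `reps`,
#' `seed`.
#'
#' @param path path to the config file.
#' @return A named list of numeric values (not yet validated; pass to
#'   [validate_config()]).
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*[=:]\\s*(.+)$", ln))[[1]]
    if (length(m) != 3L) {
      stop(sprintf("cannot parse config line: '%s'", ln), call. = FALSE)
    }
    val <- suppressWarnings(as.numeric(m[3]))
    if (is.na(val)) {
      stop(sprintf("config value for '%s' is not numeric: '%s'", m[2], m[3]),
           call. = FALSE)
    }
    out[[m[2]]] <- val
  }
  out
}

config_keys <- c("R", "r_f", "r_m", "alpha", "w", "h", "q", "reps", "seed")

#' Validate a raw parameter bundle
#'
#' Enforces every domain constraint on a named list of scalar parameters
#' (as produced by [read_config()] or assembled from CLI flags): positivity
#' of `R`, `r_f`, `r_m`; `alpha` in (0, 1); `w` in (0, 1]; `h >= 1`; `q` in
#' (0, 1]; whole-number `reps >= 1` and `seed`; and the cross-constraint
#' `F = alpha R / r_f <= h` when all four are present. Unknown keys are
#' rejected. All violations are collected and reported together.
#'
#' @param raw named list of scalar values.
#' @param require character vector of keys that must be present (default
#'   none beyond what cross-checks need).
#' @return The canonicalised list (numeric scalars, defaults `w = 1`,
#'   `q = 1` filled in when absent), invisibly usable as a parameter
#'   bundle.
#' @examples
#' validate_config(list(R = 5000, r_f = 10, r_m = 1, alpha = 0.5, h = 1000))
#' @export
validate_config <- function(raw, require = character()) {
  errs <- character()
  unknown <- setdiff(names(raw), config_keys)
  if (length(unknown)) {
    errs <- c(errs, sprintf("unknown key(s): %s",
                            paste(unknown, collapse = ", ")))
  }
  missing <- setdiff(require, names(raw))
  if (length(missing)) {
    errs <- c(errs, sprintf("missing required key(s): %s",
                            paste(missing, collapse = ", ")))
  }
  chk <- function(key, what) {
    v <- raw[[key]]
    if (is.null(v)) return(invisible(NULL))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      errs <<- c(errs, sprintf("%s must be a single finite number", key))
      return(invisible(NULL))
    }
    msg <- tryCatch({ what(v); NULL }, error = function(e) conditionMessage(e))
    if (!is.null(msg)) errs <<- c(errs, msg)
  }
  chk("R", function(v) check_scalar(v, "R", lower = 0, strict = TRUE))
  chk("r_f", function(v) check_scalar(v, "r_f", lower = 0, strict = TRUE))
  chk("r_m", function(v) check_scalar(v, "r_m", lower = 0, strict = TRUE))
  chk("alpha", function(v) {
    if (v <= 0 || v >= 1) stop("alpha must lie in (0,1)", call. = FALSE)
  })
  chk("w", function(v) {
    if (v <= 0 || v > 1) stop("w must lie in (0,1]", call. = FALSE)
  })
  chk("h", function(v) {
    if (v < 1) stop("h must be at least 1", call. = FALSE)
  })
  chk("q", function(v) {
    if (v <= 0 || v > 1) stop("q must lie in (0,1]", call. = FALSE)
  })
  chk("reps", function(v) {
    if (v < 1 || v != round(v)) stop("reps must be a whole number >= 1",
                                     call. = FALSE)
  })
  chk("seed", function(v) {
    if (v != round(v)) stop("seed must be a whole number", call. = FALSE)
  })
  # cross-constraint: every ovule needs its own spatial unit
  if (all(c("R", "r_f", "alpha", "h") %in% names(raw)) && !length(errs)) {
    F <- raw$alpha * raw$R / raw$r_f
    if (F > raw$h) {
      errs <- c(errs, sprintf(
        "F = alpha*R/r_f = %g exceeds h = %g, violating 'h >= F'",
        F, raw$h))
    }
  }
  if (length(errs)) {
    stop(paste0("invalid configuration:\n",
                paste0("  - ", errs, collapse = "\n")), call. = FALSE)
  }
  out <- raw
  if (is.null(out$w)) out$w <- 1
  if (is.null(out$q)) out$q <- 1
  out[config_keys[config_keys %in% names(out)]]
}
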