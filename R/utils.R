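#' Evaluate an expression under a locally scoped RNG
#'
#' All stochastic functions in the package route their randomness through
#' this helper: the expression sees a generator seeded with `seed`, and the
#' caller's global RNG state is left untouched. Identical `(seed, expr)`
#' therefore always yields identical results.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_local_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

stop_invalid <- function(...) {
  stop(..., call. = FALSE)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Standardize continuous covariates to mean 0, sd 1 within the analysis
# subset; constant columns are an error (they would be aliased with the
# intercept after centering).
standardize_covariates <- function(df, continuous) {
  for (nm in continuous) {
    v <- df[[nm]]
    if (!is.numeric(v)) stop_invalid("covariate '", nm, "' is not numeric")
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0)
      stop_invalid("covariate '", nm, "' is constant in this subset")
    df[[nm]] <- (v - mean(v)) / s
  }
  df
}

# Gray-matter region labels: cortical layers I-VI.
GM_REGIONS <- c("layer I", "layer II", "layer III", "layer IV",
                "layer V", "layer VI")

is_gray_matter <- function(region) region %in% GM_REGIONS
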