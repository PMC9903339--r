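#' @useDynLib canopy3d, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats quantile rnorm runif sd median complete.cases
#' @importFrom utils read.csv write.csv head tail
NULL

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. All seeded operations in the package go through
# this so library calls never perturb user RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Half-up decimal rounding (R's round() is round-half-even); used for the
# reported table statistics which follow the printed convention.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_orthonormal <- function(R, tol = 1e-8, what = "R") {
  if (!is.matrix(R) || !all(dim(R) == c(3L, 3L))) {
    stopf("%s must be a 3x3 matrix", what)
  }
  if (max(abs(crossprod(R) - diag(3))) > tol) {
    stopf("%s is not orthonormal (R'R != I within %g)", what, tol)
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
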