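#' Unit helpers
#'
#' The package computes in SI internally (metres, pascals, newtons) because
#' the experimental literature mixes micrometres, nanometres, megapascals and
#' piconewtons. These helpers convert reported values into SI (`um()`, `nm()`,
#' `mm()`, `MPa()`, `pN()`) and SI values back to reporting units (`as_um()`,
#' `as_nm()`, `as_MPa()`, `as_pN()`).
#'
#' @param x Numeric vector.
#' @return Numeric vector in the target unit.
#' @examples
#' um(21.14)        # 2.114e-05 m
#' as_pN(4.7e-13)   # 0.47 pN
#' @name units
NULL

#' @rdname units
#' @export
um <- function(x) x * 1e-6

#' @rdname units
#' @export
nm <- function(x) x * 1e-9

#' @rdname units
#' @export
mm <- function(x) x * 1e-3

#' @rdname units
#' @export
MPa <- function(x) x * 1e6

#' @rdname units
#' @export
pN <- function(x) x * 1e-12

#' @rdname units
#' @export
as_um <- function(x) x * 1e6

#' @rdname units
#' @export
as_nm <- function(x) x * 1e9

#' @rdname units
#' @export
as_MPa <- function(x) x * 1e-6

#' @rdname units
#' @export
as_pN <- function(x) x * 1e12

# Avogadro's number, mol^-1
.N_AVOGADRO <- 6.02214076e23

# ---- internal validation helpers -------------------------------------------

check_positive <- function(x, name, allow_zero = FALSE) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop(sprintf("`%s` must be finite numeric", name), call. = FALSE)
  }
  if (allow_zero) {
    if (any(x < 0)) stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  } else {
    if (any(x <= 0)) stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  invisible(x)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) {
      old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(expr)
}
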