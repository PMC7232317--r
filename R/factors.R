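#' Define an experimental factor for coded designs
#'
#' A factor is described by the real value at the design center (coded 0) and
#' the step change per coded unit, so that a real value \eqn{X} maps to the
#' dimensionless coded value \eqn{x = (X - X_0) / \Delta X}.
#'
#' @param name Factor label (e.g. \code{"pH"}); used to name design columns.
#' @param center Real value at the center point \eqn{X_0}, in factor units.
#' @param step Step change \eqn{\Delta X} per coded unit; must be > 0.
#' @param units Optional unit string, for display only.
#'
#' @return An object of class \code{rsm_factor}.
#' @seealso [code_value()], [decode_value()], [ccd_design()]
#' @examples
#' temp <- rsm_factor("temperature", center = 26, step = 4, units = "degC")
#' code_value(30, temp)    # +1
#' decode_value(1.68, temp)
#' @export
rsm_factor <- function(name, center, step, units = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(center) || length(center) != 1L || !is.finite(center))
    stop("'center' must be a single finite number", call. = FALSE)
  if (!is.numeric(step) || length(step) != 1L || !is.finite(step) || step <= 0)
    stop("'step' must be a single finite number > 0", call. = FALSE)
  structure(
    list(name = name, center = as.numeric(center), step = as.numeric(step),
         units = as.character(units)),
    class = "rsm_factor"
  )
}

#' @export
print.rsm_factor <- function(x, ...) {
  u <- if (nzchar(x$units)) paste0(" ", x$units) else ""
  cat(sprintf("Factor %s: center %g%s, step %g%s per coded unit\n",
              x$name, x$center, u, x$step, u))
  invisible(x)
}

#' Convert between real and coded factor values
#'
#' \code{code_value} maps a real value onto the dimensionless coded scale,
#' \eqn{x = (X - X_0)/\Delta X}; \code{decode_value} is its exact inverse,
#' \eqn{X = X_0 + x \Delta X}.
#'
#' @param X,x Real (resp. coded) values; finite numeric vectors.
#' @param factor An [rsm_factor()].
#' @return Numeric vector of the same length.
#' @examples
#' ph <- rsm_factor("pH", center = 6, step = 1)
#' code_value(6, ph)        # 0: the center maps to coded zero
#' decode_value(-1.68, ph)  # low axial level
#' @export
code_value <- function(X, factor) {
  check_factor(factor)
  if (!is.numeric(X) || any(!is.finite(X)))
    stop("'X' must be finite numeric", call. = FALSE)
  (X - factor$center) / factor$step
}

#' @rdname code_value
#' @export
decode_value <- function(x, factor) {
  check_factor(factor)
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("'x' must be finite numeric", call. = FALSE)
  factor$center + x * factor$step
}

check_factor <- function(factor) {
  if (!inherits(factor, "rsm_factor"))
    stop("'factor' must be an 'rsm_factor' object", call. = FALSE)
  if (!is.finite(factor$step) || factor$step <= 0)
    stop("factor step must be > 0", call. = FALSE)
  invisible(factor)
}

# default coded-unit factors x1..xk when the user supplies only k
default_factors <- function(k) {
  lapply(seq_len(k), function(i) rsm_factor(paste0("x", i), 0, 1))
}
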