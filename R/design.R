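#' Generate a central composite design
#'
#' Builds the three classical blocks of a central composite design (CCD):
#' the \eqn{2^k} full-factorial vertices at coded \eqn{\pm 1}, the \eqn{2k}
#' axial (star) points at coded \eqn{\pm\alpha}, and \code{n_center}
#' replicated center runs.  With the default rotatable spacing,
#' \eqn{\alpha = (2^k)^{1/4}}, giving the familiar five coded levels
#' \eqn{-\alpha, -1, 0, +1, +\alpha} (for three factors
#' \eqn{\alpha = 1.6818}, printed as 1.68).
#'
#' @param factors Either an integer number of factors \code{k} (>= 2), in
#'   which case unit factors \code{x1..xk} centered at 0 are used, or a list
#'   of [rsm_factor()] objects defining the real-unit scaling.
#' @param n_center Number of replicated center runs (>= 1).
#' @param alpha \code{"rotatable"} (default), \code{"face_centered"}
#'   (\eqn{\alpha = 1}), or a positive number giving the axial distance
#'   explicitly.
#'
#' @return A data frame of class \code{ccd_design} with one row per run and
#'   columns \code{run}, \code{class} (\code{factorial}/\code{axial}/
#'   \code{center}), coded coordinates \code{x_<name>} and real coordinates
#'   \code{X_<name>}.  The factor list and axial distance are carried as
#'   attributes \code{"factors"} and \code{"alpha"}.  Runs are in block order
#'   (factorial, axial, center); see [randomize_runs()] for a seeded shuffle.
#' @examples
#' des <- ccd_design(3, n_center = 10)
#' nrow(des)              # 24 = 2^3 + 2*3 + 10
#' attr(des, "alpha")     # 1.6818
#' @export
ccd_design <- function(factors, n_center = 6L, alpha = "rotatable") {
  if (is.numeric(factors) && length(factors) == 1L) {
    k <- as.integer(factors)
    factors <- default_factors(k)
  } else if (is.list(factors) && all(vapply(factors, inherits, TRUE, "rsm_factor"))) {
    k <- length(factors)
  } else {
    stop("'factors' must be an integer k or a list of rsm_factor objects",
         call. = FALSE)
  }
  if (k < 2L)
    stop("central composite designs need at least 2 factors", call. = FALSE)
  n_center <- as.integer(n_center)
  if (is.na(n_center) || n_center < 1L)
    stop("'n_center' must be >= 1", call. = FALSE)

  a <- if (identical(alpha, "rotatable")) {
    (2^k)^(1 / 4)
  } else if (identical(alpha, "face_centered")) {
    1
  } else if (is.numeric(alpha) && length(alpha) == 1L && is.finite(alpha) &&
             alpha > 0) {
    as.numeric(alpha)
  } else {
    stop("'alpha' must be \"rotatable\", \"face_centered\" or a number > 0",
         call. = FALSE)
  }

  fact <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
  axial <- matrix(0, 2L * k, k)
  for (i in seq_len(k)) {
    axial[2L * i - 1L, i] <- -a
    axial[2L * i, i] <- a
  }
  center <- matrix(0, n_center, k)
  coded <- rbind(fact, axial, center)
  dimnames(coded) <- NULL

  nm <- vapply(factors, `[[`, "", "name")
  actual <- vapply(seq_len(k),
                   function(i) decode_value(coded[, i], factors[[i]]),
                   numeric(nrow(coded)))
  des <- data.frame(
    run = seq_len(nrow(coded)),
    class = rep(c("factorial", "axial", "center"),
                c(nrow(fact), nrow(axial), n_center)),
    stringsAsFactors = FALSE
  )
  des[paste0("x_", nm)] <- as.data.frame(coded)
  des[paste0("X_", nm)] <- as.data.frame(actual)
  new_ccd_design(des, factors, a)
}

new_ccd_design <- function(df, factors, alpha) {
  structure(df, factors = factors, alpha = alpha,
            class = c("ccd_design", "data.frame"))
}

#' @export
print.ccd_design <- function(x, ...) {
  k <- length(design_factors(x))
  cat(sprintf("Central composite design: %d runs, %d factors, alpha = %.2f\n",
              nrow(x), k, attr(x, "alpha")))
  print.data.frame(x, ...)
  invisible(x)
}

design_factors <- function(design) {
  f <- attr(design, "factors")
  if (is.null(f)) stop("design carries no factor definitions", call. = FALSE)
  f
}

#' Extract the coded design matrix
#'
#' @param design A \code{ccd_design} data frame.
#' @return Numeric matrix of the coded coordinates (columns \code{x_*}).
#' @export
coded_matrix <- function(design) {
  cols <- grep("^x_", names(design), value = TRUE)
  if (!length(cols)) stop("no coded columns 'x_*' found", call. = FALSE)
  m <- as.matrix(as.data.frame(design)[cols])
  colnames(m) <- sub("^x_", "", cols)
  m
}

#' Randomize the run order of a design
#'
#' Applies a seeded pseudo-random permutation to the runs and reassigns
#' consecutive run indices.  The same seed always yields the same order.
#'
#' @param design A \code{ccd_design}.
#' @param seed Integer seed for the permutation.
#' @return The design with permuted rows and fresh run indices.
#' @export
randomize_runs <- function(design, seed) {
  stopifnot(inherits(design, "ccd_design"))
  seed <- as.integer(seed)
  if (is.na(seed)) stop("'seed' must be an integer", call. = FALSE)
  ord <- local_seed(seed, sample.int(nrow(design)))
  out <- design[ord, , drop = FALSE]
  out$run <- seq_len(nrow(out))
  rownames(out) <- NULL
  new_ccd_design(out, design_factors(design), attr(design, "alpha"))
}

# evaluate expr under a temporary RNG state
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Attach observed responses to a design
#'
#' @param design A \code{ccd_design}.
#' @param y_mean Mean response per run (same order as the design rows).
#' @param y_se Replicate standard error per run (optional).
#' @param n_rep Replicates per run (optional; recycled).
#' @return The design with \code{y_mean}, \code{y_se}, \code{n_rep} columns.
#' @export
set_response <- function(design, y_mean, y_se = NA_real_, n_rep = NA_integer_) {
  stopifnot(inherits(design, "ccd_design"))
  if (length(y_mean) != nrow(design))
    stop("'y_mean' must have one value per run", call. = FALSE)
  if (any(!is.finite(y_mean)))
    stop("all mean responses must be finite", call. = FALSE)
  if (!all(is.na(y_se)) && any(y_se < 0, na.rm = TRUE))
    stop("replicate standard errors must be non-negative", call. = FALSE)
  design$y_mean <- as.numeric(y_mean)
  design$y_se <- rep_len(as.numeric(y_se), nrow(design))
  design$n_rep <- rep_len(as.integer(n_rep), nrow(design))
  design
}

#' Read / write a design table as delimited text
#'
#' The on-disk format is a comma-separated table with a mandatory header:
#' \code{run, class, x_<factor>..., X_<factor>..., y_mean, y_se, n_rep}
#' (response columns optional).  Factor centers and steps are recovered from
#' the coded/real column pairs.
#'
#' @param path File path.
#' @param design A \code{ccd_design} (for writing).
#' @return \code{read_design} returns a \code{ccd_design};
#'   \code{write_design} returns \code{path} invisibly.
#' @export
read_design <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("run", "class")
  if (!all(need %in% names(df)))
    stop("design file must have 'run' and 'class' columns", call. = FALSE)
  xcols <- grep("^x_", names(df), value = TRUE)
  if (length(xcols) < 2L)
    stop("design file must carry at least two coded columns 'x_*'", call. = FALSE)
  nm <- sub("^x_", "", xcols)
  factors <- lapply(nm, function(f) {
    xc <- df[[paste0("x_", f)]]
    Xc <- df[[paste0("X_", f)]]
    if (is.null(Xc)) return(rsm_factor(f, 0, 1))
    # recover center/step by least squares on X = center + step * x
    co <- stats::coef(stats::lm(Xc ~ xc))
    rsm_factor(f, unname(co[1]), unname(co[2]))
  })
  a <- max(abs(as.matrix(df[xcols])))
  new_ccd_design(df, factors, a)
}

#' @rdname read_design
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "ccd_design"))
  utils::write.csv(as.data.frame(design), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
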