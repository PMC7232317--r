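#' Bundled allethrin biodegradation design table
#'
#' The 24-run, three-factor central composite design (pH, temperature,
#' incubation time; 8 factorial + 6 axial + 10 center runs) with the mean
#' percent allethrin degradation and replicate standard error observed for
#' each run in the original optimization experiment.  Axial coordinates are
#' stored at full rotatable precision (\eqn{\alpha = 2^{3/4} = 1.6818},
#' displayed elsewhere as 1.68); real factor levels use pH 6 +/- 1 per coded
#' unit, temperature 26 +/- 4 degC, incubation time 5 +/- 1 days.
#'
#' @return A \code{ccd_design} with responses attached (\code{y_mean},
#'   \code{y_se}, \code{n_rep}).
#' @examples
#' des <- allethrin_ccd()
#' table(des$class)
#' @export
allethrin_ccd <- function() {
  path <- system.file("extdata", "allethrin_ccd.csv", package = "rsmkin",
                      mustWork = TRUE)
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, "26f01a275a3017afad4f7b12ff0fc525"))
    stop("bundled design table is corrupted (checksum mismatch); ",
         "reinstall the package", call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  factors <- list(
    rsm_factor("pH", center = 6, step = 1),
    rsm_factor("temperature", center = 26, step = 4, units = "degC"),
    rsm_factor("time", center = 5, step = 1, units = "days")
  )
  new_ccd_design(df, factors, (2^3)^(1 / 4))
}

#' Reference values for the bundled allethrin study
#'
#' The headline numbers reported for the allethrin optimization and
#' kinetics experiments, with the tolerance used by
#' [reproduce_reference()] and a provenance note for each.  Shipped as a
#' versioned delimited-text file so the comparison rules are data, not code.
#'
#' @return Data frame with columns \code{id}, \code{quantity},
#'   \code{printed}, \code{tolerance}, \code{cmp} (\code{eq} two-sided,
#'   \code{mag} magnitude-only, \code{note} annotation-only) and
#'   \code{provenance}.
#' @export
reference_checks <- function() {
  path <- system.file("extdata", "reference_checks.csv", package = "rsmkin",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Reported rate constants for the allethrin kinetics experiment
#'
#' Quoted first-order rate constants (1/h) for the non-inoculated control
#' and the fungus-treated series of the original dissipation experiment.
#'
#' @return Named numeric vector with elements \code{control} and
#'   \code{treatment}.
#' @export
reference_rate_constants <- function() {
  c(control = 0.0013, treatment = 0.0193)
}
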