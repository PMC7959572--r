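#' Isotope constants closing the open-system mass balance
#'
#' The open-system model expresses the diatom isotope composition as
#' \eqn{\delta^{30}Si_{diatom} = \delta^{30}Si_{lake} + \epsilon f}, where
#' \eqn{f} is the fraction of supplied silicic acid remaining in the photic
#' zone. Both constants have been determined for Lake Baikal from modern
#' water-column and river measurements: the deep-water dissolved silicic acid
#' composition \eqn{\delta^{30}Si_{lake}} = 1.71 permil (vs NBS28) and the
#' diatom--silicic acid enrichment factor \eqn{\epsilon} = -1.61 permil.
#'
#' @param delta_lake Isotope composition of silicic acid supplied to the
#'   photic zone, permil vs NBS28. Default 1.71.
#' @param epsilon Enrichment factor between diatom opal and dissolved silicic
#'   acid, permil. Must be negative (diatoms prefer the light isotope).
#'   Default -1.61.
#' @return An object of class `isotope_constants`.
#' @examples
#' isotope_constants()
#' @export
isotope_constants <- function(delta_lake = 1.71, epsilon = -1.61) {
  if (!is.finite(delta_lake) || !is.finite(epsilon))
    stop("isotope constants must be finite", call. = FALSE)
  if (epsilon >= 0)
    stop("enrichment factor epsilon must be negative (got ", epsilon, ")",
         call. = FALSE)
  structure(list(delta_lake = delta_lake, epsilon = epsilon),
            class = "isotope_constants")
}

#' @export
print.isotope_constants <- function(x, ...) {
  cat("Open-system isotope constants:\n")
  cat("  delta30Si_lake:", x$delta_lake, "permil vs NBS28\n")
  cat("  epsilon:       ", x$epsilon, "permil\n")
  invisible(x)
}

#' Named climate-period boundaries used for between-period comparisons
#'
#' Dark Ages Cold Period (DACP) 500--750 CE, Medieval Climate Anomaly (MCA)
#' 880--1180 CE, Little Ice Age (LIA) 1180--1840 CE and the modern period from
#' 1900 CE onward. Boundaries follow diatom-inferred environmental zonation of
#' south-basin Lake Baikal records and can be overridden wherever a period
#' argument is accepted.
#'
#' @param end_modern Final year of the modern period (default 2013).
#' @return Named list of `c(start, end)` year pairs (calendar years CE).
#' @examples
#' climate_periods()$LIA
#' @export
climate_periods <- function(end_modern = 2013) {
  list(
    DACP   = c(500, 750),
    MCA    = c(880, 1180),
    LIA    = c(1180, 1840),
    Modern = c(1900, end_modern)
  )
}

# internal input checkers shared across modules ------------------------------

stop_if_not_numeric <- function(x, what) {
  if (!is.numeric(x)) stop(what, " must be numeric", call. = FALSE)
  invisible(x)
}

check_strictly_increasing <- function(x, what) {
  if (any(diff(x) <= 0))
    stop(what, " must be strictly increasing", call. = FALSE)
  invisible(x)
}
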