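#' Canonical parameter names and group labels
#'
#' The six LV parameters measured per exam, in reporting order, and the four
#' treatment groups of the hypertrophy study design (saline control, AngII
#' infusion, sRAGE treatment, and the AngII + sRAGE combination).
#'
#' @return character vector.
#' @export
lvParameterNames <- function() c("EDbv", "ESbv", "EDmv", "EDmw", "LVWT", "EF")

#' @rdname lvParameterNames
#' @export
lvGroupLabels <- function() c("saline", "AngII", "sRAGE", "AngII+sRAGE")

#' Published group summary statistics for the six LV parameters
#'
#' Mean and standard deviation of each parameter per treatment group and
#' timepoint (pre = before pump implantation, post = after 4 weeks of
#' infusion), as reported for the AngII-induced hypertrophy mouse study the
#' simulator emulates. Units: EDbv/ESbv/EDmv mm^3, EDmw mg, LVWT um, EF
#' percent. These are the default distribution parameters of
#' [cohortSpec()].
#'
#' @return data.frame with columns `group`, `timepoint`, `parameter`,
#'   `mean`, `sd`.
#' @export
referenceGroupStats <- function() {
  groups <- lvGroupLabels()
  p <- lvParameterNames()
  # rows: EDbv, ESbv, EDmv, EDmw, LVWT, EF per group
  pre <- list(
    saline        = c(44.0, 11.9, 77.1, 81.0, 656.4, 73.0),
    AngII         = c(45.7, 13.4, 73.2, 76.9, 660.0, 71.5),
    sRAGE         = c(50.7, 17.5, 76.8, 80.6, 632.2, 65.6),
    `AngII+sRAGE` = c(48.6, 16.5, 78.1, 82.0, 642.2, 67.4))
  preSd <- list(
    saline        = c(3.9, 1.7, 8.6, 9.0, 49.9, 2.6),
    AngII         = c(4.1, 3.4, 3.8, 4.0, 35.0, 6.4),
    sRAGE         = c(4.2, 4.6, 5.2, 5.5, 45.5, 7.8),
    `AngII+sRAGE` = c(4.4, 4.5, 7.4, 7.8, 27.4, 6.3))
  post <- list(
    saline        = c(46.6, 11.5, 88.6, 93.0, 818.4, 75.4),
    AngII         = c(69.9, 26.3, 112.3, 118.0, 813.5, 68.3),
    sRAGE         = c(51.0, 13.7, 86.8, 91.1, 769.7, 73.2),
    `AngII+sRAGE` = c(66.4, 23.4, 100.8, 105.8, 796.8, 65.4))
  postSd <- list(
    saline        = c(5.4, 2.0, 6.6, 7.0, 60.5, 2.4),
    AngII         = c(19.5, 18.2, 17.7, 18.6, 66.2, 2.4),
    sRAGE         = c(2.7, 3.9, 7.1, 7.5, 74.3, 7.2),
    `AngII+sRAGE` = c(9.5, 5.2, 10.5, 11.0, 53.0, 3.5))
  out <- do.call(rbind, lapply(groups, function(g) {
    rbind(
      data.frame(group = g, timepoint = "pre", parameter = p,
                 mean = pre[[g]], sd = preSd[[g]]),
      data.frame(group = g, timepoint = "post", parameter = p,
                 mean = post[[g]], sd = postSd[[g]]))
  }))
  rownames(out) <- NULL
  out
}

#' Group sizes of the reference study design
#'
#' @return named integer vector (animals per group).
#' @export
referenceGroupSizes <- function() {
  c(saline = 10L, AngII = 9L, sRAGE = 10L, `AngII+sRAGE` = 10L)
}

#' Myocardial density used for mass computation
#'
#' Myocardial tissue density, 1.05 g/mL, i.e. 1.05 mg per mm^3.
#'
#' @return numeric scalar, mg per mm^3.
#' @export
myocardialDensity <- function() 1.05

#' Report rounding: half away from zero
#'
#' Rounds to `digits` decimals with halves moving away from zero, the
#' convention published parameter tables use (base `round()` rounds half to
#' even).
#'
#' @param x numeric.
#' @param digits decimal places (default 1).
#' @return rounded numeric.
#' @export
roundHalfAway <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
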