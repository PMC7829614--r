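#' Classify synovial histology into B-cell pathotypes
#'
#' Semi-quantitative immunohistochemistry rule used for randomization
#' strata: ungradable tissue is `unknown`; a CD20 score below 2 is
#' `bcell_poor`; a CD20 score of 2--4 is `bcell_rich`; B-cell rich tissue
#' with CD21+ follicular dendritic cell networks is `gc_positive`.
#'
#' The published rule couples the rich class to the presence of CD20
#' aggregates and leaves CD20 >= 2 without aggregates undefined; here the
#' score alone is operative (the poor rule is purely "less than two") and
#' the aggregates flag is carried for audit. See the methods vignette.
#'
#' @param cd20 ordinal CD20 score in 0--4.
#' @param cd20_aggregates logical, CD20 B-cell aggregates present.
#' @param cd21_fdc_networks logical, CD21+ follicular dendritic cell
#'   networks present (implies gradable tissue).
#' @param tissue_gradable logical, definite synovial tissue identified.
#' @return Factor with levels `bcell_poor`, `bcell_rich`, `gc_positive`,
#'   `unknown`; attribute `basis` is `"histology"`.
#' @export
classify_histology <- function(cd20, cd20_aggregates = FALSE,
                               cd21_fdc_networks = FALSE,
                               tissue_gradable = TRUE) {
  n <- max(length(cd20), length(cd20_aggregates),
           length(cd21_fdc_networks), length(tissue_gradable))
  cd20 <- rep_len(cd20, n)
  cd20_aggregates <- rep_len(cd20_aggregates, n)
  cd21_fdc_networks <- rep_len(cd21_fdc_networks, n)
  tissue_gradable <- rep_len(tissue_gradable, n)
  if (any(!is.na(cd20) & !(cd20 %in% 0:4)))
    stop("cd20 scores must be ordinal values in 0..4")
  if (any(cd21_fdc_networks & !tissue_gradable, na.rm = TRUE))
    stop("cd21_fdc_networks implies tissue_gradable")
  lab <- ifelse(!tissue_gradable, "unknown",
         ifelse(cd20 < 2, "bcell_poor",
         ifelse(cd21_fdc_networks, "gc_positive", "bcell_rich")))
  structure(factor(lab, levels = pathotype_levels()), basis = "histology")
}

#' Pathotype factor levels
#' @return Character vector of the four pathotype labels.
#' @export
pathotype_levels <- function() {
  c("bcell_poor", "bcell_rich", "gc_positive", "unknown")
}

#' Primary-analysis population mask
#'
#' Only patients classified B-cell poor or B-cell rich enter the primary
#' analysis; germinal-centre-positive and unknown tissue is excluded.
#'
#' @param labels factor/character of pathotype labels.
#' @return Logical mask.
#' @export
primary_population_filter <- function(labels) {
  as.character(labels) %in% c("bcell_poor", "bcell_rich")
}

#' Dual-observer classification disagreement report
#'
#' Independent-evaluation adjudication is modelled as a report, not an
#' automated resolution: returns the cross-tabulation of the two readers'
#' labels and the indices where they disagree.
#'
#' @param labels_a,labels_b pathotype labels from the two observers.
#' @return List with `table` (cross-tabulation) and `disagree` (indices).
#' @export
observer_disagreement <- function(labels_a, labels_b) {
  stopifnot(length(labels_a) == length(labels_b))
  a <- as.character(labels_a); b <- as.character(labels_b)
  list(table = table(observer_a = a, observer_b = b),
       disagree = which(a != b))
}
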