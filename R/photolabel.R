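#' Photolabeling efficiency from chromatographic areas
#'
#' Efficiency = 100 * labeled / (labeled + unlabeled), from the areas under
#' extracted chromatograms of the labeled and unlabeled forms of a peptide.
#'
#' @param labeled_area,unlabeled_area areas under the curve (arbitrary,
#'   consistent units), >= 0, not both zero; vectorized.
#' @return Efficiency in percent, in [0, 100].
#' @examples
#' labeling_efficiency(0.77, 99.23)  # 0.77 percent
#' @export
labeling_efficiency <- function(labeled_area, unlabeled_area) {
  if (any(labeled_area < 0) || any(unlabeled_area < 0))
    stop("areas must be >= 0")
  tot <- labeled_area + unlabeled_area
  if (any(tot <= 0)) stop("labeled and unlabeled areas are both zero")
  100 * labeled_area / tot
}

#' Percent prevention of photolabeling by a competitor
#'
#' Percent reduction of labeling efficiency when a competing ligand is
#' present: 100 * (1 - eff_with_competitor / eff_control). Full prevention
#' (efficiency abolished) gives 100\%.
#'
#' @param efficiency_control labeling efficiency without competitor
#'   (percent), > 0.
#' @param efficiency_with_competitor labeling efficiency with competitor
#'   (percent), >= 0.
#' @return Percent prevention.
#' @export
percent_prevention <- function(efficiency_control,
                               efficiency_with_competitor) {
  if (any(efficiency_control <= 0)) stop("control efficiency must be > 0")
  if (any(efficiency_with_competitor < 0))
    stop("efficiencies must be >= 0")
  100 * (1 - efficiency_with_competitor / efficiency_control)
}

#' Summarize photolabeling efficiencies across replicates
#'
#' Computes per-peptide, per-condition labeling efficiency and aggregates
#' replicates as mean +/- SEM. Group-comparison statistics are deliberately
#' not computed; the summary is descriptive.
#'
#' @param areas a data frame with columns \code{peptide_id},
#'   \code{condition}, \code{labeled_area}, \code{unlabeled_area} and
#'   optionally \code{replicate}.
#' @return A data frame with one row per peptide x condition:
#'   \code{efficiency_pct} (mean), \code{sem}, \code{n}.
#' @export
summarize_labeling <- function(areas) {
  req <- c("peptide_id", "condition", "labeled_area", "unlabeled_area")
  missing_cols <- setdiff(req, names(areas))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  eff <- labeling_efficiency(areas$labeled_area, areas$unlabeled_area)
  agg <- stats::aggregate(
    eff, by = list(peptide_id = areas$peptide_id,
                   condition = areas$condition),
    FUN = function(v) c(mean = mean(v),
                        sem = stats::sd(v) / sqrt(length(v)),
                        n = length(v)))
  out <- data.frame(peptide_id = agg$peptide_id, condition = agg$condition,
                    efficiency_pct = agg$x[, "mean"], sem = agg$x[, "sem"],
                    n = as.integer(agg$x[, "n"]))
  out[order(out$peptide_id, out$condition), , drop = FALSE]
}
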