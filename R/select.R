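# The tool-selection workflow: evaluate every candidate tool's runs over a
# common curated benchmark, aggregate the three criteria (precision,
# generality, robustness) for both measurements, run the pairwise rank tests,
# and emit a recommendation that names the winner per criterion -- flagging
# disagreement between criteria instead of forcing a single champion.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Build per-tool reports for one measurement
#'
#' @param results per-complex results from [evaluate_runs()].
#' @param grouping class axis (`"warhead_class"` or `"receptor_type"`).
#' @param subgroup subgroup key for generality marks.
#' @param measurement `"best_scored"` or `"best_sampled"`.
#' @return tibble, one row per tool: precision, generality marks, normalised
#'   generality `G`, robustness, and the profiling counts.
#' @export
tool_report <- function(results, grouping = c("warhead_class", "receptor_type"),
                        subgroup = "uniprot_id",
                        measurement = c("best_scored", "best_sampled")) {
  grouping <- match.arg(grouping)
  measurement <- match.arg(measurement)
  prec <- precision(results, grouping, measurement)
  gen <- generality(results, grouping, subgroup, measurement)
  rob <- robustness(results, measurement)
  prof <- profile_tools(results)
  prec$precision |>
    dplyr::left_join(gen$generality, by = "tool_id") |>
    dplyr::left_join(rob, by = "tool_id") |>
    dplyr::left_join(prof, by = "tool_id") |>
    dplyr::mutate(measurement = measurement, grouping = grouping,
                  .after = "tool_id")
}

criterion_winners <- function(report) {
  pick <- function(v, best = min) report$tool_id[v == best(v)]
  tibble::tibble(
    criterion = c("precision", "generality", "robustness"),
    winner = c(paste(pick(report$precision), collapse = "/"),
               paste(pick(report$marks, best = max), collapse = "/"),
               paste(pick(report$robustness), collapse = "/")))
}

#' Select a covalent docking tool
#'
#' Runs the full selection workflow over evaluated results: per-tool reports
#' for both measurements (the Best Scored Pose report is the primary one,
#' since scoring accuracy is what a prospective user experiences; Best
#' Sampled is always computed alongside), the pairwise Mann-Whitney test
#' matrix, and a recommendation block listing the winner of each criterion.
#' When the criteria disagree the disagreement is reported, not resolved.
#'
#' @param results per-complex results from [evaluate_runs()] covering at
#'   least two tools on a common entry set.
#' @param grouping class axis for precision/generality.
#' @param subgroup subgroup key for generality marks.
#' @return object of class `selection_report`: `reports` (tibble over both
#'   measurements), `tests` (pairwise U-tests, both measurements),
#'   `recommendation` (criterion winners on the Best Scored Pose report),
#'   `agreement` (logical: all three criteria name a common winner).
#' @export
select_tool <- function(results, grouping = c("warhead_class", "receptor_type"),
                        subgroup = "uniprot_id") {
  grouping <- match.arg(grouping)
  if (length(unique(results$tool_id)) < 2L) {
    stop("tool selection needs at least two tools", call. = FALSE)
  }
  assert_common_entries(results)
  reports <- dplyr::bind_rows(
    tool_report(results, grouping, subgroup, "best_scored"),
    tool_report(results, grouping, subgroup, "best_sampled"))
  tests <- dplyr::bind_rows(
    dplyr::mutate(pairwise_tool_tests(results, "best_scored"),
                  measurement = "best_scored"),
    dplyr::mutate(pairwise_tool_tests(results, "best_sampled"),
                  measurement = "best_sampled"))
  primary <- reports[reports$measurement == "best_scored", ]
  rec <- criterion_winners(primary)
  winners <- strsplit(rec$winner, "/")
  agreement <- length(Reduce(intersect, winners)) > 0
  structure(list(reports = reports, tests = tests, recommendation = rec,
                 agreement = agreement, grouping = grouping),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("<selection_report> axis ", x$grouping, "\n", sep = "")
  print(x$recommendation)
  if (!x$agreement) {
    cat("criteria disagree: inspect the full reports before choosing\n")
  }
  invisible(x)
}

#' @method tidy selection_report
#' @export
tidy.selection_report <- function(x, ...) x$reports

#' @method glance selection_report
#' @export
glance.selection_report <- function(x, ...) {
  tibble::tibble(
    n_tools = length(unique(x$reports$tool_id)),
    agreement = x$agreement,
    precision_winner = x$recommendation$winner[1],
    generality_winner = x$recommendation$winner[2],
    robustness_winner = x$recommendation$winner[3])
}

# ---- plotting --------------------------------------------------------------

#' Heat-map plot of per-class median RMSDs
#'
#' @param object a `covbench_heatmap` from [heatmap_table()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot covbench_heatmap
#' @export
autoplot.covbench_heatmap <- function(object, ...) {
  tab <- object$table
  ggplot2::ggplot(tab, ggplot2::aes(
    x = .data$tool_id, y = .data[[object$class_col]],
    fill = .data$median_rmsd)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$median_rmsd)),
                       size = 3) +
    ggplot2::scale_fill_gradient(
      low = HEAT_GREEN, high = HEAT_RED,
      limits = c(object$green_anchor, object$red_anchor),
      oob = scales_squish, name = "median RMSD (Å)") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

# clamp out-of-bounds values to the gradient limits (scales::squish without
# importing scales)
scales_squish <- function(x, range = c(0, 1), ...) {
  pmin(pmax(x, range[1]), range[2])
}

#' P-deviation histogram plot
#'
#' @param results per-complex results.
#' @param binwidth histogram bin width (Angstrom).
#' @return a ggplot of the per-tool P-deviation distributions.
#' @export
plot_p_deviation <- function(results, binwidth = 0.5) {
  ggplot2::ggplot(results, ggplot2::aes(x = .data$p_deviation,
                                        fill = .data$tool_id)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            position = "identity", alpha = 0.5) +
    ggplot2::labs(x = "P-deviation  S1 - S2  (Å)", y = "complexes",
                  fill = "tool") +
    ggplot2::theme_minimal()
}

#' Criterion overview plot for a selection report
#'
#' @param object a `selection_report`.
#' @param ... unused.
#' @return a ggplot of precision, generality marks and robustness per tool.
#' @method autoplot selection_report
#' @export
autoplot.selection_report <- function(object, ...) {
  long <- object$reports |>
    tidyr::pivot_longer(c("precision", "marks", "robustness"),
                        names_to = "criterion", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$tool_id, y = .data$value,
                                     fill = .data$measurement)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~criterion, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, fill = "measurement") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
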