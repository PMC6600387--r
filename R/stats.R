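# Aggregate selection criteria over per-complex results: precision (the
# median across classes of within-class median RMSDs), generality (marks for
# attaining the best within-subgroup median across tools), robustness (the
# standard deviation of all RMSDs), the four profiling counts, P-deviation
# distributions and pairwise rank tests.

measurement_column <- function(measurement = c("best_scored", "best_sampled")) {
  switch(match.arg(measurement), best_scored = "s1", best_sampled = "s2")
}

#' Precision: median-of-medians RMSD
#'
#' For one grouping axis (warhead class or receptor type), computes each
#' tool's within-class median RMSD and then the median across class medians.
#' The inner median runs over the co-crystal structures of a class; the outer
#' median runs over classes, so rare classes weigh as much as common ones.
#' Lower is better. Classes with no finite RMSD are dropped from the outer
#' median with a warning. Even-length medians are the mean of the two central
#' values.
#'
#' @param results per-complex results tibble from [evaluate_runs()] (or any
#'   table with `tool_id`, the grouping column, and `s1`/`s2`).
#' @param grouping grouping column: `"warhead_class"` or `"receptor_type"`.
#' @param measurement `"best_scored"` (S1) or `"best_sampled"` (S2).
#' @return list of class `tool_precision`: `per_class` tibble
#'   (`tool_id`, class, `n`, `median_rmsd`) and `precision` tibble
#'   (`tool_id`, `precision`).
#' @export
precision <- function(results, grouping = c("warhead_class", "receptor_type"),
                      measurement = c("best_scored", "best_sampled")) {
  grouping <- match.arg(grouping)
  col <- measurement_column(measurement)
  if (any(is.na(results[[grouping]]))) {
    warning("dropping results with missing ", grouping, call. = FALSE)
    results <- results[!is.na(results[[grouping]]), ]
  }
  per_class <- results |>
    dplyr::group_by(.data$tool_id, .data[[grouping]]) |>
    dplyr::summarise(n = dplyr::n(),
                     median_rmsd = stats::median(.data[[col]], na.rm = TRUE),
                     .groups = "drop")
  empty <- is.na(per_class$median_rmsd)
  if (any(empty)) {
    warning(sum(empty), " empty class(es) omitted from the outer median",
            call. = FALSE)
    per_class <- per_class[!empty, ]
  }
  prec <- per_class |>
    dplyr::group_by(.data$tool_id) |>
    dplyr::summarise(precision = stats::median(.data$median_rmsd),
                     .groups = "drop")
  structure(list(per_class = per_class, precision = prec,
                 grouping = grouping,
                 measurement = match.arg(measurement)),
            class = "tool_precision")
}

#' @export
print.tool_precision <- function(x, ...) {
  cat("<tool_precision> axis ", x$grouping, ", measurement ", x$measurement,
      "\n", sep = "")
  print(x$precision)
  invisible(x)
}

#' @method tidy tool_precision
#' @export
tidy.tool_precision <- function(x, ...) x$per_class

#' @method glance tool_precision
#' @export
glance.tool_precision <- function(x, ...) {
  tidyr::pivot_wider(x$precision, names_from = "tool_id",
                     values_from = "precision")
}

#' Outer median over per-class medians
#'
#' The second stage of the precision statistic, exposed separately so that
#' published per-class median tables can be reduced directly.
#' @param medians numeric vector of per-class median RMSDs.
#' @return their median (even lengths: mean of the two central values).
#' @export
precision_from_medians <- function(medians) stats::median(medians, na.rm = TRUE)

assert_common_entries <- function(results) {
  sets <- results |>
    dplyr::group_by(.data$tool_id) |>
    dplyr::summarise(key = paste(sort(unique(.data$entry_id)), collapse = "|"),
                     .groups = "drop")
  if (length(unique(sets$key)) != 1L) {
    stop("tools were evaluated on different entry sets; comparison invalid",
         call. = FALSE)
  }
}

#' Generality: best-median mark counting
#'
#' For every (class, subgroup) cell -- receptor type grouped by UniProt
#' accession, or warhead class grouped by core variant -- each tool's median
#' RMSD is computed and the tool(s) attaining the minimum receive a mark (all
#' minimisers are marked on exact ties). `marks` is the total number of marks
#' for a tool; the normalised score `G` additionally divides each class's
#' marks by the number of structures the tool evaluated in that class and
#' scales by 100. Higher is better.
#'
#' @param results per-complex results for *all* tools over a common entry set.
#' @param grouping class column (`"warhead_class"` or `"receptor_type"`).
#' @param subgroup subgroup column (`"uniprot_id"` or `"core_variant"`).
#' @param measurement `"best_scored"` or `"best_sampled"`.
#' @return list of class `tool_generality`: `per_subgroup` (tibble of cell
#'   winners) and `generality` (tibble `tool_id`, `marks`, `G`).
#' @export
generality <- function(results, grouping = c("warhead_class", "receptor_type"),
                       subgroup = "uniprot_id",
                       measurement = c("best_scored", "best_sampled")) {
  grouping <- match.arg(grouping)
  col <- measurement_column(measurement)
  assert_common_entries(results)
  cell <- results |>
    dplyr::group_by(.data$tool_id, .data[[grouping]], .data[[subgroup]]) |>
    dplyr::summarise(median_rmsd = stats::median(.data[[col]]),
                     .groups = "drop")
  cell <- cell |>
    dplyr::group_by(.data[[grouping]], .data[[subgroup]]) |>
    dplyr::mutate(mark = .data$median_rmsd <= min(.data$median_rmsd) + 1e-12) |>
    dplyr::ungroup()
  n_class <- results |>
    dplyr::group_by(.data$tool_id, .data[[grouping]]) |>
    dplyr::summarise(n_structures = dplyr::n(), .groups = "drop")
  per_class_marks <- cell |>
    dplyr::group_by(.data$tool_id, .data[[grouping]]) |>
    dplyr::summarise(marks = sum(.data$mark), .groups = "drop") |>
    dplyr::left_join(n_class, by = c("tool_id", grouping))
  gen <- per_class_marks |>
    dplyr::group_by(.data$tool_id) |>
    dplyr::summarise(marks = sum(.data$marks),
                     G = sum(.data$marks / .data$n_structures) * 100,
                     .groups = "drop")
  structure(list(per_subgroup = cell, per_class = per_class_marks,
                 generality = gen, grouping = grouping, subgroup = subgroup,
                 measurement = match.arg(measurement)),
            class = "tool_generality")
}

#' @export
print.tool_generality <- function(x, ...) {
  cat("<tool_generality> axis ", x$grouping, " / subgroup ", x$subgroup,
      ", measurement ", x$measurement, "\n", sep = "")
  print(x$generality)
  invisible(x)
}

#' @method tidy tool_generality
#' @export
tidy.tool_generality <- function(x, ...) x$per_subgroup

#' @method glance tool_generality
#' @export
glance.tool_generality <- function(x, ...) x$generality

#' Robustness: spread of a tool's RMSDs
#'
#' The sample standard deviation of the chosen measurement's RMSDs across all
#' evaluated complexes; a narrower spread means more consistent docking.
#'
#' @param results per-complex results for one or more tools.
#' @param measurement `"best_scored"` or `"best_sampled"`.
#' @return tibble `tool_id`, `n`, `robustness` (Angstrom).
#' @export
robustness <- function(results, measurement = c("best_scored", "best_sampled")) {
  col <- measurement_column(measurement)
  if (any(table(results$tool_id) < 2L)) {
    stop("robustness needs at least 2 results per tool", call. = FALSE)
  }
  results |>
    dplyr::group_by(.data$tool_id) |>
    dplyr::summarise(n = dplyr::n(), robustness = stats::sd(.data[[col]]),
                     .groups = "drop")
}

#' Success/failure profiling counts
#'
#' Per tool: `s_count` (successes, `s1 <= tau`), `f_count` (failures,
#' `s1 > tau` and `s2 > tau`), `s_only` (entries where only this tool
#' succeeded), `f_only` (only this tool failed), `s_ge2` (this tool and at
#' least one other succeeded) and `f_ge2` (this tool and at least one other
#' failed). Requires at least two tools evaluated on a common entry set.
#'
#' @param results per-complex results for all tools.
#' @param tau near-native threshold; defaults to the `tau` recorded in the
#'   results.
#' @return tibble, one row per tool.
#' @export
profile_tools <- function(results, tau = NULL) {
  if (length(unique(results$tool_id)) < 2L) {
    stop("profiling counts need at least two tools", call. = FALSE)
  }
  assert_common_entries(results)
  if (is.null(tau)) tau <- results$tau[1] %||% 2.0
  flags <- results |>
    dplyr::mutate(succ = .data$s1 <= tau,
                  fail = .data$s1 > tau & .data$s2 > tau) |>
    dplyr::group_by(.data$entry_id) |>
    dplyr::mutate(n_succ = sum(.data$succ), n_fail = sum(.data$fail)) |>
    dplyr::ungroup()
  flags |>
    dplyr::group_by(.data$tool_id) |>
    dplyr::summarise(
      s_count = sum(.data$succ),
      f_count = sum(.data$fail),
      s_only = sum(.data$succ & .data$n_succ == 1L),
      f_only = sum(.data$fail & .data$n_fail == 1L),
      s_ge2 = sum(.data$succ & .data$n_succ >= 2L),
      f_ge2 = sum(.data$fail & .data$n_fail >= 2L),
      .groups = "drop")
}

#' P-deviation distribution
#'
#' Bins each tool's `s1 - s2` gaps (the difference between scoring accuracy
#' and sampling accuracy) into a histogram table; the distribution's spread
#' measures the tool's docking error range.
#'
#' @param results per-complex results.
#' @param binwidth bin width in Angstrom.
#' @return tibble `tool_id`, `bin_lo`, `bin_hi`, `bin_mid`, `count`.
#' @export
p_deviation_distribution <- function(results, binwidth = 0.5) {
  top <- max(results$p_deviation, 0) + binwidth
  breaks <- seq(0, top, by = binwidth)
  results |>
    dplyr::group_by(.data$tool_id) |>
    dplyr::reframe({
      h <- graphics::hist(.data$p_deviation, breaks = breaks, plot = FALSE,
                          right = FALSE)
      tibble::tibble(bin_lo = utils::head(breaks, -1),
                     bin_hi = breaks[-1],
                     bin_mid = h$mids, count = h$counts)
    })
}

#' Pairwise Mann-Whitney comparison of two tools
#'
#' Two-sided, tie-corrected rank-sum test on the two tools' RMSD samples.
#' Identical (all-equal) degenerate samples return p = 1 with a warning.
#'
#' @param results per-complex results containing both tools.
#' @param tool_a,tool_b tool identifiers.
#' @param measurement `"best_scored"` or `"best_sampled"`.
#' @return tibble `tool_a`, `tool_b`, `n_a`, `n_b`, `U`, `p_value`.
#' @export
compare_tools <- function(results, tool_a, tool_b,
                          measurement = c("best_scored", "best_sampled")) {
  col <- measurement_column(measurement)
  xa <- results[[col]][results$tool_id == tool_a]
  xb <- results[[col]][results$tool_id == tool_b]
  if (length(xa) < 3L || length(xb) < 3L) {
    stop("need at least 3 results per tool", call. = FALSE)
  }
  if (length(unique(c(xa, xb))) == 1L) {
    warning("degenerate all-equal samples; p = 1 by convention", call. = FALSE)
    return(tibble::tibble(tool_a = tool_a, tool_b = tool_b,
                          n_a = length(xa), n_b = length(xb),
                          U = length(xa) * length(xb) / 2, p_value = 1))
  }
  wt <- suppressWarnings(stats::wilcox.test(xa, xb, exact = FALSE,
                                            correct = TRUE))
  tibble::tibble(tool_a = tool_a, tool_b = tool_b,
                 n_a = length(xa), n_b = length(xb),
                 U = unname(wt$statistic), p_value = wt$p.value)
}

#' All pairwise tool comparisons with Holm adjustment
#'
#' @param results per-complex results.
#' @param measurement `"best_scored"` or `"best_sampled"`.
#' @return tibble of all unordered tool pairs with raw and Holm-adjusted p.
#' @export
pairwise_tool_tests <- function(results,
                                measurement = c("best_scored", "best_sampled")) {
  tools <- sort(unique(results$tool_id))
  pairs <- utils::combn(tools, 2, simplify = FALSE)
  out <- purrr::map_dfr(pairs, function(p)
    compare_tools(results, p[1], p[2], measurement = measurement))
  out$p_holm <- stats::p.adjust(out$p_value, method = "holm")
  out
}

# ---- heat-map table --------------------------------------------------------

HEAT_GREEN <- "#006837"
HEAT_RED <- "#A50026"

interp_color <- function(f, from = HEAT_GREEN, to = HEAT_RED) {
  a <- as.vector(grDevices::col2rgb(from))
  b <- as.vector(grDevices::col2rgb(to))
  v <- vapply(f, function(ff) round(a + ff * (b - a)), numeric(3))
  grDevices::rgb(v[1, ], v[2, ], v[3, ], maxColorValue = 255)
}

#' Colour-coded per-class median table
#'
#' Linear colour interpolation of median RMSDs between a deep-green anchor
#' (values at or below `green_anchor`) and a deep-red anchor (values at or
#' above `red_anchor`), clamped outside the anchors -- the rendering used for
#' benchmark performance tables.
#'
#' @param per_class tibble with `tool_id`, a class column, and `median_rmsd`
#'   (e.g. `precision(...)$per_class`).
#' @param green_anchor,red_anchor colour anchors in Angstrom.
#' @return object of class `covbench_heatmap`: the input with `fraction` and
#'   `color` columns plus a wide value matrix in `$matrix`.
#' @export
heatmap_table <- function(per_class, green_anchor = 1.0, red_anchor = 5.0) {
  class_col <- setdiff(names(per_class),
                       c("tool_id", "n", "median_rmsd", "measurement"))[1]
  frac <- pmin(pmax((per_class$median_rmsd - green_anchor) /
                      (red_anchor - green_anchor), 0), 1)
  tab <- dplyr::mutate(per_class, fraction = frac, color = interp_color(frac))
  wide <- tidyr::pivot_wider(
    per_class[, c("tool_id", class_col, "median_rmsd")],
    names_from = "tool_id", values_from = "median_rmsd")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide[[class_col]]
  structure(list(table = tab, matrix = m, class_col = class_col,
                 green_anchor = green_anchor, red_anchor = red_anchor),
            class = "covbench_heatmap")
}

#' @export
print.covbench_heatmap <- function(x, ...) {
  cat("<covbench_heatmap> anchors ", x$green_anchor, " (green) .. ",
      x$red_anchor, " (red) A\n", sep = "")
  print(round(x$matrix, 2))
  invisible(x)
}
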