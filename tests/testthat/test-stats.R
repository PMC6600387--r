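bcde_csv <- function(name) {
  readr::read_csv(system.file("extdata", "bcde", name, package = "covbench"),
                  show_col_types = FALSE)
}

test_that("precision is the median of within-class medians", {
  # planted small case: tool A has class medians 1, 2, 3 -> P = 2
  res <- tibble::tibble(
    tool_id = "A",
    entry_id = sprintf("e%d", 1:9),
    warhead_class = rep(c("w1", "w2", "w3"), each = 3),
    s1 = c(0.5, 1.0, 1.5, 1.8, 2.0, 2.2, 2.0, 3.0, 4.0),
    s2 = c(0.5, 1.0, 1.5, 1.8, 2.0, 2.2, 2.0, 3.0, 4.0) - 0.25)
  p <- precision(res, "warhead_class", "best_scored")
  expect_equal(sort(p$per_class$median_rmsd), c(1, 2, 3))
  expect_equal(p$precision$precision, 2)
  # best-sampled precision never exceeds best-scored precision
  p2 <- precision(res, "warhead_class", "best_sampled")
  expect_lte(p2$precision$precision, p$precision$precision)
  # singleton class: P equals the single value
  one <- precision(res[1, ], "warhead_class")
  expect_equal(one$precision$precision, 0.5)
  # even-length outer median: mean of the two central values
  expect_equal(precision_from_medians(c(1, 2, 3, 10)), 2.5)
})

test_that("published per-class median tables reduce to the printed bottom lines", {
  wm <- bcde_csv("warhead_medians.csv")
  moe_bs <- wm$median_rmsd[wm$tool == "MOE" & wm$measurement == "best_scored"]
  expect_length(moe_bs, 15)
  expect_equal(precision_from_medians(moe_bs), 1.94)
  cd_bsamp <- wm$median_rmsd[wm$tool == "CovDock" & wm$measurement == "best_sampled"]
  expect_equal(precision_from_medians(cd_bsamp), 1.33)
  rm_ <- bcde_csv("receptor_medians.csv")
  cd_bs <- rm_$median_rmsd[rm_$tool == "CovDock" & rm_$measurement == "best_scored"]
  expect_length(cd_bs, 9)
  expect_equal(precision_from_medians(cd_bs), 1.71)
  gold_bsamp <- rm_$median_rmsd[rm_$tool == "GOLD" & rm_$measurement == "best_sampled"]
  expect_equal(precision_from_medians(gold_bsamp), 1.17)
})

planted_results <- function(winner_map, s_base = 2) {
  # 2 tools x 3 subgroups x 2 entries; winner_map names the better tool per
  # subgroup
  rows <- list()
  for (g in seq_along(winner_map)) {
    for (e in 1:2) {
      for (tool in c("A", "B")) {
        bonus <- if (tool == winner_map[g]) -0.5 else 0.5
        rows[[length(rows) + 1L]] <- tibble::tibble(
          tool_id = tool, entry_id = sprintf("g%de%d", g, e),
          warhead_class = "w1", uniprot_id = sprintf("U%d", g),
          s1 = s_base + bonus, s2 = s_base + bonus - 0.3)
      }
    }
  }
  dplyr::bind_rows(rows)
}

test_that("generality marks the per-subgroup minimum and normalises per class", {
  res <- planted_results(c("A", "A", "B"))
  g <- generality(res, "warhead_class", "uniprot_id", "best_scored")
  marks <- setNames(g$generality$marks, g$generality$tool_id)
  expect_identical(marks[["A"]], 2L)
  expect_identical(marks[["B"]], 1L)
  # G normalisation: marks within one class divided by per-tool class size x100
  expect_equal(sort(g$generality$G), sort(c(2 / 6, 1 / 6) * 100))

  # single tool wins every subgroup
  solo <- res[res$tool_id == "A", ]
  gs <- generality(solo, "warhead_class", "uniprot_id")
  expect_identical(gs$generality$marks, 3L)

  # exact tie: both tools marked, total marks exceed subgroup count
  tied <- res
  tied$s1 <- 2; tied$s2 <- 1.5
  gt <- generality(tied, "warhead_class", "uniprot_id")
  expect_identical(gt$generality$marks, c(3L, 3L))
  expect_gte(sum(gt$generality$marks), 3L)

  # disjoint entry coverage is an invalid comparison
  broken <- res[!(res$tool_id == "B" & res$entry_id == "g1e1"), ]
  expect_error(generality(broken, "warhead_class", "uniprot_id"),
               "different entry sets")
})

test_that("robustness is the sample standard deviation of the RMSDs", {
  res <- tibble::tibble(tool_id = "A", entry_id = c("a", "b"),
                        s1 = c(1, 3), s2 = c(1, 3))
  expect_equal(robustness(res)$robustness, sqrt(2))
  const <- tibble::tibble(tool_id = "A", entry_id = c("a", "b", "c"),
                          s1 = 2, s2 = 2)
  expect_equal(robustness(const)$robustness, 0)
  expect_error(robustness(res[1, ]), "at least 2")
  # planted spread recovered within sampling error
  set.seed(41)
  big <- tibble::tibble(tool_id = "A", entry_id = sprintf("e%d", 1:500),
                        s1 = abs(rnorm(500, 2, 0.5)))
  big$s2 <- big$s1
  expect_equal(robustness(big)$robustness, 0.5, tolerance = 0.1)
})

test_that("profiling counts match an exhaustive recount of a success matrix", {
  set.seed(73)
  n_tools <- 4; n_entries <- 50
  succ <- matrix(runif(n_tools * n_entries) < 0.5, n_tools, n_entries)
  fail <- matrix(runif(n_tools * n_entries) < 0.3, n_tools, n_entries) & !succ
  res <- purrr::map_dfr(seq_len(n_tools), function(t)
    tibble::tibble(
      tool_id = LETTERS[t], entry_id = sprintf("e%02d", seq_len(n_entries)),
      s1 = ifelse(succ[t, ], 1.0, 3.0),
      s2 = ifelse(succ[t, ], 0.8, ifelse(fail[t, ], 2.6, 1.2)),
      tau = 2.0))
  prof <- profile_tools(res)
  for (t in seq_len(n_tools)) {
    row <- prof[prof$tool_id == LETTERS[t], ]
    other_s <- colSums(succ[-t, , drop = FALSE])
    other_f <- colSums(fail[-t, , drop = FALSE])
    expect_identical(row$s_count, sum(succ[t, ]))
    expect_identical(row$f_count, sum(fail[t, ]))
    expect_identical(row$s_only, sum(succ[t, ] & other_s == 0))
    expect_identical(row$f_only, sum(fail[t, ] & other_f == 0))
    expect_identical(row$s_ge2, sum(succ[t, ] & other_s >= 1))
    expect_identical(row$f_ge2, sum(fail[t, ] & other_f >= 1))
  }
  # an entry contributes s_only to at most one tool
  expect_lte(sum(prof$s_only), n_entries)
  expect_error(profile_tools(res[res$tool_id == "A", ]), "at least two")
})

test_that("P-deviation histograms recover planted structure", {
  res0 <- tibble::tibble(tool_id = "A", entry_id = sprintf("e%d", 1:20),
                         s1 = 1.5, s2 = 1.5, p_deviation = 0)
  h0 <- p_deviation_distribution(res0)
  expect_identical(sum(h0$count), 20L)
  expect_identical(h0$count[h0$bin_lo == 0], 20L)

  set.seed(12)
  dev <- c(rnorm(150, 2.25, 0.12), rnorm(150, 4.75, 0.12))
  res2 <- tibble::tibble(tool_id = "B", entry_id = sprintf("e%d", 1:300),
                         s1 = 3 + dev, s2 = 3, p_deviation = dev)
  h2 <- p_deviation_distribution(res2, binwidth = 0.5)
  expect_identical(sum(h2$count), 300L)
  top2 <- h2$bin_mid[order(h2$count, decreasing = TRUE)][1:2]
  expect_setequal(round(top2, 2), c(2.25, 4.75))
})

test_that("Mann-Whitney comparisons behave at the extremes", {
  same <- tibble::tibble(tool_id = rep(c("A", "B"), each = 5),
                         entry_id = rep(sprintf("e%d", 1:5), 2),
                         s1 = 1, s2 = 1)
  expect_warning(out <- compare_tools(same, "A", "B"), "degenerate")
  expect_equal(out$p_value, 1)

  sep <- tibble::tibble(tool_id = rep(c("A", "B"), each = 3),
                        entry_id = rep(sprintf("e%d", 1:3), 2),
                        s1 = c(1, 2, 3, 10, 11, 12), s2 = s1)
  out2 <- compare_tools(sep, "A", "B")
  expect_equal(unname(out2$U), 0)   # complete separation
  expect_lt(out2$p_value, 0.1)

  ranked <- pairwise_tool_tests(sep)
  expect_true(all(ranked$p_holm >= ranked$p_value))
})

test_that("heat-map colours interpolate linearly and clamp at the anchors", {
  per_class <- tibble::tibble(
    tool_id = "A", warhead_class = c("w1", "w2", "w3"),
    n = 1L, median_rmsd = c(0.5, 6, 3))
  hm <- heatmap_table(per_class)
  expect_identical(hm$table$fraction, c(0, 1, 0.5))
  deep_green <- hm$table$color[1]
  deep_red <- hm$table$color[2]
  mid <- hm$table$color[3]
  expect_identical(toupper(deep_green), "#006837")
  expect_identical(toupper(deep_red), "#A50026")
  rgb_mid <- grDevices::col2rgb(mid)
  rgb_expected <- round((grDevices::col2rgb(deep_green) +
                           grDevices::col2rgb(deep_red)) / 2)
  expect_true(all(abs(rgb_mid - rgb_expected) <= 1))
})
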