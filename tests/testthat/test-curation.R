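entry_with <- function(entry_id = "E1", resolution = 2.0, ligand = NULL,
                       n_links = 1L, nucleic = FALSE, cofactor_dist = NULL,
                       anchor = "CYS") {
  e <- tiny_entry(entry_id = entry_id, resolution = resolution,
                  warhead_class = if (anchor == "CYS") "Nitrile(cys)"
                                  else "Lactam")
  if (!is.null(ligand)) {
    e$reference_ligand <- ligand
    e$pre_reaction_ligand <- ligand
  }
  e$n_links <- n_links
  if (nucleic) {
    e$context <- dplyr::bind_rows(e$context, tibble::tibble(
      name = "P", element = "P", resid = "DA", chain = "B", resno = 1L,
      x = 50, y = 50, z = 50, category = "nucleic"))
  }
  if (!is.null(cofactor_dist)) {
    lig1 <- ligand_coords(e$reference_ligand)[1, ]
    e$context <- dplyr::bind_rows(e$context, tibble::tibble(
      name = "FE", element = "C", resid = "NAD", chain = "A", resno = 500L,
      # placed on the far side of the ligand's first atom so the minimum
      # ligand-cofactor distance is exactly cofactor_dist
      x = lig1[1] - cofactor_dist, y = lig1[2], z = lig1[3],
      category = "cofactor"))
  }
  e
}

test_that("resolution filter is strict at the cutoff and flags missing values", {
  entries <- list(entry_with("a", 2.1), entry_with("b", 3.0),
                  entry_with("c", 2.99))
  kept <- filter_resolution(entries)
  expect_identical(vapply(kept, `[[`, character(1), "entry_id"), c("a", "c"))
  expect_identical(filter_resolution(list()), list())

  # derived recount: uniform resolutions, retained count equals brute count
  set.seed(31)
  res <- runif(100, 1, 5)
  panel <- lapply(seq_along(res), function(k)
    entry_with(sprintf("r%03d", k), res[k]))
  expect_length(filter_resolution(panel), sum(res < 3.0))

  e_na <- entry_with("x", 2.0)
  e_na$resolution <- NA_real_
  rep <- run_curation(list(e_na))
  expect_identical(rep$table$failure_reason, "no resolution")
})

test_that("ligand size filter applies the heavy-atom and rotatable-bond bounds", {
  ethanol <- cov_ligand(data.frame(element = c("C", "O"), x = 0:1, y = 0, z = 0),
                        data.frame(i = 1, j = 2, order = 1))
  hexane <- chain_alkane(6)        # 6 heavy, 3 rotatable: included
  mega <- chain_alkane(34)         # 31 rotatable: excluded (strict < 30)
  entries <- list(entry_with("small", ligand = ethanol),
                  entry_with("hex", ligand = hexane),
                  entry_with("mega", ligand = mega))
  kept <- filter_ligand_size(entries)
  expect_identical(vapply(kept, `[[`, character(1), "entry_id"), "hex")
})

test_that("anchor filter requires a single covalent linkage", {
  entries <- list(entry_with("one", n_links = 1L),
                  entry_with("two", n_links = 2L))
  kept <- filter_anchor(entries)
  expect_identical(vapply(kept, `[[`, character(1), "entry_id"), "one")
})

test_that("context filter excludes nucleic acids and near cofactors", {
  entries <- list(entry_with("clean"),
                  entry_with("dna", nucleic = TRUE),
                  entry_with("cof_near", cofactor_dist = 7.9),
                  entry_with("cof_far", cofactor_dist = 8.1))
  kept <- filter_context(entries)
  expect_identical(vapply(kept, `[[`, character(1), "entry_id"),
                   c("clean", "cof_far"))
})

test_that("the full pipeline attributes each exclusion to its planted filter", {
  panel <- list(
    entry_with("ok1"), entry_with("ok2"), entry_with("ok3"),
    entry_with("bad_res", resolution = 3.4),
    entry_with("bad_dna", nucleic = TRUE),
    entry_with("bad_link", n_links = 2L),
    entry_with("bad_cof", cofactor_dist = 5.0),
    entry_with("bad_small", ligand = cov_ligand(
      data.frame(element = c("C", "N"), x = 0:1, y = 0, z = 0),
      data.frame(i = 1, j = 2, order = 3))),
    entry_with("bad_rot", ligand = chain_alkane(40)),
    entry_with("ok4"))
  rep <- run_curation(panel)
  tab <- rep$table
  expect_identical(sort(vapply(rep$retained, `[[`, character(1), "entry_id")),
                   c("ok1", "ok2", "ok3", "ok4"))
  attribution <- setNames(tab$first_failure, tab$entry_id)
  expect_identical(attribution[["bad_res"]], "resolution")
  expect_identical(attribution[["bad_dna"]], "nucleic")
  expect_identical(attribution[["bad_link"]], "single_link")
  expect_identical(attribution[["bad_cof"]], "cofactor")
  expect_identical(attribution[["bad_small"]], "ligand_size")
  expect_identical(attribution[["bad_rot"]], "ligand_size")
  expect_true(all(is.na(attribution[c("ok1", "ok2", "ok3", "ok4")])))

  # counts along the pipeline never increase
  expect_true(all(diff(rep$counts$n) <= 0))

  # all-clean panel: everything retained
  clean <- run_curation(panel[c(1, 2, 3, 10)])
  expect_length(clean$retained, 4)
})

test_that("the retained set is order-insensitive and filters are monotone", {
  set.seed(99)
  panel <- list(entry_with("a"), entry_with("b", resolution = 3.6),
                entry_with("c", cofactor_dist = 4), entry_with("d"),
                entry_with("e", n_links = 3L))
  ids <- function(x) sort(vapply(x, `[[`, character(1), "entry_id"))
  # set composition is the same whichever filter order is applied
  seq1 <- filter_ligand_size(filter_context(filter_anchor(
    filter_resolution(panel))))
  seq2 <- filter_resolution(filter_anchor(filter_context(
    filter_ligand_size(panel))))
  expect_identical(ids(seq1), ids(seq2))
  expect_identical(ids(seq1), ids(run_curation(panel)$retained))
  # adding a filter never increases the retained count
  expect_lte(length(seq1), length(filter_resolution(panel)))
})
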