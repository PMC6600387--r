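tax <- warhead_taxonomy()

test_that("canonical chemotypes classify to the expected classes", {
  acrylamide <- warhead_example_ligand("Alkene(cys)")
  cl <- classify(acrylamide, "CYS", tax)
  expect_identical(cl$warhead_class, "Alkene(cys)")
  expect_identical(cl$reaction_class, "Nucleophilic Addition")
  expect_true(cl$link_atom_index %in% cl$matched_atoms)

  nitrile <- warhead_example_ligand("Nitrile(cys)")
  expect_identical(classify(nitrile, "CYS", tax)$warhead_class, "Nitrile(cys)")
  expect_identical(classify(nitrile, "SER", tax)$warhead_class, "Nitrile(ser)")

  methane <- cov_ligand(data.frame(element = "C", x = 0, y = 0, z = 0), NULL)
  un <- classify(methane, "CYS", tax)
  expect_identical(un$warhead_class, "unclassified warhead")
  expect_length(un$matched_atoms, 0)
})

test_that("every shipped class example self-recognises (15/15)", {
  for (cl in warhead_classes()) {
    got <- classify(warhead_example_ligand(cl), warhead_anchor(cl), tax)
    expect_identical(got$warhead_class, cl,
                     info = paste("example for", cl))
  }
})

test_that("classification is a function and frequencies partition the set", {
  set.seed(5)
  classes <- sample(warhead_classes(), 40, replace = TRUE)
  entries <- lapply(seq_along(classes), function(k)
    tiny_entry(entry_id = sprintf("W%02d", k), warhead_class = classes[k],
               seed = k))
  entries <- classify_entries(entries, tax)
  freq <- tabulate_frequencies(entries)
  expect_identical(sum(freq$warhead$n), 40L)
  expect_identical(sum(freq$reaction$n), 40L)
  expect_identical(freq$total, 40L)
  got <- vapply(entries, `[[`, character(1), "warhead_class")
  expect_identical(sort(unique(got)), sort(unique(classes)))
  expect_identical(as.integer(table(got)[sort(unique(classes))]),
                   as.integer(table(classes)[sort(unique(classes))]))

  single <- tabulate_frequencies(entries[1])
  expect_identical(single$warhead$n, 1L)
})

test_that("nitrile addition yields a thioimidate with an S-C single bond", {
  lig <- warhead_example_ligand("Nitrile(cys)")
  res <- apply_reaction(lig, reaction_template("Nitrile(cys)"), anchor = "CYS")
  add <- res$adduct
  expect_identical(n_heavy_atoms(add), n_heavy_atoms(lig) + 1L)
  expect_identical(add$atoms$element[res$anchor_atom_index], "S")
  sc <- add$bonds[(add$bonds$i == res$anchor_atom_index |
                   add$bonds$j == res$anchor_atom_index), ]
  expect_identical(nrow(sc), 1L)
  expect_identical(sc$order, 1L)
  # the former triple bond is now a double bond
  cn <- add$bonds[add$bonds$i == res$link_atom_index |
                  add$bonds$j == res$link_atom_index, ]
  expect_true(2L %in% cn$order)
})

test_that("beta-lactam ring opening cleaves the ring and forms the ester", {
  lig <- warhead_example_ligand("Lactam")
  ring_count <- function(l) sum(covbench:::bond_in_ring(l))
  expect_identical(ring_count(lig), 4L)
  res <- apply_reaction(lig, reaction_template("Lactam"), anchor = "SER")
  add <- res$adduct
  expect_identical(ring_count(add), 0L)              # ring bond cleaved
  expect_identical(add$atoms$element[res$anchor_atom_index], "O")
  expect_identical(n_heavy_atoms(add), n_heavy_atoms(lig) + 1L)
})

test_that("templates without leaving groups round-trip to an isomorphic graph", {
  roundtrip <- c("Nitrile(cys)", "Nitrile(ser)", "Alkene(cys)", "Alkyne",
                 "Carbonyl(cys)", "Carbonyl(ser)", "Guanyl", "Boronic acid",
                 "Heterocyclic", "Lactam", "Lactone", "Sulfydryl")
  for (cl in roundtrip) {
    lig <- warhead_example_ligand(cl)
    t <- reaction_template(cl)
    fwd <- apply_reaction(lig, t, anchor = warhead_anchor(cl))
    back <- apply_reaction(fwd$adduct, t, anchor = warhead_anchor(cl),
                           direction = "reverse")
    expect_true(graphs_isomorphic(back$adduct, lig),
                info = paste("round-trip for", cl))
  }
})

test_that("template matching errors distinguish no-match from ambiguity", {
  methane <- cov_ligand(data.frame(element = "C", x = 0, y = 0, z = 0), NULL)
  expect_error(apply_reaction(methane, reaction_template("Nitrile(cys)"), "CYS"),
               "does not apply")
  dinitrile <- cov_ligand(
    data.frame(element = c("N", "C", "C", "C", "N"), x = 1:5, y = 0, z = 0),
    data.frame(i = c(1, 2, 3, 4), j = c(2, 3, 4, 5), order = c(3, 1, 1, 3)))
  expect_error(apply_reaction(dinitrile, reaction_template("Nitrile(cys)"), "CYS"),
               "ambiguous")
})

test_that("RXN files round-trip through write_rxn/read_rxn", {
  t <- reaction_template("Lactam")
  path <- withr::local_tempfile(fileext = ".rxn")
  write_rxn(t, path)
  t2 <- read_rxn(path)
  expect_identical(length(t2$reactants), length(t$reactants))
  expect_identical(t2$products[[1]]$maps, t$products[[1]]$maps)
  expect_identical(t2$reactants[[1]]$ligand$atoms$element,
                   t$reactants[[1]]$ligand$atoms$element)
})
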