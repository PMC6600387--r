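# Warhead taxonomy: reaction classes, warhead classes and core substructure
# patterns, loaded from an editable YAML rule file. Classification picks the
# highest-priority rule whose anchor matches and whose core pattern occurs in
# the ligand graph; ties inside a rule resolve by proximity of the matched
# core's link atom to the anchor nucleophile.

taxonomy_cache <- new.env(parent = emptyenv())

pattern_from_spec <- function(p) {
  atoms <- tibble::tibble(element = as.character(unlist(p$atoms)),
                          x = 0, y = 0, z = 0)
  b <- p$bonds
  bonds <- if (length(b)) {
    m <- do.call(rbind, lapply(b, as.integer))
    tibble::tibble(i = m[, 1], j = m[, 2], order = m[, 3])
  } else NULL
  list(graph = cov_ligand(atoms, bonds, name = p$smarts %||% "pattern"),
       link_atom = as.integer(p$link_atom),
       max_deg = if (!is.null(p$max_deg)) as.integer(unlist(p$max_deg)) else NULL,
       smarts = p$smarts %||% NA_character_)
}

#' Load the warhead taxonomy
#'
#' Reads the rule file defining the covalent-reaction/warhead hierarchy: each
#' rule names a warhead class, its reaction class and type, the anchor residue
#' it reacts with, a priority, and one or more core substructure patterns
#' (explicit element/bond graphs, annotated with a SMARTS string). The default
#' taxonomy ships with the package and covers the 15 warhead classes of the
#' benchmark: nitriles, Michael-acceptor alkenes, carbonyls, alkynes, guanyl
#' groups, boronic acids, halides, phosphonyl groups, epoxide/aziridine
#' heterocycles, lactams, lactones, thiols/disulfides and catch-all
#' substitutions.
#'
#' @param path YAML rule file; defaults to the shipped taxonomy.
#' @return object of class `warhead_taxonomy`: a list of rules sorted by
#'   decreasing priority.
#' @export
warhead_taxonomy <- function(path = covbench_config_file("warhead_taxonomy.yaml")) {
  key <- normalizePath(path)
  if (!is.null(taxonomy_cache[[key]])) return(taxonomy_cache[[key]])
  raw <- yaml::read_yaml(path)$rules
  rules <- lapply(raw, function(r) {
    list(warhead_class = r$warhead_class,
         reaction_class = r$reaction_class,
         reaction_type = r$reaction_type,
         anchor = toupper(r$anchor),
         priority = as.integer(r$priority),
         patterns = lapply(r$patterns, pattern_from_spec))
  })
  pr <- vapply(rules, `[[`, integer(1), "priority")
  anchors <- vapply(rules, `[[`, character(1), "anchor")
  cls <- vapply(rules, `[[`, character(1), "warhead_class")
  if (anyDuplicated(paste(cls, anchors))) {
    stop("taxonomy has duplicate (warhead_class, anchor) pairs", call. = FALSE)
  }
  tax <- structure(rules[order(pr, decreasing = TRUE)],
                   class = "warhead_taxonomy")
  taxonomy_cache[[key]] <- tax
  tax
}

#' @export
print.warhead_taxonomy <- function(x, ...) {
  cat("<warhead_taxonomy> ", length(x), " rules, ",
      sum(vapply(x, function(r) length(r$patterns), integer(1))),
      " core patterns\n", sep = "")
  invisible(x)
}

#' Classify a covalent ligand's warhead
#'
#' Finds the highest-priority taxonomy rule whose anchor matches and whose
#' core pattern occurs in the ligand. When several embeddings of the winning
#' rule exist and the anchor nucleophile's coordinates are supplied, the core
#' whose link atom lies closest to the nucleophile is reported.
#'
#' @param ligand a [cov_ligand()] (pre-reaction form).
#' @param anchor `"CYS"` or `"SER"`.
#' @param taxonomy a [warhead_taxonomy()].
#' @param anchor_xyz optional length-3 coordinates of the anchor SG/OG used to
#'   break ties between multiple matched cores.
#' @return object of class `warhead_classification` with fields
#'   `warhead_class`, `reaction_class`, `reaction_type`, `matched_atoms`
#'   (ligand atom indices of the core) and `link_atom_index`. An unmatched
#'   ligand returns `warhead_class = "unclassified warhead"` rather than an
#'   error.
#' @examples
#' tax <- warhead_taxonomy()
#' classify(warhead_example_ligand("Alkene(cys)"), "CYS", tax)$warhead_class
#' @export
classify <- function(ligand, anchor = c("CYS", "SER"),
                     taxonomy = warhead_taxonomy(), anchor_xyz = NULL) {
  anchor <- match.arg(anchor)
  for (rule in taxonomy) {
    if (rule$anchor != anchor) next
    hits <- list()
    for (pat in rule$patterns) {
      ms <- match_substructure(pat$graph, ligand, max_deg = pat$max_deg)
      for (m in ms) hits[[length(hits) + 1L]] <- list(map = m, pat = pat)
    }
    if (!length(hits)) next
    pick <- hits[[1]]
    if (length(hits) > 1L && !is.null(anchor_xyz)) {
      xyz <- ligand_coords(ligand)
      d <- vapply(hits, function(h)
        sqrt(sum((xyz[h$map[h$pat$link_atom], ] - anchor_xyz)^2)), numeric(1))
      pick <- hits[[which.min(d)]]
    }
    return(structure(list(
      warhead_class = rule$warhead_class,
      reaction_class = rule$reaction_class,
      reaction_type = rule$reaction_type,
      anchor = anchor,
      matched_atoms = sort(pick$map),
      link_atom_index = pick$map[pick$pat$link_atom],
      smarts = pick$pat$smarts), class = "warhead_classification"))
  }
  structure(list(warhead_class = "unclassified warhead",
                 reaction_class = NA_character_,
                 reaction_type = NA_character_,
                 anchor = anchor, matched_atoms = integer(),
                 link_atom_index = NA_integer_, smarts = NA_character_),
            class = "warhead_classification")
}

#' @export
print.warhead_classification <- function(x, ...) {
  cat("<warhead_classification> ", x$warhead_class,
      if (!is.na(x$reaction_class)) paste0(" (", x$reaction_type, ")"),
      "\n", sep = "")
  invisible(x)
}

#' Classify every entry of a benchmark
#'
#' Runs [classify()] on each entry's pre-reaction ligand (falling back to the
#' reference ligand) against its anchor and writes the resulting
#' `warhead_class`/`reaction_class` labels into the entries.
#'
#' @param entries list of [benchmark_entry()] objects.
#' @param taxonomy a [warhead_taxonomy()].
#' @return the entries with classification fields filled in.
#' @export
classify_entries <- function(entries, taxonomy = warhead_taxonomy()) {
  lapply(entries, function(e) {
    lig <- e$pre_reaction_ligand %||% e$reference_ligand
    cl <- classify(lig, e$anchor$residue_name, taxonomy,
                   anchor_xyz = anchor_atom_xyz(e$anchor, e$anchor$link_atom))
    e$warhead_class <- cl$warhead_class
    e$reaction_class <- cl$reaction_class
    e
  })
}

#' Tabulate warhead and reaction-class frequencies
#'
#' Counts classified entries per warhead class and per reaction class. Input
#' may be a list of classified [benchmark_entry()] objects or a data frame
#' with `warhead_class` (and optionally `reaction_class`) columns. Counts
#' partition the input: each entry is counted exactly once and both margins
#' sum to the number of entries.
#'
#' @param entries classified entries or a metadata data frame.
#' @return list with tibbles `warhead` (`warhead_class`, `n`) and `reaction`
#'   (`reaction_class`, `n`) plus the scalar `total`.
#' @export
tabulate_frequencies <- function(entries) {
  tbl <- if (is.data.frame(entries)) tibble::as_tibble(entries) else {
    purrr::map_dfr(entries, function(e)
      tibble::tibble(warhead_class = e$warhead_class %||% NA_character_,
                     reaction_class = e$reaction_class %||% NA_character_))
  }
  warhead <- dplyr::count(tbl, .data$warhead_class, name = "n")
  reaction <- if ("reaction_class" %in% names(tbl)) {
    dplyr::count(tbl, .data$reaction_class, name = "n")
  } else NULL
  list(warhead = warhead, reaction = reaction, total = nrow(tbl))
}

# ---- shipped example chemotypes -------------------------------------------

ring_coords <- function(n, r = 1.2, z = 0) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(r * cos(th), r * sin(th), z)
}

zigzag_coords <- function(n, start = c(0, 0, 0)) {
  idx <- seq_len(n) - 1
  cbind(start[1] + 1.3 * idx, start[2] + 0.5 * (idx %% 2), start[3])
}

build_example <- function(elements, bonds, coords, name) {
  cov_ligand(tibble::tibble(element = elements, x = coords[, 1],
                            y = coords[, 2], z = coords[, 3]),
             tibble::tibble(i = bonds[, 1], j = bonds[, 2], order = bonds[, 3]),
             name = name)
}

#' Example ligand for a warhead class
#'
#' Returns a small covalent ligand carrying the named class's core plus an
#' inert alkyl scaffold, with rough 3D coordinates. These chemotypes double as
#' the self-recognition fixtures for the shipped taxonomy and as the ligands
#' fabricated by the synthetic benchmark generator.
#'
#' @param warhead_class one of the 15 shipped class labels (see
#'   [warhead_taxonomy()]).
#' @return a [cov_ligand()].
#' @export
warhead_example_ligand <- function(warhead_class) {
  b <- function(...) matrix(c(...), ncol = 3, byrow = TRUE)
  switch(warhead_class,
    "Nitrile(cys)" = , "Nitrile(ser)" = build_example(
      c("C", "C", "C", "C", "N"),
      b(1, 2, 1, 2, 3, 1, 3, 4, 1, 4, 5, 3),
      zigzag_coords(5), "pentanenitrile"),
    "Alkene(cys)" = build_example(
      c("C", "C", "C", "O", "N", "C"),
      b(1, 2, 2, 2, 3, 1, 3, 4, 2, 3, 5, 1, 5, 6, 1),
      rbind(zigzag_coords(3), c(2.6, 1.7, 0), c(3.9, 0.4, 0), c(5.2, 0.9, 0)),
      "N-methylacrylamide"),
    "Carbonyl(cys)" = build_example(
      c("C", "C", "C", "C", "O"),
      b(1, 2, 1, 2, 3, 1, 3, 4, 1, 4, 5, 2),
      zigzag_coords(5), "butanal"),
    "Alkyne" = build_example(
      c("C", "C", "C", "C", "C"),
      b(1, 2, 3, 2, 3, 1, 3, 4, 1, 4, 5, 1),
      zigzag_coords(5), "pent-1-yne"),
    "Guanyl" = build_example(
      c("C", "N", "C", "N", "N"),
      b(1, 2, 1, 2, 3, 2, 3, 4, 1, 3, 5, 1),
      rbind(zigzag_coords(3), c(3.0, 1.8, 0), c(3.4, -0.9, 0)),
      "methylguanidine"),
    "Carbonyl(ser)" = build_example(
      c("C", "C", "O", "C", "O", "N", "C"),
      b(1, 2, 1, 2, 3, 2, 2, 4, 1, 4, 5, 2, 4, 6, 1, 6, 7, 1),
      rbind(zigzag_coords(2), c(1.5, 1.8, 0), zigzag_coords(2, c(2.6, 0, 0)),
            c(3.2, 1.8, 0), c(5.0, 0.4, 0)),
      "alpha-ketoamide"),
    "Boronic acid" = build_example(
      c("C", "C", "B", "O", "O"),
      b(1, 2, 1, 2, 3, 1, 3, 4, 1, 3, 5, 1),
      rbind(zigzag_coords(3), c(3.3, 1.8, 0), c(3.9, -0.8, 0)),
      "ethylboronic acid"),
    "Halide" = build_example(
      c("C", "C", "O", "C", "Cl"),
      b(1, 2, 1, 2, 3, 2, 2, 4, 1, 4, 5, 1),
      rbind(zigzag_coords(2), c(1.4, 1.8, 0), c(2.6, 0, 0), c(3.6, 1.2, 0)),
      "chloromethyl ketone"),
    "Others" = build_example(
      c("C", "C", "C", "S", "O", "O", "F"),
      b(1, 2, 1, 2, 3, 1, 3, 4, 1, 4, 5, 2, 4, 6, 2, 4, 7, 1),
      rbind(zigzag_coords(4), c(4.0, 1.9, 0.6), c(4.0, 1.9, -0.6),
            c(5.2, 0.2, 0)),
      "propylsulfonyl fluoride"),
    "Phosphonyl" = build_example(
      c("C", "P", "O", "O", "O", "C"),
      b(1, 2, 1, 2, 3, 2, 2, 4, 1, 2, 5, 1, 5, 6, 1),
      rbind(zigzag_coords(2), c(1.4, 1.9, 0), c(1.9, -1.2, 0.8),
            c(2.4, -0.4, -1.2), c(3.7, -0.9, -1.4)),
      "methylphosphonate ester"),
    "Heterocyclic" = build_example(
      c("C", "C", "C", "C", "O"),
      b(1, 2, 1, 2, 3, 1, 3, 4, 1, 3, 5, 1, 4, 5, 1),
      rbind(zigzag_coords(3), c(3.4, 1.3, 0.4), c(3.9, 0.1, -0.4)),
      "alkyl epoxide"),
    "Lactam" = build_example(
      c("C", "O", "N", "C", "C", "C"),
      b(1, 2, 2, 1, 3, 1, 3, 4, 1, 4, 5, 1, 5, 1, 1, 3, 6, 1),
      rbind(c(0, 0, 0), c(-0.8, 1.0, 0), c(1.5, 0, 0), c(1.5, -1.5, 0),
            c(0, -1.5, 0), c(2.3, 1.1, 0)),
      "N-methyl beta-lactam"),
    "Lactone" = {
      ring <- ring_coords(5, r = 1.25)
      build_example(
        c("C", "O", "O", "C", "C", "C", "C"),
        b(1, 2, 2, 1, 3, 1, 3, 4, 1, 4, 5, 1, 5, 6, 1, 6, 1, 1, 6, 7, 1),
        rbind(ring[1, ], c(-0.5, 1.5, 0.4), ring[2, ], ring[3, ], ring[4, ],
              ring[5, ], c(2.4, -0.9, 0)),
        "gamma-butyrolactone with methyl")
    },
    "Sulfydryl" = build_example(
      c("C", "C", "C", "C", "S"),
      b(1, 2, 1, 2, 3, 1, 3, 4, 1, 4, 5, 1),
      zigzag_coords(5), "butanethiol"),
    stop("unknown warhead class: ", warhead_class, call. = FALSE))
}

#' The 15 shipped warhead class labels
#' @return character vector.
#' @export
warhead_classes <- function() {
  c("Nitrile(cys)", "Alkene(cys)", "Carbonyl(cys)", "Alkyne", "Guanyl",
    "Nitrile(ser)", "Carbonyl(ser)", "Boronic acid", "Halide", "Others",
    "Phosphonyl", "Heterocyclic", "Lactam", "Lactone", "Sulfydryl")
}

#' Anchor residue expected by each warhead class
#' @param warhead_class class label(s).
#' @return `"CYS"` or `"SER"` per class.
#' @export
warhead_anchor <- function(warhead_class) {
  ser <- c("Nitrile(ser)", "Carbonyl(ser)", "Boronic acid", "Phosphonyl",
           "Lactam", "Lactone")
  ifelse(warhead_class %in% ser, "SER", "CYS")
}
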