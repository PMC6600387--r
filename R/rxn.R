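# MDL RXN reaction templates describing warhead -> adduct transformations.
# A template's left side holds the ligand warhead fragment plus the anchor
# nucleophile (a single S or O atom carrying atom-map 99, standing in for the
# cysteine SG / serine OG); the right side holds the covalent adduct. The MOL
# blocks inside the RXN are parsed with ChemmineR's ctab reader; the atom-atom
# mapping column (61-63), which ChemmineR drops, is sliced from the raw lines.

NUCLEOPHILE_MAP <- 99L

parse_mol_block <- function(lines) {
  natoms <- as.integer(substr(lines[4], 1, 3))
  nbonds <- as.integer(substr(lines[4], 4, 6))
  atom_lines <- lines[5:(4 + natoms)]
  maps <- vapply(atom_lines, function(l) {
    v <- suppressWarnings(as.integer(trimws(substr(l, 61, 63))))
    if (is.na(v)) 0L else v
  }, integer(1), USE.NAMES = FALSE)
  lig <- if (natoms >= 2L && nbonds >= 1L) {
    tmp <- tempfile(fileext = ".sdf")
    writeLines(c(lines, "$$$$"), tmp)
    sdf_to_ligand(ChemmineR::read.SDFset(tmp)[[1]], name = trimws(lines[1]))
  } else {
    # ChemmineR's ctab reader rejects bond-less records (the single-atom
    # nucleophile fragment); slice the fixed columns directly
    atoms <- tibble::tibble(
      element = trimws(substr(atom_lines, 32, 34)),
      x = as.numeric(substr(atom_lines, 1, 10)),
      y = as.numeric(substr(atom_lines, 11, 20)),
      z = as.numeric(substr(atom_lines, 21, 30)))
    cov_ligand(atoms, NULL, name = trimws(lines[1]))
  }
  if (length(maps) != n_heavy_atoms(lig)) {
    stop("hydrogens are not supported in reaction templates", call. = FALSE)
  }
  list(ligand = lig, maps = maps)
}

#' Read an MDL RXN reaction template
#'
#' @param path `.rxn` file with mapped reactant and product MOL blocks.
#' @return object of class `rxn_template` with `reactants` and `products`
#'   lists, each element holding a [cov_ligand()] `ligand` and its atom-map
#'   vector `maps`. Map 99 marks the anchor nucleophile atom.
#' @export
read_rxn <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "$RXN")) stop("not an RXN file: ", path, call. = FALSE)
  counts <- as.integer(strsplit(trimws(lines[5]), "\\s+")[[1]])
  nr <- counts[1]; np <- counts[2]
  mol_starts <- which(startsWith(lines, "$MOL")) + 1L
  if (length(mol_starts) != nr + np) {
    stop("RXN declares ", nr + np, " molecules but has ", length(mol_starts),
         call. = FALSE)
  }
  mol_ends <- c(mol_starts[-1] - 2L, length(lines))
  mols <- lapply(seq_along(mol_starts), function(k)
    parse_mol_block(lines[mol_starts[k]:mol_ends[k]]))
  structure(list(name = trimws(lines[2]),
                 reactants = mols[seq_len(nr)],
                 products = mols[nr + seq_len(np)]),
            class = "rxn_template")
}

#' @export
print.rxn_template <- function(x, ...) {
  cat("<rxn_template> ", x$name, ": ", length(x$reactants), " reactant(s) -> ",
      length(x$products), " product(s)\n", sep = "")
  invisible(x)
}

mol_block_text <- function(lig, maps, title) {
  n <- nrow(lig$atoms); nb <- nrow(lig$bonds)
  c(title, "  covbench", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb),
    vapply(seq_len(n), function(k) sprintf(
      "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0%3d  0  0",
      lig$atoms$x[k], lig$atoms$y[k], lig$atoms$z[k], lig$atoms$element[k],
      maps[k]), character(1)),
    vapply(seq_len(nb), function(k) sprintf(
      "%3d%3d%3d  0", lig$bonds$i[k], lig$bonds$j[k], lig$bonds$order[k]),
      character(1)),
    "M  END")
}

#' Write an MDL RXN reaction template
#' @param template an `rxn_template`.
#' @param path output `.rxn` file.
#' @return `path`, invisibly.
#' @export
write_rxn <- function(template, path) {
  lines <- c("$RXN", template$name, "  covbench", "",
             sprintf("%3d%3d", length(template$reactants),
                     length(template$products)))
  for (m in c(template$reactants, template$products)) {
    lines <- c(lines, "$MOL", mol_block_text(m$ligand, m$maps, m$ligand$name))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Shipped reaction template for a warhead class
#'
#' @param warhead_class one of the shipped class labels.
#' @return an `rxn_template` read from the package's `extdata/rxn/` library.
#' @export
reaction_template <- function(warhead_class) {
  slug <- gsub("_$", "", gsub("[^a-z]+", "_", tolower(warhead_class)))
  read_rxn(covbench_config_file(file.path("rxn", paste0(slug, ".rxn"))))
}

rxn_side_merge <- function(side) {
  # merge a side's molecules into one graph with a single map vector
  atoms <- dplyr::bind_rows(lapply(side, function(m) m$ligand$atoms))
  offset <- 0L
  bonds <- list(); maps <- integer(0)
  for (m in side) {
    b <- m$ligand$bonds
    if (nrow(b)) {
      b$i <- b$i + offset; b$j <- b$j + offset
      bonds[[length(bonds) + 1L]] <- b
    }
    maps <- c(maps, m$maps)
    offset <- offset + n_heavy_atoms(m$ligand)
  }
  list(ligand = cov_ligand(atoms, if (length(bonds)) dplyr::bind_rows(bonds)
                           else NULL, name = "side"),
       maps = maps)
}

bond_key <- function(mi, mj) paste(pmin(mi, mj), pmax(mi, mj))

side_bond_table <- function(side) {
  lig <- side$ligand; maps <- side$maps
  if (!nrow(lig$bonds)) {
    return(tibble::tibble(key = character(), mi = integer(), mj = integer(),
                          order = integer()))
  }
  mi <- maps[lig$bonds$i]; mj <- maps[lig$bonds$j]
  keep <- mi > 0L & mj > 0L
  lo <- pmin(mi, mj)[keep]; hi <- pmax(mi, mj)[keep]
  tibble::tibble(key = paste(lo, hi), mi = lo, mj = hi,
                 order = lig$bonds$order[keep])
}

#' Apply a covalent reaction template to a ligand
#'
#' Rewrites the ligand graph according to the template's mapped
#' reactant-to-product edits: bond orders change, template leaving groups
#' (mapped atoms absent from the product side) are removed, and in the forward
#' direction a new anchor nucleophile atom (S for CYS, O for SER) is attached
#' by a single bond to the template-designated warhead atom. In the reverse
#' direction the transformation is undone and the nucleophile atom removed,
#' restoring the pre-reaction ligand.
#'
#' @param ligand a [cov_ligand()]; pre-reaction form for `direction =
#'   "forward"`, covalent adduct (including the nucleophile atom) for
#'   `"reverse"`.
#' @param template an `rxn_template` from [read_rxn()].
#' @param anchor `"CYS"` or `"SER"`, or an [anchor_residue()] whose link-atom
#'   coordinates place the added nucleophile.
#' @param direction `"forward"` (warhead -> adduct) or `"reverse"`.
#' @return list with `adduct` (the rewritten [cov_ligand()]),
#'   `link_atom_index` (ligand atom bonded to the nucleophile) and
#'   `anchor_atom_index` (index of the nucleophile atom in the adduct, or `NA`
#'   after reverse application).
#' @export
apply_reaction <- function(ligand, template, anchor = "CYS",
                           direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  anchor_name <- if (inherits(anchor, "anchor_residue")) anchor$residue_name
                 else toupper(anchor)
  from <- rxn_side_merge(template$reactants)
  to <- rxn_side_merge(template$products)
  if (direction == "reverse") { tmp <- from; from <- to; to <- tmp }

  nuc_from <- which(from$maps == NUCLEOPHILE_MAP)
  forward <- direction == "forward"
  # pattern to locate in the input: the from-side minus (in forward mode) the
  # nucleophile fragment, which is not yet part of the ligand
  keep <- if (forward) setdiff(seq_along(from$maps), nuc_from)
          else seq_along(from$maps)
  patt_atoms <- from$ligand$atoms[keep, ]
  remap <- match(seq_along(from$maps), keep)
  pb <- from$ligand$bonds
  pb <- pb[!is.na(remap[pb$i]) & !is.na(remap[pb$j]), ]
  if (nrow(pb)) { pb$i <- remap[pb$i]; pb$j <- remap[pb$j] }
  pattern <- cov_ligand(patt_atoms, pb, name = "pattern")
  patt_maps <- from$maps[keep]

  hits <- match_substructure(pattern, ligand, max_matches = 2L)
  if (length(hits) == 0L) {
    stop("template does not apply: no match of the reactant pattern",
         call. = FALSE)
  }
  if (length(hits) > 1L) {
    stop("ambiguous match: reactant pattern matches the ligand more than once",
         call. = FALSE)
  }
  hit <- hits[[1]]
  map_to_lig <- stats::setNames(hit, patt_maps)   # map id -> ligand atom index

  atoms <- ligand$atoms
  bonds <- ligand$bonds
  fb <- side_bond_table(from)
  tb <- side_bond_table(to)

  lig_bond_idx <- function(i, j) {
    which((bonds$i == i & bonds$j == j) | (bonds$i == j & bonds$j == i))
  }
  resolve <- function(map_id) {
    v <- map_to_lig[as.character(map_id)]
    if (is.na(v)) NA_integer_ else as.integer(v)
  }

  # deletions and order changes: bonds present on the from side
  for (k in seq_len(nrow(fb))) {
    i <- resolve(fb$mi[k]); j <- resolve(fb$mj[k])
    if (is.na(i) || is.na(j)) next   # involves an atom not yet in the ligand
    hit_t <- which(tb$key == fb$key[k])
    idx <- lig_bond_idx(i, j)
    if (!length(idx)) next
    if (!length(hit_t)) {
      bonds <- bonds[-idx, ]
    } else if (tb$order[hit_t] != fb$order[k]) {
      bonds$order[idx] <- tb$order[hit_t]
    }
  }

  # incoming atoms: maps on the to side absent from the ligand mapping
  to_map_ids <- unique(c(tb$mi, tb$mj))
  new_maps <- to_map_ids[is.na(vapply(to_map_ids, resolve, integer(1)))]
  to_atom_of_map <- function(map_id) which(to$maps == map_id)[1]
  link_atom_index <- NA_integer_
  anchor_atom_index <- NA_integer_
  for (m_id in new_maps) {
    ta <- to_atom_of_map(m_id)
    el <- to$ligand$atoms$element[ta]
    if (m_id == NUCLEOPHILE_MAP) {
      el <- if (anchor_name == "CYS") "S" else "O"
    }
    # place the new atom near its first bonded, already-present partner
    partner_rows <- tb[tb$mi == m_id | tb$mj == m_id, ]
    pmap <- c(partner_rows$mi, partner_rows$mj)
    pmap <- pmap[pmap != m_id]
    ppos <- resolve(pmap[which(!is.na(vapply(pmap, resolve, integer(1))))[1]])
    base <- c(atoms$x[ppos], atoms$y[ppos], atoms$z[ppos])
    xyz <- if (inherits(anchor, "anchor_residue") && m_id == NUCLEOPHILE_MAP) {
      anchor_atom_xyz(anchor, anchor$link_atom)
    } else base + c(1.8, 0, 0)
    atoms <- dplyr::bind_rows(atoms, tibble::tibble(
      element = el, x = xyz[1], y = xyz[2], z = xyz[3]))
    map_to_lig[as.character(m_id)] <- nrow(atoms)
    if (m_id == NUCLEOPHILE_MAP) anchor_atom_index <- nrow(atoms)
  }

  # additions: bonds on the to side absent from the from side
  for (k in seq_len(nrow(tb))) {
    if (tb$key[k] %in% fb$key) next
    i <- resolve(tb$mi[k]); j <- resolve(tb$mj[k])
    bonds <- dplyr::bind_rows(bonds, tibble::tibble(
      i = min(i, j), j = max(i, j), order = tb$order[k]))
    if (any(c(tb$mi[k], tb$mj[k]) == NUCLEOPHILE_MAP)) {
      other <- c(i, j)[c(tb$mi[k], tb$mj[k]) != NUCLEOPHILE_MAP]
      link_atom_index <- other
    }
  }

  # leaving groups: mapped from-side atoms absent from the to side, plus (in
  # reverse mode) the nucleophile atom itself
  gone_maps <- setdiff(unique(from$maps[from$maps > 0L]),
                       unique(to$maps[to$maps > 0L]))
  drop_atoms <- stats::na.omit(vapply(gone_maps, resolve, integer(1)))
  if (!forward) {
    nuc_lig <- resolve(NUCLEOPHILE_MAP)
    if (!is.na(nuc_lig)) drop_atoms <- c(drop_atoms, nuc_lig)
  }
  drop_atoms <- unique(as.integer(drop_atoms))
  if (length(drop_atoms)) {
    keep_atoms <- setdiff(seq_len(nrow(atoms)), drop_atoms)
    remap2 <- match(seq_len(nrow(atoms)), keep_atoms)
    atoms <- atoms[keep_atoms, ]
    bonds <- bonds[!is.na(remap2[bonds$i]) & !is.na(remap2[bonds$j]), ]
    bonds$i <- remap2[bonds$i]; bonds$j <- remap2[bonds$j]
    link_atom_index <- if (!is.na(link_atom_index)) remap2[link_atom_index]
                       else NA_integer_
    anchor_atom_index <- if (!is.na(anchor_atom_index)) remap2[anchor_atom_index]
                         else NA_integer_
  }

  list(adduct = cov_ligand(atoms, bonds,
                           name = paste0(ligand$name,
                                         if (forward) "-adduct" else "-restored")),
       link_atom_index = link_atom_index,
       anchor_atom_index = anchor_atom_index)
}
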