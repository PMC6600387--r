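#' Covalent ligand molecular graph
#'
#' A `cov_ligand` is a heavy-atom molecular graph with 3D coordinates: an atom
#' table (`element`, `x`, `y`, `z`) and a bond table (`i`, `j`, `order`).
#' Hydrogens are not represented; every metric in the package (RMSD, rotatable
#' bonds, warhead cores) is defined on heavy atoms.
#'
#' @param atoms data frame with columns `element` (character) and `x`, `y`, `z`
#'   (numeric, Angstrom).
#' @param bonds data frame with columns `i`, `j` (1-based atom indices) and
#'   `order` (1, 2 or 3). May have zero rows for a single atom.
#' @param name optional molecule title.
#' @return An object of class `cov_ligand`.
#' @examples
#' eth <- cov_ligand(
#'   atoms = data.frame(element = c("C", "C", "O"),
#'                      x = c(0, 1.5, 2.1), y = c(0, 0, 1.2), z = 0),
#'   bonds = data.frame(i = c(1, 2), j = c(2, 3), order = c(1, 1)))
#' n_heavy_atoms(eth)
#' @export
cov_ligand <- function(atoms, bonds, name = "ligand") {
  atoms <- tibble::as_tibble(atoms)[, c("element", "x", "y", "z")]
  if (nrow(atoms) == 0L) stop("empty ligand: no atoms", call. = FALSE)
  if (is.null(bonds) || nrow(bonds) == 0L) {
    bonds <- tibble::tibble(i = integer(), j = integer(), order = integer())
  } else {
    bonds <- tibble::as_tibble(bonds)[, c("i", "j", "order")]
  }
  atoms$element <- as.character(atoms$element)
  storage.mode(atoms$x) <- "double"
  storage.mode(atoms$y) <- "double"
  storage.mode(atoms$z) <- "double"
  bonds$i <- as.integer(bonds$i); bonds$j <- as.integer(bonds$j)
  bonds$order <- as.integer(bonds$order)
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z)))) {
    stop("non-finite atom coordinates", call. = FALSE)
  }
  n <- nrow(atoms)
  if (nrow(bonds) && (any(bonds$i < 1L | bonds$i > n | bonds$j < 1L | bonds$j > n) ||
                      any(bonds$i == bonds$j))) {
    stop("bond indices out of range", call. = FALSE)
  }
  structure(list(atoms = atoms, bonds = bonds, name = name),
            class = "cov_ligand")
}

#' @export
print.cov_ligand <- function(x, ...) {
  cat("<cov_ligand> ", x$name, ": ", nrow(x$atoms), " heavy atoms, ",
      nrow(x$bonds), " bonds\n", sep = "")
  invisible(x)
}

#' @rdname cov_ligand
#' @param x object to test or query.
#' @export
is_cov_ligand <- function(x) inherits(x, "cov_ligand")

#' @rdname cov_ligand
#' @export
n_heavy_atoms <- function(x) nrow(x$atoms)

#' Atom coordinates as a matrix
#' @param lig a [cov_ligand()].
#' @return numeric matrix, one row per atom, columns x/y/z (Angstrom).
#' @export
ligand_coords <- function(lig) {
  m <- cbind(x = lig$atoms$x, y = lig$atoms$y, z = lig$atoms$z)
  rownames(m) <- NULL
  m
}

#' Replace atom coordinates
#' @param lig a [cov_ligand()].
#' @param xyz numeric matrix with one row per atom.
#' @return the ligand with new coordinates.
#' @export
set_ligand_coords <- function(lig, xyz) {
  stopifnot(nrow(xyz) == nrow(lig$atoms), ncol(xyz) == 3L)
  lig$atoms$x <- xyz[, 1]; lig$atoms$y <- xyz[, 2]; lig$atoms$z <- xyz[, 3]
  lig
}

# adjacency list: for each atom the indices of bonded neighbours
ligand_adjacency <- function(lig) {
  n <- nrow(lig$atoms)
  adj <- vector("list", n)
  for (k in seq_len(nrow(lig$bonds))) {
    i <- lig$bonds$i[k]; j <- lig$bonds$j[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

#' Convert a ligand to an igraph graph
#'
#' Vertices carry the `element` attribute; edges carry the bond `order`.
#' @param lig a [cov_ligand()].
#' @return an undirected [igraph::graph].
#' @export
ligand_igraph <- function(lig) {
  g <- igraph::make_empty_graph(n = nrow(lig$atoms), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "element", value = lig$atoms$element)
  if (nrow(lig$bonds)) {
    g <- igraph::add_edges(g, rbind(lig$bonds$i, lig$bonds$j))
    g <- igraph::set_edge_attr(g, "order", value = lig$bonds$order)
  }
  g
}

element_colors <- function(elements, universe = NULL) {
  if (is.null(universe)) universe <- sort(unique(elements))
  as.integer(factor(elements, levels = universe))
}

#' Heavy-atom graph isomorphisms between two ligands
#'
#' Finds every element- and bond-order-preserving vertex bijection from `a`
#' onto `b` (VF2). Used both for atom correspondence between renumbered pose
#' files and, with `a = b`, for the automorphism group entering the
#' symmetry-aware RMSD.
#'
#' @param a,b [cov_ligand()] objects with identical heavy-atom composition.
#' @param cap maximum number of mappings retained.
#' @return list of integer vectors `m` with `m[i]` the atom of `b` matched to
#'   atom `i` of `a`; empty list if the graphs are not isomorphic.
#' @export
ligand_isomorphisms <- function(a, b, cap = 10000L) {
  if (nrow(a$atoms) != nrow(b$atoms) || nrow(a$bonds) != nrow(b$bonds)) {
    return(list())
  }
  universe <- sort(unique(c(a$atoms$element, b$atoms$element)))
  maps <- igraph::graph.get.isomorphisms.vf2(
    ligand_igraph(a), ligand_igraph(b),
    vertex.color1 = element_colors(a$atoms$element, universe),
    vertex.color2 = element_colors(b$atoms$element, universe),
    edge.color1 = if (nrow(a$bonds)) a$bonds$order else NULL,
    edge.color2 = if (nrow(b$bonds)) b$bonds$order else NULL)
  # igraph returns, for each isomorphism, the vertex of `a` matched to each
  # vertex of `b`; invert so m[i] is the atom of `b` matched to atom i of `a`
  maps <- lapply(maps, function(m) order(as.integer(m)))
  if (length(maps) > cap) maps <- maps[seq_len(cap)]
  maps
}

#' @rdname ligand_isomorphisms
#' @param lig a [cov_ligand()].
#' @export
ligand_automorphisms <- function(lig, cap = 10000L) ligand_isomorphisms(lig, lig, cap)

# is the k-th bond part of a ring? (removing it disconnects its ends iff not)
bond_in_ring <- function(lig) {
  nb <- nrow(lig$bonds)
  if (nb == 0L) return(logical(0))
  g <- ligand_igraph(lig)
  vapply(seq_len(nb), function(k) {
    g2 <- igraph::delete_edges(g, k)
    # still connected through another path -> ring bond
    !is.infinite(igraph::distances(g2, v = lig$bonds$i[k],
                                   to = lig$bonds$j[k])[1, 1])
  }, logical(1))
}

#' Count rotatable bonds
#'
#' A rotatable bond is a single, acyclic bond between two heavy atoms that each
#' carry at least one further heavy neighbour, excluding amide C-N bonds
#' (single C-N where the carbon bears a double-bonded oxygen). This is the
#' strict convention used by the benchmark curation size filter.
#'
#' @param lig a [cov_ligand()].
#' @return integer count.
#' @examples
#' hexane <- chain_alkane(6)
#' n_rotatable_bonds(hexane)  # 3
#' @export
n_rotatable_bonds <- function(lig) {
  nb <- nrow(lig$bonds)
  if (nb == 0L) return(0L)
  deg <- tabulate(c(lig$bonds$i, lig$bonds$j), nbins = nrow(lig$atoms))
  ring <- bond_in_ring(lig)
  el <- lig$atoms$element
  # atoms with a double bond to oxygen (amide/acyl carbons)
  dbl_o <- rep(FALSE, nrow(lig$atoms))
  for (k in seq_len(nb)) {
    if (lig$bonds$order[k] == 2L) {
      i <- lig$bonds$i[k]; j <- lig$bonds$j[k]
      if (el[j] == "O") dbl_o[i] <- TRUE
      if (el[i] == "O") dbl_o[j] <- TRUE
    }
  }
  rot <- 0L
  for (k in seq_len(nb)) {
    if (lig$bonds$order[k] != 1L || ring[k]) next
    i <- lig$bonds$i[k]; j <- lig$bonds$j[k]
    if (deg[i] < 2L || deg[j] < 2L) next
    amide <- (el[i] == "C" && dbl_o[i] && el[j] == "N") ||
             (el[j] == "C" && dbl_o[j] && el[i] == "N")
    if (amide) next
    rot <- rot + 1L
  }
  rot
}

#' Linear alkane ligand
#'
#' Convenience constructor for an n-carbon unbranched alkane laid out as an
#' extended zig-zag chain; used in examples and size-filter tests.
#' @param n number of carbons (>= 1).
#' @return a [cov_ligand()].
#' @export
chain_alkane <- function(n) {
  stopifnot(n >= 1)
  idx <- seq_len(n)
  atoms <- tibble::tibble(element = rep("C", n),
                          x = 1.25 * idx, y = 0.4 * (idx %% 2), z = 0)
  bonds <- if (n > 1) {
    tibble::tibble(i = idx[-n], j = idx[-1], order = 1L)
  } else NULL
  cov_ligand(atoms, bonds, name = sprintf("C%d alkane", n))
}

# ---- substructure matching -------------------------------------------------

match_element <- function(pattern_el, el) {
  if (pattern_el == "*") return(TRUE)
  if (pattern_el == "X") return(el %in% c("F", "Cl", "Br", "I"))
  identical(pattern_el, el)
}

#' Match a substructure pattern against a ligand
#'
#' Backtracking subgraph matcher over element/bond-order labelled graphs.
#' Pattern atoms use element symbols, `"*"` for any heavy atom, or `"X"` for a
#' halogen; a pattern bond order of 0 matches any order. Matches that induce
#' the same atom set are collapsed to one (the first found), so a symmetric
#' pattern counts once per embedding site.
#'
#' @param pattern,lig [cov_ligand()] objects; `pattern` is the query.
#' @param max_matches stop after this many distinct matches.
#' @param max_deg optional integer vector, one per pattern atom: maximum
#'   heavy-atom degree the matched ligand atom may have (0 = unconstrained).
#'   Lets a pattern pin down e.g. an aldehyde carbon (degree 2) against amide
#'   or ester carbons.
#' @return list of integer vectors mapping pattern atom index to ligand atom
#'   index; empty list when the pattern does not occur.
#' @export
match_substructure <- function(pattern, lig, max_matches = Inf, max_deg = NULL) {
  np <- nrow(pattern$atoms); nl <- nrow(lig$atoms)
  if (np > nl) return(list())
  padj <- ligand_adjacency(pattern)
  ladj <- ligand_adjacency(lig)
  # bond order lookups
  pord <- new.env(hash = TRUE)
  for (k in seq_len(nrow(pattern$bonds))) {
    i <- pattern$bonds$i[k]; j <- pattern$bonds$j[k]
    assign(paste(min(i, j), max(i, j)), pattern$bonds$order[k], envir = pord)
  }
  lord <- new.env(hash = TRUE)
  for (k in seq_len(nrow(lig$bonds))) {
    i <- lig$bonds$i[k]; j <- lig$bonds$j[k]
    assign(paste(min(i, j), max(i, j)), lig$bonds$order[k], envir = lord)
  }
  get_ord <- function(envir, i, j) get(paste(min(i, j), max(i, j)), envir = envir)
  # order pattern atoms so each (after the first) touches an already-placed atom
  order_idx <- integer(0)
  remaining <- seq_len(np)
  while (length(remaining)) {
    nxt <- if (!length(order_idx)) remaining[1] else {
      touching <- remaining[vapply(remaining, function(r)
        any(padj[[r]] %in% order_idx), logical(1))]
      if (length(touching)) touching[1] else remaining[1]
    }
    order_idx <- c(order_idx, nxt)
    remaining <- setdiff(remaining, nxt)
  }
  matches <- list()
  seen_sets <- character(0)
  assign_map <- integer(np)   # pattern -> ligand, 0 = unassigned
  used <- logical(nl)
  pel <- pattern$atoms$element; lel <- lig$atoms$element
  pdeg <- lengths(padj)
  ldeg <- lengths(ladj)
  recurse <- function(pos) {
    if (length(matches) >= max_matches) return(invisible())
    if (pos > np) {
      key <- paste(sort(assign_map), collapse = ",")
      if (!(key %in% seen_sets)) {
        seen_sets <<- c(seen_sets, key)
        matches[[length(matches) + 1L]] <<- assign_map
      }
      return(invisible())
    }
    p <- order_idx[pos]
    placed_nb <- padj[[p]][assign_map[padj[[p]]] != 0L]
    cands <- if (length(placed_nb)) {
      # candidates must be ligand neighbours of every placed pattern neighbour
      cand <- ladj[[assign_map[placed_nb[1]]]]
      for (q in placed_nb[-1]) cand <- intersect(cand, ladj[[assign_map[q]]])
      cand
    } else seq_len(nl)
    for (a in cands) {
      if (used[a] || !match_element(pel[p], lel[a]) || ldeg[a] < pdeg[p]) next
      if (!is.null(max_deg) && max_deg[p] > 0L && ldeg[a] > max_deg[p]) next
      ok <- TRUE
      for (q in placed_nb) {
        po <- get_ord(pord, p, q)
        lo <- get_ord(lord, a, assign_map[q])
        if (po != 0L && po != lo) { ok <- FALSE; break }
      }
      if (!ok) next
      assign_map[p] <<- a; used[a] <<- TRUE
      recurse(pos + 1L)
      assign_map[p] <<- 0L; used[a] <<- FALSE
      if (length(matches) >= max_matches) return(invisible())
    }
    invisible()
  }
  recurse(1L)
  matches
}

#' Test whether two ligands share a molecular graph
#' @param a,b [cov_ligand()] objects.
#' @return logical.
#' @export
graphs_isomorphic <- function(a, b) length(ligand_isomorphisms(a, b, cap = 1L)) > 0
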