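#' Anchor residue of a covalent complex
#'
#' The receptor residue whose side-chain nucleophile forms the covalent bond:
#' a cysteine linking through SG or a serine linking through OG.
#'
#' @param chain chain identifier.
#' @param residue_number author residue number (as deposited).
#' @param residue_name `"CYS"` or `"SER"`.
#' @param atoms data frame of the residue's atoms with columns `name`
#'   (PDB atom name: N, CA, CB, SG/OG, ...), `element`, `x`, `y`, `z`.
#' @return object of class `anchor_residue` with a `link_atom` field
#'   (`"SG"` for CYS, `"OG"` for SER).
#' @export
anchor_residue <- function(chain, residue_number, residue_name, atoms) {
  residue_name <- toupper(residue_name)
  if (!residue_name %in% c("CYS", "SER")) {
    stop("unsupported anchor: residue ", residue_name,
         " (only CYS and SER anchors are supported)", call. = FALSE)
  }
  link_atom <- if (residue_name == "CYS") "SG" else "OG"
  atoms <- tibble::as_tibble(atoms)
  if (!link_atom %in% atoms$name) {
    stop("anchor residue lacks its link atom ", link_atom, call. = FALSE)
  }
  structure(list(chain = as.character(chain),
                 residue_number = as.integer(residue_number),
                 residue_name = residue_name,
                 link_atom = link_atom,
                 atoms = atoms),
            class = "anchor_residue")
}

anchor_atom_xyz <- function(anchor, name) {
  row <- anchor$atoms[anchor$atoms$name == name, , drop = FALSE]
  if (nrow(row) == 0L) stop("anchor residue missing atom ", name, call. = FALSE)
  c(row$x[1], row$y[1], row$z[1])
}

#' A single docked (or crystallographic) ligand pose
#'
#' @param ligand a [cov_ligand()] holding the pose coordinates.
#' @param rank pose rank, 1 = best by the producing tool's own convention.
#' @param score engine-native score, or `NA`.
#' @return object of class `ligand_pose`.
#' @export
ligand_pose <- function(ligand, rank = 1L, score = NA_real_) {
  stopifnot(is_cov_ligand(ligand), rank >= 1)
  structure(list(ligand = ligand, rank = as.integer(rank),
                 score = as.numeric(score)),
            class = "ligand_pose")
}

#' An ordered, scored pose list produced by one tool for one complex
#'
#' @param tool_id identifier of the docking tool that produced the run.
#' @param entry_id identifier of the benchmark complex docked into.
#' @param poses list of [ligand_pose()] ordered by rank 1..n without gaps.
#' @param score_orientation `"lower_better"` or `"higher_better"`; rank 1 is
#'   always the tool's best regardless of orientation.
#' @return object of class `docking_run`.
#' @export
docking_run <- function(tool_id, entry_id, poses,
                        score_orientation = c("lower_better", "higher_better")) {
  score_orientation <- match.arg(score_orientation)
  if (length(poses) < 1L) stop("a docking run needs at least one pose", call. = FALSE)
  ranks <- vapply(poses, function(p) p$rank, integer(1))
  if (!identical(sort(ranks), seq_along(poses))) {
    stop("pose ranks must be 1..n without gaps", call. = FALSE)
  }
  poses <- poses[order(ranks)]
  comp <- unique(vapply(poses, function(p)
    paste(sort(p$ligand$atoms$element), collapse = ""), character(1)))
  if (length(comp) != 1L) {
    stop("poses in a run must share heavy-atom composition", call. = FALSE)
  }
  structure(list(tool_id = tool_id, entry_id = entry_id, poses = poses,
                 score_orientation = score_orientation),
            class = "docking_run")
}

#' @export
print.docking_run <- function(x, ...) {
  cat("<docking_run> tool ", x$tool_id, " on ", x$entry_id, ": ",
      length(x$poses), " poses\n", sep = "")
  invisible(x)
}

#' One curated covalent co-crystal complex
#'
#' Bundles everything the evaluation needs for one benchmark entry: the
#' stripped receptor chain, the anchor residue, the crystallographic
#' (post-reaction) ligand pose, the pre-reaction ligand to be docked, and the
#' classification metadata.
#'
#' @param entry_id 4-character PDB-style code or synthetic identifier.
#' @param receptor atom table of the retained protein chain (columns `name`,
#'   `element`, `resid`, `chain`, `resno`, `x`, `y`, `z`).
#' @param anchor an [anchor_residue()].
#' @param reference_ligand [cov_ligand()], crystallographic post-reaction pose.
#' @param pre_reaction_ligand [cov_ligand()] restored to its pre-reaction form,
#'   or `NULL` if not yet derived.
#' @param resolution crystal resolution in Angstrom (> 0).
#' @param receptor_type,uniprot_id,warhead_class,reaction_class,kinase_domain
#'   metadata labels (may be `NA`).
#' @param context full deposited atom table before stripping (used by the
#'   cofactor-proximity and nucleic-acid filters); defaults to `receptor`.
#' @param n_links number of covalent receptor-ligand linkages detected.
#' @return object of class `benchmark_entry`.
#' @export
benchmark_entry <- function(entry_id, receptor, anchor, reference_ligand,
                            pre_reaction_ligand = NULL, resolution = NA_real_,
                            receptor_type = NA_character_,
                            uniprot_id = NA_character_,
                            warhead_class = NA_character_,
                            reaction_class = NA_character_,
                            kinase_domain = NA_character_,
                            context = NULL, n_links = 1L) {
  stopifnot(inherits(anchor, "anchor_residue"), is_cov_ligand(reference_ligand))
  if (!is.na(resolution) && resolution <= 0) {
    stop("resolution must be positive", call. = FALSE)
  }
  if (n_heavy_atoms(reference_ligand) < 5L) {
    warning("reference ligand has fewer than 5 heavy atoms", call. = FALSE)
  }
  structure(list(entry_id = entry_id,
                 receptor = tibble::as_tibble(receptor),
                 anchor = anchor,
                 reference_ligand = reference_ligand,
                 pre_reaction_ligand = pre_reaction_ligand,
                 resolution = resolution,
                 receptor_type = receptor_type,
                 uniprot_id = uniprot_id,
                 warhead_class = warhead_class,
                 reaction_class = reaction_class,
                 kinase_domain = kinase_domain,
                 context = if (is.null(context)) tibble::as_tibble(receptor)
                           else tibble::as_tibble(context),
                 n_links = as.integer(n_links)),
            class = "benchmark_entry")
}

#' @export
print.benchmark_entry <- function(x, ...) {
  cat("<benchmark_entry> ", x$entry_id, ": anchor ", x$anchor$residue_name,
      x$anchor$residue_number, " (", x$anchor$link_atom, "), ",
      n_heavy_atoms(x$reference_ligand), "-atom ligand, ",
      ifelse(is.na(x$resolution), "?", format(x$resolution)), " A\n", sep = "")
  invisible(x)
}
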