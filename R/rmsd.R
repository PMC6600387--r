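# Symmetry-aware, no-fit heavy-atom RMSD between docked poses and the
# crystallographic ligand, and the per-complex measurements derived from a
# docking run: Best Scored Pose (S1), Best Sampled Pose (S2), the maximal
# deviated pose (Smax), the P-deviation S1 - S2, and the success/failure
# flags at the near-native threshold (2.0 A by default).

as_ligand <- function(x) {
  if (is_cov_ligand(x)) x
  else if (inherits(x, "ligand_pose")) x$ligand
  else stop("expected a cov_ligand or ligand_pose", call. = FALSE)
}

#' Heavy-atom no-fit RMSD between a pose and a reference
#'
#' Computes the root-mean-square deviation over heavy atoms in the common
#' (receptor) coordinate frame -- no superposition is performed, since docking
#' accuracy is positional. Atom correspondence between the (possibly
#' renumbered) pose and the reference is established by graph isomorphism on
#' the heavy-atom skeleton (element plus bond order); with `symmetry = TRUE`
#' the RMSD is minimised over all graph automorphisms of the ligand, so
#' topologically equivalent atoms (e.g. the two arms of a para-disubstituted
#' ring) are interchangeable.
#'
#' @param pose,reference [cov_ligand()] or [ligand_pose()] objects with
#'   identical heavy-atom composition.
#' @param symmetry minimise over automorphisms (default `TRUE`).
#' @param cap automorphism cap; above it the canonical identity mapping is
#'   used with a warning.
#' @return RMSD in Angstrom.
#' @examples
#' ref <- chain_alkane(5)
#' moved <- set_ligand_coords(ref, ligand_coords(ref) + rep(c(3, 0, 0), each = 5))
#' ligand_rmsd(moved, ref)  # exactly 3
#' @export
ligand_rmsd <- function(pose, reference, symmetry = TRUE, cap = 10000L) {
  pose <- as_ligand(pose); reference <- as_ligand(reference)
  if (!identical(sort(pose$atoms$element), sort(reference$atoms$element))) {
    stop("atom correspondence failure: heavy-atom compositions differ",
         call. = FALSE)
  }
  maps <- ligand_isomorphisms(reference, pose, cap = cap + 1L)
  if (length(maps) == 0L) {
    stop("atom correspondence failure: ligand graphs are not isomorphic",
         call. = FALSE)
  }
  pc <- ligand_coords(pose); rc <- ligand_coords(reference)
  identity_ok <- identical(reference$atoms$element, pose$atoms$element)
  if (length(maps) > cap) {
    warning("automorphism count exceeds cap (", cap,
            "); falling back to identity atom mapping", call. = FALSE)
    maps <- if (identity_ok) list(seq_len(nrow(rc))) else maps[1]
  } else if (!symmetry) {
    # canonical single mapping: identity when atom order already corresponds
    ident <- Filter(function(m) all(m == seq_along(m)), maps)
    maps <- if (identity_ok && length(ident)) ident[1] else maps[1]
  }
  rmsds <- vapply(maps, function(m)
    sqrt(mean(rowSums((pc[m, , drop = FALSE] - rc)^2))), numeric(1))
  min(rmsds)
}

#' Per-pose RMSD table for a docking run
#'
#' @param run a [docking_run()].
#' @param reference reference ligand ([cov_ligand()]) or a
#'   [benchmark_entry()].
#' @param symmetry,cap passed to [ligand_rmsd()].
#' @return tibble with `tool_id`, `entry_id`, `pose_rank`, `score`, `rmsd`.
#' @export
pose_rmsd_table <- function(run, reference, symmetry = TRUE, cap = 10000L) {
  ref <- if (inherits(reference, "benchmark_entry")) reference$reference_ligand
         else as_ligand(reference)
  purrr::map_dfr(run$poses, function(p) tibble::tibble(
    tool_id = run$tool_id, entry_id = run$entry_id, pose_rank = p$rank,
    score = p$score, rmsd = ligand_rmsd(p, ref, symmetry = symmetry, cap = cap)))
}

#' Evaluate one docking run against its reference complex
#'
#' Derives the per-complex measurements: `s1` (RMSD of the top-ranked pose,
#' the Best Scored Pose), `s2` (minimum RMSD over all poses, the Best Sampled
#' Pose), `smax` (maximal deviated pose), `p_deviation = s1 - s2`, and the
#' flags `success` (`s1 <= tau`) and `failure` (`s1 > tau` and `s2 > tau`).
#' Note success and failure are deliberately non-complementary: a run whose
#' top pose misses but whose sampling found a near-native pose is neither.
#'
#' @param run a [docking_run()].
#' @param entry the [benchmark_entry()] docked into (or a reference ligand).
#' @param tau near-native threshold in Angstrom (default 2.0; a pose at
#'   exactly `tau` counts as a success).
#' @param symmetry,cap passed to [ligand_rmsd()].
#' @return one-row tibble (a ComplexResult).
#' @export
evaluate_run <- function(run, entry, tau = 2.0, symmetry = TRUE, cap = 10000L) {
  tab <- pose_rmsd_table(run, entry, symmetry = symmetry, cap = cap)
  s1 <- tab$rmsd[tab$pose_rank == 1L]
  s2 <- min(tab$rmsd)
  smax <- max(tab$rmsd)
  tibble::tibble(
    tool_id = run$tool_id, entry_id = run$entry_id,
    s1 = s1, s2 = s2, smax = smax,
    p_deviation = s1 - s2,
    success = s1 <= tau,
    failure = s1 > tau & s2 > tau,
    tau = tau, n_poses = length(run$poses))
}

#' Evaluate a collection of docking runs
#'
#' Applies [evaluate_run()] to every run and joins the entries' metadata
#' labels (receptor type, UniProt accession, warhead class, kinase domain)
#' onto the result rows, giving the long table that the aggregation
#' statistics consume.
#'
#' @param runs list of [docking_run()] objects.
#' @param entries list of [benchmark_entry()] objects (matched by `entry_id`).
#' @param tau,symmetry,cap passed to [evaluate_run()].
#' @return tibble with one row per (tool, entry).
#' @export
evaluate_runs <- function(runs, entries, tau = 2.0, symmetry = TRUE,
                          cap = 10000L) {
  ids <- vapply(entries, `[[`, character(1), "entry_id")
  res <- purrr::map_dfr(runs, function(r) {
    k <- match(r$entry_id, ids)
    if (is.na(k)) stop("run references unknown entry ", r$entry_id, call. = FALSE)
    evaluate_run(r, entries[[k]], tau = tau, symmetry = symmetry, cap = cap)
  })
  meta <- purrr::map_dfr(entries, function(e) tibble::tibble(
    entry_id = e$entry_id,
    receptor_type = e$receptor_type %||% NA_character_,
    uniprot_id = e$uniprot_id %||% NA_character_,
    warhead_class = e$warhead_class %||% NA_character_,
    reaction_class = e$reaction_class %||% NA_character_,
    kinase_domain = e$kinase_domain %||% NA_character_))
  dplyr::left_join(res, meta, by = "entry_id")
}
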