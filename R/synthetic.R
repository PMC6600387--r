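# Synthetic benchmark fabrication: license-free toy covalent complexes
# (peptide receptor stubs with a Cys/Ser anchor, ligands carrying each
# warhead class's core) and mock docking runs built from rigid translations of
# the reference ligand, so every planted RMSD is analytically exact (the
# no-fit RMSD of a pure translation is the translation norm, for any atom
# mapping that permutes identical coordinates' centroid -- identity attains
# it and automorphisms cannot beat it).

AMINO3 <- c(G = "GLY", A = "ALA")

peptide_backbone <- function(resnames, chain = "A", start_resno = 21L) {
  out <- list()
  for (i in seq_along(resnames)) {
    off <- c(3.8 * (i - 1), 1.2 * (i %% 2), 0)
    res <- tibble::tibble(
      name = c("N", "CA", "C", "O"),
      element = c("N", "C", "C", "O"),
      resid = resnames[i], chain = chain,
      resno = start_resno + i - 1L,
      x = off[1] + c(0, 1.46, 2.5, 2.4),
      y = off[2] + c(0, 0, 1.0, 2.2),
      z = off[3] + c(0, 0, 0, 0))
    out[[i]] <- res
  }
  dplyr::bind_rows(out)
}

add_anchor_sidechain <- function(rec, resno, residue_name) {
  ca <- rec[rec$resno == resno & rec$name == "CA", ]
  link <- if (residue_name == "CYS") "SG" else "OG"
  link_el <- if (residue_name == "CYS") "S" else "O"
  cb <- c(ca$x + 0.56, ca$y - 1.34, ca$z + 0.44)
  bond_len <- if (residue_name == "CYS") 1.81 else 1.42
  dirv <- c(0.45, -0.72, 0.53); dirv <- dirv / sqrt(sum(dirv^2))
  lk <- cb + bond_len * dirv
  dplyr::bind_rows(rec, tibble::tibble(
    name = c("CB", link), element = c("C", link_el),
    resid = residue_name, chain = ca$chain, resno = resno,
    x = c(cb[1], lk[1]), y = c(cb[2], lk[2]), z = c(cb[3], lk[3])))
}

#' Fabricate one synthetic covalent complex
#'
#' Builds a five-residue peptide stub whose centre residue is the anchor
#' (cysteine or serine), places the named warhead class's example ligand so
#' that its warhead link atom sits at covalent-bond distance from the anchor
#' SG/OG, and fills in metadata. With `dir` given, writes the complex as a
#' PDB file (with LINK and CONECT records) and the ligand as an SDF, both
#' byte-reproducible for a fixed seed.
#'
#' @param warhead_class one of [warhead_classes()].
#' @param anchor `"CYS"` or `"SER"`; defaults to the class's natural anchor.
#' @param entry_id identifier (default derived from the class).
#' @param seed integer seed controlling the entry's random metadata.
#' @param dir optional output directory.
#' @param receptor_type,uniprot_id,kinase_domain,resolution metadata
#'   overrides; resolution defaults to a seeded draw on 1.2-2.8 Angstrom.
#' @return a [benchmark_entry()]; with `dir`, the file paths are attached as
#'   attributes `pdb_path` and `sdf_path`.
#' @export
make_entry <- function(warhead_class, anchor = warhead_anchor(warhead_class),
                       entry_id = NULL, seed = 1L, dir = NULL,
                       receptor_type = "Hydrolase",
                       uniprot_id = "P00001",
                       kinase_domain = NA_character_,
                       resolution = NULL) {
  set.seed(seed)
  if (is.null(entry_id)) {
    entry_id <- sprintf("S%03d", seed %% 1000L)
  }
  if (is.null(resolution)) resolution <- round(stats::runif(1, 1.2, 2.8), 2)
  resnames <- c("GLY", "ALA", anchor, "ALA", "GLY")
  rec <- peptide_backbone(resnames)
  anchor_resno <- 23L
  rec <- add_anchor_sidechain(rec, anchor_resno, anchor)
  link_name <- if (anchor == "CYS") "SG" else "OG"
  link_row <- rec[rec$resno == anchor_resno & rec$name == link_name, ]
  link_xyz <- c(link_row$x, link_row$y, link_row$z)

  lig <- warhead_example_ligand(warhead_class)
  tax <- warhead_taxonomy()
  cl <- classify(lig, anchor, tax)
  if (cl$warhead_class != warhead_class) {
    stop("internal: example ligand for ", warhead_class,
         " classifies as ", cl$warhead_class, call. = FALSE)
  }
  bond_len <- if (anchor == "CYS") 1.81 else 1.42
  dirv <- c(0.35, -0.65, 0.67); dirv <- dirv / sqrt(sum(dirv^2))
  target <- link_xyz + bond_len * dirv
  shift <- target - ligand_coords(lig)[cl$link_atom_index, ]
  lig <- set_ligand_coords(lig, sweep(ligand_coords(lig), 2, -shift))
  lig$name <- entry_id

  anc_rows <- rec[rec$resno == anchor_resno, ]
  entry <- benchmark_entry(
    entry_id = entry_id, receptor = rec,
    anchor = anchor_residue("A", anchor_resno, anchor,
                            tibble::tibble(name = anc_rows$name,
                                           element = anc_rows$element,
                                           x = anc_rows$x, y = anc_rows$y,
                                           z = anc_rows$z)),
    reference_ligand = lig, pre_reaction_ligand = lig,
    resolution = resolution, receptor_type = receptor_type,
    uniprot_id = uniprot_id, warhead_class = warhead_class,
    reaction_class = cl$reaction_class, kinase_domain = kinase_domain,
    context = dplyr::mutate(rec, category = "protein"))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    pdb_path <- file.path(dir, paste0(entry_id, ".pdb"))
    sdf_path <- file.path(dir, paste0(entry_id, ".sdf"))
    write_entry_pdb(entry, pdb_path)
    write_pose_file(lig, sdf_path)
    attr(entry, "pdb_path") <- pdb_path
    attr(entry, "sdf_path") <- sdf_path
  }
  entry
}

random_unit_vector <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

#' Fabricate a docking run with planted pose accuracies
#'
#' Generates `n_poses` rigid translations of the entry's reference ligand
#' whose no-fit RMSDs are exactly the requested values: the rank-1 pose at
#' `target_s1`, the best pose at `target_s2`, the worst at `target_smax`, and
#' the remainder spread between `target_s2` and `target_smax`. Because each
#' pose is a pure translation, [evaluate_run()] recovers the targets exactly
#' (to numerical precision) regardless of the symmetry setting.
#'
#' @param entry a [benchmark_entry()].
#' @param target_s1,target_s2,target_smax planted RMSDs with
#'   `0 <= target_s2 <= target_s1 <= target_smax`.
#' @param n_poses number of poses (default 10).
#' @param seed integer seed for the translation directions.
#' @param tool_id tool label recorded in the run.
#' @return a [docking_run()].
#' @export
make_run <- function(entry, target_s1, target_s2, target_smax, n_poses = 10L,
                     seed = 1L, tool_id = "mock_tool") {
  if (!(target_s2 <= target_s1 && target_s1 <= target_smax && target_s2 >= 0)) {
    stop("infeasible targets: need 0 <= S2 <= S1 <= Smax", call. = FALSE)
  }
  if (n_poses < 1L) stop("n_poses must be >= 1", call. = FALSE)
  if (n_poses == 1L && !(target_s1 == target_s2 && target_s1 == target_smax)) {
    stop("a single-pose run requires S1 = S2 = Smax", call. = FALSE)
  }
  if (n_poses == 2L && target_smax != max(target_s1, target_s2)) {
    stop("a two-pose run requires Smax = max(S1, S2)", call. = FALSE)
  }
  set.seed(seed)
  ref <- entry$reference_ligand
  norms <- numeric(n_poses)
  norms[1] <- target_s1
  if (n_poses >= 2L) norms[2] <- target_s2
  if (n_poses >= 3L) norms[n_poses] <- target_smax
  if (n_poses >= 4L) {
    norms[3:(n_poses - 1L)] <- stats::runif(n_poses - 3L, target_s2, target_smax)
  }
  poses <- lapply(seq_len(n_poses), function(k) {
    shift <- if (norms[k] == 0) c(0, 0, 0) else norms[k] * random_unit_vector()
    lig <- set_ligand_coords(ref, sweep(ligand_coords(ref), 2, -shift))
    lig$name <- sprintf("%s_pose%02d", entry$entry_id, k)
    ligand_pose(lig, rank = k, score = -10 + k * 0.5)
  })
  docking_run(tool_id, entry$entry_id, poses, score_orientation = "lower_better")
}

#' Specification for a synthetic benchmark
#'
#' The generator's defaults emulate the study conditions of the curated
#' benchmark: 330 complexes distributed over the 15 warhead classes in the
#' published class proportions, four docking tools, 10 retained poses per run,
#' and a score-RMSD rank agreement of 0.7 (the top-scored pose is the best
#' sampled pose for about 70 percent of runs).
#'
#' @param n_entries number of complexes.
#' @param warhead_mix named numeric vector of class proportions (summing
#'   to 1); default: the benchmark's published class frequencies.
#' @param tools named list: per tool a list with `mu` and `sigma`, the
#'   location/spread (Angstrom) of its planted pose-RMSD distribution, either
#'   scalars or vectors named by warhead class.
#' @param n_poses poses per run.
#' @param rho probability that the top-scored pose is the best sampled pose.
#' @param seed integer seed.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_entries = 330L,
                           warhead_mix = NULL,
                           tools = list(
                             mockMOE = list(mu = 1.9, sigma = 0.9),
                             mockGOLD = list(mu = 2.3, sigma = 1.1),
                             mockCovDock = list(mu = 2.1, sigma = 1.0),
                             mockICM = list(mu = 2.5, sigma = 1.3)),
                           n_poses = 10L, rho = 0.7, seed = 42L) {
  if (is.null(warhead_mix)) {
    freq <- readr::read_csv(covbench_config_file("bcde/warhead_frequencies.csv"),
                            show_col_types = FALSE)
    warhead_mix <- stats::setNames(freq$n / sum(freq$n), freq$warhead_class)
  }
  stopifnot(abs(sum(warhead_mix) - 1) < 1e-8, n_poses >= 1L,
            all(vapply(tools, function(t) all(t$sigma >= 0), logical(1))))
  structure(list(n_entries = as.integer(n_entries), warhead_mix = warhead_mix,
                 tools = tools, n_poses = as.integer(n_poses), rho = rho,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

tool_param <- function(tool, field, class) {
  v <- tool[[field]]
  if (length(v) > 1L && !is.null(names(v)) && class %in% names(v)) v[[class]]
  else v[[1]]
}

RECEPTOR_TYPES <- c("Hydrolase", "Transferase", "Ligase", "Lyase",
                    "Oxidoreductase", "Isomerase", "Transcription",
                    "Viral Protein", "Metal binding protein")

#' Generate a complete synthetic benchmark
#'
#' Fabricates `n_entries` complexes according to the class mix, assigns
#' receptor types and UniProt-style subgroup accessions (about three
#' structures per accession), and for every (tool, entry) pair draws planted
#' pose RMSDs from the tool's accuracy profile and materialises a
#' [make_run()] docking run. The planted per-complex values are returned as a
#' ground-truth table against which the evaluation pipeline can be closed.
#'
#' @param spec a [synthetic_spec()].
#' @param dir optional directory; when given, entries, ligands, runs and the
#'   metadata/ground-truth CSVs are written under it.
#' @return list of class `synthetic_benchmark`: `entries`, `runs` (flat list),
#'   `ground_truth` tibble (`tool_id`, `entry_id`, planted `s1`, `s2`,
#'   `smax`), `metadata` tibble and the `spec`.
#' @export
make_benchmark <- function(spec = synthetic_spec(), dir = NULL) {
  set.seed(spec$seed)
  n <- spec$n_entries
  if (n == 0L) {
    return(structure(list(entries = list(), runs = list(),
                          ground_truth = tibble::tibble(),
                          metadata = tibble::tibble(), spec = spec),
                     class = "synthetic_benchmark"))
  }
  classes <- rep(names(spec$warhead_mix),
                 times = round(spec$warhead_mix * n))
  classes <- classes[seq_len(min(length(classes), n))]
  if (length(classes) < n) {
    classes <- c(classes, sample(names(spec$warhead_mix),
                                 n - length(classes), replace = TRUE,
                                 prob = spec$warhead_mix))
  }
  entry_seeds <- sample.int(1e6, n)
  receptor_types <- RECEPTOR_TYPES[(seq_len(n) - 1L) %% length(RECEPTOR_TYPES) + 1L]
  # ~3 structures per accession, accessions nested within warhead class
  uniprot <- character(n)
  for (cl in unique(classes)) {
    idx <- which(classes == cl)
    uniprot[idx] <- sprintf("P%s%03d", substr(gsub("[^A-Za-z]", "", cl), 1, 2),
                            ceiling(seq_along(idx) / 3))
  }
  entries <- vector("list", n)
  for (k in seq_len(n)) {
    entries[[k]] <- make_entry(
      classes[k], entry_id = sprintf("S%04d", k), seed = entry_seeds[k],
      dir = if (!is.null(dir)) file.path(dir, "entries") else NULL,
      receptor_type = receptor_types[k], uniprot_id = uniprot[k])
  }
  runs <- list()
  gt <- list()
  for (tool in names(spec$tools)) {
    tp <- spec$tools[[tool]]
    for (k in seq_len(n)) {
      mu <- tool_param(tp, "mu", classes[k])
      sg <- tool_param(tp, "sigma", classes[k])
      draws <- sort(abs(stats::rnorm(spec$n_poses, mu, sg)))
      s2 <- draws[1]; smax <- draws[spec$n_poses]
      # rho: chance the top-scored pose is the best sampled one
      s1 <- if (stats::runif(1) < spec$rho) s2
            else draws[sample.int(spec$n_poses, 1)]
      run <- make_run(entries[[k]], s1, s2, smax, n_poses = spec$n_poses,
                      seed = entry_seeds[k] + match(tool, names(spec$tools)),
                      tool_id = tool)
      runs[[length(runs) + 1L]] <- run
      gt[[length(gt) + 1L]] <- tibble::tibble(
        tool_id = tool, entry_id = entries[[k]]$entry_id,
        s1 = s1, s2 = s2, smax = smax, mu = mu, sigma = sg)
      if (!is.null(dir)) {
        run_dir <- file.path(dir, "runs", tool)
        dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
        write_pose_file(run$poses,
                        file.path(run_dir, paste0(run$entry_id, ".sdf")))
      }
    }
  }
  ground_truth <- dplyr::bind_rows(gt)
  metadata <- purrr::map_dfr(entries, function(e) tibble::tibble(
    entry_id = e$entry_id, receptor_type = e$receptor_type,
    uniprot_id = e$uniprot_id, warhead_class = e$warhead_class,
    reaction_class = e$reaction_class, resolution = e$resolution,
    kinase_domain = e$kinase_domain))
  if (!is.null(dir)) {
    readr::write_csv(metadata, file.path(dir, "metadata.csv"))
    readr::write_csv(ground_truth, file.path(dir, "ground_truth.csv"))
  }
  structure(list(entries = entries, runs = runs, ground_truth = ground_truth,
                 metadata = metadata, spec = spec),
            class = "synthetic_benchmark")
}

#' @export
print.synthetic_benchmark <- function(x, ...) {
  cat("<synthetic_benchmark> ", length(x$entries), " entries, ",
      length(x$runs), " runs (",
      length(unique(x$ground_truth$tool_id)), " tools)\n", sep = "")
  invisible(x)
}
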