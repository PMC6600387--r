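# Anchor-site descriptors: solvent accessible surface area of the anchor
# residue (rolling-probe / point-sampling construction) and the side-chain
# dihedral N-CA-CB-SG (Cys) or N-CA-CB-OG (Ser), plus the binning of docking
# accuracy against these features.

#' Van der Waals radius table for SASA
#'
#' @param path YAML file with `probe_radius`, a `radii` map and a `default`;
#'   the shipped file holds a fixed published (Bondi-type) set.
#' @return list with `probe`, `radii` (named numeric), `default`.
#' @export
sasa_radii <- function(path = covbench_config_file("atomic_radii.yaml")) {
  y <- yaml::read_yaml(path)
  list(probe = as.numeric(y$probe_radius),
       radii = unlist(y$radii), default = as.numeric(y$default))
}

# deterministic, approximately uniform sphere points (golden-spiral lattice)
sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

element_radius <- function(elements, radii) {
  r <- radii$radii[elements]
  r[is.na(r)] <- radii$default
  unname(r)
}

#' Per-atom solvent accessible surface area
#'
#' Rolling-probe SASA by spherical point sampling: each atom's sphere of
#' radius (vdW + probe) is covered with a deterministic golden-spiral lattice
#' and the accessible fraction is the share of lattice points not buried
#' inside any neighbouring atom's expanded sphere.
#'
#' @param atoms data frame with `element`, `x`, `y`, `z` (all heavy atoms of
#'   the structure that occlude each other).
#' @param indices atom rows for which SASA is returned (default: all).
#' @param probe probe radius in Angstrom (default from the shipped radius
#'   table, 1.4).
#' @param n_points lattice points per atom (default 960).
#' @param radii radius table from [sasa_radii()].
#' @return numeric vector of per-atom accessible areas (Angstrom squared).
#' @export
sasa_atoms <- function(atoms, indices = seq_len(nrow(atoms)), probe = NULL,
                       n_points = 960L, radii = sasa_radii()) {
  if (is.null(probe)) probe <- radii$probe
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  rr <- element_radius(atoms$element, radii) + probe
  pts <- sphere_points(n_points)
  vapply(indices, function(i) {
    ri <- rr[i]
    d2 <- rowSums((xyz - matrix(xyz[i, ], nrow(xyz), 3, byrow = TRUE))^2)
    nb <- which(d2 > 0 & d2 < (ri + rr)^2)
    if (!length(nb)) return(4 * pi * ri^2)
    p <- pts * ri + matrix(xyz[i, ], n_points, 3, byrow = TRUE)
    free <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(free)) break
      dj <- rowSums((p[free, , drop = FALSE] -
                       matrix(xyz[j, ], sum(free), 3, byrow = TRUE))^2)
      free[free] <- dj >= rr[j]^2
    }
    4 * pi * ri^2 * sum(free) / n_points
  }, numeric(1))
}

#' Solvent accessible surface area of the anchor residue
#'
#' Sums the per-atom accessible areas of the anchor residue's atoms within the
#' ligand-free receptor (the entry's stripped receptor chain, which does not
#' contain the ligand).
#'
#' @param entry a [benchmark_entry()].
#' @param probe probe radius (Angstrom); `NULL` takes the radius table's
#'   default (1.4).
#' @param n_points sampling density per atom.
#' @param radii radius table from [sasa_radii()].
#' @return SASA in Angstrom squared.
#' @export
anchor_sasa <- function(entry, probe = NULL, n_points = 960L,
                        radii = sasa_radii()) {
  rec <- entry$receptor
  idx <- which(rec$chain == entry$anchor$chain &
                 rec$resno == entry$anchor$residue_number &
                 rec$resid == entry$anchor$residue_name)
  if (!length(idx)) stop("anchor residue not found in receptor", call. = FALSE)
  need <- c("N", "CA", "CB", entry$anchor$link_atom)
  missing <- setdiff(need, rec$name[idx])
  if (length(missing)) {
    stop("anchor residue missing atom(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sum(sasa_atoms(rec, indices = idx, probe = probe, n_points = n_points,
                 radii = radii))
}

#' Signed torsion angle of four points
#'
#' IUPAC convention: looking down the 2-3 axis, the angle from the 1-2 bond
#' to the 3-4 bond, positive clockwise, in (-180, 180] degrees.
#' @param p1,p2,p3,p4 length-3 numeric coordinates.
#' @return angle in degrees.
#' @export
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sqrt(sum(n1^2)) < 1e-9 || sqrt(sum(n2^2)) < 1e-9) {
    stop("degenerate (collinear) geometry: torsion undefined", call. = FALSE)
  }
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  if (ang > 180) ang <- ang - 360
  if (ang == -180) ang <- 180
  ang
}

#' Side-chain dihedral of the anchor residue
#'
#' The N-CA-CB-SG torsion for a cysteine anchor, N-CA-CB-OG for serine, in
#' (-180, 180] degrees (the -180 boundary reports as 180).
#'
#' @param entry a [benchmark_entry()] (or an [anchor_residue()]).
#' @return dihedral in degrees.
#' @export
anchor_dihedral <- function(entry) {
  anchor <- if (inherits(entry, "anchor_residue")) entry else entry$anchor
  ang <- torsion_angle(anchor_atom_xyz(anchor, "N"),
                       anchor_atom_xyz(anchor, "CA"),
                       anchor_atom_xyz(anchor, "CB"),
                       anchor_atom_xyz(anchor, anchor$link_atom))
  if (ang == -180) 180 else ang
}

#' Anchor-site descriptor table
#'
#' @param entries list of [benchmark_entry()] objects.
#' @param n_points SASA sampling density.
#' @return tibble `entry_id`, `sasa`, `dihedral`, `kinase_domain`.
#' @export
site_descriptors <- function(entries, n_points = 960L) {
  purrr::map_dfr(entries, function(e) tibble::tibble(
    entry_id = e$entry_id,
    sasa = anchor_sasa(e, n_points = n_points),
    dihedral = anchor_dihedral(e),
    kinase_domain = e$kinase_domain %||% NA_character_))
}

#' Docking accuracy binned by an anchor-site feature
#'
#' Joins per-complex results to site descriptors on `entry_id` and reports the
#' per-bin median Best Scored Pose RMSD per tool. SASA bins default to 10
#' Angstrom squared, dihedral bins to 30 degrees; the kinase-domain feature is
#' categorical. Bins with no entries are reported as missing (`NA` median),
#' never as zero.
#'
#' @param results per-complex results from [evaluate_runs()].
#' @param descriptors tibble from [site_descriptors()].
#' @param feature `"sasa"`, `"dihedral"` or `"kinase_domain"`.
#' @param binwidth bin width overriding the feature default.
#' @param measurement `"best_scored"` or `"best_sampled"`.
#' @return tibble `tool_id`, `bin`, `n`, `median_rmsd`.
#' @export
accuracy_by_feature <- function(results, descriptors,
                                feature = c("sasa", "dihedral", "kinase_domain"),
                                binwidth = NULL,
                                measurement = c("best_scored", "best_sampled")) {
  feature <- match.arg(feature)
  col <- measurement_column(measurement)
  d <- dplyr::inner_join(results, descriptors, by = "entry_id")
  if (feature == "kinase_domain") {
    d$bin <- d$kinase_domain
  } else {
    if (is.null(binwidth)) binwidth <- if (feature == "sasa") 10 else 30
    lo <- if (feature == "sasa") 0 else -180
    v <- d[[feature]]
    hi <- max(v, lo + binwidth)
    breaks <- seq(lo, lo + binwidth * ceiling((hi - lo) / binwidth),
                  by = binwidth)
    d$bin <- cut(v, breaks = breaks, right = FALSE, include.lowest = TRUE)
  }
  out <- d |>
    dplyr::group_by(.data$tool_id, .data$bin) |>
    dplyr::summarise(n = dplyr::n(),
                     median_rmsd = stats::median(.data[[col]]),
                     .groups = "drop")
  if (feature != "kinase_domain") {
    out <- tidyr::complete(out, .data$tool_id, .data$bin,
                           fill = list(n = NA_integer_,
                                       median_rmsd = NA_real_))
  }
  out
}
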