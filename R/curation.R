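# Benchmark curation: the auditable filter pipeline that turns candidate
# covalent co-crystal complexes into a qualified benchmark set. Filters are
# applied in the construction order: resolution, nucleic-acid exclusion,
# anchor identity, single-linkage, cofactor proximity, ligand size.

check_resolution <- function(entry, cutoff) {
  if (is.na(entry$resolution)) return(list(pass = FALSE, reason = "no resolution"))
  list(pass = entry$resolution < cutoff,
       reason = sprintf("resolution %.2f A >= %.2f A", entry$resolution, cutoff))
}

check_nucleic <- function(entry) {
  has_na <- "category" %in% names(entry$context) &&
    any(entry$context$category == "nucleic")
  list(pass = !has_na, reason = "nucleic-acid chain present")
}

check_anchor <- function(entry) {
  ok <- entry$anchor$residue_name %in% c("CYS", "SER")
  list(pass = ok, reason = paste0("anchor residue ", entry$anchor$residue_name,
                                  " is not CYS/SER"))
}

check_single_link <- function(entry) {
  list(pass = entry$n_links == 1L,
       reason = sprintf("%d covalent linkages (exactly one required)",
                        entry$n_links))
}

check_cofactor <- function(entry, radius) {
  ctx <- entry$context
  if (!"category" %in% names(ctx) || !any(ctx$category == "cofactor")) {
    return(list(pass = TRUE, reason = ""))
  }
  cof <- ctx[ctx$category == "cofactor", , drop = FALSE]
  lig <- ligand_coords(entry$reference_ligand)
  cxyz <- cbind(cof$x, cof$y, cof$z)
  dmin <- min(vapply(seq_len(nrow(cxyz)), function(k)
    min(sqrt(colSums((t(lig) - cxyz[k, ])^2))), numeric(1)))
  list(pass = dmin > radius,
       reason = sprintf("cofactor atom %.2f A from ligand (<= %.1f A)",
                        dmin, radius))
}

check_ligand_size <- function(entry, min_heavy, max_rotatable) {
  lig <- entry$pre_reaction_ligand %||% entry$reference_ligand
  nh <- n_heavy_atoms(lig)
  if (nh == 0L) return(list(pass = FALSE, reason = "empty ligand"))
  nr <- n_rotatable_bonds(lig)
  pass <- nh >= min_heavy && nr < max_rotatable
  list(pass = pass,
       reason = if (nh < min_heavy)
         sprintf("%d heavy atoms (< %d)", nh, min_heavy)
       else sprintf("%d rotatable bonds (>= %d)", nr, max_rotatable))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

curation_checks <- function(entries, resolution_cutoff = 3.0,
                            min_heavy = 5L, max_rotatable = 30L,
                            cofactor_radius = 8.0) {
  purrr::map_dfr(entries, function(e) {
    checks <- list(
      resolution = check_resolution(e, resolution_cutoff),
      nucleic = check_nucleic(e),
      anchor = check_anchor(e),
      single_link = check_single_link(e),
      cofactor = check_cofactor(e, cofactor_radius),
      ligand_size = check_ligand_size(e, min_heavy, max_rotatable))
    fails <- names(checks)[!vapply(checks, `[[`, logical(1), "pass")]
    tibble::tibble(
      entry_id = e$entry_id,
      pass_resolution = checks$resolution$pass,
      pass_nucleic = checks$nucleic$pass,
      pass_anchor = checks$anchor$pass,
      pass_single_link = checks$single_link$pass,
      pass_cofactor = checks$cofactor$pass,
      pass_ligand_size = checks$ligand_size$pass,
      retained = length(fails) == 0L,
      first_failure = if (length(fails)) fails[1] else NA_character_,
      failure_reason = if (length(fails)) checks[[fails[1]]]$reason
                       else NA_character_)
  })
}

filter_by <- function(entries, flags) entries[flags]

#' Resolution filter
#'
#' Retains complexes with crystallographic resolution strictly below the
#' cutoff; entries with no recorded resolution fail with reason
#' `"no resolution"`.
#'
#' @param entries list of [benchmark_entry()] objects.
#' @param cutoff resolution cutoff in Angstrom (default 3.0).
#' @return the retained sublist.
#' @export
filter_resolution <- function(entries, cutoff = 3.0) {
  filter_by(entries, vapply(entries, function(e)
    check_resolution(e, cutoff)$pass, logical(1)))
}

#' Ligand-size filter
#'
#' Retains complexes whose (pre-reaction) ligand has at least `min_heavy`
#' non-hydrogen atoms and strictly fewer than `max_rotatable` rotatable bonds
#' (see [n_rotatable_bonds()] for the convention).
#'
#' @inheritParams filter_resolution
#' @param min_heavy minimum heavy-atom count (default 5).
#' @param max_rotatable exclusive rotatable-bond bound (default 30).
#' @return the retained sublist.
#' @export
filter_ligand_size <- function(entries, min_heavy = 5L, max_rotatable = 30L) {
  filter_by(entries, vapply(entries, function(e)
    check_ligand_size(e, min_heavy, max_rotatable)$pass, logical(1)))
}

#' Anchor filter
#'
#' Retains complexes covalently linked to a cysteine SG or serine OG through
#' exactly one single bond.
#'
#' @inheritParams filter_resolution
#' @return the retained sublist.
#' @export
filter_anchor <- function(entries) {
  filter_by(entries, vapply(entries, function(e)
    check_anchor(e)$pass && check_single_link(e)$pass, logical(1)))
}

#' Structural-context filter
#'
#' Excludes complexes containing nucleic-acid chains and complexes where any
#' cofactor heavy atom lies within `radius` of any ligand heavy atom. The scan
#' runs on the deposited structure (the entry's `context` table), i.e. before
#' stripping, so cofactors removed from the final receptor still trigger the
#' proximity rule.
#'
#' @inheritParams filter_resolution
#' @param radius cofactor proximity radius in Angstrom (default 8.0).
#' @return the retained sublist.
#' @export
filter_context <- function(entries, radius = 8.0) {
  filter_by(entries, vapply(entries, function(e)
    check_nucleic(e)$pass && check_cofactor(e, radius)$pass, logical(1)))
}

#' Run the full curation pipeline
#'
#' Applies the benchmark construction filters in order -- resolution,
#' nucleic-acid exclusion, anchor identity, single covalent linkage, cofactor
#' proximity, ligand size -- and reports, for every candidate, which checks
#' passed and which filter fired first for excluded entries.
#'
#' @inheritParams filter_resolution
#' @param resolution_cutoff,min_heavy,max_rotatable,cofactor_radius filter
#'   parameters; see the individual filters.
#' @return a `curation_report`: list with `table` (per-entry audit tibble),
#'   `retained` (list of retained entries) and `counts` (entries surviving
#'   after each successive filter).
#' @export
run_curation <- function(entries, resolution_cutoff = 3.0, min_heavy = 5L,
                         max_rotatable = 30L, cofactor_radius = 8.0) {
  tab <- curation_checks(entries, resolution_cutoff, min_heavy, max_rotatable,
                         cofactor_radius)
  stage_cols <- c("pass_resolution", "pass_nucleic", "pass_anchor",
                  "pass_single_link", "pass_cofactor", "pass_ligand_size")
  surviving <- rep(TRUE, nrow(tab))
  counts <- tibble::tibble(stage = "input", n = nrow(tab))
  for (cl in stage_cols) {
    surviving <- surviving & tab[[cl]]
    counts <- dplyr::bind_rows(counts,
      tibble::tibble(stage = sub("^pass_", "", cl), n = sum(surviving)))
  }
  structure(list(table = tab, retained = entries[tab$retained], counts = counts),
            class = "curation_report")
}

#' @export
print.curation_report <- function(x, ...) {
  cat("<curation_report> ", nrow(x$table), " candidates -> ",
      length(x$retained), " retained\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' @method tidy curation_report
#' @export
tidy.curation_report <- function(x, ...) x$table

#' @method glance curation_report
#' @export
glance.curation_report <- function(x, ...) {
  tibble::tibble(n_candidates = nrow(x$table),
                 n_retained = length(x$retained),
                 retention_rate = length(x$retained) / nrow(x$table))
}
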