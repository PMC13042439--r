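# QM-region definitions: empirical (explicit fragment list), short-range
# (distance cutoff plus pair-interaction-energy rule) and MO-based
# (R_min <= R_conv from the gap-shift convergence analysis). Regions always
# include the guest.

new_region <- function(model, fragmap, fragment_ids, criteria) {
  fragment_ids <- sort(unique(as.integer(fragment_ids)))
  unknown <- setdiff(fragment_ids, fragmap$id)
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown fragment id(s): ",
                        paste(unknown, collapse = ", ")))
  }
  g_ids <- fragmap$id[fragmap$role == "guest"]
  fragment_ids <- sort(union(fragment_ids, g_ids))
  atoms <- sort(unlist(fragmap$atoms[fragmap$id %in% fragment_ids],
                       use.names = FALSE))
  out <- list(
    model = model,
    fragment_ids = fragment_ids,
    atom_indices = atoms,
    criteria = criteria,
    n_fragments = length(fragment_ids),
    n_atoms = length(atoms)
  )
  class(out) <- "region_definition"
  out
}

#' @export
print.region_definition <- function(x, ...) {
  cat(sprintf("<region_definition> model '%s': %d fragments, %d atoms\n",
              x$model, x$n_fragments, x$n_atoms))
  invisible(x)
}

#' @export
glance.region_definition <- function(x, ...) {
  tibble::tibble(model = x$model, n_fragments = x$n_fragments,
                 n_atoms = x$n_atoms)
}

#' Turn a region definition into a QM/MM partition
#'
#' @param region A `region_definition`.
#' @param fragmap The fragment map it was built from.
#' @param mm_charge_source Passed to [partition_spec()].
#' @return A [partition_spec()] with the region QM and the rest MM.
#' @export
region_partition <- function(region, fragmap,
                             mm_charge_source = "frozen_reference") {
  partition_spec(region$fragment_ids,
                 setdiff(fragmap$id, region$fragment_ids),
                 mm_charge_source)
}

#' Empirical QM region from an explicit fragment list
#'
#' @param fragmap A `fragment_map`.
#' @param fragment_ids Fragments to include (guest added automatically; set
#'   semantics, duplicates ignored).
#' @return A `region_definition` with model `"empirical"`.
#' @export
select_region_empirical <- function(fragmap, fragment_ids = integer()) {
  new_region("empirical", fragmap, fragment_ids,
             list(explicit_ids = sort(unique(as.integer(fragment_ids)))))
}

#' Short-range QM region: distance cutoff plus interaction-energy rule
#'
#' The conventional short-range recipe: guest plus every fragment within
#' `r_cut` of the guest, united with every fragment whose total pair
#' interaction energy with the guest exceeds `e_thresh` in magnitude
#' (attractive energies are negative, so the test is on `|E_int|`). With
#' `intersect = TRUE` the two rules are intersected instead of united.
#'
#' @param fragmap A `fragment_map`.
#' @param rmin Distance map (`fragment_id`, `rmin`) covering all fragments.
#' @param guest_pairs [fmo2()] pair table; pairs containing the guest are
#'   used. `NULL` falls back to distance-only selection with a warning.
#' @param r_cut Distance cutoff in Angstrom (default 5).
#' @param e_thresh Interaction-energy threshold in kcal/mol (default 2).
#' @param intersect Use the conjunctive reading of the rule (default FALSE).
#' @return A `region_definition` with model `"short_range"`.
#' @export
select_region_short_range <- function(fragmap, rmin, guest_pairs = NULL,
                                      r_cut = 5, e_thresh = 2,
                                      intersect = FALSE) {
  rmin <- tibble::as_tibble(rmin)
  missing_r <- setdiff(fragmap$id, rmin$fragment_id)
  if (length(missing_r) > 0) {
    rlang::abort(paste0("rmin map misses fragments: ",
                        paste(missing_r, collapse = ", ")))
  }
  g_ids <- fragmap$id[fragmap$role == "guest"]
  by_dist <- rmin$fragment_id[rmin$rmin <= r_cut]
  by_energy <- integer()
  if (is.null(guest_pairs)) {
    rlang::warn("no pair data; short-range selection is distance-only")
    sel <- by_dist
  } else {
    gp <- guest_pairs[guest_pairs$i %in% g_ids | guest_pairs$j %in% g_ids, ]
    partner <- ifelse(gp$i %in% g_ids, gp$j, gp$i)
    by_energy <- unique(partner[abs(gp$total) > e_thresh])
    sel <- if (intersect) intersect(by_dist, by_energy) else
      union(by_dist, by_energy)
  }
  new_region("short_range", fragmap, sel,
             list(r_cut = r_cut, e_thresh = e_thresh,
                  rule = if (intersect) "intersection" else "union",
                  by_distance = sort(setdiff(by_dist, g_ids)),
                  by_energy = sort(setdiff(by_energy, g_ids))))
}

#' MO-based QM region from the gap-shift convergence radius
#'
#' Guest plus every fragment with `rmin <= r_conv` (boundary inclusive).
#'
#' @param fragmap A `fragment_map`.
#' @param rmin Distance map (`fragment_id`, `rmin`).
#' @param r_conv Convergence radius in Angstrom, e.g. from
#'   [convergence_radius()].
#' @return A `region_definition` with model `"mo_based"`.
#' @export
select_region_mo_based <- function(fragmap, rmin, r_conv) {
  if (inherits(r_conv, "convergence_radius")) r_conv <- r_conv$r_conv
  if (r_conv < 0) rlang::abort("r_conv must be non-negative")
  rmin <- tibble::as_tibble(rmin)
  sel <- rmin$fragment_id[rmin$rmin <= r_conv]
  new_region("mo_based", fragmap, sel, list(r_conv = r_conv))
}

#' Whole-system region (all fragments QM)
#'
#' @param fragmap A `fragment_map`.
#' @return A `region_definition` with model `"whole"`.
#' @export
select_region_whole <- function(fragmap) {
  new_region("whole", fragmap, fragmap$id, list())
}

#' Emit a region definition to a file
#'
#' Formats: `atomlist` (sorted 0-based atom indices, one per line, with a
#' header naming the convention), `pdb_subset` (valid PDB of the selected
#' atoms with metadata preserved) and `json` (the full definition; atom
#' indices 0-based as in all serialized artifacts).
#'
#' @param region A `region_definition`.
#' @param structure The structure the region refers to.
#' @param path Output file path.
#' @param format `"atomlist"`, `"pdb_subset"` or `"json"`.
#' @return `path`, invisibly.
#' @export
emit_region <- function(region, structure, path,
                        format = c("atomlist", "pdb_subset", "json")) {
  format <- match.arg(format)
  if (max(region$atom_indices) > nrow(structure$atoms)) {
    rlang::abort("region refers to atoms beyond the structure")
  }
  if (format == "atomlist") {
    writeLines(c("# qmregion atom list (0-based indices)",
                 as.character(sort(region$atom_indices) - 1L)), path)
  } else if (format == "pdb_subset") {
    sub <- structure_from_atoms(
      structure$atoms[region$atom_indices, , drop = FALSE],
      title = structure$title, net_charge = structure$net_charge)
    write_structure(sub, path, format = "pdb")
  } else {
    payload <- list(
      model = region$model,
      fragment_ids = region$fragment_ids,
      atom_indices = sort(region$atom_indices) - 1L,
      criteria = region$criteria,
      n_fragments = region$n_fragments,
      n_atoms = region$n_atoms
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Read a region definition emitted as JSON
#'
#' @param path JSON path written by [emit_region()].
#' @return A `region_definition`.
#' @export
read_region <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list(
    model = raw$model,
    fragment_ids = sort(as.integer(raw$fragment_ids)),
    atom_indices = sort(as.integer(raw$atom_indices)) + 1L,
    criteria = raw$criteria,
    n_fragments = raw$n_fragments,
    n_atoms = raw$n_atoms
  )
  class(out) <- "region_definition"
  out
}
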