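# Structure and fragment-map handling: PDB/XYZ input, residue-based
# fragmentation with host/guest/solvent roles, and minimum-distance profiles
# relative to the guest.

SOLVENT_RESNAMES <- c("HOH", "WAT", "TIP3", "SOL", "DOD")

#' Build a structure from an atom table
#'
#' The in-memory structure is a thin wrapper around an atom tibble with one
#' row per atom: `element`, Cartesian `x`, `y`, `z` in Angstrom, and optional
#' PDB-style metadata (`resname`, `resno`, `chain`, `het`, `serial`). Atom
#' indices are 1-based and stable; serialized artifacts (fragment-map JSON,
#' atom lists) use 0-based indices as documented there.
#'
#' @param atoms Data frame with at least `element`, `x`, `y`, `z`.
#' @param title Free-text title.
#' @param net_charge Total charge in elementary charges.
#' @param params Parameter set used to flag unknown elements (default
#'   [toy_params()]).
#' @return An object of class `mol_structure`.
#' @export
structure_from_atoms <- function(atoms, title = "", net_charge = 0,
                                 params = toy_params()) {
  atoms <- tibble::as_tibble(atoms)
  need <- c("element", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0) {
    rlang::abort(paste0("atom table misses columns: ", paste(miss, collapse = ", ")))
  }
  n <- nrow(atoms)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) rlang::abort("atom positions must be finite")
  atoms$x <- as.numeric(atoms$x); atoms$y <- as.numeric(atoms$y)
  atoms$z <- as.numeric(atoms$z)
  if (!"resname" %in% names(atoms)) atoms$resname <- "MOL"
  if (!"resno" %in% names(atoms)) atoms$resno <- 1L
  if (!"chain" %in% names(atoms)) atoms$chain <- "A"
  if (!"het" %in% names(atoms)) atoms$het <- FALSE
  if (!"serial" %in% names(atoms)) atoms$serial <- seq_len(n)
  atoms$known <- atoms$element %in% params$elements$element
  if (any(!atoms$known)) {
    rlang::warn(paste0("unknown element(s) flagged: ",
                       paste(unique(atoms$element[!atoms$known]), collapse = ", ")))
  }
  out <- list(atoms = atoms, title = title, net_charge = net_charge)
  class(out) <- "mol_structure"
  out
}

#' @export
print.mol_structure <- function(x, ...) {
  cat(sprintf("<mol_structure> %d atoms, net charge %+d%s\n",
              nrow(x$atoms), x$net_charge,
              if (nzchar(x$title)) paste0(" - ", x$title) else ""))
  print(utils::head(x$atoms, 5))
  if (nrow(x$atoms) > 5) cat(sprintf("  ... %d more atoms\n", nrow(x$atoms) - 5))
  invisible(x)
}

#' @export
as_tibble.mol_structure <- function(x, ...) x$atoms

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("pdb", "ent")) return("pdb")
  if (ext == "xyz") return("xyz")
  rlang::abort(sprintf("cannot guess structure format from '%s'", path))
}

element_from_name <- function(name) {
  s <- gsub("[^A-Za-z]", "", name)
  two <- paste0(toupper(substr(s, 1, 1)), tolower(substr(s, 2, 2)))
  ifelse(two %in% default_element_table()$element & nchar(s) >= 2,
         two, toupper(substr(s, 1, 1)))
}

read_pdb_structure <- function(path, params) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  bad <- which(rec & nchar(lines) < 54)
  if (length(bad) > 0) {
    rlang::abort(sprintf("malformed ATOM/HETATM record at line %d of %s",
                         bad[1], path))
  }
  for (i in which(rec)) {
    coords <- suppressWarnings(as.numeric(c(substr(lines[i], 31, 38),
                                            substr(lines[i], 39, 46),
                                            substr(lines[i], 47, 54))))
    if (anyNA(coords)) {
      rlang::abort(sprintf("unparseable coordinates at line %d of %s", i, path))
    }
  }
  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE))
  at <- pdb$atom
  keep <- is.na(at$alt) | at$alt %in% c("", " ", "A")
  at <- at[keep, , drop = FALSE]
  elem <- at$elesy
  no_sym <- is.na(elem) | !nzchar(trimws(elem))
  elem[no_sym] <- element_from_name(at$elety[no_sym])
  elem <- trimws(elem)
  elem <- paste0(toupper(substr(elem, 1, 1)), tolower(substr(elem, 2, 2)))
  structure_from_atoms(
    tibble::tibble(
      element = elem,
      x = at$x, y = at$y, z = at$z,
      resname = at$resid,
      resno = at$resno,
      chain = ifelse(is.na(at$chain), "A", at$chain),
      het = at$type == "HETATM",
      serial = at$eleno
    ),
    title = basename(path), params = params
  )
}

read_xyz_structure <- function(path, params) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1) rlang::abort(sprintf("empty XYZ file: %s", path))
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) rlang::abort(sprintf("line 1 of %s is not an atom count", path))
  if (length(lines) < n + 2) {
    rlang::abort(sprintf("%s declares %d atoms but has %d coordinate lines",
                         path, n, max(0, length(lines) - 2)))
  }
  rows <- lines[seq(3, 2 + n)]
  parts <- strsplit(trimws(rows), "\\s+")
  bad <- which(vapply(parts, length, 1L) < 4)
  if (length(bad) > 0) {
    rlang::abort(sprintf("malformed coordinate record at line %d of %s",
                         bad[1] + 2, path))
  }
  elem <- vapply(parts, `[[`, "", 1)
  num <- function(k) {
    v <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", k)))
    if (anyNA(v)) {
      rlang::abort(sprintf("non-numeric coordinate at line %d of %s",
                           which(is.na(v))[1] + 2, path))
    }
    v
  }
  structure_from_atoms(
    tibble::tibble(element = elem, x = num(2), y = num(3), z = num(4)),
    title = trimws(lines[2]), params = params
  )
}

#' Read a molecular structure
#'
#' Reads PDB (one atom per ATOM/HETATM record, residue metadata preserved,
#' altloc conformers other than blank/'A' dropped) or plain XYZ
#' (count/comment/element-x-y-z records). Elements absent from the engine
#' parameter table are kept but flagged with a warning.
#'
#' @param path File path.
#' @param format `"pdb"`, `"xyz"`, or `"auto"` (from the extension).
#' @param params Parameter set used to flag unknown elements.
#' @return A `mol_structure`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "xyz"),
                           params = toy_params()) {
  format <- match.arg(format)
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  if (format == "auto") format <- guess_format(path)
  switch(format,
         pdb = read_pdb_structure(path, params),
         xyz = read_xyz_structure(path, params))
}

#' Write a molecular structure
#'
#' @param structure A `mol_structure`.
#' @param path Output path.
#' @param format `"pdb"`, `"xyz"`, or `"auto"` (from the extension).
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  at <- structure$atoms
  if (format == "xyz") {
    lines <- c(
      as.character(nrow(at)),
      if (nzchar(structure$title)) structure$title else "generated by qmregion",
      sprintf("%-2s %14.6f %14.6f %14.6f", at$element, at$x, at$y, at$z)
    )
    writeLines(lines, path)
  } else {
    bio3d::write.pdb(
      file = path,
      xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
      type = ifelse(at$het, "HETATM", "ATOM"),
      resno = at$resno,
      resid = at$resname,
      chain = at$chain,
      eleno = at$serial,
      elety = at$element,
      elesy = at$element
    )
  }
  invisible(path)
}

new_fragment_map <- function(df, n_atoms) {
  df <- tibble::as_tibble(df)
  df$id <- as.integer(df$id)
  df$formal_charge <- as.numeric(df$formal_charge)
  class(df) <- c("fragment_map", class(tibble::tibble()))
  attr(df, "n_atoms") <- n_atoms
  validate_fragment_map(df, n_atoms)
  df
}

validate_fragment_map <- function(fragmap, n_atoms = attr(fragmap, "n_atoms")) {
  sizes <- lengths(fragmap$atoms)
  if (any(sizes == 0)) {
    rlang::abort(paste0("empty fragment(s): ",
                        paste(fragmap$id[sizes == 0], collapse = ", ")))
  }
  all_idx <- sort(unlist(fragmap$atoms, use.names = FALSE))
  dup <- unique(all_idx[duplicated(all_idx)])
  if (length(dup) > 0) {
    rlang::abort(paste0("atoms assigned to more than one fragment: ",
                        paste(utils::head(dup, 10), collapse = ", ")))
  }
  missing_idx <- setdiff(seq_len(n_atoms), all_idx)
  if (length(missing_idx) > 0) {
    rlang::abort(paste0("atoms not covered by any fragment: ",
                        paste(utils::head(missing_idx, 10), collapse = ", ")))
  }
  if (anyDuplicated(fragmap$id) > 0) rlang::abort("fragment ids must be unique")
  if (!all(fragmap$role %in% c("host", "guest", "solvent"))) {
    rlang::abort("fragment roles must be host, guest or solvent")
  }
  invisible(fragmap)
}

#' Partition a structure into fragments
#'
#' In `by_residue` mode atoms are grouped by (chain, residue number), the
#' field-standard fragmentation for proteins where each fragment is one amino
#' acid residue. HETATM residues matching `guest` get role `"guest"`,
#' water-like residues become `"solvent"` (treated host-like downstream), and
#' everything else is `"host"`. In `explicit` mode a user-supplied list of
#' fragments must cover all atoms disjointly.
#'
#' @param structure A `mol_structure`.
#' @param mode `"by_residue"` or `"explicit"`.
#' @param explicit For explicit mode: a list of lists (or tibble rows) with
#'   fields `atoms` (1-based indices) and optionally `id`, `name`, `role`,
#'   `formal_charge`.
#' @param guest Guest selector: character vector of residue names, or integer
#'   vector of fragment ids (in construction order).
#' @param guest_charge Formal charge assigned to guest fragments.
#' @param require_guest Error when a guest selector matches nothing
#'   (default `TRUE` when `guest` is given).
#' @return A `fragment_map` tibble with columns `id`, `name`, `role`,
#'   `formal_charge` and list-column `atoms`.
#' @export
build_fragment_map <- function(structure, mode = c("by_residue", "explicit"),
                               explicit = NULL, guest = NULL,
                               guest_charge = 0,
                               require_guest = !is.null(guest)) {
  mode <- match.arg(mode)
  at <- structure$atoms
  n <- nrow(at)
  if (mode == "by_residue") {
    key <- paste(at$chain, at$resno, sep = "|")
    groups <- split(seq_len(n), factor(key, levels = unique(key)))
    ids <- seq_along(groups)
    first <- vapply(groups, `[`, 1L, 1)
    resname <- at$resname[first]
    name <- sprintf("%s_%s%s", resname, at$resno[first], at$chain[first])
    het <- vapply(groups, function(ix) any(at$het[ix]), TRUE)
    role <- rep("host", length(groups))
    role[resname %in% SOLVENT_RESNAMES] <- "solvent"
    if (!is.null(guest)) {
      hit <- if (is.character(guest)) {
        het & resname %in% guest
      } else {
        ids %in% as.integer(guest)
      }
      role[hit] <- "guest"
    }
    fragmap <- tibble::tibble(
      id = ids, name = name, role = role,
      formal_charge = ifelse(role == "guest", guest_charge, 0),
      atoms = unname(groups)
    )
  } else {
    if (is.null(explicit)) rlang::abort("explicit mode requires a fragment list")
    if (is.data.frame(explicit)) {
      explicit <- purrr::transpose(as.list(explicit))
    }
    fragmap <- purrr::imap_dfr(explicit, function(fr, i) {
      tibble::tibble(
        id = as.integer(fr$id %||% i),
        name = fr$name %||% sprintf("frag_%d", as.integer(fr$id %||% i)),
        role = fr$role %||% "host",
        formal_charge = as.numeric(fr$formal_charge %||% 0),
        atoms = list(as.integer(fr$atoms))
      )
    })
    if (!is.null(guest)) {
      fragmap$role[fragmap$id %in% as.integer(guest) |
                     fragmap$name %in% as.character(guest)] <- "guest"
    }
  }
  if (require_guest && !any(fragmap$role == "guest")) {
    rlang::abort("no fragment matched the guest selector")
  }
  new_fragment_map(fragmap, n)
}

#' Read or write a fragment map as JSON
#'
#' The on-disk schema is
#' `{"fragments": [{"id": int, "name": str, "atoms": [int, ...],
#' "role": "host|guest|solvent", "formal_charge": int}]}` with 0-based atom
#' indices; in-memory maps use 1-based indices.
#'
#' @param path File path.
#' @param n_atoms Total atom count of the structure the map belongs to
#'   (defaults to the largest index found).
#' @return `read_fragment_map()` returns a `fragment_map`;
#'   `write_fragment_map()` returns `path` invisibly.
#' @export
read_fragment_map <- function(path, n_atoms = NULL) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  frs <- raw$fragments
  df <- purrr::map_dfr(frs, function(fr) {
    tibble::tibble(
      id = as.integer(fr$id), name = as.character(fr$name),
      role = as.character(fr$role),
      formal_charge = as.numeric(fr$formal_charge %||% 0),
      atoms = list(as.integer(unlist(fr$atoms)) + 1L)
    )
  })
  n_atoms <- n_atoms %||% max(unlist(df$atoms))
  new_fragment_map(df, n_atoms)
}

#' @param fragmap A `fragment_map`.
#' @rdname read_fragment_map
#' @export
write_fragment_map <- function(fragmap, path) {
  frs <- purrr::pmap(fragmap, function(id, name, role, formal_charge, atoms) {
    list(id = id, name = name, atoms = as.integer(atoms) - 1L,
         role = role, formal_charge = formal_charge)
  })
  jsonlite::write_json(list(fragments = frs), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

guest_atoms <- function(fragmap) {
  sort(unlist(fragmap$atoms[fragmap$role == "guest"], use.names = FALSE))
}

#' Minimum fragment-to-guest distance profile
#'
#' For every fragment, computes R_min: the minimum interatomic Euclidean
#' distance between the fragment's atoms and the guest's atoms (Angstrom).
#' Guest fragments map to 0.
#'
#' @param structure A `mol_structure`.
#' @param fragmap A `fragment_map` containing at least one guest fragment.
#' @return A tibble with `fragment_id`, `name`, `role`, `rmin`.
#' @export
min_distance_profile <- function(structure, fragmap) {
  validate_fragment_map(fragmap, nrow(structure$atoms))
  g_idx <- guest_atoms(fragmap)
  if (length(g_idx) == 0) rlang::abort("fragment map has no guest fragment")
  g_xyz <- coords_matrix(structure, g_idx)
  rmin <- purrr::map2_dbl(fragmap$atoms, fragmap$role, function(ix, role) {
    if (role == "guest") return(0)
    min_cross_dist(coords_matrix(structure, ix), g_xyz)
  })
  tibble::tibble(fragment_id = fragmap$id, name = fragmap$name,
                 role = fragmap$role, rmin = rmin)
}

# Pairwise fragment-fragment minimum distances (matrix keyed by fragment id).
fragment_pair_rmin <- function(structure, fragmap) {
  xyz <- purrr::map(fragmap$atoms, ~coords_matrix(structure, .x))
  nf <- nrow(fragmap)
  m <- matrix(0, nf, nf, dimnames = list(fragmap$id, fragmap$id))
  if (nf > 1) {
    for (i in seq_len(nf - 1)) {
      for (j in seq((i + 1), nf)) {
        m[i, j] <- m[j, i] <- min_cross_dist(xyz[[i]], xyz[[j]])
      }
    }
  }
  m
}

#' Extract fragments into a standalone structure
#'
#' Pulls the atoms of the selected fragments (in structure order) into a new
#' `mol_structure`, with net charge equal to the summed fragment formal
#' charges. Useful for isolated-guest runs.
#'
#' @param structure A `mol_structure`.
#' @param fragmap A `fragment_map`.
#' @param ids Fragment ids to keep.
#' @return A `mol_structure`.
#' @export
extract_fragments <- function(structure, fragmap, ids) {
  sel <- fragmap[fragmap$id %in% ids, ]
  if (nrow(sel) != length(unique(ids))) {
    rlang::abort("unknown fragment id(s) in extraction")
  }
  idx <- sort(unlist(sel$atoms, use.names = FALSE))
  structure_from_atoms(structure$atoms[idx, , drop = FALSE],
                       title = structure$title,
                       net_charge = sum(sel$formal_charge))
}

# Sum a per-atom charge vector over fragments -> tibble(fragment_id, q).
fragment_charges <- function(fragmap, atomic_charges) {
  tibble::tibble(
    fragment_id = fragmap$id,
    q = vapply(fragmap$atoms, function(ix) sum(atomic_charges[ix]), 0)
  )
}
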