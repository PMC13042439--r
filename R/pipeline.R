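# End-to-end protocol driver: apo/holo FMO runs, MO-shift profile,
# convergence radius, region selection, per-region observables, charge-flow
# network and the model comparison report.

#' Pipeline configuration
#'
#' Bundles and validates everything [run_protocol()] needs. Structures and
#' the fragment map may be given as file paths or in-memory objects. The
#' host subsystem is always derived from the complex by dropping the guest
#' fragments, so the apo and holo states share one geometry and one
#' fragment numbering; a separately supplied host structure is validated
#' against the derived one.
#'
#' @param complex Complex structure (`mol_structure` or PDB/XYZ path).
#' @param fragmap Fragment map (`fragment_map` or JSON path); `NULL` builds
#'   one by residue using `guest_selector`.
#' @param host Optional host structure for cross-validation.
#' @param guest_selector Residue-name selector for by-residue fragmentation.
#' @param params Engine parameter set (`toy_params` or JSON path).
#' @param delta Gap-shift convergence tolerance, eV.
#' @param dimer_cutoff FMO2 dimer cutoff, Angstrom.
#' @param network_threshold Charge-flow edge threshold, e.
#' @param region_modes Region models to evaluate, a subset of
#'   `c("mo_based", "short_range", "empirical", "whole")`.
#' @param empirical_ids Explicit fragment list for the empirical model.
#' @param r_cut,e_thresh Short-range rule settings (Angstrom, kcal/mol).
#' @param mm_charge_source MM charge model for truncated regions.
#' @param seed Integer seed recorded in the manifest (the protocol itself is
#'   deterministic).
#' @param out_dir Output directory.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(complex, fragmap = NULL, host = NULL,
                            guest_selector = "LIG", params = toy_params(),
                            delta = 0.01, dimer_cutoff = 6,
                            network_threshold = 0.005,
                            region_modes = c("mo_based", "short_range", "whole"),
                            empirical_ids = NULL, r_cut = 5, e_thresh = 2,
                            mm_charge_source = "frozen_reference",
                            seed = 1L, out_dir = tempfile("qmregion_run_")) {
  if (delta <= 0) rlang::abort("delta must be positive")
  known_modes <- c("mo_based", "short_range", "empirical", "whole")
  bad <- setdiff(region_modes, known_modes)
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown region mode(s): ", paste(bad, collapse = ", ")))
  }
  if (length(region_modes) == 0) rlang::abort("request at least one region mode")
  if ("empirical" %in% region_modes && is.null(empirical_ids)) {
    rlang::abort("empirical mode requires empirical_ids")
  }
  for (f in c("complex", "host", "fragmap", "params")) {
    v <- get(f)
    if (is.character(v) && !file.exists(v)) {
      rlang::abort(sprintf("%s file not found: %s", f, v))
    }
  }
  out <- list(complex = complex, fragmap = fragmap, host = host,
              guest_selector = guest_selector, params = params, delta = delta,
              dimer_cutoff = dimer_cutoff,
              network_threshold = network_threshold,
              region_modes = region_modes, empirical_ids = empirical_ids,
              r_cut = r_cut, e_thresh = e_thresh,
              mm_charge_source = mm_charge_source,
              seed = as.integer(seed), out_dir = out_dir)
  class(out) <- "pipeline_config"
  out
}

#' Evaluate the observables of one QM-region model
#'
#' Runs the complex, host and isolated guest under the region's partition
#' (guest always QM; fragments outside the region become MM point charges)
#' and collects the binding energy, the guest's embedded IP/EA, and the
#' guest PIEDA aggregate.
#'
#' @param structure Complex structure.
#' @param fragmap Complex fragment map.
#' @param params Engine parameters.
#' @param region A `region_definition` (or a [partition_spec()]).
#' @param dimer_cutoff FMO2 cutoff, Angstrom.
#' @param host_reference Optional all-QM [fmo1()] of the host (reused for
#'   frozen-reference MM charges).
#' @param mm_charge_source MM charge model.
#' @return One-row tibble: `model`, `n_fragments`, `n_atoms`, `e_bind`,
#'   `ip`, `ea`, `gap`, `es`, `ex`, `ct`, `di` (energies kcal/mol, orbital
#'   properties eV).
#' @export
evaluate_region <- function(structure, fragmap, params, region,
                            dimer_cutoff = 6, host_reference = NULL,
                            mm_charge_source = "frozen_reference") {
  if (inherits(region, "region_definition")) {
    partition <- region_partition(region, fragmap, mm_charge_source)
    model <- region$model
    n_frag <- region$n_fragments
    n_atoms <- region$n_atoms
  } else {
    partition <- region
    model <- "custom"
    n_frag <- length(partition$qm_ids)
    n_atoms <- length(unlist(fragmap$atoms[fragmap$id %in% partition$qm_ids]))
  }
  g_ids <- fragmap$id[fragmap$role == "guest"]
  host_ids <- setdiff(fragmap$id, g_ids)
  host_sys <- subset_system(structure, fragmap, host_ids)
  guest_sys <- subset_system(structure, fragmap, g_ids)

  needs_ref <- length(partition$mm_ids) > 0 &&
    partition$mm_charge_source == "frozen_reference"
  mm_complex <- NULL; mm_host <- NULL
  if (needs_ref) {
    if (is.null(host_reference)) {
      host_reference <- fmo1(host_sys$structure, host_sys$fragmap, params)
    }
    mm_host <- host_reference$atomic_charges
    mm_complex <- numeric(nrow(structure$atoms))
    mm_complex[host_sys$atom_index] <- mm_host
  }

  r1c <- fmo1(structure, fragmap, params, partition = partition,
              mm_charges = mm_complex)
  pc <- fmo2(r1c, dimer_cutoff = dimer_cutoff)
  e_complex <- system_energy(r1c, pc)

  host_partition <- partition_spec(intersect(partition$qm_ids, host_ids),
                                   intersect(partition$mm_ids, host_ids),
                                   partition$mm_charge_source)
  r1h <- fmo1(host_sys$structure, host_sys$fragmap, params,
              partition = host_partition, mm_charges = mm_host)
  e_host <- system_energy(r1h, fmo2(r1h, dimer_cutoff = dimer_cutoff))
  r1g <- fmo1(guest_sys$structure, guest_sys$fragmap, params)
  e_guest <- system_energy(r1g, fmo2(r1g, dimer_cutoff = dimer_cutoff))

  fp <- guest_ip_ea(r1c, if (length(g_ids) == 1) g_ids else NULL)
  pieda <- pieda_aggregate(pc, g_ids[1])
  tibble::tibble(
    model = model, n_fragments = n_frag, n_atoms = n_atoms,
    e_bind = as.numeric(e_complex) - as.numeric(e_host) - as.numeric(e_guest),
    ip = fp$ip, ea = fp$ea, gap = fp$gap,
    es = pieda$es, ex = pieda$ex, ct = pieda$ct, di = pieda$di
  )
}

resolve_structure <- function(x, params) {
  if (is.character(x)) read_structure(x, params = params) else x
}

#' Run the full region-selection protocol
#'
#' Executes the pipeline end to end: structure and fragment-map loading, an
#' all-QM FMO1 sweep of the host (apo) and of the complex (holo) plus FMO2
#' dimers, the MO-shift profile and its convergence radius, region selection
#' for each requested model, per-region observables, the charge-flow network
#' with hub detection, and a deviation table against the whole-system
#' reference. All outputs are written under `config$out_dir` together with a
#' manifest listing every file with its checksum; reruns over the same
#' inputs are byte-identical (use `force = TRUE` to overwrite).
#'
#' @param config A [pipeline_config()].
#' @param force Overwrite a non-empty output directory.
#' @return A `protocol_result` list with the profile, convergence radius,
#'   regions, observables table, comparison table, network, hub report and
#'   manifest.
#' @export
run_protocol <- function(config, force = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force) {
    rlang::abort(sprintf("output directory %s is not empty (use force = TRUE)",
                         out_dir))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("pipeline stage '%s' failed: %s", name,
                           conditionMessage(e)))
    })
  }

  params <- if (is.character(config$params)) read_toy_params(config$params) else
    config$params

  cmplx <- stage("structio", resolve_structure(config$complex, params))
  fragmap <- stage("structio", {
    if (is.null(config$fragmap)) {
      build_fragment_map(cmplx, "by_residue", guest = config$guest_selector)
    } else if (is.character(config$fragmap)) {
      read_fragment_map(config$fragmap, n_atoms = nrow(cmplx$atoms))
    } else config$fragmap
  })
  g_ids <- fragmap$id[fragmap$role == "guest"]
  if (length(g_ids) == 0) rlang::abort("pipeline stage 'structio' failed: no guest fragment")
  host_sys <- subset_system(cmplx, fragmap, setdiff(fragmap$id, g_ids))
  if (!is.null(config$host)) {
    host_given <- resolve_structure(config$host, params)
    if (!identical(host_given$atoms$element, host_sys$structure$atoms$element)) {
      rlang::abort("pipeline stage 'structio' failed: supplied host does not match complex minus guest")
    }
  }

  rmin <- stage("structio", min_distance_profile(cmplx, fragmap))

  apo <- stage("fmo", fmo1(host_sys$structure, host_sys$fragmap, params))
  holo <- stage("fmo", fmo1(cmplx, fragmap, params))
  pairs_holo <- stage("fmo", fmo2(holo, dimer_cutoff = config$dimer_cutoff))
  pairs_apo <- stage("fmo", fmo2(apo, dimer_cutoff = config$dimer_cutoff))

  # Shift profile joins on complex fragment ids; the derived host system
  # keeps them unchanged. Fragment charges carry the FMO2 dimer corrections
  # (monomer charges are fixed at the formal charge by construction).
  profile <- stage("descriptors", {
    q_apo <- fmo2_fragment_charges(apo, pairs_apo)
    q_holo <- fmo2_fragment_charges(holo, pairs_holo)
    apo_tab <- apo$fragments[apo$fragments$qm, ]
    holo_tab <- holo$fragments[holo$fragments$qm, ]
    mo_shift_profile(
      tibble::tibble(fragment_id = apo_tab$fragment_id, name = apo_tab$name,
                     role = apo_tab$role, gap = apo_tab$gap,
                     q = q_apo$q[match(apo_tab$fragment_id, q_apo$fragment_id)]),
      tibble::tibble(fragment_id = holo_tab$fragment_id, name = holo_tab$name,
                     role = holo_tab$role, gap = holo_tab$gap,
                     q = q_holo$q[match(holo_tab$fragment_id, q_holo$fragment_id)]),
      rmin)
  })
  rconv <- stage("descriptors",
                 convergence_radius(profile, delta = config$delta))
  write_shift_profile(profile, file.path(out_dir, "profile.tsv"))
  jsonlite::write_json(glance(rconv), file.path(out_dir, "rconv.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  regions <- stage("regions", {
    out <- list()
    for (mode in config$region_modes) {
      out[[mode]] <- switch(
        mode,
        mo_based = select_region_mo_based(fragmap, rmin, rconv),
        short_range = select_region_short_range(fragmap, rmin, pairs_holo,
                                                r_cut = config$r_cut,
                                                e_thresh = config$e_thresh),
        empirical = select_region_empirical(fragmap, config$empirical_ids),
        whole = select_region_whole(fragmap)
      )
    }
    out
  })
  dir.create(file.path(out_dir, "regions"), showWarnings = FALSE)
  for (mode in names(regions)) {
    emit_region(regions[[mode]], cmplx,
                file.path(out_dir, "regions", paste0(mode, ".json")), "json")
  }

  observables <- stage("fmo", {
    purrr::map_dfr(regions, function(rg) {
      evaluate_region(cmplx, fragmap, params, rg,
                      dimer_cutoff = config$dimer_cutoff,
                      host_reference = apo,
                      mm_charge_source = config$mm_charge_source)
    })
  })
  utils::write.table(observables, file.path(out_dir, "observables.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  comparison <- NULL
  if ("whole" %in% names(regions)) {
    comparison <- stage("bench", {
      long <- tidyr::pivot_longer(
        observables[, c("model", "e_bind", "ip", "ea", "es", "ex", "ct", "di")],
        -"model", names_to = "label", values_to = "value")
      model_comparison(long, "whole", units = "kcal/mol (e_bind, PIEDA), eV (ip/ea)")
    })
    write_deviation_table(comparison, file.path(out_dir, "comparison.tsv"))
  }

  network <- stage("network", {
    charge_flow_graph(apo, holo, pairs_holo, rmin,
                      threshold = config$network_threshold,
                      pairs_apo = pairs_apo)
  })
  hubs <- stage("network", detect_hubs(network))
  write_flow_graph(network, file.path(out_dir, "net"))
  utils::write.table(hubs$scores, file.path(out_dir, "net", "hubs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- stage("app", {
    files <- setdiff(list.files(out_dir, recursive = TRUE), "manifest.json")
    sums <- tools::md5sum(file.path(out_dir, files))
    settings <- config[c("guest_selector", "delta", "dimer_cutoff",
                         "network_threshold", "region_modes", "empirical_ids",
                         "r_cut", "e_thresh", "mm_charge_source", "seed")]
    m <- list(
      package = "qmregion",
      version = as.character(utils::packageVersion("qmregion")),
      seed = config$seed,
      config_hash = rlang::hash(list(settings, cmplx$atoms, fragmap$atoms,
                                     fragmap$formal_charge)),
      r_conv = rconv$r_conv,
      files = purrr::map2(files, unname(sums), ~list(path = .x, md5 = .y))
    )
    jsonlite::write_json(m, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    m
  })

  out <- list(profile = profile, rconv = rconv, regions = regions,
              observables = observables, comparison = comparison,
              network = network, hubs = hubs, manifest = manifest,
              rmin = rmin, apo = apo, holo = holo, pairs = pairs_holo,
              out_dir = out_dir)
  class(out) <- "protocol_result"
  out
}

#' @export
print.protocol_result <- function(x, ...) {
  cat("<protocol_result>\n")
  cat(sprintf("  R_conv = %.3f A (delta = %g eV)\n", x$rconv$r_conv,
              x$rconv$delta))
  cat(sprintf("  regions: %s\n", paste(names(x$regions), collapse = ", ")))
  cat(sprintf("  hubs: %s\n",
              if (length(x$hubs$hubs) > 0) paste(x$hubs$hubs, collapse = ", ")
              else "none"))
  cat(sprintf("  outputs in %s\n", x$out_dir))
  invisible(x)
}
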