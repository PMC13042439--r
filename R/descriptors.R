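# MO-shift analysis: per-fragment HOMO-LUMO gap shifts (delta_eps) and
# charge shifts (delta_q) between the guest-free (apo) and guest-bound
# (holo) states, and detection of the convergence radius R_conv beyond which
# orbital perturbations fall under a tolerance.

as_property_table <- function(x, label) {
  if (inherits(x, "fmo1_result")) {
    fr <- x$fragments[x$fragments$qm, ]
    return(tibble::tibble(fragment_id = fr$fragment_id, name = fr$name,
                          role = fr$role, gap = fr$gap, q = fr$q))
  }
  x <- tibble::as_tibble(x)
  need <- c("fragment_id", "gap", "q")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    rlang::abort(sprintf("%s table misses columns: %s", label,
                         paste(miss, collapse = ", ")))
  }
  if (!"name" %in% names(x)) x$name <- as.character(x$fragment_id)
  if (!"role" %in% names(x)) x$role <- "host"
  x[, c("fragment_id", "name", "role", "gap", "q")]
}

#' Per-fragment MO-shift profile between apo and holo states
#'
#' Joins the apo (guest-free) and holo (guest-bound) per-fragment properties
#' by fragment id and computes the binding-induced shifts
#' `delta_eps = gap_holo - gap_apo` (eV, on the HOMO-LUMO gap) and
#' `delta_q = q_holo - q_apo` (e). Guest fragments are excluded (their apo
#' state does not exist). Rows are ordered by ascending R_min, ties by
#' fragment id.
#'
#' @param apo An [fmo1()] result of the host alone, or a property table with
#'   columns `fragment_id`, `gap`, `q` (optionally `name`).
#' @param holo Same for the complex; host fragment ids must match `apo`.
#' @param rmin Distance map: tibble with `fragment_id` and `rmin`, as from
#'   [min_distance_profile()] on the complex.
#' @return A `shift_profile` tibble with columns `fragment_id`, `name`,
#'   `rmin`, `gap_apo`, `gap_holo`, `delta_eps`, `q_apo`, `q_holo`,
#'   `delta_q`.
#' @export
mo_shift_profile <- function(apo, holo, rmin) {
  a <- as_property_table(apo, "apo")
  h <- as_property_table(holo, "holo")
  h <- h[h$role != "guest", ]
  a <- a[a$role != "guest", ]
  only_a <- setdiff(a$fragment_id, h$fragment_id)
  only_h <- setdiff(h$fragment_id, a$fragment_id)
  if (length(only_a) > 0 || length(only_h) > 0) {
    rlang::abort(sprintf(
      "fragment ids differ between apo and holo (apo-only: %s; holo-only: %s)",
      paste(only_a, collapse = ","), paste(only_h, collapse = ",")))
  }
  rmin <- tibble::as_tibble(rmin)
  if (!all(c("fragment_id", "rmin") %in% names(rmin))) {
    rlang::abort("rmin map needs columns fragment_id, rmin")
  }
  missing_r <- setdiff(a$fragment_id, rmin$fragment_id)
  if (length(missing_r) > 0) {
    rlang::abort(paste0("rmin map misses fragments: ",
                        paste(missing_r, collapse = ",")))
  }
  out <- dplyr::inner_join(
    dplyr::rename(a, gap_apo = "gap", q_apo = "q"),
    dplyr::select(dplyr::rename(h, gap_holo = "gap", q_holo = "q"),
                  "fragment_id", "gap_holo", "q_holo"),
    by = "fragment_id"
  )
  out <- dplyr::inner_join(out, rmin[, c("fragment_id", "rmin")],
                           by = "fragment_id")
  out <- dplyr::mutate(out,
                       delta_eps = .data$gap_holo - .data$gap_apo,
                       delta_q = .data$q_holo - .data$q_apo)
  out <- dplyr::arrange(out, .data$rmin, .data$fragment_id)
  out <- out[, c("fragment_id", "name", "rmin", "gap_apo", "gap_holo",
                 "delta_eps", "q_apo", "q_holo", "delta_q")]
  class(out) <- c("shift_profile", class(tibble::tibble()))
  out
}

new_shift_profile <- function(df, truth = NULL, provenance = "synthetic") {
  df <- tibble::as_tibble(df)
  class(df) <- c("shift_profile", class(tibble::tibble()))
  attr(df, "truth") <- truth
  attr(df, "provenance") <- provenance
  df
}

#' Convergence radius of the MO-shift profile
#'
#' Finds the radius R_conv beyond which gap perturbations are negligible:
#' in `strict` mode, the smallest sampled R such that every fragment with
#' `rmin > R` has `|delta_eps| <= delta` (0 when all rows already satisfy
#' the bound); in `quantile` mode "every" is relaxed to the `q`-quantile of
#' `|delta_eps|` over the tail beyond each candidate radius. The fragments
#' selected by `rmin <= R_conv` constitute the MO-based QM region.
#'
#' @param profile A [mo_shift_profile()] tibble.
#' @param delta Gap-shift tolerance in eV (default 0.01).
#' @param mode `"strict"` or `"quantile"`.
#' @param q Quantile level for quantile mode (default 0.95).
#' @return A list of class `convergence_radius` with `r_conv` (Angstrom),
#'   `converged` flag, `tail_max` (max |delta_eps| beyond `r_conv`),
#'   `offenders` (fragments still above `delta` just below `r_conv`), and
#'   the settings used.
#' @export
convergence_radius <- function(profile, delta = 0.01,
                               mode = c("strict", "quantile"), q = 0.95) {
  mode <- match.arg(mode)
  if (nrow(profile) == 0) rlang::abort("profile is empty")
  if (delta <= 0) rlang::abort("delta must be positive")
  pr <- dplyr::arrange(tibble::as_tibble(profile), .data$rmin, .data$fragment_id)
  abs_eps <- abs(pr$delta_eps)
  n <- nrow(pr)

  tail_stat <- function(above_idx) {
    if (length(above_idx) == 0) return(0)
    v <- abs_eps[above_idx]
    if (mode == "strict") max(v) else stats::quantile(v, q, names = FALSE, type = 7)
  }

  # The largest sampled radius is excluded from the candidate list: beyond
  # it there is no data, so declaring convergence there would be vacuous.
  r_top <- max(pr$rmin)
  candidates <- c(0, pr$rmin[pr$rmin < r_top])
  r_conv <- NA_real_
  for (r in candidates) {
    above <- which(pr$rmin > r)
    if (tail_stat(above) <= delta) { r_conv <- r; break }
  }
  converged <- !is.na(r_conv)
  if (!converged) r_conv <- r_top
  above <- which(pr$rmin > r_conv)
  offenders <- pr[pr$rmin <= r_conv & abs_eps > delta, c("fragment_id", "name", "rmin", "delta_eps")]
  out <- list(
    r_conv = r_conv,
    converged = converged,
    tail_max = if (length(above) > 0) max(abs_eps[above]) else 0,
    offenders = offenders,
    delta = delta, mode = mode, q = if (mode == "quantile") q else NA_real_,
    n_fragments = n
  )
  class(out) <- "convergence_radius"
  out
}

#' @export
print.convergence_radius <- function(x, ...) {
  cat(sprintf("<convergence_radius> R_conv = %.3f A (%s mode, delta = %g eV)%s\n",
              x$r_conv, x$mode, x$delta,
              if (x$converged) "" else "  [NOT converged: no radius satisfies the criterion]"))
  cat(sprintf("  tail max |delta_eps| beyond R_conv: %.4g eV; %d fragments\n",
              x$tail_max, x$n_fragments))
  invisible(x)
}

#' @export
glance.convergence_radius <- function(x, ...) {
  tibble::tibble(r_conv = x$r_conv, converged = x$converged,
                 tail_max = x$tail_max, delta = x$delta, mode = x$mode,
                 n_fragments = x$n_fragments)
}

#' Write or read a shift profile as TSV
#'
#' Columns: `fragment_id`, `name`, `rmin_A`, `gap_apo_eV`, `gap_holo_eV`,
#' `delta_eps_eV`, `q_apo_e`, `q_holo_e`, `delta_q_e`.
#'
#' @param profile A shift profile.
#' @param path File path.
#' @return `write_shift_profile()` returns `path` invisibly;
#'   `read_shift_profile()` returns a `shift_profile` tibble.
#' @export
write_shift_profile <- function(profile, path) {
  out <- tibble::as_tibble(profile)
  names(out) <- c("fragment_id", "name", "rmin_A", "gap_apo_eV",
                  "gap_holo_eV", "delta_eps_eV", "q_apo_e", "q_holo_e",
                  "delta_q_e")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_shift_profile
#' @export
read_shift_profile <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  names(df) <- c("fragment_id", "name", "rmin", "gap_apo", "gap_holo",
                 "delta_eps", "q_apo", "q_holo", "delta_q")
  new_shift_profile(df, provenance = path)
}
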