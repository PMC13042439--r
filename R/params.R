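#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
NULL

# 1 eV in kcal/mol, used for all interface-level energy reporting.
EV_TO_KCAL <- 23.0609

# Coulomb constant in eV * Angstrom * e^-2.
K_E <- 14.399

default_element_table <- function() {
  tibble::tribble(
    ~element, ~alpha,  ~n0, ~U,   ~A_rep, ~rho, ~C6,
    "H",      -7.0,    1,   6.0,  20,     0.30, 2,
    "C",      -8.0,    1,   5.0,  80,     0.35, 16,
    "N",      -9.5,    1,   5.5,  90,     0.34, 12,
    "O",      -11.0,   2,   6.0,  100,    0.33, 10,
    "Si",     -7.5,    1,   4.0,  150,    0.40, 80,
    "Al",     -3.5,    1,   3.8,  140,    0.40, 60,
    "F",      -13.0,   2,   7.0,  90,     0.30, 6,
    "Cl",     -11.5,   2,   5.0,  120,    0.36, 40,
    "Br",     -11.0,   2,   4.5,  130,    0.38, 70,
    "I",      -10.5,   2,   4.0,  140,    0.40, 120
  )
}

#' Parameter set for the one-orbital tight-binding engine
#'
#' Builds the parameter object consumed by [scc_solve()] and the FMO layer.
#' The model places a single s-like orbital on every atom in an orthogonal
#' basis. Per-element parameters are the onsite energy `alpha` (eV), the
#' valence electron count `n0` filling that orbital in the neutral atom, the
#' Hubbard `U` (eV) controlling charge stiffness, a Born-Mayer repulsion
#' amplitude `A_rep` (eV) with range `rho` (Angstrom), and a dispersion
#' coefficient `C6` (eV A^6). Global parameters control the distance-decaying
#' hopping integral, the damped dispersion sum, and the self-consistent-charge
#' (SCC) loop.
#'
#' @param elements Data frame of per-element parameters overriding/extending
#'   the shipped table (columns `element`, `alpha`, `n0`, `U`, `A_rep`,
#'   `rho`, `C6`).
#' @param beta0 Hopping prefactor in eV; must be negative (bonding).
#' @param kappa Hopping decay constant, 1/Angstrom.
#' @param r0 Hopping reference distance, Angstrom.
#' @param hop_cutoff Distance beyond which hopping is exactly zero, Angstrom.
#' @param r_damp Dispersion damping radius, Angstrom.
#' @param mixing Linear SCC mixing factor in (0, 1].
#' @param scc_tol SCC convergence tolerance on the max atomic-charge change, e.
#' @param max_iter Maximum SCC iterations.
#' @return An object of class `toy_params`.
#' @examples
#' p <- toy_params()
#' p$elements
#' @export
toy_params <- function(elements = NULL,
                       beta0 = -2.5,
                       kappa = 1.2,
                       r0 = 1.4,
                       hop_cutoff = 6.0,
                       r_damp = 3.0,
                       mixing = 0.2,
                       scc_tol = 1e-6,
                       max_iter = 200) {
  el <- default_element_table()
  if (!is.null(elements)) {
    elements <- tibble::as_tibble(elements)
    need <- c("element", "alpha", "n0", "U", "A_rep", "rho", "C6")
    missing_cols <- setdiff(need, names(elements))
    if (length(missing_cols) > 0) {
      rlang::abort(paste0("element table misses columns: ",
                          paste(missing_cols, collapse = ", ")))
    }
    el <- dplyr::bind_rows(
      elements[, need],
      el[!el$element %in% elements$element, ]
    )
  }
  if (beta0 >= 0) rlang::abort("beta0 must be negative (bonding hopping)")
  if (any(el$U <= 0)) rlang::abort("Hubbard U must be positive for all elements")
  if (hop_cutoff <= 0 || r_damp <= 0) rlang::abort("cutoffs must be positive")
  if (mixing <= 0 || mixing > 1) rlang::abort("mixing must lie in (0, 1]")
  out <- list(
    elements = el,
    beta0 = beta0, kappa = kappa, r0 = r0, hop_cutoff = hop_cutoff,
    k_e = K_E, r_damp = r_damp,
    mixing = mixing, scc_tol = scc_tol, max_iter = max_iter
  )
  class(out) <- "toy_params"
  out
}

#' @export
print.toy_params <- function(x, ...) {
  cat("<toy_params> one-orbital SCC tight-binding parameter set\n")
  cat(sprintf("  elements: %s\n", paste(x$elements$element, collapse = " ")))
  cat(sprintf("  hopping: beta0 = %g eV, kappa = %g 1/A, r0 = %g A, cutoff = %g A\n",
              x$beta0, x$kappa, x$r0, x$hop_cutoff))
  cat(sprintf("  SCC: mixing %g, tol %g e, max %d iterations\n",
              x$mixing, x$scc_tol, x$max_iter))
  invisible(x)
}

#' Read or write an engine parameter set
#'
#' Parameter sets serialize to JSON with one block per element plus the global
#' block, so external runs can pin the exact Hamiltonian.
#'
#' @param path File path.
#' @return `read_toy_params()` returns a `toy_params` object;
#'   `write_toy_params()` returns `path` invisibly.
#' @export
read_toy_params <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  toy_params(
    elements = tibble::as_tibble(raw$elements),
    beta0 = raw$global$beta0, kappa = raw$global$kappa, r0 = raw$global$r0,
    hop_cutoff = raw$global$hop_cutoff, r_damp = raw$global$r_damp,
    mixing = raw$global$mixing, scc_tol = raw$global$scc_tol,
    max_iter = raw$global$max_iter
  )
}

#' @param params A `toy_params` object.
#' @rdname read_toy_params
#' @export
write_toy_params <- function(params, path) {
  stopifnot(inherits(params, "toy_params"))
  payload <- list(
    elements = params$elements,
    global = params[c("beta0", "kappa", "r0", "hop_cutoff", "r_damp",
                      "mixing", "scc_tol", "max_iter")]
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

element_params <- function(params, elements) {
  idx <- match(elements, params$elements$element)
  if (anyNA(idx)) {
    rlang::abort(paste0("unparameterized element(s): ",
                        paste(unique(elements[is.na(idx)]), collapse = ", ")))
  }
  params$elements[idx, ]
}
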