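# One-orbital self-consistent-charge (SCC) tight-binding engine.
#
# Each atom carries a single s-like orbital in an orthogonal basis. The
# Hamiltonian is
#   H_ab = beta0 * exp(-kappa * (r_ab - r0))   for r_ab <= hop_cutoff,
#   H_aa = alpha_a - sum_b gamma_ab * q_b - sum_ext gamma(r) * Q_ext,
# with a Klopman-Ohno charge kernel
#   gamma_ab = k_e / sqrt(r_ab^2 + (k_e / U_avg)^2),  gamma_aa = U_a.
# Charges are Mulliken-style (q > 0 means electron-deficient) and iterated to
# self-consistency with linear mixing. The total energy is the variationally
# consistent functional
#   E = tr(P H0) + 1/2 q' Gamma q + E_rep - E_disp + sum_a q_a V_ext(a),
# whose stationarity condition reproduces the H above; evaluating the band
# term against the charge-independent H0 avoids double counting the Coulomb
# shift that is already folded into the occupied eigenvalues.

# Klopman-Ohno kernel between sites with Hubbard parameters ua, ub at
# distances d. ua/ub may be Inf (bare point charge) -> plain k_e / d.
ko_gamma <- function(d, ua, ub) {
  uavg <- (ua + ub) / 2
  soft <- ifelse(is.finite(uavg), (K_E / uavg)^2, 0)
  K_E / sqrt(d^2 + soft)
}

# Gamma matrix for one atom set: off-diagonal Klopman-Ohno, diagonal U_a.
gamma_matrix <- function(d, U) {
  n <- length(U)
  uavg <- outer(U, U, "+") / 2
  g <- K_E / sqrt(d^2 + (K_E / uavg)^2)
  diag(g) <- U
  g
}

# External electrostatic potential (eV per unit charge) at each atom from a
# table of embedding charges. ext: data frame with x, y, z, q and optional U.
external_potential <- function(xyz, U_atoms, ext) {
  if (is.null(ext) || nrow(ext) == 0) return(numeric(nrow(xyz)))
  d <- cross_dist(xyz, cbind(ext$x, ext$y, ext$z))
  u_ext <- if ("U" %in% names(ext)) ext$U else rep(Inf, nrow(ext))
  uavg <- outer(U_atoms, u_ext, "+") / 2
  soft <- ifelse(is.finite(uavg), (K_E / uavg)^2, 0)
  g <- K_E / sqrt(d^2 + soft)
  as.numeric(g %*% ext$q)
}

# Pairwise Born-Mayer repulsion and damped dispersion sums plus the cross
# matrices (needed by the PIEDA decomposition).
rep_disp_matrices <- function(d, ep, r_damp) {
  A <- sqrt(outer(ep$A_rep, ep$A_rep))
  rho <- outer(ep$rho, ep$rho, "+") / 2
  C6 <- sqrt(outer(ep$C6, ep$C6))
  rep_m <- A * exp(-d / rho)
  disp_m <- C6 / (d^6 + r_damp^6)
  diag(rep_m) <- 0
  diag(disp_m) <- 0
  list(rep = rep_m, disp = disp_m)
}

occupation_vector <- function(n_orb, n_elec) {
  if (n_elec < 0 || n_elec > 2 * n_orb) {
    rlang::abort(sprintf("electron count %g outside [0, %d]", n_elec, 2 * n_orb))
  }
  occ <- rep(0, n_orb)
  full <- n_elec %/% 2
  if (full > 0) occ[seq_len(full)] <- 2
  if (n_elec %% 2 == 1) occ[full + 1] <- 1
  occ
}

#' Solve the self-consistent-charge tight-binding problem for an atom subset
#'
#' Builds the one-orbital Hamiltonian for the selected atoms, embeds them in
#' an optional external point-charge field, and iterates Mulliken charges to
#' self-consistency with linear mixing. Orbitals are filled from the bottom
#' with two electrons each (one singly occupied orbital for odd counts, no
#' spin polarization).
#'
#' @param structure A structure as returned by [read_structure()] or
#'   [structure_from_atoms()].
#' @param params A [toy_params()] parameter set.
#' @param subset Optional integer vector of 1-based atom indices to solve;
#'   default all atoms.
#' @param external_charges Optional data frame of embedding charges with
#'   columns `x`, `y`, `z`, `q` and optionally `U` (Hubbard parameter of the
#'   source site; `Inf`, the default, gives a bare `k_e / r` Coulomb kernel).
#' @param net_charge Net charge of the computed subset, in elementary charges.
#' @param q_init Optional initial atomic charges (warm start).
#' @param scc_tol,mixing,max_iter Optional overrides of the parameter-set
#'   SCC controls.
#' @return An object of class `electronic_state` with ascending orbital
#'   energies (eV), occupations, atomic charges (e, positive =
#'   electron-deficient), energy components and total energy (eV), the SCC
#'   iteration count and a convergence flag.
#' @examples
#' s <- structure_from_atoms(data.frame(element = c("C", "C"),
#'                                      x = c(0, 1.4), y = 0, z = 0))
#' st <- scc_solve(s, toy_params())
#' frontier_properties(st)
#' @export
scc_solve <- function(structure, params, subset = NULL,
                      external_charges = NULL, net_charge = 0,
                      q_init = NULL, scc_tol = NULL, mixing = NULL,
                      max_iter = NULL) {
  stopifnot(inherits(params, "toy_params"))
  atoms <- structure$atoms
  if (is.null(subset)) subset <- seq_len(nrow(atoms))
  if (length(subset) == 0) rlang::abort("atom subset is empty")
  atoms <- atoms[subset, , drop = FALSE]
  n <- nrow(atoms)
  ep <- element_params(params, atoms$element)

  scc_tol <- scc_tol %||% params$scc_tol
  mixing <- mixing %||% params$mixing
  max_iter <- max_iter %||% params$max_iter

  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  d <- pair_dist(xyz)

  h0 <- params$beta0 * exp(-params$kappa * (d - params$r0))
  h0[d > params$hop_cutoff] <- 0
  diag(h0) <- ep$alpha

  gam <- gamma_matrix(d, ep$U)
  v_ext <- external_potential(xyz, ep$U, external_charges)
  rd <- rep_disp_matrices(d, ep, params$r_damp)
  e_rep <- sum(rd$rep) / 2
  e_disp <- sum(rd$disp) / 2

  n_elec <- sum(ep$n0) - net_charge
  if (abs(n_elec - round(n_elec)) > 1e-9) {
    rlang::abort("electron count is not an integer; check net_charge")
  }
  n_elec <- round(n_elec)
  occ <- occupation_vector(n, n_elec)
  occ_idx <- which(occ > 0)

  run_scc <- function(q_start, mix, iter_budget) {
    q <- q_start
    iter <- 0
    delta <- Inf
    repeat {
      iter <- iter + 1
      h <- h0
      diag(h) <- ep$alpha - as.numeric(gam %*% q) - v_ext
      eig <- eigen(h, symmetric = TRUE)
      ord <- order(eig$values)           # ascending, stable
      pop <- as.numeric((eig$vectors[, ord, drop = FALSE][, occ_idx, drop = FALSE]^2) %*%
                          occ[occ_idx])
      q_new <- ep$n0 - pop
      delta <- max(abs(q_new - q))
      if (delta < scc_tol) return(list(q = q_new, iter = iter,
                                       converged = TRUE, delta = delta))
      if (iter >= iter_budget) return(list(q = q_new, iter = iter,
                                           converged = FALSE, delta = delta))
      q <- q + mix * (q_new - q)
    }
  }

  # Linear mixing with a deterministic damped restart: oscillatory cases
  # (near-degenerate frontier levels) are retried at a quarter of the mixing
  # factor with a proportionally larger iteration budget.
  res <- run_scc(q_init %||% rep(0, n), mixing, max_iter)
  iter <- res$iter
  if (!res$converged) {
    res2 <- run_scc(q_init %||% rep(0, n), mixing / 4, 4 * max_iter)
    iter <- iter + res2$iter
    res <- res2
  }
  q <- res$q
  converged <- res$converged
  if (!converged) {
    rlang::warn(sprintf("SCC not converged in %d iterations (last dq = %.3g e)",
                        iter, res$delta))
  }

  # One more diagonalization at the output charges so the reported state is
  # evaluated at a single consistent charge vector.
  h <- h0
  diag(h) <- ep$alpha - as.numeric(gam %*% q) - v_ext
  eig <- eigen(h, symmetric = TRUE)
  ord <- order(eig$values)
  evals <- eig$values[ord]
  evecs <- eig$vectors[, ord, drop = FALSE]
  pop <- as.numeric((evecs[, occ_idx, drop = FALSE]^2) %*% occ[occ_idx])
  q <- ep$n0 - pop

  c_occ <- evecs[, occ_idx, drop = FALSE]
  e_band <- sum(occ[occ_idx] * colSums(c_occ * (h0 %*% c_occ)))
  e_coul <- 0.5 * as.numeric(t(q) %*% gam %*% q)
  e_ext <- sum(q * v_ext)
  total <- e_band + e_coul + e_rep - e_disp + e_ext

  out <- list(
    orbital_energies = evals,
    occupations = occ,
    atomic_charges = q,
    energy_components = c(band = e_band, coulomb = e_coul,
                          repulsion = e_rep, dispersion = -e_disp,
                          external = e_ext),
    total_energy = total,
    scc_iterations = iter,
    converged = converged,
    n_electrons = n_elec,
    net_charge = net_charge,
    elements = atoms$element,
    atom_subset = subset
  )
  class(out) <- "electronic_state"
  out
}

#' @export
print.electronic_state <- function(x, ...) {
  fp <- tryCatch(frontier_properties(x), error = function(e) NULL)
  cat(sprintf("<electronic_state> %d atoms, %d electrons, net charge %+d\n",
              length(x$atomic_charges), x$n_electrons, x$net_charge))
  cat(sprintf("  total energy %.6f eV (%s, %d SCC iterations)\n",
              x$total_energy,
              if (x$converged) "converged" else "NOT converged",
              x$scc_iterations))
  if (!is.null(fp)) {
    cat(sprintf("  HOMO %.4f eV, LUMO %.4f eV, gap %.4f eV\n",
                fp$homo, fp$lumo, fp$gap))
  }
  invisible(x)
}

#' Frontier-orbital properties of an electronic state
#'
#' Extracts the HOMO/LUMO energies and the gap, plus Koopmans estimates of
#' the ionization potential (`ip = -homo`) and electron affinity
#' (`ea = -lumo`). For odd electron counts the singly occupied orbital counts
#' as the HOMO. Degenerate frontier levels are resolved by orbital index
#' after a stable ascending sort.
#'
#' @param state An `electronic_state` from [scc_solve()].
#' @return A one-row tibble with columns `homo`, `lumo`, `gap`, `ip`, `ea`
#'   (all eV).
#' @export
frontier_properties <- function(state) {
  stopifnot(inherits(state, "electronic_state"))
  occ_idx <- which(state$occupations > 0)
  vir_idx <- which(state$occupations == 0)
  if (length(occ_idx) == 0) rlang::abort("spectrum fully empty: no HOMO")
  if (length(vir_idx) == 0) rlang::abort("spectrum fully occupied: no LUMO")
  homo <- state$orbital_energies[max(occ_idx)]
  lumo <- state$orbital_energies[min(vir_idx)]
  tibble::tibble(homo = homo, lumo = lumo, gap = lumo - homo,
                 ip = -homo, ea = -lumo)
}

#' @export
tidy.electronic_state <- function(x, ...) {
  tibble::tibble(
    orbital = seq_along(x$orbital_energies),
    energy = x$orbital_energies,
    occupation = x$occupations
  )
}

#' @export
glance.electronic_state <- function(x, ...) {
  fp <- tryCatch(frontier_properties(x), error = function(e) {
    tibble::tibble(homo = NA_real_, lumo = NA_real_, gap = NA_real_,
                   ip = NA_real_, ea = NA_real_)
  })
  tibble::tibble(
    n_atoms = length(x$atomic_charges),
    n_electrons = x$n_electrons,
    net_charge = x$net_charge,
    total_energy = x$total_energy,
    homo = fp$homo, lumo = fp$lumo, gap = fp$gap,
    scc_iterations = x$scc_iterations,
    converged = x$converged
  )
}
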