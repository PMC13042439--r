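# Seeded generators for every input class the pipeline consumes: planted
# exponential-decay shift profiles (known analytic crossover), planted-hub
# flow graphs (known hub set), and toy host-guest structures (concentric
# quasi-uniform shells around a central guest cluster). Every generator is a
# pure function of its parameters and seed.

#' Planted exponential-decay shift profile
#'
#' Emulates the radial decay of binding-induced gap perturbations:
#' `delta_eps_i = s_i * A * exp(-R_i / lam) + eta_i` with random signs `s_i`,
#' Gaussian noise `eta ~ N(0, sigma^2)` and `R_i ~ U(0, r_max]`. The planted
#' truth stores the analytic crossover `lam * log(A / delta)` at which the
#' noiseless envelope falls below a threshold `delta`.
#'
#' @param A Decay amplitude, eV (> 0).
#' @param lam Decay length, Angstrom (> 0).
#' @param sigma Noise standard deviation, eV (>= 0).
#' @param n Number of fragments (>= 2).
#' @param r_max Largest sampled radius, Angstrom.
#' @param seed Integer seed.
#' @return A `shift_profile` tibble whose `truth` attribute holds the
#'   generator parameters and the crossover function.
#' @export
gen_decay_profile <- function(A, lam, sigma, n, r_max, seed) {
  if (A <= 0 || lam <= 0 || r_max <= 0) {
    rlang::abort("A, lam and r_max must be positive")
  }
  if (sigma < 0) rlang::abort("sigma must be non-negative")
  if (n < 2) rlang::abort("need at least 2 fragments")
  withr::with_seed(seed, {
    r <- stats::runif(n, 0, r_max)
    r[r == 0] <- r_max / n
    s <- sample(c(-1, 1), n, replace = TRUE)
    eta <- if (sigma > 0) stats::rnorm(n, 0, sigma) else numeric(n)
    delta_raw <- s * A * exp(-r / lam) + eta
    dq <- numeric(n)
    gap0 <- rep(5, n)
    gap1 <- gap0 + delta_raw
    df <- tibble::tibble(
      fragment_id = seq_len(n),
      name = sprintf("F%03d", seq_len(n)),
      rmin = r,
      gap_apo = gap0,
      gap_holo = gap1,
      delta_eps = gap1 - gap0,
      q_apo = dq, q_holo = dq, delta_q = dq
    )
    df <- dplyr::arrange(df, .data$rmin, .data$fragment_id)
    truth <- list(kind = "decay", A = A, lam = lam, sigma = sigma, n = n,
                  r_max = r_max, seed = seed,
                  crossover = function(delta) lam * log(A / delta))
    new_shift_profile(df, truth = truth)
  })
}

#' Planted-hub charge-flow network
#'
#' Builds a flow graph in which each planted hub connects to its spokes with
#' super-threshold weights and no spoke-spoke edges exist, so every hub
#' mediates `choose(n_spokes, 2)` triplets. Optional noise edges are placed
#' only between filler nodes (neither hub nor spoke) with filler degree
#' capped at 2, so no noise node can accumulate more than one mediation
#' triplet and the planted hubs stay strictly dominant.
#'
#' @param n_nodes Total node count.
#' @param n_hubs Number of planted hubs.
#' @param n_spokes Spokes per hub (>= 3 keeps hubs dominant).
#' @param noise_edges Number of filler-filler noise edges requested.
#' @param threshold Planting threshold in e; edge weights are drawn above it.
#' @param seed Integer seed.
#' @return A `flow_graph` whose `metadata$truth` lists the planted hub ids.
#' @export
gen_hub_network <- function(n_nodes = 40, n_hubs = 3, n_spokes = 4,
                            noise_edges = 6, threshold = 0.005, seed = 1) {
  if (n_hubs * (1 + n_spokes) > n_nodes) {
    rlang::abort("not enough nodes for the requested hubs and spokes")
  }
  withr::with_seed(seed, {
    ids <- seq_len(n_nodes)
    perm <- sample(ids)
    hubs <- sort(perm[seq_len(n_hubs)])
    spoke_pool <- setdiff(perm, hubs)
    spokes <- vector("list", n_hubs)
    used <- 0
    for (h in seq_len(n_hubs)) {
      spokes[[h]] <- sort(spoke_pool[used + seq_len(n_spokes)])
      used <- used + n_spokes
    }
    fillers <- setdiff(ids, c(hubs, unlist(spokes)))

    mk_edge <- function(a, b) {
      w <- stats::runif(1, 2 * threshold, 10 * threshold)
      if (stats::runif(1) < 0.5) c(a, b, w) else c(b, a, w)
    }
    edges <- list()
    for (h in seq_len(n_hubs)) {
      for (s in spokes[[h]]) {
        edges[[length(edges) + 1]] <- mk_edge(hubs[h], s)
      }
    }
    deg <- integer(n_nodes)
    placed <- 0
    attempts <- 0
    max_attempts <- 50 * max(1, noise_edges)
    existing <- character()
    while (placed < noise_edges && attempts < max_attempts) {
      attempts <- attempts + 1
      if (length(fillers) < 2) break
      uv <- sample(fillers, 2)
      key <- paste(min(uv), max(uv))
      if (key %in% existing) next
      if (deg[uv[1]] >= 2 || deg[uv[2]] >= 2) next
      edges[[length(edges) + 1]] <- mk_edge(uv[1], uv[2])
      existing <- c(existing, key)
      deg[uv] <- deg[uv] + 1
      placed <- placed + 1
    }
    if (placed < noise_edges) {
      rlang::abort(sprintf(
        "could only place %d of %d noise edges without breaking hub dominance",
        placed, noise_edges))
    }
    em <- do.call(rbind, edges)
    edge_df <- tibble::tibble(source = as.integer(em[, 1]),
                              target = as.integer(em[, 2]),
                              weight = em[, 3],
                              derived_from = "planted")
    edge_df <- dplyr::arrange(edge_df, .data$source, .data$target)
    nodes <- tibble::tibble(fragment_id = ids,
                            name = sprintf("F%03d", ids),
                            delta_q = 0, rmin = NA_real_)
    truth <- list(kind = "hubs", hubs = hubs, spokes = spokes,
                  n_nodes = n_nodes, noise_edges = noise_edges, seed = seed)
    new_flow_graph(nodes, edge_df, threshold,
                   metadata = list(truth = truth))
  })
}

# Quasi-uniform points on a unit sphere (Fibonacci spiral); consecutive
# indices are spatially adjacent, so index blocks make contiguous patches.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

random_rotation <- function() {
  # Uniform random rotation from a normalized quaternion.
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

# One compact bonded cluster: k atoms on a dimerized ring (alternating
# short/long bonds) of radius cluster_radius. The bond alternation opens a
# Peierls-like gap at half filling, so each cluster is a well-behaved closed
# shell; odd k falls back to an even ring (k = 1 is a single atom).
#
# Orientation: with `axis = NULL` the ring is rotated uniformly at random;
# with a unit `axis` the ring plane is constrained to contain that
# direction (random azimuth about it). The generator passes the radial
# direction for host fragments so every fragment presents radial extent to
# the guest — a tangentially oriented ring sits at a single distance and
# carries no distance gradient, which would make its gap response vanish by
# symmetry rather than by distance.
cluster_coords <- function(k, cluster_radius, jitter, axis = NULL) {
  if (k == 1) {
    xyz <- matrix(0, nrow = 1, ncol = 3)
  } else {
    if (k %% 2 == 0) {
      npairs <- k / 2
      pair_centre <- 2 * pi * (seq_len(npairs) - 1) / npairs
      half_short <- 0.21 * (2 * pi / npairs)
      ang <- as.numeric(rbind(pair_centre - half_short, pair_centre + half_short))
    } else {
      ang <- 2 * pi * (seq_len(k) - 1) / k
    }
    if (is.null(axis)) {
      xyz <- cbind(cluster_radius * cos(ang), cluster_radius * sin(ang), 0)
      xyz <- xyz %*% random_rotation()
    } else {
      # Orthonormal frame: axis plus a random perpendicular.
      v <- stats::rnorm(3)
      v <- v - sum(v * axis) * axis
      v <- v / sqrt(sum(v^2))
      xyz <- outer(cos(ang), axis) * cluster_radius +
        outer(sin(ang), v) * cluster_radius
    }
  }
  xyz + matrix(stats::rnorm(3 * k, 0, jitter), ncol = 3)
}

#' Toy host-guest complex generator
#'
#' Builds a guest cluster at the origin surrounded by `n_shells` concentric
#' shells of host fragments. Each host fragment is a compact bonded cluster
#' (a dimerized ring, randomly oriented, with Gaussian jitter) whose centre
#' sits on a quasi-uniform Fibonacci spiral over its shell — the desk-scale
#' analogue of residue- or framework-unit-sized fragments. Defaults emulate
#' a small templating guest
#' inside a framework cavity: dimerized, radially oriented Si/C host rings
#' (gapped closed shells whose frontier orbitals polarize across the ring)
#' and a small C/O guest cluster carrying the templating +1 charge. The guest
#' monopole perturbs nearby fragments strongly and distant ones weakly,
#' reproducing the radial decay of gap shifts the descriptors detect.
#'
#' @param n_shell_atoms Total host atoms over all shells (grouped into
#'   fragments of `atoms_per_fragment`).
#' @param cavity_radius Radius of the innermost shell of fragment centres,
#'   Angstrom.
#' @param guest_atoms Number of guest atoms: an equatorial ring of
#'   `guest_atoms - 2` atoms plus two axial caps, centred on the cavity
#'   within ~1.3 Angstrom of the origin. The default C3O2(+) is a gapped
#'   closed shell.
#' @param palette List with `host` and `guest` element vectors (recycled
#'   within each fragment; keep the per-fragment electron count even for
#'   gapped, well-converging monomers).
#' @param n_shells Number of concentric shells.
#' @param shell_gap Radial spacing between shells, Angstrom.
#' @param atoms_per_fragment Host fragment (cluster) size.
#' @param cluster_radius Host fragment ring radius, Angstrom.
#' @param guest_radius Guest equatorial ring radius, Angstrom.
#' @param guest_charge Guest formal charge (e).
#' @param jitter Positional jitter s.d., Angstrom.
#' @param seed Integer seed.
#' @return A list with `host` and `complex` structures (host atoms first,
#'   guest last, same order in both), `fragmap` (complex), `fragmap_host`,
#'   and `truth` (generator parameters, guest fragment id, minimum
#'   host-guest distance).
#' @export
gen_host_guest <- function(n_shell_atoms = 44, cavity_radius = 5,
                           guest_atoms = 5,
                           palette = list(host = c("Si", "C"),
                                          guest = c("C", "O")),
                           n_shells = 3, shell_gap = 4.5,
                           atoms_per_fragment = 4, cluster_radius = 1.2,
                           guest_radius = 0.81, guest_charge = 1,
                           jitter = 0.1, seed = 1) {
  if (n_shell_atoms < 1 || guest_atoms < 1) {
    rlang::abort("need at least one host and one guest atom")
  }
  withr::with_seed(seed, {
    radii <- cavity_radius + shell_gap * (seq_len(n_shells) - 1)
    n_frag_total <- max(n_shells, round(n_shell_atoms / atoms_per_fragment))
    w <- radii^2 / sum(radii^2)
    counts <- pmax(1L, as.integer(round(w * n_frag_total)))
    counts[n_shells] <- counts[n_shells] + (n_frag_total - sum(counts))
    if (counts[n_shells] < 1) rlang::abort("shell fragment allocation infeasible")

    host_xyz <- NULL
    frag_atoms <- list()
    frag_shell <- integer()
    for (s in seq_len(n_shells)) {
      dirs <- fibonacci_sphere(counts[s])
      centres <- dirs * radii[s]
      for (cc in seq_len(counts[s])) {
        xyz <- cluster_coords(atoms_per_fragment, cluster_radius, jitter,
                              axis = dirs[cc, ])
        xyz <- sweep(xyz, 2, centres[cc, ], "+")
        frag_atoms[[length(frag_atoms) + 1]] <-
          nrow(host_xyz %||% matrix(0, 0, 3)) + seq_len(atoms_per_fragment)
        frag_shell <- c(frag_shell, s)
        host_xyz <- rbind(host_xyz, xyz)
      }
    }
    # Elements are assigned per dimer pair (A-A, B-B, ...), so each short
    # pair is homonuclear and the frontier orbitals of a fragment localize
    # on chemically distinct pairs at different radii.
    pair_el <- rep(rep_len(palette$host, max(1, atoms_per_fragment %/% 2)),
                   each = 2)[seq_len(atoms_per_fragment)]
    host_el <- rep(pair_el, length(frag_atoms))
    shell_of <- rep(frag_shell, each = atoms_per_fragment)

    # Guest: equatorial ring of (guest_atoms - 2) first-palette atoms capped
    # axially by two second-palette atoms (trigonal-bipyramid-like). With a
    # C3 ring and O caps the +1 cation is a gapped closed shell (the ring
    # bonding orbital is the HOMO, the degenerate antibonding pair the LUMO).
    n_eq <- guest_atoms - 2
    eq_ang <- 2 * pi * (seq_len(n_eq) - 1) / n_eq
    cap <- 1.48 * guest_radius
    g_xyz <- rbind(
      cbind(guest_radius * cos(eq_ang), guest_radius * sin(eq_ang), 0),
      cbind(0, 0, c(cap, -cap))
    )
    g_xyz <- g_xyz %*% random_rotation() +
      matrix(stats::rnorm(3 * guest_atoms, 0, jitter), ncol = 3)
    g_el <- c(rep(palette$guest[1], n_eq),
              rep(palette$guest[length(palette$guest)], 2))

    min_hg <- min_cross_dist(host_xyz, g_xyz)
    if (min_hg < 1.5) {
      rlang::abort(sprintf(
        "cavity too small: minimum host-guest distance %.2f A", min_hg))
    }

    host <- structure_from_atoms(
      tibble::tibble(element = host_el,
                     x = host_xyz[, 1], y = host_xyz[, 2], z = host_xyz[, 3],
                     resname = "HST", resno = shell_of, chain = "A",
                     het = FALSE),
      title = sprintf("synthetic host (seed %d)", seed), net_charge = 0)
    cmplx <- structure_from_atoms(
      dplyr::bind_rows(
        host$atoms[, c("element", "x", "y", "z", "resname", "resno",
                       "chain", "het")],
        tibble::tibble(element = g_el,
                       x = g_xyz[, 1], y = g_xyz[, 2], z = g_xyz[, 3],
                       resname = "LIG", resno = max(shell_of) + 1L,
                       chain = "B", het = TRUE)),
      title = sprintf("synthetic host-guest complex (seed %d)", seed),
      net_charge = guest_charge)

    nh <- length(frag_atoms)
    fragmap <- new_fragment_map(tibble::tibble(
      id = c(seq_len(nh), nh + 1L),
      name = c(sprintf("shell%d_%02d", frag_shell, seq_len(nh)), "guest"),
      role = c(rep("host", nh), "guest"),
      formal_charge = c(rep(0, nh), guest_charge),
      atoms = c(frag_atoms, list(nrow(host_xyz) + seq_len(guest_atoms)))
    ), nrow(cmplx$atoms))
    fragmap_host <- new_fragment_map(fragmap[fragmap$role != "guest", ],
                                     nrow(host$atoms))

    truth <- list(kind = "complex", seed = seed,
                  cavity_radius = cavity_radius, radii = radii,
                  n_shells = n_shells, guest_fragment_id = nh + 1L,
                  guest_charge = guest_charge, min_host_guest = min_hg,
                  shell_of_fragment = frag_shell)
    list(host = host, complex = cmplx, fragmap = fragmap,
         fragmap_host = fragmap_host, truth = truth)
  })
}
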