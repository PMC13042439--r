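# Shared fixtures: bare-bones parameter sets with analytically known spectra
# and small randomized gapped structures for engine/FMO property tests.

# Two-level toy: one element "X" with onsite alpha, unit hopping (kappa = 0
# makes the hopping distance-independent inside the cutoff) and negligible
# charge kernel, so eigenvalues are alpha +/- |beta0| exactly.
huckel_params <- function(alpha = -5, beta0 = -1, n0 = 1, U = 1e-9,
                          hop_cutoff = 2) {
  toy_params(
    elements = data.frame(element = "X", alpha = alpha, n0 = n0, U = U,
                          A_rep = 0, rho = 0.3, C6 = 0),
    beta0 = beta0, kappa = 0, r0 = 1.0, hop_cutoff = hop_cutoff
  )
}

# Structure made only of "X" atoms at given coordinates.
x_structure <- function(xyz, net_charge = 0) {
  xyz <- matrix(xyz, ncol = 3)
  suppressWarnings(structure_from_atoms(
    data.frame(element = "X", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
    net_charge = net_charge
  ))
}

# Random dimerized heteronuclear chain (alternating C/N, alternating
# short/long bonds along a jittered direction): gapped closed shell for even
# n, converges under default engine settings.
random_chain <- function(n, seed, spread = 0.12) {
  withr::with_seed(seed, {
    bonds <- rep(c(1.25, 1.55), length.out = n - 1)
    dir <- c(1, 0, 0)
    pos <- matrix(0, n, 3)
    for (i in seq_len(n - 1)) {
      kick <- stats::rnorm(3, 0, spread)
      step <- dir + kick
      step <- step / sqrt(sum(step^2))
      pos[i + 1, ] <- pos[i, ] + bonds[i] * step
    }
    structure_from_atoms(
      data.frame(element = rep_len(c("C", "N"), n),
                 x = pos[, 1], y = pos[, 2], z = pos[, 3])
    )
  })
}

# Rigid motion: random rotation plus translation.
rigid_motion <- function(structure, seed) {
  withr::with_seed(seed, {
    q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    R <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
                  2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
                  2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
                nrow = 3, byrow = TRUE)
    tr <- stats::runif(3, -20, 20)
    at <- structure$atoms
    xyz <- as.matrix(at[, c("x", "y", "z")]) %*% t(R)
    at$x <- xyz[, 1] + tr[1]; at$y <- xyz[, 2] + tr[2]; at$z <- xyz[, 3] + tr[3]
    out <- structure
    out$atoms <- at
    out
  })
}

# Single-fragment map covering a whole structure.
whole_map <- function(structure, role = "guest", formal_charge = 0) {
  build_fragment_map(
    structure, "explicit",
    explicit = list(list(atoms = seq_len(nrow(structure$atoms)), role = role,
                         formal_charge = formal_charge)),
    require_guest = FALSE
  )
}

# Two-fragment far-apart fixture: two 4-atom C chains separated by `gap` A,
# second fragment flagged guest. Neutral, nonpolar, closed shell.
far_pair_fixture <- function(gap = 50, seed = 1, polar = TRUE) {
  a <- random_chain(4, seed)
  b <- random_chain(4, seed + 1000)
  if (!polar) {
    a$atoms$element <- "C"
    b$atoms$element <- "C"
  }
  at_b <- b$atoms
  at_b$x <- at_b$x + gap
  at_b$resno <- 2L
  cmplx <- structure_from_atoms(dplyr::bind_rows(a$atoms, at_b))
  fm <- build_fragment_map(
    cmplx, "explicit",
    explicit = list(list(atoms = 1:4, role = "host"),
                    list(atoms = 5:8, role = "guest")),
    require_guest = FALSE
  )
  list(structure = cmplx, fragmap = fm)
}

quiet <- function(expr) {
  withCallingHandlers(expr, warning = function(w) invokeRestart("muffleWarning"))
}
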