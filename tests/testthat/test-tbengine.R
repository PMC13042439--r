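# SCC tight-binding engine: analytic spectra, charge self-consistency,
# energy invariances.

test_that("homonuclear dimer reproduces the two-level spectrum alpha +/- |beta|", {
  p <- huckel_params(alpha = -5, beta0 = -1)
  s <- x_structure(c(0, 0, 0, 1.4, 0, 0))
  st <- scc_solve(s, p)
  expect_equal(st$orbital_energies, c(-6, -4), tolerance = 1e-10)
  expect_equal(st$atomic_charges, c(0, 0), tolerance = 1e-8)
  fp <- frontier_properties(st)
  expect_equal(fp$homo, -6, tolerance = 1e-10)
  expect_equal(fp$lumo, -4, tolerance = 1e-10)
  expect_equal(fp$gap, 2, tolerance = 1e-10)
  expect_equal(fp$ip, 6, tolerance = 1e-10)
  expect_equal(fp$ea, 4, tolerance = 1e-10)
})

test_that("an isolated atom has orbital energy alpha and band energy occ * alpha", {
  st <- scc_solve(suppressWarnings(structure_from_atoms(
    data.frame(element = "C", x = 0, y = 0, z = 0))), toy_params())
  expect_equal(st$orbital_energies, -8)
  expect_equal(st$atomic_charges, 0, tolerance = 1e-12)
  expect_equal(unname(st$energy_components["band"]), -8)
  expect_equal(st$total_energy, -8, tolerance = 1e-12)
})

test_that("six-membered ring matches the closed-form Hueckel spectrum", {
  # Regular hexagon, radius chosen so only nearest neighbours are inside the
  # hopping cutoff; kappa = 0 gives a constant beta.
  beta <- -1.3
  r <- 1 # chord (NN) = 1, next-NN = sqrt(3) > cutoff 1.2
  ang <- 2 * pi * (0:5) / 6
  p <- huckel_params(alpha = -5, beta0 = beta, hop_cutoff = 1.2)
  s <- x_structure(cbind(r * cos(ang), r * sin(ang), 0))
  st <- scc_solve(s, p)
  expected <- sort(-5 + 2 * beta * cos(2 * pi * (0:5) / 6))
  expect_equal(st$orbital_energies, expected, tolerance = 1e-9)
  fp <- frontier_properties(st)
  expect_equal(fp$homo, -5 - abs(beta), tolerance = 1e-9)
  expect_equal(fp$lumo, -5 + abs(beta), tolerance = 1e-9)
})

test_that("gap equals IP minus EA for arbitrary states", {
  for (seed in 1:5) {
    st <- scc_solve(random_chain(6, seed), toy_params())
    fp <- frontier_properties(st)
    expect_equal(fp$gap, fp$ip - fp$ea, tolerance = 1e-12)
  }
})

test_that("SCC charges and energy match an independent unmixed fixed-point oracle", {
  # 4-atom heteroatomic chain with moderate U; the oracle iterates the bare
  # fixed-point map (no mixing) to 1e-10 and recomputes the energy from its
  # own expressions.
  p <- toy_params(
    elements = data.frame(element = c("A", "B"), alpha = c(-6, -8),
                          n0 = c(1, 1), U = c(3, 3.5),
                          A_rep = c(10, 12), rho = c(0.3, 0.35),
                          C6 = c(4, 6)),
    scc_tol = 1e-12, max_iter = 2000
  )
  xyz <- cbind(c(0, 1.3, 2.8, 4.1), 0, 0)
  s <- suppressWarnings(structure_from_atoms(
    data.frame(element = c("A", "B", "A", "B"),
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])))
  st <- scc_solve(s, p)

  ep <- qmregion:::element_params(p, s$atoms$element)
  d <- as.matrix(dist(xyz))
  h0 <- p$beta0 * exp(-p$kappa * (d - p$r0)); h0[d > p$hop_cutoff] <- 0
  diag(h0) <- ep$alpha
  uavg <- outer(ep$U, ep$U, "+") / 2
  gam <- 14.399 / sqrt(d^2 + (14.399 / uavg)^2); diag(gam) <- ep$U
  q <- rep(0, 4)
  for (i in 1:5000) {
    h <- h0; diag(h) <- ep$alpha - as.numeric(gam %*% q)
    e <- eigen(h, symmetric = TRUE)
    ord <- order(e$values)
    V <- e$vectors[, ord]
    pop <- 2 * rowSums(V[, 1:2]^2)
    qn <- ep$n0 - pop
    if (max(abs(qn - q)) < 1e-10) { q <- qn; break }
    q <- qn
  }
  expect_lt(max(abs(qn - q)), 1e-10) # oracle itself converged
  expect_equal(st$atomic_charges, q, tolerance = 1e-7)

  h <- h0; diag(h) <- ep$alpha - as.numeric(gam %*% q)
  e <- eigen(h, symmetric = TRUE); ord <- order(e$values)
  V <- e$vectors[, ord]
  band <- 2 * sum(V[, 1] * (h0 %*% V[, 1])) + 2 * sum(V[, 2] * (h0 %*% V[, 2]))
  coul <- 0.5 * as.numeric(t(q) %*% gam %*% q)
  A <- sqrt(outer(ep$A_rep, ep$A_rep)); rho <- outer(ep$rho, ep$rho, "+") / 2
  C6 <- sqrt(outer(ep$C6, ep$C6))
  rep_m <- A * exp(-d / rho); diag(rep_m) <- 0
  disp_m <- C6 / (d^6 + p$r_damp^6); diag(disp_m) <- 0
  e_oracle <- band + coul + sum(rep_m) / 2 - sum(disp_m) / 2
  expect_equal(st$total_energy, e_oracle, tolerance = 1e-7)
})

test_that("occupations are 0/1/2, sum to the electron count, odd counts leave a SOMO", {
  st <- scc_solve(random_chain(6, 3), toy_params())
  expect_true(all(st$occupations %in% c(0, 1, 2)))
  expect_equal(sum(st$occupations), st$n_electrons)

  st_odd <- quiet(scc_solve(random_chain(6, 3), toy_params(), net_charge = 1))
  expect_equal(sum(st_odd$occupations), st_odd$n_electrons)
  expect_equal(sum(st_odd$occupations == 1), 1)
})

test_that("total charge is conserved to machine precision on converged solves", {
  for (seed in 1:10) {
    n <- sample(4:12, 1) * 2
    st <- quiet(scc_solve(random_chain(n, seed), toy_params()))
    expect_lt(abs(sum(st$atomic_charges) - st$net_charge), 1e-10)
  }
})

test_that("energies and charges are invariant under rigid motion", {
  s <- random_chain(8, 11)
  st0 <- scc_solve(s, toy_params())
  for (seed in 1:3) {
    st1 <- scc_solve(rigid_motion(s, seed), toy_params())
    expect_equal(st1$total_energy, st0$total_energy, tolerance = 1e-8)
    expect_equal(st1$atomic_charges, st0$atomic_charges, tolerance = 1e-7)
    expect_equal(st1$orbital_energies, st0$orbital_energies, tolerance = 1e-8)
  }
})

test_that("two neutral nonpolar subsystems 200 A apart are size consistent", {
  a <- random_chain(4, 21)
  b <- random_chain(4, 22)
  a$atoms$element <- "C"
  b$atoms$element <- "C"
  at_b <- b$atoms; at_b$x <- at_b$x + 200
  un <- structure_from_atoms(dplyr::bind_rows(a$atoms, at_b))
  tp <- toy_params(scc_tol = 1e-12)
  st_a <- scc_solve(a, tp)
  st_b <- scc_solve(b, tp)
  st_u <- scc_solve(un, tp)
  expect_lt(abs(st_u$total_energy - (st_a$total_energy + st_b$total_energy)),
            1e-6)
  expect_lt(max(abs(st_u$atomic_charges -
                      c(st_a$atomic_charges, st_b$atomic_charges))), 1e-8)
})

test_that("a remote unit charge shifts onsite levels by about -k_e/R", {
  s <- suppressWarnings(structure_from_atoms(
    data.frame(element = "C", x = 0, y = 0, z = 0)))
  st0 <- scc_solve(s, toy_params())
  for (R in c(30, 50, 100)) {
    st <- scc_solve(s, toy_params(),
                    external_charges = data.frame(x = R, y = 0, z = 0, q = 1))
    shift <- st$orbital_energies - st0$orbital_energies
    expect_equal(shift, -14.399 / R, tolerance = abs(14.399 / R) * 0.01)
  }
})

test_that("engine input validation fails loudly", {
  p <- toy_params()
  s <- random_chain(4, 1)
  expect_error(scc_solve(s, p, subset = integer()), "empty")
  s_bad <- suppressWarnings(structure_from_atoms(
    data.frame(element = "Zz", x = 0, y = 0, z = 0)))
  expect_error(scc_solve(s_bad, p), "unparameterized")
  # fully occupied spectrum: all orbitals filled
  s_o <- suppressWarnings(structure_from_atoms(
    data.frame(element = c("O", "O"), x = c(0, 40), y = 0, z = 0)))
  st_o <- scc_solve(s_o, p)
  expect_error(frontier_properties(st_o), "fully occupied")
  expect_error(frontier_properties(
    quiet(scc_solve(s_o, p, net_charge = 4))), "fully empty")
})

test_that("hitting the iteration cap warns and flags the state", {
  expect_warning(
    st <- scc_solve(random_chain(8, 5), toy_params(max_iter = 1)),
    "not converged")
  expect_false(st$converged)
})
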