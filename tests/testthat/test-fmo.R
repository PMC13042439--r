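# FMO layer: exactness limits, embedding behaviour, PIEDA decomposition,
# binding energies.

EVK <- 23.0609

test_that("single-fragment FMO reproduces the whole-system solve", {
  s <- random_chain(8, 2)
  fm <- whole_map(s)
  r1 <- fmo1(s, fm, toy_params())
  e <- system_energy(r1, fmo2(r1))
  whole <- scc_solve(s, toy_params())
  expect_equal(as.numeric(e), whole$total_energy * EVK, tolerance = 1e-12)
})

test_that("far-separated neutral monomers equal their isolated solves", {
  fx <- far_pair_fixture(gap = 200, polar = FALSE)
  tp <- toy_params(scc_tol = 1e-12)
  r1 <- fmo1(fx$structure, fx$fragmap, tp, outer_tol = 1e-10)
  iso1 <- scc_solve(fx$structure, tp, subset = fx$fragmap$atoms[[1]])
  iso2 <- scc_solve(fx$structure, tp, subset = fx$fragmap$atoms[[2]])
  expect_lt(max(abs(r1$atomic_charges -
                      c(iso1$atomic_charges, iso2$atomic_charges))), 1e-8)
})

test_that("converged FMO1 charges do not depend on the sweep order", {
  sys <- gen_host_guest(seed = 4, n_shell_atoms = 16, n_shells = 2)
  r_fwd <- fmo1(sys$complex, sys$fragmap, toy_params(), outer_tol = 1e-8)
  fm_perm <- sys$fragmap
  # reverse the id order; atom sets unchanged
  fm_perm$id <- rev(fm_perm$id)
  part <- partition_spec(fm_perm$id)
  r_rev <- fmo1(sys$complex, fm_perm, toy_params(), partition = part,
                outer_tol = 1e-8)
  expect_lt(max(abs(r_fwd$atomic_charges - r_rev$atomic_charges)), 1e-6)
})

test_that("two-fragment FMO2 telescopes to the whole-system energy exactly", {
  fx <- far_pair_fixture(gap = 4, seed = 3)
  tp <- toy_params(scc_tol = 1e-12)
  r1 <- fmo1(fx$structure, fx$fragmap, tp, outer_tol = 1e-10)
  pr <- fmo2(r1, dimer_cutoff = Inf)
  e_fmo <- system_energy(r1, pr)
  whole <- scc_solve(fx$structure, tp)
  expect_lt(abs(e_fmo - whole$total_energy * EVK) / abs(e_fmo), 1e-9)
})

test_that("all PIEDA components vanish for far-separated neutral pairs", {
  fx <- far_pair_fixture(gap = 200, polar = FALSE)
  r1 <- fmo1(fx$structure, fx$fragmap, toy_params(scc_tol = 1e-12),
             outer_tol = 1e-10)
  pr <- fmo2(r1, dimer_cutoff = Inf)   # force the explicit dimer path
  expect_equal(pr$method, "dimer")
  expect_lt(abs(pr$es), 1e-6)
  expect_lt(abs(pr$ex), 1e-6)
  expect_lt(abs(pr$ct), 1e-6)
  expect_lt(abs(pr$di), 1e-6)
})

test_that("ES between two opposite unit charges matches the closed-form kernel", {
  # Two single-atom fragments with formal charges +1/-1 and no hopping at
  # this range: ES must equal -gamma(R) with the Klopman-Ohno kernel, and
  # the charge-transfer remainder must vanish.
  R <- 14.399
  s <- suppressWarnings(structure_from_atoms(
    data.frame(element = c("C", "C"), x = c(0, R), y = 0, z = 0)))
  fm <- build_fragment_map(
    s, "explicit",
    explicit = list(list(atoms = 1, formal_charge = 1, role = "host"),
                    list(atoms = 2, formal_charge = -1, role = "guest")))
  tp <- toy_params(scc_tol = 1e-12)
  r1 <- fmo1(s, fm, tp, outer_tol = 1e-10)
  pr <- fmo2(r1, dimer_cutoff = Inf)
  U <- 5 # carbon Hubbard parameter of the default table
  gamma_expected <- 14.399 / sqrt(R^2 + (14.399 / U)^2)
  expect_equal(pr$es, -gamma_expected * EVK, tolerance = 1e-8)
  expect_equal(pr$es, -1 * EVK, tolerance = 0.05) # within the KO softening of -k_e/R
  expect_lt(abs(pr$ct), 1e-6)
})

test_that("ES sign follows the fragment charge product", {
  R <- 10
  s <- suppressWarnings(structure_from_atoms(
    data.frame(element = c("C", "C"), x = c(0, R), y = 0, z = 0)))
  for (qs in list(c(1, -1), c(1, 1), c(-1, -1))) {
    fm <- build_fragment_map(
      s, "explicit",
      explicit = list(list(atoms = 1, formal_charge = qs[1], role = "host"),
                      list(atoms = 2, formal_charge = qs[2], role = "guest")))
    r1 <- quiet(fmo1(s, fm, toy_params(), outer_tol = 1e-8))
    pr <- fmo2(r1, dimer_cutoff = Inf)
    expect_equal(sign(pr$es), sign(prod(qs)))
  }
})

test_that("pair interactions are symmetric under fragment relabelling", {
  sys <- gen_host_guest(seed = 5, n_shell_atoms = 12, n_shells = 1)
  r1 <- fmo1(sys$complex, sys$fragmap, toy_params(), outer_tol = 1e-8)
  pr <- fmo2(r1, dimer_cutoff = Inf)
  fm_swapped <- sys$fragmap
  fm_swapped$id <- c(rev(fm_swapped$id[fm_swapped$role != "guest"]),
                     fm_swapped$id[fm_swapped$role == "guest"])
  r2 <- fmo1(sys$complex, fm_swapped, toy_params(),
             partition = partition_spec(fm_swapped$id), outer_tol = 1e-8)
  pr2 <- fmo2(r2, dimer_cutoff = Inf)
  # compare the guest/shell pair under both labellings via atom sets
  key <- function(fm, id) paste(sort(fm$atoms[[match(id, fm$id)]]), collapse = ",")
  for (r in seq_len(nrow(pr))) {
    k1 <- key(sys$fragmap, pr$i[r]); k2 <- key(sys$fragmap, pr$j[r])
    match_row <- which(vapply(seq_len(nrow(pr2)), function(rr) {
      setequal(c(key(fm_swapped, pr2$i[rr]), key(fm_swapped, pr2$j[rr])),
               c(k1, k2))
    }, TRUE))
    expect_length(match_row, 1)
    expect_equal(pr2$total[match_row], pr$total[r], tolerance = 1e-6)
    expect_equal(pr2$es[match_row], pr$es[r], tolerance = 1e-6)
  }
})

test_that("pair totals equal the sum of their components", {
  sys <- gen_host_guest(seed = 6, n_shell_atoms = 16, n_shells = 2)
  r1 <- fmo1(sys$complex, sys$fragmap, toy_params())
  pr <- fmo2(r1, dimer_cutoff = Inf)
  expect_true(all(abs(pr$total - (pr$es + pr$ex + pr$ct + pr$di)) < 1e-9))
})

test_that("three-fragment FMO2 stays within the truncation bound of the whole system", {
  # 12-atom cluster of three 4-atom chains a few Angstrom apart; the
  # two-body expansion misses only three-body terms, bounded well below
  # 2 kcal/mol at these separations.
  a <- random_chain(4, 41)$atoms
  b <- random_chain(4, 42)$atoms; b$x <- b$x + 4.5
  c_ <- random_chain(4, 43)$atoms; c_$y <- c_$y + 4.5
  s <- structure_from_atoms(dplyr::bind_rows(a, b, c_))
  fm <- build_fragment_map(s, "explicit",
                           explicit = list(list(atoms = 1:4, role = "host"),
                                           list(atoms = 5:8, role = "host"),
                                           list(atoms = 9:12, role = "guest")))
  tp <- toy_params(scc_tol = 1e-12)
  r1 <- fmo1(s, fm, tp, outer_tol = 1e-10)
  e_fmo <- system_energy(r1, fmo2(r1, dimer_cutoff = Inf))
  whole <- scc_solve(s, tp)
  expect_lt(abs(e_fmo - whole$total_energy * EVK), 2)
})

test_that("system_energy rejects pair tables from a different run", {
  fx <- far_pair_fixture(gap = 6, seed = 9)
  r1 <- fmo1(fx$structure, fx$fragmap, toy_params())
  other <- fmo1(fx$structure, fx$fragmap, toy_params(beta0 = -2))
  pr_other <- fmo2(other)
  expect_error(system_energy(r1, pr_other), "does not belong")
})

test_that("binding energy vanishes in the non-interacting neutral limit", {
  fx <- far_pair_fixture(gap = 100, polar = FALSE)
  eb <- binding_energy(fx$structure, fx$fragmap, toy_params(scc_tol = 1e-12),
                       outer_tol = 1e-10)
  expect_lt(abs(as.numeric(eb)), 1e-4)
})

test_that("all-QM binding of a host+guest pair equals the whole-system difference", {
  # 20-atom complex: one 16-atom host fragment + 4-atom guest; with a single
  # dimer the FMO2 assembly is exact, so the binding energy must match plain
  # whole-system solves.
  host <- random_chain(16, 51)
  guest <- random_chain(4, 52)
  g_at <- guest$atoms
  g_at$x <- g_at$x + max(host$atoms$x) / 2
  g_at$y <- g_at$y + 4
  s <- structure_from_atoms(dplyr::bind_rows(host$atoms, g_at))
  fm <- build_fragment_map(s, "explicit",
                           explicit = list(list(atoms = 1:16, role = "host"),
                                           list(atoms = 17:20, role = "guest")))
  tp <- toy_params(scc_tol = 1e-12)
  eb <- binding_energy(s, fm, tp, dimer_cutoff = Inf, outer_tol = 1e-10)
  w_cplx <- scc_solve(s, tp)
  w_host <- scc_solve(host, tp)
  w_guest <- scc_solve(structure_from_atoms(g_at), tp)
  direct <- (w_cplx$total_energy - w_host$total_energy - w_guest$total_energy) * EVK
  expect_equal(as.numeric(eb), direct, tolerance = 1e-6)
})

test_that("the cavity fixtures bind their guest", {
  for (seed in 1:3) {
    sys <- gen_host_guest(seed = seed)
    eb <- binding_energy(sys$complex, sys$fragmap, toy_params())
    expect_lt(as.numeric(eb), 0)
  }
})

test_that("guest IP/EA equals the isolated values without environment and
           shifts uniformly under a remote charge", {
  g <- random_chain(4, 61)
  fm <- whole_map(g)
  r1 <- fmo1(g, fm, toy_params())
  iso <- frontier_properties(scc_solve(g, toy_params()))
  emb <- guest_ip_ea(r1)
  expect_equal(emb$ip, iso$ip, tolerance = 1e-9)
  expect_equal(emb$ea, iso$ea, tolerance = 1e-9)

  # compact dimer with the charge on the perpendicular bisector: every atom
  # sits at the same distance, so the level shift is uniform
  dimer <- suppressWarnings(structure_from_atoms(
    data.frame(element = "C", x = c(-0.65, 0.65), y = 0, z = 0)))
  iso_d <- frontier_properties(scc_solve(dimer, toy_params()))
  st <- scc_solve(dimer, toy_params(),
                  external_charges = data.frame(x = 0, y = 30, z = 0, q = 1))
  fp <- frontier_properties(st)
  shift <- 14.399 / sqrt(30^2 + 0.65^2)
  expect_equal(fp$ip - iso_d$ip, shift, tolerance = 0.01)
  expect_equal(fp$ea - iso_d$ea, shift, tolerance = 0.01)
  expect_equal(fp$gap, iso_d$gap, tolerance = 1e-3)
})

test_that("guest IP/EA deviations shrink as the QM region grows", {
  devs <- matrix(0, nrow = 3, ncol = 2)
  n_seeds <- 3
  for (seed in seq_len(n_seeds)) {
    sys <- gen_host_guest(seed = seed)
    rmin <- min_distance_profile(sys$complex, sys$fragmap)
    host_ref <- fmo1(sys$host, sys$fragmap_host, toy_params())
    ref <- fmo1(sys$complex, sys$fragmap, toy_params())
    fp_ref <- guest_ip_ea(ref)
    for (k in seq_along(radii <- c(0, 6))) {
      reg <- select_region_mo_based(sys$fragmap, rmin, radii[k])
      part <- region_partition(reg, sys$fragmap)
      mm <- numeric(nrow(sys$complex$atoms))
      mm[seq_len(nrow(sys$host$atoms))] <- host_ref$atomic_charges
      r1 <- fmo1(sys$complex, sys$fragmap, toy_params(), partition = part,
                 mm_charges = mm)
      fp <- guest_ip_ea(r1)
      devs[seed, k] <- abs(fp$ip - fp_ref$ip) + abs(fp$ea - fp_ref$ea)
    }
  }
  means <- colMeans(devs[seq_len(n_seeds), , drop = FALSE])
  expect_lte(means[2], means[1])
})

test_that("PIEDA aggregation over guest pairs matches a hand loop", {
  sys <- gen_host_guest(seed = 6, n_shell_atoms = 16, n_shells = 2)
  r1 <- fmo1(sys$complex, sys$fragmap, toy_params())
  pr <- fmo2(r1, dimer_cutoff = Inf)
  g_id <- sys$fragmap$id[sys$fragmap$role == "guest"]
  agg <- pieda_aggregate(pr, g_id)
  es <- 0; total <- 0; n <- 0
  for (r in seq_len(nrow(pr))) {
    if (pr$i[r] == g_id || pr$j[r] == g_id) {
      es <- es + pr$es[r]; total <- total + pr$total[r]; n <- n + 1
    }
  }
  expect_equal(agg$es, es, tolerance = 1e-12)
  expect_equal(agg$total, total, tolerance = 1e-12)
  expect_equal(agg$n_pairs, n)
  empty <- pieda_aggregate(pr[pr$i != g_id & pr$j != g_id, ], g_id)
  expect_equal(empty$total, 0)
  expect_equal(empty$n_pairs, 0)
})

test_that("FMO2-corrected fragment charges conserve the total charge", {
  sys <- gen_host_guest(seed = 8)
  r1 <- fmo1(sys$complex, sys$fragmap, toy_params())
  pr <- fmo2(r1)
  q0 <- r1$fragments$q
  qc <- fmo2_fragment_charges(r1, pr)
  expect_equal(sum(qc$q), sum(q0), tolerance = 1e-10)
  expect_gt(max(abs(qc$q - q0)), 0) # dimers actually moved charge
})

test_that("partitions are validated against the fragment map", {
  sys <- gen_host_guest(seed = 9, n_shell_atoms = 12, n_shells = 1)
  g <- sys$fragmap$id[sys$fragmap$role == "guest"]
  hosts <- setdiff(sys$fragmap$id, g)
  expect_error(partition_spec(c(1, 2), c(2, 3)), "overlap")
  expect_error(fmo1(sys$complex, sys$fragmap, toy_params(),
                    partition = partition_spec(hosts, integer())),
               "cover|guest")
  expect_error(fmo1(sys$complex, sys$fragmap, toy_params(),
                    partition = partition_spec(setdiff(sys$fragmap$id, g), g)),
               "guest")
  expect_error(fmo1(sys$complex, sys$fragmap, toy_params(),
                    partition = partition_spec(sys$fragmap$id, integer(),
                                               "frozen_reference")),
               NA) # all-QM needs no MM charges
  part <- partition_spec(c(g, hosts[1]), hosts[-1], "frozen_reference")
  expect_error(fmo1(sys$complex, sys$fragmap, toy_params(), partition = part),
               "mm_charges")
})
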