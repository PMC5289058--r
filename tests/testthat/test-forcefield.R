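test_that("packaged parameter table loads and residues are charge-consistent", {
  ff <- read_forcefield()
  expect_true(all(ff$atoms$eps >= 0))
  expect_true(all(ff$atoms$sigma > 0))
  for (res in unique(ff$atoms$res)) {
    expect_equal(sum(ff$atoms$charge[ff$atoms$res == res]),
                 unname(ff$formal[res]), tolerance = 1e-9)
  }
  expect_match(ff$hash, "^[0-9a-f]{32}$")
})

test_that("parameter assignment covers every atom and flags offenders", {
  pa <- make_mini_domains()
  expect_false(anyNA(pa$params$charge))
  expect_false(anyNA(pa$params$sigma))
  # a ligand-like record has no parameters
  bad <- pa
  bad$atoms$resid[1] <- "LIG"
  expect_error(assign_parameters(new_assembly(bad$atoms)),
               "parameterization error.*LIG")
  # the Gln carboxamide dihedral has torsion terms attached
  ax <- tcrdom:::carboxamide_axis(pa, "A", 3L)
  expect_gt(length(tcrdom:::axis_torsion_terms(pa, ax)), 0L)
})

test_that("two-atom Lennard-Jones limits hold exactly", {
  sg <- 3.2; ep <- 0.1
  mk <- function(r) {
    a <- make_lj_dimer(sigma = sg, eps = ep, separation = r)
    nonbonded_energy(a, unit_indices(a, "VA"), unit_indices(a, "VB"))
  }
  expect_equal(mk(sg), 0, tolerance = 1e-12)          # zero crossing at sigma
  expect_equal(mk(2^(1 / 6) * sg), -ep, tolerance = 1e-12)  # minimum depth
})

test_that("nonbonded energy equals the brute-force pair-sum oracle", {
  for (seed in 1:10) {
    pa <- random_atom_system(20L, seed = seed)
    xyz <- assembly_xyz(pa)
    all_idx <- seq_len(nrow(xyz))
    pr <- oracle_pairs(nrow(xyz), pa$bonds, all_idx)
    want <- oracle_pair_sum(xyz, pa$params$charge, pa$params$sigma,
                            pa$params$eps, pr)
    got <- nonbonded_energy(pa, all_idx)
    expect_rel_equal(got, want, 1e-10)
    # symmetry of the two-group form
    ia <- unit_indices(pa, "VA"); ib <- unit_indices(pa, "VB")
    expect_identical(nonbonded_energy(pa, ia, ib),
                     nonbonded_energy(pa, ib, ia))
  }
})

test_that("charge-free systems match an LJ-only oracle and eps-free a Coulomb-only one", {
  pa_lj <- random_atom_system(16L, seed = 3, charged = FALSE)
  xyz <- assembly_xyz(pa_lj)
  idx <- seq_len(nrow(xyz))
  pr <- oracle_pairs(nrow(xyz), pa_lj$bonds, idx)
  want <- oracle_pair_sum(xyz, rep(0, 16), pa_lj$params$sigma,
                          pa_lj$params$eps, pr)
  expect_rel_equal(nonbonded_energy(pa_lj, idx), want, 1e-10)

  pa_c <- random_atom_system(16L, seed = 4, lj = FALSE)
  xyz <- assembly_xyz(pa_c)
  want <- oracle_pair_sum(xyz, pa_c$params$charge, pa_c$params$sigma,
                          rep(0, 16), pr)
  expect_rel_equal(nonbonded_energy(pa_c, idx), want, 1e-10)
})

test_that("intra-residue exclusions and 1-4 scaling follow the bond graph", {
  pa <- make_mini_domains()
  idx <- unit_indices(pa, "VA")
  xyz <- assembly_xyz(pa)
  pr <- oracle_pairs(nrow(xyz), pa$bonds, idx)
  want <- oracle_pair_sum(xyz, pa$params$charge, pa$params$sigma,
                          pa$params$eps, pr)
  expect_rel_equal(nonbonded_energy(pa, idx), want, 1e-9)
})

test_that("side-chain torsion energy is periodic and matches a per-term oracle", {
  pa <- make_mini_domains()
  e0 <- sidechain_bonded_energy(pa, "A", 3L)
  expect_equal(sidechain_bonded_energy(pa, "A", 3L, delta_angle = 2 * pi),
               e0, tolerance = 1e-12)
  # independent cosine-series evaluation over a rotation profile
  ax <- tcrdom:::carboxamide_axis(pa, "A", 3L)
  terms <- tcrdom:::axis_torsion_terms(pa, ax)
  xyz <- assembly_xyz(pa)
  for (delta in seq(-pi, pi, length.out = 13)) {
    want <- 0
    for (t in terms) {
      p <- lapply(t$atoms, function(k) xyz[k, ])
      phi <- dihedral_angle(p[[1]], p[[2]], p[[3]], p[[4]]) + delta
      want <- want + t$K * (1 + cos(t$n * phi - t$phase))
    }
    expect_equal(sidechain_bonded_energy(pa, "A", 3L, delta_angle = delta),
                 want, tolerance = 1e-12)
  }
  expect_error(sidechain_bonded_energy(pa, "A", 1L), "unsupported residue")
})

test_that("binding energy decomposes exactly and vanishes for separated units", {
  pa <- make_mini_domains()
  rep1 <- binding_energy(pa)
  expect_identical(rep1$E_bind,
                   rep1$E_complex - (rep1$E_alpha + rep1$E_beta))
  expect_true(is.na(rep1$E_mu))
  # oracle: explicit inter-unit pair sum
  ia <- unit_indices(pa, "VA"); ib <- unit_indices(pa, "VB")
  xyz <- assembly_xyz(pa)
  pr <- oracle_pairs(nrow(xyz), pa$bonds, ia, ib)
  want <- oracle_pair_sum(xyz, pa$params$charge, pa$params$sigma,
                          pa$params$eps, pr)
  expect_equal(rep1$E_bind, want, tolerance = 1e-9)
  # duplicate assembly gives an identical report (determinism)
  expect_identical(unclass(binding_energy(pa)), unclass(rep1))
  # separated units do not interact
  far <- pa
  xyz2 <- xyz
  xyz2[ib, ] <- xyz2[ib, ] + matrix(rep(c(5e4, 0, 0), each = length(ib)),
                                    ncol = 3)
  far <- set_assembly_xyz(far, xyz2)
  expect_lt(abs(binding_energy(far)$E_bind), 1e-8)
})

test_that("energies are invariant under a global rigid motion", {
  pa <- make_mini_ternary()
  e1 <- binding_energy(pa)
  pose <- rigid_pose(c(0.4, -1.1, 0.7), c(12, -8, 5))
  moved <- set_assembly_xyz(pa, apply_rigid_pose(assembly_xyz(pa), pose,
                                                 c(1, 2, 3)))
  e2 <- binding_energy(moved)
  expect_rel_equal(e2$E_complex, e1$E_complex, 1e-8)
  expect_lt(abs(e2$E_bind - e1$E_bind), 1e-6)
  # three-unit report carries E_mu and the same exact identity
  expect_identical(e1$E_bind,
                   e1$E_complex - (e1$E_alpha + e1$E_beta + e1$E_mu))
})
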