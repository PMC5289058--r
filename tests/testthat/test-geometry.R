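box_corners <- function(a = 2, b = 1, c = 0.5) {
  as.matrix(expand.grid(x = c(-a, a), y = c(-b, b), z = c(-c, c)))
}

test_that("cuboid fitting recovers symmetric boxes and is equivariant", {
  cb <- fit_cuboid(box_corners())
  expect_equal(cb$center, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(abs(cb$axes), diag(3), tolerance = 1e-9)
  expect_equal(unname(cb$extents), c(2, 1, 0.5), tolerance = 1e-12)
  # rotating the points rotates the axes by exactly the same matrix
  withr::with_seed(9, {
    pts <- matrix(stats::rnorm(60, sd = 3), 20, 3) %*% diag(c(3, 1.5, 0.7))
    R <- rotation_from_vector(c(0.4, -0.9, 0.2))
    c1 <- fit_cuboid(pts)
    c2 <- fit_cuboid(pts %*% t(R))
    expect_lt(max(abs(c2$axes - R %*% c1$axes)), 1e-9)
    expect_equal(c2$extents, c1$extents, tolerance = 1e-9)
  })
  expect_error(fit_cuboid(cbind(1:5, 2 * (1:5), -1 * (1:5))),
               "geometry error")
  expect_error(fit_cuboid(matrix(0, 3, 3)), "geometry error")
})

test_that("Euler measurement is exact on axis rotations and round-trips", {
  expect_equal(as.numeric(measure_orientation(diag(3))), c(0, 0, 0))
  R30 <- rotation_from_vector(c(pi / 6, 0, 0))
  expect_equal(as.numeric(measure_orientation(R30)), c(30, 0, 0),
               tolerance = 1e-9)
  withr::with_seed(13, {
    for (k in 1:20) {
      R <- rotation_from_vector(stats::rnorm(3, sd = 1))
      ang <- measure_orientation(R)
      expect_lt(max(abs(angles_to_matrix(as.numeric(ang)) - R)), 1e-9)
      back <- measure_orientation(angles_to_matrix(as.numeric(ang)))
      expect_equal(as.numeric(back), as.numeric(ang), tolerance = 1e-9)
    }
  })
  # gimbal proximity is flagged
  g <- measure_orientation(angles_to_matrix(c(20, 90, 0)))
  expect_true(attr(g, "gimbal"))
})

test_that("Valpha-frame alignment is canonical and recovers known motions", {
  pa <- make_mini_domains()  # generator output is already in the frame
  re <- align_to_va_frame(pa)
  expect_lt(max(abs(re$meta$alignment$R - diag(3))), 1e-6)
  expect_lt(max(abs(re$meta$alignment$t)), 1e-6)
  # rotate the whole assembly, realign against the original frame atoms
  R <- rotation_from_vector(c(0.7, 0.2, -0.4))
  moved <- set_assembly_xyz(pa, assembly_xyz(pa) %*% t(R))
  idx <- unit_indices(pa, "VA")
  idx <- idx[pa$atoms$elety[idx] %in% c("N", "CA", "C")]
  back <- align_to_va_frame(moved, reference = assembly_xyz(pa)[idx, ])
  expect_lt(max(abs(assembly_xyz(back) - assembly_xyz(pa))), 1e-6)
  # least-squares optimality: no random rotation beats the fit
  fit_rmsd <- sqrt(mean(rowSums((assembly_xyz(back)[idx, ] -
                                   assembly_xyz(pa)[idx, ])^2)))
  withr::with_seed(3, {
    for (k in 1:5) {
      Rr <- rotation_from_vector(stats::rnorm(3, sd = 0.5))
      alt <- assembly_xyz(moved)[idx, ] %*% t(Rr)
      alt_rmsd <- sqrt(mean(rowSums((alt - assembly_xyz(pa)[idx, ])^2)))
      expect_gte(alt_rmsd, fit_rmsd - 1e-12)
    }
  })
})

test_that("CoR_beta is the carboxamide midpoint and moves with the domains", {
  pa <- make_mini_domains()
  cor <- locate_cor_beta(pa)
  ca <- tcrdom:::carboxamide_centroid(pa, "A", 3L)
  cb <- tcrdom:::carboxamide_centroid(pa, "B", 3L)
  expect_equal(cor$point, (ca + cb) / 2, tolerance = 1e-9)
  shift <- c(3, -4, 5)
  moved <- set_assembly_xyz(pa, sweep(assembly_xyz(pa), 2, -shift))
  expect_equal(locate_cor_beta(moved)$point, cor$point + shift,
               tolerance = 1e-9)
  # no glutamine -> cor_undefined condition
  ala_only <- pa
  ala_only$atoms$resid[ala_only$atoms$resid == "GLN" &
                         ala_only$atoms$unit == "VA"] <- "XXX"
  expect_error(locate_cor_beta(ala_only), class = "cor_undefined")
})

test_that("CoR_mu is the peptide backbone centroid, a function of pMHC only", {
  pt <- make_mini_ternary()
  cor <- locate_cor_mu(pt)
  idx <- unit_indices(pt, "PMHC")
  bb <- idx[pt$atoms$chain[idx] == "P" &
              pt$atoms$elety[idx] %in% c("N", "CA", "C", "O")]
  expect_equal(cor$point, unname(colMeans(assembly_xyz(pt)[bb, ])),
               tolerance = 1e-12)
  # equivariance under rigid motion of the pMHC unit
  xyz <- assembly_xyz(pt)
  xyz[idx, ] <- apply_rigid_pose(xyz[idx, , drop = FALSE],
                                 rigid_pose(c(0, 0, 0.3), c(1, 2, 3)),
                                 cor$point)
  moved <- set_assembly_xyz(pt, xyz)
  expect_equal(locate_cor_mu(moved)$point,
               as.numeric(apply_rigid_pose(matrix(cor$point, 1),
                                           rigid_pose(c(0, 0, 0.3),
                                                      c(1, 2, 3)),
                                           cor$point)),
               tolerance = 1e-9)
  # independence from the TCR coordinates
  xyz2 <- assembly_xyz(pt)
  tcr <- c(unit_indices(pt, "VA"), unit_indices(pt, "VB"))
  xyz2[tcr, ] <- xyz2[tcr, ] + 50
  expect_equal(locate_cor_mu(set_assembly_xyz(pt, xyz2))$point, cor$point)
  # 2-unit assemblies have no CoR_mu
  expect_error(locate_cor_mu(make_mini_domains()), class = "cor_undefined")
})

test_that("start-orientation generation is pure, rigid and identity-first", {
  pa <- make_mini_domains()
  ss <- generate_start_orientations(pa)
  expect_length(ss$assemblies, 11L)
  expect_equal(as.numeric(ss$provenance[1, ]), c(0, 0, 0))
  expect_lt(max(abs(assembly_xyz(ss$assemblies[[1]]) - assembly_xyz(pa))),
            1e-12)
  vb <- unit_indices(pa, "VB")
  d0 <- as.matrix(dist(assembly_xyz(pa)[vb, ]))
  for (k in c(2, 7, 11)) {
    dk <- as.matrix(dist(assembly_xyz(ss$assemblies[[k]])[vb, ]))
    expect_lt(max(abs(dk - d0)), 1e-9)
  }
  ss2 <- generate_start_orientations(pa)
  expect_identical(assembly_xyz(ss2$assemblies[[5]]),
                   assembly_xyz(ss$assemblies[[5]]))
  expect_error(generate_start_orientations(pa, matrix(numeric(), 0, 3)),
               "configuration error")
})

test_that("pMHC pre-placement translates CoR_mu by the offset along the axis", {
  pt <- make_mini_ternary()
  cor0 <- locate_cor_mu(pt)$point
  same <- preplace_pmhc(pt, offset = 0)
  expect_equal(assembly_xyz(same), assembly_xyz(pt), tolerance = 1e-12)
  off <- preplace_pmhc(pt, offset = 15)
  expect_equal(sqrt(sum((locate_cor_mu(off)$point - cor0)^2)), 15,
               tolerance = 1e-9)
  # larger offsets never decrease the minimum TCR-pMHC distance
  tcr <- c(unit_indices(pt, "VA"), unit_indices(pt, "VB"))
  pm <- unit_indices(pt, "PMHC")
  min_d <- function(a) {
    x <- assembly_xyz(a)
    min(as.matrix(dist(rbind(x[tcr, ], x[pm, ])))[seq_along(tcr),
                                                  length(tcr) + seq_along(pm)])
  }
  d5 <- min_d(preplace_pmhc(pt, offset = 5))
  d15 <- min_d(off)
  expect_gte(d15, d5)
  # a missing axis is a configuration error
  no_axis <- pt
  no_axis$meta$pmhc_axis <- NULL
  expect_error(preplace_pmhc(no_axis, offset = 5), "configuration error")
})

test_that("the pMHC Euler pose grid is a full factorial with identity center", {
  pt <- make_mini_ternary()
  g <- generate_pmhc_pose_grid(pt, delta_deg = 5)
  expect_length(g$assemblies, 27L)
  center <- which(g$provenance$a1 == 0 & g$provenance$a2 == 0 &
                    g$provenance$a3 == 0)
  expect_equal(assembly_xyz(g$assemblies[[center]]), assembly_xyz(pt),
               tolerance = 1e-12)
  g1 <- generate_pmhc_pose_grid(pt, delta_deg = 5, values_per_axis = 1)
  expect_length(g1$assemblies, 1L)
  expect_equal(assembly_xyz(g1$assemblies[[1]]), assembly_xyz(pt),
               tolerance = 1e-12)
})

test_that("orientation reports carry angles and rotation centers", {
  pt <- make_mini_ternary()
  rep <- orientation_report(pt, id = "fixture")
  expect_equal(nrow(rep), 1L)
  expect_true(all(c("vb_a1", "corb_x", "pmhc_a1", "corm_z") %in% names(rep)))
  expect_false(anyNA(unlist(rep[, -1])))
})
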