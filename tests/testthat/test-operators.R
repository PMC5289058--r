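test_that("rigid operator objective is the inter-unit pair sum only", {
  pa <- make_mini_domains()
  cor <- locate_cor_beta(pa)
  obj <- make_objective(pa, list(rigid_operator(pa, "VB", cor)))
  ia <- unit_indices(pa, "VA"); ib <- unit_indices(pa, "VB")
  xyz <- assembly_xyz(pa)
  pr <- oracle_pairs(nrow(xyz), pa$bonds, ia, ib)
  want <- oracle_pair_sum(xyz, pa$params$charge, pa$params$sigma,
                          pa$params$eps, pr)
  expect_rel_equal(obj$fn(numeric(6)), want, 1e-10)
  # moving a unit with an empty context costs nothing
  obj0 <- make_objective(pa, list(rigid_operator(pa, "VB", cor,
                                                 context = list())))
  expect_identical(obj0$fn(c(0.2, -0.1, 0.3, 1, 2, 3)), 0)
})

test_that("rigid operator rejects an undefined center", {
  pa <- make_mini_domains()
  expect_error(rigid_operator(pa, "VB", NULL), "configuration error")
  expect_error(rigid_operator(pa, "VB", c(NA, 0, 0)), "configuration error")
})

test_that("carboxamide operator moves only the amide group, periodically", {
  pa <- make_mini_domains()
  op <- carboxamide_operator(pa, "B", 3L, context = "assembly")
  obj <- make_objective(pa, list(op))
  x0 <- assembly_xyz(pa)
  moved <- op$axis_info$moved
  x_full <- obj$apply(2 * pi)
  expect_lt(max(abs(x_full - x0)), 1e-9)           # 360 degrees = identity
  x_half <- obj$apply(pi)
  expect_identical(x_half[-moved, ], x0[-moved, ]) # only the amide moves
  expect_gt(max(abs(x_half[moved, ] - x0[moved, ])), 0.5)
  # two successive 180-degree rotations are the identity
  pa2 <- set_assembly_xyz(pa, x_half)
  obj2 <- make_objective(pa2, list(carboxamide_operator(pa2, "B", 3L,
                                                        context = "assembly")))
  expect_lt(max(abs(obj2$apply(pi) - x0)), 1e-9)
  expect_error(carboxamide_operator(pa, "A", 1L), "unsupported residue")
})

test_that("carboxamide objective profile matches from-scratch recomputation", {
  pa <- make_mini_domains()
  op <- carboxamide_operator(pa, "B", 3L, context = "assembly")
  obj <- make_objective(pa, list(op))
  ax <- op$axis_info
  x0 <- assembly_xyz(pa)
  p <- x0[ax$b_prox, ]; a <- x0[ax$b_dist, ] - p
  env <- setdiff(seq_len(nrow(x0)), ax$moved)
  pr <- oracle_pairs(nrow(x0), pa$bonds, ax$moved, env)
  for (ang in seq(0, 2 * pi, length.out = 9)[-9]) {
    xr <- x0
    xr[ax$moved, ] <- oracle_rotate(x0[ax$moved, , drop = FALSE], p, a, ang)
    want <- oracle_pair_sum(xr, pa$params$charge, pa$params$sigma,
                            pa$params$eps, pr) +
      sidechain_bonded_energy(set_assembly_xyz(pa, xr), "B", 3L)
    expect_equal(obj$fn(ang), want, tolerance = 1e-9)
  }
})

test_that("restraint operators contribute additively and vanish at rest", {
  pa <- make_mini_domains()
  cor <- locate_cor_beta(pa)
  spec <- restraint_spec(cor$point, threshold = 1, force_constant = 10)
  plain <- make_objective(pa, list(rigid_operator(pa, "VB", cor)))
  with_r <- make_objective(pa, list(rigid_operator(pa, "VB", cor),
                                    restraint_operator(pa, "VB", spec,
                                                       anchor = cor$point)))
  expect_identical(with_r$fn(numeric(6)), plain$fn(numeric(6)))  # d = 0
  theta <- c(0.1, -0.2, 0.05, 2.5, 0, 0)  # translation beyond threshold
  d <- sqrt(sum(c(2.5, 0, 0)^2))
  expect_equal(with_r$fn(theta) - plain$fn(theta),
               0.5 * 10 * (d - 1)^2, tolerance = 1e-9)
})

test_that("concurrent operators never double-count shared pairs", {
  pa <- make_mini_domains()
  cor <- locate_cor_beta(pa)
  ops <- list(rigid_operator(pa, "VB", cor),
              carboxamide_operator(pa, "A", 3L, context = "assembly"),
              carboxamide_operator(pa, "B", 3L, context = "assembly"))
  obj <- make_objective(pa, ops)
  withr::with_seed(21, {
    for (k in 1:4) {
      t1 <- stats::rnorm(8, sd = 0.3)
      t2 <- stats::rnorm(8, sd = 0.3)
      # objective differences equal full-system energy differences
      d_obj <- obj$fn(t1) - obj$fn(t2)
      d_sys <- oracle_total_energy(pa, obj$apply(t1)) -
        oracle_total_energy(pa, obj$apply(t2))
      expect_equal(d_obj, d_sys, tolerance = 1e-7)
    }
  })
})

test_that("every operator family's gradient slice matches finite differences", {
  pa <- make_mini_domains(perturb_rotation = c(6, -4, 3),
                          perturb_translation = c(0.4, 0.2, -0.3))
  cor <- locate_cor_beta(pa)
  ops <- list(rigid_operator(pa, "VB", cor),
              carboxamide_operator(pa, "A", 3L, context = "assembly"),
              carboxamide_operator(pa, "B", 3L, context = "assembly"),
              restraint_operator(pa, "VB",
                                 restraint_spec(cor$point, 0.05, 10),
                                 anchor = cor$point))
  obj <- make_objective(pa, ops)
  withr::with_seed(31, {
    theta <- stats::rnorm(obj$npar, sd = 0.05)
    g <- obj$gr(theta)
    fd <- fd_gradient(obj$fn, theta)
    expect_lt(max(abs(g - fd) / pmax(abs(fd), 1e-6)), 1e-5)
  })
  # three mobile units: parameter bookkeeping
  pt <- make_mini_ternary()
  cor_b <- locate_cor_beta(pt)
  cor_m <- locate_cor_mu(pt)
  obj3 <- make_objective(pt, list(rigid_operator(pt, "VB", cor_b),
                                  rigid_operator(pt, "PMHC", cor_m)))
  expect_equal(obj3$npar, 12L)
  expect_equal(obj3$gr(numeric(12)), fd_gradient(obj3$fn, numeric(12)),
               tolerance = 1e-4)
})

test_that("zero-interaction systems have exactly zero gradient", {
  d <- make_lj_dimer(eps = 0, separation = 1e3)
  obj <- make_objective(d, list(rigid_operator(d, "VB", c(0, 0, 0))))
  expect_equal(obj$fn(numeric(6)), 0, tolerance = 1e-40)
  expect_equal(max(abs(obj$gr(numeric(6)))), 0, tolerance = 1e-30)
})
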