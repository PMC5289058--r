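# Independent oracles used across the suite. These deliberately avoid the
# package's vectorized energy path: plain double loops and their own
# rotation arithmetic.

COULOMB_K <- 332.0636

# brute-force nonbonded sum over explicit pairs (i, j, scale_lj, scale_coul)
oracle_pair_sum <- function(xyz, charge, sigma, eps, pairs) {
  e <- 0
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    s_lj <- pairs[r, 3]; s_c <- pairs[r, 4]
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    sg <- sqrt(sigma[i] * sigma[j])
    ep <- sqrt(eps[i] * eps[j])
    e <- e + s_lj * 4 * ep * ((sg / d)^12 - (sg / d)^6) +
      s_c * COULOMB_K * charge[i] * charge[j] / d
  }
  as.numeric(e)
}

# bonded separations recomputed independently from a bond matrix by BFS
oracle_separation <- function(n, bonds, i, j) {
  adj <- vector("list", n)
  for (r in seq_len(nrow(bonds))) {
    a <- bonds[r, 1]; b <- bonds[r, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  depth <- rep(Inf, n); depth[i] <- 0
  frontier <- i
  for (d in 1:3) {
    frontier <- setdiff(unique(unlist(adj[frontier])), which(is.finite(depth)))
    depth[frontier] <- d
    if (j %in% frontier) return(d)
  }
  if (is.finite(depth[j])) depth[j] else Inf
}

# all in-scope pairs (with scales) between two index sets or within one,
# deriving exclusions only from the bond matrix
oracle_pairs <- function(n, bonds, set_a, set_b = NULL,
                         s14_lj = 0.5, s14_c = 0.5) {
  out <- NULL
  if (is.null(set_b)) {
    if (length(set_a) >= 2) {
      cmb <- t(utils::combn(set_a, 2))
    } else cmb <- matrix(numeric(), 0, 2)
  } else {
    cmb <- as.matrix(expand.grid(set_a, set_b))
    cmb <- cmb[cmb[, 1] != cmb[, 2], , drop = FALSE]
  }
  for (r in seq_len(nrow(cmb))) {
    sep <- oracle_separation(n, bonds, cmb[r, 1], cmb[r, 2])
    if (sep <= 2) next
    sc <- if (sep == 3) c(s14_lj, s14_c) else c(1, 1)
    out <- rbind(out, c(cmb[r, 1], cmb[r, 2], sc))
  }
  if (is.null(out)) matrix(numeric(), 0, 4) else out
}

# full system energy (nonbonded with exclusions + carboxamide torsions),
# recomputed from scratch for de-duplication checks
oracle_total_energy <- function(pa, xyz) {
  n <- nrow(xyz)
  pr <- oracle_pairs(n, pa$bonds, seq_len(n))
  e <- oracle_pair_sum(xyz, pa$params$charge, pa$params$sigma,
                       pa$params$eps, pr)
  qres <- unique(pa$atoms[pa$atoms$resid %in% c("ASN", "GLN"),
                          c("chain", "resno", "insert")])
  for (k in seq_len(nrow(qres))) {
    pa2 <- set_assembly_xyz(pa, xyz)
    e <- e + sidechain_bonded_energy(pa2, qres$chain[k], qres$resno[k],
                                     qres$insert[k])
  }
  e
}

# independent Rodrigues rotation for oracle-side coordinate moves
oracle_rotate <- function(xyz, point, axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  t(apply(xyz, 1, function(p) as.numeric(R %*% (p - point)) + point))
}

# central finite differences of a scalar function
fd_gradient <- function(fn, x, h = 1e-5) {
  vapply(seq_along(x), function(k) {
    e <- numeric(length(x)); e[k] <- h
    (fn(x + e) - fn(x - e)) / (2 * h)
  }, numeric(1))
}

# small random free-atom system (no bonds) as a parameterized assembly
random_atom_system <- function(n = 20L, seed = 1L, charged = TRUE,
                               lj = TRUE) {
  withr::with_seed(seed, {
    half <- ceiling(n / 2)
    xyz <- matrix(stats::runif(3 * n, 0, 12), n, 3)
    # keep pairs off the singularity
    repeat {
      d <- stats::dist(xyz)
      if (min(d) > 1.5) break
      xyz <- matrix(stats::runif(3 * n, 0, 12), n, 3)
    }
    atoms <- do.call(rbind, lapply(seq_len(n), function(k) {
      data.frame(unit = if (k <= half) "VA" else "VB",
                 chain = if (k <= half) "A" else "B",
                 resno = k, insert = "", resid = "RND",
                 elety = paste0("X", k), elesy = "C",
                 x = xyz[k, 1], y = xyz[k, 2], z = xyz[k, 3],
                 o = 1, b = 0, stringsAsFactors = FALSE)
    }))
    a <- new_assembly(atoms, meta = list(kind = "RANDOM"))
    a$params <- data.frame(
      type = "RND",
      charge = if (charged) stats::runif(n, -0.5, 0.5) else rep(0, n),
      sigma = stats::runif(n, 2.5, 3.8),
      eps = if (lj) stats::runif(n, 0.02, 0.3) else rep(0, n))
    a$bonds <- matrix(integer(), 0L, 2L)
    a$excl <- integer(); a$pairs14 <- integer()
    a$torsions <- default_forcefield()$torsions
    a$ff_hash <- "embedded"
    class(a) <- c("parameterized_assembly", class(a))
    a
  })
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / max(abs(expected), 1e-12), tol)
}
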