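test_that("the orientational metric behaves as a rotation-group distance", {
  q1 <- c(1, 0, 0, 0)
  expect_equal(orientational_distance(q1, q1), 0)
  # double cover: q and -q are the same rotation
  expect_equal(orientational_distance(q1, -q1), 0)
  expect_equal(orientational_distance(c(1, 0, 0, 0), c(0, 1, 0, 0)), pi)
  # symmetric and bounded on random pairs
  set.seed(5)
  qs <- random_quaternions(40)
  for (k in 1:20) {
    a <- qs[2 * k - 1, ]; b <- qs[2 * k, ]
    d <- orientational_distance(a, b)
    expect_equal(d, orientational_distance(b, a))
    expect_gte(d, 0); expect_lte(d, pi)
    # folding the water symmetry can only shrink the distance
    expect_lte(orientational_distance(a, b, water_symmetry = TRUE), d)
  }
})

test_that("minimum-image distances match 27-image enumeration", {
  box <- c(9, 7, 5)
  expect_equal(translational_distance(c(0, 0, 0), c(8, 0, 0), box), 1)
  expect_equal(translational_distance(c(1, 1, 1), c(1, 1, 1), box), 0)
  set.seed(6)
  for (k in 1:50) {
    # in-box points: the nearest periodic image lies within one shift
    p1 <- runif(3) * box
    p2 <- runif(3) * box
    expect_equal(translational_distance(p1, p2, box),
                 dist_27_images(p1, p2, box), tolerance = 1e-12)
  }
})

test_that("the nearest-neighbour search agrees exactly with brute force", {
  g <- gen_uniform_water_box(n_frames = 60, n_waters = 5,
                             box = c(12, 12, 12), seed = 15)
  obs <- water_observations(g$ensemble, g$topology)
  M <- nrow(obs$position)
  expect_lte(M, 500)
  cfg <- estimator_config()
  # brute force in the combined metric, same-frame exclusion
  d_bf <- vapply(seq_len(M), function(i) {
    best <- Inf
    for (j in seq_len(M)) {
      if (j == i || obs$frame_index[j] == obs$frame_index[i]) next
      dt <- translational_distance(obs$position[i, ], obs$position[j, ],
                                   obs$box)
      do <- orientational_distance(obs$quaternion[i, ],
                                   obs$quaternion[j, ])
      best <- min(best, sqrt(dt^2 + do^2))
    }
    best
  }, numeric(1))
  s_bf <- (M / obs$n_frames) * cfg$gas_constant_R *
    (mean(log(pi * d_bf^6 * M / (48 * obs$volume))) + cfg$euler_gamma)
  expect_equal(ssw_knn(obs, cfg), s_bf, tolerance = 1e-12)
})

test_that("a homogeneous sample is the estimator's zero point", {
  g <- gen_uniform_water_box(n_frames = 5000, n_waters = 1,
                             box = c(6, 6, 6), seed = 16)
  s <- ssw_knn(water_observations(g$ensemble, g$topology),
               estimator_config())
  expect_lt(abs(s), 0.1 * R_GAS)
})

test_that("Gaussian confinement matches the analytic differential entropy", {
  sigma <- 0.25; L <- 20
  g <- gen_gaussian_sites(n_frames = 5000,
                          centers = matrix(c(10, 10, 10), 1),
                          sigma = sigma, box = c(L, L, L),
                          orientation = "uniform", seed = 17)
  s <- ssw_knn(water_observations(g$ensemble, g$topology),
               estimator_config())
  s_analytic <- R_GAS * (1.5 * log(2 * pi * exp(1) * sigma^2) - log(L^3))
  expect_lt(abs(s - s_analytic) / abs(s_analytic), 0.05)
})

test_that("halving the accessible volume lowers the entropy by R ln 2", {
  L <- 8
  g1 <- gen_uniform_water_box(n_frames = 4000, n_waters = 1,
                              box = c(L, L, L), seed = 18)
  # periodic half-box realisation of the confinement; the frame volume
  # entering the estimator stays that of the full system
  g2 <- gen_uniform_water_box(n_frames = 4000, n_waters = 1,
                              box = c(L, L, L / 2), seed = 19)
  o1 <- water_observations(g1$ensemble, g1$topology)
  o2 <- water_observations(g2$ensemble, g2$topology)
  o2$volume <- rep(L^3, length(o2$volume))
  shift <- ssw_knn(o2, estimator_config()) - ssw_knn(o1, estimator_config())
  expect_lt(abs(shift - (-R_GAS * log(2))), 0.1 * R_GAS)
})

test_that("tighter translational confinement never increases the entropy", {
  vals <- vapply(c(0.2, 0.3, 0.45), function(sg) {
    g <- gen_gaussian_sites(n_frames = 1200,
                            centers = matrix(c(10, 10, 10), 1),
                            sigma = sg, box = c(20, 20, 20),
                            orientation = "fixed", seed = 20)
    ssw_knn(water_observations(g$ensemble, g$topology),
            estimator_config())
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("degenerate observation sets are rejected or trimmed with warning", {
  # duplicated observations give zero distances
  g <- gen_gaussian_sites(n_frames = 5, centers = matrix(c(5, 5, 5), 1),
                          sigma = 0.2, box = c(10, 10, 10),
                          orientation = "fixed", seed = 21)
  obs <- water_observations(g$ensemble, g$topology)
  obs$position <- obs$position[c(1, 1, 1, 1, 1), ]
  obs$frame_index <- 1:5
  expect_error(suppressWarnings(ssw_knn(obs, estimator_config())),
               "degenerate")
  obs2 <- water_observations(g$ensemble, g$topology)
  obs2$position[2, ] <- obs2$position[1, ]
  obs2$quaternion[2, ] <- obs2$quaternion[1, ]
  expect_warning(ssw_knn(obs2, estimator_config()), "zero-distance")
  # fewer than two observations cannot be estimated
  one <- lapply(obs2, function(x) if (is.matrix(x)) x[1, , drop = FALSE]
                else x[1])
  one$box <- obs2$box; one$n_frames <- 1L
  expect_error(ssw_knn(one, estimator_config()), "at least 2")
})

test_that("planted hydration sites are recovered and filtered by the surface rule", {
  centers <- rbind(c(6, 6, 6), c(14, 6, 6), c(10, 14, 10))
  g <- gen_gaussian_sites(n_frames = 400, centers = centers, sigma = 0.3,
                          box = c(20, 20, 20), seed = 22)
  sites <- cluster_hydration_sites(g$ensemble, g$topology,
                                   protein_atoms = NULL)
  expect_equal(nrow(sites), 3L)
  errs <- vapply(seq_len(3), function(s)
    min(sqrt(colSums((t(centers) -
                        as.numeric(sites[s, c("x", "y", "z")]))^2))),
    numeric(1))
  expect_true(all(errs < 0.2))
  expect_true(all(sites$occupancy > 0.9))
  # a uniform bulk box with the filter disabled yields no high-occupancy site
  gu <- gen_uniform_water_box(n_frames = 200, n_waters = 25,
                              box = c(20, 20, 20), seed = 23)
  su <- cluster_hydration_sites(gu$ensemble, gu$topology,
                                protein_atoms = NULL)
  expect_equal(nrow(su), 0L)
  # the surface filter drops loci farther than the cutoff from the protein
  prot <- data.frame(
    atom_name = "CA", residue_name = "GLY", residue_number = 1L,
    molecule_class = "protein", element = "C", partial_charge = 0,
    lj_epsilon = 0.1, lj_rmin_half = 2, is_acceptor = FALSE)
  wt <- water_box_topology(2, first_resid = 101L)
  topo <- make_topology(rbind(prot, wt$atoms[, names(prot)]),
                        wt$bonds + 1L)
  near <- c(10 + 3, 10, 10); far <- c(10 + 9, 10, 10)
  set.seed(24)
  frames <- lapply(1:200, function(f) {
    w1 <- water_coords_at(near + rnorm(3, sd = 0.2))
    w2 <- water_coords_at(far + rnorm(3, sd = 0.2))
    make_frame(rbind(c(10, 10, 10), w1, w2), c(24, 24, 24))
  })
  ens <- make_ensemble(frames, ensemble_kind = "fixed_NVT")
  kept <- cluster_hydration_sites(ens, topo, protein_atoms = 0L,
                                  surface_cutoff = 4.1)
  expect_equal(nrow(kept), 1L)
  expect_lt(abs(kept$x - near[1]), 0.3)
})

test_that("site energies match a brute-force pairwise oracle", {
  g <- gen_gaussian_sites(n_frames = 5, centers = rbind(c(6, 6, 6),
                                                        c(11, 6, 6)),
                          sigma = 0.2, box = c(16, 16, 16), seed = 25)
  topo <- g$topology
  sites <- cluster_hydration_sites(g$ensemble, topo, protein_atoms = NULL)
  bulk <- get_bulk_reference("TIP3P", 0)
  se <- site_energy(sites[1, ], g$ensemble, topo, energy_options(), bulk)
  # brute force: full water-environment interaction of the occupying water
  obs <- water_observations(g$ensemble, topo)
  opts <- energy_options()
  center <- as.numeric(sites[1, c("x", "y", "z")])
  e_frames <- vapply(seq_len(5), function(fi) {
    sel <- which(obs$frame_index == fi)
    d <- vapply(sel, function(k)
      translational_distance(obs$position[k, ], center, obs$box),
      numeric(1))
    res <- obs$residue[sel[which.min(d)]]
    at <- topo$atoms
    mol <- at$atom_index[at$residue_number == res &
                           at$molecule_class == "water"]
    env <- setdiff(at$atom_index, mol)
    fr <- g$ensemble$frames[[fi]]
    s <- 0
    for (i in mol) for (j in env) s <- s + pair_energy(i, j, fr, topo, opts)
    s
  }, numeric(1))
  expect_equal(se$E_site, mean(e_frames), tolerance = 1e-9)
  expect_equal(se$delta_E_ifst, se$E_site - se$n_eff * bulk$E_bulk,
               tolerance = 1e-12)
  # a site water with no charges and no dispersion interacts with nothing
  topo0 <- topo
  topo0$atoms$partial_charge[] <- 0
  topo0$atoms$lj_epsilon[] <- 0
  se0 <- site_energy(sites[1, ], g$ensemble, topo0, opts, bulk)
  expect_equal(se0$E_site, 0)
  expect_equal(se0$delta_E_ifst, -se0$n_eff * bulk$E_bulk)
})

test_that("free-energy accounting is exact and bulk references are coherent", {
  bulk <- get_bulk_reference("TIP3P", 0)
  expect_equal(bulk$E_bulk, -9.8)
  expect_equal(bulk$G_bulk - bulk$E_bulk, bulk$minus_T_S_bulk,
               tolerance = 0.05)
  # every bundled reference row satisfies G = E - T S within the printing
  # rounding of three 0.1-resolution values
  tab <- bulk_reference_table()
  expect_true(all(abs(tab$G_bulk - tab$E_bulk - tab$minus_T_S_bulk) <=
                    0.15 + 1e-12))
  # accounting identity on a completed site
  site <- list(delta_E_ifst = -2.4, S_sw = -0.012, n_eff = 0.97)
  done <- site_free_energy(site, bulk, estimator_config())
  expect_identical(done$delta_G_ifst,
                   done$delta_E_ifst + done$minus_T_delta_S)
  # a mean site energy equal to n_eff * E_bulk makes the energy term vanish
  s2 <- site_free_energy(list(delta_E_ifst = 0, S_sw = 0, n_eff = 1),
                         bulk, estimator_config())
  expect_equal(s2$delta_G_ifst, s2$minus_T_delta_S)
  # an inconsistent reference triple is rejected
  expect_error(bulk_reference("TIP3P", 0, -9.8, 3.5, G_bulk = -5.5),
               "inconsistent")
})
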