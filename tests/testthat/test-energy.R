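test_that("the pair kernel reproduces hand-evaluated Coulomb and LJ", {
  box <- c(50, 50, 50)
  # pure Coulomb: unit charges at 1 A
  topo <- two_atom_topology(q = c(1, 1))
  fr <- make_frame(rbind(c(10, 10, 10), c(11, 10, 10)), box)
  expect_equal(pair_energy(0L, 1L, fr, topo), 332.0636)
  fr2 <- make_frame(rbind(c(10, 10, 10), c(12, 10, 10)), box)
  expect_equal(pair_energy(0L, 1L, fr2, topo), 332.0636 / 2)
  # neutral, eps = 0 at any r
  topo0 <- two_atom_topology()
  expect_equal(pair_energy(0L, 1L, fr, topo0), 0)
  # LJ minimum: identical neutral atoms at r = rmin_ij inside switch-on
  topoLJ <- two_atom_topology(eps = c(0.2, 0.2), rmin_half = c(1.9, 1.9))
  frLJ <- make_frame(rbind(c(10, 10, 10), c(13.8, 10, 10)), box)
  expect_equal(pair_energy(0L, 1L, frLJ, topoLJ), -0.2)
  # symmetry is exact
  expect_identical(pair_energy(0L, 1L, frLJ, topoLJ),
                   pair_energy(1L, 0L, frLJ, topoLJ))
  # overlap errors out
  fr0 <- make_frame(rbind(c(1, 1, 1), c(1, 1, 1)), box)
  expect_error(pair_energy(0L, 1L, fr0, topo), "overlap")
})

test_that("excluded 1-2/1-3/1-4 pairs contribute zero energy", {
  topo <- frag_topology()
  fr <- make_frame(rbind(c(0, 0, 0), c(1.23, 0, 0), c(2.2, 1, 0),
                         c(3.2, 1, 0)), c(30, 30, 30))
  expect_equal(pair_energy(0L, 1L, fr, topo), 0)  # bonded C-O
  # N-HN bonded as well
  expect_equal(pair_energy(2L, 3L, fr, topo), 0)
  # non-excluded cross pair is nonzero
  expect_gt(abs(pair_energy(1L, 2L, fr, topo)), 0)
})

test_that("the LJ switching function is continuous and vanishes at cutoff", {
  topo <- two_atom_topology(eps = c(0.15, 0.15), rmin_half = c(1.9, 1.9))
  opts <- energy_options(vdw_switch_on = 9, vdw_cutoff = 11)
  box <- c(60, 60, 60)
  e_at <- function(r) pair_energy(
    0L, 1L, make_frame(rbind(c(20, 20, 20), c(20 + r, 20, 20)), box),
    topo, opts)
  rs <- seq(8.0, 12.0, by = 0.005)
  es <- vapply(rs, e_at, numeric(1))
  # no jump anywhere on the sweep
  expect_lt(max(abs(diff(es))), 1e-4)
  # exactly zero at and beyond the cutoff
  expect_equal(e_at(11.0), 0)
  expect_equal(e_at(11.5), 0)
  # unswitched below switch-on
  s6 <- (3.8 / 8.9)^6
  expect_equal(e_at(8.9), 0.15 * (s6^2 - 2 * s6))
})

test_that("group energies obey the half-sum identities", {
  g <- gen_uniform_water_box(n_frames = 1, n_waters = 6,
                             box = c(14, 14, 14), seed = 21)
  topo <- g$topology
  fr <- g$ensemble$frames[[1]]
  n <- nrow(topo$atoms)
  opts <- energy_options()
  total <- total_nonbonded_energy(fr, topo, opts)
  # full set reproduces the total via the 1/2 double-count identity
  expect_equal(group_energy(seq_len(n) - 1L, fr, topo, opts), total)
  # per-atom half-sums add to the total
  per_atom <- vapply(seq_len(n) - 1L, group_energy, numeric(1),
                     frame_or_ensemble = fr, topology = topo,
                     options = opts)
  expect_equal(sum(per_atom), total, tolerance = 1e-9)
  # brute-force pairwise oracle
  bf <- 0
  for (i in 0:(n - 2)) for (j in (i + 1):(n - 1))
    bf <- bf + pair_energy(i, j, fr, topo, opts)
  expect_equal(total, bf, tolerance = 1e-9)
  # two isolated atoms: the pair's group energy is exactly E_ij
  topo2 <- two_atom_topology(q = c(0.5, -0.5))
  fr2 <- make_frame(rbind(c(3, 3, 3), c(6, 3, 3)), c(20, 20, 20))
  expect_equal(group_energy(c(0L, 1L), fr2, topo2, opts),
               pair_energy(0L, 1L, fr2, topo2, opts))
  # an empty set is rejected
  expect_error(group_energy(integer(0), fr, topo, opts), "empty")
})

test_that("energies are invariant under lattice translations", {
  g <- gen_uniform_water_box(n_frames = 1, n_waters = 6,
                             box = c(14, 14, 14), seed = 22)
  topo <- g$topology
  fr <- g$ensemble$frames[[1]]
  ref <- total_nonbonded_energy(fr, topo)
  for (shift in list(c(3.1, -5.7, 0.4), c(14, 0, 0), c(28, -14, 14))) {
    fr2 <- make_frame(sweep(fr$coordinates, 2, shift, "+"), fr$box)
    expect_equal(total_nonbonded_energy(fr2, topo), ref,
                 tolerance = 1e-9)
  }
})

test_that("bonded terms match independent per-term evaluation", {
  topo <- frag_topology()
  params <- list(
    bonds = data.frame(i = c(0L, 2L), j = c(1L, 3L), kb = c(620, 440),
                       b0 = c(1.23, 1.0)),
    angles = data.frame(i = 0L, j = 1L, k = 2L, ktheta = 50,
                        theta0 = 120),
    dihedrals = data.frame(i = 0L, j = 1L, k = 2L, l = 3L, kchi = 2.5,
                           n = 2, delta = 180),
    impropers = NULL)
  co <- rbind(c(0, 0, 0), c(1.3, 0, 0), c(2.0, 1.1, 0.4),
              c(3.1, 1.4, 0.2))
  fr <- make_frame(co, c(30, 30, 30))
  e <- bonded_energy(fr, topo, params)
  # independent term-by-term evaluation
  blen <- function(a, b) sqrt(sum((co[a, ] - co[b, ])^2))
  ang <- function(a, b, c2) {
    u <- co[a, ] - co[b, ]; v <- co[c2, ] - co[b, ]
    acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2)))
  }
  dih <- function(a, b, c2, d) {
    b1 <- co[b, ] - co[a, ]; b2 <- co[c2, ] - co[b, ]
    b3 <- co[d, ] - co[c2, ]
    n1 <- c(b1[2]*b2[3]-b1[3]*b2[2], b1[3]*b2[1]-b1[1]*b2[3],
            b1[1]*b2[2]-b1[2]*b2[1])
    n2 <- c(b2[2]*b3[3]-b2[3]*b3[2], b2[3]*b3[1]-b2[1]*b3[3],
            b2[1]*b3[2]-b2[2]*b3[1])
    m1 <- c(n1[2]*b2[3]-n1[3]*b2[2], n1[3]*b2[1]-n1[1]*b2[3],
            n1[1]*b2[2]-n1[2]*b2[1]) / sqrt(sum(b2^2))
    atan2(sum(m1 * n2), sum(n1 * n2))
  }
  expected <- 620 * (blen(1, 2) - 1.23)^2 + 440 * (blen(3, 4) - 1.0)^2 +
    50 * (ang(1, 2, 3) - 120 * pi / 180)^2 +
    2.5 * (1 + cos(2 * dih(1, 2, 3, 4) - pi))
  expect_equal(e, expected, tolerance = 1e-10)
  # equilibrium geometry scores zero
  co_eq <- rbind(c(0, 0, 0), c(1.23, 0, 0), c(10, 0, 0), c(11, 0, 0))
  fr_eq <- make_frame(co_eq, c(40, 40, 40))
  p_eq <- list(bonds = data.frame(i = c(0L, 2L), j = c(1L, 3L),
                                  kb = c(620, 440), b0 = c(1.23, 1.0)))
  expect_equal(bonded_energy(fr_eq, topo, p_eq), 0, tolerance = 1e-12)
  # a single bond stretched by delta scores k * delta^2
  co_st <- co_eq; co_st[2, 1] <- 1.23 + 0.1
  expect_equal(bonded_energy(make_frame(co_st, c(40, 40, 40)), topo, p_eq),
               620 * 0.1^2, tolerance = 1e-10)
  # missing bond parameter names the term
  expect_error(bonded_energy(fr, topo,
                             list(bonds = data.frame(i = 0L, j = 1L,
                                                     kb = 620,
                                                     b0 = 1.23))),
               "no bond parameter")
})

test_that("per-atom decomposition conserves the total and partitions by polarity", {
  toy <- gen_two_state_toy(n_frames = 3, n_waters = 6, seed = 31)
  tab <- atom_energy_table(toy$compact, toy$extended, toy$topology)
  expect_equal(tab$sums[["polar"]] + tab$sums[["nonpolar"]],
               tab$sums[["total"]], tolerance = 1e-9)
  expect_equal(sum(tab$table$delta_E_atom), tab$sums[["total"]],
               tolerance = 1e-9)
  expect_equal(tab$table$delta_E_atom,
               tab$table$E_atom_native - tab$table$E_atom_extended)
  # protein-atom half-sums plus water/ion half-sums recover the frame total
  fr <- toy$compact$frames[[1]]
  n <- nrow(toy$topology$atoms)
  per_atom <- vapply(seq_len(n) - 1L, group_energy, numeric(1),
                     frame_or_ensemble = fr, topology = toy$topology)
  expect_equal(sum(per_atom), total_nonbonded_energy(fr, toy$topology),
               tolerance = 1e-9)
})

test_that("the class-pair breakdown partitions the total energy", {
  # protein + waters + two ions
  toy <- gen_two_state_toy(n_frames = 2, n_waters = 5, seed = 41)
  at <- toy$topology$atoms
  ion_rows <- data.frame(
    atom_name = c("SOD", "CLA"), residue_name = c("SOD", "CLA"),
    residue_number = c(900L, 901L), molecule_class = "ion",
    element = c("NA", "CL"), partial_charge = c(1, -1),
    lj_epsilon = c(0.0469, 0.15), lj_rmin_half = c(1.41, 2.27),
    is_acceptor = FALSE)
  cols <- names(ion_rows)
  topo <- make_topology(rbind(at[, cols], ion_rows), toy$topology$bonds)
  frames <- lapply(toy$compact$frames, function(f)
    make_frame(rbind(f$coordinates, c(2, 2, 2), c(28, 28, 28)), f$box))
  ens <- make_ensemble(frames, state_label = "native")
  bd <- component_breakdown(ens, topo)
  expect_setequal(bd$interaction,
                  c("protein-protein", "protein-water", "protein-salt",
                    "water-water", "water-salt", "salt-salt"))
  total <- mean(vapply(frames, total_nonbonded_energy, numeric(1),
                       topology = topo))
  expect_equal(sum(bd$energy), total, tolerance = 1e-6 * abs(total))
  # a pure water box collapses to a single water-water entry
  g <- gen_uniform_water_box(n_frames = 2, n_waters = 5,
                             box = c(14, 14, 14), seed = 42)
  bd2 <- component_breakdown(g$ensemble, g$topology)
  expect_equal(bd2$interaction, "water-water")
  expect_equal(bd2$energy,
               mean(vapply(g$ensemble$frames, total_nonbonded_energy,
                           numeric(1), topology = g$topology)))
})

test_that("state energy differences behave as planted", {
  toy <- gen_two_state_toy(n_frames = 4, n_waters = 6, seed = 51)
  # a state compared with itself scores zero
  expect_equal(state_energy_difference(toy$compact, toy$compact,
                                       toy$topology), 0)
  # particle inventories must match
  other <- water_box_topology(6)
  expect_error(
    state_energy_difference(toy$compact, toy$compact, toy$topology,
                            state_topology = other),
    "inventory")
  # replicate aggregation returns mean and spread
  reps_a <- list(toy$compact, toy$compact)
  reps_b <- list(toy$extended, toy$extended)
  res <- state_energy_difference(reps_b, reps_a, toy$topology)
  expect_named(res, c("delta", "std", "per_replicate"))
  expect_equal(res$std, 0)
})
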