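test_that("hydrogen-bond cutoffs are boundary-inclusive as worded", {
  topo <- frag_topology()
  # collinear N-H...O at exactly 3.2 A: detected
  expect_equal(nrow(detect_hbonds(hb_frame(3.2, 180), topo)), 1L)
  # just outside the distance cutoff: not detected
  expect_equal(nrow(detect_hbonds(hb_frame(3.21, 180), topo)), 0L)
  # angle boundary at fixed 2.8 A separation
  expect_equal(nrow(detect_hbonds(hb_frame(2.8, 130.0), topo)), 1L)
  expect_equal(nrow(detect_hbonds(hb_frame(2.8, 129.5), topo)), 0L)
  expect_equal(nrow(detect_hbonds(hb_frame(2.8, 130.1), topo)), 1L)
  # the report names donor, hydrogen, acceptor
  det <- detect_hbonds(hb_frame(2.9, 170), topo)
  expect_equal(det$donor, 2L)
  expect_equal(det$hydrogen, 3L)
  expect_equal(det$acceptor, 1L)
})

test_that("non-polar detection honours element, bonding and residue rules", {
  topo <- phe_pair_topology()
  co <- matrix(0, 6, 3)
  co[1, ] <- c(10, 10, 10); co[2, ] <- c(11.4, 10, 10)
  co[3, ] <- c(8.6, 10, 10)
  co[4, ] <- c(10, 18, 10); co[5, ] <- c(11.4, 14.4, 10)
  co[6, ] <- c(8.6, 18, 10)
  fr <- make_frame(co, box30)
  det <- detect_nonpolar(fr, topo)
  # CD1(res47)-CD1(res58) at 4.4 A detected; same-residue pairs never are
  expect_true(any(det$i == 1L & det$j == 4L))
  expect_false(any(topo$atoms$residue_number[det$i + 1] ==
                     topo$atoms$residue_number[det$j + 1]))
  # boundary inclusivity at 4.5 / just beyond
  co2 <- co; co2[5, ] <- c(10, 14.5, 10)
  expect_true(any({d <- detect_nonpolar(make_frame(co2, box30), topo);
                   d$i == 0L & d$j == 4L}))
  co2[5, ] <- c(10, 14.51, 10)
  expect_false(any({d <- detect_nonpolar(make_frame(co2, box30), topo);
                    d$i == 0L & d$j == 4L}))
  # a carbon bonded to oxygen never qualifies: carbonyl frame has no
  # non-polar contacts at any separation
  topo2 <- frag_topology()
  expect_equal(nrow(detect_nonpolar(hb_frame(3.0, 180), topo2)), 0L)
})

test_that("water-bridged detection enforces all four criteria", {
  topo <- bridge_topology(1)
  # the constructed bridge passes (acceptor angles ~123 degrees)
  expect_equal(nrow(detect_coophyd(bridge_frame(5.0, 3.0), topo)), 1L)
  det <- detect_coophyd(bridge_frame(5.0, 3.0), topo)
  expect_equal(det$water_o, 4L)
  # partners below the range floor are hydrogen-bond territory
  expect_equal(nrow(detect_coophyd(bridge_frame(3.0, 3.0), topo)), 0L)
  # floor itself is inclusive
  expect_equal(nrow(detect_coophyd(bridge_frame(3.2, 3.0), topo)), 1L)
  # ceiling inclusive / beyond
  expect_equal(nrow(detect_coophyd(bridge_frame(6.0, 3.9), topo)), 1L)
  expect_equal(nrow(detect_coophyd(bridge_frame(6.05, 3.9), topo)), 0L)
  # water too far from one partner (4.2 A) fails the bridge criterion
  fr <- bridge_frame(5.0, 3.0, water_shift = c(2.4, 0.9, 0))
  d1 <- sqrt(sum((fr$coordinates[5, ] - fr$coordinates[2, ])^2))
  expect_gt(d1, 4.0)
  expect_equal(nrow(detect_coophyd(fr, topo)), 0L)
  # acceptor angle criterion: water on the bond side of the carbonyl fails
  co <- bridge_frame(5.0, 3.0)$coordinates[1:4, ]
  below <- co[2, ] + c(2.5, -sqrt(9 - 6.25), 0)  # below, near the C atoms
  fr2 <- make_frame(rbind(co, water_coords_at(below)), box30)
  expect_equal(nrow(detect_coophyd(fr2, topo)), 0L)
})

test_that("donor partners satisfy the bridge criteria through a hydrogen", {
  # amide donor + carbonyl acceptor 5 A apart, water bridging above
  topo <- local({
    solute <- data.frame(
      atom_name = c("C", "O", "N", "HN"),
      residue_name = c("GLY", "GLY", "ALA", "ALA"),
      residue_number = c(5L, 5L, 6L, 6L), molecule_class = "protein",
      element = c("C", "O", "N", "H"),
      partial_charge = c(0.51, -0.51, -0.47, 0.31),
      lj_epsilon = c(0.11, 0.12, 0.2, 0.046),
      lj_rmin_half = c(2, 1.7, 1.85, 0.2245),
      is_acceptor = c(FALSE, TRUE, FALSE, FALSE))
    wt <- water_box_topology(1, first_resid = 101L)
    assign_symmetry_groups(make_topology(
      rbind(solute, wt$atoms[, names(solute)]),
      rbind(rbind(c(0L, 1L), c(2L, 3L)), wt$bonds + 4L)))
  })
  co <- matrix(0, 4, 3)
  co[2, ] <- c(10, 10, 10); co[1, ] <- co[2, ] + c(0, -1.23, 0)
  co[3, ] <- co[2, ] + c(5, 0, 0)                     # N donor
  co[4, ] <- co[3, ] + c(-0.5, 0.87, 0)               # H toward the bridge
  wpos <- co[2, ] + c(2.5, sqrt(9 - 6.25), 0)
  fr <- make_frame(rbind(co, water_coords_at(wpos)), box30)
  expect_equal(nrow(detect_coophyd(fr, topo)), 1L)
  # flip the hydrogen away: donor angle < 90 and the bridge is rejected
  co[4, ] <- co[3, ] + c(0.5, -0.87, 0)
  fr2 <- make_frame(rbind(co, water_coords_at(wpos)), box30)
  expect_equal(nrow(detect_coophyd(fr2, topo)), 0L)
})

test_that("symmetry resolution picks the shortest alternative and counts multiplicity", {
  topo <- asp_pair_topology()
  co <- matrix(0, 5, 3)
  co[1, ] <- c(10, 10, 10)                       # CG
  co[2, ] <- c(11.2, 10.6, 10)                   # OD1
  co[3, ] <- c(11.2, 9.4, 10)                    # OD2
  co[4, ] <- c(14, 10.6, 10)                     # N donor
  co[5, ] <- c(13, 10.6, 10)                     # HN pointing at OD1
  fr <- make_frame(co, box30)
  rec <- contact_record(topo, "hbond", 3L, 1L)   # donor N, acceptor slot
  expect_setequal(rec$slots[[2]], c(1L, 2L))
  res <- resolve_symmetry(rec, fr, topo)
  expect_equal(res$atoms, c(3L, 1L))             # OD1 is nearer
  expect_equal(res$count, 1L)
  expect_true(res$passed)
  # neither alternative in range: count 0
  co2 <- co; co2[4, 1] <- 20; co2[5, 1] <- 19
  res2 <- resolve_symmetry(rec, make_frame(co2, box30), topo)
  expect_equal(res2$count, 0L)
  # a symmetric contact is one contact even when both alternatives pass
  det <- detect_hbonds(fr, topo)
  expect_equal(nrow(det), 2L)   # both carboxylate oxygens pass
  ids <- vapply(seq_len(nrow(det)), function(r)
    contact_record(topo, "hbond", det$donor[r], det$acceptor[r])$id,
    character(1))
  expect_equal(length(unique(ids)), 1L)   # ... but it is one contact
  # non-polar multiplicity: both ring alternatives within reach => count 2
  topo2 <- phe_pair_topology()
  co3 <- matrix(0, 6, 3)
  co3[1, ] <- c(10, 10, 10); co3[2, ] <- c(11.4, 10.5, 10)
  co3[3, ] <- c(11.4, 9.5, 10)
  co3[4, ] <- c(15, 18, 10); co3[5, ] <- c(14, 10, 10)
  co3[6, ] <- c(14, 9, 10)
  fr3 <- make_frame(co3, box30)
  rec_np <- contact_record(topo2, "nonpolar", 1L, 4L)
  res3 <- resolve_symmetry(rec_np, fr3, topo2)
  expect_gte(res3$count, 2L)
})

test_that("symmetry resolution is invariant to alternative-label order", {
  topo <- asp_pair_topology()
  co <- matrix(0, 5, 3)
  co[1, ] <- c(10, 10, 10); co[2, ] <- c(11.2, 10.6, 10)
  co[3, ] <- c(11.2, 9.4, 10); co[4, ] <- c(14, 10.6, 10)
  co[5, ] <- c(13, 10.6, 10)
  fr <- make_frame(co, box30)
  rec_a <- contact_record(topo, "hbond", 3L, 1L)
  rec_b <- contact_record(topo, "hbond", 3L, 2L)  # seeded from OD2
  expect_identical(rec_a$id, rec_b$id)
  expect_identical(resolve_symmetry(rec_a, fr, topo)$count,
                   resolve_symmetry(rec_b, fr, topo)$count)
})

test_that("detection is invariant under rigid motions and lattice shifts", {
  toy <- gen_two_state_toy(n_frames = 1, n_waters = 6, seed = 61)
  topo <- toy$topology
  fr <- toy$compact$frames[[1]]
  counts <- function(f) c(nrow(detect_hbonds(f, topo)),
                          nrow(detect_nonpolar(f, topo)),
                          nrow(detect_coophyd(f, topo)))
  ref <- counts(fr)
  expect_equal(ref, c(1, 1, 1))
  # translation (including a full lattice vector)
  for (shift in list(c(1.7, -2.4, 5.0), fr$box, 2 * fr$box)) {
    fr_t <- make_frame(sweep(fr$coordinates, 2, shift, "+"), fr$box)
    expect_equal(counts(fr_t), ref)
  }
  # rigid rotation about the box center
  th <- 0.7
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  cen <- fr$box / 2
  rot <- sweep(sweep(fr$coordinates, 2, cen, "-") %*% t(Rz), 2, cen, "+")
  expect_equal(counts(make_frame(rot, fr$box)), ref)
})

test_that("persistence recovers planted Bernoulli rates and filters at 0.5", {
  bc <- gen_bernoulli_contacts(p = c(1.0, 0.6, 0.4), n_replicates = 12,
                               n_frames = 60, seed = 71)
  cc <- collect_contacts(bc$ensembles, bc$topology, kinds = "hbond")
  cc <- cc[order(cc$slot2), ]   # planted order GLY1, GLY3, GLY5
  expect_equal(cc$persistence[1], 1.0)
  expect_equal(cc$persistence_std[1], 0.0)
  n_obs <- 12 * 60
  expect_lt(abs(cc$persistence[2] - 0.6), 3 * sqrt(0.6 * 0.4 / n_obs))
  expect_lt(abs(cc$persistence[3] - 0.4), 3 * sqrt(0.4 * 0.6 / n_obs))
  expect_equal(cc$persistent, c(TRUE, TRUE, FALSE))
  # the single-record interface agrees
  pr <- persistence(bc$records[[2]], bc$ensembles, bc$topology)
  expect_equal(pr$mean, cc$persistence[2])
  expect_true(pr$persistent)
  expect_error(persistence(bc$records[[1]], list(), bc$topology),
               "no ensembles")
})

test_that("the census separates total from persistent contacts", {
  bc <- gen_bernoulli_contacts(p = c(0.9, 0.9, 0.9, 0.15, 0.15),
                               n_replicates = 6, n_frames = 40, seed = 81)
  cen <- contact_census(bc$ensembles, bc$topology, kinds = "hbond")
  expect_equal(cen$total[cen$kind == "hbond"], 5L)
  expect_equal(cen$persistent[cen$kind == "hbond"], 3L)
  expect_true(all(cen$persistent <= cen$total))
  # water-only system: all zeros
  g <- gen_uniform_water_box(n_frames = 2, n_waters = 4,
                             box = c(14, 14, 14), seed = 82)
  cen2 <- contact_census(g$ensemble, g$topology)
  expect_true(all(cen2$total == 0L))
})
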