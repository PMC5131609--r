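# Small systems built in code for the tests.

# two free atoms with configurable charge / LJ, no bonds
two_atom_topology <- function(q = c(0, 0), eps = c(0, 0),
                              rmin_half = c(1, 1), element = c("C", "C"),
                              class = "protein") {
  atoms <- data.frame(
    atom_name = c("A1", "A2"), residue_name = "TOY",
    residue_number = 1:2, molecule_class = class, element = element,
    partial_charge = q, lj_epsilon = eps, lj_rmin_half = rmin_half,
    is_acceptor = FALSE)
  make_topology(atoms)
}

# carbonyl (C=O acceptor) + amide (N-H donor) fragment; coordinates are
# supplied per test
frag_topology <- function() {
  atoms <- data.frame(
    atom_name = c("C", "O", "N", "HN"),
    residue_name = c("GLY", "GLY", "ALA", "ALA"),
    residue_number = c(1L, 1L, 2L, 2L), molecule_class = "protein",
    element = c("C", "O", "N", "H"),
    partial_charge = c(0.51, -0.51, -0.47, 0.31),
    lj_epsilon = c(0.11, 0.12, 0.2, 0.046),
    lj_rmin_half = c(2.0, 1.7, 1.85, 0.2245),
    is_acceptor = c(FALSE, TRUE, FALSE, FALSE))
  assign_symmetry_groups(make_topology(atoms, rbind(c(0L, 1L), c(2L, 3L))))
}

# aspartate-like carboxylate (CG + OD1/OD2, both acceptors) + amide donor
asp_pair_topology <- function() {
  atoms <- data.frame(
    atom_name = c("CG", "OD1", "OD2", "N", "HN"),
    residue_name = c("ASP", "ASP", "ASP", "ALA", "ALA"),
    residue_number = c(44L, 44L, 44L, 55L, 55L),
    molecule_class = "protein",
    element = c("C", "O", "O", "N", "H"),
    partial_charge = c(0.62, -0.76, -0.76, -0.47, 0.31),
    lj_epsilon = c(0.07, 0.12, 0.12, 0.2, 0.046),
    lj_rmin_half = c(2.0, 1.7, 1.7, 1.85, 0.2245),
    is_acceptor = c(FALSE, TRUE, TRUE, FALSE, FALSE))
  bonds <- rbind(c(0L, 1L), c(0L, 2L), c(3L, 4L))
  assign_symmetry_groups(make_topology(atoms, bonds))
}

# two phenylalanine-like ring pairs (CD1/CD2 each), carbons without O/N
phe_pair_topology <- function() {
  atoms <- data.frame(
    atom_name = rep(c("CG", "CD1", "CD2"), 2),
    residue_name = "PHE",
    residue_number = rep(c(47L, 58L), each = 3),
    molecule_class = "protein",
    element = "C",
    partial_charge = 0.0, lj_epsilon = 0.07, lj_rmin_half = 1.99,
    is_acceptor = FALSE)
  bonds <- rbind(c(0L, 1L), c(0L, 2L), c(3L, 4L), c(3L, 5L))
  assign_symmetry_groups(make_topology(atoms, bonds))
}

# two carbonyl groups (water-bridge partners) plus n waters
bridge_topology <- function(n_waters = 1) {
  solute <- data.frame(
    atom_name = rep(c("C", "O"), 2),
    residue_name = "GLY",
    residue_number = rep(c(5L, 6L), each = 2),
    molecule_class = "protein",
    element = rep(c("C", "O"), 2),
    partial_charge = rep(c(0.51, -0.51), 2),
    lj_epsilon = rep(c(0.11, 0.12), 2),
    lj_rmin_half = rep(c(2.0, 1.7), 2),
    is_acceptor = rep(c(FALSE, TRUE), 2))
  wt <- water_box_topology(n_waters, first_resid = 101L)
  atoms <- rbind(solute, wt$atoms[, names(solute)])
  bonds <- rbind(rbind(c(0L, 1L), c(2L, 3L)), wt$bonds + 4L)
  assign_symmetry_groups(make_topology(atoms, bonds))
}

# coordinates of a rigid water placed by oxygen position and quaternion
water_coords_at <- function(pos, quat = c(1, 0, 0, 0)) {
  build_rigid_water(pos, quat, water_geometry("TIP3P"))
}

box30 <- c(30, 30, 30)

# carbonyl + amide with an exact donor-acceptor geometry: the acceptor O
# sits at `dist` from the donor N and the N-H...O angle at the hydrogen is
# exactly `angle` degrees (solved analytically for the H-O distance)
hb_frame <- function(dist, angle) {
  co <- matrix(0, 4, 3)
  co[3, ] <- c(10, 10, 10)                 # N
  co[4, ] <- c(11, 10, 10)                 # HN, N-H along +x
  phi <- (180 - angle) * pi / 180          # direction of H->O from +x
  # |N-O| = dist with O = H + t * (cos phi, sin phi, 0), |N-H| = 1
  t <- -cos(phi) + sqrt(cos(phi)^2 - 1 + dist^2)
  co[2, ] <- co[4, ] + t * c(cos(phi), sin(phi), 0)
  co[1, ] <- co[2, ] + c(0, 1.23, 0)       # C bonded to O
  make_frame(co, box30)
}

# two carbonyl oxygens `sep` apart with a bridging water whose oxygen is
# equidistant from both at `dw`; the water hydrogens point away
bridge_frame <- function(sep, dw, water_shift = c(0, 0, 0)) {
  co <- matrix(0, 4, 3)
  co[2, ] <- c(10, 10, 10)                       # O res5
  co[1, ] <- co[2, ] + c(0, -1.23, 0)            # C res5
  co[4, ] <- co[2, ] + c(sep, 0, 0)              # O res6
  co[3, ] <- co[4, ] + c(0, -1.23, 0)            # C res6
  h <- sqrt(dw^2 - (sep / 2)^2)
  wpos <- co[2, ] + c(sep / 2, h, 0) + water_shift
  make_frame(rbind(co, water_coords_at(wpos)), box30)
}

# brute-force minimum-image distance over 27 lattice images
dist_27_images <- function(p1, p2, box) {
  best <- Inf
  for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
    d <- p2 + c(ix, iy, iz) * box - p1
    best <- min(best, sqrt(sum(d^2)))
  }
  best
}

R_GAS <- 0.0019872
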