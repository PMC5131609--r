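# Seeded synthetic-snapshot generators.  These produce ensembles with known
# statistical structure (uniform water boxes, Gaussian-confined hydration
# sites, two-state toy solutes with planted contacts, Bernoulli contact
# persistence) so that every pipeline stage can be exercised without MD.
# Generators emit ordinary Topology / TrajectoryEnsemble objects, so
# synthetic and real inputs flow through identical code paths.

#' Rigid water model geometry
#'
#' @param model_name `"TIP3P"` (3-site) or `"TIP4P-2005"` (4-site with a
#'   massless charge site on the bisector)
#' @return object of class `WaterGeometry` with `r_OH` (A), `theta_HOH`
#'   (deg), and for 4-site models `r_OL` (A) and `theta_HOL` (deg)
#' @export
water_geometry <- function(model_name = c("TIP3P", "TIP4P-2005")) {
  model_name <- match.arg(model_name)
  structure(list(r_OH = 0.9572, theta_HOH = 104.52,
                 r_OL = 0.1546, theta_HOL = 52.26,
                 model_name = model_name),
            class = "WaterGeometry")
}

# per-model charges and LJ parameters (kcal/mol, A)
.water_params <- function(model_name) {
  if (model_name == "TIP3P") {
    list(qO = -0.834, qH = 0.417, qM = NULL,
         epsO = 0.1521, rminO = 1.7682, epsH = 0.046, rminH = 0.2245)
  } else {
    list(qO = 0.0, qH = 0.5564, qM = -1.1128,
         epsO = 0.1852, rminO = 1.7729, epsH = 0.0, rminH = 0.0)
  }
}

#' Build rigid water coordinates
#'
#' Places a water with the exact model geometry at the given oxygen
#' position and orientation.  The reference orientation has the oxygen at
#' the origin, the H-O-H bisector along +z, the molecular plane in xz with
#' H1 on the +x side; the 4-site charge site lies on the bisector.
#'
#' @param position oxygen coordinates (A)
#' @param orientation unit quaternion, scalar-first
#' @param geometry a [water_geometry()]
#' @return 3 x 3 (or 4 x 3) matrix of O, H1, H2 (and M-site) coordinates
#' @export
build_rigid_water <- function(position, orientation = c(1, 0, 0, 0),
                              geometry = water_geometry()) {
  half <- geometry$theta_HOH / 2 * pi / 180
  ref <- rbind(c(0, 0, 0),
               geometry$r_OH * c(sin(half), 0, cos(half)),
               geometry$r_OH * c(-sin(half), 0, cos(half)))
  if (geometry$model_name == "TIP4P-2005")
    ref <- rbind(ref, c(0, 0, geometry$r_OL))
  R <- .quat_to_matrix(.quat_normalize(orientation))
  sweep(ref %*% t(R), 2, position, "+")
}

#' Topology of a pure water box
#'
#' @param n_waters number of water molecules
#' @param model_name water model
#' @param first_resid residue number of the first water
#' @return a `Topology` with symmetry groups assigned
#' @export
water_box_topology <- function(n_waters, model_name = "TIP3P",
                               first_resid = 1L) {
  p <- .water_params(model_name)
  four <- model_name == "TIP4P-2005"
  per <- if (four) 4L else 3L
  resname <- if (four) "TIP4" else "TIP3"
  rows <- lapply(seq_len(n_waters), function(w) {
    base <- data.frame(
      atom_name = c("OH2", "H1", "H2"), residue_name = resname,
      residue_number = first_resid + w - 1L, molecule_class = "water",
      element = c("O", "H", "H"),
      partial_charge = c(p$qO, p$qH, p$qH),
      lj_epsilon = c(p$epsO, p$epsH, p$epsH),
      lj_rmin_half = c(p$rminO, p$rminH, p$rminH),
      is_acceptor = c(TRUE, FALSE, FALSE))
    if (four)
      base <- rbind(base, data.frame(
        atom_name = "MW", residue_name = resname,
        residue_number = first_resid + w - 1L, molecule_class = "water",
        element = "M", partial_charge = p$qM, lj_epsilon = 0,
        lj_rmin_half = 0, is_acceptor = FALSE))
    base
  })
  atoms <- do.call(rbind, rows)
  b <- lapply(seq_len(n_waters) - 1L, function(w) {
    o <- w * per
    rb <- rbind(c(o, o + 1L), c(o, o + 2L))
    if (four) rb <- rbind(rb, c(o, o + 3L))
    rb
  })
  assign_symmetry_groups(make_topology(atoms, do.call(rbind, b)))
}

# frame coordinates for a set of waters given O positions and quaternions
.water_frame_coords <- function(positions, quats, geometry) {
  do.call(rbind, lapply(seq_len(nrow(positions)), function(w)
    build_rigid_water(positions[w, ], quats[w, ], geometry)))
}

#' Specification of a synthetic ensemble
#'
#' A fixed spec (including the seed) generates byte-identical output.
#'
#' @param recipe one of `"uniform_box"`, `"gaussian_sites"`,
#'   `"two_state_toy"`, `"bernoulli_contacts"`
#' @param seed integer RNG seed
#' @param n_frames number of frames
#' @param box box lengths (A)
#' @param water_model water model name
#' @param ... recipe parameters, passed to the generator
#' @return object of class `GeneratorSpec`
#' @export
generator_spec <- function(recipe = c("uniform_box", "gaussian_sites",
                                      "two_state_toy",
                                      "bernoulli_contacts"),
                           seed = 1L, n_frames = 100L,
                           box = c(20, 20, 20), water_model = "TIP3P",
                           ...) {
  recipe <- match.arg(recipe)
  structure(list(recipe = recipe, seed = as.integer(seed),
                 n_frames = as.integer(n_frames), box = box,
                 water_model = water_model, params = list(...)),
            class = "GeneratorSpec")
}

#' Generate an ensemble from a spec
#'
#' @param spec a [generator_spec()]
#' @return the generator's return value (see the individual `gen_*`
#'   functions)
#' @export
generate_ensemble <- function(spec) {
  args <- c(list(seed = spec$seed, n_frames = spec$n_frames,
                 box = spec$box, water_model = spec$water_model),
            spec$params)
  fn <- switch(spec$recipe,
               uniform_box = gen_uniform_water_box,
               gaussian_sites = gen_gaussian_sites,
               two_state_toy = gen_two_state_toy,
               bernoulli_contacts = gen_bernoulli_contacts)
  if (spec$recipe == "bernoulli_contacts") {
    args$box <- NULL; args$water_model <- NULL
  }
  do.call(fn, args)
}

#' Uniform water box (the entropy-estimator zero point)
#'
#' Oxygen positions uniform in the box, orientations uniform over the
#' rotation group, constant volume.  A homogeneous sample like this is the
#' estimator's zero point: its solute-water entropy tends to zero as the
#' sample grows.
#'
#' @param n_frames number of frames
#' @param n_waters waters per frame
#' @param box box lengths (A)
#' @param water_model water model
#' @param seed RNG seed
#' @param region optional 3 x 2 matrix of lower/upper bounds confining the
#'   positions to a sub-volume of the box (the box, and hence the frame
#'   volume entering the entropy estimator, is unchanged); used for
#'   closed-form confinement checks such as the ln 2 shift under volume
#'   halving
#' @return list with `ensemble` and `topology`
#' @export
gen_uniform_water_box <- function(n_frames = 100L, n_waters = 50L,
                                  box = c(20, 20, 20),
                                  water_model = "TIP3P", seed = 1L,
                                  region = NULL) {
  set.seed(seed)
  if (is.null(region)) region <- cbind(c(0, 0, 0), box)
  topo <- water_box_topology(n_waters, water_model)
  geom <- water_geometry(water_model)
  frames <- lapply(seq_len(n_frames), function(f) {
    pos <- cbind(runif(n_waters, region[1, 1], region[1, 2]),
                 runif(n_waters, region[2, 1], region[2, 2]),
                 runif(n_waters, region[3, 1], region[3, 2]))
    make_frame(.water_frame_coords(pos, random_quaternions(n_waters),
                                   geom), box)
  })
  list(ensemble = make_ensemble(frames, state_label = "native",
                                ensemble_kind = "fixed_NVT"),
       topology = topo)
}

#' Gaussian-confined hydration sites
#'
#' One water per site per frame, oxygen positions scattered isotropically
#' (standard deviation `sigma`) about the given centers, with a choice of
#' orientation law.  An oracle input for site clustering and for the
#' translational part of the entropy estimator.
#'
#' @param n_frames number of frames
#' @param centers k x 3 matrix of site centers (A), pairwise at least
#'   2.4 A apart
#' @param sigma positional standard deviation (A)
#' @param box box lengths (A)
#' @param orientation `"uniform"`, `"fixed"` or `"concentrated"`
#' @param kappa for `"concentrated"`: rotations about uniformly random axes
#'   with normal angles of sd `1/sqrt(kappa)` radians about identity
#' @param water_model water model
#' @param seed RNG seed
#' @return list with `ensemble`, `topology` and `centers`
#' @export
gen_gaussian_sites <- function(n_frames = 1000L,
                               centers = rbind(c(6, 6, 6), c(14, 6, 6),
                                               c(10, 14, 10)),
                               sigma = 0.3, box = c(20, 20, 20),
                               orientation = c("uniform", "fixed",
                                               "concentrated"),
                               kappa = 25, water_model = "TIP3P",
                               seed = 1L) {
  orientation <- match.arg(orientation)
  stopifnot(sigma > 0)
  centers <- as.matrix(centers)
  if (nrow(centers) > 1) {
    dd <- as.matrix(dist(centers))
    if (min(dd[upper.tri(dd)]) < 2.4)
      stop("site centers closer than 2.4 A overlap")
  }
  set.seed(seed)
  k <- nrow(centers)
  topo <- water_box_topology(k, water_model)
  geom <- water_geometry(water_model)
  frames <- lapply(seq_len(n_frames), function(f) {
    pos <- centers + matrix(rnorm(3 * k, sd = sigma), k, 3)
    quats <- switch(orientation,
      uniform = random_quaternions(k),
      fixed = matrix(rep(c(1, 0, 0, 0), k), k, 4, byrow = TRUE),
      concentrated = t(vapply(seq_len(k), function(i) {
        ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
        th <- rnorm(1, sd = 1 / sqrt(kappa))
        c(cos(th / 2), sin(th / 2) * ax)
      }, numeric(4))))
    make_frame(.water_frame_coords(pos, quats, geom), box)
  })
  list(ensemble = make_ensemble(frames, state_label = "native",
                                ensemble_kind = "fixed_NVT"),
       topology = topo, centers = centers)
}

# ---------------------------------------------------------------------------
# Two-state toy solute with planted contacts
# ---------------------------------------------------------------------------

# small bundled parameter set with values typical of CHARMM atom classes
.TOY_PARAMS <- list(
  C_carbonyl = list(q = 0.51, eps = 0.110, rmin = 2.000, el = "C"),
  O_carbonyl = list(q = -0.51, eps = 0.120, rmin = 1.700, el = "O"),
  N_amide = list(q = -0.47, eps = 0.200, rmin = 1.850, el = "N"),
  H_amide = list(q = 0.31, eps = 0.046, rmin = 0.2245, el = "H"),
  C_aliphatic = list(q = -0.27, eps = 0.078, rmin = 2.050, el = "C"),
  H_aliphatic = list(q = 0.09, eps = 0.024, rmin = 1.340, el = "H")
)

.toy_atom <- function(name, resname, resid, par, acceptor = FALSE) {
  p <- .TOY_PARAMS[[par]]
  data.frame(atom_name = name, residue_name = resname,
             residue_number = resid, molecule_class = "protein",
             element = p$el, partial_charge = p$q, lj_epsilon = p$eps,
             lj_rmin_half = p$rmin, is_acceptor = acceptor)
}

# place waters uniformly, rejecting close approaches to existing atoms
.place_waters_reject <- function(n, box, existing, min_sep = 2.8,
                                 max_tries = 2000L) {
  out <- matrix(0, n, 3)
  placed <- existing
  for (w in seq_len(n)) {
    for (t in seq_len(max_tries)) {
      cand <- c(runif(1, 0, box[1]), runif(1, 0, box[2]),
                runif(1, 0, box[3]))
      d <- t(placed) - cand
      d <- d - box * round(d / box)
      if (nrow(placed) == 0 || min(colSums(d^2)) >= min_sep^2) break
      if (t == max_tries) stop("could not place waters without overlap")
    }
    out[w, ] <- cand
    placed <- rbind(placed, cand)
  }
  out
}

#' Two-state toy solute with planted contacts
#'
#' Builds a small solute rendered in a compact conformation -- with a
#' planted hydrogen bond (amide N-H to carbonyl O at 2.9 A, collinear), a
#' planted non-polar contact (two aliphatic carbons at 4.0 A) and a planted
#' water-bridged pair (two carbonyl oxygens 5.0 A apart with a bridging
#' water equidistant at 3.0 A) -- and an extended conformation in which the
#' same groups are solvent-separated (partner distances of order 10 A).
#' Both states carry an identical particle inventory.  Remaining waters are
#' placed uniformly away from the solute; small Gaussian jitter is applied
#' per frame (rigid-body for waters).
#'
#' @param n_frames frames per state
#' @param n_waters waters per state (the bridge water is one of them when a
#'   `coophyd` contact is planted)
#' @param box box lengths (A)
#' @param contacts subset of `c("hbond", "nonpolar", "coophyd")` to plant
#' @param jitter per-frame positional jitter sd (A), small enough to keep
#'   the planted geometries inside (compact) / outside (extended) criteria
#' @param water_model water model
#' @param seed RNG seed
#' @return list with `compact`, `extended` (ensembles), `topology` and
#'   `planted` (data frame naming the planted contacts and their atoms)
#' @export
gen_two_state_toy <- function(n_frames = 20L, n_waters = 20L,
                              box = c(30, 30, 30),
                              contacts = c("hbond", "nonpolar", "coophyd"),
                              jitter = 0.02, water_model = "TIP3P",
                              seed = 1L) {
  contacts <- match.arg(contacts, several.ok = TRUE)
  if ("coophyd" %in% contacts && n_waters < 1)
    stop("a planted water bridge needs at least one water")
  set.seed(seed)
  cen <- box / 2
  # methyl groups are net neutral (C -0.27 + 3 H +0.09) so the planted
  # non-polar contact is dispersion-dominated, as in the real force field
  atoms <- rbind(
    .toy_atom("C", "ALA", 1L, "C_carbonyl"),
    .toy_atom("O", "ALA", 1L, "O_carbonyl", acceptor = TRUE),
    .toy_atom("N", "ALA", 2L, "N_amide"),
    .toy_atom("HN", "ALA", 2L, "H_amide"),
    .toy_atom("CD1", "LEU", 3L, "C_aliphatic"),
    .toy_atom("HD1", "LEU", 3L, "H_aliphatic"),
    .toy_atom("HD2", "LEU", 3L, "H_aliphatic"),
    .toy_atom("HD3", "LEU", 3L, "H_aliphatic"),
    .toy_atom("CD1", "LEU", 4L, "C_aliphatic"),
    .toy_atom("HD1", "LEU", 4L, "H_aliphatic"),
    .toy_atom("HD2", "LEU", 4L, "H_aliphatic"),
    .toy_atom("HD3", "LEU", 4L, "H_aliphatic"),
    .toy_atom("C", "GLY", 5L, "C_carbonyl"),
    .toy_atom("O", "GLY", 5L, "O_carbonyl", acceptor = TRUE),
    .toy_atom("C", "GLY", 6L, "C_carbonyl"),
    .toy_atom("O", "GLY", 6L, "O_carbonyl", acceptor = TRUE)
  )
  solute_bonds <- rbind(c(0L, 1L), c(2L, 3L),
                        c(4L, 5L), c(4L, 6L), c(4L, 7L),
                        c(8L, 9L), c(8L, 10L), c(8L, 11L),
                        c(12L, 13L), c(14L, 15L))
  n_solute <- nrow(atoms)
  wt <- water_box_topology(n_waters, water_model, first_resid = 101L)
  wt_atoms <- wt$atoms[, names(atoms)]
  topo <- make_topology(rbind(atoms, wt_atoms),
                        rbind(solute_bonds, wt$bonds + n_solute))
  topo <- assign_symmetry_groups(topo)
  geom <- water_geometry(water_model)

  # methyl hydrogen fans, pointing away from the contact partner
  hfan <- function(center, sign_x) {
    dirs <- rbind(c(-0.50, 0.87, 0), c(-0.50, -0.44, 0.75),
                  c(-0.50, -0.44, -0.75))
    dirs[, 1] <- dirs[, 1] * sign_x
    sweep(1.1 * dirs, 2, center, "+")
  }

  # compact: planted geometries around the box center
  compact <- matrix(NA_real_, n_solute, 3)
  compact[2, ] <- cen + c(0, 0, 0)                 # O (acceptor)
  compact[1, ] <- cen + c(-1.23, 0, 0)             # C
  compact[3, ] <- cen + c(2.9, 0, 0)               # N (donor), d(N,O)=2.9
  compact[4, ] <- cen + c(1.9, 0, 0)               # HN, collinear
  compact[5, ] <- cen + c(0, 8, 0)                 # CD1 res 3
  compact[6:8, ] <- hfan(compact[5, ], +1)
  compact[9, ] <- cen + c(4.0, 8, 0)               # CD1 res 4, d = 4.0
  compact[10:12, ] <- hfan(compact[9, ], +1)
  compact[13, ] <- cen + c(0, -9.23, 0)            # C res 5
  compact[14, ] <- cen + c(0, -8, 0)               # O res 5
  compact[15, ] <- cen + c(5.0, -9.23, 0)          # C res 6
  compact[16, ] <- cen + c(5.0, -8, 0)             # O res 6, d(O,O)=5.0
  bridge <- cen + c(2.5, -8 + sqrt(3^2 - 2.5^2), 0) # 3.0 A from each O
  # bridging water oriented to donate a hydrogen toward each carbonyl O
  u1 <- (compact[14, ] - bridge); u1 <- u1 / sqrt(sum(u1^2))
  u2 <- (compact[16, ] - bridge); u2 <- u2 / sqrt(sum(u2^2))
  zb <- u1 + u2; zb <- zb / sqrt(sum(zb^2))
  xb <- u1 - u2; xb <- xb / sqrt(sum(xb^2))
  yb <- c(zb[2] * xb[3] - zb[3] * xb[2], zb[3] * xb[1] - zb[1] * xb[3],
          zb[1] * xb[2] - zb[2] * xb[1])
  bridge_quat <- .matrix_to_quat(cbind(xb, yb, zb))

  # extended: the same groups, solvent-separated
  extended <- matrix(NA_real_, n_solute, 3)
  extended[1, ] <- c(5, 5, 5) + c(-1.23, 0, 0)
  extended[2, ] <- c(5, 5, 5)
  extended[3, ] <- c(17, 5, 5)
  extended[4, ] <- c(16, 5, 5)
  extended[5, ] <- c(5, 17, 5)
  extended[6:8, ] <- hfan(extended[5, ], +1)
  extended[9, ] <- c(17, 17, 5)
  extended[10:12, ] <- hfan(extended[9, ], +1)
  extended[13, ] <- c(5, 3.77, 17)
  extended[14, ] <- c(5, 5, 17)
  extended[15, ] <- c(17, 3.77, 17)
  extended[16, ] <- c(17, 5, 17)

  build_state <- function(solute_base, with_bridge) {
    free_n <- n_waters - as.integer(with_bridge)
    lapply(seq_len(n_frames), function(f) {
      sol <- solute_base + matrix(rnorm(3 * n_solute, sd = jitter),
                                  n_solute, 3)
      wpos <- matrix(0, 0, 3)
      quats <- matrix(0, 0, 4)
      if (with_bridge) {
        wpos <- rbind(wpos, bridge + rnorm(3, sd = jitter))
        quats <- rbind(quats, bridge_quat)
      }
      if (free_n > 0) {
        wpos <- rbind(wpos, .place_waters_reject(
          free_n, box, rbind(solute_base, bridge, wpos), min_sep = 4.0))
        quats <- rbind(quats, random_quaternions(free_n))
      }
      make_frame(rbind(sol, .water_frame_coords(wpos, quats, geom)), box)
    })
  }
  # identical particle inventory in both states: the bridge water is simply
  # one of the n_waters, free in the extended state
  plant_bridge <- "coophyd" %in% contacts
  frames_c <- build_state(compact, plant_bridge)
  frames_e <- build_state(extended, FALSE)
  planted <- data.frame(
    kind = c("hbond", "nonpolar", "coophyd"),
    i = c(2L, 4L, 13L), j = c(1L, 8L, 15L))
  planted <- planted[planted$kind %in% contacts, ]
  list(compact = make_ensemble(frames_c, state_label = "native"),
       extended = make_ensemble(frames_e, state_label = "extended"),
       topology = topo, planted = planted)
}

#' Replicate ensembles with Bernoulli contact persistence
#'
#' Plants `length(p)` donor/acceptor pairs, each rendered in-criteria
#' (N-H...O=C at 2.9 A, collinear) with probability `p[k]` per frame and
#' out-of-criteria (5.5 A) otherwise, across independent replicates.  The
#' oracle input for the persistence filter: recovered persistence converges
#' to the planted rate.
#'
#' @param p vector of per-contact presence probabilities
#' @param n_replicates number of replicate ensembles
#' @param n_frames frames per replicate
#' @param seed RNG seed
#' @return list with `ensembles` (list of replicates), `topology`, `p` and
#'   `records` (one [contact_record()] per planted contact)
#' @export
gen_bernoulli_contacts <- function(p = c(0.6, 0.4), n_replicates = 40L,
                                   n_frames = 100L, seed = 1L) {
  stopifnot(all(p >= 0 & p <= 1))
  set.seed(seed)
  k <- length(p)
  atoms <- do.call(rbind, lapply(seq_len(k), function(c_i) rbind(
    .toy_atom("C", "GLY", 2L * c_i - 1L, "C_carbonyl"),
    .toy_atom("O", "GLY", 2L * c_i - 1L, "O_carbonyl", acceptor = TRUE),
    .toy_atom("N", "ALA", 2L * c_i, "N_amide"),
    .toy_atom("HN", "ALA", 2L * c_i, "H_amide"))))
  bonds <- do.call(rbind, lapply(seq_len(k) - 1L, function(c_i)
    rbind(c(4L * c_i, 4L * c_i + 1L), c(4L * c_i + 2L, 4L * c_i + 3L))))
  topo <- assign_symmetry_groups(make_topology(atoms, bonds))
  box <- c(12 * k + 12, 24, 24)
  base_y <- 12; base_z <- 12
  frame_coords <- function(present) {
    do.call(rbind, lapply(seq_len(k), function(c_i) {
      x0 <- 12 * c_i - 6
      dNO <- if (present[c_i]) 2.9 else 5.5
      rbind(c(x0 - 1.23, base_y, base_z),        # C
            c(x0, base_y, base_z),               # O
            c(x0 + dNO, base_y, base_z),         # N
            c(x0 + dNO - 1.0, base_y, base_z))   # HN
    }))
  }
  ensembles <- lapply(seq_len(n_replicates), function(r) {
    frames <- lapply(seq_len(n_frames), function(f)
      make_frame(frame_coords(runif(k) < p), box))
    make_ensemble(frames, state_label = "native", replicate_id = r)
  })
  records <- lapply(seq_len(k), function(c_i)
    contact_record(topo, "hbond", 4L * (c_i - 1L) + 2L,
                   4L * (c_i - 1L) + 1L))
  list(ensembles = ensembles, topology = topo, p = p, records = records)
}
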