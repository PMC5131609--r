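# Pairwise non-bonded energy kernel and the energy decompositions built on
# it.  Electrostatics are direct pairwise Coulomb sums under the minimum
# image convention (attributing energy to atoms or atom groups is only well
# defined for a pairwise form, so no reciprocal-space mesh term appears
# here); Lennard-Jones uses the CHARMM switching function between switch_on
# and cutoff.  All energies in kcal/mol, distances in Angstrom.

#' Options for the non-bonded energy kernel
#'
#' @param coulomb_constant Coulomb prefactor in kcal A / mol / e^2.  The
#'   default 332.0636 is the convention of the common MD engines.
#' @param vdw_switch_on,vdw_cutoff Lennard-Jones switching window (A): the
#'   LJ term is unmodified below `vdw_switch_on`, switched smoothly to zero
#'   at `vdw_cutoff`, and zero beyond.
#' @param elec_scheme `"direct_all_pairs"` (no electrostatic cutoff, the
#'   default for decompositions) or `"direct_cutoff"` (truncate at
#'   `elec_cutoff`)
#' @param elec_cutoff electrostatic truncation radius (A), required for
#'   `"direct_cutoff"`
#' @param minimum_image apply the minimum image convention to distances
#' @return object of class `EnergyOptions`
#' @export
energy_options <- function(coulomb_constant = 332.0636,
                           vdw_switch_on = 9.0, vdw_cutoff = 11.0,
                           elec_scheme = c("direct_all_pairs",
                                           "direct_cutoff"),
                           elec_cutoff = NULL, minimum_image = TRUE) {
  elec_scheme <- match.arg(elec_scheme)
  if (vdw_switch_on >= vdw_cutoff)
    stop("vdw_switch_on must be below vdw_cutoff")
  if (elec_scheme == "direct_cutoff" && is.null(elec_cutoff))
    stop("direct_cutoff electrostatics need an elec_cutoff")
  structure(list(coulomb_constant = coulomb_constant,
                 vdw_switch_on = vdw_switch_on, vdw_cutoff = vdw_cutoff,
                 elec_scheme = elec_scheme, elec_cutoff = elec_cutoff,
                 minimum_image = minimum_image),
            class = "EnergyOptions")
}

.check_cutoffs_vs_box <- function(options, box) {
  if (options$minimum_image && options$vdw_cutoff >= min(box) / 2)
    stop("vdw_cutoff must be below half the smallest box length (",
         min(box) / 2, " A) under minimum image")
  invisible(TRUE)
}

# minimum-image component-wise displacement
.min_image <- function(d, L) d - L * round(d / L)

# CHARMM switching function on r in [switch_on, cutoff]
.lj_switch <- function(r, r_on, r_off) {
  s <- ifelse(r <= r_on, 1, 0)
  mid <- r > r_on & r < r_off
  if (any(mid)) {
    r2 <- r[mid]^2; on2 <- r_on^2; off2 <- r_off^2
    s[mid] <- (off2 - r2)^2 * (off2 + 2 * r2 - 3 * on2) / (off2 - on2)^3
  }
  s
}

# Vectorised energies of ordered atom pairs (i_vec[k], j_vec[k]) in one
# frame.  Excluded (1-2/1-3/1-4) pairs contribute zero.  Errors on exact
# overlap of interacting atoms.
.pair_energies_vec <- function(i_vec, j_vec, frame, topology, options) {
  at <- topology$atoms
  n <- nrow(at)
  co <- frame$coordinates
  dx <- co[i_vec + 1L, 1] - co[j_vec + 1L, 1]
  dy <- co[i_vec + 1L, 2] - co[j_vec + 1L, 2]
  dz <- co[i_vec + 1L, 3] - co[j_vec + 1L, 3]
  if (options$minimum_image) {
    dx <- .min_image(dx, frame$box[1])
    dy <- .min_image(dy, frame$box[2])
    dz <- .min_image(dz, frame$box[3])
  }
  r2 <- dx * dx + dy * dy + dz * dz
  excl <- .pair_keys(i_vec, j_vec, n) %in% topology$exclusions
  if (any(r2[!excl] < 1e-12))
    stop("overlapping atoms (r = 0) in pair energy evaluation")
  r <- sqrt(r2)
  qq <- at$partial_charge[i_vec + 1L] * at$partial_charge[j_vec + 1L]
  elec <- options$coulomb_constant * qq / r
  if (options$elec_scheme == "direct_cutoff")
    elec[r > options$elec_cutoff] <- 0
  eps <- sqrt(at$lj_epsilon[i_vec + 1L] * at$lj_epsilon[j_vec + 1L])
  rmin <- at$lj_rmin_half[i_vec + 1L] + at$lj_rmin_half[j_vec + 1L]
  lj <- numeric(length(r))
  act <- eps > 0 & r <= options$vdw_cutoff
  if (any(act)) {
    s6 <- (rmin[act] / r[act])^6
    lj[act] <- eps[act] * (s6 * s6 - 2 * s6) *
      .lj_switch(r[act], options$vdw_switch_on, options$vdw_cutoff)
  }
  e <- elec + lj
  e[excl] <- 0
  e
}

#' Non-bonded interaction energy of one atom pair
#'
#' Coulomb term plus Lorentz-Berthelot-combined Lennard-Jones with CHARMM
#' switching, at the minimum-image distance.  Pairs in the 1-2/1-3/1-4
#' exclusion sets return 0.
#'
#' @param i,j 0-based atom indices (distinct)
#' @param frame a `Frame`
#' @param topology a `Topology`
#' @param options an [energy_options()] object
#' @return energy in kcal/mol
#' @export
pair_energy <- function(i, j, frame, topology,
                        options = energy_options()) {
  if (i == j) stop("pair energy of an atom with itself")
  .pair_energies_vec(i, j, frame, topology, options)
}

# Sum over ordered pairs (i in I) x (j in J), i != j.  Chunked to bound
# memory.  With I = J = all atoms this double-counts every unordered pair,
# hence the callers' 1/2 factors.
.cross_energy_sum <- function(I, J, frame, topology, options,
                              chunk = 250000L) {
  nI <- length(I); nJ <- length(J)
  if (nI == 0 || nJ == 0) return(0)
  total <- 0
  per <- max(1L, chunk %/% nJ)
  for (start in seq(1L, nI, by = per)) {
    block <- I[start:min(nI, start + per - 1L)]
    ii <- rep(block, each = nJ)
    jj <- rep(J, times = length(block))
    keep <- ii != jj
    total <- total +
      sum(.pair_energies_vec(ii[keep], jj[keep], frame, topology, options))
  }
  total
}

# Per-atom half-sums for atoms in I: E_atom(a) = 1/2 sum_{j != a} E_aj
.atom_energies_frame <- function(I, frame, topology, options,
                                 chunk = 250000L) {
  n <- nrow(topology$atoms)
  all_idx <- seq_len(n) - 1L
  out <- numeric(length(I))
  per <- max(1L, chunk %/% n)
  for (start in seq(1L, length(I), by = per)) {
    sel <- start:min(length(I), start + per - 1L)
    block <- I[sel]
    ii <- rep(block, each = n)
    jj <- rep(all_idx, times = length(block))
    keep <- ii != jj
    e <- numeric(length(ii))
    e[keep] <- .pair_energies_vec(ii[keep], jj[keep], frame, topology,
                                  options)
    out[sel] <- colSums(matrix(e, nrow = n)) / 2
  }
  out
}

#' Group interaction energy (half-sum convention)
#'
#' Returns `1/2 * sum_{i in set} sum_{j != i, all atoms} E_ij`: pairs
#' internal to the set count once, pairs with external atoms count at half
#' weight.  With the set equal to all atoms this is the total non-bonded
#' energy of the frame; with a single atom it is that atom's energy
#' contribution.  Over an ensemble the snapshot mean is returned.
#'
#' @param member_atoms non-empty vector of 0-based atom indices
#' @param frame_or_ensemble a `Frame` or a `TrajectoryEnsemble`
#' @param topology a `Topology`
#' @param options an [energy_options()] object
#' @return energy in kcal/mol
#' @export
group_energy <- function(member_atoms, frame_or_ensemble, topology,
                         options = energy_options()) {
  member_atoms <- unique(as.integer(member_atoms))
  if (length(member_atoms) == 0) stop("empty atom set")
  n <- nrow(topology$atoms)
  if (any(member_atoms < 0 | member_atoms >= n))
    stop("atom index out of range")
  all_idx <- seq_len(n) - 1L
  eval1 <- function(frame)
    .cross_energy_sum(member_atoms, all_idx, frame, topology, options) / 2
  if (inherits(frame_or_ensemble, "Frame")) return(eval1(frame_or_ensemble))
  mean(vapply(frame_or_ensemble$frames, eval1, numeric(1)))
}

#' Total non-bonded energy of a frame or ensemble mean
#'
#' @inheritParams group_energy
#' @param frame_or_ensemble a `Frame` or `TrajectoryEnsemble`
#' @return kcal/mol
#' @export
total_nonbonded_energy <- function(frame_or_ensemble, topology,
                                   options = energy_options()) {
  n <- nrow(topology$atoms)
  group_energy(seq_len(n) - 1L, frame_or_ensemble, topology, options)
}

# particle inventory: counts by (molecule_class, element, charge, LJ type)
.particle_inventory <- function(topology) {
  at <- topology$atoms
  key <- sprintf("%s|%s|%.4f|%.4f|%.4f", at$molecule_class, at$element,
                 at$partial_charge, at$lj_epsilon, at$lj_rmin_half)
  sort(table(key))
}

#' Mean energy difference between a state and the native state
#'
#' Mean total non-bonded energy of `state` minus that of `native`.  The two
#' ensembles must have identical particle inventories (same counts of every
#' atom type), otherwise the difference is not meaningful.  Lists of
#' replicate ensembles may be given, in which case the per-replicate
#' differences are aggregated to a mean and sample standard deviation.
#'
#' @param state,native a `TrajectoryEnsemble` each, or lists of replicate
#'   ensembles of equal length
#' @param topology shared `Topology`
#' @param options an [energy_options()] object
#' @param bonded_params optional bonded parameter set; when given, bonded
#'   energies are included in the totals
#' @param state_topology optional separate `Topology` for the state
#'   ensemble; its particle inventory must match `topology`'s
#' @return for single ensembles a number (kcal/mol); for replicate lists a
#'   list with `delta`, `std` and `per_replicate`
#' @export
state_energy_difference <- function(state, native, topology,
                                    options = energy_options(),
                                    bonded_params = NULL,
                                    state_topology = NULL) {
  if (is.null(state_topology)) state_topology <- topology
  if (!identical(.particle_inventory(state_topology),
                 .particle_inventory(topology)))
    stop("particle inventory mismatch between state and native systems")
  total1 <- function(ens, topo) {
    e <- total_nonbonded_energy(ens, topo, options)
    if (!is.null(bonded_params))
      e <- e + mean(vapply(ens$frames, bonded_energy, numeric(1),
                           topology = topo,
                           bonded_params = bonded_params))
    e
  }
  if (inherits(state, "TrajectoryEnsemble")) {
    return(total1(state, state_topology) - total1(native, topology))
  }
  if (length(state) != length(native))
    stop("replicate lists differ in length")
  per <- vapply(seq_along(state), function(r)
    total1(state[[r]], state_topology) - total1(native[[r]], topology),
    numeric(1))
  list(delta = mean(per),
       std = if (length(per) > 1) sd(per) else 0,
       per_replicate = per)
}

#' Per-atom energy decomposition between native and extended states
#'
#' For every protein atom `a`, `E_atom = 1/2 sum_{j != a} E_aj` is averaged
#' over the frames of each state and differenced.  The polar / non-polar
#' partition follows the |charge| >= 0.3 e rule, which is exhaustive and
#' exclusive over protein atoms.
#'
#' @param native,extended one `TrajectoryEnsemble` each (replicate
#'   aggregation is done by the caller)
#' @param topology shared `Topology`
#' @param options an [energy_options()] object
#' @return list with `table` (one row per protein atom: `atom_index`,
#'   `E_atom_native`, `E_atom_extended`, `delta_E_atom`, `partial_charge`,
#'   `is_polar`) and `sums` (named vector: `total`, `polar`, `nonpolar`)
#' @export
atom_energy_table <- function(native, extended, topology,
                              options = energy_options()) {
  at <- topology$atoms
  prot <- at$atom_index[at$molecule_class == "protein"]
  if (length(prot) == 0) stop("no protein atoms in topology")
  state_mean <- function(ens) {
    acc <- numeric(length(prot))
    for (f in ens$frames)
      acc <- acc + .atom_energies_frame(prot, f, topology, options)
    acc / length(ens$frames)
  }
  e_nat <- state_mean(native)
  e_ext <- state_mean(extended)
  tab <- data.frame(
    atom_index = prot,
    E_atom_native = e_nat, E_atom_extended = e_ext,
    delta_E_atom = e_nat - e_ext,
    partial_charge = at$partial_charge[prot + 1L],
    is_polar = at$is_polar[prot + 1L]
  )
  sums <- c(total = sum(tab$delta_E_atom),
            polar = sum(tab$delta_E_atom[tab$is_polar]),
            nonpolar = sum(tab$delta_E_atom[!tab$is_polar]))
  list(table = tab, sums = sums)
}

#' Energy breakdown by molecule-class pair
#'
#' Bins the total non-bonded energy of an ensemble (snapshot mean) into the
#' unordered molecule-class pairs protein-protein, protein-water,
#' protein-salt, water-water, water-salt and salt-salt.  Bonded terms (when
#' parameters are given) are reported for protein-protein only.  The entries
#' sum to the total system energy.
#'
#' @param ensemble a `TrajectoryEnsemble`
#' @param topology a `Topology`
#' @param options an [energy_options()] object
#' @param bonded_params optional bonded parameter set for the protein
#' @return data frame with columns `interaction`, `term`, `energy`
#' @export
component_breakdown <- function(ensemble, topology,
                                options = energy_options(),
                                bonded_params = NULL) {
  at <- topology$atoms
  idx <- list(protein = at$atom_index[at$molecule_class == "protein"],
              water = at$atom_index[at$molecule_class == "water"],
              salt = at$atom_index[at$molecule_class == "ion"])
  pairs <- list(c("protein", "protein"), c("protein", "water"),
                c("protein", "salt"), c("water", "water"),
                c("water", "salt"), c("salt", "salt"))
  rows <- list()
  for (p in pairs) {
    I <- idx[[p[1]]]; J <- idx[[p[2]]]
    if (length(I) == 0 || length(J) == 0) next
    val <- mean(vapply(ensemble$frames, function(f) {
      s <- .cross_energy_sum(I, J, f, topology, options)
      if (p[1] == p[2]) s / 2 else s
    }, numeric(1)))
    rows[[length(rows) + 1L]] <- data.frame(
      interaction = paste(p[1], p[2], sep = "-"),
      term = "non-bonded", energy = val)
  }
  if (!is.null(bonded_params)) {
    val <- mean(vapply(ensemble$frames, bonded_energy, numeric(1),
                       topology = topology, bonded_params = bonded_params))
    rows[[length(rows) + 1L]] <- data.frame(
      interaction = "protein-protein", term = "bonded", energy = val)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---------------------------------------------------------------------------
# Bonded energies (internal-consistency use).  CHARMM k-convention: no 1/2
# prefactors; E_bond = kb (b - b0)^2, E_angle = ktheta (theta - theta0)^2,
# E_dihedral = kchi (1 + cos(n chi - delta)), E_improper = kpsi (psi-psi0)^2.
# Angles in the parameter tables are degrees.
# ---------------------------------------------------------------------------

#' Bonded energy of a frame
#'
#' @param frame a `Frame`
#' @param topology a `Topology` (used to verify that every protein bond has
#'   a parameter row)
#' @param bonded_params list with data frames `bonds` (i, j, kb, b0),
#'   `angles` (i, j, k, ktheta, theta0), `dihedrals` (i, j, k, l, kchi, n,
#'   delta) and `impropers` (i, j, k, l, kpsi, psi0); indices 0-based,
#'   angles in degrees
#' @return kcal/mol
#' @export
bonded_energy <- function(frame, topology, bonded_params) {
  co <- frame$coordinates
  p <- bonded_params
  e <- 0
  if (!is.null(p$bonds) && nrow(p$bonds) > 0) {
    # every protein-protein topology bond must be parameterised
    at <- topology$atoms
    prot_bonds <- topology$bonds[
      at$molecule_class[topology$bonds[, 1] + 1L] == "protein" &
      at$molecule_class[topology$bonds[, 2] + 1L] == "protein", ,
      drop = FALSE]
    if (nrow(prot_bonds) > 0) {
      have <- .pair_keys(p$bonds$i, p$bonds$j, nrow(at))
      need <- .pair_keys(prot_bonds[, 1], prot_bonds[, 2], nrow(at))
      miss <- which(!(need %in% have))
      if (length(miss) > 0)
        stop("no bond parameter for bond ", prot_bonds[miss[1], 1], "-",
             prot_bonds[miss[1], 2])
    }
    d <- co[p$bonds$i + 1L, , drop = FALSE] - co[p$bonds$j + 1L, , drop = FALSE]
    b <- sqrt(rowSums(d^2))
    e <- e + sum(p$bonds$kb * (b - p$bonds$b0)^2)
  }
  if (!is.null(p$angles) && nrow(p$angles) > 0) {
    th <- .angle_deg(co[p$angles$i + 1L, , drop = FALSE],
                     co[p$angles$j + 1L, , drop = FALSE],
                     co[p$angles$k + 1L, , drop = FALSE])
    e <- e + sum(p$angles$ktheta * ((th - p$angles$theta0) * pi / 180)^2)
  }
  if (!is.null(p$dihedrals) && nrow(p$dihedrals) > 0) {
    chi <- .dihedral_deg(co[p$dihedrals$i + 1L, , drop = FALSE],
                         co[p$dihedrals$j + 1L, , drop = FALSE],
                         co[p$dihedrals$k + 1L, , drop = FALSE],
                         co[p$dihedrals$l + 1L, , drop = FALSE])
    e <- e + sum(p$dihedrals$kchi *
                   (1 + cos((p$dihedrals$n * chi - p$dihedrals$delta) *
                              pi / 180)))
  }
  if (!is.null(p$impropers) && nrow(p$impropers) > 0) {
    psi <- .dihedral_deg(co[p$impropers$i + 1L, , drop = FALSE],
                         co[p$impropers$j + 1L, , drop = FALSE],
                         co[p$impropers$k + 1L, , drop = FALSE],
                         co[p$impropers$l + 1L, , drop = FALSE])
    e <- e + sum(p$impropers$kpsi * ((psi - p$impropers$psi0) * pi / 180)^2)
  }
  e
}

# angle at b, degrees (rows of matrices)
.angle_deg <- function(a, b, c) {
  u <- a - b; v <- c - b
  cosang <- rowSums(u * v) / sqrt(rowSums(u^2) * rowSums(v^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

# signed dihedral i-j-k-l, degrees
.dihedral_deg <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- .rowcross(b1, b2); n2 <- .rowcross(b2, b3)
  m1 <- .rowcross(n1, b2 / sqrt(rowSums(b2^2)))
  atan2(rowSums(m1 * n2), rowSums(n1 * n2)) * 180 / pi
}

.rowcross <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}
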