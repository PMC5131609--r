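# Hydration-site identification and per-site thermodynamics under
# inhomogeneous fluid solvation theory (IFST).
#
# Per site: E_site is the mean interaction energy of the site water with
# its whole environment; dE = E_site - n * E_bulk; the solute-water entropy
# S_sw comes from a nearest-neighbour estimator in the combined
# translational (A) + orientational (rad) space; dS = S_sw - n * S_bulk
# (the water-water term is assigned zero); dG = dE - T dS.

.GAS_CONSTANT_R <- 0.0019872   # kcal/mol/K
.EULER_GAMMA <- 0.5772156649015329

#' Configuration of the nearest-neighbour entropy estimator
#'
#' @param k neighbour order (the first nearest neighbour by default; higher
#'   k replaces the Euler-constant bias correction by `-digamma(k)`)
#' @param gas_constant_R gas constant, kcal/mol/K
#' @param temperature_T temperature in K
#' @param water_symmetry_in_orientation fold the H1/H2 exchange symmetry
#'   into the orientational metric.  The default `FALSE` is fixed by the
#'   zero-point calibration: with orientations drawn uniformly over the
#'   full rotation group, the estimator's normalisation constant makes
#'   S_sw vanish only when the metric does not fold the symmetry.
#' @param exclude_same_frame_neighbors exclude observations from the same
#'   frame from the neighbour search (waters in one frame are correlated)
#' @return object of class `EstimatorConfig`
#' @export
estimator_config <- function(k = 1L, gas_constant_R = .GAS_CONSTANT_R,
                             temperature_T = 300,
                             water_symmetry_in_orientation = FALSE,
                             exclude_same_frame_neighbors = TRUE) {
  stopifnot(k >= 1, temperature_T > 0)
  structure(list(k = as.integer(k), gas_constant_R = gas_constant_R,
                 temperature_T = temperature_T,
                 euler_gamma = .EULER_GAMMA,
                 water_symmetry_in_orientation =
                   water_symmetry_in_orientation,
                 exclude_same_frame_neighbors =
                   exclude_same_frame_neighbors),
            class = "EstimatorConfig")
}

#' Bulk-water reference values
#'
#' Mean energy and entropy of a water molecule in neat solvent for a given
#' water model and salt concentration; subtracted per occupying water from
#' site values.  The package ships a reference table for TIP3P and
#' TIP4P-2005 at several NaCl concentrations (see [bulk_reference_table()]).
#'
#' @param water_model water model name
#' @param nacl_mM salt concentration (mM)
#' @param E_bulk mean water-environment interaction energy (kcal/mol)
#' @param minus_T_S_bulk `-T S_bulk` (kcal/mol)
#' @param G_bulk free energy (kcal/mol); must equal
#'   `E_bulk + minus_T_S_bulk` within printing rounding (each of the three
#'   values is reported to 0.1 kcal/mol, so the triple can disagree by up
#'   to 0.15)
#' @return object of class `BulkReference`
#' @export
bulk_reference <- function(water_model, nacl_mM, E_bulk, minus_T_S_bulk,
                           G_bulk = E_bulk + minus_T_S_bulk) {
  if (abs(G_bulk - (E_bulk + minus_T_S_bulk)) > 0.15)
    stop("inconsistent bulk reference: G_bulk != E_bulk - T S_bulk")
  structure(list(water_model = water_model, nacl_mM = nacl_mM,
                 E_bulk = E_bulk, minus_T_S_bulk = minus_T_S_bulk,
                 G_bulk = G_bulk),
            class = "BulkReference")
}

#' Bundled bulk-water reference table
#'
#' Thermodynamic properties of bulk water (kcal/mol) for the supported
#' water models and salt concentrations, as shipped in
#' `extdata/bulk_water_reference.tsv`.
#'
#' @return data frame: `water_model`, `nacl_mM`, `E_bulk`, `G_bulk`,
#'   `minus_T_S_bulk`
#' @export
bulk_reference_table <- function() {
  path <- system.file("extdata", "bulk_water_reference.tsv",
                      package = "coophyd", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Look up a bundled bulk reference
#'
#' @param water_model e.g. `"TIP3P"`
#' @param nacl_mM salt concentration (mM)
#' @return a [bulk_reference()] object
#' @export
get_bulk_reference <- function(water_model = "TIP3P", nacl_mM = 0) {
  tab <- bulk_reference_table()
  row <- tab[tab$water_model == water_model & tab$nacl_mM == nacl_mM, ]
  if (nrow(row) != 1)
    stop("no bulk reference for ", water_model, " at ", nacl_mM, " mM")
  bulk_reference(water_model, nacl_mM, row$E_bulk, row$minus_T_S_bulk,
                 row$G_bulk)
}

# ---------------------------------------------------------------------------
# Water observations
# ---------------------------------------------------------------------------

#' Extract water observations from an ensemble
#'
#' One observation per water molecule per frame: oxygen position,
#' orientation quaternion relative to the reference water orientation, the
#' frame index and the frame volume.
#'
#' @param ensemble a `TrajectoryEnsemble`
#' @param topology a `Topology`
#' @param waters optional subset of water residue numbers
#' @return object of class `WaterObservations`: list with `position`
#'   (M x 3), `quaternion` (M x 4), `frame_index`, `residue`, `volume`
#'   (per observation), `box` and `n_frames`
#' @export
water_observations <- function(ensemble, topology, waters = NULL) {
  at <- topology$atoms
  w <- at[at$molecule_class == "water", ]
  res <- unique(w$residue_number)
  if (!is.null(waters)) res <- intersect(res, waters)
  if (length(res) == 0) stop("no water molecules selected")
  o_idx <- vapply(res, function(r)
    w$atom_index[w$residue_number == r & w$element == "O"][1], integer(1))
  h_idx <- t(vapply(res, function(r)
    w$atom_index[w$residue_number == r & w$element == "H"][1:2],
    integer(2)))
  F <- n_frames(ensemble)
  M <- F * length(res)
  pos <- matrix(0, M, 3); quat <- matrix(0, M, 4)
  fidx <- integer(M); resid <- integer(M); vol <- numeric(M)
  k <- 0L
  for (fi in seq_len(F)) {
    fr <- ensemble$frames[[fi]]
    v <- prod(fr$box)
    for (wi in seq_along(res)) {
      k <- k + 1L
      pos[k, ] <- fr$coordinates[o_idx[wi] + 1L, ]
      quat[k, ] <- water_orientation(fr$coordinates[o_idx[wi] + 1L, ],
                                     fr$coordinates[h_idx[wi, 1] + 1L, ],
                                     fr$coordinates[h_idx[wi, 2] + 1L, ])
      fidx[k] <- fi; resid[k] <- res[wi]; vol[k] <- v
    }
  }
  structure(list(position = pos, quaternion = quat, frame_index = fidx,
                 residue = resid, volume = vol,
                 box = ensemble$frames[[1]]$box, n_frames = F),
            class = "WaterObservations")
}

# ---------------------------------------------------------------------------
# Nearest-neighbour entropy estimator
# ---------------------------------------------------------------------------

# k-th nearest neighbour distances in the combined metric, chunked brute
# force.  Returns a vector of distances (NA where no usable neighbour).
.knn_distances <- function(obs, k = 1L, box = NULL,
                           water_symmetry = FALSE,
                           exclude_same_frame = TRUE, chunk = 512L) {
  pos <- obs$position; quat <- obs$quaternion
  M <- nrow(pos)
  if (is.null(box)) box <- obs$box
  qsym <- if (water_symmetry)
    t(apply(quat, 1, .quat_multiply, b = c(0, 0, 0, 1)))
  else NULL
  out <- rep(NA_real_, M)
  dropped_zero <- FALSE
  for (start in seq(1L, M, by = chunk)) {
    rows <- start:min(M, start + chunk - 1L)
    d2t <- matrix(0, length(rows), M)
    for (c3 in 1:3) {
      dd <- outer(pos[rows, c3], pos[, c3], "-")
      dd <- dd - box[c3] * round(dd / box[c3])
      d2t <- d2t + dd * dd
    }
    dot <- abs(quat[rows, , drop = FALSE] %*% t(quat))
    if (!is.null(qsym)) {
      dot2 <- abs(quat[rows, , drop = FALSE] %*% t(qsym))
      dot <- pmax(dot, dot2)
    }
    dor <- 2 * acos(pmin(1, dot))
    d2 <- d2t + dor * dor
    # self and same-frame masking
    for (ri in seq_along(rows)) {
      i <- rows[ri]
      d2[ri, i] <- Inf
      if (exclude_same_frame) {
        same <- obs$frame_index == obs$frame_index[i]
        same[i] <- TRUE
        d2[ri, same] <- Inf
      }
    }
    zero <- d2 < 1e-20 & is.finite(d2)
    if (any(zero)) { dropped_zero <- TRUE; d2[zero] <- Inf }
    for (ri in seq_along(rows)) {
      v <- d2[ri, ]
      v <- v[is.finite(v)]
      if (length(v) >= k) out[rows[ri]] <- sqrt(sort(v, partial = k)[k])
    }
  }
  if (dropped_zero)
    warning("zero-distance neighbours (duplicated observations) excluded")
  out
}

#' Solute-water entropy from a nearest-neighbour estimator
#'
#' Estimates `S_sw` from water observations in the combined translational +
#' orientational space: for each observation the k-th nearest neighbour
#' distance `d_total = sqrt(d_trans^2 + d_orient^2)` is found (minimum
#' image in translation, rotation-group metric in orientation), and
#'
#' `S_sw = n R [ mean ln( pi d_total^6 M / (48 V_i) ) + gamma ]`
#'
#' with `M` the number of observations, `V_i` the frame volume, `n` the
#' mean number of waters per frame in the region, and `gamma` Euler's
#' constant correcting the asymptotic bias (for k > 1, `-digamma(k)` is
#' used).  The normalisation is such that uniformly distributed positions
#' and orientations give zero: the bundled constant corresponds to the
#' full rotation-group volume, which is why the water-symmetry fold is off
#' by default.
#'
#' @param observations a [water_observations()] object (or compatible list)
#' @param config an [estimator_config()]
#' @param box optional box override for the minimum image convention
#' @return `S_sw` in kcal/mol/K
#' @export
ssw_knn <- function(observations, config = estimator_config(), box = NULL) {
  M <- nrow(observations$position)
  if (M < 2) stop("need at least 2 observations")
  d <- .knn_distances(observations, k = config$k, box = box,
                      water_symmetry = config$water_symmetry_in_orientation,
                      exclude_same_frame =
                        config$exclude_same_frame_neighbors)
  usable <- which(is.finite(d) & d > 0)
  if (length(usable) < 2)
    stop("degenerate observation set: no usable neighbour distances")
  if (length(usable) < M)
    warning(M - length(usable), " observation(s) without usable neighbours",
            " dropped")
  bias <- if (config$k == 1) config$euler_gamma else -digamma(config$k)
  F <- observations$n_frames
  n_per_frame <- M / F
  terms <- log(pi * d[usable]^6 * M / (48 * observations$volume[usable]))
  n_per_frame * config$gas_constant_R * (mean(terms) + bias)
}

# ---------------------------------------------------------------------------
# Hydration-site clustering
# ---------------------------------------------------------------------------

# neighbour counts within radius r (minimum image), chunked brute force
.neighbor_counts <- function(pos, r, box, alive = NULL, chunk = 1024L) {
  M <- nrow(pos)
  if (is.null(alive)) alive <- rep(TRUE, M)
  idx_alive <- which(alive)
  counts <- rep(0L, M)
  r2 <- r * r
  for (start in seq(1L, M, by = chunk)) {
    rows <- start:min(M, start + chunk - 1L)
    d2 <- matrix(0, length(rows), length(idx_alive))
    for (c3 in 1:3) {
      dd <- outer(pos[rows, c3], pos[idx_alive, c3], "-")
      dd <- dd - box[c3] * round(dd / box[c3])
      d2 <- d2 + dd * dd
    }
    counts[rows] <- rowSums(d2 <= r2)
  }
  counts  # includes self when alive
}

#' Identify hydration sites by greedy density clustering
#'
#' Water-oxygen observations from a fixed-solute ensemble are ranked by
#' their neighbour count within `site_radius`; the densest observation is
#' accepted as a site center, its members removed, and the procedure
#' repeats subject to a minimum separation between site centers, stopping
#' when the best remaining candidate would be occupied in fewer than
#' `min_occupancy` of the frames.  Optionally only sites within
#' `surface_cutoff` of a protein heavy atom are retained.
#'
#' @param ensemble a fixed-solute `TrajectoryEnsemble`
#' @param topology a `Topology`
#' @param protein_atoms 0-based indices of protein heavy atoms used for the
#'   surface filter, or `NULL` to disable the filter
#' @param surface_cutoff retain sites within this distance of a protein
#'   heavy atom (A)
#' @param site_radius site membership radius (A)
#' @param min_center_sep minimum distance between accepted site centers (A)
#' @param min_occupancy stop when the best candidate's occupied-frame
#'   fraction falls below this
#' @return data frame of sites: `site`, `x`, `y`, `z`, `n_obs`,
#'   `occupancy`, `n_eff` (= occupancy: sites hold at most one water per
#'   frame by construction), `site_radius`
#' @export
cluster_hydration_sites <- function(ensemble, topology,
                                    protein_atoms = NULL,
                                    surface_cutoff = 4.1,
                                    site_radius = 1.0,
                                    min_center_sep = 2.4,
                                    min_occupancy = 0.5) {
  obs <- water_observations(ensemble, topology)
  pos <- obs$position
  M <- nrow(pos)
  if (M == 0) stop("no water observations")
  F <- obs$n_frames
  box <- obs$box
  alive <- rep(TRUE, M)
  eligible <- rep(TRUE, M)
  sites <- list()
  repeat {
    counts <- .neighbor_counts(pos, site_radius, box, alive)
    counts[!alive | !eligible] <- -1L
    best <- which.max(counts)
    if (counts[best] < min_occupancy * F) break
    center <- pos[best, ]
    # members: alive observations within the site radius
    d2 <- colSums((t(pos) - center -
                     box * round((t(pos) - center) / box))^2)
    members <- which(alive & d2 <= site_radius^2)
    occ_frames <- length(unique(obs$frame_index[members]))
    sites[[length(sites) + 1L]] <- c(center, length(members),
                                     occ_frames / F)
    alive[members] <- FALSE
    # enforce separation between centers
    d2c <- colSums((t(pos) - center -
                      box * round((t(pos) - center) / box))^2)
    eligible[d2c <= min_center_sep^2] <- FALSE
  }
  if (length(sites) == 0)
    return(data.frame(site = integer(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), n_obs = integer(0),
                      occupancy = numeric(0), n_eff = numeric(0),
                      site_radius = numeric(0)))
  m <- do.call(rbind, sites)
  out <- data.frame(site = seq_len(nrow(m)), x = m[, 1], y = m[, 2],
                    z = m[, 3], n_obs = as.integer(m[, 4]),
                    occupancy = m[, 5], n_eff = m[, 5],
                    site_radius = site_radius)
  if (!is.null(protein_atoms) && length(protein_atoms) > 0) {
    at <- topology$atoms
    heavy <- protein_atoms[at$element[protein_atoms + 1L] != "H"]
    pco <- ensemble$frames[[1]]$coordinates[heavy + 1L, , drop = FALSE]
    keep <- vapply(seq_len(nrow(out)), function(s) {
      c0 <- as.numeric(out[s, c("x", "y", "z")])
      d <- .mi_disp(matrix(c0, nrow(pco), 3, byrow = TRUE), pco, box)
      min(sqrt(rowSums(d^2))) <= surface_cutoff
    }, logical(1))
    out <- out[keep, , drop = FALSE]
    out$site <- seq_len(nrow(out))
  }
  rownames(out) <- NULL
  out
}

# water residue occupying a site in each frame (NA if unoccupied):
# the nearest water oxygen within the site radius
.site_occupants <- function(site_center, site_radius, obs) {
  F <- obs$n_frames
  occ <- rep(NA_integer_, F)
  d <- t(obs$position) - site_center
  d <- d - obs$box * round(d / obs$box)
  dist <- sqrt(colSums(d^2))
  for (fi in seq_len(F)) {
    sel <- which(obs$frame_index == fi & dist <= site_radius)
    if (length(sel) > 0) occ[fi] <- obs$residue[sel[which.min(dist[sel])]]
  }
  occ
}

#' Site water energy and its difference from bulk
#'
#' `E_site` is the mean (over occupied frames) of the site water's total
#' interaction energy with all other atoms in the system -- the full
#' water-environment interaction, matching the convention of the bulk
#' reference, with no half-weighting.  `dE = E_site - n_eff * E_bulk`.
#'
#' @param site one row of a [cluster_hydration_sites()] table (or a list
#'   with `x`, `y`, `z`, `site_radius`, `n_eff`)
#' @param ensemble the `TrajectoryEnsemble` the sites were clustered from
#' @param topology a `Topology`
#' @param options an [energy_options()] object
#' @param bulk a [bulk_reference()]
#' @return list with `E_site`, `delta_E_ifst` and `n_eff`
#' @export
site_energy <- function(site, ensemble, topology,
                        options = energy_options(),
                        bulk = get_bulk_reference()) {
  obs <- water_observations(ensemble, topology)
  center <- as.numeric(c(site$x, site$y, site$z))
  occ <- .site_occupants(center, site$site_radius, obs)
  frames_occ <- which(!is.na(occ))
  if (length(frames_occ) == 0) stop("site has zero occupancy")
  at <- topology$atoms
  all_idx <- at$atom_index
  e <- vapply(frames_occ, function(fi) {
    mol <- at$atom_index[at$molecule_class == "water" &
                           at$residue_number == occ[fi]]
    # ordered cross sum counts intra-molecular pairs twice, but those are
    # all 1-2/1-3 exclusions and contribute zero
    .cross_energy_sum(mol, all_idx, ensemble$frames[[fi]], topology,
                      options)
  }, numeric(1))
  E_site <- mean(e)
  n_eff <- if (!is.null(site$n_eff)) site$n_eff
           else length(frames_occ) / obs$n_frames
  list(E_site = E_site, delta_E_ifst = E_site - n_eff * bulk$E_bulk,
       n_eff = n_eff)
}

#' Complete a hydration site's free energy
#'
#' `dS_IFST = S_sw - n_eff * S_bulk` (the water-water term is assigned
#' zero), `-T dS = -T S_sw + n_eff * (-T S_bulk)`, and
#' `dG = dE - T dS`.
#'
#' @param site list or one-row data frame with `delta_E_ifst`, `S_sw` and
#'   `n_eff`
#' @param bulk a [bulk_reference()]
#' @param config an [estimator_config()] (supplies the temperature)
#' @return the site as a list with `minus_T_delta_S` and `delta_G_ifst`
#'   added
#' @export
site_free_energy <- function(site, bulk = get_bulk_reference(),
                             config = estimator_config()) {
  if (is.null(site$delta_E_ifst) || is.null(site$S_sw))
    stop("site needs delta_E_ifst and S_sw before the free energy")
  minus_T_S_sw <- -config$temperature_T * site$S_sw
  site$minus_T_delta_S <- minus_T_S_sw + site$n_eff * bulk$minus_T_S_bulk
  site$delta_G_ifst <- site$delta_E_ifst + site$minus_T_delta_S
  site
}

#' Full hydration-site analysis of a fixed-solute ensemble
#'
#' Clusters hydration sites, computes per-site energies against the bulk
#' reference, estimates per-site solute-water entropies with the
#' nearest-neighbour estimator, and assembles `dG = dE - T dS` per site.
#'
#' @inheritParams cluster_hydration_sites
#' @param options an [energy_options()] object
#' @param bulk a [bulk_reference()]
#' @param config an [estimator_config()]
#' @param ... passed to [cluster_hydration_sites()]
#' @return data frame: one row per site with center, occupancy, `E_site`,
#'   `delta_E_ifst`, `S_sw`, `minus_T_delta_S`, `delta_G_ifst`
#' @export
hydration_site_analysis <- function(ensemble, topology,
                                    protein_atoms = NULL,
                                    options = energy_options(),
                                    bulk = get_bulk_reference(),
                                    config = estimator_config(), ...) {
  sites <- cluster_hydration_sites(ensemble, topology, protein_atoms, ...)
  if (nrow(sites) == 0) return(sites)
  obs <- water_observations(ensemble, topology)
  out <- vector("list", nrow(sites))
  for (s in seq_len(nrow(sites))) {
    row <- as.list(sites[s, ])
    en <- site_energy(row, ensemble, topology, options, bulk)
    row$E_site <- en$E_site
    row$delta_E_ifst <- en$delta_E_ifst
    center <- as.numeric(c(row$x, row$y, row$z))
    occ <- .site_occupants(center, row$site_radius, obs)
    keep <- which(!is.na(occ))
    idx <- vapply(keep, function(fi)
      which(obs$frame_index == fi & obs$residue == occ[fi])[1], integer(1))
    site_obs <- list(position = obs$position[idx, , drop = FALSE],
                     quaternion = obs$quaternion[idx, , drop = FALSE],
                     frame_index = obs$frame_index[idx],
                     volume = obs$volume[idx],
                     box = obs$box, n_frames = obs$n_frames)
    row$S_sw <- if (length(idx) >= 2)
      tryCatch(ssw_knn(site_obs, config), error = function(e) NA_real_)
    else NA_real_
    row <- site_free_energy(row, bulk, config)
    out[[s]] <- as.data.frame(row[c("site", "x", "y", "z", "n_obs",
                                    "occupancy", "n_eff", "site_radius",
                                    "E_site", "delta_E_ifst", "S_sw",
                                    "minus_T_delta_S", "delta_G_ifst")])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
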