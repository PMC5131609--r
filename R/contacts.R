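# Geometric detection of direct hydrogen bonds, non-polar contacts and
# water-bridged (cooperatively hydrated) interactions, molecular-symmetry
# resolution, and persistence across replicate ensembles.
#
# All cutoff boundaries are inclusive exactly as worded: "3.2 A or less",
# "130 degrees or more", etc.  Comparisons carry a guard far below any
# physically meaningful resolution (1e-9 A, 1e-6 deg) so that geometries
# constructed exactly on a boundary classify inclusively regardless of
# floating-point rounding.

.EPS_DIST <- 1e-9    # Angstrom
.EPS_ANGLE <- 1e-6   # degrees

#' Geometric detection criteria
#'
#' @param hb_heavy_dist_max donor-acceptor heavy-atom distance ceiling for a
#'   direct hydrogen bond (A)
#' @param hb_angle_min donor-H-acceptor angle floor (degrees)
#' @param np_dist_max non-polar heavy-atom distance ceiling (A)
#' @param ch_polar_dist_min,ch_polar_dist_max separation window of the two
#'   polar partners of a water-bridged interaction (A); the floor keeps
#'   direct hydrogen-bond territory out
#' @param ch_water_dist_max bridging-water oxygen distance ceiling to each
#'   partner (A)
#' @param ch_donor_angle_min donor-H-waterO angle floor (degrees)
#' @param ch_acceptor_angle_min acceptor-(bonded heavy)-waterO angle floor
#'   (degrees, vertex at the bonded heavy atom)
#' @param persistence_threshold a contact is persistent when its mean count
#'   per frame, averaged over replicates, is strictly greater than this
#' @return object of class `DetectionCriteria`
#' @export
detection_criteria <- function(hb_heavy_dist_max = 3.2, hb_angle_min = 130,
                               np_dist_max = 4.5,
                               ch_polar_dist_min = 3.2,
                               ch_polar_dist_max = 6.0,
                               ch_water_dist_max = 4.0,
                               ch_donor_angle_min = 90,
                               ch_acceptor_angle_min = 90,
                               persistence_threshold = 0.5) {
  stopifnot(hb_heavy_dist_max > 0, np_dist_max > 0,
            ch_polar_dist_min > 0, ch_polar_dist_max > ch_polar_dist_min,
            ch_water_dist_max > 0,
            hb_angle_min > 0, hb_angle_min <= 180,
            ch_donor_angle_min > 0, ch_acceptor_angle_min > 0)
  structure(list(hb_heavy_dist_max = hb_heavy_dist_max,
                 hb_angle_min = hb_angle_min, np_dist_max = np_dist_max,
                 ch_polar_dist_min = ch_polar_dist_min,
                 ch_polar_dist_max = ch_polar_dist_max,
                 ch_water_dist_max = ch_water_dist_max,
                 ch_donor_angle_min = ch_donor_angle_min,
                 ch_acceptor_angle_min = ch_acceptor_angle_min,
                 persistence_threshold = persistence_threshold),
            class = "DetectionCriteria")
}

# minimum-image displacement rows from[k,] -> to[k,]
.mi_disp <- function(from, to, box) {
  d <- to - from
  d[, 1] <- .min_image(d[, 1], box[1])
  d[, 2] <- .min_image(d[, 2], box[2])
  d[, 3] <- .min_image(d[, 3], box[3])
  d
}

# minimum-image distances between atom index vectors (0-based, recycled)
.mi_dist_idx <- function(frame, i, j) {
  co <- frame$coordinates
  d <- .mi_disp(co[i + 1L, , drop = FALSE], co[j + 1L, , drop = FALSE],
                frame$box)
  sqrt(rowSums(d^2))
}

# angle (degrees) at vertex v between rays v->a and v->b, minimum image
.mi_angle_idx <- function(frame, a, v, b) {
  co <- frame$coordinates
  u <- .mi_disp(co[v + 1L, , drop = FALSE], co[a + 1L, , drop = FALSE],
                frame$box)
  w <- .mi_disp(co[v + 1L, , drop = FALSE], co[b + 1L, , drop = FALSE],
                frame$box)
  cosang <- rowSums(u * w) / sqrt(rowSums(u^2) * rowSums(w^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

.scope_atoms <- function(topology, scope) {
  at <- topology$atoms
  if (scope == "protein") at$atom_index[at$molecule_class == "protein"]
  else at$atom_index
}

.bonded_hydrogens <- function(topology, i) {
  nb <- topology$adjacency[[i + 1L]]
  nb[topology$atoms$element[nb + 1L] == "H"]
}

.bonded_heavy <- function(topology, i) {
  nb <- topology$adjacency[[i + 1L]]
  nb[topology$atoms$element[nb + 1L] != "H"]
}

#' Detect direct hydrogen bonds in one frame
#'
#' A donor-acceptor pair is reported iff the heavy-atom minimum-image
#' distance is at most `hb_heavy_dist_max` and the donor-H-acceptor angle is
#' at least `hb_angle_min` for some hydrogen bonded to the donor (both
#' boundaries inclusive).  Pairs in the 1-2/1-3/1-4 exclusion sets are
#' skipped.
#'
#' @param frame a `Frame`
#' @param topology a `Topology` with donor/acceptor flags
#' @param criteria a [detection_criteria()] object
#' @param scope `"protein"` (both partners protein atoms, the default) or
#'   `"all"`
#' @return data frame: `donor`, `hydrogen`, `acceptor` (0-based indices),
#'   `distance` (A), `angle` (degrees); the hydrogen is the passing one with
#'   the widest angle
#' @export
detect_hbonds <- function(frame, topology, criteria = detection_criteria(),
                          scope = c("protein", "all")) {
  scope <- match.arg(scope)
  at <- topology$atoms
  pool <- .scope_atoms(topology, scope)
  donors <- pool[at$is_donor[pool + 1L]]
  acceptors <- pool[at$is_acceptor[pool + 1L]]
  empty <- data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), distance = numeric(0),
                      angle = numeric(0))
  if (length(donors) == 0 || length(acceptors) == 0) return(empty)
  dd <- rep(donors, times = length(acceptors))
  aa <- rep(acceptors, each = length(donors))
  keep <- dd != aa
  dd <- dd[keep]; aa <- aa[keep]
  dist <- .mi_dist_idx(frame, dd, aa)
  ok <- dist <= criteria$hb_heavy_dist_max + .EPS_DIST &
    !is_excluded_pair(topology, dd, aa)
  dd <- dd[ok]; aa <- aa[ok]; dist <- dist[ok]
  if (length(dd) == 0) return(empty)
  rows <- vector("list", length(dd))
  for (k in seq_along(dd)) {
    hs <- .bonded_hydrogens(topology, dd[k])
    if (length(hs) == 0)
      stop("donor atom ", dd[k], " has no bonded hydrogen")
    ang <- .mi_angle_idx(frame, rep(dd[k], length(hs)), hs,
                         rep(aa[k], length(hs)))
    pass <- ang >= criteria$hb_angle_min - .EPS_ANGLE
    if (any(pass)) {
      best <- hs[pass][which.max(ang[pass])]
      rows[[k]] <- data.frame(donor = dd[k], hydrogen = best,
                              acceptor = aa[k], distance = dist[k],
                              angle = max(ang[pass]))
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# carbon/sulfur atoms with no bonded oxygen or nitrogen
.nonpolar_atoms <- function(topology, scope = "protein") {
  at <- topology$atoms
  pool <- .scope_atoms(topology, scope)
  keep <- vapply(pool, function(i) {
    if (!(at$element[i + 1L] %in% c("C", "S"))) return(FALSE)
    nb <- topology$adjacency[[i + 1L]]
    !any(at$element[nb + 1L] %in% c("O", "N"))
  }, logical(1))
  pool[keep]
}

#' Detect non-polar contacts in one frame
#'
#' Qualifying atoms are carbon or sulfur atoms with no bonded oxygen or
#' nitrogen.  A contact is a pair of qualifying atoms within `np_dist_max`
#' (inclusive), excluding same-residue pairs and 1-2/1-3/1-4 pairs.
#'
#' @inheritParams detect_hbonds
#' @return data frame: `i`, `j` (0-based, i < j), `distance` (A)
#' @export
detect_nonpolar <- function(frame, topology,
                            criteria = detection_criteria(),
                            scope = c("protein", "all")) {
  scope <- match.arg(scope)
  q <- .nonpolar_atoms(topology, scope)
  empty <- data.frame(i = integer(0), j = integer(0), distance = numeric(0))
  if (length(q) < 2) return(empty)
  at <- topology$atoms
  pairs <- t(utils::combn(q, 2))
  ii <- pairs[, 1]; jj <- pairs[, 2]
  same_res <- at$residue_number[ii + 1L] == at$residue_number[jj + 1L] &
    at$molecule_class[ii + 1L] == at$molecule_class[jj + 1L]
  dist <- .mi_dist_idx(frame, ii, jj)
  ok <- !same_res & dist <= criteria$np_dist_max + .EPS_DIST &
    !is_excluded_pair(topology, ii, jj)
  out <- data.frame(i = ii[ok], j = jj[ok], distance = dist[ok])
  rownames(out) <- NULL
  out
}

# role of a polar partner in a bridged interaction: donors act through a
# bonded hydrogen, pure acceptors through a bonded heavy atom
.ch_partner_pass <- function(frame, topology, criteria, p, w) {
  at <- topology$atoms
  if (at$is_donor[p + 1L]) {
    hs <- .bonded_hydrogens(topology, p)
    ang <- .mi_angle_idx(frame, rep(p, length(hs)), hs, rep(w, length(hs)))
    if (any(ang >= criteria$ch_donor_angle_min - .EPS_ANGLE)) return(TRUE)
  }
  if (at$is_acceptor[p + 1L]) {
    bh <- .bonded_heavy(topology, p)
    if (length(bh) > 0) {
      # vertex at the acceptor: angle between the acceptor->bonded-heavy
      # bond and the acceptor->waterO direction, i.e. the water must sit on
      # the lone-pair side of the acceptor
      ang <- .mi_angle_idx(frame, bh, rep(p, length(bh)),
                           rep(w, length(bh)))
      if (any(ang >= criteria$ch_acceptor_angle_min - .EPS_ANGLE)) return(TRUE)
    }
  }
  FALSE
}

#' Detect cooperatively hydrated (water-bridged) interactions in one frame
#'
#' A pair of polar protein atoms (each a donor or an acceptor) is reported
#' iff (i) their separation lies in `[ch_polar_dist_min,
#' ch_polar_dist_max]`; (ii) a single water oxygen lies within
#' `ch_water_dist_max` of both; (iii) each donor partner passes the
#' donor-H-waterO angle floor for some bonded hydrogen; (iv) each acceptor
#' partner passes the acceptor-(bonded heavy)-waterO angle floor.  When
#' several waters bridge, the one minimising the sum of the two oxygen
#' distances defines the record for the frame, and the angle criteria are
#' evaluated with that water only.
#'
#' @inheritParams detect_hbonds
#' @return data frame: `i`, `j` (0-based, i < j), `water_o` (bridging water
#'   oxygen index), `distance` (partner separation, A)
#' @export
detect_coophyd <- function(frame, topology,
                           criteria = detection_criteria(),
                           scope = c("protein", "all")) {
  scope <- match.arg(scope)
  at <- topology$atoms
  pool <- .scope_atoms(topology, scope)
  polar <- pool[at$is_donor[pool + 1L] | at$is_acceptor[pool + 1L]]
  wat_o <- at$atom_index[at$molecule_class == "water" & at$element == "O"]
  empty <- data.frame(i = integer(0), j = integer(0), water_o = integer(0),
                      distance = numeric(0))
  if (length(polar) < 2 || length(wat_o) == 0) return(empty)
  pairs <- t(utils::combn(polar, 2))
  ii <- pairs[, 1]; jj <- pairs[, 2]
  dist <- .mi_dist_idx(frame, ii, jj)
  ok <- dist >= criteria$ch_polar_dist_min - .EPS_DIST &
    dist <= criteria$ch_polar_dist_max + .EPS_DIST
  ii <- ii[ok]; jj <- jj[ok]; dist <- dist[ok]
  if (length(ii) == 0) return(empty)
  # water-partner distance table, |waters| x |polar atoms involved|
  partners <- unique(c(ii, jj))
  dw <- matrix(0, nrow = length(wat_o), ncol = length(partners))
  for (c_idx in seq_along(partners))
    dw[, c_idx] <- .mi_dist_idx(frame, wat_o, rep(partners[c_idx],
                                                  length(wat_o)))
  colnames(dw) <- as.character(partners)
  rows <- vector("list", length(ii))
  for (k in seq_along(ii)) {
    di <- dw[, as.character(ii[k])]
    dj <- dw[, as.character(jj[k])]
    cand <- which(di <= criteria$ch_water_dist_max + .EPS_DIST &
                  dj <= criteria$ch_water_dist_max + .EPS_DIST)
    if (length(cand) == 0) next
    w <- wat_o[cand[which.min(di[cand] + dj[cand])]]
    if (.ch_partner_pass(frame, topology, criteria, ii[k], w) &&
        .ch_partner_pass(frame, topology, criteria, jj[k], w)) {
      rows[[k]] <- data.frame(i = ii[k], j = jj[k], water_o = w,
                              distance = dist[k])
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---------------------------------------------------------------------------
# Contact identities and symmetry resolution
# ---------------------------------------------------------------------------

#' Construct a contact record
#'
#' A contact is identified by its kind and by two slots, each the set of
#' symmetry-equivalent atoms containing the given atom.  Hydrogen bonds are
#' directional (donor slot, acceptor slot); non-polar and water-bridged
#' contacts are unordered.
#'
#' @param topology a `Topology` (after [assign_symmetry_groups()])
#' @param kind `"hbond"`, `"nonpolar"` or `"coophyd"`
#' @param i,j 0-based atom indices of one concrete realisation (for hbond:
#'   `i` = donor heavy atom, `j` = acceptor)
#' @return object of class `ContactRecord` with `kind`, `slots` (two
#'   integer vectors of alternatives), `labels` and `id`
#' @export
contact_record <- function(topology, kind, i, j) {
  kind <- match.arg(kind, c("hbond", "nonpolar", "coophyd"))
  s1 <- symmetry_alternatives(topology, i)
  s2 <- symmetry_alternatives(topology, j)
  l1 <- .slot_label(topology, i)
  l2 <- .slot_label(topology, j)
  if (kind != "hbond" && l2 < l1) {   # canonical order for unordered kinds
    tmp <- s1; s1 <- s2; s2 <- tmp
    tmp <- l1; l1 <- l2; l2 <- tmp
  }
  structure(list(kind = kind, slots = list(s1, s2),
                 labels = c(l1, l2),
                 id = paste(kind, l1, l2, sep = "||")),
            class = "ContactRecord")
}

#' @export
print.ContactRecord <- function(x, ...) {
  cat(sprintf("ContactRecord[%s] %s -- %s\n", x$kind, x$labels[1],
              x$labels[2]))
  invisible(x)
}

# does a specific concrete pair pass its kind's criteria in this frame?
.concrete_pass <- function(frame, topology, criteria, kind, i, j) {
  if (kind == "hbond") {
    d <- .mi_dist_idx(frame, i, j)
    if (d > criteria$hb_heavy_dist_max + .EPS_DIST) return(FALSE)
    if (is_excluded_pair(topology, i, j)) return(FALSE)
    hs <- .bonded_hydrogens(topology, i)
    if (length(hs) == 0) return(FALSE)
    ang <- .mi_angle_idx(frame, rep(i, length(hs)), hs, rep(j, length(hs)))
    any(ang >= criteria$hb_angle_min - .EPS_ANGLE)
  } else if (kind == "nonpolar") {
    at <- topology$atoms
    if (at$residue_number[i + 1L] == at$residue_number[j + 1L] &&
        at$molecule_class[i + 1L] == at$molecule_class[j + 1L])
      return(FALSE)
    if (is_excluded_pair(topology, i, j)) return(FALSE)
    .mi_dist_idx(frame, i, j) <= criteria$np_dist_max + .EPS_DIST
  } else {
    d <- .mi_dist_idx(frame, i, j)
    if (d < criteria$ch_polar_dist_min - .EPS_DIST ||
        d > criteria$ch_polar_dist_max + .EPS_DIST)
      return(FALSE)
    at <- topology$atoms
    wat_o <- at$atom_index[at$molecule_class == "water" &
                             at$element == "O"]
    if (length(wat_o) == 0) return(FALSE)
    di <- .mi_dist_idx(frame, wat_o, rep(i, length(wat_o)))
    dj <- .mi_dist_idx(frame, wat_o, rep(j, length(wat_o)))
    cand <- which(di <= criteria$ch_water_dist_max + .EPS_DIST &
                  dj <= criteria$ch_water_dist_max + .EPS_DIST)
    if (length(cand) == 0) return(FALSE)
    w <- wat_o[cand[which.min(di[cand] + dj[cand])]]
    .ch_partner_pass(frame, topology, criteria, i, w) &&
      .ch_partner_pass(frame, topology, criteria, j, w)
  }
}

#' Resolve a symmetric contact to concrete atoms in one frame
#'
#' Among all alternative atom pairs of the record's two slots, the pair
#' minimising the defining heavy-atom distance is selected (matching the
#' shortest-distance rule used for symmetric hydrogen bonds).  For
#' hydrogen-bonded and water-bridged contacts the frame count is 1 if any
#' alternative passes the criteria; for non-polar contacts it is the number
#' of alternative pairs passing simultaneously, so persistence can exceed 1.
#'
#' @param record a [contact_record()]
#' @param frame a `Frame`
#' @param topology a `Topology`
#' @param criteria a [detection_criteria()] object
#' @return list with `atoms` (the selected concrete pair), `distance`,
#'   `count` (frame count) and `passed`
#' @export
resolve_symmetry <- function(record, frame, topology,
                             criteria = detection_criteria()) {
  alts1 <- record$slots[[1]]; alts2 <- record$slots[[2]]
  ii <- rep(alts1, times = length(alts2))
  jj <- rep(alts2, each = length(alts1))
  keep <- ii != jj
  ii <- ii[keep]; jj <- jj[keep]
  d <- .mi_dist_idx(frame, ii, jj)
  pass <- vapply(seq_along(ii), function(k)
    .concrete_pass(frame, topology, criteria, record$kind, ii[k], jj[k]),
    logical(1))
  count <- if (record$kind == "nonpolar") sum(pass) else as.integer(any(pass))
  best <- which.min(d)
  list(atoms = c(ii[best], jj[best]), distance = d[best],
       count = count, passed = any(pass))
}

# per-frame identity counts for one kind: named integer vector
.frame_contact_counts <- function(frame, topology, criteria, kind,
                                  scope = "protein") {
  det <- switch(kind,
    hbond = detect_hbonds(frame, topology, criteria, scope),
    nonpolar = detect_nonpolar(frame, topology, criteria, scope),
    coophyd = detect_coophyd(frame, topology, criteria, scope))
  if (nrow(det) == 0) return(integer(0))
  a <- if (kind == "hbond") det$donor else det$i
  b <- if (kind == "hbond") det$acceptor else det$j
  ids <- vapply(seq_along(a), function(k)
    contact_record(topology, kind, a[k], b[k])$id, character(1))
  if (kind == "nonpolar") {
    tab <- table(ids)
    out <- as.integer(tab); names(out) <- names(tab)
  } else {
    u <- unique(ids)
    out <- rep(1L, length(u)); names(out) <- u
  }
  out
}

#' Collect contacts over replicate ensembles with persistence
#'
#' Runs the detectors on every frame of every replicate, aggregates frame
#' counts per contact identity, and computes the persistence (mean count
#' per frame, averaged over replicates) with its standard deviation over
#' replicates.  A contact is persistent when the mean is strictly greater
#' than the threshold.
#'
#' @param ensembles a `TrajectoryEnsemble` or list of replicate ensembles
#' @param topology a `Topology` (after [assign_symmetry_groups()])
#' @param criteria a [detection_criteria()] object
#' @param kinds subset of `c("hbond", "nonpolar", "coophyd")`
#' @param scope detector scope, see [detect_hbonds()]
#' @return data frame: `kind`, `id`, `slot1`, `slot2`, `persistence`,
#'   `persistence_std`, `persistent`
#' @export
collect_contacts <- function(ensembles, topology,
                             criteria = detection_criteria(),
                             kinds = c("hbond", "nonpolar", "coophyd"),
                             scope = "protein") {
  if (inherits(ensembles, "TrajectoryEnsemble")) ensembles <- list(ensembles)
  if (length(ensembles) == 0) stop("no ensembles given")
  per_rep <- list()   # replicate -> named vector of per-frame mean counts
  for (r in seq_along(ensembles)) {
    ens <- ensembles[[r]]
    if (n_frames(ens) == 0) stop("replicate ", r, " has no frames")
    acc <- list()
    for (f in ens$frames) {
      for (kind in kinds) {
        cnt <- .frame_contact_counts(f, topology, criteria, kind, scope)
        for (id in names(cnt))
          acc[[id]] <- (if (is.null(acc[[id]])) 0L else acc[[id]]) + cnt[[id]]
      }
    }
    v <- vapply(acc, function(x) x / n_frames(ens), numeric(1))
    per_rep[[r]] <- v
  }
  all_ids <- unique(unlist(lapply(per_rep, names)))
  if (length(all_ids) == 0)
    return(data.frame(kind = character(0), id = character(0),
                      slot1 = character(0), slot2 = character(0),
                      persistence = numeric(0),
                      persistence_std = numeric(0),
                      persistent = logical(0)))
  mat <- sapply(per_rep, function(v) {
    out <- rep(0, length(all_ids)); names(out) <- all_ids
    out[names(v)] <- v
    out
  })
  mat <- matrix(mat, nrow = length(all_ids))
  pers <- rowMeans(mat)
  pstd <- if (ncol(mat) > 1) apply(mat, 1, sd) else rep(0, length(all_ids))
  parts <- strsplit(all_ids, "||", fixed = TRUE)
  out <- data.frame(
    kind = vapply(parts, `[`, "", 1), id = all_ids,
    slot1 = vapply(parts, `[`, "", 2), slot2 = vapply(parts, `[`, "", 3),
    persistence = pers, persistence_std = pstd,
    persistent = pers > criteria$persistence_threshold
  )
  out <- out[order(out$kind, -out$persistence), ]
  rownames(out) <- NULL
  out
}

#' Persistence of one contact across replicate ensembles
#'
#' @param record a [contact_record()]
#' @param ensembles a `TrajectoryEnsemble` or list of replicate ensembles
#' @param topology a `Topology`
#' @param criteria a [detection_criteria()] object
#' @return list with `mean`, `std` (over replicates) and `persistent`
#' @export
persistence <- function(record, ensembles, topology,
                        criteria = detection_criteria()) {
  if (inherits(ensembles, "TrajectoryEnsemble")) ensembles <- list(ensembles)
  if (length(ensembles) == 0) stop("no ensembles given")
  per <- vapply(ensembles, function(ens) {
    if (n_frames(ens) == 0) stop("ensemble with no frames")
    mean(vapply(ens$frames, function(f)
      resolve_symmetry(record, f, topology, criteria)$count, numeric(1)))
  }, numeric(1))
  list(mean = mean(per),
       std = if (length(per) > 1) sd(per) else 0,
       persistent = mean(per) > criteria$persistence_threshold)
}

#' Contact census over native-state replicates
#'
#' "Total" counts contacts observed in at least one frame of any replicate;
#' "persistent" counts those passing the persistence threshold.
#'
#' @inheritParams collect_contacts
#' @return data frame: `kind`, `total`, `persistent`
#' @export
contact_census <- function(ensembles, topology,
                           criteria = detection_criteria(),
                           kinds = c("hbond", "nonpolar", "coophyd"),
                           scope = "protein") {
  cc <- collect_contacts(ensembles, topology, criteria, kinds, scope)
  out <- data.frame(kind = kinds,
                    total = vapply(kinds, function(k)
                      sum(cc$kind == k), integer(1)),
                    persistent = vapply(kinds, function(k)
                      sum(cc$kind == k & cc$persistent), integer(1)))
  rownames(out) <- NULL
  out
}

# ---------------------------------------------------------------------------
# Contact interaction-energy evaluation (shared group-energy kernel)
# ---------------------------------------------------------------------------

# the atom set whose environment energy defines the contact, resolved per
# frame.  hbond: donor + passing H + acceptor + atoms bonded to the
# acceptor.  nonpolar: both heavy atoms + their bonded hydrogens.  coophyd:
# per partner, donor heavy + its hydrogen or acceptor heavy + its bonded
# heavy atom; the bridging water is part of the environment, not the set.
.contact_atom_set <- function(record, frame, topology, criteria) {
  res <- resolve_symmetry(record, frame, topology, criteria)
  i <- res$atoms[1]; j <- res$atoms[2]
  at <- topology$atoms
  if (record$kind == "hbond") {
    hs <- .bonded_hydrogens(topology, i)
    ang <- .mi_angle_idx(frame, rep(i, length(hs)), hs, rep(j, length(hs)))
    h <- hs[which.max(ang)]
    unique(c(i, h, j, topology$adjacency[[j + 1L]]))
  } else if (record$kind == "nonpolar") {
    unique(c(i, .bonded_hydrogens(topology, i),
             j, .bonded_hydrogens(topology, j)))
  } else {
    part <- function(p, other) {
      if (at$is_donor[p + 1L]) {
        hs <- .bonded_hydrogens(topology, p)
        d <- .mi_dist_idx(frame, hs, rep(other, length(hs)))
        c(p, hs[which.min(d)])
      } else {
        bh <- .bonded_heavy(topology, p)
        c(p, if (length(bh) > 0) bh[1] else integer(0))
      }
    }
    unique(c(part(i, j), part(j, i)))
  }
}

#' Interaction energy of a contact in one state
#'
#' Evaluates the half-sum group energy of the contact's atom set (resolved
#' per frame by the shortest-distance symmetry rule) over the frames of
#' each replicate and aggregates over replicates.
#'
#' @param record a [contact_record()]
#' @param ensembles a `TrajectoryEnsemble` or list of replicate ensembles
#' @param topology a `Topology`
#' @param options an [energy_options()] object
#' @param criteria a [detection_criteria()] object
#' @return list with `mean`, `std` (over replicates) and `per_replicate`
#' @export
contact_energy <- function(record, ensembles, topology,
                           options = energy_options(),
                           criteria = detection_criteria()) {
  if (inherits(ensembles, "TrajectoryEnsemble")) ensembles <- list(ensembles)
  per <- vapply(ensembles, function(ens) {
    mean(vapply(ens$frames, function(f) {
      set <- .contact_atom_set(record, f, topology, criteria)
      group_energy(set, f, topology, options)
    }, numeric(1)))
  }, numeric(1))
  list(mean = mean(per),
       std = if (length(per) > 1) sd(per) else 0,
       per_replicate = per)
}
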