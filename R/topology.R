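#' @importFrom stats sd rnorm runif dist
#' @importFrom utils write.table head tail
NULL

# Polarity threshold on |partial charge|, in units of the elementary charge.
# Carbonyl oxygens (q ~ -0.51) must classify as polar, so the absolute value
# is taken.
.POLAR_CHARGE_THRESHOLD <- 0.3

#' Construct a molecular topology
#'
#' A `Topology` holds the per-atom force-field information needed by the
#' energy kernel and the contact detectors: names, residues, molecule class
#' (`protein`, `water` or `ion`), partial charges (e), Lennard-Jones
#' parameters (kcal/mol, Angstrom), the covalent bond list, and derived
#' donor/acceptor/polarity flags.  Non-bonded exclusions (all 1-2, 1-3 and
#' 1-4 pairs) are derived from the bond graph at construction time.
#'
#' Atom indices are 0-based throughout the package; residue numbers are
#' preserved as read (author numbering such as 42-76 is kept verbatim).
#'
#' @param atoms data frame with columns `atom_name`, `residue_name`,
#'   `residue_number`, `molecule_class`, `element`, `partial_charge`,
#'   `lj_epsilon`, `lj_rmin_half` and optionally `is_acceptor` (lone-pair
#'   availability cannot be derived from charges and must be declared).
#' @param bonds two-column integer matrix of 0-based atom indices, one row
#'   per covalent bond.
#' @return object of class `Topology`: the validated atom table (with
#'   derived `is_polar`, `is_donor`, `is_acceptor`, `atom_index` and
#'   `symmetry_group` columns), the bond list, the exclusion pair set and
#'   an (initially empty) symmetry-group map.
#' @export
make_topology <- function(atoms, bonds = matrix(integer(0), ncol = 2)) {
  required <- c("atom_name", "residue_name", "residue_number",
                "molecule_class", "element", "partial_charge",
                "lj_epsilon", "lj_rmin_half")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0)
    stop("topology atom table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  n <- nrow(atoms)
  if (n == 0) stop("topology has no atoms")
  for (col in c("partial_charge", "lj_epsilon", "lj_rmin_half")) {
    bad <- which(!is.finite(atoms[[col]]))
    if (length(bad) > 0)
      stop("missing ", col, " for atom ", bad[1] - 1L,
           " (", atoms$atom_name[bad[1]], " ",
           atoms$residue_name[bad[1]], atoms$residue_number[bad[1]], ")")
  }
  if (any(atoms$lj_epsilon < 0)) stop("negative Lennard-Jones well depth")
  if (!all(atoms$molecule_class %in% c("protein", "water", "ion")))
    stop("molecule_class must be one of protein/water/ion")
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (nrow(bonds) > 0) {
    if (any(bonds < 0 | bonds >= n))
      stop("bond references nonexistent atom index (valid range 0..",
           n - 1L, ")")
    if (any(bonds[, 1] == bonds[, 2])) stop("bond joins an atom to itself")
    # canonical order, deduplicated
    bonds <- unique(cbind(pmin(bonds[, 1], bonds[, 2]),
                          pmax(bonds[, 1], bonds[, 2])))
  }
  atoms$atom_index <- seq_len(n) - 1L

  adj <- .adjacency_list(bonds, n)
  bonded_h <- vapply(seq_len(n), function(i) {
    any(atoms$element[adj[[i]] + 1L] == "H")
  }, logical(1))

  atoms$is_polar <- abs(atoms$partial_charge) >= .POLAR_CHARGE_THRESHOLD
  atoms$is_donor <- atoms$element %in% c("N", "O") & bonded_h
  if (is.null(atoms$is_acceptor)) atoms$is_acceptor <- FALSE
  atoms$is_acceptor <- as.logical(atoms$is_acceptor)
  bad_acc <- which(atoms$is_acceptor & !(atoms$element %in% c("N", "O")))
  if (length(bad_acc) > 0)
    stop("acceptor flag on non-N/O atom ", bad_acc[1] - 1L)
  if (is.null(atoms$symmetry_group)) atoms$symmetry_group <- NA_character_

  topo <- structure(list(
    atoms = atoms,
    bonds = bonds,
    adjacency = adj,
    exclusions = .derive_exclusions(adj, n),
    symmetry_groups = list()
  ), class = "Topology")
  .validate_waters(topo)
  topo
}

.adjacency_list <- function(bonds, n) {
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  if (nrow(bonds) > 0) {
    for (r in seq_len(nrow(bonds))) {
      a <- bonds[r, 1]; b <- bonds[r, 2]
      adj[[a + 1L]] <- c(adj[[a + 1L]], b)
      adj[[b + 1L]] <- c(adj[[b + 1L]], a)
    }
  }
  adj
}

# All 1-2, 1-3 and 1-4 pairs from the bond graph, as a sorted numeric key
# vector (i * n + j with i < j) for O(1)-ish membership tests.
.derive_exclusions <- function(adj, n) {
  keys <- numeric(0)
  for (a in seq_len(n)) {
    a0 <- a - 1L
    n1 <- adj[[a]]                               # 1-2
    n2 <- unique(unlist(lapply(n1 + 1L, function(i) adj[[i]])))  # 1-3
    n3 <- unique(unlist(lapply(n2 + 1L, function(i) adj[[i]])))  # 1-4
    part <- unique(c(n1, n2, n3))
    part <- part[part != a0]
    if (length(part) > 0) {
      i <- pmin(a0, part); j <- pmax(a0, part)
      keys <- c(keys, i * n + j)
    }
  }
  sort(unique(keys))
}

.pair_keys <- function(i, j, n) {
  pmin(i, j) * n + pmax(i, j)
}

#' Test whether atom pairs are non-bonded exclusions
#'
#' @param topology a `Topology`
#' @param i,j 0-based atom index vectors (recycled)
#' @return logical vector, `TRUE` where the pair is a 1-2, 1-3 or 1-4 pair
#' @export
is_excluded_pair <- function(topology, i, j) {
  n <- nrow(topology$atoms)
  .pair_keys(i, j, n) %in% topology$exclusions
}

.validate_waters <- function(topo) {
  at <- topo$atoms
  w <- at[at$molecule_class == "water", ]
  if (nrow(w) == 0) return(invisible(TRUE))
  for (res in unique(w$residue_number)) {
    el <- w$element[w$residue_number == res]
    if (sum(el == "O") != 1 || sum(el == "H") != 2)
      stop("water residue ", res, " must have 1 oxygen and 2 hydrogens")
  }
  invisible(TRUE)
}

#' @export
print.Topology <- function(x, ...) {
  at <- x$atoms
  cat("Topology:", nrow(at), "atoms,", nrow(x$bonds), "bonds,",
      length(x$exclusions), "excluded pairs\n")
  cat("  classes:", paste(sprintf("%s=%d", names(table(at$molecule_class)),
                                  table(at$molecule_class)), collapse = " "),
      "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Tabular topology format (canonical plain-text input)
#
# Tab-separated, one atom per line, '#' comments allowed.  Columns:
#   name residue resid class element charge epsilon rmin_half acceptor bonds
# 'bonds' is a comma-separated list of 0-based partner indices ('-' if none);
# each bond may be listed on either endpoint.
# ---------------------------------------------------------------------------

#' Read a topology file
#'
#' The canonical input is a documented tab-separated table (see
#' [write_topology()] for the column layout).  A minimal PSF-style reader is
#' provided as a convenience; since PSF files carry no Lennard-Jones
#' parameters, those must be supplied via `lj_params` keyed by atom type.
#'
#' @param path file path
#' @param format `"tabular"` (default) or `"psf-like"`
#' @param lj_params for `"psf-like"` only: data frame with columns `type`,
#'   `epsilon`, `rmin_half`
#' @return a [make_topology()] `Topology`
#' @export
read_topology <- function(path, format = c("tabular", "psf-like"),
                          lj_params = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("topology file not found: ", path)
  if (format == "tabular") .read_topology_tabular(path)
  else .read_topology_psf(path, lj_params)
}

.read_topology_tabular <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  body <- lines[keep]
  lineno <- which(keep)
  if (length(body) == 0) stop("empty topology file: ", path)
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  expected <- c("name", "residue", "resid", "class", "element", "charge",
                "epsilon", "rmin_half", "acceptor", "bonds")
  if (!identical(header, expected))
    stop("malformed topology header at line ", lineno[1],
         ": expected columns ", paste(expected, collapse = " "))
  rows <- lapply(seq_along(body[-1]) + 1L, function(k) {
    f <- strsplit(body[k], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(expected))
      stop("malformed topology line ", lineno[k], " in ", path,
           " (expected ", length(expected), " fields, got ", length(f), ")")
    f
  })
  m <- do.call(rbind, rows)
  charge <- suppressWarnings(as.numeric(m[, 6]))
  eps    <- suppressWarnings(as.numeric(m[, 7]))
  rmh    <- suppressWarnings(as.numeric(m[, 8]))
  for (k in which(!is.finite(charge) | !is.finite(eps) | !is.finite(rmh))) {
    stop("missing or non-numeric parameter for atom ", m[k, 1], " ",
         m[k, 2], m[k, 3], " at line ", lineno[k + 1L])
  }
  atoms <- data.frame(
    atom_name = m[, 1], residue_name = m[, 2],
    residue_number = as.integer(m[, 3]), molecule_class = m[, 4],
    element = m[, 5], partial_charge = charge,
    lj_epsilon = eps, lj_rmin_half = rmh,
    is_acceptor = m[, 9] %in% c("1", "TRUE", "true"),
    stringsAsFactors = FALSE
  )
  bond_rows <- list()
  for (k in seq_len(nrow(m))) {
    b <- m[k, 10]
    if (b != "-" && nzchar(b)) {
      partners <- as.integer(strsplit(b, ",", fixed = TRUE)[[1]])
      bond_rows[[length(bond_rows) + 1L]] <-
        cbind(rep(k - 1L, length(partners)), partners)
    }
  }
  bonds <- if (length(bond_rows) > 0) do.call(rbind, bond_rows)
           else matrix(integer(0), ncol = 2)
  make_topology(atoms, bonds)
}

.read_topology_psf <- function(path, lj_params) {
  if (is.null(lj_params))
    stop("psf-like input needs lj_params (type, epsilon, rmin_half): ",
         "PSF files carry no Lennard-Jones parameters")
  lines <- readLines(path)
  natom_at <- grep("!NATOM", lines)
  nbond_at <- grep("!NBOND", lines)
  if (length(natom_at) != 1) stop("no !NATOM section in ", path)
  natom <- as.integer(strsplit(trimws(lines[natom_at]), "\\s+")[[1]][1])
  rec <- lines[(natom_at + 1):(natom_at + natom)]
  f <- strsplit(trimws(rec), "\\s+")
  type <- vapply(f, `[`, "", 6)
  idx <- match(type, lj_params$type)
  if (anyNA(idx))
    stop("no Lennard-Jones parameters for atom type(s): ",
         paste(unique(type[is.na(idx)]), collapse = ", "))
  segid <- vapply(f, `[`, "", 2)
  atoms <- data.frame(
    atom_name = vapply(f, `[`, "", 5),
    residue_name = vapply(f, `[`, "", 4),
    residue_number = as.integer(vapply(f, `[`, "", 3)),
    molecule_class = ifelse(grepl("^W", segid), "water",
                     ifelse(grepl("^ION", segid), "ion", "protein")),
    element = substr(vapply(f, `[`, "", 5), 1, 1),
    partial_charge = as.numeric(vapply(f, `[`, "", 7)),
    lj_epsilon = lj_params$epsilon[idx],
    lj_rmin_half = lj_params$rmin_half[idx],
    stringsAsFactors = FALSE
  )
  bonds <- matrix(integer(0), ncol = 2)
  if (length(nbond_at) == 1) {
    nb <- as.integer(strsplit(trimws(lines[nbond_at]), "\\s+")[[1]][1])
    vals <- integer(0)
    k <- nbond_at + 1
    while (length(vals) < 2 * nb) {
      vals <- c(vals, as.integer(strsplit(trimws(lines[k]), "\\s+")[[1]]))
      k <- k + 1
    }
    bonds <- matrix(vals[seq_len(2 * nb)], ncol = 2, byrow = TRUE) - 1L
  }
  make_topology(atoms, bonds)
}

#' Write a topology in the package's tabular format
#'
#' @param topology a `Topology`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_topology <- function(topology, path) {
  at <- topology$atoms
  n <- nrow(at)
  partners <- vector("character", n)
  for (k in seq_len(n)) partners[k] <- "-"
  if (nrow(topology$bonds) > 0) {
    for (r in seq_len(nrow(topology$bonds))) {
      a <- topology$bonds[r, 1] + 1L
      partners[a] <- if (partners[a] == "-")
        as.character(topology$bonds[r, 2])
      else paste(partners[a], topology$bonds[r, 2], sep = ",")
    }
  }
  hdr <- paste(c("name", "residue", "resid", "class", "element", "charge",
                 "epsilon", "rmin_half", "acceptor", "bonds"),
               collapse = "\t")
  body <- sprintf("%s\t%s\t%d\t%s\t%s\t%.6g\t%.6g\t%.6g\t%d\t%s",
                  at$atom_name, at$residue_name, at$residue_number,
                  at$molecule_class, at$element, at$partial_charge,
                  at$lj_epsilon, at$lj_rmin_half,
                  as.integer(at$is_acceptor), partners)
  writeLines(c("# coophyd topology v1", hdr, body), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Symmetry groups
# ---------------------------------------------------------------------------

# Exchangeable atom-name sets for CHARMM residue naming.  Atoms exchangeable
# by a torsion rotation or ring flip are chemically indistinguishable, so a
# contact made by either member is the same contact.
.SYMMETRY_TEMPLATES <- list(
  ASP = list(c("OD1", "OD2")),
  GLU = list(c("OE1", "OE2")),
  ARG = list(c("NH1", "NH2"), c("HH11", "HH12", "HH21", "HH22")),
  LYS = list(c("HZ1", "HZ2", "HZ3")),
  PHE = list(c("CD1", "CD2"), c("CE1", "CE2")),
  TYR = list(c("CD1", "CD2"), c("CE1", "CE2")),
  LEU = list(c("CD1", "CD2")),
  VAL = list(c("CG1", "CG2"))
)

#' Assign molecular-symmetry groups from built-in residue templates
#'
#' Applies the standard exchangeable-atom templates (carboxylate OD1/OD2 and
#' OE1/OE2, guanidinium NH1/NH2 and its hydrogens, ammonium HZ1/HZ2/HZ3,
#' aromatic ring CD/CE pairs, isopropyl CD/CG pairs, C-terminal OT1/OT2,
#' water H1/H2).  Atoms without a template keep no group.  An atom belongs
#' to at most one group.
#'
#' @param topology a `Topology`
#' @return the topology with `symmetry_group` labels filled in and a
#'   `symmetry_groups` map (group id to 0-based member indices)
#' @export
assign_symmetry_groups <- function(topology) {
  at <- topology$atoms
  at$symmetry_group <- NA_character_
  groups <- list()
  add_group <- function(members_idx, resname, resid, names_set) {
    gid <- sprintf("%s%d:%s", resname, resid, paste(names_set, collapse = "/"))
    groups[[gid]] <<- members_idx
    at$symmetry_group[members_idx + 1L] <<- gid
  }
  res_key <- paste(at$molecule_class, at$residue_number)
  for (rk in unique(res_key)) {
    sel <- which(res_key == rk)
    resname <- at$residue_name[sel[1]]
    resid <- at$residue_number[sel[1]]
    if (at$molecule_class[sel[1]] == "water") {
      h <- sel[at$atom_name[sel] %in% c("H1", "H2")]
      if (length(h) == 2)
        add_group(at$atom_index[h], resname, resid, c("H1", "H2"))
      next
    }
    tmpl <- .SYMMETRY_TEMPLATES[[resname]]
    if (!is.null(tmpl)) {
      for (names_set in tmpl) {
        m <- sel[at$atom_name[sel] %in% names_set]
        if (length(m) == length(names_set))
          add_group(at$atom_index[m], resname, resid, names_set)
      }
    }
    # C-terminal carboxylate on any residue
    m <- sel[at$atom_name[sel] %in% c("OT1", "OT2")]
    if (length(m) == 2)
      add_group(at$atom_index[m], resname, resid, c("OT1", "OT2"))
  }
  topology$atoms <- at
  topology$symmetry_groups <- groups
  topology
}

#' Symmetry-equivalent alternatives of an atom
#'
#' @param topology a `Topology` (after [assign_symmetry_groups()])
#' @param i 0-based atom index
#' @return integer vector of 0-based indices (the atom itself if ungrouped)
#' @export
symmetry_alternatives <- function(topology, i) {
  g <- topology$atoms$symmetry_group[i + 1L]
  if (is.na(g)) return(i)
  sort(topology$symmetry_groups[[g]])
}

# Canonical display label of the slot containing atom i, e.g. "ASP44 OD1/OD2"
.slot_label <- function(topology, i) {
  at <- topology$atoms
  alts <- symmetry_alternatives(topology, i)
  nm <- sort(at$atom_name[alts + 1L])
  sprintf("%s%d %s", at$residue_name[i + 1L], at$residue_number[i + 1L],
          paste(nm, collapse = "/"))
}
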