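# Per-treatment orchestration: detect persistent contacts on the native
# replicates, evaluate the same atom sets in both states, run the
# hydration-site analysis on fixed-solute ensembles, and aggregate into
# report tables with footer means.

#' Mean and sample standard deviation over replicates
#'
#' @param values numeric vector of per-replicate values (non-empty)
#' @return list with `mean` and `std` (`NA` for a single value)
#' @export
aggregate_replicates <- function(values) {
  if (length(values) == 0) stop("no replicate values to aggregate")
  list(mean = mean(values),
       std = if (length(values) > 1) sd(values) else NA_real_)
}

#' Temperature-correct a folding enthalpy with a constant heat capacity
#'
#' `dH(T_target) = dH(Tm) + Cp * (Tm - T_target)`.  With the folding
#' convention (folded minus unfolded, dH < 0) and a positive folding heat
#' capacity decrement this makes folding less exothermic at lower
#' temperature, e.g. -31 kcal/mol at 74.4 C maps to about -12.5 kcal/mol
#' at 25 C with Cp = 0.374 kcal/mol/K.
#'
#' @param dH_at_Tm folding enthalpy at the melting temperature (kcal/mol)
#' @param Tm melting temperature (degrees C)
#' @param Cp heat capacity change (kcal/mol/K), non-negative
#' @param T_target target temperature (degrees C)
#' @return corrected enthalpy (kcal/mol)
#' @export
temperature_correct_enthalpy <- function(dH_at_Tm, Tm, Cp, T_target) {
  if (Cp < 0) stop("heat capacity change must be non-negative")
  dH_at_Tm + Cp * (Tm - T_target)
}

#' Build a report table with a footer of column means
#'
#' @param rows data frame of per-contact (or per-component) rows
#' @param value_cols names of the numeric columns the footer averages
#' @return the data frame with class `coophyd_report` and a `footer`
#'   attribute (named vector of column means)
#' @export
report_table <- function(rows, value_cols) {
  footer <- vapply(value_cols, function(cn) mean(rows[[cn]]), numeric(1))
  structure(rows, footer = footer, value_cols = value_cols,
            class = c("coophyd_report", class(rows)))
}

#' Footer (column means) of a report table
#' @param x a [report_table()]
#' @return named numeric vector
#' @export
report_footer <- function(x) attr(x, "footer")

#' @export
print.coophyd_report <- function(x, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, 2)
  print(df, row.names = FALSE)
  f <- attr(x, "footer")
  cat("Mean:", paste(sprintf("%s=%.1f", names(f), f), collapse = "  "),
      "\n")
  invisible(x)
}

#' Write a report table as TSV (energies to 1 decimal, footer row "Mean")
#'
#' @param x a [report_table()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_report_tsv <- function(x, path) {
  df <- as.data.frame(x)
  vc <- attr(x, "value_cols")
  out <- df
  for (cn in vc) out[[cn]] <- sprintf("%.1f", df[[cn]])
  f <- attr(x, "footer")
  footer <- as.list(rep("", ncol(out)))
  names(footer) <- names(out)
  footer[[1]] <- "Mean"
  for (cn in vc) footer[[cn]] <- sprintf("%.1f", f[[cn]])
  out <- rbind(out, as.data.frame(footer, stringsAsFactors = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a report bundle as JSON (full precision)
#'
#' @param tables named list of data frames / report tables
#' @param path output path
#' @param meta optional metadata list (config echo, seeds)
#' @return `path`, invisibly
#' @export
write_report_json <- function(tables, path, meta = list()) {
  payload <- c(list(metadata = meta),
               lapply(tables, function(t) as.data.frame(t)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Assemble a treatment configuration
#'
#' @param forcefield_label free-text label, e.g. `"CHARMM22"`
#' @param water_model water model name; must match the bulk reference
#' @param nacl_mM salt concentration (mM)
#' @param bulk a [bulk_reference()] (defaults to the bundled value for the
#'   model/salt combination)
#' @param criteria a [detection_criteria()]
#' @param options an [energy_options()]
#' @param estimator an [estimator_config()]
#' @param kinds contact kinds to analyse
#' @return object of class `TreatmentConfig`
#' @export
treatment_config <- function(forcefield_label = "CHARMM22",
                             water_model = "TIP3P", nacl_mM = 0,
                             bulk = NULL,
                             criteria = detection_criteria(),
                             options = energy_options(),
                             estimator = estimator_config(),
                             kinds = c("hbond", "nonpolar", "coophyd")) {
  if (is.null(bulk)) bulk <- get_bulk_reference(water_model, nacl_mM)
  if (bulk$water_model != water_model)
    stop("bulk reference water model (", bulk$water_model,
         ") does not match treatment water model (", water_model, ")")
  structure(list(forcefield_label = forcefield_label,
                 water_model = water_model, nacl_mM = nacl_mM,
                 bulk = bulk, criteria = criteria, options = options,
                 estimator = estimator, kinds = kinds),
            class = "TreatmentConfig")
}

#' Run a full per-treatment analysis
#'
#' Persistent contacts are identified on the native-state replicates only,
#' then the same atom sets are evaluated in both states; the state energy
#' difference, atom-energy partition and contact census are computed, and
#' (when a fixed-solute ensemble is supplied) hydration sites are analysed
#' by IFST.  All outputs are deterministic functions of the inputs.
#'
#' @param config a [treatment_config()]
#' @param topology shared `Topology` (with symmetry groups assigned)
#' @param native,extended lists of replicate `TrajectoryEnsemble`s (a bare
#'   ensemble is treated as one replicate)
#' @param fixed_native optional fixed-solute ensemble for the
#'   hydration-site analysis
#' @param protein_atoms 0-based protein heavy-atom indices for the
#'   hydration-site surface filter (default: all protein atoms)
#' @param out_dir optional directory; when given, every table is written
#'   as TSV plus a JSON bundle with provenance metadata
#' @return list of tables: `contacts` (one [report_table()] per kind),
#'   `census`, `state_energy`, `atom_partition`, `sites` (or `NULL`)
#' @export
run_treatment <- function(config, topology, native, extended,
                          fixed_native = NULL, protein_atoms = NULL,
                          out_dir = NULL) {
  if (inherits(native, "TrajectoryEnsemble")) native <- list(native)
  if (inherits(extended, "TrajectoryEnsemble")) extended <- list(extended)
  if (length(native) == 0) stop("missing native state ensembles")
  if (length(extended) == 0) stop("missing extended state ensembles")

  found <- collect_contacts(native, topology, config$criteria,
                            config$kinds)
  pers <- found[found$persistent, , drop = FALSE]

  contact_tables <- list()
  for (kind in config$kinds) {
    sel <- pers[pers$kind == kind, , drop = FALSE]
    if (nrow(sel) == 0) {
      contact_tables[[kind]] <- report_table(
        data.frame(slot1 = character(0), slot2 = character(0),
                   persistence = numeric(0), persistence_std = numeric(0),
                   E_native = numeric(0), E_native_std = numeric(0),
                   E_extended = numeric(0), E_extended_std = numeric(0),
                   delta_E = numeric(0)),
        c("E_native", "E_extended", "delta_E"))
      next
    }
    rows <- lapply(seq_len(nrow(sel)), function(r) {
      rec <- .record_from_id(topology, sel$id[r])
      en <- contact_energy(rec, native, topology, config$options,
                           config$criteria)
      ee <- contact_energy(rec, extended, topology, config$options,
                           config$criteria)
      data.frame(slot1 = sel$slot1[r], slot2 = sel$slot2[r],
                 persistence = sel$persistence[r],
                 persistence_std = sel$persistence_std[r],
                 E_native = en$mean, E_native_std = en$std,
                 E_extended = ee$mean, E_extended_std = ee$std,
                 delta_E = en$mean - ee$mean)
    })
    contact_tables[[kind]] <- report_table(
      do.call(rbind, rows), c("E_native", "E_extended", "delta_E"))
  }

  census <- contact_census(native, topology, config$criteria, config$kinds)

  se <- state_energy_difference(extended, native, topology, config$options)
  state_energy <- data.frame(
    comparison = "extended - native",
    delta_E = if (is.list(se)) se$delta else se,
    std = if (is.list(se)) se$std else NA_real_)

  ap <- atom_energy_table(native[[1]], extended[[1]], topology,
                          config$options)
  atom_partition <- data.frame(
    set = c("all", "polar", "nonpolar"),
    delta_E = as.numeric(ap$sums[c("total", "polar", "nonpolar")]))

  sites <- NULL
  if (!is.null(fixed_native)) {
    if (is.null(protein_atoms)) {
      at <- topology$atoms
      protein_atoms <- at$atom_index[at$molecule_class == "protein"]
    }
    sites <- hydration_site_analysis(fixed_native, topology,
                                     protein_atoms,
                                     options = config$options,
                                     bulk = config$bulk,
                                     config = config$estimator)
  }

  out <- list(contacts = contact_tables, census = census,
              state_energy = state_energy,
              atom_partition = atom_partition, sites = sites)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (kind in names(contact_tables))
      write_report_tsv(contact_tables[[kind]],
                       file.path(out_dir, paste0("contacts_", kind,
                                                 ".tsv")))
    utils::write.table(census, file.path(out_dir, "census.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(state_energy,
                       file.path(out_dir, "state_energy.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(atom_partition,
                       file.path(out_dir, "atom_partition.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(sites))
      utils::write.table(sites, file.path(out_dir, "sites.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    meta <- list(forcefield = config$forcefield_label,
                 water_model = config$water_model,
                 nacl_mM = config$nacl_mM,
                 elec_scheme = config$options$elec_scheme,
                 n_native_replicates = length(native),
                 n_extended_replicates = length(extended))
    tables <- c(lapply(contact_tables, as.data.frame),
                list(census = census, state_energy = state_energy,
                     atom_partition = atom_partition))
    if (!is.null(sites)) tables$sites <- sites
    write_report_json(tables, file.path(out_dir, "report.json"), meta)
  }
  out
}

# rebuild a ContactRecord from its identity string by locating one concrete
# atom per slot label
.record_from_id <- function(topology, id) {
  parts <- strsplit(id, "||", fixed = TRUE)[[1]]
  kind <- parts[1]
  find_atom <- function(label) {
    sp <- strsplit(label, " ", fixed = TRUE)[[1]]
    resspec <- sp[1]; names_set <- strsplit(sp[2], "/", fixed = TRUE)[[1]]
    at <- topology$atoms
    m <- regmatches(resspec, regexec("^([A-Za-z0-9]+?)(-?[0-9]+)$",
                                     resspec))[[1]]
    resname <- m[2]; resid <- as.integer(m[3])
    idx <- at$atom_index[at$residue_name == resname &
                           at$residue_number == resid &
                           at$atom_name %in% names_set]
    if (length(idx) == 0) stop("no atoms matching slot ", label)
    idx[1]
  }
  contact_record(topology, kind, find_atom(parts[2]), find_atom(parts[3]))
}

# ---------------------------------------------------------------------------
# Bundled villin headpiece reference tables
# ---------------------------------------------------------------------------

#' Bundled villin headpiece reference tables
#'
#' Curated per-contact and per-state reference values for the villin
#' headpiece subdomain (N68H, PDB 1YRF): state energy components, the
#' atom-energy partition, the fifteen most persistent hydrogen-bonded,
#' non-polar and water-bridged contacts of the CHARMM22/TIP3P/NaCl
#' treatment, the contact census, hydration-site summaries, bridged-site
#' free energies around GLU45/LYS48, and folding calorimetry.  These serve
#' as aggregation inputs and worked examples; regenerating their absolute
#' magnitudes would require the original long trajectories.
#'
#' @param name one of `"state_energy_components"`, `"atom_partition"`,
#'   `"hbond_contacts"`, `"nonpolar_contacts"`, `"coophyd_contacts"`,
#'   `"contact_census"`, `"hydration_sites"`, `"bridge_site_free_energy"`,
#'   `"folding_calorimetry"`
#' @return data frame
#' @export
villin_reference <- function(name = c("state_energy_components",
                                      "atom_partition", "hbond_contacts",
                                      "nonpolar_contacts",
                                      "coophyd_contacts", "contact_census",
                                      "hydration_sites",
                                      "bridge_site_free_energy",
                                      "folding_calorimetry")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("villin_", name, ".tsv"),
                      package = "coophyd", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
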