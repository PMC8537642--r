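# The 248-column feature schema and its blocks: 52 contact features, 20
# Rosetta InterfaceAnalyzer energy terms, 44 FoldX AnalyseComplex energy
# terms, and 132 interface-property features (66 descriptor sums for the
# paratope and 66 for the epitope).  Energy values come from externally run
# programs and are ingested by name; an absent term is an explicit missing
# value (NA), never a silent zero, so that the tree learner can exploit its
# native missing-value handling.

#' Canonical Rosetta InterfaceAnalyzer energy columns (20)
#'
#' The fixed set of InterfaceAnalyzer score-file columns mapped into the
#' energy block, including the interface energy density
#' `dG_cross/dSASAx100`.
#'
#' @return Character vector of length 20.
#' @export
rosetta_energy_names <- function() {
  c("dG_cross", "dG_cross/dSASAx100", "dG_separated", "dG_separated/dSASAx100",
    "dSASA_hphobic", "dSASA_int", "dSASA_polar", "delta_unsatHbonds",
    "hbond_E_fraction", "hbonds_int", "nres_all", "nres_int", "packstat",
    "per_residue_energy_int", "sc_value", "side1_normalized", "side1_score",
    "side2_normalized", "side2_score", "complex_normalized")
}

#' Canonical FoldX AnalyseComplex energy columns (44)
#'
#' The interaction-energy decomposition between the two chain groups plus the
#' per-group (paratope-side / epitope-side) terms, normalised to lower-case
#' underscore names.
#'
#' @return Character vector of length 44.
#' @export
foldx_energy_names <- function() {
  pair <- c("interaction_energy", "intraclashes_group1", "intraclashes_group2",
            "stability_group1", "stability_group2",
            "backbone_hbond", "sidechain_hbond", "van_der_waals",
            "electrostatics", "solvation_polar", "solvation_hydrophobic",
            "van_der_waals_clashes", "entropy_sidechain", "entropy_mainchain",
            "sloop_entropy", "mloop_entropy", "cis_bond", "torsional_clash",
            "backbone_clash", "helix_dipole", "water_bridge", "disulfide",
            "electrostatic_kon", "partial_covalent_bonds", "energy_ionisation",
            "entropy_complex", "number_of_residues", "interface_residues",
            "interface_residues_clashing", "interface_residues_vdw_clashing",
            "interface_residues_bb_clashing")
  per_group <- c("total_energy_group1", "total_energy_group2",
                 "backbone_hbond_group1", "backbone_hbond_group2",
                 "sidechain_hbond_group1", "sidechain_hbond_group2",
                 "van_der_waals_group1", "van_der_waals_group2",
                 "electrostatics_group1", "electrostatics_group2",
                 "solvation_polar_group1", "solvation_polar_group2",
                 "solvation_hydrophobic_group1")
  c(pair, per_group)
}

SCHEMA_BLOCKS <- c("contact", "rosetta", "foldx", "property")

#' Feature schema
#'
#' Ordered, named column layout of the feature vector.  The full schema has
#' exactly 248 columns: 52 contact + 20 Rosetta + 44 FoldX + 132 property
#' (66 descriptors x paratope/epitope), in that block order.  Blocks can be
#' disabled (e.g. `c("contact", "property")` for poses without external
#' energy runs).
#'
#' @param blocks Character vector of enabled blocks, a subset of
#'   `c("contact", "rosetta", "foldx", "property")` (default all).
#' @return A `feature_schema`: list with `columns` (ordered names), `block`
#'   (block tag per column) and `blocks` (enabled set).
#' @export
feature_schema <- function(blocks = SCHEMA_BLOCKS) {
  blocks <- match.arg(blocks, SCHEMA_BLOCKS, several.ok = TRUE)
  blocks <- SCHEMA_BLOCKS[SCHEMA_BLOCKS %in% blocks]  # canonical order
  desc <- colnames(aa_descriptor_table())
  parts <- list(
    contact = contact_feature_names(),
    rosetta = paste0("rosetta_", rosetta_energy_names()),
    foldx = paste0("foldx_", foldx_energy_names()),
    property = c(paste0("para_", desc), paste0("epi_", desc))
  )
  stopifnot(lengths(parts) == c(52L, 20L, 44L, 132L),
            sum(lengths(parts)) == 248L)
  columns <- unlist(parts[blocks], use.names = FALSE)
  stopifnot(!anyDuplicated(columns))
  structure(list(
    columns = columns,
    block = rep(blocks, lengths(parts[blocks])),
    blocks = blocks
  ), class = "feature_schema")
}

#' @export
print.feature_schema <- function(x, ...) {
  tab <- table(factor(x$block, levels = x$blocks))
  cat(sprintf("feature_schema: %d columns (%s)\n", length(x$columns),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Parse a Rosetta InterfaceAnalyzer score file
#'
#' Whitespace-delimited score file with a header line (an optional leading
#' `SCORE:` token is stripped).  Canonical columns (see
#' [rosetta_energy_names()]) are mapped by name; unknown columns are ignored
#' and absent canonical columns are returned as `NA` (explicitly missing).
#'
#' @param path Score file path.
#' @param which Data row to use when the file scores several poses
#'   (default 1).
#' @return Named numeric vector over [rosetta_energy_names()], `NA` where
#'   absent.
#' @export
parse_rosetta_scores <- function(path, which = 1L) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("^SCORE:\\s*", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^SEQUENCE:", lines)]
  if (length(lines) < 2L) {
    abort("score file needs a header line and at least one data row",
          "nbrank_parse_error")
  }
  toks <- strsplit(lines, "\\s+")
  header <- toks[[1]]
  if (length(toks) < which + 1L) {
    abort("requested data row not present in score file", "nbrank_parse_error")
  }
  row <- toks[[which + 1L]]
  vals <- suppressWarnings(as.numeric(row[seq_along(header)]))
  names(vals) <- header
  out <- vals[rosetta_energy_names()]
  names(out) <- rosetta_energy_names()
  out
}

normalize_colname <- function(x) {
  x <- gsub("([a-z0-9])([A-Z])", "\\1_\\2", x)  # split camelCase
  x <- tolower(x)
  x <- gsub("[^a-z0-9]+", "_", x)
  gsub("^_+|_+$", "", x)
}

#' Parse a FoldX AnalyseComplex output table
#'
#' Tab-delimited `.fxout`-style table; banner lines before the header (the
#' line starting with `Pdb`) are skipped.  Columns are matched against
#' [foldx_energy_names()] after normalisation (lower-case, non-alphanumerics
#' collapsed to `_`), so e.g. `"Interaction Energy"` maps to
#' `interaction_energy`.  Absent canonical columns are `NA`.
#'
#' @param path FoldX output file path.
#' @param which Data row to use (default 1).
#' @return Named numeric vector over [foldx_energy_names()], `NA` where
#'   absent.
#' @export
parse_foldx_complex <- function(path, which = 1L) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr_idx <- grep("^Pdb\\t", lines)
  if (length(hdr_idx) == 0L) {
    hdr_idx <- which(grepl("\t", lines))[1]
  } else {
    hdr_idx <- hdr_idx[1]
  }
  if (is.na(hdr_idx) || length(lines) < hdr_idx + 1L) {
    abort("no tab-delimited header/data rows found", "nbrank_parse_error")
  }
  header <- normalize_colname(strsplit(lines[hdr_idx], "\t", fixed = TRUE)[[1]])
  data_lines <- lines[-seq_len(hdr_idx)]
  if (length(data_lines) < which) {
    abort("requested data row not present", "nbrank_parse_error")
  }
  row <- strsplit(data_lines[which], "\t", fixed = TRUE)[[1]]
  vals <- suppressWarnings(as.numeric(row[seq_along(header)]))
  names(vals) <- header
  out <- vals[foldx_energy_names()]
  names(out) <- foldx_energy_names()
  out
}

#' Assemble one feature vector against a schema
#'
#' Concatenates the enabled blocks in fixed order
#' contact | rosetta | foldx | property.  Energy vectors may be `NULL`
#' (block entirely missing -> all `NA`) or carry `NA` entries; missingness is
#' preserved.
#'
#' @param contact Named 52-vector from [contact_features()] (required when
#'   the contact block is enabled).
#' @param rosetta,foldx Named energy vectors from the parsers, or `NULL`.
#' @param props_paratope,props_epitope Named 66-vectors from
#'   [property_profile()] (required when the property block is enabled).
#' @param schema A [feature_schema()].
#' @return Named numeric vector with exactly `length(schema$columns)`
#'   entries.
#' @export
assemble_features <- function(contact = NULL, rosetta = NULL, foldx = NULL,
                              props_paratope = NULL, props_epitope = NULL,
                              schema = feature_schema()) {
  take <- function(x, expected_names, prefix) {
    if (is.null(x)) {
      out <- rep(NA_real_, length(expected_names))
    } else {
      if (!identical(names(x), expected_names)) {
        abort(sprintf("%s block does not conform to the schema", prefix),
              "nbrank_schema_error")
      }
      out <- as.numeric(x)
    }
    names(out) <- paste0(if (prefix %in% c("rosetta", "foldx")) paste0(prefix, "_") else "",
                         expected_names)
    out
  }
  pieces <- list()
  if ("contact" %in% schema$blocks) {
    if (is.null(contact)) abort("contact block required", "nbrank_schema_error")
    pieces$contact <- take(contact, contact_feature_names(), "contact")
  }
  if ("rosetta" %in% schema$blocks) {
    pieces$rosetta <- take(rosetta, rosetta_energy_names(), "rosetta")
  }
  if ("foldx" %in% schema$blocks) {
    pieces$foldx <- take(foldx, foldx_energy_names(), "foldx")
  }
  if ("property" %in% schema$blocks) {
    if (is.null(props_paratope) || is.null(props_epitope)) {
      abort("property block required", "nbrank_schema_error")
    }
    desc <- colnames(aa_descriptor_table())
    pp <- take(props_paratope, desc, "property")
    pe <- take(props_epitope, desc, "property")
    names(pp) <- paste0("para_", desc)
    names(pe) <- paste0("epi_", desc)
    pieces$property <- c(pp, pe)
  }
  out <- unlist(pieces, use.names = TRUE)
  names(out) <- sub("^(contact|rosetta|foldx|property)\\.", "", names(out))
  if (!identical(names(out), schema$columns)) {
    abort("assembled vector does not match schema column order",
          "nbrank_schema_error")
  }
  out
}

#' Bundle records into a pose dataset
#'
#' @param meta Data frame with columns `complex_id`, `docking_mode`,
#'   `parent_id`, `refined_id`, `dockq`, `label` (and optionally
#'   `parent_dockq`, `parent_label`); one row per refined pose.
#' @param X Numeric feature matrix, rows aligned with `meta`, columns equal
#'   to `schema$columns`.
#' @param schema The [feature_schema()] the matrix conforms to.
#' @return A `pose_dataset` object.
#' @export
pose_dataset <- function(meta, X, schema) {
  need <- c("complex_id", "docking_mode", "parent_id", "refined_id", "dockq", "label")
  if (!all(need %in% names(meta))) {
    abort(sprintf("meta must have columns: %s", paste(need, collapse = ", ")),
          "nbrank_invalid_argument")
  }
  X <- as.matrix(X)
  if (nrow(X) != nrow(meta) || !identical(colnames(X), schema$columns)) {
    abort("feature matrix does not conform to the schema", "nbrank_schema_error")
  }
  ids <- paste(meta$complex_id, meta$parent_id, meta$refined_id, sep = "/")
  if (anyDuplicated(ids)) {
    abort("(complex_id, parent_id, refined_id) must be unique",
          "nbrank_invalid_argument")
  }
  structure(list(meta = meta, X = X, schema = schema), class = "pose_dataset")
}

#' @export
print.pose_dataset <- function(x, ...) {
  cat(sprintf("pose_dataset: %d refined poses, %d complexes, %d features (%d native-like)\n",
              nrow(x$meta), length(unique(x$meta$complex_id)),
              ncol(x$X), sum(x$meta$label == 1)))
  invisible(x)
}

#' Write a pose dataset as CSV + JSON schema sidecar
#'
#' @param ds A `pose_dataset`.
#' @param prefix Output path prefix; writes `<prefix>_features.csv` (meta +
#'   feature columns) and `<prefix>_schema.json`.
#' @return Invisibly, the two paths.
#' @export
write_pose_dataset <- function(ds, prefix) {
  fcsv <- paste0(prefix, "_features.csv")
  fjson <- paste0(prefix, "_schema.json")
  utils::write.csv(cbind(ds$meta, as.data.frame(ds$X, check.names = FALSE)),
                   fcsv, row.names = FALSE)
  jsonlite::write_json(
    list(columns = ds$schema$columns, block = ds$schema$block,
         blocks = ds$schema$blocks),
    fjson, auto_unbox = TRUE
  )
  invisible(c(features = fcsv, schema = fjson))
}
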