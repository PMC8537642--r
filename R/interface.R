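# Interface detection, CDR annotation, and the 52-column contact feature
# block.  The interface is distance-defined: a residue is interfacial iff any
# of its heavy atoms lies within the cutoff of any heavy atom of the partner
# chain (inclusive comparison).  The default 5 A cutoff is the Fnat contact
# convention of the DockQ standard, so the same notion of "contact" is used
# for labelling poses and for describing them.

#' Interface definition
#'
#' @param contact_cutoff Heavy-atom distance cutoff in Angstrom (default 5.0).
#' @return An `interface_definition` object.
#' @export
interface_definition <- function(contact_cutoff = 5.0) {
  if (!is.numeric(contact_cutoff) || length(contact_cutoff) != 1L ||
      !is.finite(contact_cutoff) || contact_cutoff <= 0) {
    abort("contact_cutoff must be a positive number", "nbrank_invalid_argument")
  }
  structure(list(contact_cutoff = contact_cutoff, atom_subset = "heavy"),
            class = "interface_definition")
}

# Squared-distance matrix between two coordinate sets (rows = atoms).
cross_dist2 <- function(A, B) {
  outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
}

# Atom-index -> residue-position map: positional index (1-based, file order)
# of each atom's residue within its chain.
atom_res_position <- function(at) {
  key <- res_key(at$chain, at$resno, at$ins)
  match(key, unique(key))
}

#' Detect interface residues (epitope and paratope)
#'
#' A nanobody residue belongs to the paratope (and an antigen residue to the
#' epitope) iff any heavy-atom pair between the residue and the partner chain
#' is within `def$contact_cutoff` (inclusive).
#'
#' @param cs A `complex_structure`.
#' @param def An [interface_definition()].
#' @return An `interface_residues` object: sorted 1-based residue positions
#'   `paratope` (on the nanobody chain) and `epitope` (on the antigen chain),
#'   plus the cutoff used.  Chains out of range give empty sets.
#' @export
detect_interface <- function(cs, def = interface_definition()) {
  ag <- chain_atoms(cs, "antigen")
  nb <- chain_atoms(cs, "nanobody")
  d2 <- cross_dist2(coords(ag), coords(nb))
  hit <- which(d2 <= def$contact_cutoff^2, arr.ind = TRUE)
  structure(list(
    paratope = sort(unique(atom_res_position(nb)[hit[, 2]])),
    epitope  = sort(unique(atom_res_position(ag)[hit[, 1]])),
    contact_cutoff = def$contact_cutoff
  ), class = "interface_residues")
}

# ---- CDR annotation ---------------------------------------------------------

# Anchor-based CDR heuristic offsets (Chothia-like, relative to the two
# conserved framework cysteines).  CDR3 runs from two residues after the
# second cysteine up to the "WG.G" J-segment anchor.
CDR1_OFFSET <- c(4L, 10L)   # cdr1 = (c1+4) .. (c1+10), 7 residues
CDR2_OFFSET <- c(30L, 35L)  # cdr2 = (c1+30) .. (c1+35), 6 residues
CDR3_START_OFFSET <- 3L     # cdr3 starts at c2 + 3

span_to_positions <- function(span) {
  # 0-based half-open [start, end) -> 1-based inclusive positions
  if (length(span) != 2L || !all(is.finite(span)) || span[2] <= span[1] || span[1] < 0) {
    abort("CDR span must be a 0-based half-open [start, end) pair with end > start",
          "nbrank_invalid_spans")
  }
  seq.int(span[1] + 1L, span[2])
}

positions_to_span <- function(pos) c(min(pos) - 1L, max(pos))

#' Annotate the three CDR loops of a nanobody sequence
#'
#' Either validates user-supplied spans (0-based half-open, as in the JSON/
#' YAML configuration format) or locates the loops with a built-in anchor
#' heuristic: the two conserved framework cysteines are found (first `C` in
#' the window 16-30, first `C` in 85-110), CDR1/CDR2 are placed at fixed
#' Chothia-like offsets from the first cysteine, and CDR3 runs from two
#' residues after the second cysteine to the `WG.G` J-segment anchor.
#' Structures for which any loop cannot be resolved are rejected, mirroring
#' the requirement that all three CDR loops be present.
#'
#' @param nb_sequence Nanobody one-letter sequence (length >= 60 for the
#'   heuristic).
#' @param user_spans Optional list with elements `cdr1`, `cdr2`, `cdr3`, each
#'   a 0-based half-open `c(start, end)` pair; returned verbatim after
#'   validation.
#' @return A `cdr_annotation`: list of 1-based position vectors `cdr1`,
#'   `cdr2`, `cdr3`.
#' @export
annotate_cdrs <- function(nb_sequence, user_spans = NULL) {
  n <- if (is.null(nb_sequence)) Inf else nchar(nb_sequence)
  if (!is.null(user_spans)) {
    if (!all(c("cdr1", "cdr2", "cdr3") %in% names(user_spans))) {
      abort("user_spans must name cdr1, cdr2 and cdr3", "nbrank_invalid_spans")
    }
    ann <- lapply(user_spans[c("cdr1", "cdr2", "cdr3")], span_to_positions)
    return(validate_cdr_annotation(ann, n))
  }
  if (n < 60L) {
    abort("nanobody sequence shorter than 60 residues", "nbrank_missing_cdr")
  }
  s <- strsplit(nb_sequence, "")[[1]]
  c1 <- find_first(s, "C", 16L, 30L)
  c2 <- find_first(s, "C", 85L, min(110L, n))
  if (is.na(c1) || is.na(c2)) {
    abort("conserved cysteine anchors not found", "nbrank_missing_cdr")
  }
  wg <- regexpr("WG.G", substr(nb_sequence, c2 + CDR3_START_OFFSET + 1L, n))
  if (wg < 0) abort("J-segment WG.G anchor not found", "nbrank_missing_cdr")
  wg_pos <- c2 + CDR3_START_OFFSET + as.integer(wg)  # 1-based position of W
  cdr3 <- seq.int(c2 + CDR3_START_OFFSET, wg_pos - 1L)
  ann <- list(
    cdr1 = seq.int(c1 + CDR1_OFFSET[1], c1 + CDR1_OFFSET[2]),
    cdr2 = seq.int(c1 + CDR2_OFFSET[1], c1 + CDR2_OFFSET[2]),
    cdr3 = cdr3
  )
  validate_cdr_annotation(ann, n)
}

find_first <- function(s, char, from, to) {
  idx <- which(s[from:min(to, length(s))] == char)
  if (length(idx) == 0L) NA_integer_ else from + idx[1] - 1L
}

validate_cdr_annotation <- function(ann, seq_length) {
  lens <- vapply(ann, length, integer(1))
  if (any(lens == 0L)) abort("empty CDR span", "nbrank_missing_cdr")
  if (max(ann$cdr3) > seq_length || min(ann$cdr1) < 1L) {
    abort("CDR span outside sequence", "nbrank_missing_cdr")
  }
  ordered <- max(ann$cdr1) < min(ann$cdr2) && max(ann$cdr2) < min(ann$cdr3)
  if (!ordered) abort("CDR spans must be ordered and non-overlapping",
                      "nbrank_missing_cdr")
  structure(ann, class = "cdr_annotation")
}

#' CDR spans in the external 0-based half-open convention
#'
#' @param ann A `cdr_annotation`.
#' @return List of `c(start, end)` pairs (0-based half-open), the format used
#'   in JSON/YAML span configuration files.
#' @export
cdr_spans <- function(ann) lapply(unclass(ann), positions_to_span)

#' Read CDR spans for one complex from a JSON or YAML configuration file
#'
#' The file maps complex ids to `{cdr1: [s, e), cdr2: ..., cdr3: ...}`
#' 0-based half-open spans.
#'
#' @param path JSON (`.json`) or YAML file path.
#' @param complex_id Complex identifier to look up.
#' @return The span list for `complex_id`, suitable for
#'   `annotate_cdrs(user_spans = )`.
#' @export
read_cdr_spans <- function(path, complex_id) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg[[complex_id]])) {
    abort(sprintf("no CDR spans for complex '%s' in %s", complex_id, path),
          "nbrank_invalid_spans")
  }
  cfg[[complex_id]]
}

# ---- contact feature block --------------------------------------------------

contact_feature_names <- function() {
  c("n_paratope", "n_epitope",
    paste0("n_interacting_cdr", 1:3),
    paste0("len_cdr", 1:3),
    "frac_cdr_in_paratope",
    paste0("frac_interacting_cdr", 1:3, "_vs_len"),
    paste0("aa_paratope_", AA1),
    paste0("aa_epitope_", AA1))
}

#' Contact features of one pose (52 columns)
#'
#' Counts of paratope/epitope residues, per-CDR interacting-residue counts and
#' loop lengths, the proportion of the paratope falling inside the CDRs, the
#' proportion of each CDR loop that is interacting, and per-amino-acid counts
#' on both interface sides (20 standard residues; `X` residues are counted in
#' the interface sizes but in none of the 20 bins).
#'
#' @param iface An `interface_residues` object.
#' @param cdrs A `cdr_annotation`.
#' @param cs The `complex_structure` the interface was detected on.
#' @return Named numeric vector of length 52.
#' @export
contact_features <- function(iface, cdrs, cs) {
  nb <- residue_table(cs, "nanobody")
  ag <- residue_table(cs, "antigen")
  para <- iface$paratope
  epi <- iface$epitope
  cdr_all <- c(cdrs$cdr1, cdrs$cdr2, cdrs$cdr3)

  n_int <- vapply(cdrs, function(p) length(intersect(para, p)), integer(1))
  lens <- vapply(cdrs, length, integer(1))
  frac_in_para <- if (length(para) == 0L) 0 else
    length(intersect(para, cdr_all)) / length(para)

  aa_counts <- function(codes) {
    tab <- table(factor(codes, levels = AA1))
    as.numeric(tab)
  }
  out <- c(
    length(para), length(epi),
    as.numeric(n_int), as.numeric(lens),
    frac_in_para, as.numeric(n_int) / as.numeric(lens),
    aa_counts(nb$code1[para]), aa_counts(ag$code1[epi])
  )
  names(out) <- contact_feature_names()
  out
}
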