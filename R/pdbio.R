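# Structure I/O: two-chain nanobody-antigen complexes read from / written to
# PDB, plus the rigid-body geometry primitives used by the docking-quality
# module.  Parsing is delegated to bio3d; this layer enforces the two-chain
# heavy-atom model the rest of the package works on.

# 3-letter -> 1-letter translation for the 20 standard amino acids.  Anything
# else (MSE, SEC, modified residues, ...) deliberately maps to "X": features
# are defined over the standard alphabet only.
AA3 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

# Standard one-letter alphabet in alphabetical order; fixed ordering of all
# per-amino-acid feature columns.
AA1 <- sort(unname(AA3))

# Non-standard amino-acid HETATM residues retained on read (sequence code "X").
NONSTANDARD_AA3 <- c("MSE", "SEC", "PYL", "MLY", "PTR", "SEP", "TPO", "CSO", "HYP")

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

aa_three_to_one <- function(resid) {
  out <- unname(AA3[resid])
  out[is.na(out)] <- "X"
  out
}

#' Read a two-chain nanobody-antigen complex from a PDB file
#'
#' Reads the first model of a PDB file, keeps heavy atoms only (hydrogens and
#' deuteriums dropped), keeps the first alternate location, and restricts the
#' structure to exactly two chains: the antigen and the nanobody.  `HETATM`
#' records are kept only for common non-standard amino acids (e.g. MSE);
#' waters and ligands are ignored.
#'
#' @param path Path to a PDB file.
#' @param antigen_chain Chain identifier of the antigen (default `"A"`).
#' @param nanobody_chain Chain identifier of the nanobody (default `"H"`).
#' @return A `complex_structure` object: a list with an `atoms` data frame
#'   (`chain`, `resno`, `ins`, `resid`, `elety`, `x`, `y`, `z`; residue order
#'   as in the file) and the two chain identifiers.
#' @export
read_complex <- function(path, antigen_chain = "A", nanobody_chain = "H") {
  if (!file.exists(path)) {
    abort(sprintf("PDB file not found: %s", path), "nbrank_io_error")
  }
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = TRUE,
                                          verbose = FALSE))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) {
    abort(sprintf("no ATOM records in %s", path), "nbrank_empty_structure")
  }
  keep <- at$type == "ATOM" | (at$type == "HETATM" & at$resid %in% NONSTANDARD_AA3)
  at <- at[keep, , drop = FALSE]
  # drop hydrogens / deuteriums by element symbol (derived from the atom name
  # when the element column is blank)
  ele <- at$elesy
  missing_ele <- is.na(ele) | ele == ""
  if (any(missing_ele)) {
    ele[missing_ele] <- suppressWarnings(
      bio3d::atom2ele(at$elety[missing_ele], rescue = TRUE)
    )
  }
  at <- at[!(toupper(ele) %in% c("H", "D")), , drop = FALSE]
  if (nrow(at) == 0L) {
    abort(sprintf("no heavy atoms in %s", path), "nbrank_empty_structure")
  }
  for (ch in c(antigen_chain, nanobody_chain)) {
    if (!ch %in% at$chain) {
      abort(sprintf("chain '%s' not present in %s", ch, path),
            "nbrank_missing_chain")
    }
  }
  at <- at[at$chain %in% c(antigen_chain, nanobody_chain), , drop = FALSE]
  # first conformer wins: one coordinate per (chain, residue, atom name)
  at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety)), , drop = FALSE]
  atoms <- data.frame(
    chain = at$chain,
    resno = at$resno,
    ins   = ifelse(is.na(at$insert) | at$insert == "", "", at$insert),
    resid = at$resid,
    elety = at$elety,
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE
  )
  new_complex_structure(atoms, antigen_chain, nanobody_chain)
}

new_complex_structure <- function(atoms, antigen_chain, nanobody_chain) {
  stopifnot(all(c("chain", "resno", "ins", "resid", "elety", "x", "y", "z")
                %in% names(atoms)))
  if (!any(atoms$chain == antigen_chain) || !any(atoms$chain == nanobody_chain)) {
    abort("both chains must contain at least one residue", "nbrank_missing_chain")
  }
  structure(
    list(atoms = atoms, antigen_chain = antigen_chain,
         nanobody_chain = nanobody_chain),
    class = "complex_structure"
  )
}

#' @export
print.complex_structure <- function(x, ...) {
  ag <- residue_table(x, "antigen")
  nb <- residue_table(x, "nanobody")
  cat(sprintf(
    "complex_structure: antigen chain %s (%d res), nanobody chain %s (%d res), %d heavy atoms\n",
    x$antigen_chain, nrow(ag), x$nanobody_chain, nrow(nb), nrow(x$atoms)
  ))
  invisible(x)
}

chain_atoms <- function(cs, side = c("antigen", "nanobody")) {
  side <- match.arg(side)
  ch <- if (side == "antigen") cs$antigen_chain else cs$nanobody_chain
  cs$atoms[cs$atoms$chain == ch, , drop = FALSE]
}

#' Residue table of one chain
#'
#' One row per residue in file order, with the residue key used for
#' cross-pose matching and the one-letter code (`"X"` for non-standard).
#'
#' @param cs A `complex_structure`.
#' @param side `"antigen"` or `"nanobody"`.
#' @return Data frame with columns `chain`, `resno`, `ins`, `resid`, `code1`,
#'   `key`.
#' @export
residue_table <- function(cs, side = c("antigen", "nanobody")) {
  at <- chain_atoms(cs, side)
  key <- res_key(at$chain, at$resno, at$ins)
  first <- !duplicated(key)
  data.frame(
    chain = at$chain[first], resno = at$resno[first], ins = at$ins[first],
    resid = at$resid[first], code1 = aa_three_to_one(at$resid[first]),
    key = key[first], stringsAsFactors = FALSE
  )
}

#' One-letter sequence of a chain
#'
#' @param cs A `complex_structure`.
#' @param side `"antigen"` or `"nanobody"`.
#' @return Character scalar; one letter per residue, `"X"` for residues
#'   outside the 20 standard amino acids.
#' @export
chain_sequence <- function(cs, side = c("antigen", "nanobody")) {
  rt <- residue_table(cs, side)
  if (nrow(rt) == 0L) abort("empty residue list", "nbrank_empty_input")
  paste(rt$code1, collapse = "")
}

#' Write a complex back to a minimal PDB file
#'
#' Emits plain `ATOM` records (occupancy 1.00, B-factor 0.00) preserving chain
#' ids, residue numbering, insertion codes and atom names.
#'
#' @param cs A `complex_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_complex <- function(cs, path) {
  at <- cs$atoms
  suppressWarnings(bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
    type = rep("ATOM", nrow(at)),
    resno = at$resno,
    resid = at$resid,
    chain = at$chain,
    insert = ifelse(at$ins == "", NA, at$ins),
    elety = at$elety,
    o = rep(1, nrow(at)),
    b = rep(0, nrow(at))
  ))
  invisible(path)
}

coords <- function(at) as.matrix(at[, c("x", "y", "z"), drop = FALSE])

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimising the RMSD
#' between `mobile %*% t(R) + t` and `target` over paired points.
#'
#' @param mobile,target Numeric n x 3 coordinate matrices with equal row
#'   counts (n >= 3), rows paired.
#' @return List with `rotation` (3 x 3), `translation` (length 3) and `rmsd`
#'   (Angstrom) at the optimum.
#' @export
superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (!identical(dim(mobile), dim(target)) || ncol(mobile) != 3L) {
    abort("coordinate sets must be equal-size n x 3 matrices", "nbrank_shape_error")
  }
  if (nrow(mobile) < 3L) {
    abort("need at least 3 paired points", "nbrank_insufficient_atoms")
  }
  cm <- colMeans(mobile); ct <- colMeans(target)
  A <- sweep(mobile, 2, cm); B <- sweep(target, 2, ct)
  s <- svd(crossprod(A, B))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- A %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  list(rotation = R, translation = as.numeric(ct - cm %*% t(R)), rmsd = rmsd)
}

#' Apply a rigid transform to coordinates
#'
#' @param xyz Numeric n x 3 matrix.
#' @param transform A list with `rotation` and `translation`, as returned by
#'   [superpose()].
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(xyz, transform) {
  sweep(as.matrix(xyz) %*% t(transform$rotation), 2, transform$translation, `+`)
}

rmsd_plain <- function(a, b) sqrt(mean(rowSums((as.matrix(a) - as.matrix(b))^2)))
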