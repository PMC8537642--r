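# The 66-descriptor amino-acid table behind the interface-property feature
# block.  Ten families with the canonical sizes (cruciani 3, kidera 10,
# zscales 5, fasgai 6, tscales 5, vhse 8, protfp 8, stscales 8, blosum 10,
# mswhim 3; 66 in total).
#
# The original published scale tables are not redistributed here.  Instead
# the package derives a deterministic stand-in with the same family structure:
# each family is a set of principal components of a hardcoded matrix of
# classical residue constants (Kyte-Doolittle hydropathy, residue mass, pI,
# van der Waals volume, Grantham polarity, net charge, aromaticity,
# Chou-Fasman helix/sheet propensities, side-chain rotatable bonds, H-bond
# donor/acceptor atom counts, maximal ASA), computed under family-specific
# emphasis weights; the `blosum` family is the first 10 principal components
# of the BLOSUM62 substitution scores.  Components within a family are
# orthogonal, unit-variance across the 20 residues, and sign-fixed, so sums
# over interface residues behave like the published scale sums (e.g. the
# hydrophobicity-dominated components track interface hydrophobicity).

# Classical per-residue constants; rows in AA1 (alphabetical) order.
aa_property_matrix <- function() {
  p <- rbind(
    #     hydro   mass    pI  volume polar charge arom helix sheet rot hbd hba asa
    A = c(  1.8,  71.08, 6.00,  88.6,  8.1,  0.0, 0, 1.42, 0.83, 0, 0, 0, 129),
    C = c(  2.5, 103.14, 5.07, 108.5,  5.5,  0.0, 0, 0.70, 1.19, 1, 1, 0, 167),
    D = c( -3.5, 115.09, 2.77, 111.1, 13.0, -1.0, 0, 1.01, 0.54, 2, 0, 2, 193),
    E = c( -3.5, 129.12, 3.22, 138.4, 12.3, -1.0, 0, 1.51, 0.37, 3, 0, 2, 223),
    F = c(  2.8, 147.18, 5.48, 189.9,  5.2,  0.0, 1, 1.13, 1.38, 2, 0, 0, 240),
    G = c( -0.4,  57.05, 5.97,  60.1,  9.0,  0.0, 0, 0.57, 0.75, 0, 0, 0, 104),
    H = c( -3.2, 137.14, 7.59, 153.2, 10.4,  0.1, 1, 1.00, 0.87, 2, 1, 1, 224),
    I = c(  4.5, 113.16, 6.02, 166.7,  5.2,  0.0, 0, 1.08, 1.60, 2, 0, 0, 197),
    K = c( -3.9, 128.17, 9.74, 168.6, 11.3,  1.0, 0, 1.16, 0.74, 4, 1, 0, 236),
    L = c(  3.8, 113.16, 5.98, 166.7,  4.9,  0.0, 0, 1.21, 1.30, 2, 0, 0, 201),
    M = c(  1.9, 131.19, 5.74, 162.9,  5.7,  0.0, 0, 1.45, 1.05, 3, 0, 0, 224),
    N = c( -3.5, 114.10, 5.41, 114.1, 11.6,  0.0, 0, 0.67, 0.89, 2, 1, 1, 195),
    P = c( -1.6,  97.12, 6.30, 112.7,  8.0,  0.0, 0, 0.57, 0.55, 0, 0, 0, 159),
    Q = c( -3.5, 128.13, 5.65, 143.8, 10.5,  0.0, 0, 1.11, 1.10, 3, 1, 1, 225),
    R = c( -4.5, 156.19,10.76, 173.4, 10.5,  1.0, 0, 0.98, 0.93, 4, 3, 0, 274),
    S = c( -0.8,  87.08, 5.68,  89.0,  9.2,  0.0, 0, 0.77, 0.75, 1, 1, 1, 155),
    T = c( -0.7, 101.10, 5.60, 116.1,  8.6,  0.0, 0, 0.83, 1.19, 1, 1, 1, 172),
    V = c(  4.2,  99.13, 5.96, 140.0,  5.9,  0.0, 0, 1.06, 1.70, 1, 0, 0, 174),
    W = c( -0.9, 186.21, 5.89, 227.8,  5.4,  0.0, 1, 1.08, 1.37, 2, 1, 0, 285),
    Y = c( -1.3, 163.18, 5.66, 193.6,  6.2,  0.0, 1, 0.69, 1.47, 2, 1, 1, 263)
  )
  colnames(p) <- c("hydropathy", "mass", "pI", "volume", "polarity", "charge",
                   "aromatic", "helix", "sheet", "rotbonds", "hbd", "hba", "asa")
  p
}

# BLOSUM62 substitution scores, 20 standard residues (alphabetical order).
blosum62_matrix <- function() {
  aa <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
  m <- matrix(c(
     4,-1,-2,-2, 0,-1,-1, 0,-2,-1,-1,-1,-1,-2,-1, 1, 0,-3,-2, 0,
    -1, 5, 0,-2,-3, 1, 0,-2, 0,-3,-2, 2,-1,-3,-2,-1,-1,-3,-2,-3,
    -2, 0, 6, 1,-3, 0, 0, 0, 1,-3,-3, 0,-2,-3,-2, 1, 0,-4,-2,-3,
    -2,-2, 1, 6,-3, 0, 2,-1,-1,-3,-4,-1,-3,-3,-1, 0,-1,-4,-3,-3,
     0,-3,-3,-3, 9,-3,-4,-3,-3,-1,-1,-3,-1,-2,-3,-1,-1,-2,-2,-1,
    -1, 1, 0, 0,-3, 5, 2,-2, 0,-3,-2, 1, 0,-3,-1, 0,-1,-2,-1,-2,
    -1, 0, 0, 2,-4, 2, 5,-2, 0,-3,-3, 1,-2,-3,-1, 0,-1,-3,-2,-2,
     0,-2, 0,-1,-3,-2,-2, 6,-2,-4,-4,-2,-3,-3,-2, 0,-2,-2,-3,-3,
    -2, 0, 1,-1,-3, 0, 0,-2, 8,-3,-3,-1,-2,-1,-2,-1,-2,-2, 2,-3,
    -1,-3,-3,-3,-1,-3,-3,-4,-3, 4, 2,-3, 1, 0,-3,-2,-1,-3,-1, 3,
    -1,-2,-3,-4,-1,-2,-3,-4,-3, 2, 4,-2, 2, 0,-3,-2,-1,-2,-1, 1,
    -1, 2, 0,-1,-3, 1, 1,-2,-1,-3,-2, 5,-1,-3,-1, 0,-1,-3,-2,-2,
    -1,-1,-2,-3,-1, 0,-2,-3,-2, 1, 2,-1, 5, 0,-2,-1,-1,-1,-1, 1,
    -2,-3,-3,-3,-2,-3,-3,-3,-1, 0, 0,-3, 0, 6,-4,-2,-2, 1, 3,-1,
    -1,-2,-2,-1,-3,-1,-1,-2,-2,-3,-3,-1,-2,-4, 7,-1,-1,-4,-3,-2,
     1,-1, 1, 0,-1, 0, 0, 0,-1,-2,-2, 0,-1,-2,-1, 4, 1,-3,-2,-2,
     0,-1, 0,-1,-1,-1,-1,-2,-2,-1,-1,-1,-1,-2,-1, 1, 5,-2,-2, 0,
    -3,-3,-4,-4,-2,-2,-3,-2,-2,-3,-2,-3,-1, 1,-4,-3,-2,11, 2,-3,
    -2,-2,-2,-3,-2,-1,-2,-3, 2,-1,-1,-2,-1, 3,-3,-2,-2, 2, 7,-1,
     0,-3,-3,-3,-1,-2,-2,-3,-3, 3, 1,-2, 1,-1,-2,-2, 0,-3,-1, 4
  ), nrow = 20, byrow = TRUE, dimnames = list(aa, aa))
  m[AA1, AA1]
}

#' Descriptor family sizes
#'
#' @return Named integer vector: number of components per family (sums to 66).
#' @export
descriptor_families <- function() {
  c(cruciani = 3L, kidera = 10L, zscales = 5L, fasgai = 6L, tscales = 5L,
    vhse = 8L, protfp = 8L, stscales = 8L, blosum = 10L, mswhim = 3L)
}

# Family-specific emphasis weights over the 13 property columns.
descriptor_family_weights <- function() {
  list(
    cruciani = c(2.0, 0.5, 1.0, 0.5, 2.0, 1.0, 0.5, 0.5, 0.5, 0.5, 2.0, 2.0, 1.0),
    kidera   = rep(1, 13),
    zscales  = c(2.0, 1.5, 1.5, 1.5, 1.5, 1.5, 0.5, 0.5, 0.5, 1.0, 1.0, 1.0, 1.5),
    fasgai   = c(1.5, 1.0, 1.0, 1.5, 1.0, 1.0, 0.5, 1.5, 1.5, 1.0, 0.5, 0.5, 1.0),
    tscales  = c(0.5, 2.0, 0.5, 2.0, 0.5, 0.5, 1.0, 0.5, 0.5, 2.0, 1.0, 1.0, 2.0),
    vhse     = c(2.0, 1.0, 1.5, 1.5, 1.0, 1.5, 0.5, 0.5, 0.5, 0.5, 1.0, 1.0, 1.0),
    protfp   = c(1.0, 1.2, 1.0, 1.2, 1.0, 1.0, 1.0, 1.2, 1.2, 1.0, 1.0, 1.0, 1.2),
    stscales = c(0.5, 1.5, 1.0, 1.5, 1.0, 0.5, 1.5, 1.0, 1.0, 1.5, 1.0, 1.0, 1.5),
    mswhim   = c(1.0, 0.5, 2.0, 0.5, 1.5, 2.0, 0.5, 0.5, 0.5, 0.5, 1.5, 1.5, 0.5)
  )
}

family_components <- function(P, w, k) {
  X <- sweep(scale(P), 2, w, `*`)
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  sc <- pr$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    # deterministic sign convention: dominant loading positive
    lead <- which.max(abs(pr$rotation[, j]))
    if (pr$rotation[lead, j] < 0) sc[, j] <- -sc[, j]
    s <- stats::sd(sc[, j])
    if (s > 1e-12) sc[, j] <- sc[, j] / s
  }
  sc
}

.descriptor_cache <- new.env(parent = emptyenv())

#' The 66-column amino-acid descriptor table
#'
#' 20 standard residues x 66 descriptors in ten families (see
#' [descriptor_families()]).  Values are package-derived components of
#' classical residue constants (and, for the `blosum` family, principal
#' components of BLOSUM62) patterned on the published scale families; they
#' are not the original published tables.  Deterministic: the same table is
#' returned on every call.
#'
#' @return Numeric 20 x 66 matrix; rownames are one-letter residue codes,
#'   colnames `<family><index>`.
#' @export
aa_descriptor_table <- function() {
  if (!is.null(.descriptor_cache$table)) return(.descriptor_cache$table)
  P <- aa_property_matrix()
  fam <- descriptor_families()
  wts <- descriptor_family_weights()
  blocks <- lapply(names(fam), function(f) {
    sc <- if (f == "blosum") {
      family_components(blosum62_matrix(), rep(1, 20), fam[[f]])
    } else {
      family_components(P, wts[[f]], fam[[f]])
    }
    colnames(sc) <- paste0(f, seq_len(ncol(sc)))
    sc
  })
  tab <- round(do.call(cbind, blocks), 4)
  stopifnot(ncol(tab) == 66L, nrow(tab) == 20L, !anyDuplicated(colnames(tab)))
  rownames(tab) <- AA1
  .descriptor_cache$table <- tab
  tab
}

#' Summed descriptor profile of a residue set (66 values)
#'
#' Element-wise sum of descriptor rows over the given residues; residues
#' outside the standard alphabet (`"X"`) contribute zero; the empty set gives
#' 66 zeros.
#'
#' @param codes Character vector of one-letter residue codes.
#' @param table Descriptor table (default [aa_descriptor_table()]).
#' @return Named numeric vector of length 66.
#' @export
property_profile <- function(codes, table = aa_descriptor_table()) {
  keep <- codes %in% rownames(table)
  if (!any(keep)) {
    out <- numeric(ncol(table))
    names(out) <- colnames(table)
    return(out)
  }
  colSums(table[codes[keep], , drop = FALSE])
}
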