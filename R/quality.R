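# Docking quality assessment: Fnat, interface RMSD (iRMS), ligand RMSD
# (LRMS), the combined DockQ score, the CAPRI quality band and the binary
# nativeness label used for training.  The antigen is the receptor and the
# nanobody is the ligand throughout.  Residues are matched between a model
# pose and the native complex by (chain id, residue number, insertion code).

#' Docking-quality parameters
#'
#' Constants of the DockQ scheme: the 5 A heavy-atom cutoff defining native
#' contacts (Fnat), the 10 A heavy-atom cutoff defining interface residues
#' (iRMS), the scaling constants d1 = 1.5 A (iRMS term) and d2 = 8.5 A (LRMS
#' term), and the nativeness threshold 0.23 separating incorrect from
#' acceptable-or-better poses.
#'
#' @param fnat_cutoff Contact cutoff in Angstrom (default 5.0).
#' @param iface_cutoff Interface-residue cutoff in Angstrom (default 10.0).
#' @param d1,d2 DockQ scaling constants in Angstrom (defaults 1.5 and 8.5).
#' @param native_threshold DockQ score below which a pose is non-native-like
#'   (default 0.23).
#' @return A `quality_params` object.
#' @export
quality_params <- function(fnat_cutoff = 5.0, iface_cutoff = 10.0,
                           d1 = 1.5, d2 = 8.5, native_threshold = 0.23) {
  vals <- c(fnat_cutoff, iface_cutoff, d1, d2, native_threshold)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    abort("all quality parameters must be positive", "nbrank_invalid_argument")
  }
  structure(list(fnat_cutoff = fnat_cutoff, iface_cutoff = iface_cutoff,
                 d1 = d1, d2 = d2, native_threshold = native_threshold),
            class = "quality_params")
}

CAPRI_CLASSES <- c("Incorrect", "Acceptable", "Medium", "High")

#' Cross-chain residue contacts of a complex
#'
#' All antigen-nanobody residue pairs with any heavy-atom pair within
#' `cutoff` (inclusive), identified by residue keys
#' (`chain:resno[insert]`) so pairs are comparable across poses.
#'
#' @param cs A `complex_structure`.
#' @param cutoff Heavy-atom distance cutoff in Angstrom.
#' @return Character vector of `"antigenKey||nanobodyKey"` pair ids (sorted,
#'   unique).
#' @export
native_contacts <- function(cs, cutoff = 5.0) {
  ag <- chain_atoms(cs, "antigen")
  nb <- chain_atoms(cs, "nanobody")
  d2 <- cross_dist2(coords(ag), coords(nb))
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(character(0))
  akey <- res_key(ag$chain, ag$resno, ag$ins)[hit[, 1]]
  hkey <- res_key(nb$chain, nb$resno, nb$ins)[hit[, 2]]
  sort(unique(paste0(akey, "||", hkey)))
}

#' Fraction of native contacts preserved in a model pose
#'
#' @param model,native `complex_structure` objects sharing residue
#'   identifiers.
#' @param params A [quality_params()].
#' @return Fraction in \[0, 1\].
#' @export
fnat <- function(model, native, params = quality_params()) {
  nat <- native_contacts(native, params$fnat_cutoff)
  if (length(nat) == 0L) {
    abort("native complex has no cross-chain contacts", "nbrank_degenerate_native")
  }
  mod <- native_contacts(model, params$fnat_cutoff)
  length(intersect(mod, nat)) / length(nat)
}

# Matched backbone coordinate pairs between model and native for a residue
# subset (by key) on one or both chains.  Atom matching is by residue key +
# atom name; order follows the native.
matched_backbone <- function(model, native, keys = NULL) {
  tag <- function(cs) {
    at <- cs$atoms
    at <- at[at$elety %in% BACKBONE_ATOMS, , drop = FALSE]
    at$akey <- paste0(res_key(at$chain, at$resno, at$ins), "@", at$elety)
    at
  }
  m <- tag(model); n <- tag(native)
  if (!is.null(keys)) {
    n <- n[res_key(n$chain, n$resno, n$ins) %in% keys, , drop = FALSE]
  }
  idx <- match(n$akey, m$akey)
  ok <- !is.na(idx)
  list(model = coords(m[idx[ok], , drop = FALSE]),
       native = coords(n[ok, , drop = FALSE]))
}

#' Ligand RMSD of a model pose
#'
#' Superposes the model on the native over the antigen (receptor) backbone
#' (N, CA, C, O) and reports the backbone RMSD over the nanobody (ligand).
#'
#' @inheritParams fnat
#' @return RMSD in Angstrom.
#' @export
lrms <- function(model, native, params = quality_params()) {
  ag_keys <- residue_table(native, "antigen")$key
  nb_keys <- residue_table(native, "nanobody")$key
  rec <- matched_backbone(model, native, ag_keys)
  if (nrow(rec$model) < 3L) {
    abort("fewer than 3 shared receptor backbone atoms", "nbrank_insufficient_atoms")
  }
  fit <- superpose(rec$model, rec$native)
  lig <- matched_backbone(model, native, nb_keys)
  if (nrow(lig$model) < 3L) {
    abort("fewer than 3 shared ligand backbone atoms", "nbrank_insufficient_atoms")
  }
  rmsd_plain(apply_transform(lig$model, fit), lig$native)
}

# Keys of native interface residues (both chains) at the iRMS cutoff.
interface_residue_keys <- function(native, cutoff) {
  pairs <- native_contacts(native, cutoff)
  if (length(pairs) == 0L) return(character(0))
  unique(unlist(strsplit(pairs, "||", fixed = TRUE)))
}

#' Interface RMSD of a model pose
#'
#' Native interface residues are all residues (either chain) with a
#' cross-chain heavy-atom contact within `params$iface_cutoff` (10 A).  The
#' model is superposed on the native over the backbone atoms of exactly those
#' residues and that backbone RMSD is reported.
#'
#' @inheritParams fnat
#' @return RMSD in Angstrom.
#' @export
irms <- function(model, native, params = quality_params()) {
  keys <- interface_residue_keys(native, params$iface_cutoff)
  if (length(keys) == 0L) {
    abort("native complex has an empty interface", "nbrank_degenerate_native")
  }
  mb <- matched_backbone(model, native, keys)
  if (nrow(mb$model) < 3L) {
    abort("fewer than 3 shared interface backbone atoms", "nbrank_insufficient_atoms")
  }
  superpose(mb$model, mb$native)$rmsd
}

#' Combined DockQ score
#'
#' `DockQ = (Fnat + 1/(1+(iRMS/d1)^2) + 1/(1+(LRMS/d2)^2)) / 3`.
#'
#' @param fnat Fraction of native contacts in \[0, 1\].
#' @param irms,lrms RMSD components in Angstrom.
#' @param params A [quality_params()].
#' @return Score in \[0, 1\].
#' @export
dockq_score <- function(fnat, irms, lrms, params = quality_params()) {
  stopifnot(is.finite(fnat), fnat >= 0, fnat <= 1, irms >= 0, lrms >= 0)
  (fnat + 1 / (1 + (irms / params$d1)^2) + 1 / (1 + (lrms / params$d2)^2)) / 3
}

#' Binary nativeness label and CAPRI band of a DockQ score
#'
#' Label 0 (non-native-like) iff `dockq < native_threshold` (0.23), else 1
#' (native-like, pooling Acceptable/Medium/High).  CAPRI bands:
#' \[0, 0.23) Incorrect, \[0.23, 0.49) Acceptable, \[0.49, 0.80) Medium,
#' \[0.80, 1\] High.
#'
#' @param dockq DockQ score in \[0, 1\].
#' @param params A [quality_params()].
#' @return List with `label` (0/1 integer) and `capri` (character).
#' @export
label_pose <- function(dockq, params = quality_params()) {
  if (!is.numeric(dockq) || length(dockq) != 1L || !is.finite(dockq) ||
      dockq < 0 || dockq > 1) {
    abort("dockq score must lie in [0, 1]", "nbrank_domain_error")
  }
  capri <- CAPRI_CLASSES[findInterval(dockq, c(0, 0.23, 0.49, 0.80), rightmost.closed = FALSE)]
  list(label = as.integer(dockq >= params$native_threshold), capri = capri)
}

#' Full docking-quality assessment of one pose
#'
#' @param model,native `complex_structure` objects sharing residue
#'   identifiers.
#' @param params A [quality_params()].
#' @return A `pose_quality` list: `fnat`, `irms`, `lrms`, `dockq`, `capri`,
#'   `label`.
#' @export
pose_quality <- function(model, native, params = quality_params()) {
  f <- fnat(model, native, params)
  i <- irms(model, native, params)
  l <- lrms(model, native, params)
  q <- dockq_score(f, i, l, params)
  lab <- label_pose(q, params)
  structure(list(fnat = f, irms = i, lrms = l, dockq = q,
                 capri = lab$capri, label = lab$label),
            class = "pose_quality")
}

#' @export
print.pose_quality <- function(x, ...) {
  cat(sprintf("DockQ %.3f (Fnat %.3f, iRMS %.2f A, LRMS %.2f A) -> %s, label %d\n",
              x$dockq, x$fnat, x$irms, x$lrms, x$capri, x$label))
  invisible(x)
}

#' Batch docking-quality assessment from a pose manifest
#'
#' Reads a manifest (data frame or CSV path) with columns `model_path`,
#' `native_path`, `complex_id`, `parent_id`, `refined_id` and optional chain
#' id columns `antigen_chain`, `nanobody_chain`, assesses every model against
#' its native, and returns (optionally writes) the quality table.
#'
#' @param manifest Data frame or CSV file path.
#' @param params A [quality_params()].
#' @param out Optional output CSV path.
#' @return Data frame: manifest id columns plus `fnat`, `irms`, `lrms`,
#'   `dockq`, `capri`, `label`.
#' @export
quality_table <- function(manifest, params = quality_params(), out = NULL) {
  if (is.character(manifest)) {
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  need <- c("model_path", "native_path", "complex_id", "parent_id", "refined_id")
  if (!all(need %in% names(manifest))) {
    abort(sprintf("manifest must have columns: %s", paste(need, collapse = ", ")),
          "nbrank_invalid_argument")
  }
  ag <- manifest$antigen_chain %||% rep("A", nrow(manifest))
  nb <- manifest$nanobody_chain %||% rep("H", nrow(manifest))
  natives <- new.env(parent = emptyenv())
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    np <- manifest$native_path[i]
    if (is.null(natives[[np]])) {
      natives[[np]] <- read_complex(np, ag[i], nb[i])
    }
    model <- read_complex(manifest$model_path[i], ag[i], nb[i])
    q <- pose_quality(model, natives[[np]], params)
    data.frame(complex_id = manifest$complex_id[i],
               parent_id = manifest$parent_id[i],
               refined_id = manifest$refined_id[i],
               fnat = q$fnat, irms = q$irms, lrms = q$lrms,
               dockq = q$dockq, capri = q$capri, label = q$label,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (!is.null(out)) utils::write.csv(res, out, row.names = FALSE)
  res
}
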