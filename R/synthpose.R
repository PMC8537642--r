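# Synthetic study generator: toy two-chain nanobody-antigen complexes,
# parent decoy poses produced by seeded rigid-body perturbation of the
# nanobody, and refined child poses produced by small secondary
# perturbations.  Ground-truth docking quality spans all DockQ bands, so the
# labelling, featurization, training and re-ranking machinery can be
# exercised end to end without any docking program.
#
# Chains are ideal helical mini-domains (CA/N/C/O/CB pseudo-backbone); the
# nanobody sequence carries the conserved anchor motifs (two framework
# cysteines and the WG.G J-segment) that the CDR heuristic keys on, so
# ground-truth CDR spans are recoverable from sequence alone.  No physical
# realism beyond well-defined geometry is attempted.

#' Configuration of the synthetic study
#'
#' Defaults define the study conditions used throughout the package's own
#' evaluation: 12 complexes, 10 parent poses per docking run of which the
#' two smallest perturbation scales are required to stay native-like
#' (DockQ >= 0.23) and the rest non-native-like, and 5 refined children per
#' parent.
#'
#' @param n_complexes Number of complexes (default 12).
#' @param parents_per_complex Parent poses per docking run (default 10).
#' @param refined_per_parent Refined children per parent (default 5).
#' @param translation_scales Parent translation scales in Angstrom, small to
#'   large (default `c(1, 3, 8, 16, 32)`); parents cycle through the scales.
#' @param rotation_scales Parent rotation scales in degrees, paired with
#'   `translation_scales` (default `c(3, 8, 20, 45, 90)`).
#' @param native_scale_count Number of leading (small) scales whose parents
#'   must be native-like (default 2).
#' @param child_translation,child_rotation Maximum child perturbation
#'   (default 0.5 A, 3 degrees).
#' @param antigen_length Antigen chain length (default 60).
#' @param docking_modes Docking runs to emulate per complex (default
#'   `"default"`; may include `"antibody"`).
#' @param retry_cap Resampling attempts per parent before a band is declared
#'   unreachable (default 25).
#' @param seed Base seed; all generation is reproducible from it.
#' @return A `synthetic_config` object.
#' @export
synthetic_config <- function(n_complexes = 12L, parents_per_complex = 10L,
                             refined_per_parent = 5L,
                             translation_scales = c(1, 3, 8, 16, 32),
                             rotation_scales = c(3, 8, 20, 45, 90),
                             native_scale_count = 2L,
                             child_translation = 0.5, child_rotation = 3,
                             antigen_length = 60L,
                             docking_modes = "default",
                             retry_cap = 25L, seed = 1L) {
  stopifnot(n_complexes >= 1, parents_per_complex >= 1, refined_per_parent >= 1,
            length(translation_scales) == length(rotation_scales),
            all(translation_scales > 0), all(rotation_scales > 0),
            native_scale_count >= 1,
            native_scale_count < length(translation_scales),
            antigen_length >= 20, retry_cap >= 1)
  structure(as.list(environment()), class = "synthetic_config")
}

# Filler alphabet excludes C and W so the planted anchors are unambiguous.
FILLER_AA <- setdiff(AA1, c("C", "W"))

# Ideal-helix pseudo-backbone for a sequence: CA on a helix, N/C along the
# local tangent, O/CB along the outward radial (CB absent for GLY).
build_helix_chain <- function(seq1, chain_id, axis_origin, axis_dir, perp_u,
                              phase = 0, radius = 2.3, rise = 1.5,
                              twist = 100 * pi / 180, jitter = 0, rng_jitter = NULL) {
  n <- nchar(seq1)
  codes1 <- strsplit(seq1, "")[[1]]
  resid3 <- names(AA3)[match(codes1, AA3)]
  a <- axis_dir / sqrt(sum(axis_dir^2))
  u <- perp_u - sum(perp_u * a) * a
  u <- u / sqrt(sum(u^2))
  v <- c(a[2] * u[3] - a[3] * u[2], a[3] * u[1] - a[1] * u[3],
         a[1] * u[2] - a[2] * u[1])
  i <- seq_len(n)
  ang <- twist * i + phase
  axial <- rise * (i - (n + 1) / 2)
  ca <- t(vapply(i, function(k) {
    axis_origin + axial[k] * a + radius * (cos(ang[k]) * u + sin(ang[k]) * v)
  }, numeric(3)))
  if (jitter > 0) ca <- ca + matrix(stats::rnorm(3 * n, 0, jitter), n, 3)
  tang <- matrix(0, n, 3)
  tang[1, ] <- ca[2, ] - ca[1, ]
  if (n > 2) tang[2:(n - 1), ] <- ca[3:n, ] - ca[1:(n - 2), ]
  tang[n, ] <- ca[n, ] - ca[n - 1, ]
  tang <- tang / sqrt(rowSums(tang^2))
  radial <- t(vapply(i, function(k) cos(ang[k]) * u + sin(ang[k]) * v, numeric(3)))
  rows <- lapply(i, function(k) {
    at <- rbind(
      N  = ca[k, ] - 1.46 * tang[k, ],
      CA = ca[k, ],
      C  = ca[k, ] + 1.52 * tang[k, ],
      O  = ca[k, ] + 1.52 * tang[k, ] + 1.23 * radial[k, ]
    )
    if (codes1[k] != "G") at <- rbind(at, CB = ca[k, ] + 1.53 * radial[k, ])
    data.frame(chain = chain_id, resno = k, ins = "", resid = resid3[k],
               elety = rownames(at), x = at[, 1], y = at[, 2], z = at[, 3],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Generate one synthetic native complex
#'
#' Builds a helical antigen and a helical nanobody whose CDR3 segment is
#' placed in contact with the antigen (crossed-axes geometry), verifying at
#' least 5 native cross-chain residue contacts at 5 A and no steric clash
#' below 2 A.  The nanobody sequence carries the planted anchor motifs; the
#' ground-truth CDR spans are returned with the structure.
#'
#' @param config A [synthetic_config()].
#' @param complex_index Index of the complex (1-based); determines the
#'   per-complex seed.
#' @return List with `complex_id`, `native` (a `complex_structure`), `cdrs`
#'   (a `cdr_annotation`) and `sequence` (nanobody sequence).
#' @export
make_native <- function(config, complex_index) {
  set.seed(config$seed * 1000L + complex_index)
  ag_seq <- paste(sample(FILLER_AA, config$antigen_length, replace = TRUE),
                  collapse = "")
  c1 <- sample(20:24, 1)
  c2 <- sample(88:96, 1)
  len3 <- sample(8:14, 1)
  w <- c2 + CDR3_START_OFFSET + len3
  n_nb <- w + 3L + 8L
  s <- sample(FILLER_AA, n_nb, replace = TRUE)
  s[c1] <- "C"; s[c2] <- "C"
  s[w] <- "W"; s[w + 1L] <- "G"; s[w + 3L] <- "G"
  nb_seq <- paste(s, collapse = "")
  cdrs <- validate_cdr_annotation(list(
    cdr1 = seq.int(c1 + CDR1_OFFSET[1], c1 + CDR1_OFFSET[2]),
    cdr2 = seq.int(c1 + CDR2_OFFSET[1], c1 + CDR2_OFFSET[2]),
    cdr3 = seq.int(c2 + CDR3_START_OFFSET, w - 1L)
  ), n_nb)

  mid3 <- round(mean(cdrs$cdr3))
  twist <- 100 * pi / 180
  # nanobody axis along x, antigen axis along z; CDR3 midpoint sits at the
  # axis crossing with its radial vector facing the antigen (-y)
  phase_nb <- pi - twist * mid3
  x_shift <- -1.5 * (mid3 - (nchar(nb_seq) + 1) / 2)
  cs <- NULL
  for (attempt in seq_len(config$retry_cap)) {
    ag_atoms <- build_helix_chain(ag_seq, "A", c(0, 0, 0), c(0, 0, 1),
                                  c(1, 0, 0), phase = stats::runif(1, 0, 2 * pi),
                                  jitter = 0.08)
    for (d in seq(10, 4.5, by = -0.25)) {
      nb_atoms <- build_helix_chain(nb_seq, "H", c(x_shift, d, 0), c(1, 0, 0),
                                    c(0, 1, 0), phase = phase_nb, jitter = 0.08)
      cand <- new_complex_structure(rbind(ag_atoms, nb_atoms), "A", "H")
      dmin <- sqrt(min(cross_dist2(coords(chain_atoms(cand, "antigen")),
                                   coords(chain_atoms(cand, "nanobody")))))
      if (dmin < 2.0) break
      if (length(native_contacts(cand, 5.0)) >= 5L) cs <- cand  # keep closest clash-free placement
    }
    if (!is.null(cs)) break
  }
  if (is.null(cs)) {
    abort("could not place chains with >= 5 native contacts",
          "nbrank_generation_error")
  }
  list(complex_id = sprintf("SYN%03d", complex_index), native = cs,
       cdrs = cdrs, sequence = nb_seq)
}

# Rigid-body perturbation of the nanobody chain about its centroid.
perturb_nanobody <- function(cs, trans_mag, rot_deg) {
  at <- cs$atoms
  nb <- at$chain == cs$nanobody_chain
  xyz <- as.matrix(at[nb, c("x", "y", "z")])
  centroid <- colMeans(xyz)
  axis <- stats::rnorm(3); axis <- axis / sqrt(sum(axis^2))
  th <- rot_deg * pi / 180
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
  new_xyz <- sweep(sweep(xyz, 2, centroid) %*% t(R), 2,
                   centroid + trans_mag * dir, `+`)
  at[nb, c("x", "y", "z")] <- new_xyz
  new_complex_structure(at, cs$antigen_chain, cs$nanobody_chain)
}

#' Generate parent and refined decoy poses for one native complex
#'
#' Parents cycle through the configured perturbation scales; parents at the
#' leading `native_scale_count` scales are resampled (up to `retry_cap`
#' attempts) until native-like (DockQ >= 0.23), the rest until
#' non-native-like, so every docking run contains both bands.  Each parent
#' spawns `refined_per_parent` children by small secondary perturbations.
#' Ground-truth DockQ and labels are recorded per pose.
#'
#' @param native_obj Output of [make_native()].
#' @param config A [synthetic_config()].
#' @param params A [quality_params()].
#' @return List with `manifest` (one row per refined pose: ids, `dockq`,
#'   `label`, `parent_dockq`, `parent_label`) and `structures` (named list of
#'   refined `complex_structure` objects, names = `refined_id`).
#' @export
make_decoys <- function(native_obj, config, params = quality_params()) {
  native <- native_obj$native
  n_scales <- length(config$translation_scales)
  rows <- list(); structures <- list()
  for (mode in config$docking_modes) {
    set.seed(config$seed * 1000L + match(mode, config$docking_modes) * 211L +
               as.integer(sub("SYN", "", native_obj$complex_id)))
    for (j in seq_len(config$parents_per_complex)) {
      s <- ((j - 1L) %% n_scales) + 1L
      want_native <- s <= config$native_scale_count
      parent <- NULL
      for (try in seq_len(config$retry_cap)) {
        t_mag <- stats::runif(1, 0.25, 1) * config$translation_scales[s]
        r_deg <- stats::runif(1, 0.25, 1) * config$rotation_scales[s]
        cand <- perturb_nanobody(native, t_mag, r_deg)
        q <- pose_quality(cand, native, params)
        if ((q$label == 1L) == want_native) { parent <- list(cs = cand, q = q); break }
      }
      if (is.null(parent)) {
        abort(sprintf("DockQ band unreachable for parent %d (scale %d)", j, s),
              "nbrank_generation_error")
      }
      parent_id <- sprintf("%s_P%02d", mode, j)
      for (k in seq_len(config$refined_per_parent)) {
        child <- perturb_nanobody(parent$cs,
                                  stats::runif(1, 0, config$child_translation),
                                  stats::runif(1, 0, config$child_rotation))
        cq <- pose_quality(child, native, params)
        refined_id <- sprintf("%s_R%d", parent_id, k)
        rows[[length(rows) + 1L]] <- data.frame(
          complex_id = native_obj$complex_id, docking_mode = mode,
          parent_id = parent_id, refined_id = refined_id,
          dockq = cq$dockq, label = cq$label,
          parent_dockq = parent$q$dockq, parent_label = parent$q$label,
          stringsAsFactors = FALSE
        )
        structures[[refined_id]] <- child
      }
    }
  }
  list(manifest = do.call(rbind, rows), structures = structures)
}

# Pseudo-energy fixture: deterministic affine function of DockQ plus seeded
# noise, one slope/offset pair per canonical energy column.
pseudo_energy <- function(dockq, names_vec) {
  k <- seq_along(names_vec)
  slope <- ((k * 37) %% 7) - 3
  offset <- ((k * 13) %% 11) - 5
  vals <- offset + slope * dockq + stats::rnorm(length(k), 0, 0.25)
  names(vals) <- names_vec
  vals
}

#' Featurize one pose
#'
#' Detects the interface, computes the contact block and the paratope/epitope
#' property profiles, and assembles the feature vector for the given schema.
#' Energy blocks, when enabled, are either explicitly missing (`NA`) or
#' filled with deterministic pseudo-energy fixtures.
#'
#' @param cs A `complex_structure` (one pose).
#' @param cdrs A `cdr_annotation` for the nanobody.
#' @param schema A [feature_schema()].
#' @param def An [interface_definition()].
#' @param energy_mode `"missing"` or `"pseudo"`.
#' @param dockq DockQ score of the pose (used by pseudo-energies only).
#' @return Named feature vector conforming to `schema`.
#' @export
featurize_pose <- function(cs, cdrs, schema = feature_schema(c("contact", "property")),
                           def = interface_definition(),
                           energy_mode = c("missing", "pseudo"), dockq = NA_real_) {
  energy_mode <- match.arg(energy_mode)
  iface <- detect_interface(cs, def)
  nb <- residue_table(cs, "nanobody")
  ag <- residue_table(cs, "antigen")
  contact <- contact_features(iface, cdrs, cs)
  pp <- property_profile(nb$code1[iface$paratope])
  pe <- property_profile(ag$code1[iface$epitope])
  rosetta <- foldx <- NULL
  if (energy_mode == "pseudo") {
    rosetta <- pseudo_energy(dockq, rosetta_energy_names())
    foldx <- pseudo_energy(dockq, foldx_energy_names())
  }
  assemble_features(contact = contact, rosetta = rosetta, foldx = foldx,
                    props_paratope = pp, props_epitope = pe, schema = schema)
}

#' Generate a complete synthetic pose dataset
#'
#' Runs [make_native()] and [make_decoys()] for every complex, featurizes all
#' refined poses, and bundles everything into a [pose_dataset()].  With
#' `out_dir` set, also writes per-pose PDB files, the manifest CSV and a
#' ground-truth JSON (CDR spans, labels, planted feature).
#'
#' @param config A [synthetic_config()].
#' @param schema_blocks Feature blocks to compute (default contact +
#'   property; energy blocks use pseudo-fixtures when enabled).
#' @param energy_mode Passed to [featurize_pose()]; default `"pseudo"` when
#'   an energy block is enabled, else `"missing"`.
#' @param out_dir Optional output directory.
#' @param params A [quality_params()].
#' @return A [pose_dataset()] with an extra `truth` element (per-complex CDR
#'   spans and sequences).
#' @export
simulate_dataset <- function(config = synthetic_config(),
                             schema_blocks = c("contact", "property"),
                             energy_mode = NULL, out_dir = NULL,
                             params = quality_params()) {
  schema <- feature_schema(schema_blocks)
  energy_mode <- energy_mode %||%
    (if (any(c("rosetta", "foldx") %in% schema_blocks)) "pseudo" else "missing")
  manifests <- list(); feats <- list(); truth <- list()
  for (ci in seq_len(config$n_complexes)) {
    nat <- make_native(config, ci)
    dec <- make_decoys(nat, config, params)
    mf <- dec$manifest
    fv <- t(vapply(seq_len(nrow(mf)), function(r) {
      featurize_pose(dec$structures[[mf$refined_id[r]]], nat$cdrs,
                     schema = schema, energy_mode = energy_mode,
                     dockq = mf$dockq[r])
    }, numeric(length(schema$columns))))
    manifests[[ci]] <- mf
    feats[[ci]] <- fv
    truth[[nat$complex_id]] <- list(cdr_spans = cdr_spans(nat$cdrs),
                                    sequence = nat$sequence)
    if (!is.null(out_dir)) {
      cdir <- file.path(out_dir, nat$complex_id)
      dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
      write_complex(nat$native, file.path(cdir, "native.pdb"))
      for (rid in names(dec$structures)) {
        write_complex(dec$structures[[rid]], file.path(cdir, paste0(rid, ".pdb")))
      }
    }
  }
  meta <- do.call(rbind, manifests)
  X <- do.call(rbind, feats)
  colnames(X) <- schema$columns
  ds <- pose_dataset(meta, X, schema)
  ds$truth <- truth
  if (!is.null(out_dir)) {
    utils::write.csv(meta, file.path(out_dir, "manifest.csv"), row.names = FALSE)
    jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE)
  }
  ds
}

#' Plant an informative feature signal into a labelled dataset
#'
#' Adds `strength` to one designated property-block feature for native-like
#' (label 1) rows only, recording which feature was shifted.  Used to verify
#' that training, re-ranking and attribution recover a known signal.
#'
#' @param ds A [pose_dataset()].
#' @param strength Shift added to label-1 rows (0 leaves the data unchanged).
#' @param feature Feature column to shift (default `"para_cruciani1"`, a
#'   polarity/hydrophobicity-dominated paratope descriptor sum).
#' @return The dataset with the shift applied and a `planted` element
#'   (`feature`, `strength`).
#' @export
plant_signal <- function(ds, strength, feature = "para_cruciani1") {
  if (!feature %in% colnames(ds$X)) {
    abort(sprintf("feature '%s' not in schema", feature), "nbrank_schema_error")
  }
  ds$X[ds$meta$label == 1, feature] <- ds$X[ds$meta$label == 1, feature] + strength
  ds$planted <- list(feature = feature, strength = strength)
  ds
}
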