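# Helper: rigid perturbation of the nanobody with a recorded transform.
translate_nanobody <- function(cs, shift) {
  at <- cs$atoms
  nb <- at$chain == cs$nanobody_chain
  at[nb, c("x", "y", "z")] <- sweep(as.matrix(at[nb, c("x", "y", "z")]), 2,
                                    shift, `+`)
  nbrank:::new_complex_structure(at, cs$antigen_chain, cs$nanobody_chain)
}

test_that("native contact sets match brute-force enumeration", {
  cfg <- synthetic_config(n_complexes = 1, antigen_length = 30, seed = 2)
  nat <- make_native(cfg, 1)
  expect_equal(native_contacts(nat$native, 5.0),
               brute_contact_pairs(nat$native, 5.0))
  expect_length(native_contacts(nat$native, 0.1), 0)
  far <- translate_nanobody(nat$native, c(500, 0, 0))
  expect_length(native_contacts(far, 5.0), 0)
})

test_that("fnat is 1 for the native, 0 for a far decoy, exact for partial", {
  cfg <- synthetic_config(n_complexes = 1, seed = 2)
  nat <- make_native(cfg, 1)
  expect_equal(fnat(nat$native, nat$native), 1.0)
  expect_equal(fnat(translate_nanobody(nat$native, c(100, 0, 0)), nat$native), 0.0)

  # fraction oracle on a perturbed decoy: preserved pairs counted by hand
  set.seed(4)
  decoy <- nbrank:::perturb_nanobody(nat$native, 2.5, 10)
  nat_pairs <- brute_contact_pairs(nat$native, 5.0)
  dec_pairs <- brute_contact_pairs(decoy, 5.0)
  expect_equal(fnat(decoy, nat$native),
               length(intersect(dec_pairs, nat_pairs)) / length(nat_pairs))

  # degenerate native: separated chains
  far_native <- translate_nanobody(nat$native, c(200, 0, 0))
  expect_error(fnat(nat$native, far_native), class = "nbrank_degenerate_native")
})

test_that("lrms equals the applied rigid translation after receptor fit", {
  cfg <- synthetic_config(n_complexes = 1, seed = 6)
  nat <- make_native(cfg, 1)
  expect_equal(lrms(nat$native, nat$native), 0, tolerance = 1e-9)
  moved <- translate_nanobody(nat$native, c(6, 0, 0))
  expect_equal(lrms(moved, nat$native), 6, tolerance = 1e-6)
  moved2 <- translate_nanobody(nat$native, c(3, 4, 0))
  expect_equal(lrms(moved2, nat$native), 5, tolerance = 1e-6)
})

test_that("irms and lrms agree with the quaternion oracle on random decoys", {
  cfg <- synthetic_config(n_complexes = 1, seed = 8)
  nat <- make_native(cfg, 1)
  expect_equal(irms(nat$native, nat$native), 0, tolerance = 1e-9)
  set.seed(15)
  params <- quality_params()
  iface_keys <- nbrank:::interface_residue_keys(nat$native, params$iface_cutoff)
  for (i in 1:5) {
    decoy <- nbrank:::perturb_nanobody(nat$native, runif(1, 1, 20), runif(1, 5, 90))
    mb <- nbrank:::matched_backbone(decoy, nat$native, iface_keys)
    expect_equal(irms(decoy, nat$native),
                 quaternion_rmsd(mb$model, mb$native), tolerance = 1e-6)
    # lrms oracle: receptor fit computed independently, then plain rmsd
    rec <- nbrank:::matched_backbone(decoy, nat$native,
                                     residue_table(nat$native, "antigen")$key)
    lig <- nbrank:::matched_backbone(decoy, nat$native,
                                     residue_table(nat$native, "nanobody")$key)
    fit <- superpose(rec$model, rec$native)
    expect_equal(lrms(decoy, nat$native),
                 nbrank:::rmsd_plain(apply_transform(lig$model, fit), lig$native),
                 tolerance = 1e-6)
  }
})

test_that("dockq_score matches its closed form at anchor points", {
  expect_equal(dockq_score(1, 0, 0), 1.0)
  expect_equal(dockq_score(0.5, 1.5, 8.5), 0.5)  # each term is 0.5
  expect_lt(dockq_score(0, 1e9, 1e9), 1e-6)
})

test_that("pose labels and CAPRI bands follow the 0.23/0.49/0.80 cuts", {
  expect_equal(label_pose(0.10), list(label = 0L, capri = "Incorrect"))
  expect_equal(label_pose(0.23), list(label = 1L, capri = "Acceptable"))
  expect_equal(label_pose(0.60), list(label = 1L, capri = "Medium"))
  expect_equal(label_pose(0.2299999), list(label = 0L, capri = "Incorrect"))
  expect_equal(label_pose(0.85), list(label = 1L, capri = "High"))
  expect_equal(label_pose(1.0)$capri, "High")
  expect_error(label_pose(1.2), class = "nbrank_domain_error")
  expect_error(label_pose(-0.1), class = "nbrank_domain_error")
})

test_that("dockq decreases monotonically with pure translation magnitude", {
  cfg <- synthetic_config(n_complexes = 1, seed = 10)
  nat <- make_native(cfg, 1)
  qs <- vapply(c(0.5, 1, 2, 4, 8, 16, 32), function(t) {
    pose_quality(translate_nanobody(nat$native, c(0, t, 0)), nat$native)$dockq
  }, numeric(1))
  expect_true(all(diff(qs) < 0))
  expect_equal(pose_quality(nat$native, nat$native)$dockq, 1.0)
})

test_that("labels partition any pose set", {
  cfg <- synthetic_config(n_complexes = 1, parents_per_complex = 5,
                          refined_per_parent = 2, seed = 12)
  nat <- make_native(cfg, 1)
  dec <- make_decoys(nat, cfg)
  expect_equal(sum(dec$manifest$label == 0) + sum(dec$manifest$label == 1),
               nrow(dec$manifest))
})

test_that("batch quality_table reproduces per-pose assessment from disk", {
  cfg <- synthetic_config(n_complexes = 1, parents_per_complex = 2,
                          refined_per_parent = 2, seed = 14)
  nat <- make_native(cfg, 1)
  dec <- make_decoys(nat, cfg)
  dir <- withr::local_tempdir()
  native_path <- file.path(dir, "native.pdb")
  write_complex(nat$native, native_path)
  mf <- dec$manifest
  mf$model_path <- vapply(mf$refined_id, function(r) {
    p <- file.path(dir, paste0(r, ".pdb"))
    write_complex(dec$structures[[r]], p)
    p
  }, character(1))
  mf$native_path <- native_path
  out <- file.path(dir, "quality.csv")
  qt <- quality_table(mf, out = out)
  expect_equal(qt$label, mf$label)
  expect_equal(qt$dockq, mf$dockq, tolerance = 1e-3)  # PDB coordinate precision
  expect_true(file.exists(out))
  expect_equal(utils::read.csv(out)$refined_id, mf$refined_id)
})
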