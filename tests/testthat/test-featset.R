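test_that("schema modes have the expected column counts and blocks", {
  full <- feature_schema()
  expect_length(full$columns, 248)
  expect_equal(as.numeric(table(factor(full$block, levels = full$blocks))),
               c(52, 20, 44, 132))
  expect_false(anyDuplicated(full$columns) > 0)
  expect_length(feature_schema("contact")$columns, 52)
  expect_length(feature_schema("property")$columns, 132)
  expect_length(feature_schema(c("contact", "property"))$columns, 184)
  # blocks are re-ordered canonically regardless of request order
  expect_equal(feature_schema(c("property", "contact"))$blocks,
               c("contact", "property"))
})

test_that("descriptor table has 10 families of the canonical sizes", {
  fam <- descriptor_families()
  expect_equal(sum(fam), 66)
  expect_equal(unname(fam[c("cruciani", "kidera", "zscales", "blosum")]),
               c(3L, 10L, 5L, 10L))
  tab <- aa_descriptor_table()
  expect_equal(dim(tab), c(20L, 66L))
  expect_true(all(is.finite(tab)))
  expect_equal(rownames(tab), sort(rownames(tab)))
  # every family's columns are present in declared sizes
  for (f in names(fam)) {
    expect_length(grep(paste0("^", f, "[0-9]+$"), colnames(tab)), fam[[f]])
  }
  # deterministic across calls
  expect_identical(tab, aa_descriptor_table())
})

test_that("property profiles are table-row sums and additive", {
  tab <- aa_descriptor_table()
  expect_equal(property_profile(character(0)), setNames(numeric(66), colnames(tab)))
  expect_equal(unname(property_profile("A")), unname(tab["A", ]))
  expect_equal(unname(property_profile(c("A", "G"))),
               unname(tab["A", ] + tab["G", ]))
  # X contributes nothing
  expect_equal(property_profile(c("A", "X")), property_profile("A"))
  # additivity over a random partition
  set.seed(3)
  codes <- sample(rownames(tab), 30, replace = TRUE)
  expect_equal(property_profile(codes),
               property_profile(codes[1:11]) + property_profile(codes[12:30]))
})

test_that("Rosetta score files parse by column name", {
  f <- withr::local_tempfile(fileext = ".sc")
  writeLines(c(
    "SEQUENCE: ",
    "SCORE: total_score complex_normalized dG_cross dG_cross/dSASAx100 dG_separated dSASA_int packstat sc_value mystery description",
    "SCORE:     -310.52    -1.99   -15.40    -2.31   -12.30   666.0   0.65   0.71  9.9 pose_0001"
  ), f)
  r <- parse_rosetta_scores(f)
  expect_named(r, rosetta_energy_names())
  expect_equal(unname(r["dG_separated"]), -12.3)
  expect_equal(unname(r["dG_cross/dSASAx100"]), -2.31)
  expect_equal(unname(r["packstat"]), 0.65)
  expect_true(is.na(r["hbond_E_fraction"]))  # absent -> explicit missing
  expect_false("mystery" %in% names(r))

  header_only <- withr::local_tempfile(fileext = ".sc")
  writeLines("SCORE: total_score dG_separated description", header_only)
  expect_error(parse_rosetta_scores(header_only), class = "nbrank_parse_error")
})

test_that("FoldX AnalyseComplex tables parse with banner lines and gaps", {
  f <- withr::local_tempfile(fileext = ".fxout")
  hdr <- c("Pdb", "Group1", "Group2", "IntraclashesGroup1", "IntraclashesGroup2",
           "Interaction Energy", "Backbone Hbond", "Sidechain Hbond",
           "Van der Waals", "Electrostatics")
  writeLines(c(
    "FoldX interaction analysis banner",
    "",
    paste(hdr, collapse = "\t"),
    paste(c("model.pdb", "A", "H", "1.21", "0.87", "-8.7", "-1.1", "-0.4",
            "-6.2", "-0.8"), collapse = "\t")
  ), f)
  x <- parse_foldx_complex(f)
  expect_named(x, foldx_energy_names())
  expect_equal(unname(x["interaction_energy"]), -8.7)
  expect_equal(unname(x["intraclashes_group1"]), 1.21)
  expect_equal(unname(x["van_der_waals"]), -6.2)
  # columns absent from the file are explicitly missing, populated ones not
  expect_equal(sum(!is.na(x)), 7)
  expect_true(all(is.na(x[c("solvation_polar", "entropy_complex",
                            "total_energy_group1")])))

  empty <- withr::local_tempfile(fileext = ".fxout")
  writeLines("just a banner", empty)
  expect_error(parse_foldx_complex(empty), class = "nbrank_parse_error")
})

test_that("energy parsing is lossless through re-serialization", {
  f <- withr::local_tempfile(fileext = ".sc")
  set.seed(8)
  vals <- round(rnorm(20), 3)
  writeLines(c(
    paste("SCORE:", paste(rosetta_energy_names(), collapse = " "), "description"),
    paste("SCORE:", paste(vals, collapse = " "), "pose_1")
  ), f)
  r <- parse_rosetta_scores(f)
  f2 <- withr::local_tempfile(fileext = ".sc")
  writeLines(c(
    paste("SCORE:", paste(names(r), collapse = " "), "description"),
    paste("SCORE:", paste(unname(r), collapse = " "), "pose_1")
  ), f2)
  expect_equal(parse_rosetta_scores(f2), r)
  expect_equal(unname(r), vals)
})

test_that("assemble_features enforces the schema and preserves missingness", {
  cfg <- synthetic_config(n_complexes = 1, seed = 20)
  nat <- make_native(cfg, 1)
  iface <- detect_interface(nat$native)
  contact <- contact_features(iface, nat$cdrs, nat$native)
  pp <- property_profile(residue_table(nat$native, "nanobody")$code1[iface$paratope])
  pe <- property_profile(residue_table(nat$native, "antigen")$code1[iface$epitope])

  full <- assemble_features(contact = contact, rosetta = NULL, foldx = NULL,
                            props_paratope = pp, props_epitope = pe,
                            schema = feature_schema())
  expect_length(full, 248)
  expect_equal(names(full), feature_schema()$columns)
  expect_equal(sum(is.na(full)), 64)  # both energy blocks missing

  cp <- assemble_features(contact = contact, props_paratope = pp,
                          props_epitope = pe,
                          schema = feature_schema(c("contact", "property")))
  expect_length(cp, 184)
  expect_equal(sum(is.na(cp)), 0)

  expect_error(assemble_features(contact = contact[-1], props_paratope = pp,
                                 props_epitope = pe,
                                 schema = feature_schema(c("contact", "property"))),
               class = "nbrank_schema_error")
  expect_error(assemble_features(props_paratope = pp, props_epitope = pe,
                                 schema = feature_schema(c("contact", "property"))),
               class = "nbrank_schema_error")
})

test_that("pose datasets validate identity uniqueness and schema", {
  ds <- toy_dataset(n_complexes = 3, poses_per_complex = 4)
  expect_s3_class(ds, "pose_dataset")
  meta2 <- ds$meta; meta2[2, ] <- meta2[1, ]
  expect_error(pose_dataset(meta2, ds$X, ds$schema),
               class = "nbrank_invalid_argument")
  expect_error(pose_dataset(ds$meta, ds$X[, -1], ds$schema),
               class = "nbrank_schema_error")
  # CSV + JSON sidecar round trip
  dir <- withr::local_tempdir()
  paths <- write_pose_dataset(ds, file.path(dir, "toy"))
  expect_true(all(file.exists(paths)))
  sc <- jsonlite::fromJSON(paths["schema"])
  expect_equal(sc$columns, ds$schema$columns)
  back <- utils::read.csv(paths["features"], check.names = FALSE)
  expect_equal(as.matrix(back[, ds$schema$columns]), ds$X,
               ignore_attr = TRUE, tolerance = 1e-12)
})
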