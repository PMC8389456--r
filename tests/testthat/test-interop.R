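test_that("Dynamo particles export to RELION coordinates with shifts folded in", {
  tbl <- new_dynamo_rows(1)
  m <- unclass(tbl)
  m[1, 24:26] <- c(100, 110, 50)
  m[1, 4:6] <- c(0.5, -0.5, 0)
  tbl <- dynamo_table(m)
  doc <- dynamo_to_relion(tbl, coordinate_scale = 1)
  df <- star_table(doc)
  expect_equal(df$rlnCoordinateX, 100.5)
  expect_equal(df$rlnCoordinateY, 109.5)
  expect_equal(df$rlnCoordinateZ, 50)
  # zero Dynamo angles map to an identity rotation in RELION terms
  ang <- as.matrix(df[c("rlnAngleRot", "rlnAngleTilt", "rlnAnglePsi")])
  expect_lt(max(abs(euler_to_matrix("relion", ang) - diag(3))), 1e-10)
  # scale factor multiplies coordinates
  df2 <- star_table(dynamo_to_relion(tbl, coordinate_scale = 4))
  expect_equal(df2$rlnCoordinateX, 402)
})

test_that("unmapped tomogram ids are reported", {
  tbl <- random_dynamo_table(3, 6)
  expect_error(dynamo_to_relion(tbl, tomogram_map = c("99" = "a.tomostar")),
               "no micrograph name mapped")
})

test_that("dynamo -> relion -> dynamo round trip preserves geometry", {
  tbl <- random_dynamo_table(17, 200)
  doc <- dynamo_to_relion(tbl, coordinate_scale = 2)
  # through actual STAR text, not just in memory
  doc2 <- read_star(write_star(doc))
  back <- relion_to_dynamo(doc2, coordinate_scale = 2)
  combined <- dyn_positions(tbl) + dyn_shifts(tbl)
  expect_lt(max(abs(dyn_positions(back) - combined)), 1e-6)
  expect_equal(unname(dyn_shifts(back)), matrix(0, nrow(tbl), 3))
  R1 <- euler_to_matrix("dynamo", dyn_angles(tbl))
  R2 <- euler_to_matrix("dynamo", dyn_angles(back))
  expect_lt(max(abs(R1 - R2)), 1e-8)
  expect_equal(dyn_tomogram(back), dyn_tomogram(tbl))
})

test_that("documents without the required tags are refused", {
  doc <- star_document(list(star_loop_block(data.frame(rlnCoordinateX = 1))))
  expect_error(relion_to_dynamo(doc), "rlnCoordinateY")
  expect_error(relion_to_dynamo(doc), "rlnAngleRot")
})

test_that("star_downgrade flattens optics groups into particle rows", {
  flat <- star_downgrade(star31_fixture())
  expect_length(flat$blocks, 1)
  df <- star_table(flat)
  expect_equal(nrow(df), 3)
  # per-row acquisition fields follow each particle's optics group
  expect_equal(df$rlnImagePixelSize, c(1.35, 2.7, 1.35))
  expect_equal(df$rlnVoltage, rep(300, 3))
  # Angstrom origins become pixel origins via the group pixel size
  expect_equal(df$rlnOriginX, c(2, 2, -2))
  expect_false("rlnOriginXAngst" %in% names(df))
  expect_false("rlnOpticsGroup" %in% names(df))
  # particle order preserved
  expect_equal(df$rlnCoordinateX, c(10, 20, 30))
})

test_that("star_downgrade is idempotent and flags broken references", {
  flat <- star_downgrade(star31_fixture())
  expect_identical(star_downgrade(flat), flat)
  broken <- star31_fixture()
  broken$blocks$particles$data$rlnOpticsGroup[2] <- "7"
  expect_error(star_downgrade(broken), "absent optics group")
})

test_that("Tomography 5 filenames parse to their fields", {
  p <- parse_tomo5_filename("TS01_003[-12.00]_fractions.mrc")
  expect_equal(p$basename, "TS01")
  expect_equal(p$count, 3L)
  expect_equal(p$tilt_angle, -12)
  expect_equal(parse_tomo5_filename("TS01_000[0.00]_fractions.mrc")$tilt_angle, 0)
  # Unicode minus and extra suffix text are tolerated
  expect_equal(
    parse_tomo5_filename("Pos_2_0012[−24.50]_fractions_ali.mrc")$tilt_angle,
    -24.5)
  expect_error(parse_tomo5_filename("TS01_003_fractions.mrc"),
               "does not match")
})

test_that("rendered filenames parse back to their fields", {
  set.seed(20)
  for (i in 1:25) {
    base <- paste0("TS", sample(99, 1))
    count <- sample(0:999, 1)
    tilt <- round(runif(1, -60, 60), 2)
    name <- render_tomo5_filename(base, count, tilt)
    p <- parse_tomo5_filename(name)
    expect_equal(p$basename, base)
    expect_equal(p$count, count)
    expect_equal(p$tilt_angle, tilt)
    expect_equal(p$original_name, name)
  }
})

test_that("mdoc spoofing groups interleaved basenames and orders by count", {
  files <- c("TS_A_000[0.00]_fractions.mrc",
             "TS_B_000[0.00]_fractions.mrc",
             "TS_A_001[3.00]_fractions.mrc",
             "TS_B_001[-3.00]_fractions.mrc",
             "TS_A_002[-3.00]_fractions.mrc")
  docs <- spoof_mdoc(files, pixel_spacing = 1.35, voltage = 300, dose = 3.2)
  expect_equal(sort(names(docs)), c("TS_A", "TS_B"))
  expect_equal(mdoc_tilt_angles(docs$TS_A), c(0, 3, -3))
  expect_equal(mdoc_tilt_angles(docs$TS_B), c(0, -3))
  expect_equal(docs$TS_A$header[["PixelSpacing"]], "1.35")
  expect_equal(vapply(docs$TS_A$sections, `[[`, "", "SubFramePath"),
               files[c(1, 3, 5)])
  # outputs re-read losslessly
  for (d in docs) expect_identical(read_mdoc(write_mdoc(d)), d)
})

test_that("unparseable listings are skipped with a summary warning", {
  expect_warning(
    docs <- spoof_mdoc(c("TS_A_000[0.00]_fractions.mrc", "junk.mrc"), 1),
    "skipped 1 file")
  expect_length(docs, 1)
  expect_length(spoof_mdoc(character(), 1), 0)
})

test_that("pose sets round-trip through Dynamo tables at the matrix level", {
  ps <- seed_sphere(c(50, 60, 70), 40, 15, tomogram = 2L, seed = 5)
  ps$score <- runif(length(ps))
  tbl <- poses_to_dynamo_table(ps)
  expect_equal(unname(dyn_positions(tbl)), unname(ps$positions))
  back <- poses_from_dynamo_table(tbl)
  expect_lt(max(abs(back$orientations - ps$orientations)), 1e-8)
  expect_equal(back$tomogram, rep(2, length(ps)))
  expect_equal(back$score, ps$score)
})

test_that("annotation files parse from text and JSON", {
  txt <- tempfile(); js <- tempfile(fileext = ".json")
  on.exit(unlink(c(txt, js)))
  writeLines(c("0 0 0", "10 0 0"), txt)
  expect_equal(read_sphere_annotation(txt)$radius, 10)
  jsonlite::write_json(list(center = c(1, 2, 3),
                            edge_point = c(4, 6, 3)), js,
                       auto_unbox = TRUE)
  expect_equal(read_sphere_annotation(js)$radius, 5)
  surf <- tempfile()
  on.exit(unlink(surf), add = TRUE)
  writeLines(c("0 0 0", "10 0 0", "10 10 0", "0 10 0", "",
               "0 0 20", "10 0 20", "10 10 20", "0 10 20"), surf)
  slices <- read_surface_annotation(surf)
  expect_length(slices, 2)
  mesh <- mesh_from_annotation(slices)
  expect_equal(nrow(mesh$faces), 8)
})
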