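toy_structure <- function(vel = FALSE) {
  out <- tibble::tibble(
    resid = c(1L, 1L, 2L, 3L),
    resname = c("SOL", "SOL", "NA", "CL"),
    name = c("OW", "HW1", "NA", "CL"),
    atomnum = 1:4,
    x = c(1.0, 1.05, 2.0, 0.5),
    y = c(2.0, 2.05, 1.0, 0.25),
    z = c(3.0, 3.05, 3.0, 7.5)
  )
  if (vel) {
    out$vx <- c(0.1, -0.2, 0.3, 0)
    out$vy <- c(0, 0.5, -0.25, 0.1)
    out$vz <- c(0.01, 0.02, -0.03, 0)
  }
  out <- tibble::new_tibble(out, class = "fb_structure")
  attr(out, "title") <- "toy system"
  attr(out, "box") <- c(3, 3, 8)
  out
}

test_that("GRO write -> read -> write round trip is byte-stable", {
  for (vel in c(FALSE, TRUE)) {
    s <- toy_structure(vel)
    f1 <- withr::local_tempfile(fileext = ".gro")
    f2 <- withr::local_tempfile(fileext = ".gro")
    write_gro(s, f1)
    s2 <- read_gro(f1)
    write_gro(s2, f2)
    expect_identical(readLines(f1), readLines(f2))
    expect_equal(s2$z, s$z, tolerance = 1e-9)
    expect_identical(attr(s2, "box")[1:3], c(3, 3, 8))
    if (vel) expect_equal(s2$vz, s$vz, tolerance = 1e-9)
  }
})

test_that("malformed GRO files are rejected", {
  f <- withr::local_tempfile(fileext = ".gro")
  writeLines(c("title only"), f)
  expect_error(read_gro(f), "malformed")
  writeLines(c("t", "nonsense", "junk"), f)
  expect_error(read_gro(f), "atom-count")
  writeLines(c("t", "    5", "    1SOL     OW    1   1.000   2.000   3.000"), f)
  expect_error(read_gro(f), "truncated")
})

test_that("reference coordinates zero exactly the z column", {
  s <- toy_structure(vel = TRUE)
  ref <- make_reference_coordinates(s, c("NA", "CL"))
  expect_equal(ref$z, c(3.0, 3.05, 0, 0))
  expect_equal(ref$x, s$x)
  expect_equal(ref$vz, s$vz)
  # idempotence
  expect_identical(make_reference_coordinates(ref, c("NA", "CL")), ref)
  expect_error(make_reference_coordinates(s, "K"), "no atoms")

  # byte-level: only columns 37-44 of selected atom lines may change
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_gro(s, f1)
  reference_coordinate_file(f1, f2, c("NA", "CL"))
  a <- readLines(f1)
  b <- readLines(f2)
  expect_identical(a[c(1, 2, 3, 4, 7)], b[c(1, 2, 3, 4, 7)])
  for (ln in 5:6) {
    expect_identical(substr(a[ln], 1, 36), substr(b[ln], 1, 36))
    expect_identical(substr(b[ln], 37, 44), "   0.000")
    expect_identical(substr(a[ln], 45, nchar(a[ln])),
                     substr(b[ln], 45, nchar(b[ln])))
  }
  # the tibble-level and file-level paths agree byte for byte
  f3 <- withr::local_tempfile()
  write_gro(make_reference_coordinates(read_gro(f1), c("NA", "CL")), f3)
  expect_identical(readLines(f2), readLines(f3))
})

test_that("restraint stanza reproduces the canonical line and re-parses", {
  fb <- flat_bottom_restraint(r = 0.3, k = 10000)
  txt <- emit_restraint_stanza(fb, "NA", 1L)
  lines <- strsplit(txt, "\n")[[1]]
  expect_true("[ position_restraints ]" %in% lines)
  expect_identical(lines[length(lines)], "1 2 5 -0.3 10000")
  # heavy-atom list for a larger molecule
  txt2 <- emit_restraint_stanza(fb, "PEP", c(1L, 5L, 9L))
  body <- parse_restraint_stanza(txt2)
  expect_equal(body$i, c(1L, 5L, 9L))
  expect_equal(body$r, rep(0.3, 3))
  expect_equal(body$k, rep(10000, 3))
  expect_equal(body$funct, rep(2L, 3))
  expect_equal(body$geometry, rep(5L, 3))
  # large k must not switch to scientific notation
  txt3 <- emit_restraint_stanza(flat_bottom_restraint(r = 0.5, k = 1e5), "K")
  expect_match(txt3, "1 2 5 -0.5 100000", fixed = TRUE)
  expect_warning(out <- emit_restraint_stanza(fb, "NA", integer(0)), "empty")
  expect_equal(nrow(parse_restraint_stanza(out)), 0L)
  expect_error(emit_restraint_stanza(
    flat_bottom_restraint(r = 0.3, k = 1, inverted = FALSE), "NA"), "inverted")
})

test_that("extra-water recommendation follows the slab-volume estimate", {
  fb <- flat_bottom_restraint(r = 0.3, k = 10000)
  rec <- recommend_extra_water(c(3, 3, 8), fb)
  expect_equal(rec$thickness_per_side, 0.3)
  expect_equal(rec$n_water, 180L)
  rec4 <- recommend_extra_water(c(6, 6, 8), fb)
  expect_equal(rec4$n_water, 4L * rec$n_water)
  s <- toy_structure()
  expect_equal(recommend_extra_water(s, fb)$n_water, 180L)
})

test_that("ion-side validation catches misplaced ions", {
  fb <- flat_bottom_restraint(r = 0.3, k = 10000)
  s <- toy_structure()   # NA at z = 3 (lower), CL at z = 7.5 (upper)
  v <- validate_ion_sides(s, c("NA" = "lower", "CL" = "upper"),
                          membrane_z = c(3.5, 5.5), restraint = fb)
  expect_true(v$pass)
  v2 <- validate_ion_sides(s, c("NA" = "upper", "CL" = "upper"),
                           membrane_z = c(3.5, 5.5), restraint = fb)
  expect_false(v2$pass)
  expect_equal(v2$issues$issue, "wrong_side")
  expect_equal(v2$issues$atomnum, 3L)
  # an ion inside the restrained slab would start on the barrier
  s3 <- toy_structure()
  s3$z[4] <- 7.8
  v3 <- validate_ion_sides(s3, c("CL" = "upper"), c(3.5, 5.5), fb)
  expect_false(v3$pass)
  expect_true("inside_restrained_region" %in% v3$issues$issue)
  # an ion buried in the membrane
  s4 <- toy_structure()
  s4$z[3] <- 4.0
  v4 <- validate_ion_sides(s4, c("NA" = "lower"), c(3.5, 5.5), fb)
  expect_false(v4$pass)
  expect_true("inside_membrane" %in% v4$issues$issue)
  expect_error(validate_ion_sides(s, c("K" = "lower"), c(3.5, 5.5), fb),
               "unknown species")
  expect_match(v$notes, "refcoord_scaling")
})

test_that("prep_bundle assembles reference, stanzas and validation", {
  fb <- flat_bottom_restraint(r = 0.3, k = 10000)
  s <- toy_structure()
  b <- prep_bundle(s, fb, restrained = c("NA", "CL"),
                   side_map = c("NA" = "lower", "CL" = "upper"),
                   membrane_z = c(3.5, 5.5))
  expect_equal(b$reference$z[3:4], c(0, 0))
  expect_named(b$stanzas, c("NA", "CL"))
  expect_match(b$stanzas[["NA"]], "1 2 5 -0.3 10000", fixed = TRUE)
  expect_true(b$validation$pass)
  expect_equal(b$extra_water$n_water, 180L)
})
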