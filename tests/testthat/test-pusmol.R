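test_that("command lines parse per the grammar, with diagnostics", {
  cmd <- parse_command("add methyl 3")
  expect_identical(cmd$verb, "add")
  expect_identical(cmd$kind, "METHYL")
  expect_identical(cmd$uid, 3L)
  cmd <- parse_command("setangle 3 45.5")
  expect_identical(cmd$uid, 3L)
  expect_equal(cmd$angle, 45.5)
  expect_null(parse_command("   # just a comment"))
  expect_null(parse_command(""))
  expect_error(parse_command("add unobtainium 9"), "unknown part kind")
  expect_error(parse_command("warp 1", line_no = 7L), "line 7.*unknown verb")
  expect_error(parse_command("add methyl"), "takes 2 argument")
  expect_error(parse_command("setangle three 5"), "expected an integer")
})

test_that("sessions record only successful scene-mutating commands", {
  ses <- pusmol_session()
  ses <- execute_command(ses, parse_command("add alpha_carbon 1"))
  ses <- execute_command(ses, parse_command("add methyl 2"))
  ses <- execute_command(ses, parse_command("link 1 2 2 0"))
  expect_error(execute_command(ses, parse_command("add methyl 2")),
               "already present")
  expect_error(execute_command(ses, parse_command("link 1 2 2 0")))
  expect_length(ses$history, 3L)
  path <- withr::local_tempfile(fileext = ".pusmol")
  save_pusmol(ses, path)
  expect_identical(readLines(path), ses$history)
  replay <- load_pusmol(path)
  expect_same_scene(replay$scene, ses$scene)
})

test_that("save/load round-trips arbitrary generated scenes", {
  for (seed in c(2, 17)) {
    ses <- run_script(make_backbone(3, seed = seed))
    path <- withr::local_tempfile(fileext = ".pusmol")
    save_pusmol(ses, path)
    expect_same_scene(load_pusmol(path)$scene, ses$scene)
  }
  # empty history loads to an empty scene
  path <- withr::local_tempfile(fileext = ".pusmol")
  save_pusmol(pusmol_session(), path)
  expect_length(load_pusmol(path)$scene$parts, 0L)
})

test_that("script errors abort with their line number", {
  expect_error(run_script(c("add methyl 1", "link 1 0 99 0")),
               "line 2")
})

test_that("programmatic generation builds long backbones", {
  ses <- run_script(make_backbone(20, seed = 5))
  kinds <- vapply(ses$scene$parts, `[[`, character(1), "kind")
  expect_identical(sum(kinds == "ALPHA_CARBON"), 20L)
  expect_length(ses$scene$roots, 1L)
  # the session's own record replays to the same scene
  expect_same_scene(run_script(ses$history)$scene, ses$scene)
  # empty program leaves the session untouched
  expect_length(run_script(character())$scene$parts, 0L)
})

test_that("script replay is deterministic down to the PDB text", {
  lines <- make_backbone(5, seed = 13)
  pdb1 <- export_structure(run_script(lines)$scene)
  pdb2 <- export_structure(run_script(lines)$scene)
  expect_identical(pdb1, pdb2)
})

test_that("export converts model millimetres to Angstrom at the given scale", {
  # a part whose single atom sits 18.7 mm along +X must export at 1.000 A
  geo <- default_geometry()
  geo$parts$METHYL$atoms <- data.frame(symbol = "Cr", x = 18.7, y = 0,
                                       z = 0, radius = 13)
  s <- add_part(scene_new(geo), "METHYL", 1)
  lines <- export_structure(s, scale_mm_per_angstrom = 18.7)
  atom <- grep("^ATOM", lines, value = TRUE)[1]
  expect_equal(as.numeric(substr(atom, 31, 38)), 1.000, tolerance = 1e-6)
  expect_equal(as.numeric(substr(atom, 39, 46)), 0.000, tolerance = 1e-6)
  # atom at the origin exports at the origin
  s0 <- add_part(scene_new(), "METHYL", 1)
  a0 <- grep("^ATOM", export_structure(s0), value = TRUE)[1]
  expect_equal(as.numeric(substr(a0, 31, 38)), 0, tolerance = 1e-6)
  # halving the scale doubles every coordinate
  sc <- run_script(make_backbone(2, seed = 3))$scene
  xyz <- function(scale) {
    at <- grep("^ATOM", export_structure(sc, scale_mm_per_angstrom = scale),
               value = TRUE)
    vapply(at, function(l) as.numeric(c(substr(l, 31, 38), substr(l, 39, 46),
                                        substr(l, 47, 54))),
           numeric(3), USE.NAMES = FALSE)
  }
  expect_equal(xyz(9.35), 2 * xyz(18.7), tolerance = 1e-2)
  expect_error(export_structure(scene_new()), "empty")
})

test_that("exported inter-atom distances equal model distances over the scale", {
  sc <- run_script(make_backbone(2, seed = 23))$scene
  coords <- do.call(rbind, world_coordinates(sc))
  model_d <- as.numeric(dist(coords[, c("x", "y", "z")])) / 18.7
  path <- withr::local_tempfile(fileext = ".pdb")
  export_structure(sc, file = path)
  pdb <- bio3d::read.pdb(path)   # independent fixed-column parse
  xyz <- matrix(pdb$xyz, ncol = 3, byrow = TRUE)
  # same atom count; distances agree to PDB's 3-decimal precision
  expect_identical(nrow(xyz), nrow(coords))
  pdb_d <- as.numeric(dist(xyz))
  expect_equal(sort(pdb_d), sort(model_d), tolerance = 1e-2)
  # programming symbols Cr/Ca export as element C
  expect_true(all(pdb$atom$elesy %in% c("C", "N", "O", "H")))
})
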