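test_that("parts are added as roots with unique uids", {
  s <- scene_new()
  s <- add_part(s, "METHYL", 3)
  expect_length(s$parts, 1L)
  expect_identical(s$roots, 3L)
  expect_error(add_part(s, "AMIDE", 3), "already present")
  for (u in 10:14) s <- add_part(s, "ALPHA_CARBON", u)
  expect_length(s$parts, 6L)
  expect_length(s$roots, 6L)
})

test_that("linking places the child with anti-parallel shaft axes", {
  s <- build_pentamer()
  fr <- world_frames(s)
  for (u in linked_uids(s)) {
    p <- s$parts[[as.character(u)]]
    pl <- p$parent_link
    parent <- s$parts[[as.character(pl$parent_uid)]]
    pf <- Filter(function(f) f$face_id == pl$parent_face_id, parent$faces)[[1]]
    cf <- Filter(function(f) f$face_id == pl$own_face_id, p$faces)[[1]]
    ax_p <- as.numeric(fr[[as.character(pl$parent_uid)]]$R %*% pf$axis)
    ax_c <- as.numeric(fr[[as.character(u)]]$R %*% cf$axis)
    expect_equal(sum(ax_p * ax_c), -1, tolerance = 1e-9)
  }
  # and stays anti-parallel for arbitrary joint angles
  set.seed(4)
  for (u in linked_uids(s)) s <- set_joint_angle(s, u, runif(1, 0, 360))
  fr <- world_frames(s)
  u <- 4L  # the amide junction
  pf <- s$parts[["1"]]$faces[[2]]
  cf <- s$parts[["4"]]$faces[[1]]
  expect_equal(sum(as.numeric(fr[["1"]]$R %*% pf$axis) *
                     as.numeric(fr[["4"]]$R %*% cf$axis)),
               -1, tolerance = 1e-9)
})

test_that("link enforces chemistry, occupancy and topology rules", {
  s <- scene_new()
  s <- add_part(s, "METHYL", 1)
  s <- add_part(s, "METHYL", 2)
  expect_error(link(s, 1, 0, 2, 0), "chemistry")
  s <- add_part(s, "ALPHA_CARBON", 3)
  s <- link(s, 3, 2, 1, 0)
  # occupied parent face
  expect_error(link(s, 3, 2, 2, 0), "occupied")
  # child not a root
  s <- add_part(s, "ALPHA_CARBON", 4)
  expect_error(link(s, 4, 2, 1, 0), "not a sub-chain root")
})

test_that("one valid cross-chain link merges two sub-chains", {
  # two separately built sub-chains (the multi-protein workflow)
  s <- scene_new()
  s <- add_part(s, "ALPHA_CARBON", 1)
  s <- add_part(s, "N_TERM", 2)
  s <- link(s, 1, 0, 2, 0)
  s <- add_part(s, "AMIDE", 10)
  s <- add_part(s, "ALPHA_CARBON", 11)
  s <- link(s, 10, 1, 11, 0)
  expect_length(s$roots, 2L)
  s <- link(s, 1, 1, 10, 0)   # alpha C-side face hosts the amide C face
  expect_length(s$roots, 1L)
  expect_identical(peppytwin:::.root_of(s, 11), 1L)
})

test_that("rigid-body distances are invariant under any joint configuration", {
  s <- build_pentamer()
  ref <- intra_part_distances(world_coordinates(s))
  set.seed(21)
  for (rep in 1:10) {
    for (u in linked_uids(s)) s <- set_joint_angle(s, u, runif(1, 0, 360))
    expect_equal(intra_part_distances(world_coordinates(s)), ref,
                 tolerance = 1e-9)
  }
})

test_that("joint angles are absolute and periodic", {
  s <- build_pentamer()
  ref <- world_coordinates(set_joint_angle(s, 4, 0))
  full <- world_coordinates(set_joint_angle(s, 4, 360))
  expect_equal(full, ref, tolerance = 1e-9)
  a <- set_joint_angle(set_joint_angle(s, 4, 120), 4, 300)
  b <- set_joint_angle(s, 4, 300)
  expect_same_scene(a, b)
  expect_error(set_joint_angle(s, 1, 10), "no joint")
})

test_that("rotating a mid-chain joint moves only its descendants", {
  s <- build_pentamer()
  before <- world_coordinates(s)
  after <- world_coordinates(set_joint_angle(s, 4, 77))
  # descendants of the amide junction: 4 and 5
  expect_equal(after[["1"]], before[["1"]], tolerance = 1e-12)
  expect_equal(after[["2"]], before[["2"]], tolerance = 1e-12)
  expect_equal(after[["3"]], before[["3"]], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(after[["5"]], before[["5"]],
                                tolerance = 1e-6)))
})

test_that("the scene stays a forest reachable from its roots", {
  session <- run_script(make_backbone(4, seed = 9))
  s <- session$scene
  seen <- integer()
  visit <- function(u) {
    expect_false(u %in% seen)
    seen <<- c(seen, u)
    for (cu in s$parts[[as.character(u)]]$children) {
      expect_identical(s$parts[[as.character(cu)]]$parent_link$parent_uid, u)
      visit(cu)
    }
  }
  for (r in s$roots) visit(r)
  expect_setequal(seen, as.integer(names(s$parts)))
})

test_that("disconnect removes the subtree and frees the parent face", {
  s <- build_pentamer()
  s2 <- disconnect(s, 4)   # amide + second alpha-carbon
  expect_length(s2$parts, 3L)
  expect_false("4" %in% names(s2$parts))
  expect_false("5" %in% names(s2$parts))
  expect_false(peppytwin:::.face_occupied(s2, 1, 1))
  # a new part can occupy the freed face
  s3 <- add_part(s2, "C_TERM", 9)
  expect_silent(link(s3, 1, 1, 9, 0))
  # disconnecting a root removes the whole sub-chain
  expect_length(disconnect(s, 1)$parts, 0L)
  expect_error(disconnect(s, 99), "no part")
})

test_that("disconnect then reconnect is the identity on scenes", {
  s <- build_pentamer()
  set.seed(2)
  for (u in linked_uids(s)) s <- set_joint_angle(s, u, runif(1, 0, 360))
  back <- reconnect(disconnect(s, 4), 4)
  expect_same_scene(back, s)
  expect_error(reconnect(back, 4), "no reconnection record")
  # randomized round trip on a generated 13-part scene, at every cut point
  big <- run_script(make_backbone(4, seed = 31))$scene
  for (u in linked_uids(big)) {
    expect_same_scene(reconnect(disconnect(big, u), u), big)
  }
  # disconnecting a root and reconnecting restores its coordinates too
  expect_same_scene(reconnect(disconnect(big, 1), 1), big)
})
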