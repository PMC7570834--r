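# shared builders for the test suite

# minimal dipeptide-style chain: Cα(1) with N-term(2), methyl(3) and an
# amide(4) carrying a second Cα(5)
build_pentamer <- function() {
  s <- scene_new()
  s <- add_part(s, "ALPHA_CARBON", 1)
  s <- add_part(s, "N_TERM", 2)
  s <- link(s, 1, 0, 2, 0)
  s <- add_part(s, "METHYL", 3)
  s <- link(s, 1, 2, 3, 0)
  s <- add_part(s, "AMIDE", 4)
  s <- link(s, 1, 1, 4, 0)
  s <- add_part(s, "ALPHA_CARBON", 5)
  s <- link(s, 4, 1, 5, 0)
  s
}

# all linked (non-root) uids of a scene
linked_uids <- function(scene) {
  sort(unlist(lapply(scene$parts, function(p) {
    if (!is.null(p$parent_link)) p$uid
  })))
}

# world frame (rotation, origin) of every part, accumulated from the
# package's per-junction relative frames
world_frames <- function(scene) {
  frames <- list()
  walk <- function(uid, R, t) {
    frames[[as.character(uid)]] <<- list(R = R, t = t)
    p <- scene$parts[[as.character(uid)]]
    for (cu in sort(p$children)) {
      child <- scene$parts[[as.character(cu)]]
      fr <- peppytwin:::.relative_frame(scene, child)
      walk(cu, R %*% fr$R, t + as.numeric(R %*% fr$t))
    }
  }
  for (r in sort(scene$roots)) walk(r, diag(3), c(0, 0, 0))
  frames
}

# all pairwise atom distances within each part, as one sorted vector
intra_part_distances <- function(coords) {
  unlist(lapply(coords, function(df) {
    as.numeric(stats::dist(df[, c("x", "y", "z")]))
  }))
}

# circular difference a - b wrapped to (-180, 180]
angle_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

expect_same_scene <- function(a, b, tol = 1e-9) {
  expect_setequal(names(a$parts), names(b$parts))
  expect_setequal(a$roots, b$roots)
  for (k in names(a$parts)) {
    expect_identical(a$parts[[k]]$kind, b$parts[[k]]$kind)
    expect_identical(a$parts[[k]]$parent_link, b$parts[[k]]$parent_link)
    expect_equal(a$parts[[k]]$joint_angle, b$parts[[k]]$joint_angle,
                 tolerance = tol)
  }
  ca <- world_coordinates(a)
  cb <- world_coordinates(b)
  for (k in names(ca)) {
    expect_equal(as.matrix(ca[[k]][, c("x", "y", "z")]),
                 as.matrix(cb[[k]][, c("x", "y", "z")]),
                 tolerance = tol)
  }
}
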