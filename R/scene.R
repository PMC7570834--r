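#' Create an empty scene
#'
#' A scene is the dictionary of all instantiated molecule parts, keyed by
#' unique integer ID, together with the list of sub-chain roots and the
#' tombstone records used for recursive reconnection of removed
#' sub-chains.  All scene operations are functional: they return a
#' modified copy.
#'
#' @param geometry Geometry table used to instantiate parts,
#'   see \code{\link{default_geometry}}.
#' @return An empty \code{scene} object.
#' @export
scene_new <- function(geometry = default_geometry()) {
  structure(list(parts = list(), roots = integer(),
                 root_order = integer(),   # creation order, for chain IDs
                 tombstones = list(), geometry = geometry),
            class = "scene")
}

.uid_key <- function(uid) as.character(as.integer(uid))

.get_part <- function(scene, uid) {
  p <- scene$parts[[.uid_key(uid)]]
  if (is.null(p)) stop("no part with uid ", uid, " in scene", call. = FALSE)
  p
}

#' @export
print.scene <- function(x, ...) {
  cat("<scene> ", length(x$parts), " part(s), ",
      length(x$roots), " sub-chain(s)\n", sep = "")
  for (key in names(x$parts)) {
    p <- x$parts[[key]]
    if (is.null(p$parent_link)) {
      cat("  [", p$uid, "] ", p$kind, " (root)\n", sep = "")
    } else {
      cat("  [", p$uid, "] ", p$kind, " <- parent ", p$parent_link$parent_uid,
          " face ", p$parent_link$parent_face_id,
          ", angle ", format(p$joint_angle), " deg\n", sep = "")
    }
  }
  invisible(x)
}

#' Add a part to a scene
#'
#' The part is instantiated from the scene's geometry table as a new
#' sub-chain root sitting at the origin frame.
#'
#' @param scene A \code{scene}.
#' @param kind One of \code{\link{part_kinds}}.
#' @param uid Integer unique ID, must be unused in the scene.
#' @return The modified scene.
#' @export
add_part <- function(scene, kind, uid) {
  uid <- as.integer(uid)
  stopifnot(length(uid) == 1L, !is.na(uid))
  key <- .uid_key(uid)
  if (!is.null(scene$parts[[key]]))
    stop("uid ", uid, " already present in scene", call. = FALSE)
  tpl <- instantiate_part(kind, scene$geometry)
  scene$parts[[key]] <- list(uid = uid, kind = tpl$kind, atoms = tpl$atoms,
                             faces = tpl$faces, parent_link = NULL,
                             joint_angle = 0, children = integer())
  scene$roots <- c(scene$roots, uid)
  scene$root_order <- c(scene$root_order, uid)
  scene
}

.face_occupied <- function(scene, uid, face_id) {
  p <- .get_part(scene, uid)
  if (!is.null(p$parent_link) && p$parent_link$own_face_id == face_id)
    return(TRUE)
  for (cu in p$children) {
    cl <- .get_part(scene, cu)$parent_link
    if (cl$parent_uid == uid && cl$parent_face_id == face_id) return(TRUE)
  }
  FALSE
}

#' Link a child part onto a parent face
#'
#' Rigidly places the child so that its face axis is anti-aligned with
#' the parent's face axis at the shared junction point; the junction then
#' permits a single rotational degree of freedom about that shaft axis.
#' The child must currently be a sub-chain root (this is what keeps the
#' scene a forest), the pairing must satisfy the chemistry rules, and
#' both faces must be unoccupied.  The joint angle is initialised to 0.
#'
#' @param scene A \code{scene}.
#' @param parent_uid,parent_face_id Parent part and face.
#' @param child_uid,child_face_id Child part (a root) and face.
#' @return The modified scene.
#' @export
link <- function(scene, parent_uid, parent_face_id, child_uid, child_face_id) {
  parent_uid <- as.integer(parent_uid); child_uid <- as.integer(child_uid)
  parent_face_id <- as.integer(parent_face_id)
  child_face_id <- as.integer(child_face_id)
  if (parent_uid == child_uid)
    stop("cannot link a part to itself", call. = FALSE)
  parent <- .get_part(scene, parent_uid)
  child <- .get_part(scene, child_uid)
  pf <- .find_face(parent, parent_face_id)
  cf <- .find_face(child, child_face_id)
  if (!validate_connection(parent$kind, pf, child$kind, cf))
    stop("chemistry rules forbid plugging ", child$kind, " face ",
         child_face_id, " into ", parent$kind, " face ", parent_face_id,
         call. = FALSE)
  if (!child_uid %in% scene$roots)
    stop("child ", child_uid, " is not a sub-chain root", call. = FALSE)
  if (.face_occupied(scene, parent_uid, parent_face_id))
    stop("face ", parent_face_id, " of part ", parent_uid,
         " is already occupied", call. = FALSE)
  if (.face_occupied(scene, child_uid, child_face_id))
    stop("face ", child_face_id, " of part ", child_uid,
         " is already occupied", call. = FALSE)
  # would create a cycle only if parent lives in the child's subtree;
  # impossible while child is a root of a different tree, but guard anyway
  if (.root_of(scene, parent_uid) == child_uid)
    stop("link would create a cycle", call. = FALSE)

  ck <- .uid_key(child_uid); pk <- .uid_key(parent_uid)
  scene$parts[[ck]]$parent_link <- list(parent_uid = parent_uid,
                                        parent_face_id = parent_face_id,
                                        own_face_id = child_face_id)
  scene$parts[[ck]]$joint_angle <- 0
  scene$parts[[pk]]$children <- sort(c(parent$children, child_uid))
  scene$roots <- setdiff(scene$roots, child_uid)
  scene$root_order <- setdiff(scene$root_order, child_uid)
  scene
}

.root_of <- function(scene, uid) {
  repeat {
    p <- .get_part(scene, uid)
    if (is.null(p$parent_link)) return(uid)
    uid <- p$parent_link$parent_uid
  }
}

#' Set the absolute joint angle of a linked part
#'
#' Rotates the part and its whole subtree rigidly about the junction
#' shaft axis to the given absolute angle (the reference placement, angle
#' 0, is the pose established by \code{\link{link}}).  Angles are
#' absolute, matching the semantics of an absolute-position rotary
#' sensor: two successive calls are equivalent to the last one alone.
#'
#' @param scene A \code{scene}.
#' @param child_uid The linked part whose junction is rotated.
#' @param angle_degrees Absolute angle in degrees; wrapped to [0, 360).
#' @return The modified scene.
#' @export
set_joint_angle <- function(scene, child_uid, angle_degrees) {
  key <- .uid_key(child_uid)
  p <- .get_part(scene, child_uid)
  if (is.null(p$parent_link))
    stop("part ", child_uid, " is a sub-chain root and has no joint",
         call. = FALSE)
  stopifnot(is.numeric(angle_degrees), length(angle_degrees) == 1L,
            is.finite(angle_degrees))
  scene$parts[[key]]$joint_angle <- wrap360(angle_degrees)
  scene
}

# frame of a child relative to its parent's local frame: rotation and
# origin such that the two face axes are anti-aligned at the junction
.relative_frame <- function(scene, child) {
  pl <- child$parent_link
  parent <- .get_part(scene, pl$parent_uid)
  pf <- .find_face(parent, pl$parent_face_id)
  cf <- .find_face(child, pl$own_face_id)
  R0 <- rotation_between(cf$axis, -pf$axis)
  Rj <- rotation_about(pf$axis, child$joint_angle)
  R <- Rj %*% R0
  junction <- pf$anchor + pf$axis * pf$length_mm
  origin <- junction - as.numeric(R %*% (cf$anchor + cf$axis * cf$length_mm))
  list(R = R, t = origin)
}

#' World coordinates of every atom in the scene
#'
#' Performs one forward-kinematic pass from each sub-chain root (which
#' sits at the origin frame), visiting parts parent-before-child with
#' children in uid order, so the result is deterministic for a given
#' scene.
#'
#' @param scene A \code{scene}.
#' @return Named list, one entry per uid, each a data frame with columns
#'   \code{symbol, x, y, z} (model millimetres) and \code{radius}.
#' @export
world_coordinates <- function(scene) {
  out <- list()
  place <- function(uid, R, t) {
    p <- .get_part(scene, uid)
    xyz <- t(R %*% t(as.matrix(p$atoms[, c("x", "y", "z")]))) +
      matrix(t, nrow(p$atoms), 3, byrow = TRUE)
    df <- p$atoms
    df[, c("x", "y", "z")] <- xyz
    out[[.uid_key(uid)]] <<- df
    for (cu in sort(p$children)) {
      child <- .get_part(scene, cu)
      fr <- .relative_frame(scene, child)
      place(cu, R %*% fr$R, t + as.numeric(R %*% fr$t))
    }
  }
  for (r in sort(scene$roots)) place(r, diag(3), c(0, 0, 0))
  out
}

.subtree_uids <- function(scene, uid) {
  p <- .get_part(scene, uid)
  c(uid, unlist(lapply(sort(p$children),
                       function(cu) .subtree_uids(scene, cu))))
}

#' Disconnect a part and its subtree from the scene
#'
#' The part and all parts linked below it are removed from the scene
#' dictionary, mirroring an unplug of the physical model.  The pair-face
#' records of the removed sub-chain (kinds, uids, links and joint
#' angles) are retained as a tombstone so \code{\link{reconnect}} can
#' recursively rebuild it.
#'
#' @param scene A \code{scene}.
#' @param uid Part to remove (with its whole subtree).
#' @return The modified scene.
#' @export
disconnect <- function(scene, uid) {
  uid <- as.integer(uid)
  p <- .get_part(scene, uid)   # errors on unknown uid
  sub <- .subtree_uids(scene, uid)
  # record, in parent-before-child order, everything needed to rebuild
  record <- lapply(sub, function(u) {
    q <- .get_part(scene, u)
    list(uid = u, kind = q$kind, parent_link = q$parent_link,
         joint_angle = q$joint_angle)
  })
  # detach from parent (its face becomes free again)
  if (!is.null(p$parent_link)) {
    pk <- .uid_key(p$parent_link$parent_uid)
    scene$parts[[pk]]$children <-
      setdiff(scene$parts[[pk]]$children, uid)
  } else {
    scene$roots <- setdiff(scene$roots, uid)
    scene$root_order <- setdiff(scene$root_order, uid)
  }
  scene$parts[sapply(sub, .uid_key)] <- NULL
  scene$tombstones[[.uid_key(uid)]] <- record
  scene
}

#' Recursively rebuild a previously disconnected sub-chain
#'
#' Re-instantiates the removed parts with their prior kinds, uids, links
#' and joint angles from the tombstone record left by
#' \code{\link{disconnect}}.  After reconnection the scene is identical
#' to the pre-disconnect scene.
#'
#' @param scene A \code{scene}.
#' @param uid Root uid of the removed sub-chain.
#' @return The modified scene.
#' @export
reconnect <- function(scene, uid) {
  key <- .uid_key(uid)
  record <- scene$tombstones[[key]]
  if (is.null(record))
    stop("no reconnection record for uid ", uid, call. = FALSE)
  for (entry in record) {
    scene <- add_part(scene, entry$kind, entry$uid)
    pl <- entry$parent_link
    if (!is.null(pl)) {
      scene <- link(scene, pl$parent_uid, pl$parent_face_id,
                    entry$uid, pl$own_face_id)
      scene <- set_joint_angle(scene, entry$uid, entry$joint_angle)
    }
  }
  scene$tombstones[[key]] <- NULL
  scene
}
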