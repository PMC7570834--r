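#' 14-bit angle sensor model
#'
#' The rotary position sensor at each junction reports a raw 14-bit
#' angle code (0..16383 over a full turn) plus a magnetic field
#' magnitude in dimensionless sensor units.  Each physical magnet is
#' glued with an unknown orientation, so every junction carries a
#' per-board offset that must be subtracted; offsets live in a static
#' calibration table keyed by node uid.
#'
#' \code{raw_to_degrees} maps a raw code to a corrected angle,
#' \eqn{(raw/2^{14}) \cdot 360 - offset}, wrapped to [0, 360); increasing
#' raw codes turn counter-clockwise about the junction's +Z shaft.
#' \code{degrees_to_raw} is its rounding inverse (used by the fixture
#' generator), accurate to half a quantization step
#' (360/2^14 = 0.02197 degrees).
#'
#' @param raw_angle Integer vector in [0, 16384).
#' @param offset_degrees Per-board calibration offset, degrees.
#' @param angle_degrees Any finite angle in degrees.
#' @return \code{raw_to_degrees}: corrected angle(s) in [0, 360);
#'   \code{degrees_to_raw}: nearest raw code(s) in [0, 16384).
#' @examples
#' raw_to_degrees(8192, 0)    # 180
#' raw_to_degrees(8192, 200)  # 340
#' degrees_to_raw(90, 0)      # 4096
#' @export
raw_to_degrees <- function(raw_angle, offset_degrees = 0) {
  stopifnot(is.numeric(raw_angle), all(is.finite(raw_angle)))
  if (any(raw_angle < 0 | raw_angle >= 16384 | raw_angle != floor(raw_angle)))
    stop("raw_angle must be an integer in [0, 16384)", call. = FALSE)
  wrap360(raw_angle / 16384 * 360 - offset_degrees)
}

#' @rdname raw_to_degrees
#' @export
degrees_to_raw <- function(angle_degrees, offset_degrees = 0) {
  stopifnot(is.numeric(angle_degrees), all(is.finite(angle_degrees)))
  as.integer(round(wrap360(angle_degrees + offset_degrees) / 360 * 16384)) %% 16384L
}

#' Plug detection from the magnetic field magnitude
#'
#' A junction counts as plugged when the sensed field magnitude is
#' strictly above the experimental threshold of 4000 sensor units.
#'
#' @param field Non-negative numeric vector, field magnitude in sensor
#'   units.
#' @param threshold Detection threshold, default 4000 units.
#' @return Logical vector.
#' @export
detect_plug <- function(field, threshold = 4000) {
  stopifnot(is.numeric(field), all(field >= 0))
  field > threshold
}

#' Read / write sensor streams and offset tables
#'
#' A sensor stream is the on-disk stand-in for the live radio feed: a
#' TSV with columns \code{timestamp_ms}, \code{node_uid},
#' \code{raw_angle}, \code{field}.  An offset table is a two-column TSV
#' \code{uid<TAB>offset_degrees}.
#'
#' @param path File path.
#' @param stream Data frame with the four stream columns.
#' @param offsets Named numeric vector (names = uids) or data frame
#'   \code{uid, offset_degrees}.
#' @return The read object, or \code{path} invisibly for writers.
#' @export
read_stream <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("timestamp_ms", "node_uid", "raw_angle", "field")
  if (!all(need %in% names(df)))
    stop("stream file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  df[need]
}

#' @rdname read_stream
#' @export
write_stream <- function(stream, path) {
  utils::write.table(stream, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname read_stream
#' @export
read_offsets <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("uid", "offset_degrees"))
  stats::setNames(wrap360(df$offset_degrees), df$uid)
}

#' @rdname read_stream
#' @export
write_offsets <- function(offsets, path) {
  if (is.data.frame(offsets)) {
    df <- offsets[, c("uid", "offset_degrees")]
  } else {
    df <- data.frame(uid = names(offsets),
                     offset_degrees = as.numeric(offsets))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Apply a sensor stream to a scene
#'
#' Replays readings in timestamp order, driving the corresponding joint
#' angles through the offset correction — this is how the virtual model
#' follows the physical one.  Readings whose uid does not name a linked
#' junction in the scene are logged as warnings and skipped, so a noisy
#' stream cannot corrupt the scene.  Field-magnitude crossings of the
#' plug threshold (off to on) are collected as plug events, the trigger
#' for the pairing handshake.
#'
#' @param scene A \code{scene}.
#' @param readings Stream data frame (\code{timestamp_ms, node_uid,
#'   raw_angle, field}).
#' @param offsets Named numeric vector of offsets, degrees, keyed by uid
#'   (missing uids get offset 0).
#' @return List with \code{scene} (updated) and \code{plug_events}
#'   (data frame \code{timestamp_ms, node_uid}).
#' @export
apply_stream <- function(scene, readings, offsets = numeric()) {
  stopifnot(inherits(scene, "scene"))
  if (nrow(readings) == 0L)
    return(list(scene = scene,
                plug_events = data.frame(timestamp_ms = numeric(),
                                         node_uid = integer())))
  readings <- readings[order(readings$timestamp_ms), , drop = FALSE]
  plugged <- logical()    # last known plug state per uid
  events <- list()
  for (i in seq_len(nrow(readings))) {
    r <- readings[i, ]
    key <- .uid_key(r$node_uid)
    off <- if (key %in% names(offsets)) offsets[[key]] else 0
    now <- detect_plug(r$field)
    was <- isTRUE(plugged[key])
    plugged[key] <- now
    if (now && !was)
      events[[length(events) + 1L]] <-
        data.frame(timestamp_ms = r$timestamp_ms, node_uid = r$node_uid)
    part <- scene$parts[[key]]
    if (is.null(part) || is.null(part$parent_link)) {
      warning("stream reading for uid ", r$node_uid,
              " does not name a linked junction; skipped", call. = FALSE)
      next
    }
    scene <- set_joint_angle(scene, r$node_uid,
                             raw_to_degrees(r$raw_angle, off))
  }
  list(scene = scene,
       plug_events = if (length(events)) do.call(rbind, events)
                     else data.frame(timestamp_ms = numeric(),
                                     node_uid = integer()))
}
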