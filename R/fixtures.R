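## Synthetic generators: chains, sensor streams, and network scenarios.
## Everything is reproducible from its seed; the generators emit the same
## .pusmol / TSV formats the rest of the package consumes, standing in
## for the physical interface.

# run `expr` under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

.sample_angles <- function(n, distribution) {
  switch(distribution,
         uniform = stats::runif(n, 0, 360),
         rotamer = sample(c(60, 180, 300), n, replace = TRUE),
         stop("unknown angle distribution: ", distribution, call. = FALSE))
}

#' Generate a backbone-building script
#'
#' Emits a \code{.pusmol} script that builds an n-residue backbone: an
#' N-terminal cap, then alternating alpha-carbon/amide units each with a
#' methyl side chain, closed by a C-terminal cap, with every joint set
#' to a random absolute angle.  The script always replays cleanly
#' through \code{\link{run_script}}.
#'
#' @param n_residues Number of residues (alpha-carbons), >= 1.
#' @param seed Integer seed; fully determines the script.
#' @param angle_distribution \code{"uniform"} on [0, 360) or
#'   \code{"rotamer"} (a discrete 60/180/300 degree stand-in for
#'   rotameric preferences).
#' @return Character vector of command lines.
#' @export
make_backbone <- function(n_residues, seed = 1L,
                          angle_distribution = c("uniform", "rotamer")) {
  stopifnot(n_residues >= 1)
  angle_distribution <- match.arg(angle_distribution)
  .with_seed(seed, {
    lines <- character()
    uid <- 0L
    new_uid <- function() { uid <<- uid + 1L; uid }
    ang <- function() {
      formatC(.sample_angles(1, angle_distribution), digits = 6,
              format = "f")
    }
    emit <- function(...) lines <<- c(lines, paste(...))

    a <- new_uid()
    emit("add alpha_carbon", a)
    nt <- new_uid()
    emit("add n_term", nt); emit("link", a, 0, nt, 0)
    emit("setangle", nt, ang())
    for (i in seq_len(n_residues)) {
      if (i > 1L) {
        d <- new_uid()
        emit("add amide", d); emit("link", a, 1, d, 0)
        emit("setangle", d, ang())
        a <- new_uid()
        emit("add alpha_carbon", a); emit("link", d, 1, a, 0)
        emit("setangle", a, ang())
      }
      m <- new_uid()
      emit("add methyl", m); emit("link", a, 2, m, 0)
      emit("setangle", m, ang())
    }
    ct <- new_uid()
    emit("add c_term", ct); emit("link", a, 1, ct, 0)
    emit("setangle", ct, ang())
    lines
  })
}

#' Generate a sensor stream with known ground truth
#'
#' Produces timestamped readings for every linked junction of a scene:
#' a ground-truth angle per junction, a per-board magnet offset, and raw
#' 14-bit codes obtained through the inverse sensor mapping plus
#' optional Gaussian placement jitter (truncated at 4 standard
#' deviations, emulating the roughly one-degree mechanical placement
#' tolerance of the boards).  The ground truth is returned alongside so
#' recovery through \code{\link{apply_stream}} can be checked.
#'
#' @param scene A \code{scene} with at least one linked junction.
#' @param seed Integer seed.
#' @param jitter_sd_degrees Jitter standard deviation, degrees (0 =
#'   noiseless).
#' @param n_repeats Readings per junction (later readings carry fresh
#'   jitter around the same ground truth).
#' @param interval_ms Spacing of consecutive timestamps.
#' @param field_units Field magnitude stamped on each reading (above
#'   the 4000-unit threshold by default, i.e. plugged).
#' @return List with \code{readings} (stream data frame),
#'   \code{truth} (data frame \code{node_uid, angle_degrees}) and
#'   \code{offsets} (named vector, degrees).
#' @export
make_stream <- function(scene, seed = 1L, jitter_sd_degrees = 0,
                        n_repeats = 1L, interval_ms = 10,
                        field_units = 6000) {
  stopifnot(inherits(scene, "scene"), jitter_sd_degrees >= 0,
            n_repeats >= 1)
  uids <- sort(unlist(lapply(scene$parts, function(p) {
    if (!is.null(p$parent_link)) p$uid else NULL
  })))
  if (length(uids) == 0L)
    stop("scene has no linked junctions to stream", call. = FALSE)
  .with_seed(seed, {
    truth <- data.frame(node_uid = uids,
                        angle_degrees = stats::runif(length(uids), 0, 360))
    offsets <- stats::setNames(stats::runif(length(uids), 0, 360),
                               as.character(uids))
    n <- length(uids) * n_repeats
    jit <- if (jitter_sd_degrees > 0) {
      z <- stats::rnorm(n)
      while (any(bad <- abs(z) > 4)) z[bad] <- stats::rnorm(sum(bad))
      z * jitter_sd_degrees
    } else {
      numeric(n)
    }
    uid_seq <- rep(uids, times = n_repeats)
    readings <- data.frame(
      timestamp_ms = seq(0, by = interval_ms, length.out = n),
      node_uid = uid_seq,
      raw_angle = degrees_to_raw(
        truth$angle_degrees[match(uid_seq, truth$node_uid)] + jit,
        offsets[as.character(uid_seq)]),
      field = field_units)
    list(readings = readings, truth = truth, offsets = offsets)
  })
}

#' Generate a network scenario
#'
#' A scenario is a timed event table (TSV-compatible data frame with
#' columns \code{time_s, event, node}) of node joins followed by random
#' drops, exercising the join/reroute paths.
#'
#' @param n_nodes Number of nodes to join (IDs 1..n, <= 254).
#' @param n_drops Number of distinct nodes dropped after all joins.
#' @param seed Integer seed.
#' @return Data frame of events.
#' @export
make_net_scenario <- function(n_nodes, n_drops = 0L, seed = 1L) {
  stopifnot(n_nodes >= 1, n_nodes <= 254, n_drops >= 0, n_drops <= n_nodes)
  .with_seed(seed, {
    join_order <- sample(seq_len(n_nodes))
    ev <- data.frame(time_s = seq_along(join_order),
                     event = "join", node = join_order)
    if (n_drops > 0L) {
      dropped <- sample(join_order, n_drops)
      ev <- rbind(ev, data.frame(
        time_s = n_nodes + seq_len(n_drops),
        event = "drop", node = dropped))
    }
    ev
  })
}

#' Run a network scenario
#'
#' Applies a scenario's events in time order to a fresh network.  In
#' STATIC mode join events are attached under the closest-to-gateway
#' node with free capacity (the deterministic equivalent of plugging
#' into the next free pipe).
#'
#' @param events Scenario data frame from \code{\link{make_net_scenario}}
#'   or \code{\link{read_scenario}}.
#' @param mode Network topology mode.
#' @return The final \code{network_state}.
#' @export
run_net_scenario <- function(events, mode = c("DYNAMIC", "STATIC")) {
  mode <- match.arg(mode)
  net <- network_new(mode)
  events <- events[order(events$time_s), , drop = FALSE]
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    net <- switch(as.character(e$event),
      join = if (mode == "STATIC") {
        join(net, e$node, preferred_parent = .auto_parent(net))
      } else {
        join(net, e$node)
      },
      drop = drop_node(net, e$node),
      stop("unknown scenario event: ", e$event, call. = FALSE))
  }
  net
}

#' Read / write network scenario files
#'
#' @param events Scenario data frame.
#' @param path File path (TSV).
#' @return The events data frame, or \code{path} invisibly.
#' @export
write_scenario <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
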