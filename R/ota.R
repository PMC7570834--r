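.PAGE_BYTES <- 16L
.WATCHDOG_S <- 4

#' Build a firmware image
#'
#' Splits a payload into ordered 16-byte pages, the unit of the
#' over-the-air bootloader protocol; the last page is zero-padded.
#'
#' @param payload Raw vector (or integer vector of byte values).
#' @return A \code{firmware_image}: list with \code{payload},
#'   \code{pages} (list of 16-byte raw blocks) and \code{n_pages}.
#' @export
firmware_image <- function(payload) {
  if (is.numeric(payload)) payload <- as.raw(payload)
  stopifnot(is.raw(payload))
  n_pages <- ceiling(length(payload) / .PAGE_BYTES)
  pages <- lapply(seq_len(n_pages), function(i) {
    pg <- payload[seq((i - 1L) * .PAGE_BYTES + 1L,
                      min(i * .PAGE_BYTES, length(payload)))]
    c(pg, raw(.PAGE_BYTES - length(pg)))            # zero-pad last page
  })
  structure(list(payload = payload, pages = pages,
                 n_pages = as.integer(n_pages)),
            class = "firmware_image")
}

#' Simulate an over-the-air firmware update
#'
#' The node's bootloader requests the new firmware from the gateway page
#' by page (16 bytes each), in burst mode: after a successful page it
#' immediately requests the next.  A lost request or reply is recovered
#' by the watchdog, which forces a page re-request every 4 s of
#' simulated time, guaranteeing a minimal update speed of 16 bytes per
#' 4 s and making bricking impossible.  On completion the reassembled
#' bytes equal the image payload exactly.
#'
#' @param net A \code{network_state} (the target must be live, or the
#'   gateway itself for bench testing).
#' @param node Target node ID.
#' @param image A \code{firmware_image}.
#' @param loss_prob Per-transfer loss probability in [0, 1) for fault
#'   injection; draws come from R's RNG, so set a seed for
#'   reproducibility.
#' @param burst_interval_s Simulated time of one successful page
#'   transfer, seconds.
#' @return List with \code{ok}, \code{firmware} (reassembled raw
#'   payload), \code{n_pages}, \code{trace} (data frame \code{time_s,
#'   page, attempt, outcome}) and \code{max_request_interval_s}.
#' @export
ota_update <- function(net, node, image, loss_prob = 0,
                       burst_interval_s = 0.05) {
  stopifnot(inherits(image, "firmware_image"),
            loss_prob >= 0, loss_prob < 1)
  node <- as.integer(node)
  if (node != 0L && !node %in% .live_nodes(net))
    stop("node ", node, " is not live", call. = FALSE)

  trace <- list()
  t <- 0
  request_times <- 0
  got <- vector("list", image$n_pages)
  for (pg in seq_len(image$n_pages)) {
    attempt <- 0L
    repeat {
      attempt <- attempt + 1L
      request_times <- c(request_times, t)
      lost <- loss_prob > 0 && stats::runif(1) < loss_prob
      trace[[length(trace) + 1L]] <-
        data.frame(time_s = t, page = pg, attempt = attempt,
                   outcome = if (lost) "LOST" else "OK",
                   stringsAsFactors = FALSE)
      if (!lost) {
        got[[pg]] <- image$pages[[pg]]
        t <- t + burst_interval_s
        break
      }
      t <- t + .WATCHDOG_S            # watchdog fires, page re-requested
    }
  }
  firmware <- if (length(got)) do.call(c, got) else raw()
  length(firmware) <- length(image$payload)   # strip padding
  list(ok = identical(firmware, image$payload),
       firmware = firmware, n_pages = image$n_pages,
       trace = do.call(rbind, trace),
       max_request_interval_s = if (length(request_times) > 1)
         max(diff(request_times)) else 0)
}

## --- node ID allocation ---------------------------------------------------

# printed ID ranges per part kind; the alpha-carbon is passive (no radio)
# under the EXTENDED strategy and may live beyond the 8-bit space
.ID_RANGES <- list(
  CURRENT = list(METHYL = c(1L, 40L), AMIDE = c(41L, 80L),
                 ALPHA_CARBON = c(81L, 120L)),
  EXTENDED = list(METHYL = c(1L, 85L), AMIDE = c(86L, 255L),
                  ALPHA_CARBON = c(257L, 510L)))

#' Create an ID allocation pool
#'
#' @param strategy \code{"CURRENT"} (all kinds inside the radio ID
#'   space: methyl 1-40, amide 41-80, alpha-carbon 81-120) or
#'   \code{"EXTENDED"} (methyl 1-85, amide 86-255, and the passive
#'   alpha-carbons relocated beyond the 8-bit space at 257-510).
#' @return An \code{id_pool}.
#' @export
id_pool <- function(strategy = c("CURRENT", "EXTENDED")) {
  structure(list(strategy = match.arg(strategy), used = integer()),
            class = "id_pool")
}

#' Allocate a node ID for a part kind
#'
#' Hands out the lowest free ID in the kind's range under the pool's
#' strategy.
#'
#' @param pool An \code{id_pool}.
#' @param kind \code{"METHYL"}, \code{"AMIDE"} or
#'   \code{"ALPHA_CARBON"} (the terminal caps follow the methyl pattern
#'   of a single sensed junction and share its range).
#' @return List with \code{id} and the updated \code{pool}.
#' @export
allocate_id <- function(pool, kind) {
  stopifnot(inherits(pool, "id_pool"))
  kind <- as_part_kind(kind)
  if (kind %in% c("C_TERM", "N_TERM")) kind <- "METHYL"
  rng <- .ID_RANGES[[pool$strategy]][[kind]]
  free <- setdiff(seq(rng[1], rng[2]), pool$used)
  if (length(free) == 0L)
    stop("ID pool exhausted for ", kind, " (range ", rng[1], "-", rng[2],
         " under ", pool$strategy, ")", call. = FALSE)
  id <- min(free)
  pool$used <- c(pool$used, id)
  list(id = as.integer(id), pool = pool)
}
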