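## Timing of the IR link: 1 ms per bit (>= 1000 bps for near-instant
## pairing), each bit split into 8 intervals so special START/STOP
## symbols can be sequenced, hence a timer tick of 125 us.

#' Link clock constants
#'
#' @return List with \code{tick_period_us} (125), \code{ticks_per_bit}
#'   (8) and \code{bit_period_ms} (1).
#' @export
link_clock <- function() {
  list(tick_period_us = 125, ticks_per_bit = 8L, bit_period_ms = 1)
}

# sub-bit (8-tick) patterns of each line symbol
.SYMBOL_TICKS <- list(
  START = c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L),
  STOP  = c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L),
  `0`   = rep(0L, 8),
  `1`   = rep(1L, 8))

#' Encode a byte as a framed bit sequence
#'
#' One frame is START, the 8 data bits least-significant first, then
#' STOP — 10 bit-periods in all.  Each symbol occupies one 1 ms bit
#' period realised as 8 ticks of 125 us on the line.
#'
#' @param value Integer in [0, 255].
#' @return A \code{bit_frame}: character vector of symbols.
#' @examples
#' encode_byte(0xA5)  # data bits 1,0,1,0,0,1,0,1
#' @export
encode_byte <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1L,
            value == floor(value), value >= 0, value <= 255)
  bits <- as.integer(intToBits(as.integer(value))[1:8])  # LSB first
  structure(c("START", as.character(bits), "STOP"), class = "bit_frame")
}

#' Decode a framed bit sequence back to its byte value(s)
#'
#' Accepts a frame of one START, 8k data bits (LSB first per byte) and
#' one STOP, and returns the k byte values.
#'
#' @param frame A \code{bit_frame}.
#' @return Integer vector of decoded bytes.
#' @export
decode_frame <- function(frame) {
  syms <- unclass(frame)
  if (syms[1] != "START" || syms[length(syms)] != "STOP")
    stop("malformed frame: missing START/STOP", call. = FALSE)
  bits <- as.integer(syms[-c(1, length(syms))])
  if (length(bits) %% 8 != 0 || any(is.na(bits)) || any(!bits %in% 0:1))
    stop("malformed frame: payload is not whole bytes", call. = FALSE)
  vapply(split(bits, (seq_along(bits) - 1) %/% 8),
         function(b) sum(b * 2^(0:7)), numeric(1), USE.NAMES = FALSE)
}

# expand a frame to its per-tick line levels
frame_ticks <- function(frame) {
  unlist(.SYMBOL_TICKS[unclass(frame)], use.names = FALSE)
}

#' Simulated IR line
#'
#' The transmitter drives its pin through a NOT gate (inverted logic,
#' the LED is wired pull-up); on the receiving side the parallel
#' photodiodes pull the Rx pin high whenever light arrives (direct
#' logic).  The composition of the two inversions delivers every level
#' unchanged.
#'
#' @param levels Integer vector of logical levels (0/1) to transmit.
#' @return List with \code{tx_pin} (inverted), \code{rx_pin} (as seen by
#'   the receiver) per tick.
#' @export
ir_line_transmit <- function(levels) {
  stopifnot(all(levels %in% c(0L, 1L)))
  tx_pin <- 1L - as.integer(levels)   # NOT gate on the output pin
  rx_pin <- 1L - tx_pin               # photodiode pulls Rx to the light level
  list(tx_pin = tx_pin, rx_pin = rx_pin)
}

## --- generic Rx-/Tx-matons (per-tick state machines) ---------------------

#' Per-tick transmitter and receiver automatons
#'
#' \code{tx_maton_new}/\code{tx_maton_step} emit a frame one 125 us tick
#' at a time, idling low once done.  \code{rx_maton_new}/\code{rx_maton_step}
#' idle until the line-interrupt (first high tick) fires, then sample
#' \code{8} ticks per symbol until the expected frame (START +
#' \code{n_data_bits} + STOP) is complete and decode it.  A silent line
#' leaves the Rx-maton's state unchanged.
#'
#' @param frame A \code{bit_frame} to send.
#' @param n_data_bits Number of payload bits the receiver expects.
#' @param state A maton state.
#' @param level Line level (0/1) seen this tick.
#' @return \code{*_step} returns the updated state; the Tx state carries
#'   \code{$level} (the level emitted this tick) and both carry
#'   \code{$done}.
#' @export
tx_maton_new <- function(frame) {
  list(ticks = frame_ticks(frame), pos = 0L, done = FALSE, level = 0L)
}

#' @rdname tx_maton_new
#' @export
tx_maton_step <- function(state) {
  if (state$pos < length(state$ticks)) {
    state$pos <- state$pos + 1L
    state$level <- state$ticks[state$pos]
    state$done <- state$pos == length(state$ticks)
  } else {
    state$level <- 0L
    state$done <- TRUE
  }
  state
}

#' @rdname tx_maton_new
#' @export
rx_maton_new <- function(n_data_bits) {
  list(phase = "IDLE", buf = integer(), n_ticks = (n_data_bits + 2L) * 8L,
       symbols = character(), bytes = integer(), done = FALSE)
}

.classify_symbol <- function(ticks8) {
  for (s in names(.SYMBOL_TICKS))
    if (all(ticks8 == .SYMBOL_TICKS[[s]])) return(s)
  "INVALID"
}

#' @rdname tx_maton_new
#' @export
rx_maton_step <- function(state, level) {
  level <- as.integer(level)
  if (state$phase == "IDLE") {
    if (level == 0L) return(state)       # waiting for the pin interrupt
    state$phase <- "RECEIVING"
  }
  if (state$phase == "RECEIVING") {
    state$buf <- c(state$buf, level)
    if (length(state$buf) == state$n_ticks) {
      groups <- split(state$buf, (seq_along(state$buf) - 1L) %/% 8L)
      state$symbols <- vapply(groups, .classify_symbol, character(1),
                              USE.NAMES = FALSE)
      state$bytes <- decode_frame(structure(state$symbols,
                                            class = "bit_frame"))
      state$phase <- "DONE"
      state$done <- TRUE
    }
  }
  state
}

## --- the pairing handshake ------------------------------------------------

.DEAD_BITS <- 4L   # dead time between the two frames, in bit-periods

#' Simulate the automated pairing handshake
#'
#' When the master side of a fresh junction detects a plug (field above
#' threshold), it sends its 8-bit ID over the IR line and waits for the
#' slave's reply: the slave's own 8-bit ID followed by an 8-bit check
#' ID echoing what the slave received.  If the check ID equals the
#' master's own ID the pairing succeeded; otherwise it restarts after
#' one idle bit-period.  One handshake is
#' START + 8 bits + STOP + 4 dead bits + START + 16 bits + STOP =
#' 32 bit-periods = 32 ms at the 1 ms bit period — constant, whatever
#' the IDs.
#'
#' @param master_id,slave_id Integer IDs in [0, 255].
#' @param corrupt_check_bit Optional bit position 0..7 flipped in the
#'   check-ID on the line during the first attempt (fault injection).
#' @param max_attempts Attempt cap before giving up.
#' @return A \code{pairing_session}: list with \code{outcome}
#'   (\code{"SUCCESS"} or \code{"RESTARTED"}), \code{attempts},
#'   \code{handshake_ms} (32), \code{n_bit_periods} (32),
#'   \code{elapsed_ms} (all attempts plus idle gaps) and
#'   \code{transcript} (per-symbol data frame).
#' @export
run_pairing <- function(master_id, slave_id, corrupt_check_bit = NULL,
                        max_attempts = 5L) {
  stopifnot(master_id >= 0, master_id <= 255, slave_id >= 0, slave_id <= 255)
  if (!is.null(corrupt_check_bit))
    stopifnot(corrupt_check_bit %in% 0:7)

  one_attempt <- function(attempt) {
    master_frame <- encode_byte(master_id)
    # honest slave echoes the ID it decoded from the master frame
    received <- decode_frame(master_frame)
    check_id <- received
    if (!is.null(corrupt_check_bit) && attempt == 1L)
      check_id <- bitwXor(check_id, bitwShiftL(1L, corrupt_check_bit))
    reply_bits <- c(as.integer(intToBits(as.integer(slave_id))[1:8]),
                    as.integer(intToBits(as.integer(check_id))[1:8]))
    reply_frame <- structure(c("START", as.character(reply_bits), "STOP"),
                             class = "bit_frame")
    symbols <- c(unclass(master_frame), rep("DEAD", .DEAD_BITS),
                 unclass(reply_frame))
    phase <- c(rep("master_id", length(master_frame)),
               rep("dead", .DEAD_BITS),
               rep("reply", length(reply_frame)))
    decoded <- decode_frame(reply_frame)
    list(n_bits = length(symbols),
         transcript = data.frame(attempt = attempt,
                                 bit_period = seq_along(symbols),
                                 phase = phase, symbol = symbols,
                                 stringsAsFactors = FALSE),
         neighbor_id = decoded[1], check_id = decoded[2],
         success = decoded[2] == master_id)
  }

  transcripts <- list()
  elapsed <- 0
  outcome <- "RESTARTED"
  attempt <- 0L
  last <- NULL
  while (attempt < max_attempts) {
    attempt <- attempt + 1L
    if (attempt > 1L) elapsed <- elapsed + link_clock()$bit_period_ms  # idle
    last <- one_attempt(attempt)
    transcripts[[attempt]] <- last$transcript
    elapsed <- elapsed + last$n_bits * link_clock()$bit_period_ms
    if (last$success) { outcome <- "SUCCESS"; break }
  }
  structure(list(master_id = master_id, slave_id = slave_id,
                 neighbor_id = last$neighbor_id, check_id = last$check_id,
                 outcome = outcome, attempts = attempt,
                 n_bit_periods = last$n_bits,
                 handshake_ms = last$n_bits * link_clock()$bit_period_ms,
                 elapsed_ms = elapsed,
                 transcript = do.call(rbind, transcripts)),
            class = "pairing_session")
}

#' @export
print.pairing_session <- function(x, ...) {
  cat("<pairing_session> master", x$master_id, "<-> slave", x$slave_id,
      "|", x$outcome, "in", x$attempts, "attempt(s),",
      x$handshake_ms, "ms per handshake\n")
  invisible(x)
}

#' Tick-level co-simulation of the pairing handshake
#'
#' Runs the master's Tx-maton against the slave's Rx-maton (and then the
#' reverse direction for the reply) in lock step over a shared simulated
#' IR line, one 125 us tick at a time.  This is an independent,
#' lower-level realisation of the same protocol as
#' \code{\link{run_pairing}} and must agree with it byte for byte and
#' tick for tick.
#'
#' @param master_id,slave_id Integer IDs in [0, 255].
#' @return List with the decoded \code{neighbor_id} and \code{check_id},
#'   \code{total_ticks} of line activity (first START tick to last STOP
#'   tick) and \code{total_ms}.
#' @export
run_pairing_ticks <- function(master_id, slave_id) {
  clk <- link_clock()
  master_tx <- tx_maton_new(encode_byte(master_id))
  slave_rx <- rx_maton_new(8L)
  ticks <- 0L
  while (!slave_rx$done) {
    master_tx <- tx_maton_step(master_tx)
    line <- ir_line_transmit(master_tx$level)
    slave_rx <- rx_maton_step(slave_rx, line$rx_pin)
    ticks <- ticks + 1L
  }
  # dead time: the master waits for the slave Rx to get ready
  ticks <- ticks + .DEAD_BITS * clk$ticks_per_bit

  check_id <- slave_rx$bytes[1]
  reply_bits <- c(as.integer(intToBits(as.integer(slave_id))[1:8]),
                  as.integer(intToBits(as.integer(check_id))[1:8]))
  reply_frame <- structure(c("START", as.character(reply_bits), "STOP"),
                           class = "bit_frame")
  slave_tx <- tx_maton_new(reply_frame)
  master_rx <- rx_maton_new(16L)
  while (!master_rx$done) {
    slave_tx <- tx_maton_step(slave_tx)
    line <- ir_line_transmit(slave_tx$level)
    master_rx <- rx_maton_step(master_rx, line$rx_pin)
    ticks <- ticks + 1L
  }
  list(neighbor_id = master_rx$bytes[1], check_id = master_rx$bytes[2],
       success = master_rx$bytes[2] == master_id,
       total_ticks = ticks,
       total_ms = ticks * clk$tick_period_us / 1000)
}

#' Write a pairing transcript as TSV
#'
#' @param session A \code{pairing_session}.
#' @param path File path.
#' @return \code{path}, invisibly.
#' @export
write_transcript <- function(session, path) {
  utils::write.table(session$transcript, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
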