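## Command grammar (one command per line, lowercase verbs, whitespace
## separated, '#' starts a comment):
##   add <kind> <uid>                      kind: methyl|amide|alpha_carbon|
##                                               c_term|n_term
##   link <parent_uid> <parent_face> <child_uid> <child_face>
##   setangle <uid> <angle_degrees>
##   disconnect <uid>
##   reconnect <uid>
##   save <path> | load <path> | list

.CMD_ARITY <- c(add = 2L, link = 4L, setangle = 2L, disconnect = 1L,
                reconnect = 1L, save = 1L, load = 1L, list = 0L)

.parse_int <- function(tok, what, line_no) {
  v <- suppressWarnings(as.integer(tok))
  if (is.na(v) || as.character(v) != sub("^\\+", "", tok))
    stop(sprintf("line %d: expected an integer %s, got '%s'",
                 line_no, what, tok), call. = FALSE)
  v
}

.parse_num <- function(tok, what, line_no) {
  v <- suppressWarnings(as.numeric(tok))
  if (is.na(v) || !is.finite(v))
    stop(sprintf("line %d: expected a number %s, got '%s'",
                 line_no, what, tok), call. = FALSE)
  v
}

#' Parse one command line
#'
#' Parses and validates a single line of the chain-construction
#' language.  Invalid lines raise an error naming the offending line
#' number and token; they are never executed or recorded.
#'
#' @param line Character scalar, one command.
#' @param line_no Line number used in diagnostics.
#' @return A \code{pusmol_command} (list with \code{verb} and
#'   \code{args}), or \code{NULL} for a blank/comment line.
#' @export
parse_command <- function(line, line_no = 1L) {
  stopifnot(is.character(line), length(line) == 1L)
  line <- sub("#.*$", "", line)
  toks <- strsplit(trimws(line), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0L) return(NULL)
  verb <- tolower(toks[1])
  if (!verb %in% names(.CMD_ARITY))
    stop(sprintf("line %d: unknown verb '%s'", line_no, toks[1]),
         call. = FALSE)
  args <- toks[-1]
  if (length(args) != .CMD_ARITY[[verb]])
    stop(sprintf("line %d: '%s' takes %d argument(s), got %d",
                 line_no, verb, .CMD_ARITY[[verb]], length(args)),
         call. = FALSE)
  cmd <- switch(verb,
    add = {
      kind <- toupper(args[1])
      if (!kind %in% part_kinds())
        stop(sprintf("line %d: unknown part kind '%s'", line_no, args[1]),
             call. = FALSE)
      list(kind = kind, uid = .parse_int(args[2], "uid", line_no))
    },
    link = list(parent_uid = .parse_int(args[1], "parent uid", line_no),
                parent_face_id = .parse_int(args[2], "parent face", line_no),
                child_uid = .parse_int(args[3], "child uid", line_no),
                child_face_id = .parse_int(args[4], "child face", line_no)),
    setangle = list(uid = .parse_int(args[1], "uid", line_no),
                    angle = .parse_num(args[2], "angle", line_no)),
    disconnect = ,
    reconnect = list(uid = .parse_int(args[1], "uid", line_no)),
    save = ,
    load = list(path = args[1]),
    list = list())
  structure(c(list(verb = verb), cmd, list(text = paste(toks, collapse = " "))),
            class = "pusmol_command")
}

#' Create a command session
#'
#' A session couples a scene with the history of successfully executed
#' scene-mutating commands; the history is what \code{\link{save_pusmol}}
#' records, so a saved script replays to exactly the saved scene.
#'
#' @param geometry Geometry table for the session's scene.
#' @return A \code{pusmol_session}.
#' @export
pusmol_session <- function(geometry = default_geometry()) {
  structure(list(scene = scene_new(geometry), history = character()),
            class = "pusmol_session")
}

#' Execute a parsed command against a session
#'
#' Scene-mutating verbs (\code{add}, \code{link}, \code{setangle},
#' \code{disconnect}, \code{reconnect}) are applied to the scene and, on
#' success, appended to the session history.  \code{save}/\code{load}
#' perform script I/O and \code{list} prints the scene; these three are
#' not recorded.  A failed command leaves the session unchanged.
#'
#' @param session A \code{pusmol_session}.
#' @param cmd A \code{pusmol_command} (or \code{NULL}, a no-op).
#' @return The modified session.
#' @export
execute_command <- function(session, cmd) {
  if (is.null(cmd)) return(session)
  stopifnot(inherits(cmd, "pusmol_command"))
  recorded <- TRUE
  scene <- switch(cmd$verb,
    add = add_part(session$scene, cmd$kind, cmd$uid),
    link = link(session$scene, cmd$parent_uid, cmd$parent_face_id,
                cmd$child_uid, cmd$child_face_id),
    setangle = set_joint_angle(session$scene, cmd$uid, cmd$angle),
    disconnect = disconnect(session$scene, cmd$uid),
    reconnect = reconnect(session$scene, cmd$uid),
    save = { save_pusmol(session, cmd$path); recorded <- FALSE
             session$scene },
    load = { session <- load_pusmol(cmd$path, session)
             recorded <- FALSE; session$scene },
    list = { print(session$scene); recorded <- FALSE; session$scene })
  session$scene <- scene
  if (recorded) session$history <- c(session$history, cmd$text)
  session
}

#' Run a script programmatically
#'
#' Executes an ordered set of command lines against a session with
#' semantics identical to interactive execution — this is the procedural
#' generation path used to build long chains from code.  The first
#' invalid or failing line aborts with its line number.
#'
#' @param lines Character vector of command lines.
#' @param session A \code{pusmol_session}; a fresh one by default.
#' @return The resulting \code{pusmol_session}.
#' @export
run_script <- function(lines, session = pusmol_session()) {
  for (i in seq_along(lines)) {
    cmd <- parse_command(lines[i], line_no = i)
    session <- tryCatch(execute_command(session, cmd), error = function(e) {
      stop(sprintf("line %d ('%s'): %s", i, trimws(lines[i]),
                   conditionMessage(e)), call. = FALSE)
    })
  }
  session
}

#' Save / load a .pusmol script
#'
#' A \code{.pusmol} file is UTF-8 text with one command per line: the
#' record of every valid scene-mutating command executed in the session.
#' Replaying it on an empty session reproduces the saved scene exactly.
#'
#' @param session A \code{pusmol_session}.
#' @param path File path (conventionally \code{.pusmol}).
#' @return \code{save_pusmol} returns \code{path} invisibly;
#'   \code{load_pusmol} returns the session after replay.
#' @export
save_pusmol <- function(session, path) {
  stopifnot(inherits(session, "pusmol_session"))
  writeLines(session$history, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname save_pusmol
#' @export
load_pusmol <- function(path, session = pusmol_session()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  run_script(readLines(path, warn = FALSE), session)
}
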