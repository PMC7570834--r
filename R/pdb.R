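.RESID3 <- c(METHYL = "MTH", AMIDE = "AMD", ALPHA_CARBON = "CAL",
             C_TERM = "CTR", N_TERM = "NTR")
.ELEMENT <- c(C = "C", Cr = "C", Ca = "C", N = "N", O = "O", H = "H")

#' Export a scene as PDB text
#'
#' Writes one ATOM record per atom of the coarse-grained model.  Model
#' millimetres are divided by the physical scale (default the scene
#' geometry's, 18.7 mm per Angstrom) to recover Angstrom, and the
#' internal left-handed frame is converted to the right-handed PDB
#' convention by negating the X axis.  The programming symbols Cr
#' (methyl's radical carbon) and Ca (the alpha-carbon's carbon) are
#' exported as element C; each part becomes one residue and each
#' sub-chain one chain ID (A, B, C... in root creation order).  The
#' handedness conversion negates the Z (forward) axis, so X and Y carry
#' over unchanged.
#'
#' @param scene A non-empty \code{scene}.
#' @param file Optional path; when given the PDB is also written there.
#' @param scale_mm_per_angstrom Millimetres of model per Angstrom.
#' @return Character vector of PDB lines, invisibly when \code{file} is
#'   given.
#' @export
export_structure <- function(scene, file = NULL,
                             scale_mm_per_angstrom = scene$geometry$scale) {
  stopifnot(inherits(scene, "scene"))
  if (length(scene$parts) == 0L)
    stop("scene is empty: nothing to export", call. = FALSE)
  stopifnot(is.numeric(scale_mm_per_angstrom), scale_mm_per_angstrom > 0)

  coords <- world_coordinates(scene)
  rows <- list()
  resno_counter <- 0L
  walk <- function(uid, chain_id) {
    resno_counter <<- resno_counter + 1L
    p <- .get_part(scene, uid)
    df <- coords[[.uid_key(uid)]]
    # unique atom names within the residue (H -> H1 H2 H3, O -> O1 O2 ...)
    nm <- toupper(df$symbol)
    for (s in unique(nm)) {
      idx <- which(nm == s)
      if (length(idx) > 1L) nm[idx] <- paste0(s, seq_along(idx))
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      elety = nm,
      elesy = unname(.ELEMENT[df$symbol]),
      resid = unname(.RESID3[p$kind]),
      resno = resno_counter,
      chain = chain_id,
      x = df$x / scale_mm_per_angstrom,
      y = df$y / scale_mm_per_angstrom,
      z = -df$z / scale_mm_per_angstrom,   # left- to right-handed

      stringsAsFactors = FALSE)
    for (cu in sort(p$children)) walk(cu, chain_id)
  }
  for (i in seq_along(scene$root_order)) {
    walk(scene$root_order[i], LETTERS[(i - 1L) %% 26L + 1L])
  }
  at <- do.call(rbind, rows)

  tmp <- if (is.null(file)) tempfile(fileext = ".pdb") else file
  bio3d::write.pdb(file = tmp,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(at)),
                   eleno = seq_len(nrow(at)),
                   elety = at$elety, resid = at$resid, resno = at$resno,
                   chain = at$chain, elesy = at$elesy,
                   o = rep(1, nrow(at)), b = rep(0, nrow(at)))
  lines <- readLines(tmp, warn = FALSE)
  if (is.null(file)) {
    unlink(tmp)
    lines
  } else {
    invisible(lines)
  }
}
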