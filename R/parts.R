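#' Part kinds of the coarse-grained peptide model
#'
#' The model is built from five printable module types: methyl (side
#' chain), amide (the peptide-bond unit with distinct C and N faces),
#' alpha-carbon (the three-faced hub of each residue), and the C- and
#' N-terminal caps.
#'
#' @return Character vector of the five kind names.
#' @export
part_kinds <- function() {
  c("METHYL", "AMIDE", "ALPHA_CARBON", "C_TERM", "N_TERM")
}

as_part_kind <- function(kind) {
  k <- toupper(as.character(kind))
  if (length(k) != 1L || !k %in% part_kinds())
    stop("unknown part kind: ", kind, call. = FALSE)
  k
}

# connector roles: the hall sensor sits on the methyl/amide/terminal side
# of each junction, the magnet on the (passive) alpha-carbon side
.role_for <- function(kind) if (kind == "ALPHA_CARBON") "MAGNET" else "SENSOR"

.face <- function(face_id, axis, anchor, length_mm, role, partners) {
  structure(list(face_id = as.integer(face_id),
                 axis = vunit(axis),
                 anchor = as.numeric(anchor),
                 length_mm = as.numeric(length_mm),
                 connector_role = role,
                 allowed_partners = partners),
            class = "pt_face")
}

#' Default part geometry table
#'
#' Internal coordinates for the five part kinds.  The published
#' description of the tangible model does not tabulate its parts'
#' internal coordinates, so these defaults are a synthetic
#' reconstruction from the Peppytide coarse-grained model it is based
#' on, using standard peptide bond lengths and angles (e.g. Calpha-N
#' 1.455 A, Calpha-C 1.51 A, peptide C-N 1.325 A, C=O 1.23 A, trans
#' amide plane).  All positions are stored in model millimetres at the
#' table's scale; junctions sit at the midpoint of the corresponding
#' chemical bond, so each face carries half a bond length of shaft.
#'
#' Face numbering is fixed: alpha-carbon face 0 points towards the
#' N-side amide (or N-terminus), face 1 towards the C-side amide (or
#' C-terminus) and face 2 towards the methyl side chain; the amide's
#' face 0 is its C face and face 1 its N face; single-face parts use
#' face 0.
#'
#' @param scale_mm_per_angstrom Physical scale of the model,
#'   millimetres per Angstrom.  Default 18.7 (the instrumented model;
#'   the original passive model used 9.35).
#' @return A geometry table: list with elements \code{scale} and
#'   \code{parts} (one entry per kind with \code{atoms} data frame and
#'   \code{faces} list).
#' @export
default_geometry <- function(scale_mm_per_angstrom = 18.7) {
  s <- scale_mm_per_angstrom
  stopifnot(is.numeric(s), length(s) == 1L, s > 0)

  # bond lengths in Angstrom
  b <- list(CaN = 1.455, CaC = 1.51, CaCb = 1.53, CN = 1.325,
            CO = 1.23, NH = 1.01, CH = 1.09, CtO = 1.25)
  # display radii in Angstrom, by element role
  rad <- c(C = 0.70, Cr = 0.70, Ca = 0.70, N = 0.65, O = 0.60, H = 0.35)

  atom <- function(symbol, pos) {
    data.frame(symbol = symbol, x = pos[1], y = pos[2], z = pos[3],
               radius = unname(rad[symbol]), stringsAsFactors = FALSE)
  }
  deg <- function(a) a * pi / 180

  # three hydrogens arranged tetrahedrally behind a +Z face
  tripod <- function(bond) {
    zc <- -1 / 3                      # cos(109.47 deg)
    rxy <- sqrt(1 - zc^2)
    do.call(rbind, lapply(c(90, 210, 330), function(ph) {
      atom("H", bond * c(rxy * cos(deg(ph)), rxy * sin(deg(ph)), zc))
    }))
  }

  t3 <- 1 / sqrt(3)                   # tetrahedral unit component
  parts <- list()

  ## METHYL: radical carbon Cr + 3 H; one junction on its forward (+Z) axis
  parts$METHYL <- list(
    atoms = rbind(atom("Cr", c(0, 0, 0)), tripod(b$CH)),
    faces = list(.face(0, c(0, 0, 1), c(0, 0, 0), b$CaCb / 2, "SENSOR",
                       list(c("ALPHA_CARBON", "2")))))

  ## ALPHA_CARBON: Ca + H, three tetrahedral faces (passive part: magnets)
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) * t3
  parts$ALPHA_CARBON <- list(
    atoms = rbind(atom("Ca", c(0, 0, 0)), atom("H", b$CH * tet[4, ])),
    faces = list(
      .face(0, tet[1, ], c(0, 0, 0), b$CaN / 2, "MAGNET",
            list(c("AMIDE", "1"), c("N_TERM", "0"))),
      .face(1, tet[2, ], c(0, 0, 0), b$CaC / 2, "MAGNET",
            list(c("AMIDE", "0"), c("C_TERM", "0"))),
      .face(2, tet[3, ], c(0, 0, 0), b$CaCb / 2, "MAGNET",
            list(c("METHYL", "0")))))

  ## AMIDE: planar trans peptide unit C(=O)-N(H); face 0 = C face, 1 = N face
  nPos <- c(0, 0, b$CN)
  axC <- c(sin(deg(116)), 0, cos(deg(116)))      # C -> previous Calpha
  axN <- c(-sin(deg(121.7)), 0, cos(deg(58.3)))  # N -> next Calpha (trans)
  parts$AMIDE <- list(
    atoms = rbind(
      atom("C", c(0, 0, 0)),
      atom("O", b$CO * c(-sin(deg(123)), 0, cos(deg(123)))),
      atom("N", nPos),
      atom("H", nPos + b$NH * c(sin(deg(119)), 0, cos(deg(61))))),
    faces = list(
      .face(0, axC, c(0, 0, 0), b$CaC / 2, "SENSOR",
            list(c("ALPHA_CARBON", "1"))),
      .face(1, axN, nPos, b$CaN / 2, "SENSOR",
            list(c("ALPHA_CARBON", "0")))))

  ## C_TERM: carboxylate cap, junction towards the alpha-carbon on +Z
  oAx <- function(sgn) c(sgn * sin(deg(117)), 0, cos(deg(117)))
  parts$C_TERM <- list(
    atoms = rbind(atom("C", c(0, 0, 0)),
                  atom("O", b$CtO * oAx(1)),
                  atom("O", b$CtO * oAx(-1))),
    faces = list(.face(0, c(0, 0, 1), c(0, 0, 0), b$CaC / 2, "SENSOR",
                       list(c("ALPHA_CARBON", "1")))))

  ## N_TERM: ammonium cap (N + 3 H), junction on +Z
  parts$N_TERM <- list(
    atoms = rbind(atom("N", c(0, 0, 0)), tripod(b$NH)),
    faces = list(.face(0, c(0, 0, 1), c(0, 0, 0), b$CaN / 2, "SENSOR",
                       list(c("ALPHA_CARBON", "0")))))

  # convert Angstrom coordinates/lengths to model millimetres
  for (k in names(parts)) {
    parts[[k]]$atoms[, c("x", "y", "z", "radius")] <-
      parts[[k]]$atoms[, c("x", "y", "z", "radius")] * s
    parts[[k]]$faces <- lapply(parts[[k]]$faces, function(f) {
      f$anchor <- f$anchor * s
      f$length_mm <- f$length_mm * s
      f
    })
  }
  structure(list(scale = s, parts = parts), class = "geometry_table")
}

#' Instantiate a part template from a geometry table
#'
#' @param kind One of \code{\link{part_kinds}} (case-insensitive).
#' @param geometry A geometry table, see \code{\link{default_geometry}}.
#' @return A part template: list with \code{kind}, \code{atoms}
#'   (data frame of local positions, model mm) and \code{faces}.
#' @export
instantiate_part <- function(kind, geometry = default_geometry()) {
  kind <- as_part_kind(kind)
  g <- geometry$parts[[kind]]
  if (is.null(g))
    stop("geometry table has no entry for kind ", kind, call. = FALSE)
  structure(list(kind = kind, atoms = g$atoms, faces = g$faces),
            class = "part_template")
}

#' Validate a junction between two part faces
#'
#' Applies the model's chemistry rules: methyl and the two terminal caps
#' connect only to an alpha-carbon; an amide connects only to an
#' alpha-carbon, by either its C or its N face.  The relation is
#' symmetric: which part is designated parent does not change whether the
#' physical plug is allowed.
#'
#' @param parent_kind,child_kind Part kinds.
#' @param parent_face,child_face Face objects of the respective templates.
#' @return \code{TRUE} if the plug is chemically allowed, else \code{FALSE}.
#' @export
validate_connection <- function(parent_kind, parent_face,
                                child_kind, child_face) {
  parent_kind <- as_part_kind(parent_kind)
  child_kind <- as_part_kind(child_kind)
  hosts <- function(kind_a, face_a, kind_b, face_b) {
    any(vapply(face_a$allowed_partners, function(p) {
      p[1] == kind_b && as.integer(p[2]) == face_b$face_id
    }, logical(1)))
  }
  hosts(parent_kind, parent_face, child_kind, child_face) &&
    hosts(child_kind, child_face, parent_kind, parent_face)
}

# face lookup by id within a template or part
.find_face <- function(part, face_id) {
  for (f in part$faces) if (f$face_id == face_id) return(f)
  stop("part of kind ", part$kind, " has no face ", face_id, call. = FALSE)
}

#' Read / write a geometry table
#'
#' Geometry tables are stored as YAML: a top-level
#' \code{scale_mm_per_angstrom}, then one block per part kind with an
#' \code{atoms} list (symbol, x, y, z, radius — model millimetres) and a
#' \code{faces} list (face_id, axis, anchor, length_mm, role, partners as
#' \code{"KIND:face_id"} strings).
#'
#' @param path File path.
#' @param geometry A geometry table.
#' @return \code{read_geometry} returns a geometry table;
#'   \code{write_geometry} returns \code{path} invisibly.
#' @export
read_geometry <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$scale_mm_per_angstrom) || doc$scale_mm_per_angstrom <= 0)
    stop("geometry file lacks a positive scale_mm_per_angstrom", call. = FALSE)
  parts <- list()
  for (k in part_kinds()) {
    blk <- doc$parts[[k]]
    if (is.null(blk))
      stop("geometry file lacks part kind ", k, call. = FALSE)
    atoms <- do.call(rbind, lapply(blk$atoms, function(a) {
      data.frame(symbol = a$symbol, x = a$x, y = a$y, z = a$z,
                 radius = a$radius, stringsAsFactors = FALSE)
    }))
    faces <- lapply(blk$faces, function(f) {
      partners <- lapply(f$partners, function(p) strsplit(p, ":")[[1]])
      .face(f$face_id, as.numeric(f$axis), as.numeric(f$anchor),
            f$length_mm, f$role, partners)
    })
    parts[[k]] <- list(atoms = atoms, faces = faces)
  }
  structure(list(scale = doc$scale_mm_per_angstrom, parts = parts),
            class = "geometry_table")
}

#' @rdname read_geometry
#' @export
write_geometry <- function(geometry, path) {
  doc <- list(scale_mm_per_angstrom = geometry$scale, parts = list())
  for (k in names(geometry$parts)) {
    blk <- geometry$parts[[k]]
    doc$parts[[k]] <- list(
      atoms = lapply(seq_len(nrow(blk$atoms)), function(i) {
        a <- blk$atoms[i, ]
        list(symbol = a$symbol, x = a$x, y = a$y, z = a$z,
             radius = a$radius)
      }),
      faces = lapply(blk$faces, function(f) {
        list(face_id = f$face_id,
             axis = as.numeric(f$axis),
             anchor = as.numeric(f$anchor),
             length_mm = f$length_mm,
             role = f$connector_role,
             partners = vapply(f$allowed_partners,
                               function(p) paste(p, collapse = ":"),
                               character(1)))
      }))
  }
  yaml::write_yaml(doc, path, precision = 12L)
  invisible(path)
}
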