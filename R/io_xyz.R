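## Coordinate I/O: multi-frame XYZ (own small reader/writer, the format is
## the plain "count / comment / element x y z" convention), PDB via bio3d,
## and the MEP serialization (multi-record XYZ plus a tabular sidecar).

#' Write coordinates as (multi-frame) XYZ
#'
#' @param frames a coordinate matrix or a list of matrices.
#' @param elements character vector of element symbols (one per atom).
#' @param path output path.
#' @param comments optional per-frame comment lines.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(frames, elements, path, comments = NULL) {
  frames <- as_frames(frames)
  if (is.null(comments)) comments <- rep("", length(frames))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(frames)) {
    xyz <- frames[[f]]
    writeLines(c(as.character(nrow(xyz)), comments[[f]],
                 sprintf("%-2s %14.8f %14.8f %14.8f", elements,
                         xyz[, 1L], xyz[, 2L], xyz[, 3L])), con)
  }
  invisible(path)
}

#' Read a (multi-frame) XYZ file
#'
#' @param path file path.
#' @return list with `frames` (list of coordinate matrices), `elements`,
#'   and `comments`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  frames <- list(); comments <- character(); elements <- NULL
  i <- 1L
  while (i <= length(lines)) {
    n <- as.integer(trimws(lines[[i]]))
    if (is.na(n)) stop("malformed XYZ frame header at line ", i)
    comments <- c(comments, lines[[i + 1L]])
    body <- strsplit(trimws(lines[(i + 2L):(i + 1L + n)]), "\\s+")
    elements <- vapply(body, `[[`, "", 1L)
    xyz <- t(vapply(body, function(t) as.numeric(t[2:4]), numeric(3L)))
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + n
  }
  list(frames = frames, elements = elements, comments = comments)
}

#' Write coordinates of a model peptide as PDB
#'
#' @param peptide a `model_peptide`.
#' @param coords coordinate matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(peptide, coords, path) {
  bio3d::write.pdb(file = path, xyz = as.numeric(t(coords)),
                   type = "ATOM",
                   resno = rep(1L, nrow(coords)),
                   resid = rep("LIG", nrow(coords)),
                   elety = peptide$atoms$name,
                   elesy = peptide$atoms$element)
  invisible(path)
}

#' Read coordinates from a PDB file
#'
#' @param path file path.
#' @return coordinate matrix (atoms x 3).
#' @export
read_pdb_coords <- function(path) {
  pdb <- bio3d::read.pdb(path)
  matrix(pdb$xyz[1, ], ncol = 3L, byrow = TRUE)
}

#' Serialize a minimum energy path
#'
#' Writes the geometries as a multi-record XYZ file and the `(angle,
#' energy, source, converged)` table as a TSV sidecar with the same stem.
#'
#' @param mep a `mep` object ([extract_global_mep]).
#' @param stem output path stem (files `<stem>.xyz` and `<stem>.tsv`).
#' @param elements element symbols for the XYZ records.
#' @return the two paths, invisibly.
#' @export
write_mep <- function(mep, stem, elements) {
  xyz_path <- paste0(stem, ".xyz")
  tsv_path <- paste0(stem, ".tsv")
  write_xyz(mep$geoms, elements, xyz_path,
            comments = sprintf("angle %.1f energy %.8f", mep$angles,
                               mep$energies))
  tab <- data.frame(angle = mep$angles, energy = mep$energies,
                    source = mep$source, converged = mep$converged)
  utils::write.table(tab, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(xyz = xyz_path, tsv = tsv_path))
}

#' Read a minimum energy path written by [write_mep]
#'
#' @param stem path stem.
#' @param torsion torsion label to attach.
#' @return a `mep` object.
#' @export
read_mep <- function(stem, torsion = NA_character_) {
  tab <- utils::read.delim(paste0(stem, ".tsv"), stringsAsFactors = FALSE)
  xyz <- read_xyz(paste0(stem, ".xyz"))
  new_mep(torsion = torsion, angles = tab$angle, energies = tab$energy,
          geoms = xyz$frames, source = tab$source,
          converged = tab$converged, origin = "file")
}
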