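## CHARMM-style parameter file dialect: BONDS / ANGLES / DIHEDRALS /
## NONBONDED sections with whitespace-separated records, `*` or `!`
## comments.  Units: kcal/mol, Angstrom, degrees.  The GROMACS writer emits
## [ dihedraltypes ] records with function type 9 (multiple periodic terms
## per quadruple) in kJ/mol.

#' Read a CHARMM-style parameter file
#'
#' Sections: `BONDS` (`t1 t2 Kb b0`), `ANGLES` (`t1 t2 t3 Ktheta theta0
#' [Kub S0]`), `DIHEDRALS` (`t1 t2 t3 t4 K n chi0`, `X` allowed as outer
#' wildcard), `NONBONDED` (`type eps rminhalf [eps14 rmin14half]`, epsilons
#' negative by convention).
#'
#' @param path file path.
#' @return list of data frames `bonds`, `angles`, `dihedrals`, `nonbonded`.
#' @export
read_charmm_prm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("!.*$", "", lines)
  lines <- lines[!grepl("^\\s*(\\*|$)", lines)]
  lines <- trimws(lines)
  section <- NA_character_
  secs <- list(BONDS = list(), ANGLES = list(), DIHEDRALS = list(),
               NONBONDED = list())
  for (ln in lines) {
    up <- toupper(ln)
    if (up %in% c(names(secs), "END")) {
      section <- up
      next
    }
    if (is.na(section) || section == "END") next
    secs[[section]][[length(secs[[section]]) + 1L]] <-
      strsplit(ln, "\\s+")[[1L]]
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  b <- secs$BONDS
  bonds <- data.frame(
    t1 = vapply(b, `[[`, "", 1L), t2 = vapply(b, `[[`, "", 2L),
    kb = num(vapply(b, `[[`, "", 3L)), b0 = num(vapply(b, `[[`, "", 4L)),
    stringsAsFactors = FALSE)
  a <- secs$ANGLES
  angles <- data.frame(
    t1 = vapply(a, `[[`, "", 1L), t2 = vapply(a, `[[`, "", 2L),
    t3 = vapply(a, `[[`, "", 3L),
    k = num(vapply(a, `[[`, "", 4L)), th0 = num(vapply(a, `[[`, "", 5L)),
    kub = num(vapply(a, function(x) if (length(x) >= 7L) x[[6L]] else "NA", "")),
    s0 = num(vapply(a, function(x) if (length(x) >= 7L) x[[7L]] else "NA", "")),
    stringsAsFactors = FALSE)
  d <- secs$DIHEDRALS
  dihedrals <- data.frame(
    t1 = vapply(d, `[[`, "", 1L), t2 = vapply(d, `[[`, "", 2L),
    t3 = vapply(d, `[[`, "", 3L), t4 = vapply(d, `[[`, "", 4L),
    K = num(vapply(d, `[[`, "", 5L)),
    n = as.integer(vapply(d, `[[`, "", 6L)),
    chi0 = num(vapply(d, `[[`, "", 7L)),
    stringsAsFactors = FALSE)
  nb <- secs$NONBONDED
  nonbonded <- data.frame(
    type = vapply(nb, `[[`, "", 1L),
    eps = num(vapply(nb, `[[`, "", 2L)),
    rminhalf = num(vapply(nb, `[[`, "", 3L)),
    eps14 = num(vapply(nb, function(x) if (length(x) >= 5L) x[[4L]]
                       else "NA", "")),
    rmin14half = num(vapply(nb, function(x) if (length(x) >= 5L) x[[5L]]
                            else "NA", "")),
    stringsAsFactors = FALSE)
  list(bonds = bonds, angles = angles, dihedrals = dihedrals,
       nonbonded = nonbonded)
}

#' The shipped generic parameter set
#'
#' Loads the synthetic idealized CHARMM-style parameter set used for the
#' model diamides (generic amide/aliphatic bond, angle, wildcard-dihedral
#' and Lennard-Jones parameters).
#'
#' @return parameter list as from [read_charmm_prm].
#' @export
default_parameters <- function() {
  read_charmm_prm(system.file("extdata", "betamep_generic.prm",
                              package = "betamep", mustWork = TRUE))
}

#' Write fitted dihedral terms as force-field parameter records
#'
#' Emits the proper dihedral records of a term table in the CHARMM dialect
#' (`t1 t2 t3 t4 K n chi0`, kcal/mol) or as GROMACS `[ dihedraltypes ]`
#' function-type-9 records (kJ/mol, conversion factor exactly 4.184).
#' Record order is deterministic (input order).  Barrier heights must be
#' non-negative: run [sign_adjust] first.
#'
#' @param terms term data frame with columns `t1`..`t4`, `n`, `K`, `chi0`
#'   (e.g. from [format_constraint_table]).
#' @param path output file path.
#' @param dialect `"charmm"` or `"gromacs"`.
#' @return `path`, invisibly.
#' @export
write_dihedral_parameters <- function(terms, path,
                                      dialect = c("charmm", "gromacs")) {
  dialect <- match.arg(dialect)
  if (any(terms$K < 0)) {
    stop("negative barrier heights; apply sign_adjust() before writing")
  }
  if (dialect == "charmm") {
    out <- c("* proper dihedral parameters (kcal/mol, degrees)",
             "DIHEDRALS",
             sprintf("%-6s %-6s %-6s %-6s %10.6f %2d %8.2f",
                     terms$t1, terms$t2, terms$t3, terms$t4,
                     terms$K, terms$n, terms$chi0),
             "END")
  } else {
    out <- c("; proper dihedral parameters (kJ/mol, degrees), funct 9",
             "[ dihedraltypes ]",
             ";  i      j      k      l   func    phi0        kphi  mult",
             sprintf("%-6s %-6s %-6s %-6s %4d %8.2f %12.6f %4d",
                     terms$t1, terms$t2, terms$t3, terms$t4,
                     9L, terms$chi0, terms$K * KJ_PER_KCAL, terms$n))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read dihedral parameter records written by [write_dihedral_parameters]
#'
#' @param path file path.
#' @param dialect `"charmm"` or `"gromacs"`; GROMACS kJ/mol values are
#'   converted back to kcal/mol.
#' @return data frame with columns `t1`..`t4`, `n`, `K`, `chi0`.
#' @export
read_dihedral_parameters <- function(path, dialect = c("charmm", "gromacs")) {
  dialect <- match.arg(dialect)
  if (dialect == "charmm") {
    return(read_charmm_prm(path)$dihedrals[, c("t1", "t2", "t3", "t4",
                                               "n", "K", "chi0")])
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub(";.*$", "", lines)
  lines <- trimws(lines[!grepl("^\\s*(\\[|$)", lines)])
  lines <- lines[nzchar(lines)]
  toks <- strsplit(lines, "\\s+")
  data.frame(
    t1 = vapply(toks, `[[`, "", 1L), t2 = vapply(toks, `[[`, "", 2L),
    t3 = vapply(toks, `[[`, "", 3L), t4 = vapply(toks, `[[`, "", 4L),
    n = as.integer(vapply(toks, `[[`, "", 8L)),
    K = as.numeric(vapply(toks, `[[`, "", 7L)) / KJ_PER_KCAL,
    chi0 = as.numeric(vapply(toks, `[[`, "", 6L)),
    stringsAsFactors = FALSE)
}
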