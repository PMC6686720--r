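## The four protected beta-amino-acid diamide model compounds and the
## enumeration of the backbone torsions that the new carbon atom types
## (CTA1, CTA2, CTB1, CTB2) introduce.

NEW_CARBON_TYPES <- c("CTA1", "CTA2", "CTB1", "CTB2")
DIAMIDE_NAMES <- c("beta0", "beta2", "beta3", "beta23")

#' Build one of the four beta-amino-acid diamide model compounds
#'
#' Loads the shipped topology of a protected diamide (acetyl- and
#' N-methylamide-capped beta-alanine derivative): `"beta0"` is the achiral
#' compound, `"beta3"` carries a methyl on the beta carbon (types CTA1/CTA2
#' for C-beta/C-alpha), `"beta2"` on the alpha carbon (types CTB2/CTB1) and
#' `"beta23"` on both (CTA1/CTB1).  Hydrogens on substituted backbone
#' carbons are typed HB1, on unsubstituted ones HB2.  Atom typing is
#' chirality-independent; `mirror = TRUE` builds the enantiomer, which flips
#' every chirality tag and negates all torsion values of the idealized
#' geometry.
#'
#' @param name one of `"beta0"`, `"beta2"`, `"beta3"`, `"beta23"`.
#' @param mirror logical; build the mirror image.
#' @return an object of class `model_peptide`: a list with elements `name`,
#'   `atoms` (data frame: `name`, `type`, `element`, `charge`, `backbone`),
#'   `bonds` (two-column index matrix), `chirality` (named character),
#'   `tors` (named list of backbone torsion index quadruples, names `phi`,
#'   `theta`, `psi`), `free_vars`, `vars` (default torsion variable values,
#'   degrees) and `build` (internal-coordinate construction table).
#' @examples
#' b3 <- build_diamide("beta3")
#' subset(b3$atoms, name %in% c("CB", "CA"))$type   # "CTA1" "CTA2"
#' @export
build_diamide <- function(name, mirror = FALSE) {
  if (length(name) != 1L || !name %in% DIAMIDE_NAMES) {
    stop("unknown diamide '", paste(name, collapse = ","),
         "'; valid names are: ", paste(DIAMIDE_NAMES, collapse = ", "))
  }
  path <- system.file("extdata", paste0(name, ".top"), package = "betamep",
                      mustWork = TRUE)
  pep <- read_topology(path)
  pep$name <- name
  if (mirror) {
    pep$chirality[] <- ifelse(pep$chirality == "S", "R", "S")
    pep$vars <- -pep$vars
    pep$build$torsion <- -pep$build$torsion
    pep$build$toffset <- -pep$build$toffset
    pep$build_arrays <- make_build_arrays(pep)
    pep$mirror <- TRUE
  }
  pep
}

#' Read a diamide topology file
#'
#' Parses the plain-text topology format shipped under `inst/extdata`
#' (`ATOM name type charge`, `BOND a b`, `BACKBONE ...`, `TORS label i j k
#' l`, `CHIR atom S|R`, `FREE vars`, `VAR name value`, and `BUILD` records
#' holding idealized internal coordinates; `*` starts a comment line).
#'
#' @param path file path.
#' @return a `model_peptide` object (see [build_diamide]).
#' @export
read_topology <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(\\*|!|$)", lines)]
  toks <- strsplit(trimws(lines), "\\s+")
  rec <- vapply(toks, `[[`, "", 1L)

  take <- function(key) toks[rec == key]

  at <- take("ATOM")
  atoms <- data.frame(
    name = vapply(at, `[[`, "", 2L),
    type = vapply(at, `[[`, "", 3L),
    charge = as.numeric(vapply(at, `[[`, "", 4L)),
    stringsAsFactors = FALSE
  )
  atoms$element <- substr(atoms$type, 1L, 1L)
  if (anyDuplicated(atoms$name)) stop("duplicate atom names in ", path)
  idx <- function(nm) {
    i <- match(nm, atoms$name)
    if (anyNA(i)) stop("unknown atom name(s): ",
                       paste(nm[is.na(i)], collapse = ", "))
    i
  }

  bd <- take("BOND")
  bonds <- cbind(idx(vapply(bd, `[[`, "", 2L)),
                 idx(vapply(bd, `[[`, "", 3L)))

  bb <- take("BACKBONE")
  backbone_names <- if (length(bb)) bb[[1L]][-1L] else character()
  atoms$backbone <- atoms$name %in% backbone_names

  ts <- take("TORS")
  tors <- lapply(ts, function(t) idx(t[3:6]))
  names(tors) <- vapply(ts, `[[`, "", 2L)

  ch <- take("CHIR")
  chirality <- vapply(ch, `[[`, "", 3L)
  names(chirality) <- vapply(ch, `[[`, "", 2L)

  fr <- take("FREE")
  free_vars <- if (length(fr)) fr[[1L]][-1L] else character()

  vr <- take("VAR")
  vars <- as.numeric(vapply(vr, `[[`, "", 3L))
  names(vars) <- vapply(vr, `[[`, "", 2L)

  bl <- take("BUILD")
  ref_or_na <- function(x) {
    out <- rep(NA_integer_, length(x))
    out[x != "-"] <- idx(x[x != "-"])
    out
  }
  build <- data.frame(
    atom = idx(vapply(bl, `[[`, "", 2L)),
    ref1 = ref_or_na(vapply(bl, `[[`, "", 3L)),
    ref2 = ref_or_na(vapply(bl, `[[`, "", 4L)),
    ref3 = ref_or_na(vapply(bl, `[[`, "", 5L)),
    bond = as.numeric(vapply(bl, `[[`, "", 6L)),
    angle = as.numeric(vapply(bl, `[[`, "", 7L)),
    stringsAsFactors = FALSE
  )
  parsed <- parse_torsion_expr(vapply(bl, `[[`, "", 8L))
  build$tvar <- parsed$var
  build$torsion <- parsed$base
  build$toffset <- parsed$offset

  net <- sum(atoms$charge)
  if (abs(net - round(net)) > 1e-6) {
    stop("net charge ", format(net), " of ", path, " is not an integer")
  }
  if (!graph_connected(nrow(atoms), bonds)) {
    stop("bond graph of ", path, " is not connected")
  }

  pep <- structure(list(name = NA_character_, atoms = atoms, bonds = bonds,
                        chirality = chirality, tors = tors,
                        free_vars = free_vars, vars = vars, build = build,
                        mirror = FALSE),
                   class = "model_peptide")
  pep$build_arrays <- make_build_arrays(pep)
  pep
}

## "@phi+120" -> var "phi", base NA, offset 120; "180" -> var NA, base 180.
parse_torsion_expr <- function(x) {
  var <- rep(NA_character_, length(x))
  base <- rep(NA_real_, length(x))
  offset <- rep(0, length(x))
  isvar <- startsWith(x, "@")
  base[!isvar] <- as.numeric(x[!isvar])
  body <- sub("^@", "", x[isvar])
  m <- regmatches(body, regexec("^([A-Za-z0-9]+)([+-][0-9.]+)?$", body))
  var[isvar] <- vapply(m, `[[`, "", 2L)
  off <- vapply(m, `[[`, "", 3L)
  offset[isvar] <- ifelse(off == "", 0, as.numeric(off))
  list(var = var, base = base, offset = offset)
}

graph_connected <- function(n, bonds) {
  if (n == 0L) return(TRUE)
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1L]; j <- bonds[k, 2L]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  seen <- logical(n)
  stack <- 1L
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    if (seen[v]) next
    seen[v] <- TRUE
    stack <- c(stack, adj[[v]][!seen[adj[[v]]]])
  }
  all(seen)
}

#' @export
print.model_peptide <- function(x, ...) {
  cat("Model peptide '", x$name, "': ", nrow(x$atoms), " atoms, ",
      nrow(x$bonds), " bonds\n", sep = "")
  cat("  atom types:",
      paste(sort(unique(x$atoms$type)), collapse = " "), "\n")
  if (length(x$chirality)) {
    cat("  stereocenters:",
        paste(names(x$chirality), x$chirality, sep = ":", collapse = " "),
        "\n")
  }
  invisible(x)
}

#' Canonical atom-type key of a torsion quadruple
#'
#' A proper dihedral is identified by its four atom types read in either
#' direction; the canonical key is the lexicographically smaller of the
#' forward and reversed sequence, joined by `-`.
#'
#' @param types character vector of four atom-type labels.
#' @return the canonical key string.
#' @export
canonical_quad <- function(types) {
  fwd <- paste(types, collapse = "-")
  rev_ <- paste(rev(types), collapse = "-")
  if (fwd <= rev_) fwd else rev_
}

canonical_types <- function(types) {
  fwd <- paste(types, collapse = "-")
  rev_ <- paste(rev(types), collapse = "-")
  if (fwd <= rev_) types else rev(types)
}

## All atom-index quadruples i-j-k-l around a given central bond (j, k).
quads_around_bond <- function(peptide, j, k) {
  nb <- function(v, excl) {
    b <- peptide$bonds
    out <- c(b[b[, 1L] == v, 2L], b[b[, 2L] == v, 1L])
    setdiff(out, excl)
  }
  is_ <- nb(j, k)
  ls_ <- nb(k, j)
  if (!length(is_) || !length(ls_)) return(NULL)
  g <- expand.grid(i = is_, l = ls_)
  cbind(g$i, rep(j, nrow(g)), rep(k, nrow(g)), g$l)
}

#' Enumerate the new backbone torsions of a model diamide
#'
#' Lists the proper dihedral angles around the backbone bonds (N--C-beta,
#' C-beta--C-alpha, C-alpha--C) whose central bond involves at least one of
#' the new carbon atom types (CTA1, CTA2, CTB1, CTB2).  Torsions are
#' deduplicated by canonical atom-type quadruple (a quadruple and its
#' reverse count once), and quadruples already present in `previously_seen`
#' are skipped, so processing the four compounds in the order beta0, beta2,
#' beta3, beta23 reproduces the per-molecule counts 12, 14, 14 and 13.
#'
#' @param peptide a `model_peptide`.
#' @param previously_seen character vector of canonical quadruple keys (as
#'   returned in the `key` column) found in previously processed molecules.
#' @return a data frame with one row per new torsion: atom types `t1`--`t4`
#'   (canonical orientation), `key`, the backbone bond it belongs to
#'   (`bond`, one of `"phi"`, `"theta"`, `"psi"`), the number of matching
#'   atom quadruples `n_instances`, and a list column `instances` of
#'   atom-index quadruple matrices.
#' @examples
#' nrow(enumerate_new_torsions(build_diamide("beta0")))   # 12
#' @export
enumerate_new_torsions <- function(peptide, previously_seen = character()) {
  stopifnot(inherits(peptide, "model_peptide"))
  if (!graph_connected(nrow(peptide$atoms), peptide$bonds)) {
    stop("disconnected bond graph")
  }
  types <- peptide$atoms$type
  bb <- which(peptide$atoms$backbone)
  b <- peptide$bonds
  on_bb <- b[, 1L] %in% bb & b[, 2L] %in% bb
  has_new <- types[b[, 1L]] %in% NEW_CARBON_TYPES |
    types[b[, 2L]] %in% NEW_CARBON_TYPES
  central <- b[on_bb & has_new, , drop = FALSE]

  ## label the central bond as phi/theta/psi via the backbone torsion defs
  bond_label <- function(j, k) {
    for (nm in names(peptide$tors)) {
      q <- peptide$tors[[nm]]
      if (setequal(c(j, k), q[2:3])) return(nm)
    }
    NA_character_
  }

  rows <- list()
  for (r in seq_len(nrow(central))) {
    j <- central[r, 1L]; k <- central[r, 2L]
    quads <- quads_around_bond(peptide, j, k)
    lab <- bond_label(j, k)
    for (q in seq_len(nrow(quads))) {
      tq <- types[quads[q, ]]
      key <- canonical_quad(tq)
      if (is.null(rows[[key]])) {
        rows[[key]] <- list(types = canonical_types(tq), bond = lab,
                            instances = list(quads[q, , drop = FALSE]))
      } else {
        rows[[key]]$instances <- c(rows[[key]]$instances,
                                   list(quads[q, , drop = FALSE]))
      }
    }
  }
  keep <- setdiff(names(rows), previously_seen)
  rows <- rows[keep]
  if (!length(rows)) {
    return(data.frame(t1 = character(), t2 = character(), t3 = character(),
                      t4 = character(), key = character(), bond = character(),
                      n_instances = integer()))
  }
  out <- data.frame(
    t1 = vapply(rows, function(x) x$types[1L], ""),
    t2 = vapply(rows, function(x) x$types[2L], ""),
    t3 = vapply(rows, function(x) x$types[3L], ""),
    t4 = vapply(rows, function(x) x$types[4L], ""),
    key = names(rows),
    bond = vapply(rows, function(x) x$bond, ""),
    n_instances = vapply(rows, function(x) length(x$instances), 0L),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out$instances <- lapply(rows, function(x) do.call(rbind, x$instances))
  out
}

#' Measure the backbone dihedral angles of a conformation
#'
#' @param peptide a `model_peptide`.
#' @param coords coordinate matrix (one row per atom, Angstrom).
#' @return named numeric vector of backbone torsions (degrees, IUPAC sign
#'   convention, `(-180, 180]`), typically `phi`, `theta`, `psi`.
#' @export
measure_dihedrals <- function(peptide, coords) {
  stopifnot(inherits(peptide, "model_peptide"),
            nrow(coords) == nrow(peptide$atoms))
  vapply(peptide$tors, function(q) dihedral_angle(coords, q), 0)
}
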