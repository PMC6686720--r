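## Candidate dihedral terms and the constraint algebra that reduces them to
## an independent parameter set: phases restricted to {0, 180} (stereoisomer
## and atom-order invariance), zeroing of terms that involve the aliphatic
## backbone hydrogens, supplementary amide pairs, sp3 triplets,
## histogram-based multiplicity selection, and post-fit correlation merging
## with sign adjustment.

H_ZERO_TYPES <- c("HB1", "HB2")

#' Generate candidate periodic dihedral terms
#'
#' Instantiates one term `K (1 + cos(n chi - chi0))` per (torsion,
#' multiplicity) combination.  All phases start at 0 (a phase of 180 is
#' equivalent to a negative barrier height, so the phase carries no extra
#' freedom during fitting); terms whose atom-type quadruple contains the
#' aliphatic backbone hydrogen types HB1 or HB2 are emitted with the barrier
#' height fixed to zero and are excluded from fitting, since the positions
#' of those hydrogens are dominated by angle terms.
#'
#' @param torsions data frame as returned by [enumerate_new_torsions]
#'   (columns `t1`..`t4`, `key`; a `molecule` and `torsion` label column are
#'   carried through when present).
#' @param multiplicities either a single integer vector used for every
#'   torsion, or a named list keyed by torsion `key`.
#' @return a data frame of terms with columns `molecule`, `torsion`,
#'   `t1`..`t4`, `key`, `n`, `K`, `chi0`, `fixed_zero`.
#' @examples
#' tt <- enumerate_new_torsions(build_diamide("beta0"))
#' nrow(generate_candidate_terms(tt, 1:6))   # 12 torsions x 6 = 72
#' @export
generate_candidate_terms <- function(torsions, multiplicities = c(1, 2, 3, 6)) {
  get_mult <- function(key) {
    m <- if (is.list(multiplicities)) multiplicities[[key]] else multiplicities
    if (is.null(m)) stop("no multiplicity set for torsion ", key)
    if (!all(m %in% 1:6)) {
      stop("multiplicities must lie in 1..6, got: ",
           paste(setdiff(m, 1:6), collapse = ", "))
    }
    sort(unique(as.integer(m)))
  }
  rows <- lapply(seq_len(nrow(torsions)), function(i) {
    ns <- get_mult(torsions$key[i])
    data.frame(
      molecule = if ("molecule" %in% names(torsions))
        torsions$molecule[i] else NA_character_,
      torsion = if ("torsion" %in% names(torsions))
        torsions$torsion[i] else torsions$key[i],
      t1 = torsions$t1[i], t2 = torsions$t2[i],
      t3 = torsions$t3[i], t4 = torsions$t4[i],
      key = torsions$key[i], n = ns, K = 0, chi0 = 0,
      stringsAsFactors = FALSE
    )
  })
  if (!length(rows)) {
    out <- data.frame(molecule = character(), torsion = character(),
                      t1 = character(), t2 = character(), t3 = character(),
                      t4 = character(), key = character(), n = integer(),
                      K = numeric(), chi0 = numeric())
  } else {
    out <- do.call(rbind, rows)
  }
  out$fixed_zero <- out$t1 %in% H_ZERO_TYPES | out$t2 %in% H_ZERO_TYPES |
    out$t3 %in% H_ZERO_TYPES | out$t4 %in% H_ZERO_TYPES
  rownames(out) <- NULL
  out
}

#' Constraint system over dihedral terms
#'
#' Bundles a term table with its grouping into independent parameters.
#' Every non-zero term belongs to exactly one constraint group; all members
#' of a group share one barrier-height magnitude (the group's independent
#' parameter), and each member's own phase (0 or 180) encodes its relation
#' to the representative.  Zero-fixed terms (aliphatic hydrogen quadruples)
#' carry no group.
#'
#' @param terms data frame of terms (see [generate_candidate_terms]) with an
#'   optional `group` column of group labels; terms without a label form
#'   their own singleton group.
#' @return an object of class `constraint_system` with elements `terms`
#'   (the table, with integer `group` ids) and `groups` (data frame `id`,
#'   `label`, `K`).
#' @export
constraint_system <- function(terms) {
  stopifnot(is.data.frame(terms))
  terms$fixed_zero <- isTRUE_vec(terms$fixed_zero)
  terms$K <- as.numeric(terms$K)
  terms$chi0 <- as.numeric(terms$chi0)
  own_label <- paste(terms$molecule, terms$torsion, terms$n, sep = ".")
  lab <- if ("group" %in% names(terms)) terms$group else rep(NA, nrow(terms))
  lab <- ifelse(is.na(lab) | lab == "" | lab == "-", own_label, lab)
  lab[terms$fixed_zero] <- NA
  ids <- unique(lab[!is.na(lab)])
  terms$group <- match(lab, ids)
  ## group K: taken from its first member (the representative row)
  gK <- vapply(seq_along(ids), function(g) {
    abs(terms$K[which(terms$group == g)[1L]])
  }, 0)
  sys <- structure(
    list(terms = terms,
         groups = data.frame(id = seq_along(ids), label = ids, K = gK,
                             stringsAsFactors = FALSE)),
    class = "constraint_system")
  validate_constraint_system(sys)
  sys
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else x %in% TRUE

validate_constraint_system <- function(sys) {
  tr <- sys$terms
  if (!all(tr$chi0 %in% c(0, 180))) {
    stop("term phases must be 0 or 180 degrees")
  }
  nz <- !tr$fixed_zero
  if (any(is.na(tr$group[nz]))) stop("non-zero term without constraint group")
  if (any(!is.na(tr$group[!nz]))) stop("zero-fixed term carries a group")
  invisible(sys)
}

#' @export
print.constraint_system <- function(x, ...) {
  cp <- count_parameters(x)
  cat("Constraint system: ", nrow(x$terms), " terms (",
      cp[["n_terms_nonzero"]], " non-zero, ",
      sum(x$terms$fixed_zero), " fixed to zero), ",
      cp[["n_independent"]], " independent parameters\n", sep = "")
  invisible(x)
}

#' Count non-zero terms and independent parameters
#'
#' @param system a `constraint_system`.
#' @return named integer vector `c(n_terms_nonzero, n_independent)`.  For
#'   the four shipped diamides with the published multiplicities this is
#'   exactly `c(96, 38)`.
#' @export
count_parameters <- function(system) {
  stopifnot(inherits(system, "constraint_system"))
  c(n_terms_nonzero = sum(!system$terms$fixed_zero),
    n_independent = nrow(system$groups))
}

#' The published constraint system for the four model diamides
#'
#' Loads the shipped table of optimized backbone dihedral terms of the four
#' diamides (torsion labels, atom-type quadruples, multiplicities, barrier
#' heights, phases and the constrained-to relations) and assembles the
#' corresponding `constraint_system`: 96 non-zero terms in 38 independent
#' parameter groups.
#'
#' @param file optional path to an alternative table in the same TSV layout.
#' @return a `constraint_system`.
#' @examples
#' count_parameters(published_constraint_system())
#' @export
published_constraint_system <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "published_terms.tsv",
                        package = "betamep", mustWork = TRUE)
  }
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  tab$key <- apply(tab[, c("t1", "t2", "t3", "t4")], 1L, canonical_quad)
  ind <- tab$ref_molecule == "-"
  tab$group <- ifelse(ind,
                      paste(tab$molecule, tab$torsion, tab$n, sep = "."),
                      paste(tab$ref_molecule, tab$ref_torsion, tab$n,
                            sep = "."))
  ## every reference must resolve to an independent row
  own <- paste(tab$molecule, tab$torsion, tab$n, sep = ".")
  bad <- setdiff(tab$group, own[ind])
  if (length(bad)) {
    stop("constrained-to references without independent target: ",
         paste(bad, collapse = ", "))
  }
  tab$fixed_zero <- FALSE
  ## order so that each group's first member is its independent representative
  tab <- tab[order(!ind), , drop = FALSE]
  sys <- constraint_system(tab)
  sys
}

## neighbours of atom v in a model_peptide
atom_neighbours <- function(peptide, v, excl = integer()) {
  b <- peptide$bonds
  setdiff(c(b[b[, 1L] == v, 2L], b[b[, 2L] == v, 1L]), excl)
}

#' Supplementary torsion pairs around planar amide groups
#'
#' Around a planar (sp2) centre with exactly two flanking substituents, the
#' two torsions that share the remaining three atoms are supplementary
#' (their angles sum to 180 degrees).  For terms of the same odd
#' multiplicity the pair must share one barrier-height magnitude with phases
#' differing by 180; for even multiplicities both barrier height and phase
#' are shared.  Detection assumes ideal amide planarity and works on the
#' topology alone.
#'
#' @param terms term table ([generate_candidate_terms]) for one molecule.
#' @param peptide the `model_peptide` the terms refer to.
#' @return a data frame of pair relations: term row indices `i`, `j`, their
#'   multiplicity `n`, and `phase_shift` (180 for odd `n`, 0 for even).
#' @export
supplementary_pair_groups <- function(terms, peptide) {
  types <- peptide$atoms$type
  elem <- peptide$atoms$element
  sp2 <- which(vapply(seq_len(nrow(peptide$atoms)), function(v) {
    elem[v] %in% c("C", "N") && length(atom_neighbours(peptide, v)) == 3L
  }, TRUE))

  ## map: for every sp2 centre v bonded to central partner w, the two other
  ## substituents a1, a2 give supplementary quadruple pairs
  ## (a1, v, w, x) vs (a2, v, w, x) for all x.
  pair_keys <- list()
  for (v in sp2) {
    for (w in atom_neighbours(peptide, v)) {
      subs <- atom_neighbours(peptide, v, excl = w)
      if (length(subs) != 2L) next
      far <- atom_neighbours(peptide, w, excl = v)
      for (x in far) {
        k1 <- canonical_quad(types[c(subs[1L], v, w, x)])
        k2 <- canonical_quad(types[c(subs[2L], v, w, x)])
        if (k1 == k2) next
        pr <- sort(c(k1, k2))
        pair_keys[[paste(pr, collapse = "|")]] <- pr
      }
    }
  }
  out <- list()
  for (pr in pair_keys) {
    i <- which(terms$key == pr[1L] & !terms$fixed_zero)
    j <- which(terms$key == pr[2L] & !terms$fixed_zero)
    if (!length(i) || !length(j)) next
    common_n <- intersect(terms$n[i], terms$n[j])
    for (n in common_n) {
      out[[length(out) + 1L]] <- data.frame(
        i = i[terms$n[i] == n], j = j[terms$n[j] == n], n = n,
        phase_shift = if (n %% 2L == 1L) 180 else 0)
    }
  }
  if (!length(out)) {
    return(data.frame(i = integer(), j = integer(), n = integer(),
                      phase_shift = numeric()))
  }
  do.call(rbind, out)
}

#' sp3 torsion triplets around tetrahedral backbone carbons
#'
#' Around an sp3 centre, torsions that share three common atoms are
#' separated by approximately 120 degrees.  Requiring their potential
#' contributions to be identical up to a constant is only compatible with
#' phases restricted to {0, 180} when the 120-degree shift is a whole number
#' of periods, i.e. for multiplicities 3 and 6; for other multiplicities the
#' members stay independent.
#'
#' @param terms term table for one molecule.
#' @param peptide the `model_peptide`.
#' @param multiplicities multiplicities for which grouping is valid
#'   (default `c(3, 6)`).
#' @return a data frame of triplet relations: list of term row index groups
#'   per multiplicity (columns `members` (list), `n`).
#' @export
sp3_triplet_groups <- function(terms, peptide, multiplicities = c(3, 6)) {
  types <- peptide$atoms$type
  elem <- peptide$atoms$element
  sp3 <- which(vapply(seq_len(nrow(peptide$atoms)), function(v) {
    elem[v] == "C" && length(atom_neighbours(peptide, v)) == 4L
  }, TRUE))

  trip_sets <- list()
  for (v in sp3) {
    for (w in atom_neighbours(peptide, v)) {
      subs <- atom_neighbours(peptide, v, excl = w)
      if (length(subs) != 3L) next
      far <- atom_neighbours(peptide, w, excl = v)
      for (x in far) {
        keys <- unique(vapply(subs, function(s) {
          canonical_quad(types[c(s, v, w, x)])
        }, ""))
        if (length(keys) < 2L) next
        trip_sets[[paste(sort(keys), collapse = "|")]] <- sort(keys)
      }
    }
  }
  out <- list()
  for (keys in trip_sets) {
    for (n in multiplicities) {
      members <- which(terms$key %in% keys & terms$n == n &
                         !terms$fixed_zero)
      if (length(members) >= 2L) {
        out[[length(out) + 1L]] <- list(members = members, n = n)
      }
    }
  }
  data.frame(
    members = I(lapply(out, `[[`, "members")),
    n = vapply(out, `[[`, 0, "n")
  )
}

#' Select the minimal multiplicity set covering histogram modes
#'
#' The most frequently occurring relaxed torsion values in a scan localize
#' around the minima of the torsional wells, so the multiplicities required
#' for a torsion can be read off a histogram of its relaxed values: the
#' smallest set of multiplicities from `candidates` such that every mode of
#' a circular kernel density estimate lies within `tol` of a minimum of some
#' `cos(n chi - chi0)` well, with a single phase `chi0` in {0, 180} per
#' multiplicity.  Modes at +/-60, +/-90 and +/-150 degrees, for example,
#' require the set {3, 6}.
#'
#' @param samples relaxed torsion angle samples in degrees.
#' @param candidates multiplicities considered (default `c(1, 2, 3, 6)`,
#'   the values compatible with sp2/sp3 backbone hybridization).
#' @param tol mode-to-minimum tolerance in degrees (default 15).
#' @param bandwidth circular KDE bandwidth in degrees (default 5).
#' @param prominence minimum KDE peak height relative to the largest peak
#'   (default 0.1).
#' @return integer vector: the selected multiplicity set.
#' @export
multiplicities_from_histogram <- function(samples,
                                          candidates = c(1, 2, 3, 6),
                                          tol = 15, bandwidth = 5,
                                          prominence = 0.1) {
  if (!length(samples)) stop("no torsion angle samples supplied")
  samples <- wrap_angle(samples)
  kde <- circular_kde(samples, bandwidth = bandwidth)
  d <- kde$y
  ng <- length(d)
  up <- d > d[c(ng, seq_len(ng - 1L))]
  dn <- d >= d[c(seq.int(2L, ng), 1L)]
  peaks <- which(up & dn & d >= prominence * max(d))
  modes <- kde$x[peaks]
  if (!length(modes)) modes <- kde$x[which.max(d)]

  covers <- function(set) {
    ## one chi0 per multiplicity; try all 2^|set| assignments
    grid <- expand.grid(rep(list(c(0, 180)), length(set)))
    for (g in seq_len(nrow(grid))) {
      chi0 <- as.numeric(grid[g, ])
      ok <- vapply(modes, function(m) {
        any(vapply(seq_along(set), function(s) {
          minima <- (180 + chi0[s] + 360 * (0:(set[s] - 1L))) / set[s]
          any(abs(angle_diff(m, minima)) <= tol)
        }, TRUE))
      }, TRUE)
      if (all(ok)) return(TRUE)
    }
    FALSE
  }

  candidates <- sort(unique(as.integer(candidates)))
  for (size in seq_along(candidates)) {
    sets <- utils::combn(candidates, size, simplify = FALSE)
    for (set in sets) if (covers(set)) return(set)
  }
  candidates
}

#' Merge strongly correlated independent parameters
#'
#' After a least-squares fit, parameter pairs whose correlation exceeds the
#' threshold in magnitude are constrained together: positively correlated
#' pairs share one parameter with unchanged phases; anticorrelated pairs are
#' made equal by flipping the phase (0 <-> 180) of every term of one member,
#' which is equivalent to constraining the original parameters to be
#' opposite.  Merging is applied transitively; the surviving representative
#' of each merged cluster is the group with the lowest id.
#'
#' @param system a `constraint_system`.
#' @param correlation symmetric correlation matrix over the independent
#'   parameters (unit diagonal), in group order.
#' @param threshold absolute correlation above which groups merge
#'   (default 0.9).
#' @return the merged `constraint_system`.
#' @export
merge_correlated <- function(system, correlation, threshold = 0.9) {
  stopifnot(inherits(system, "constraint_system"))
  ng <- nrow(system$groups)
  if (!is.matrix(correlation) || any(dim(correlation) != ng)) {
    stop("correlation matrix must be ", ng, " x ", ng)
  }
  if (max(abs(correlation - t(correlation))) > 1e-8) {
    stop("correlation matrix is not symmetric")
  }

  parent <- seq_len(ng)
  sign_to_parent <- rep(1, ng)
  find <- function(i) {
    s <- 1
    while (parent[i] != i) {
      s <- s * sign_to_parent[i]
      i <- parent[i]
    }
    list(root = i, sign = s)
  }
  for (i in seq_len(ng - 1L)) {
    for (j in seq.int(i + 1L, ng)) {
      r <- correlation[i, j]
      if (abs(r) <= threshold) next
      fi <- find(i); fj <- find(j)
      if (fi$root == fj$root) next
      rel <- sign(r) * fi$sign * fj$sign
      ## attach the larger root under the smaller one
      a <- min(fi$root, fj$root); b <- max(fi$root, fj$root)
      parent[b] <- a
      sign_to_parent[b] <- if (a == fi$root) rel else rel
    }
  }
  root <- integer(ng); rsign <- numeric(ng)
  for (i in seq_len(ng)) {
    f <- find(i); root[i] <- f$root; rsign[i] <- f$sign
  }

  terms <- system$terms
  flip <- !is.na(terms$group) & rsign[ifelse(is.na(terms$group), 1L,
                                             terms$group)] < 0
  terms$chi0[flip] <- (terms$chi0[flip] + 180) %% 360
  new_ids <- unique(root)
  terms$group <- ifelse(is.na(terms$group), NA,
                        match(root[ifelse(is.na(terms$group), 1L,
                                          terms$group)], new_ids))
  groups <- data.frame(id = seq_along(new_ids),
                       label = system$groups$label[new_ids],
                       K = system$groups$K[new_ids],
                       stringsAsFactors = FALSE)
  structure(list(terms = terms, groups = groups), class = "constraint_system")
}

#' Make all barrier heights non-negative by phase flipping
#'
#' A term with a negative barrier height is converted to an equivalent one
#' with positive height and the phase flipped between 0 and 180; the
#' dihedral energy profile changes only by the constant `-2K`, which has no
#' effect on forces or dynamics.
#'
#' @param terms a term data frame with columns `K` and `chi0`, or a
#'   `constraint_system` (adjusted group-wise).
#' @return the adjusted object, same class as the input.
#' @examples
#' sign_adjust(data.frame(K = -0.3, n = 2, chi0 = 0))   # K 0.3, chi0 180
#' @export
sign_adjust <- function(terms) {
  if (inherits(terms, "constraint_system")) {
    neg <- which(terms$groups$K < 0)
    for (g in neg) {
      members <- which(terms$terms$group %in% g)
      terms$terms$chi0[members] <- (terms$terms$chi0[members] + 180) %% 360
      terms$terms$K[members] <- -terms$terms$K[members]
      terms$groups$K[g] <- -terms$groups$K[g]
    }
    return(terms)
  }
  stopifnot(is.data.frame(terms))
  neg <- terms$K < 0
  terms$chi0[neg] <- (terms$chi0[neg] + 180) %% 360
  terms$K[neg] <- -terms$K[neg]
  terms
}

#' Format a constraint system as a publication-style table
#'
#' @param system a `constraint_system`.
#' @return data frame with one row per term: molecule, torsion label, atom
#'   types, multiplicity, barrier height, phase and the label of the
#'   parameter the term is constrained to (empty for representatives).
#' @export
format_constraint_table <- function(system) {
  tr <- system$terms
  first_of_group <- !duplicated(tr$group) & !is.na(tr$group)
  constrained_to <- ifelse(
    is.na(tr$group) | first_of_group, "",
    system$groups$label[tr$group])
  data.frame(
    molecule = tr$molecule, torsion = tr$torsion,
    t1 = tr$t1, t2 = tr$t2, t3 = tr$t3, t4 = tr$t4,
    n = tr$n, K = tr$K, chi0 = tr$chi0,
    constrained_to = constrained_to,
    stringsAsFactors = FALSE
  )
}
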