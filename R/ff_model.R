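## Assembly of an evaluatable force-field model for one model peptide:
## instantiates bonded terms from a CHARMM-style parameter set, proper
## dihedral terms from a constraint system (fitted backbone terms) plus the
## base parameter set (wildcards allowed for non-backbone torsions), and the
## nonbonded pair list with 1-2/1-3 exclusions and special 1-4 parameters.

#' Assemble a force-field model for a model peptide
#'
#' @param peptide a `model_peptide`.
#' @param params parameter set from [read_charmm_prm].
#' @param system optional `constraint_system` supplying the backbone proper
#'   dihedral terms; quadruples matched by canonical atom-type key.  Terms
#'   not covered by the system fall back to the parameter set (explicit
#'   quadruples first, then `X-t2-t3-X` wildcards).
#' @return an object of class `ff_model` holding the instantiated term
#'   arrays; pass to [potential_energy] and [minimize_restrained].
#' @export
build_ff_model <- function(peptide, params, system = NULL) {
  stopifnot(inherits(peptide, "model_peptide"))
  types <- peptide$atoms$type
  nat <- nrow(peptide$atoms)

  lookup2 <- function(tab, a, b) {
    hit <- which((tab$t1 == a & tab$t2 == b) | (tab$t1 == b & tab$t2 == a))
    if (!length(hit)) stop("missing bond parameter ", a, "-", b)
    tab[hit[1L], ]
  }
  lookup3 <- function(tab, a, b, c_) {
    hit <- which((tab$t1 == a & tab$t2 == b & tab$t3 == c_) |
                   (tab$t1 == c_ & tab$t2 == b & tab$t3 == a))
    if (!length(hit)) stop("missing angle parameter ", a, "-", b, "-", c_)
    tab[hit[1L], ]
  }

  ## bonds
  bonds <- peptide$bonds
  bp <- lapply(seq_len(nrow(bonds)), function(k) {
    lookup2(params$bonds, types[bonds[k, 1L]], types[bonds[k, 2L]])
  })
  bond_kb <- vapply(bp, function(p) p$kb, 0)
  bond_b0 <- vapply(bp, function(p) p$b0, 0)

  ## angles: all i-j-k bonded triples
  triples <- list()
  for (j in seq_len(nat)) {
    nb <- atom_neighbours(peptide, j)
    if (length(nb) < 2L) next
    cmb <- utils::combn(nb, 2L)
    for (c_ in seq_len(ncol(cmb))) {
      triples[[length(triples) + 1L]] <- c(cmb[1L, c_], j, cmb[2L, c_])
    }
  }
  angles <- do.call(rbind, triples)
  ap <- lapply(seq_len(nrow(angles)), function(k) {
    lookup3(params$angles, types[angles[k, 1L]], types[angles[k, 2L]],
            types[angles[k, 3L]])
  })
  ang_k <- vapply(ap, function(p) p$k, 0)
  ang_th0 <- vapply(ap, function(p) p$th0, 0)
  kub <- vapply(ap, function(p) if (is.null(p$kub) || is.na(p$kub)) 0
                else p$kub, 0)
  has_ub <- kub > 0
  ubs <- angles[has_ub, c(1L, 3L), drop = FALSE]
  ub_k <- kub[has_ub]
  ub_s0 <- vapply(ap[has_ub], function(p) p$s0, 0)

  ## proper dihedrals: all quadruples around central bonds
  quads <- list()
  for (k in seq_len(nrow(bonds))) {
    q <- quads_around_bond(peptide, bonds[k, 1L], bonds[k, 2L])
    if (!is.null(q)) quads[[length(quads) + 1L]] <- q
  }
  quads <- do.call(rbind, quads)

  sys_terms <- if (!is.null(system)) system$terms else NULL
  dih_rows <- list()
  for (q in seq_len(nrow(quads))) {
    at <- quads[q, ]
    tq <- types[at]
    key <- canonical_quad(tq)
    matched <- FALSE
    if (!is.null(sys_terms)) {
      hit <- which(sys_terms$key == key)
      if (length(hit)) {
        matched <- TRUE
        for (h in hit) {
          if (sys_terms$fixed_zero[h]) next
          dih_rows[[length(dih_rows) + 1L]] <- data.frame(
            i = at[1L], j = at[2L], k = at[3L], l = at[4L],
            K = sys_terms$K[h], n = sys_terms$n[h],
            chi0 = sys_terms$chi0[h],
            group = sys_terms$group[h],
            sign = 1)
        }
      }
    }
    if (!matched) {
      tab <- params$dihedrals
      hit <- which((tab$t1 == tq[1L] & tab$t2 == tq[2L] &
                      tab$t3 == tq[3L] & tab$t4 == tq[4L]) |
                     (tab$t1 == tq[4L] & tab$t2 == tq[3L] &
                        tab$t3 == tq[2L] & tab$t4 == tq[1L]))
      if (!length(hit)) {
        hit <- which(tab$t1 == "X" & tab$t4 == "X" &
                       ((tab$t2 == tq[2L] & tab$t3 == tq[3L]) |
                          (tab$t2 == tq[3L] & tab$t3 == tq[2L])))
      }
      if (!length(hit)) {
        stop("missing dihedral parameter ", paste(tq, collapse = "-"))
      }
      for (h in hit) {
        if (tab$K[h] == 0) next
        dih_rows[[length(dih_rows) + 1L]] <- data.frame(
          i = at[1L], j = at[2L], k = at[3L], l = at[4L],
          K = tab$K[h], n = tab$n[h], chi0 = tab$chi0[h],
          group = NA_integer_, sign = 1)
      }
    }
  }
  dih <- if (length(dih_rows)) do.call(rbind, dih_rows) else
    data.frame(i = integer(), j = integer(), k = integer(), l = integer(),
               K = numeric(), n = integer(), chi0 = numeric(),
               group = integer(), sign = numeric())

  ## nonbonded pair list with exclusions
  excl <- connectivity_classes(peptide)
  nbt <- params$nonbonded
  tix <- match(types, nbt$type)
  if (anyNA(tix)) {
    stop("missing nonbonded parameters for type(s): ",
         paste(unique(types[is.na(tix)]), collapse = ", "))
  }
  pr <- which(upper.tri(matrix(0, nat, nat)), arr.ind = TRUE)
  keep <- excl[cbind(pr[, 1L], pr[, 2L])] >= 4L
  pr <- pr[keep, , drop = FALSE]
  is14 <- excl[cbind(pr[, 1L], pr[, 2L])] == 4L
  eps_of <- function(ix, one4) {
    e <- abs(nbt$eps[ix])
    e14 <- abs(nbt$eps14[ix])
    ifelse(one4 & !is.na(e14), e14, e)
  }
  rmin_of <- function(ix, one4) {
    r <- nbt$rminhalf[ix]
    r14 <- nbt$rmin14half[ix]
    ifelse(one4 & !is.na(r14), r14, r)
  }
  i1 <- tix[pr[, 1L]]; i2 <- tix[pr[, 2L]]
  nb_eps <- sqrt(eps_of(i1, is14) * eps_of(i2, is14))
  nb_rmin <- rmin_of(i1, is14) + rmin_of(i2, is14)
  nb_qq <- 332.0716 * peptide$atoms$charge[pr[, 1L]] *
    peptide$atoms$charge[pr[, 2L]]

  ngroups <- if (!is.null(system)) nrow(system$groups) else 0L
  fit_rows <- which(!is.na(dih$group))
  structure(list(
    dih_idx = matrix(as.integer(as.matrix(dih[, c("i", "j", "k", "l")])),
                     ncol = 4L),
    fit_rows = fit_rows,
    fit_quads = matrix(as.integer(
      as.matrix(dih[fit_rows, c("i", "j", "k", "l")])), ncol = 4L),
    peptide = peptide,
    n_atoms = nat,
    bonds = matrix(as.integer(bonds), ncol = 2L),
    bond_kb = bond_kb, bond_b0 = bond_b0,
    angles = matrix(as.integer(angles), ncol = 3L),
    ang_k = ang_k, ang_th0 = ang_th0,
    ubs = matrix(as.integer(ubs), ncol = 2L), ub_k = ub_k, ub_s0 = ub_s0,
    dih = dih,
    imps = matrix(integer(), ncol = 4L),
    imp_k = numeric(), imp_chi0 = numeric(),
    pairs = matrix(as.integer(pr), ncol = 2L),
    nb_eps = nb_eps, nb_rmin = nb_rmin, nb_qq = nb_qq,
    n_groups = ngroups,
    system = system
  ), class = "ff_model")
}

## matrix of bonded-path classes: 2 = 1-2, 3 = 1-3, 4 = 1-4, 5 = further.
connectivity_classes <- function(peptide) {
  nat <- nrow(peptide$atoms)
  d <- matrix(5L, nat, nat)
  diag(d) <- 0L
  adj <- lapply(seq_len(nat), function(v) atom_neighbours(peptide, v))
  for (i in seq_len(nat)) {
    ## BFS up to depth 3
    depth <- rep(NA_integer_, nat)
    depth[i] <- 0L
    frontier <- i
    for (lev in 1:3) {
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[is.na(depth[nxt])]
      depth[nxt] <- lev
      frontier <- nxt
      if (!length(frontier)) break
    }
    hit <- which(!is.na(depth) & depth > 0L)
    d[i, hit] <- pmin(d[i, hit], depth[hit] + 1L)
  }
  d
}

#' @export
print.ff_model <- function(x, ...) {
  cat("Force-field model: ", x$n_atoms, " atoms, ", nrow(x$bonds),
      " bonds, ", nrow(x$angles), " angles, ", nrow(x$dih),
      " dihedral terms (", sum(!is.na(x$dih$group)),
      " fitted), ", nrow(x$pairs), " nonbonded pairs\n", sep = "")
  invisible(x)
}

#' Set the independent barrier-height parameters of a model
#'
#' Updates the K value of every dihedral term instance tied to a constraint
#' group from a vector of independent parameters.
#'
#' @param model an `ff_model` built with a constraint system.
#' @param k_values numeric vector, one barrier height (kcal/mol) per
#'   constraint group, in group order.
#' @return the updated model.
#' @export
set_parameters <- function(model, k_values) {
  if (length(k_values) != model$n_groups) {
    stop("expected ", model$n_groups, " parameters, got ", length(k_values))
  }
  g <- model$dih$group
  upd <- !is.na(g)
  model$dih$K[upd] <- model$dih$sign[upd] * k_values[g[upd]]
  model
}

#' Current independent parameters of a model
#'
#' @param model an `ff_model`.
#' @return numeric vector of group barrier heights.
#' @export
get_parameters <- function(model) {
  g <- model$dih$group
  k <- numeric(model$n_groups)
  for (gi in seq_len(model$n_groups)) {
    r <- which(g == gi)[1L]
    if (!is.na(r)) k[gi] <- model$dih$K[r] * model$dih$sign[r]
  }
  k
}
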