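all_torsions <- function() {
  memo("all_torsions", {
    seen <- character()
    out <- list()
    for (nm in c("beta0", "beta2", "beta3", "beta23")) {
      tt <- enumerate_new_torsions(diamide(nm), seen)
      tt$molecule <- nm
      seen <- c(seen, tt$key)
      out[[nm]] <- tt
    }
    do.call(rbind, lapply(out, function(x) {
      x$instances <- NULL
      x
    }))
  })
}

test_that("candidate-term bookkeeping matches the nominal counts", {
  tors <- all_torsions()
  expect_identical(nrow(tors), 53L)        # 12 + 14 + 14 + 13
  terms <- generate_candidate_terms(tors, 1:6)
  expect_identical(nrow(terms), 318L)      # 53 x 6 dihedral terms
  expect_identical(nrow(terms) * 2L, 636L) # K and chi0 per term
  expect_true(all(terms$chi0 == 0))

  ## aliphatic-hydrogen quadruples are fixed to zero
  h_nh1_ctb2_hb2 <- terms$key == canonical_quad(c("H", "NH1", "CTB2",
                                                  "HB2"))
  expect_true(any(h_nh1_ctb2_hb2))
  expect_true(all(terms$fixed_zero[h_nh1_ctb2_hb2]))
  phi1 <- terms$key == canonical_quad(c("C", "NH1", "CTB2", "CTA2"))
  expect_false(any(terms$fixed_zero[phi1]))

  ## single torsion, multiplicity set {3, 6}
  two <- generate_candidate_terms(tors[1, ], c(3, 6))
  expect_identical(nrow(two), 2L)
  expect_error(generate_candidate_terms(tors[1, ], c(3, 7)), "1..6")
})

test_that("published constraint system has 96 non-zero terms in 38 groups", {
  sys <- published_sys()
  cp <- count_parameters(sys)
  expect_identical(unname(cp), c(96L, 38L))

  ## per-molecule independent parameters: 8 + 12 + 12 + 6
  tr <- sys$terms
  ind <- !duplicated(tr$group)
  expect_equal(
    as.vector(table(factor(tr$molecule[ind],
                           c("beta0", "beta2", "beta3", "beta23")))),
    c(8L, 12L, 12L, 6L))

  ## group members share one barrier-height magnitude
  for (g in seq_len(nrow(sys$groups))) {
    expect_length(unique(abs(tr$K[tr$group == g])), 1L)
  }
  ## every published quadruple arises from the enumeration
  expect_true(all(tr$key %in% all_torsions()$key))

  ## empty system
  empty <- constraint_system(generate_candidate_terms(
    all_torsions()[0, ], 1:6))
  expect_identical(unname(count_parameters(empty)), c(0L, 0L))
})

test_that("supplementary amide pairs couple as the parity rule demands", {
  pep <- diamide("beta0")
  tt <- enumerate_new_torsions(pep)
  tt$molecule <- "beta0"
  terms <- generate_candidate_terms(tt, 1:3)
  pairs <- supplementary_pair_groups(terms, pep)
  expect_gt(nrow(pairs), 0)
  ## psi1/psi2 (CTB2-CTA2-C-{NH1;O}) must appear as a pair
  k1 <- canonical_quad(c("CTB2", "CTA2", "C", "NH1"))
  k2 <- canonical_quad(c("CTB2", "CTA2", "C", "O"))
  psi_pairs <- pairs[terms$key[pairs$i] %in% c(k1, k2) &
                       terms$key[pairs$j] %in% c(k1, k2), ]
  expect_identical(sort(unique(psi_pairs$n)), c(1L, 2L, 3L))
  ## odd multiplicities flip the phase, even ones share it
  expect_true(all(psi_pairs$phase_shift[psi_pairs$n %% 2 == 1] == 180))
  expect_true(all(psi_pairs$phase_shift[psi_pairs$n %% 2 == 0] == 0))

  ## the supplementary identity itself: K(1+cos(n(180-x)-chi0)) equals
  ## the partner term on a sweep
  x <- seq(0, 355, by = 5)
  for (n in 1:3) {
    shift <- if (n %% 2 == 1) 180 else 0
    lhs <- 1 + cos(deg2rad(n * (180 - x) - 0))
    rhs <- 1 + cos(deg2rad(n * x - shift))
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("sp3 triplets group only for multiplicities 3 and 6", {
  pep <- diamide("beta2")
  tt <- enumerate_new_torsions(pep)
  tt$molecule <- "beta2"
  terms <- generate_candidate_terms(tt, c(2, 3, 6))
  trips <- sp3_triplet_groups(terms, pep)
  keys <- c(canonical_quad(c("NH1", "CTB2", "CTB1", "C")),
            canonical_quad(c("NH1", "CTB2", "CTB1", "CT3")),
            canonical_quad(c("NH1", "CTB2", "CTB1", "HB1")))
  hit <- vapply(seq_len(nrow(trips)), function(i) {
    all(terms$key[trips$members[[i]]] %in% keys) && trips$n[i] == 3
  }, TRUE)
  expect_true(any(hit))
  ## no grouping offered for n = 2 (120-degree shift is not a period)
  expect_false(any(trips$n == 2))
  ## the 120-degree shift identity for n = 3 and 6
  x <- seq(-180, 179, by = 1)
  for (n in c(3, 6)) {
    expect_equal(cos(deg2rad(n * (x + 120))), cos(deg2rad(n * x)),
                 tolerance = 1e-12)
  }
  ## ... and its failure for n = 2
  expect_gt(max(abs(cos(deg2rad(2 * (x + 120))) - cos(deg2rad(2 * x)))),
            1)
})

test_that("histogram modes select the minimal multiplicity set", {
  set.seed(11)
  spread <- function(mu) rnorm(200, mu, 4)
  modes_366 <- wrap_angle(c(spread(60), spread(-60), spread(90),
                            spread(-90), spread(150), spread(-150)))
  expect_identical(multiplicities_from_histogram(modes_366), c(3L, 6L))
  expect_identical(multiplicities_from_histogram(spread(180)), 1L)
  expect_identical(
    multiplicities_from_histogram(wrap_angle(c(spread(60), spread(180),
                                               spread(-60)))), 3L)
  expect_error(multiplicities_from_histogram(numeric()), "samples")
})

test_that("correlation merging constrains pairs equal or opposite", {
  sys <- published_sys()
  ng <- nrow(sys$groups)
  ident <- diag(ng)

  same <- merge_correlated(sys, ident)
  expect_identical(count_parameters(same), count_parameters(sys))

  ## r = +0.95: two groups share one parameter, phases unchanged
  r <- ident
  r[1, 2] <- r[2, 1] <- 0.95
  merged <- merge_correlated(sys, r)
  expect_identical(unname(count_parameters(merged)[["n_independent"]]),
                   ng - 1L)
  g2_terms_old <- sys$terms$chi0[sys$terms$group %in% 2]
  g2_terms_new <- merged$terms$chi0[which(sys$terms$group %in% 2)]
  expect_identical(g2_terms_new, g2_terms_old)

  ## r = -0.95: merged with the absorbed member's phases flipped
  r[1, 2] <- r[2, 1] <- -0.95
  merged <- merge_correlated(sys, r)
  expect_identical(unname(count_parameters(merged)[["n_independent"]]),
                   ng - 1L)
  flipped <- merged$terms$chi0[which(sys$terms$group %in% 2)]
  expect_identical(flipped, (g2_terms_old + 180) %% 360)

  ## transitive closure: 1~2 and 2~3 leaves one group for all three
  r <- ident
  r[1, 2] <- r[2, 1] <- 0.95
  r[2, 3] <- r[3, 2] <- -0.95
  merged <- merge_correlated(sys, r)
  expect_identical(unname(count_parameters(merged)[["n_independent"]]),
                   ng - 2L)
  g123 <- merged$terms$group[which(sys$terms$group %in% c(1, 2, 3))]
  expect_length(unique(g123), 1L)

  bad <- ident
  bad[1, 2] <- 0.95
  expect_error(merge_correlated(sys, bad), "symmetric")
})

test_that("sign adjustment flips phases and shifts energy by a constant", {
  adj <- sign_adjust(data.frame(K = -0.3, n = 2, chi0 = 0))
  expect_equal(adj$K, 0.3)
  expect_equal(adj$chi0, 180)
  ## positive terms pass through (published theta1 row)
  keep <- sign_adjust(data.frame(K = 0.94, n = 3, chi0 = 0))
  expect_equal(keep$K, 0.94)
  expect_equal(keep$chi0, 0)

  ## energy difference before/after is the constant -2K on a full sweep
  x <- seq(0, 355, by = 5)
  before <- -0.3 * (1 + cos(deg2rad(2 * x - 0)))
  after <- 0.3 * (1 + cos(deg2rad(2 * x - 180)))
  expect_equal(unique(round(after - before, 12)), 0.6)
})

test_that("term energies are stereoisomer- and order-invariant", {
  ## chi0 restricted to {0, 180} makes cos(n chi - chi0) even in chi
  sys <- published_sys()
  tr <- sys$terms
  x <- seq(-175, 180, by = 5)
  for (i in sample(seq_len(nrow(tr)), 10)) {
    e_fwd <- tr$K[i] * (1 + cos(deg2rad(tr$n[i] * x - tr$chi0[i])))
    e_mir <- tr$K[i] * (1 + cos(deg2rad(tr$n[i] * (-x) - tr$chi0[i])))
    expect_equal(e_fwd, e_mir, tolerance = 1e-12)
  }
  ## whole-model check: energy of a conformation equals its mirror image
  pep <- diamide("beta3")
  mir <- build_diamide("beta3", mirror = TRUE)
  mod <- build_ff_model(pep, generic_params(), sys)
  mod_m <- build_ff_model(mir, generic_params(), sys)
  v <- c(phi = -77, theta = 41, psi = -150)
  e <- potential_energy(mod, build_coordinates(pep, v))$total
  e_m <- potential_energy(mod_m, build_coordinates(mir, -v))$total
  expect_equal(e, e_m, tolerance = 1e-9)
})

test_that("constraint table round-trips through the formatter", {
  sys <- published_sys()
  tab <- format_constraint_table(sys)
  expect_identical(nrow(tab), 96L)
  ## representatives have empty constrained-to entries: 38 of them
  expect_identical(sum(tab$constrained_to == ""), 38L)
  ## all published barrier heights are below 1 kcal/mol
  expect_true(all(abs(tab$K) < 1))
})
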