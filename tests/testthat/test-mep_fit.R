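## A tiny one-parameter fixture: beta0 with a single independent n = 3
## term on the central (theta) torsion, evaluated with the torsion-space
## backend so scans are fast and fully relaxable.
single_term_fixture <- function() {
  memo("single_term", {
    pep <- diamide("beta0")
    tt <- enumerate_new_torsions(pep)
    tt$molecule <- "beta0"
    key <- canonical_quad(c("NH1", "CTB2", "CTA2", "C"))
    terms <- generate_candidate_terms(tt[tt$key == key, ], 3)
    terms$torsion <- "theta1"
    terms$K <- 0.8
    sys <- constraint_system(terms)
    sys$groups$K <- 0.8
    mod <- build_ff_model(pep, generic_params(), sys)
    mod <- set_parameters(mod, 0.8)
    list(pep = pep, sys = sys,
         backend = torsion_backend(pep, mod))
  })
}

test_that("a relaxed scan of an isolated term traces its cosine profile", {
  fx <- single_term_fixture()
  ## isolate the dihedral term: compare scans at K and at 0; their
  ## difference must be the closed-form K (1 + cos(3 chi)) profile
  sc1 <- run_relaxed_scan(fx$backend, torsion = "theta", turns = 1)
  b0 <- backend_set_params(fx$backend, 0)
  sc0 <- run_relaxed_scan(b0, torsion = "theta", turns = 1)
  expect_identical(length(sc1$angles), 72L)
  diff <- sc1$energies - sc0$energies
  expected <- 0.8 * (1 + cos(deg2rad(3 * sc1$angles)))
  ## geometries relax slightly differently under the two parameter sets,
  ## so agreement is to the relaxation scale, not machine precision
  expect_lt(max(abs(diff - expected)), 0.05)
  expect_equal(max(expected) - min(expected), 2 * 0.8, tolerance = 1e-6)
})

test_that("two-turn scans are periodic and direction minima combine", {
  fx <- single_term_fixture()
  fwd <- run_relaxed_scan(fx$backend, torsion = "theta", direction = 1,
                          turns = 2)
  expect_identical(length(fwd$angles), 144L)
  ## second turn repeats the first within tolerance once the path has
  ## settled into its cycle
  e1 <- fwd$energies[1:72]
  e2 <- fwd$energies[73:144]
  a1 <- fwd$angles[1:72]
  a2 <- fwd$angles[73:144]
  expect_equal(a1, a2)
  expect_lt(max(abs(e1 - e2)), 1e-4)
  ## hysteresis is representable: opposite-direction scans may settle in
  ## different side-chain basins, and the global MEP is their pointwise
  ## minimum, never above either scan
  bwd <- run_relaxed_scan(fx$backend, torsion = "theta", direction = -1,
                          turns = 1)
  mep <- extract_global_mep(list(fwd, bwd))
  m_f <- match(mep$angles, fwd$angles[1:72])
  m_b <- match(mep$angles, bwd$angles)
  expect_true(all(mep$energies <= fwd$energies[m_f] + 1e-9))
  expect_true(all(mep$energies <= bwd$energies[m_b] + 1e-9))
  expect_equal(mep$energies, pmin(pmin(fwd$energies[m_f],
                                       fwd$energies[72 + m_f]),
                                  bwd$energies[m_b]),
               tolerance = 1e-12)
})

test_that("global MEP extraction is the per-angle minimum", {
  ## randomized synthetic scans checked against an exhaustive argmin
  set.seed(21)
  grid <- seq(-175, 180, by = 5)
  scans <- lapply(1:4, function(s) {
    structure(list(torsion = "theta", targets = grid,
                   angles = sample(grid), energies = rnorm(72),
                   geoms = replicate(72, matrix(rnorm(6), 2),
                                     simplify = FALSE),
                   converged = rep(TRUE, 72), direction = 1,
                   step_deg = 5), class = "torsion_scan")
  })
  mep <- extract_global_mep(scans)
  all_angles <- unlist(lapply(scans, `[[`, "angles"))
  all_energies <- unlist(lapply(scans, `[[`, "energies"))
  for (gi in seq_along(grid)) {
    expect_equal(mep$energies[gi],
                 min(all_energies[all_angles == grid[gi]]))
  }
  ## identical scans: MEP equals any single scan
  same <- extract_global_mep(scans[c(1, 1)])
  one <- extract_global_mep(scans[1])
  expect_equal(same$energies, one$energies)

  ## uncovered grid angle is reported by name
  short <- scans[[1]]
  drop <- short$angles != 0
  for (f in c("angles", "energies", "converged")) {
    short[[f]] <- short[[f]][drop]
  }
  short$geoms <- short$geoms[drop]
  expect_error(extract_global_mep(list(short)), "0 degrees")
})

test_that("MM MEP recomputation honours the backbone restraints", {
  sy <- synth_fixture()
  qm <- sy$meps$theta
  mm <- compute_mm_mep(sy$backend, qm)
  ## every restrained backbone torsion within 0.1 degree of its target
  dev <- abs(wrap_angle(mm$backbone - qm$backbone))
  expect_lt(max(dev), 0.1)
  ## minimization contract: restrained energy at the result does not
  ## exceed the restrained energy at its start geometry
  pep <- sy$backend$peptide
  quads <- do.call(rbind, pep$tors)
  for (i in c(1, 20, 50)) {
    rs <- dihedral_restraints(quads, qm$backbone[i, ], 1e5)
    e_start <- potential_energy(sy$backend$model, qm$geoms[[i]], rs)$total
    e_end <- potential_energy(sy$backend$model, mm$geoms[[i]], rs)$total
    expect_lte(e_end, e_start + 1e-6)
  }
})

test_that("the linear fit recovers known parameters exactly", {
  sy <- synth_fixture()
  sys <- published_sys()
  backs <- rep(list(sy$backend), 3)
  fit <- fit_barrier_heights(sy$meps, sy$meps, backs, sys)
  act <- fit$active
  expect_identical(sum(act), 8L)   # the beta0 parameters
  expect_lt(max(abs(fit$K[act] - sy$truth_K[act]) /
                  pmax(abs(sy$truth_K[act]), 1e-12)), 1e-8)
  expect_lt(fit$rms, 1e-10)
  expect_false(fit$rank_deficient)
  ## correlation matrix is symmetric with unit diagonal
  expect_equal(fit$correlation, t(fit$correlation), tolerance = 1e-10)
  expect_equal(unname(diag(fit$correlation)), rep(1, sum(act)),
               tolerance = 1e-10)

  ## reference identical to the non-fitted energies: all K zero, RMS zero
  zero_meps <- lapply(sy$meps, function(m) {
    m$energies <- vapply(m$geoms, function(g) {
      betamep:::nonfitted_energy(sy$backend$model, g)
    }, 0)
    m
  })
  fit0 <- fit_barrier_heights(zero_meps, zero_meps, backs, sys)
  expect_lt(max(abs(fit0$K[fit0$active])), 1e-10)
  expect_lt(fit0$rms, 1e-10)

  ## design linearity: scaling the fitted part of the reference scales
  ## the recovered parameters
  scaled <- lapply(sy$meps, function(m) {
    nf <- vapply(m$geoms, function(g) {
      betamep:::nonfitted_energy(sy$backend$model, g)
    }, 0)
    m$energies <- nf + 2 * (m$energies - nf)
    m
  })
  fit2 <- fit_barrier_heights(scaled, sy$meps, backs, sys)
  expect_equal(fit2$K[act], 2 * sy$truth_K[act], tolerance = 1e-8)
})

test_that("self-consistent loop converges to the known fixed point", {
  sy <- synth_fixture()
  sys <- published_sys()
  backs <- rep(list(sy$backend), 3)
  set.seed(7)
  init <- sy$truth_K + rnorm(length(sy$truth_K), sd = 0.2)
  sc <- self_consistent_optimize(backs, sy$meps, sys,
                                 initial_params = init,
                                 tol_K = 1e-3, tol_E = 1e-2,
                                 max_iter = 10)
  expect_true(sc$converged)
  expect_lte(sc$iterations, 10L)
  ## the fixed point sits at the generating parameters (up to the small
  ## restraint-equilibrium shift inherent in the protocol)
  act <- sc$fit$active
  expect_lt(max(abs(sc$params[act] - sy$truth_K[act])), 0.05)
  ## trace carries one row per iteration
  expect_identical(nrow(sc$trace), sc$iterations)

  ## rerunning from the converged state is a no-op
  sc2 <- self_consistent_optimize(backs, sy$meps, sys,
                                  initial_params = sc$params,
                                  tol_K = 1e-3, tol_E = 1e-2,
                                  max_iter = 3)
  expect_lt(sc2$trace$max_dK[1], 1e-3)
})
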