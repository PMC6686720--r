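## Shared fixtures.  Expensive objects are built once per test run and
## memoized in this environment.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

published_sys <- function() memo("sys", published_constraint_system())

diamide <- function(name) {
  memo(paste0("pep_", name), build_diamide(name))
}

generic_params <- function() memo("prm", default_parameters())

## the synthetic reference scenario shared by the fit and loop tests:
## beta0 diamide, torsion-space backend at the published ground truth
synth_fixture <- function() {
  memo("synth", {
    scen <- synthetic_scenario(seed = 42L, molecule = "beta0")
    synth_qm_meps(scen, published_sys())
  })
}

## independent slow oracle for a dihedral angle: angle between the two
## plane normals, signed by the scalar triple product
oracle_dihedral <- function(coords, quad) {
  p <- coords[quad, , drop = FALSE]
  b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  ang <- acos(max(-1, min(1, sum(n1 * n2) /
                            sqrt(sum(n1^2) * sum(n2^2))))) * 180 / pi
  ## sign from whether b1 points to the same side as the second normal
  s <- sign(sum(b1 * n2))
  if (s == 0) s <- 1
  s * ang
}

## independent greedy neighbour-count clustering, written naively
oracle_daura <- function(dmat, cutoff) {
  remaining <- seq_len(nrow(dmat))
  out <- list()
  while (length(remaining) > 0) {
    best <- NA; best_n <- -1
    for (f in remaining) {
      nn <- sum(dmat[f, remaining] <= cutoff)
      if (nn > best_n) { best_n <- nn; best <- f }
    }
    members <- remaining[dmat[best, remaining] <= cutoff]
    out[[length(out) + 1]] <- sort(members)
    remaining <- setdiff(remaining, members)
  }
  out
}

## random small-molecule-like coordinates: jittered tetrahedral chain
random_chain_coords <- function(n, seed) {
  set.seed(seed)
  xyz <- matrix(0, n, 3)
  for (i in 2:n) {
    step <- rnorm(3)
    xyz[i, ] <- xyz[i - 1, ] + 1.5 * step / sqrt(sum(step^2))
  }
  xyz + matrix(rnorm(3 * n, sd = 0.1), n, 3)
}
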