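# independent numerical oracle: stiff-capable ODE integration of the
# two-stage splicing model
ode_oracle <- function(t, alpha, beta, gamma, u0 = 0, s0 = 0) {
  rhs <- function(t, y, p) {
    list(c(p$alpha - p$beta * y[1], p$beta * y[1] - p$gamma * y[2]))
  }
  out <- deSolve::lsoda(
    c(u = u0, s = s0), c(0, t), rhs,
    list(alpha = alpha, beta = beta, gamma = gamma),
    rtol = 1e-10, atol = 1e-12
  )
  as.list(out[nrow(out), c("u", "s")])
}

test_that("closed form reaches the analytic steady state and null solution", {
  st <- kinetics_closed_form(1e4, alpha = 1, beta = 1, gamma = 1)
  expect_equal(st$u, 1, tolerance = 1e-10)
  expect_equal(st$s, 1, tolerance = 1e-10)
  # alpha = 0 from (0,0) stays at (0,0) for any t
  for (t in c(0, 0.5, 3, 50)) {
    z <- kinetics_closed_form(t, alpha = 0, beta = 1.3, gamma = 0.4)
    expect_identical(unname(c(z$u, z$s)), c(0, 0))
  }
  # general steady state u* = alpha/beta, s* = alpha/gamma
  st2 <- kinetics_closed_form(1e4, alpha = 2, beta = 0.8, gamma = 0.5)
  expect_equal(st2$u, 2 / 0.8, tolerance = 1e-8)
  expect_equal(st2$s, 2 / 0.5, tolerance = 1e-8)
})

test_that("closed form matches numerical ODE integration on random draws", {
  withr::with_seed(42, {
    worst <- 0
    for (i in 1:100) {
      alpha <- runif(1, 0, 5); beta <- runif(1, 0.2, 3)
      gamma <- runif(1, 0.1, 2); t <- runif(1, 0.05, 10)
      u0 <- runif(1, 0, 3); s0 <- runif(1, 0, 3)
      got <- kinetics_closed_form(t, alpha, beta, gamma, u0, s0)
      want <- ode_oracle(t, alpha, beta, gamma, u0, s0)
      worst <- max(worst, abs(got$u - want$u), abs(got$s - want$s))
    }
    expect_lt(worst, 1e-6)
  })
})

test_that("degenerate beta == gamma case agrees with the ODE oracle", {
  got <- kinetics_closed_form(1.7, alpha = 2, beta = 0.9, gamma = 0.9,
                              u0 = 0.3, s0 = 1.1)
  want <- ode_oracle(1.7, 2, 0.9, 0.9, 0.3, 1.1)
  expect_equal(got$u, want$u, tolerance = 1e-7)
  expect_equal(got$s, want$s, tolerance = 1e-7)
  # and is continuous in beta around gamma
  near <- kinetics_closed_form(1.7, 2, 0.9 + 1e-7, 0.9, 0.3, 1.1)
  expect_equal(got$s, near$s, tolerance = 1e-5)
})

test_that("invalid kinetic parameters are rejected", {
  expect_error(kinetics_closed_form(1, 1, beta = 0, gamma = 1), "beta")
  expect_error(kinetics_closed_form(1, 1, beta = 1, gamma = -2), "gamma")
  expect_error(kinetics_closed_form(1, alpha = -1, beta = 1, gamma = 1), "alpha")
  expect_error(
    kinetic_params(tibble::tibble(
      gene = "g", alpha_progenitor = 1, alpha_branch_a = 1,
      alpha_branch_b = 1, beta = -1, gamma = 1
    )),
    "beta"
  )
})

test_that("branch trajectories are continuous at the switch time", {
  topo <- tibble::tibble(
    cell = c("a", "b"), t = c(8 - 1e-9, 8 + 1e-9),
    branch = c("progenitor", "branch_b")
  )
  attr(topo, "t_switch") <- 8
  params <- tibble::tibble(
    gene = "g1", alpha_progenitor = 2, alpha_branch_a = 2,
    alpha_branch_b = 9, beta = 1.1, gamma = 0.5
  )
  lat <- simulate_latent_kinetics(topo, params)
  expect_equal(lat$u[1, "a"], lat$u[1, "b"], tolerance = 1e-6)
  expect_equal(lat$s[1, "a"], lat$s[1, "b"], tolerance = 1e-6)
})

test_that("steady-state initialisation keeps pre-switch cells on the line", {
  withr::with_seed(1, {
    topo <- lineage_topology(80, t_total = 20, t_switch = 10)
  })
  params <- tibble::tibble(
    gene = c("g1", "g2"), alpha_progenitor = c(3, 1),
    alpha_branch_a = c(3, 1), alpha_branch_b = c(3, 1),
    beta = c(1, 0.8), gamma = c(0.5, 0.3)
  )
  lat <- simulate_latent_kinetics(topo, params)
  # no switch anywhere: every cell sits exactly at the steady state
  expect_equal(unname(lat$u[1, ]), rep(3, 80), tolerance = 1e-12)
  expect_equal(unname(lat$s[2, ]), rep(1 / 0.3, 80), tolerance = 1e-12)
})

test_that("count sampling honours its contracts", {
  lat <- list(
    u = toy_counts(0, 4, 6) * 0,
    s = toy_counts(0, 4, 6) * 0
  )
  zero <- sample_counts(lat, depth_per_cell = 100, dispersion = 0.2, seed = 3)
  expect_true(all(zero$spliced == 0) && all(zero$unspliced == 0))

  lat2 <- list(u = toy_counts(2, 5, 10), s = toy_counts(7, 5, 10))
  a <- sample_counts(lat2, 500, dispersion = 0.3, seed = 11)
  b <- sample_counts(lat2, 500, dispersion = 0.3, seed = 11)
  expect_identical(as.matrix(a$spliced), as.matrix(b$spliced))
  expect_identical(as.matrix(a$unspliced), as.matrix(b$unspliced))
  c2 <- sample_counts(lat2, 500, dispersion = 0.3, seed = 12)
  expect_false(identical(as.matrix(a$spliced), as.matrix(c2$spliced)))

  expect_error(sample_counts(lat2, 500, dispersion = -0.1), "dispersion")
  expect_error(sample_counts(lat2, 0), "depth")
})

test_that("sampled counts are unbiased for the scaled latent abundance", {
  # one gene, many replicate cells with identical latent values
  lat <- list(u = matrix(3, 1, 10000), s = matrix(12, 1, 10000))
  dimnames(lat$u) <- dimnames(lat$s) <-
    list("g1", sprintf("c%05d", 1:10000))
  depth <- 60
  ds <- sample_counts(lat, depth_per_cell = depth, dispersion = 0.2, seed = 9)
  x <- as.vector(ds$spliced["g1", ])
  expected <- depth # latent 12 of a 12-total => full depth
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - expected), 3 * se + 1e-9)
  # dispersion = 0 degenerates to Poisson: variance ~ mean
  dp <- sample_counts(lat, depth_per_cell = depth, dispersion = 0, seed = 9)
  xp <- as.vector(dp$spliced["g1", ])
  expect_lt(abs(var(xp) / mean(xp) - 1), 0.1)
  # overdispersed draw has clearly super-Poisson variance
  expect_gt(var(x) / mean(x), 2)
})
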