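test_that("gamma fit recovers an exact line and flags sparse genes", {
  s <- matrix(seq(0.5, 10, length.out = 20), 1, 20,
              dimnames = list("g1", paste0("c", 1:20)))
  u <- 2 * s
  fits <- fit_gamma(u, s)
  expect_equal(fits$gamma_hat, 2, tolerance = 1e-12)
  expect_true(fits$fit_ok)
  # gene detected in < 10 cells is unfit
  s2 <- rbind(g1 = c(rep(0, 15), seq(1, 5)), g2 = seq(1, 20))
  colnames(s2) <- paste0("c", 1:20)
  fits2 <- fit_gamma(0.5 * s2, s2)
  expect_false(fits2$fit_ok[fits2$gene == "g1"])
  expect_true(fits2$fit_ok[fits2$gene == "g2"])
  expect_error(fit_gamma(u, s, extreme_quantile = 0), "extreme_quantile")
})

test_that("gamma_hat recovers gamma/beta on noiseless steady-state kinetics", {
  withr::with_seed(31, {
    n_draws <- 50
    rel_err <- numeric(n_draws)
    for (i in seq_len(n_draws)) {
      beta <- runif(1, 0.3, 2.5)
      gamma <- runif(1, 0.1, 1.5)
      alphas <- runif(60, 0.5, 8) # per-cell transcription spread
      u <- matrix(alphas / beta, 1, 60)
      s <- matrix(alphas / gamma, 1, 60)
      dimnames(u) <- dimnames(s) <- list("g", sprintf("c%02d", 1:60))
      fit <- fit_gamma(u, s)
      rel_err[i] <- abs(fit$gamma_hat - gamma / beta) / (gamma / beta)
    }
    expect_lt(max(rel_err), 0.10)
  })
})

test_that("velocity equals u - gamma*s and is zero on the steady-state line", {
  s <- matrix(c(1, 2, 3, 4, 5), 1, 5, dimnames = list("g1", paste0("c", 1:5)))
  u <- matrix(c(0.9, 1.2, 1.5, 1.8, 2.1), 1, 5, dimnames = dimnames(s))
  fits <- fit_gamma(u, s, min_cells = 3)
  v <- compute_velocity(u, s, fits)
  expect_equal(v, u - fits$gamma_hat * s, tolerance = 1e-12)
  # cells exactly on the line: v = 0; above the line: v > 0
  u_on <- 0.4 * s
  fits_on <- fit_gamma(u_on, s, min_cells = 3)
  expect_equal(unname(compute_velocity(u_on, s, fits_on)[1, ]), rep(0, 5),
               tolerance = 1e-12)
  expect_true(all(compute_velocity(u_on + 0.3, s, fits_on) > 0))
})

test_that("velocity graph cosine scores match a brute-force oracle", {
  v <- matrix(c(1, 0, 0, 1, -1, 0), 2, 3,
              dimnames = list(c("g1", "g2"), c("a", "b", "c")))
  x <- matrix(c(0, 0, 1, 0, 0, 1), 2, 3, dimnames = dimnames(v))
  nb <- rbind(c(2, 3), c(1, 3), c(1, 2))
  fits <- tibble::tibble(gene = c("g1", "g2"), gamma_hat = 1,
                         n_expressed = 3L, fit_ok = TRUE)
  g <- velocity_graph(v, nb, x = x)
  for (i in 1:3) for (j in nb[i, ]) {
    d <- x[, j] - x[, i]
    want <- sum(v[, i] * d) / (sqrt(sum(v[, i]^2)) * sqrt(sum(d^2)))
    expect_equal(g[i, j], want, tolerance = 1e-12)
  }
  # parallel displacement scores 1, antiparallel -1
  expect_equal(g["a", "b"], 1)
  v2 <- v; v2[, 1] <- -v2[, 1]
  g2 <- velocity_graph(v2, nb, x = x)
  expect_equal(g2["a", "b"], -1)
  # zero-velocity cell: all scores 0
  v3 <- v; v3[, 1] <- 0
  g3 <- velocity_graph(v3, nb, x = x)
  expect_equal(unname(g3[1, nb[1, ]]), c(0, 0))
})

test_that("velocity confidence is the mean neighbour cosine", {
  v <- matrix(rep(c(1, 2), 4), 2, 4,
              dimnames = list(c("g1", "g2"), paste0("c", 1:4)))
  nb <- rbind(c(2, 3), c(1, 4), c(1, 2), c(2, 3))
  conf <- velocity_confidence(v, nb)
  expect_equal(conf$confidence, rep(1, 4), tolerance = 1e-12)
  # a cell whose neighbours' velocities are its negation scores -1
  v2 <- v; v2[, 2] <- -v2[, 1]; v2[, 3] <- -v2[, 1]
  conf2 <- velocity_confidence(v2, rbind(c(2, 3), c(1, 1), c(1, 1), c(1, 1)))
  expect_equal(conf2$confidence[1], -1, tolerance = 1e-12)
  # isolated cell reported missing
  nb_na <- rbind(c(NA, NA), c(1, 3), c(1, 2), c(2, 3))
  expect_true(is.na(velocity_confidence(v, nb_na)$confidence[1]))
})

test_that("velocity is equivariant under cell permutation", {
  proc <- processed_benchmark()
  ds <- proc$ds
  perm <- withr::with_seed(4, sample(length(ds$cells)))
  ds_p <- subset_dataset(ds, cells = ds$cells[perm])
  f1 <- velocity_field(ds)
  f2 <- velocity_field(ds_p)
  expect_equal(f2$v[, ds$cells], f1$v[, ds$cells], tolerance = 1e-10)
})

test_that("confidence dips at the bifurcation interface", {
  proc <- processed_benchmark()
  truth <- proc$sim$truth
  conf <- velocity_confidence(proc$field, proc$pn$neighbors)
  info <- dplyr::inner_join(conf, truth$cells, by = "cell")
  tsw <- truth$t_switch
  zone <- info[abs(info$t - tsw) < 1.5, ]
  tips <- info[info$t > tsw + 4 & info$branch != "progenitor", ]
  expect_lt(mean(zone$confidence), mean(tips$confidence))
  w <- wilcox.test(zone$confidence, tips$confidence, alternative = "less")
  expect_lt(w$p.value, 0.01)
})

test_that("driver ranking honours contracts on toy inputs", {
  proc <- processed_benchmark()
  expect_error(rank_driver_genes(proc$field, proc$ds, "no_such"), "not found")
  drv <- rank_driver_genes(proc$field, proc$ds, "non_myogenic", top_n = 1e6)
  expect_equal(nrow(drv), nrow(proc$field$v)) # truncation to eligible genes
  expect_true(all(diff(drv$driver_score) <= 1e-12))
  # a constant gene scores 0 and ranks last
  const_gene <- drv$gene[which.min(drv$driver_score)]
  small <- rank_driver_genes(proc$field, proc$ds, "non_myogenic", top_n = 10)
  expect_equal(nrow(small), 10)
})

test_that("top drivers recover the planted switch genes", {
  proc <- processed_benchmark()
  truth <- proc$sim$truth
  drv <- rank_driver_genes(proc$field, proc$ds, "non_myogenic",
                           top_n = length(truth$driver_genes))
  precision <- mean(drv$gene %in% truth$driver_genes)
  expect_gt(precision, 0.6) # small noisy benchmark; full-scale bound is 0.8
})
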