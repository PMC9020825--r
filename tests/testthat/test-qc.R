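make_mito_dataset <- function(fracs) {
  n <- length(fracs)
  other <- matrix(100, 2, n)
  mito <- matrix(round(200 * fracs / (1 - fracs) / 2), 2, n)
  s <- rbind(other, mito)
  dimnames(s) <- list(c("gA", "gB", "mt-01", "mt-02"),
                      sprintf("c%02d", seq_len(n)))
  velocity_dataset(s, s * 0)
}

test_that("mito filter uses a strict > threshold and subsets consistently", {
  ds <- make_mito_dataset(c(0.25, 0.0, 0.20, 0.10))
  md <- ds$metadata
  # construct exact fractions in the metadata to pin boundary semantics
  md$mito_fraction <- c(0.25, 0.0, 0.20, 0.10)
  ds <- velocity_dataset(ds$spliced, ds$unspliced, md)
  filt <- filter_cells(ds, max_mito_fraction = 0.20)
  expect_setequal(filt$cells, c("c02", "c03", "c04")) # 0.25 discarded
  expect_true("c03" %in% filt$cells)                  # exactly 0.20 retained
  expect_identical(attr(filt, "qc_report")$cell, "c01")
  expect_identical(filt$metadata$cell, filt$cells)
  expect_identical(colnames(filt$unspliced), filt$cells)
})

test_that("filtering is idempotent and can error out completely", {
  sim <- small_benchmark()
  once <- filter_cells(sim$dataset)
  twice <- filter_cells(once)
  expect_identical(once$cells, twice$cells)
  expect_identical(as.matrix(once$spliced), as.matrix(twice$spliced))
  expect_error(filter_cells(sim$dataset, max_mito_fraction = -1), "mito")
  high <- make_mito_dataset(c(0.4, 0.5))
  expect_error(filter_cells(high, max_mito_fraction = 0.01), "all cells")
})

test_that("normalisation matches hand-computed median scaling", {
  s <- toy_counts(c(1, 0, 3, 2, 0, 6), 3, 2) # cells: (1,0,3) and (2,0,6)
  ds <- velocity_dataset(s, s * 0)
  norm <- normalize_log(ds)
  # depths 4 and 8, median 6; cell1 scaled by 6/4, cell2 by 6/8
  expect_equal(unname(norm[, 1]), log1p(c(1, 0, 3) * 6 / 4))
  expect_equal(unname(norm[, 2]), log1p(c(2, 0, 6) * 6 / 8))
  # proportional cells map to identical profiles; zero gene stays zero
  expect_equal(unname(norm[, 1]), unname(norm[, 2]))
  expect_equal(unname(norm[2, ]), c(0, 0))
  # zero-depth cell is named in the error
  s2 <- toy_counts(c(1, 1, 0, 0), 2, 2)
  expect_error(normalize_log(velocity_dataset(s2, s2 * 0)), "c02")
})

test_that("covariate regression equals a normal-equations oracle", {
  withr::with_seed(21, {
    n <- 5
    expr <- matrix(rnorm(3 * n), 3, n,
                   dimnames = list(paste0("g", 1:3), paste0("c", 1:n)))
    covs <- data.frame(cell = paste0("c", 1:n),
                       x1 = rnorm(n), x2 = runif(n))
    got <- regress_covariates(expr, covs)
    x <- cbind(1, covs$x1, covs$x2)
    for (g in 1:3) {
      beta <- solve(t(x) %*% x, t(x) %*% expr[g, ])
      res <- expr[g, ] - as.vector(x %*% beta)
      expect_equal(unname(got[g, ]), unname(res + mean(expr[g, ])),
                   tolerance = 1e-10)
    }
  })
})

test_that("regression preserves means, removes fitted structure, flags collinearity", {
  withr::with_seed(33, {
    n <- 40
    covs <- data.frame(x1 = rnorm(n), x2 = runif(n))
    expr <- rbind(
      lin = 2 + 3 * covs$x1,              # exact function of a covariate
      orth = rnorm(n),
      mix = rnorm(n) + covs$x2
    )
    colnames(expr) <- paste0("c", 1:n)
    got <- regress_covariates(expr, covs)
    expect_equal(rowMeans(got), rowMeans(expr), tolerance = 1e-10)
    expect_lt(sd(got["lin", ]), 1e-10)
    for (g in rownames(expr)) {
      for (cc in names(covs)) {
        dot <- sum((got[g, ] - mean(got[g, ])) * (covs[[cc]] - mean(covs[[cc]])))
        expect_lt(abs(dot), 1e-8)
      }
    }
    # a covariate orthogonal to a gene's (centred) expression leaves it alone
    g <- expr["orth", ]
    z <- rnorm(n)
    gc <- g - mean(g)
    z <- z - sum(z * gc) / sum(gc^2) * gc
    kept <- regress_covariates(expr["orth", , drop = FALSE], data.frame(z = z))
    expect_equal(unname(kept[1, ]), unname(g), tolerance = 1e-10)
    bad <- data.frame(a = covs$x1, b = 2 * covs$x1)
    expect_error(regress_covariates(expr, bad), "collinear")
  })
})

test_that("kNN graph matches a brute-force distance oracle", {
  withr::with_seed(8, {
    n <- 20
    expr <- matrix(rnorm(10 * n), 10, n,
                   dimnames = list(paste0("g", 1:10), paste0("c", 1:n)))
    res <- pca_neighbors(expr, n_pcs = 9, k = 4)
    emb <- res$embedding
    d <- as.matrix(dist(emb))
    diag(d) <- Inf
    for (i in seq_len(n)) {
      brute <- order(d[i, ])[1:4]
      expect_setequal(res$neighbors[i, ], brute)
    }
    # no self edges, degree exactly k
    expect_true(all(res$neighbors != seq_len(n)))
    expect_true(all(Matrix::rowSums(res$graph) == 4))
    expect_true(all(Matrix::diag(res$graph) == 0))
  })
})

test_that("PCA embedding captures exact low-rank structure and duplicates", {
  # duplicated cell: its nearest neighbour is its duplicate
  base <- matrix(rnorm(5 * 9), 5, 9)
  expr <- cbind(base, base[, 1])
  dimnames(expr) <- list(paste0("g", 1:5), paste0("c", 1:10))
  res <- pca_neighbors(expr, n_pcs = 4, k = 2)
  expect_equal(res$neighbors[10, 1], 1)
  expect_equal(res$neighbors[1, 1], 10)
  # data on a line: first PC explains essentially all variance
  tt <- seq(-2, 2, length.out = 15)
  line <- outer(c(1, -2, 0.5), tt)
  dimnames(line) <- list(paste0("g", 1:3), paste0("c", 1:15))
  p <- prcomp(t(line))
  expect_gt(p$sdev[1]^2 / sum(p$sdev^2), 0.999)
  expect_error(pca_neighbors(line, n_pcs = 2, k = 15), "k")
})
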