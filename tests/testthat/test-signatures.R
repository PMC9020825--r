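test_that("compartment annotation follows the marker rule", {
  s <- toy_counts(0, 4, 3)
  rownames(s) <- c("Pdgfa_like", "Myf5_like", "Myog_like", "other")
  s["other", ] <- 5
  s["Myog_like", 2] <- 3   # myogenic despite no ligand
  s["Pdgfa_like", 3] <- 5  # ligand alone is enough
  ds <- velocity_dataset(s, s * 0)
  ann <- annotate_compartments(ds, list(
    ligand = "Pdgfa_like", myogenic_genes = c("Myf5_like", "Myog_like")
  ))
  expect_equal(ann$compartment, c("non_myogenic", "myogenic", "myogenic"))
  expect_error(
    annotate_compartments(ds, list(ligand = "Nope", myogenic_genes = "Myf5_like")),
    "Nope"
  )
})

# exact two-sided rank-sum p-value by enumerating all group assignments
perm_wilcox_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  r <- rank(pooled)
  obs <- sum(r[seq_len(nx)])
  combs <- utils::combn(n, nx)
  stat <- apply(combs, 2, function(idx) sum(r[idx]))
  p_lo <- mean(stat <= obs)
  p_hi <- mean(stat >= obs)
  min(1, 2 * min(p_lo, p_hi))
}

test_that("marker p-values equal the exact-permutation oracle on a toy table", {
  withr::with_seed(14, {
    expr <- matrix(c(
      5.2, 4.8, 5.9, 6.1, 1.0, 1.3, 0.7, 0.2, # strongly up in group
      2.0, 2.2, 1.9, 2.1, 2.05, 1.95, 2.15, 1.85, # flat
      3.1, 0.5, 2.8, 1.2, 2.2, 0.9, 3.0, 1.1 # mixed
    ), nrow = 3, byrow = TRUE,
    dimnames = list(c("up", "flat", "mix"), paste0("c", 1:8)))
    labels <- rep(c("grp", "rest"), each = 4)
    mk <- find_markers(expr, labels, "grp", n_top = 10)
    for (g in mk$gene) {
      want <- perm_wilcox_p(expr[g, 1:4], expr[g, 5:8])
      expect_equal(mk$p_value[mk$gene == g], want, tolerance = 1e-12)
    }
    expect_equal(mk$gene[1], "up")
  })
})

test_that("identical and group-exclusive genes rank as specified", {
  expr <- rbind(
    only = c(3, 4, 5, 0, 0, 0),
    same = rep(2, 6),
    weak = c(2.2, 2.1, 2.3, 2.0, 1.9, 2.1)
  )
  colnames(expr) <- paste0("c", 1:6)
  labels <- rep(c("g", "r"), each = 3)
  mk <- find_markers(expr, labels, "g", n_top = 5)
  expect_equal(mk$gene[1], "only")
  expect_false("same" %in% mk$gene) # zero fold change excluded
  expect_error(find_markers(expr, labels, "g", n_top = 2)[0, ], NA)
  expect_error(find_markers(expr, rep(c("g", "r"), c(2, 4)), "g"), "3 cells")
})

test_that("signature fractions match hand computation and contracts", {
  expr <- rbind(
    m1 = c(2, 0, 1, 0), m2 = c(1, 0, 1, 0),
    n1 = c(0, 2, 1, 0), n2 = c(0, 1, 2, 0)
  )
  colnames(expr) <- paste0("c", 1:4)
  sc <- signature_scores(expr, c("m1", "m2"), c("n1", "n2"))
  expect_equal(sc$s_m, c(1, 0, 2 / 5, NA))
  expect_equal(sc$s_n, c(0, 1, 3 / 5, NA))
  expect_equal(sc$scored, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(sc$s_m + sc$s_n, c(1, 1, 1, NA))
  expect_error(signature_scores(expr, c("m1"), c("m1", "n1")), "overlap")
  expect_error(signature_scores(expr, character(), "n1"), "non-empty")
})

test_that("transition calling is strict at the threshold", {
  sc <- tibble::tibble(
    cell = c("a", "b", "c", "d"),
    S_m = 1, S_n = 1,
    s_m = c(0.5, 0.5, 0.5, 1.0),
    s_n = c(0.5, 0.4, 0.41, 0.0),
    scored = TRUE
  )
  res <- coexpression_transition(sc, threshold = 0.20)
  # 0.5 * 0.4 == 0.2 exactly in double precision: NOT a transition
  expect_identical(res$coexpression[2], 0.2)
  expect_false(res$transition[2])
  expect_true(res$transition[1])  # 0.25 > 0.20
  expect_true(res$transition[3])  # 0.205 > 0.20
  expect_false(res$transition[4]) # 0
  # boundary fraction from the quadratic f(1-f) = 0.2
  f <- (1 - sqrt(1 - 4 * 0.2)) / 2
  expect_equal(f, 0.2763932, tolerance = 1e-7)
  expect_equal(f * (1 - f), 0.2, tolerance = 1e-12)
  # ordering by increasing s_n with stable cell tie-break
  expect_equal(res$cell[order(res$order)], c("d", "b", "c", "a"))
  expect_warning(coexpression_transition(sc, threshold = 0.3), "0.25")
})

test_that("coexpression is symmetric, bounded and monotone in the threshold", {
  withr::with_seed(9, {
    f <- runif(200)
    sc <- tibble::tibble(
      cell = sprintf("c%03d", 1:200), S_m = 1, S_n = 1,
      s_m = f, s_n = 1 - f, scored = TRUE
    )
    lo <- coexpression_transition(sc, 0.10)
    hi <- coexpression_transition(sc, 0.20)
    expect_true(all(hi$coexpression <= 0.25 + 1e-15))
    expect_equal(hi$coexpression, (1 - f) * f) # symmetric in (s_m, s_n)
    expect_true(all(which(hi$transition) %in% which(lo$transition)))
  })
})

test_that("transition cells concentrate around the planted switch time", {
  proc <- processed_benchmark()
  truth <- proc$sim$truth
  sc <- signature_scores(proc$expr, truth$signature_genes_myo,
                         truth$signature_genes_nonmyo)
  sc <- coexpression_transition(sc, 0.20)
  info <- dplyr::inner_join(sc, truth$cells, by = "cell")
  flagged <- info$transition & info$scored
  expect_gt(sum(flagged), 5)
  d_flag <- median(abs(info$t[flagged] - truth$t_switch))
  d_rest <- median(abs(info$t[!flagged] - truth$t_switch))
  expect_lt(d_flag, d_rest)
})

test_that("top markers recover the planted signature genes", {
  proc <- processed_benchmark()
  truth <- proc$sim$truth
  labels <- ifelse(proc$ds$metadata$cluster == "non_myogenic",
                   "non_myogenic", "myogenic")
  mk_m <- find_markers(proc$expr, labels, "myogenic", n_top = 10)
  mk_n <- find_markers(proc$expr, labels, "non_myogenic", n_top = 10)
  hits_m <- sum(mk_m$gene %in%
                  c(truth$signature_genes_myo,
                    truth$marker_config$myogenic_genes, "Pdgfa_like"))
  hits_n <- sum(mk_n$gene %in% truth$signature_genes_nonmyo)
  expect_gte(hits_n, 8)
  expect_gte(hits_m, 8)
})
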