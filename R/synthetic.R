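with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Sample overdispersed counts from latent abundances
#'
#' Draws integer counts for each layer with a gamma-Poisson (negative
#' binomial) noise model: each cell receives a gamma-distributed capture
#' factor with mean 1 and variance `dispersion` (shared between layers, so
#' the unspliced/spliced ratio is preserved), and counts are Poisson around
#' the depth-scaled latent abundance. `dispersion = 0` degenerates to pure
#' Poisson sampling. The unspliced layer is sequenced shallower than the
#' spliced layer, mimicking intronic capture rates.
#'
#' @param latent A list with matrices `u` and `s` (genes x cells) of
#'   non-negative latent abundances, as from [simulate_latent_kinetics()].
#' @param depth_per_cell Target spliced UMI count per cell (scalar or
#'   per-cell vector).
#' @param dispersion Per-cell capture overdispersion, `>= 0`.
#' @param seed Optional integer seed; the draw is reproducible given the
#'   same seed and inputs.
#' @param unspliced_depth_frac Unspliced depth as a fraction of the spliced
#'   depth (default 0.15).
#' @param metadata Optional extra per-cell columns (e.g. cluster labels) to
#'   carry into the dataset metadata.
#' @return A [velocity_dataset()] whose metadata includes `total_umi`,
#'   `n_genes` and, when mito-prefixed genes (`mt-`) are present,
#'   `mito_fraction` computed from the sampled spliced counts.
#' @export
sample_counts <- function(latent, depth_per_cell, dispersion = 0.15,
                          seed = NULL, unspliced_depth_frac = 0.15,
                          metadata = NULL) {
  stopifnot(is.list(latent), !is.null(latent$u), !is.null(latent$s))
  if (any(latent$u < 0) || any(latent$s < 0)) abort("latent abundances must be non-negative.")
  if (any(depth_per_cell <= 0)) abort("`depth_per_cell` must be positive.")
  if (dispersion < 0) abort("`dispersion` must be non-negative.")
  ng <- nrow(latent$s); nc <- ncol(latent$s)
  depth <- rep_len(depth_per_cell, nc)
  with_seed(seed, {
    capture <- if (dispersion > 0) {
      rgamma(nc, shape = 1 / dispersion, scale = dispersion)
    } else {
      rep(1, nc)
    }
    tot_s <- colSums(latent$s)
    tot_u <- colSums(latent$u)
    f_s <- ifelse(tot_s > 0, depth / tot_s, 0) * capture
    f_u <- ifelse(tot_u > 0, depth * unspliced_depth_frac / tot_u, 0) * capture
    lam_s <- sweep(latent$s, 2, f_s, `*`)
    lam_u <- sweep(latent$u, 2, f_u, `*`)
    cs <- matrix(rpois(ng * nc, lam_s), ng, nc, dimnames = dimnames(latent$s))
    cu <- matrix(rpois(ng * nc, lam_u), ng, nc, dimnames = dimnames(latent$u))
    meta <- tibble(
      cell = colnames(cs),
      total_umi = as.numeric(colSums(cs)),
      n_genes = as.numeric(colSums(cs > 0))
    )
    mito <- grepl("^mt-", rownames(cs))
    if (any(mito)) {
      meta$mito_fraction <- ifelse(
        meta$total_umi > 0,
        colSums(cs[mito, , drop = FALSE]) / meta$total_umi, 0
      )
    }
    if (!is.null(metadata)) {
      extra <- as_tibble(metadata)
      stopifnot("cell" %in% names(extra))
      meta <- left_join(meta, extra, by = "cell")
    }
    velocity_dataset(cs, cu, meta)
  })
}

#' Benchmark generator configuration
#'
#' Default study conditions for the synthetic bifurcating lineage: desk-scale
#' cell/gene numbers, one hundred planted driver genes (genes whose
#' transcription rate switches on the non-myogenic branch), ten planted
#' regulons, ten-gene myogenic/non-myogenic signatures, three planted
#' ligand-receptor pairs (Pdgf-like signalling myogenic to non-myogenic;
#' Bmp-like and Eph-like the reverse) and a small high-mitochondrial "bad
#' cell" subpopulation for the QC filter to remove.
#'
#' @param n_cells,n_genes Dataset dimensions.
#' @param n_drivers Number of planted driver genes (includes the planted
#'   non-myogenic regulon targets, signature genes and branch-biased
#'   ligand/receptor genes).
#' @param n_drivers_branch_a Genes with a myogenic-branch transcription
#'   switch. They give the myogenic domain its own velocity flow (as real
#'   differentiation programmes do) and are bookkept separately from the
#'   non-myogenic drivers.
#' @param n_regulons Number of planted regulons (the last one,
#'   `TF_nonmyo`, targets non-myogenic driver genes).
#' @param targets_per_regulon Targets per planted regulon.
#' @param n_signature Genes per compartment signature.
#' @param prop_branch_a Post-switch proportion of myogenic-branch cells.
#' @param t_total,t_switch Simulated time span and branch switch time.
#' @param depth_per_cell Mean spliced UMI per cell.
#' @param dispersion Per-cell capture overdispersion.
#' @param driver_fold Transcription-rate fold change of generic drivers.
#' @param signature_fold Strength of the planted marker programmes: their
#'   off-compartment transcription rate is `base / signature_fold^2`, i.e.
#'   essentially silent, so that presence/absence marker rules behave as on
#'   sparse real data.
#' @param regulon_activity_sd Log-sd of the shared per-cell TF-activity
#'   factor coupling each TF to its targets.
#' @param n_mito_genes Number of `mt-` prefixed mitochondrial genes.
#' @param frac_bad_cells Fraction of cells with planted mito fraction above
#'   the QC threshold.
#' @param unspliced_depth_frac Unspliced depth relative to spliced.
#' @return A named list of class `benchmark_config`.
#' @export
benchmark_config <- function(n_cells = 3000, n_genes = 1500, n_drivers = 100,
                             n_drivers_branch_a = 50,
                             n_regulons = 10, targets_per_regulon = 20,
                             n_signature = 10, prop_branch_a = 0.5,
                             t_total = 20, t_switch = 8,
                             depth_per_cell = 5000, dispersion = 0.15,
                             driver_fold = 4, signature_fold = 8,
                             regulon_activity_sd = 0.3, n_mito_genes = 10,
                             frac_bad_cells = 0.05,
                             unspliced_depth_frac = 0.15) {
  cfg <- as.list(environment())
  class(cfg) <- "benchmark_config"
  cfg
}

lr_gene_table <- function() {
  tibble(
    ligand = c("Pdgfa_like", "Bmp4_like", "Efnb1_like"),
    receptor = c("Pdgfra_like", "Bmpr1b_like", "Ephb1_like"),
    pathway = c("Pdgf", "Bmp", "Eph"),
    # direction of signalling: ligand from the myogenic or non-myogenic side
    ligand_compartment = c("myogenic", "non_myogenic", "non_myogenic")
  )
}

#' Build the planted benchmark dataset
#'
#' Composes the full synthetic study: bifurcating topology, per-gene
#' kinetics with planted branch-B transcription switches (drivers),
#' TF-coupled co-expressed target modules (regulons), compartment signature
#' genes, branch-biased ligand-receptor pairs, mitochondrial genes with a
#' planted high-mito subpopulation, and overdispersed count sampling.
#'
#' @param config A [benchmark_config()].
#' @param seed Integer seed; all randomness flows through it.
#' @return A list with elements `dataset` (a [velocity_dataset()]) and
#'   `truth` (a `simulation_truth` list: `driver_genes`, `driver_direction`,
#'   `regulon_map`, `signature_genes_myo`, `signature_genes_nonmyo`,
#'   `lr_pairs`, `mito_genes`, `cells` tibble with branch/latent time/target
#'   mito fraction, `params`, and the latent `u`/`s` matrices).
#' @export
build_benchmark_dataset <- function(config = benchmark_config(), seed = 1L) {
  cfg <- config
  n_special <- with(cfg, n_mito_genes + n_regulons +
                      n_regulons * targets_per_regulon + 2 * n_signature + 6)
  if (n_special + cfg$n_drivers + cfg$n_drivers_branch_a > cfg$n_genes) {
    abort("requested planted gene sets exceed `n_genes`.")
  }
  with_seed(seed, {
    topo <- lineage_topology(cfg$n_cells, cfg$t_total, cfg$t_switch,
                             cfg$prop_branch_a)

    ## ---- gene universe ----
    lr <- lr_gene_table()
    genes_mito <- sprintf("mt-%02d", seq_len(cfg$n_mito_genes))
    genes_tf <- c(sprintf("TF%02d", seq_len(cfg$n_regulons - 1)), "TF_nonmyo")
    genes_sig_m <- sprintf("sigM%02d", seq_len(cfg$n_signature))
    genes_sig_n <- sprintf("sigN%02d", seq_len(cfg$n_signature))
    genes_myo_tf <- c("Myf5_like", "Myod_like", "Myog_like")
    genes_lr <- c(lr$ligand, lr$receptor)
    n_named <- length(genes_mito) + length(genes_tf) + length(genes_sig_m) +
      length(genes_sig_n) + length(genes_myo_tf) + length(genes_lr)
    genes_generic <- sprintf("gene%04d", seq_len(cfg$n_genes - n_named))
    universe <- c(genes_mito, genes_tf, genes_sig_m, genes_sig_n,
                  genes_myo_tf, genes_lr, genes_generic)
    stopifnot(length(universe) == cfg$n_genes, !anyDuplicated(universe))

    ## ---- regulon membership ----
    nm_targets <- sprintf("gene%04d", seq_len(cfg$targets_per_regulon))
    other_pool <- setdiff(genes_generic, nm_targets)
    regulon_map <- list()
    idx <- 0
    for (r in seq_len(cfg$n_regulons - 1)) {
      regulon_map[[genes_tf[r]]] <- other_pool[idx + seq_len(cfg$targets_per_regulon)]
      idx <- idx + cfg$targets_per_regulon
    }
    regulon_map[["TF_nonmyo"]] <- nm_targets
    used_generic <- c(nm_targets, other_pool[seq_len(idx)])

    ## ---- driver composition ----
    up_named <- c(genes_sig_n, "Pdgfra_like", "Bmp4_like", "Efnb1_like",
                  "TF_nonmyo", nm_targets)
    down_named <- c(genes_sig_m, "Pdgfa_like", "Bmpr1b_like", "Ephb1_like",
                    genes_myo_tf)
    if (cfg$n_drivers == 0) {
      # nothing switches: a null dataset with no planted dynamics
      up_named <- down_named <- character()
    }
    n_left <- cfg$n_drivers - length(up_named) - length(down_named)
    if (n_left < 0) {
      abort(sprintf(
        "`n_drivers` must be 0 or at least %d (the planted programme genes).",
        length(up_named) + length(down_named)
      ))
    }
    free_pool <- setdiff(genes_generic, used_generic)
    if (n_left > length(free_pool)) abort("not enough free genes to plant drivers.")
    extra <- if (n_left > 0) sample(free_pool, n_left) else character()
    up_extra <- extra[seq_len(ceiling(n_left / 2))]
    down_extra <- setdiff(extra, up_extra)
    drivers_up <- c(up_named, up_extra)
    drivers_down <- c(down_named, down_extra)
    # myogenic-branch programme: its own switch genes, so that both branches
    # carry velocity flow away from the bifurcation
    free_pool <- setdiff(free_pool, extra)
    n_a <- min(cfg$n_drivers_branch_a, length(free_pool))
    drivers_a <- if (n_a > 0) sample(free_pool, n_a) else character()
    drivers_a_up <- drivers_a[seq_len(ceiling(n_a / 2))]
    drivers_a_down <- setdiff(drivers_a, drivers_a_up)

    ## ---- kinetic parameters ----
    base_alpha <- exp(rnorm(cfg$n_genes, log(5), 0.6))
    names(base_alpha) <- universe
    # marker genes get a strong baseline on their active side; signature
    # genes are the strongest (they are planted as the compartments' top
    # markers)
    strong <- c(genes_sig_m, genes_sig_n, genes_myo_tf, genes_lr, "TF_nonmyo")
    base_alpha[strong] <- exp(rnorm(length(strong), log(10), 0.3))
    sig_genes <- c(genes_sig_m, genes_sig_n)
    base_alpha[sig_genes] <- exp(rnorm(length(sig_genes), log(16), 0.25))
    beta <- runif(cfg$n_genes, 0.8, 1.25)
    gamma <- runif(cfg$n_genes, 0.25, 0.7)
    # programme genes turn over quickly: sharp on/off markers
    names(gamma) <- names(beta) <- universe
    gamma[strong] <- runif(length(strong), 0.5, 0.9)
    fold <- cfg$driver_fold
    off <- 1 / (cfg$signature_fold^2) # near-silent "off" state
    a_prog <- base_alpha
    a_a <- base_alpha
    a_b <- base_alpha
    # generic drivers switch gradually (fold up or down) on branch B
    a_b[drivers_up] <- base_alpha[drivers_up] * fold
    a_b[drivers_down] <- base_alpha[drivers_down] / fold
    a_a[drivers_a_up] <- base_alpha[drivers_a_up] * fold
    a_a[drivers_a_down] <- base_alpha[drivers_a_down] / fold
    # marker/signature/L-R programme genes are switch-like: truly off
    # outside their compartment, so presence/absence rules behave like they
    # do on sparse real data (module targets stay graded, like generic
    # drivers)
    programme_up <- intersect(strong, drivers_up)
    programme_down <- intersect(strong, drivers_down)
    a_prog[programme_up] <- base_alpha[programme_up] * off
    a_a[programme_up] <- base_alpha[programme_up] * off
    a_b[programme_up] <- base_alpha[programme_up]
    a_b[programme_down] <- base_alpha[programme_down] * off
    # signature genes are the cleanest on/off markers of their compartment
    sig_up <- intersect(sig_genes, programme_up)
    sig_down <- intersect(sig_genes, programme_down)
    a_prog[sig_up] <- base_alpha[sig_up] * off / 8
    a_a[sig_up] <- a_prog[sig_up]
    a_b[sig_down] <- base_alpha[sig_down] * off / 8

    params <- kinetic_params(tibble(
      gene = universe,
      alpha_progenitor = unname(a_prog),
      alpha_branch_a = unname(a_a),
      alpha_branch_b = unname(a_b),
      beta = unname(beta),
      gamma = unname(gamma)
    ))
    driver_genes <- universe[a_b[universe] != a_prog[universe]]
    stopifnot(setequal(driver_genes, c(drivers_up, drivers_down)))

    ## ---- shared TF-activity fluctuations ----
    activity <- matrix(1, cfg$n_genes, cfg$n_cells,
                       dimnames = list(universe, topo$cell))
    for (tf in names(regulon_map)) {
      a <- exp(rnorm(cfg$n_cells, 0, cfg$regulon_activity_sd))
      members <- c(tf, regulon_map[[tf]])
      activity[members, ] <- activity[members, , drop = FALSE] *
        matrix(a, length(members), cfg$n_cells, byrow = TRUE)
    }

    latent <- simulate_latent_kinetics(topo, params, activity = activity)

    ## ---- planted mitochondrial fractions ----
    n_bad <- round(cfg$frac_bad_cells * cfg$n_cells)
    bad <- sample(cfg$n_cells, n_bad)
    mito_target <- stats::rbeta(cfg$n_cells, 2, 18)
    mito_target[bad] <- runif(n_bad, 0.25, 0.5)
    is_mito <- universe %in% genes_mito
    s_other <- colSums(latent$s[!is_mito, , drop = FALSE])
    s_mito <- colSums(latent$s[is_mito, , drop = FALSE])
    scale_m <- mito_target / (1 - mito_target) * s_other / pmax(s_mito, 1e-12)
    latent$u[is_mito, ] <- sweep(latent$u[is_mito, , drop = FALSE], 2, scale_m, `*`)
    latent$s[is_mito, ] <- sweep(latent$s[is_mito, , drop = FALSE], 2, scale_m, `*`)

    ## ---- counts ----
    depth <- exp(rnorm(cfg$n_cells, log(cfg$depth_per_cell), 0.2))
    cluster <- c(progenitor = "progenitor", branch_a = "myogenic",
                 branch_b = "non_myogenic")[topo$branch]
    ds <- sample_counts(
      latent, depth_per_cell = depth, dispersion = cfg$dispersion,
      unspliced_depth_frac = cfg$unspliced_depth_frac,
      metadata = tibble(cell = topo$cell, cluster = unname(cluster))
    )

    truth <- structure(list(
      driver_genes = driver_genes,
      driver_genes_branch_a = drivers_a,
      driver_direction = setNames(
        ifelse(c(drivers_up, drivers_down) %in% drivers_up, "up", "down"),
        c(drivers_up, drivers_down)
      ),
      regulon_map = regulon_map,
      signature_genes_myo = c(genes_sig_m),
      signature_genes_nonmyo = c(genes_sig_n),
      lr_pairs = lr,
      marker_config = list(
        ligand = "Pdgfa_like",
        myogenic_genes = genes_myo_tf
      ),
      mito_genes = genes_mito,
      cells = mutate(topo, cluster = unname(cluster),
                     mito_target = mito_target),
      params = params,
      t_switch = cfg$t_switch,
      latent = latent
    ), class = "simulation_truth")
    validate_truth(truth, cfg)
    list(dataset = ds, truth = truth)
  })
}

# internal consistency checks: planted structure really is in the latent data
validate_truth <- function(truth, cfg) {
  lat <- truth$latent$s
  branch <- truth$cells$branch
  a_cells <- branch == "branch_a"
  b_cells <- branch == "branch_b"
  stopifnot(length(truth$driver_genes) == cfg$n_drivers)
  if (length(truth$driver_genes) == 0) return(invisible(truth))
  for (i in seq_len(nrow(truth$lr_pairs))) {
    p <- truth$lr_pairs[i, ]
    lig_a <- mean(lat[p$ligand, a_cells]); lig_b <- mean(lat[p$ligand, b_cells])
    rec_a <- mean(lat[p$receptor, a_cells]); rec_b <- mean(lat[p$receptor, b_cells])
    ok <- if (p$ligand_compartment == "myogenic") {
      lig_a > lig_b && rec_b > rec_a
    } else {
      lig_b > lig_a && rec_a > rec_b
    }
    if (!ok) abort(sprintf("planted L-R bias violated for pathway %s", p$pathway))
  }
  invisible(truth)
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat(sprintf(
    "<simulation_truth> %d driver genes, %d regulons, %d+%d signature genes, %d L-R pairs\n",
    length(x$driver_genes), length(x$regulon_map),
    length(x$signature_genes_myo), length(x$signature_genes_nonmyo),
    nrow(x$lr_pairs)
  ))
  invisible(x)
}
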