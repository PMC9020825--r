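#' Closed-form splicing kinetics
#'
#' Solves the standard two-stage transcription model
#' \deqn{du/dt = \alpha - \beta u, \qquad ds/dt = \beta u - \gamma s}
#' in closed form for a segment of constant transcription rate \eqn{\alpha},
#' starting from state `(u0, s0)` at time 0. All arguments are recycled
#' elementwise, so vectors or matrices of equal shape can be passed.
#'
#' For \eqn{\beta \neq \gamma} the spliced solution is
#' \eqn{s(t) = \alpha/\gamma + A e^{-\beta t} + (s_0 - \alpha/\gamma - A)
#' e^{-\gamma t}} with \eqn{A = \beta(u_0 - \alpha/\beta)/(\gamma - \beta)};
#' the degenerate case \eqn{\beta = \gamma} is handled by its analytic limit.
#'
#' @param t Elapsed time(s) within the segment (non-negative).
#' @param alpha Transcription rate (molecules per unit time), `>= 0`.
#' @param beta Splicing rate (1/time), `> 0`.
#' @param gamma Degradation rate (1/time), `> 0`.
#' @param u0,s0 Initial unspliced/spliced abundance at `t = 0`.
#' @return A list with elements `u` and `s`, the shape of the recycled inputs.
#' @export
#' @examples
#' # steady state u* = alpha/beta, s* = alpha/gamma
#' kinetics_closed_form(1e3, alpha = 1, beta = 1, gamma = 1)
kinetics_closed_form <- function(t, alpha, beta, gamma, u0 = 0, s0 = 0) {
  if (any(beta <= 0)) abort("`beta` must be positive.")
  if (any(gamma <= 0)) abort("`gamma` must be positive.")
  if (any(alpha < 0)) abort("`alpha` must be non-negative.")
  if (any(t < 0)) abort("`t` must be non-negative.")
  shape <- if (is.matrix(t)) t else t + alpha + beta + gamma + u0 + s0
  # recycle everything to a common shape
  z <- t * 0 + alpha * 0 + beta * 0 + gamma * 0 + u0 * 0 + s0 * 0
  t <- t + z; alpha <- alpha + z; beta <- beta + z; gamma <- gamma + z
  u0 <- u0 + z; s0 <- s0 + z
  eb <- exp(-beta * t)
  eg <- exp(-gamma * t)
  du <- u0 - alpha / beta
  u <- alpha / beta + du * eb
  denom <- gamma - beta
  deg <- abs(denom) < 1e-8 * pmax(beta, gamma)
  denom[deg] <- 1 # placeholder, patched below
  a_coef <- beta * du / denom
  s <- alpha / gamma + a_coef * eb + (s0 - alpha / gamma - a_coef) * eg
  if (any(deg)) {
    # limit beta -> gamma: s = alpha/g + (s0 - alpha/g) e^{-gt} + b du t e^{-gt}
    s[deg] <- alpha[deg] / gamma[deg] +
      (s0[deg] - alpha[deg] / gamma[deg]) * eg[deg] +
      beta[deg] * du[deg] * t[deg] * eg[deg]
  }
  list(u = pmax(u, 0), s = pmax(s, 0))
}

#' Bifurcating lineage topology
#'
#' Draws per-cell latent times uniformly on `[0, t_total]` and assigns each
#' cell past the switch time to one of two branches: `branch_a`
#' (myogenic-like) or `branch_b` (non-myogenic-like). Cells before the switch
#' are progenitors. Uses the current RNG state; seed control belongs to the
#' caller (see [build_benchmark_dataset()]).
#'
#' @param n_cells Number of cells.
#' @param t_total Total simulated time span (unit time).
#' @param t_switch Time at which branch-specific transcription rates take
#'   effect; must lie in `(0, t_total)`.
#' @param prop_branch_a Proportion of post-switch cells assigned to branch A.
#' @return A tibble with columns `cell`, `t`, `branch` (factor-like character
#'   in `progenitor`, `branch_a`, `branch_b`), carrying `t_total` and
#'   `t_switch` as attributes.
#' @export
lineage_topology <- function(n_cells, t_total = 20, t_switch = 8,
                             prop_branch_a = 0.5) {
  stopifnot(n_cells >= 1, t_total > 0, t_switch > 0, t_switch < t_total,
            prop_branch_a >= 0, prop_branch_a <= 1)
  t <- runif(n_cells, 0, t_total)
  branch <- ifelse(t < t_switch, "progenitor",
                   ifelse(runif(n_cells) < prop_branch_a, "branch_a", "branch_b"))
  out <- tibble(
    cell = sprintf("cell%05d", seq_len(n_cells)),
    t = t,
    branch = branch
  )
  attr(out, "t_total") <- t_total
  attr(out, "t_switch") <- t_switch
  out
}

#' Per-gene kinetic parameter table
#'
#' Validates and normalises a kinetic parameter table: one row per gene with
#' segment-wise transcription rates and splicing/degradation rates.
#'
#' @param params A data frame with columns `gene`, `alpha_progenitor`,
#'   `alpha_branch_a`, `alpha_branch_b`, `beta`, `gamma`.
#' @return The validated tibble.
#' @export
kinetic_params <- function(params) {
  params <- as_tibble(params)
  needed <- c("gene", "alpha_progenitor", "alpha_branch_a", "alpha_branch_b",
              "beta", "gamma")
  missing <- setdiff(needed, names(params))
  if (length(missing)) abort(paste0("missing kinetic columns: ", toString(missing)))
  if (any(params$beta <= 0)) abort("`beta` must be positive for every gene.")
  if (any(params$gamma <= 0)) abort("`gamma` must be positive for every gene.")
  alphas <- as.matrix(params[c("alpha_progenitor", "alpha_branch_a", "alpha_branch_b")])
  if (any(alphas < 0)) abort("transcription rates must be non-negative.")
  if (anyDuplicated(params$gene)) abort("duplicate gene identifiers in params.")
  params
}

#' Latent splicing kinetics along a bifurcating lineage
#'
#' Evaluates the closed-form two-stage model per gene and cell. Each cell
#' follows the progenitor transcription rate up to the switch time and its
#' branch-specific rate afterwards; the branch segment starts from the exact
#' progenitor state at the switch, so trajectories are continuous.
#'
#' @param topology A [lineage_topology()] tibble.
#' @param params A [kinetic_params()] table covering every simulated gene.
#' @param activity Optional gene-by-cell multiplier applied to the
#'   transcription rate (e.g. shared TF-activity fluctuations); defaults to 1.
#' @param init `"steady"` starts every cell at the progenitor steady state
#'   (so pre-switch cells sit on the steady-state line); `"zero"` starts from
#'   `(0, 0)` at `t = 0`.
#' @return A list with matrices `u` and `s` (genes x cells, dimnames set).
#' @export
simulate_latent_kinetics <- function(topology, params, activity = NULL,
                                     init = c("steady", "zero")) {
  init <- match.arg(init)
  params <- kinetic_params(params)
  t_switch <- attr(topology, "t_switch")
  if (is.null(t_switch)) abort("`topology` must carry a `t_switch` attribute.")
  ng <- nrow(params)
  nc <- nrow(topology)
  if (!is.null(activity)) {
    stopifnot(identical(dim(activity), c(ng, nc)))
    if (any(activity < 0)) abort("`activity` multipliers must be non-negative.")
  } else {
    activity <- 1
  }
  tm <- matrix(topology$t, ng, nc, byrow = TRUE)
  beta <- matrix(params$beta, ng, nc)
  gamma <- matrix(params$gamma, ng, nc)
  a_prog <- matrix(params$alpha_progenitor, ng, nc) * activity
  branch_alpha <- ifelse(
    matrix(topology$branch == "branch_a", ng, nc, byrow = TRUE),
    matrix(params$alpha_branch_a, ng, nc),
    matrix(params$alpha_branch_b, ng, nc)
  ) * activity
  if (init == "steady") {
    u0 <- a_prog / beta
    s0 <- a_prog / gamma
  } else {
    u0 <- matrix(0, ng, nc)
    s0 <- matrix(0, ng, nc)
  }
  seg1 <- kinetics_closed_form(pmin(tm, t_switch), a_prog, beta, gamma, u0, s0)
  tau <- pmax(tm - t_switch, 0)
  # pre-switch cells keep the progenitor alpha so tau = 0 leaves them untouched
  alpha2 <- ifelse(tm >= t_switch, branch_alpha, a_prog)
  out <- kinetics_closed_form(tau, alpha2, beta, gamma, seg1$u, seg1$s)
  dimnames(out$u) <- dimnames(out$s) <- list(params$gene, topology$cell)
  out
}
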