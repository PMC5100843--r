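#' Specify the multi-environment field layout and noise structure
#'
#' @param n_environments number of environments (location-year combinations).
#' @param n_replicates complete replicates per environment.
#' @param incomplete_block_size plots per incomplete block within a
#'   replicate (consecutive plots are grouped; the last block may be short).
#' @param var_block variance of incomplete-block effects.
#' @param var_gxe variance of genotype x environment effects (single
#'   variance, independent draws per genotype-environment pair).
#' @param var_e residual (plot) variance.
#' @param dropout probability a plot is lost (i.i.d.; emulates stand-count
#'   discards and seed shortages).
#' @param env_effects fixed environment effects; default equally spaced
#'   around 0 with spread `env_spread`.
#' @param env_spread spread of the default environment effects.
#' @param rep_effects fixed replicate-within-environment effects (matrix
#'   n_environments x n_replicates); default 0.
#' @return A `field_spec` list.
#' @export
field_spec <- function(n_environments = 5, n_replicates = 3,
                       incomplete_block_size = 26,
                       var_block = 0.15, var_gxe = 0.45, var_e = 3.2,
                       dropout = 0.06,
                       env_effects = NULL, env_spread = 1,
                       rep_effects = NULL) {
  assert_nonneg(c(var_block, var_gxe, var_e), "variances")
  assert_scalar_prob(dropout, "dropout", upper_open = TRUE)
  stopifnot(n_environments >= 1, n_replicates >= 1, incomplete_block_size >= 1)
  if (is.null(env_effects)) {
    env_effects <- if (n_environments == 1) 0 else
      seq(-env_spread, env_spread, length.out = n_environments)
  }
  stopifnot(length(env_effects) == n_environments)
  if (is.null(rep_effects)) {
    rep_effects <- matrix(0, n_environments, n_replicates)
  }
  structure(list(
    n_environments = as.integer(n_environments),
    n_replicates = as.integer(n_replicates),
    incomplete_block_size = as.integer(incomplete_block_size),
    var_block = var_block, var_gxe = var_gxe, var_e = var_e,
    dropout = dropout, env_effects = env_effects, rep_effects = rep_effects
  ), class = "field_spec")
}

#' Simulate plot-level phenotypes for the designed single crosses
#'
#' One record per surviving plot:
#' y = mu + e_k + g_ij + (gxe)_ik + r_l(k) + b_q(kl) + eps, with environment
#' and replicate effects fixed, block and G x E effects and residuals drawn
#' independently with the spec's variances. Within each replicate the entry
#' order is randomized and consecutive plots are grouped into incomplete
#' blocks of the configured size (an alpha-design analogue). Plots are then
#' dropped i.i.d. with the dropout probability.
#'
#' @param truth a [simulate_genetic_values()] result.
#' @param field a [field_spec()].
#' @param seed integer seed.
#' @return data.frame of plot records: `hybrid`, `female`, `male`, `env`,
#'   `rep`, `iblock`, `y`.
#' @examples
#' d <- build_cross_design(crosses_per_family = matrix(2, 3, 3),
#'                         sss_sizes = c(3, 3, 3), nss_sizes = c(3, 3, 3))
#' tr <- simulate_genetic_values(d, "mvn")
#' head(simulate_trials(tr, field_spec(n_environments = 2, dropout = 0)))
#' @export
simulate_trials <- function(truth, field = field_spec(), seed = 1L) {
  stopifnot(inherits(truth, "truth_record"), inherits(field, "field_spec"))
  hyb <- rownames(truth)
  n_h <- length(hyb)
  set.seed(derive_seed(seed, "trials"))
  gxe <- matrix(rnorm(n_h * field$n_environments, 0, sqrt(field$var_gxe)),
                n_h, field$n_environments)
  recs <- vector("list", field$n_environments * field$n_replicates)
  ridx <- 0L
  for (k in seq_len(field$n_environments)) {
    for (l in seq_len(field$n_replicates)) {
      ridx <- ridx + 1L
      ord <- sample.int(n_h)                       # field order within replicate
      block_of <- ceiling(seq_len(n_h) / field$incomplete_block_size)
      n_blocks <- max(block_of)
      b_eff <- rnorm(n_blocks, 0, sqrt(field$var_block))
      eps <- rnorm(n_h, 0, sqrt(field$var_e))
      recs[[ridx]] <- data.frame(
        hybrid = hyb[ord],
        female = truth$female[ord],
        male = truth$male[ord],
        env = sprintf("E%d", k),
        rep = sprintf("E%d_R%d", k, l),
        iblock = sprintf("E%d_R%d_B%d", k, l, block_of),
        y = attr(truth, "mu") + field$env_effects[k] + field$rep_effects[k, l] +
          (truth$g[ord] - attr(truth, "mu")) + gxe[ord, k] + b_eff[block_of] + eps,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, recs)
  if (field$dropout > 0) {
    keep <- runif(nrow(out)) >= field$dropout
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
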