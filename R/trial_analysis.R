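#' Fit the multi-environment trial model (stage 1)
#'
#' y_iklq = mu + g_i + e_k + (ge)_ik + r_l(k) + b_q(kl) + eps, with
#' environment and replicate-within-environment fixed, and single-cross
#' effects g ~ N(0, I sigma2_g), genotype x environment and incomplete-block
#' effects random with identity covariance. Unbalanced data (missing plots)
#' are handled through the likelihood. With a single environment the (ge)
#' term is dropped with a warning.
#'
#' @param records data.frame of plot records with columns `hybrid`, `env`,
#'   `rep`, `iblock`, `y` (as written by [simulate_trials()]).
#' @param tol,max_iter passed to [fit_reml()].
#' @return a `trial_fit`: the [fit_reml()] result plus `records`.
#' @export
fit_trial_model <- function(records, tol = 1e-8, max_iter = 200) {
  req <- c("hybrid", "env", "rep", "iblock", "y")
  if (!all(req %in% names(records))) {
    stop("records must have columns ", paste(req, collapse = ", "))
  }
  records <- records[!is.na(records$y), , drop = FALSE]
  if (length(unique(records$hybrid)) < 2) stop("need at least 2 hybrids")
  one_env <- length(unique(records$env)) == 1
  if (one_env) warning("single environment: genotype x environment term dropped")
  rand <- list(random_term("g", records$hybrid))
  if (!one_env) {
    rand <- c(rand, list(random_term("ge", paste(records$hybrid, records$env, sep = ":"))))
  }
  rand <- c(rand, list(random_term("block", records$iblock)))
  fixed <- if (one_env && length(unique(records$rep)) == 1) ~ 1 else
    if (one_env) ~ rep else ~ env + rep
  spec <- mixed_model_spec(records$y, fixed = fixed, data = records, random = rand)
  fit <- fit_reml(spec, tol = tol, max_iter = max_iter)
  fit$records <- records
  class(fit) <- c("trial_fit", class(fit))
  fit
}

#' Single-cross BLUPs from the trial model
#'
#' Returns mu_hat + g_hat per hybrid (grand mean plus BLUP), the observed
#' single-cross performance used downstream as validation values and as the
#' y_t vector of the covariance prediction methods.
#'
#' @param fit a [fit_trial_model()] result.
#' @param centered if `TRUE`, return g_hat only (no grand mean).
#' @return data.frame with `hybrid`, `blup`, `n_obs`.
#' @export
hybrid_blups <- function(fit, centered = FALSE) {
  stopifnot(inherits(fit, "trial_fit"))
  g <- fit$u$g
  mu <- fit$beta["(Intercept)"]
  counts <- table(fit$records$hybrid)
  data.frame(hybrid = names(g),
             blup = as.vector(g) + if (centered) 0 else unname(mu),
             n_obs = as.integer(counts[names(g)]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Entry-mean heritability
#'
#' H2 = sigma2_g / (sigma2_g + sigma2_gxe / h_k + sigma2_e / h_t), with h_k
#' the harmonic mean of the number of observations per single cross within
#' an environment (over all observed entry-environment cells) and h_t the
#' harmonic mean of the total number of observations per single cross. Both
#' are computed from the realized record counts. `gxe_divisor = "n_env"`
#' replaces h_k by the number of environments (an alternative reading of the
#' divisor); the default uses h_k as printed.
#'
#' @param fit a [fit_trial_model()] result.
#' @param records plot records; defaults to those stored in the fit.
#' @param gxe_divisor `"h_k"` (default) or `"n_env"`.
#' @return list with `H2`, `sigma2_g`, `sigma2_gxe`, `sigma2_e`, `h_k`, `h_t`.
#' @export
entry_mean_heritability <- function(fit, records = NULL, gxe_divisor = c("h_k", "n_env")) {
  gxe_divisor <- match.arg(gxe_divisor)
  stopifnot(inherits(fit, "reml_fit"))
  records <- records %||% fit$records
  s2g <- unname(fit$theta["g"])
  s2ge <- if ("ge" %in% names(fit$theta)) unname(fit$theta["ge"]) else 0
  s2e <- unname(fit$theta["sigma2_e"])
  cell_counts <- as.vector(table(paste(records$hybrid, records$env)))
  h_k <- harmonic_mean(cell_counts)
  h_t <- harmonic_mean(as.vector(table(records$hybrid)))
  denom_k <- if (gxe_divisor == "h_k") h_k else length(unique(records$env))
  tot <- s2g + s2ge / denom_k + s2e / h_t
  if (tot <= 0) stop("zero total variance: heritability undefined")
  list(H2 = s2g / tot, sigma2_g = s2g, sigma2_gxe = s2ge, sigma2_e = s2e,
       h_k = h_k, h_t = h_t)
}

#' Per-family trial summaries
#'
#' For each single-cross family: mean and range of hybrid BLUPs, and the
#' genetic variance and entry-mean heritability from refitting the trial
#' model on the family's records alone. Families below `min_hybrids` are
#' skipped with a warning.
#'
#' @param records plot records (columns of [fit_trial_model()]).
#' @param sc_family named character vector: single-cross family per hybrid.
#' @param min_hybrids minimum hybrids per family (default 2).
#' @return data.frame, one row per analyzed family: `family`, `n_hybrids`,
#'   `mean`, `min`, `max`, `sigma2_g`, `H2`.
#' @export
family_summaries <- function(records, sc_family, min_hybrids = 2) {
  fams <- sort(unique(sc_family[unique(records$hybrid)]))
  rows <- list()
  for (fm in fams) {
    hyb <- names(sc_family)[sc_family == fm]
    sub <- records[records$hybrid %in% hyb, , drop = FALSE]
    if (length(unique(sub$hybrid)) < min_hybrids) {
      warning("family ", fm, " has fewer than ", min_hybrids, " hybrids: skipped")
      next
    }
    fit <- fit_trial_model(sub)
    bl <- hybrid_blups(fit)
    h2 <- entry_mean_heritability(fit, sub)
    rows[[fm]] <- data.frame(
      family = fm, n_hybrids = nrow(bl), mean = mean(bl$blup),
      min = min(bl$blup), max = max(bl$blup),
      sigma2_g = h2$sigma2_g, H2 = h2$H2, stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no family met the minimum size")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
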