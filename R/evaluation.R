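#' Eligible training pool for a validation cross under a CV scenario
#'
#' T2: all crosses except the validation cross (both parents may remain
#' tested). T1F: additionally excludes every cross sharing the validation
#' cross's male parent (only the female stays tested). T1M: excludes every
#' cross sharing its female parent. T0: excludes every cross sharing either
#' parent.
#'
#' @param validation_cross index (or "female/male" id) of the validation
#'   cross within `all_crosses`.
#' @param all_crosses data.frame with `female`, `male`.
#' @param scenario one of "T2", "T1F", "T1M", "T0".
#' @return integer indices of the eligible crosses.
#' @export
scenario_training_pool <- function(validation_cross, all_crosses,
                                   scenario = c("T2", "T1F", "T1M", "T0")) {
  scenario <- match.arg(scenario)
  ids <- paste(all_crosses$female, all_crosses$male, sep = "/")
  v <- if (is.character(validation_cross)) match(validation_cross, ids) else
    as.integer(validation_cross)
  if (is.na(v) || v < 1 || v > nrow(all_crosses)) {
    stop("validation cross not found in cross list")
  }
  keep <- rep(TRUE, nrow(all_crosses))
  keep[v] <- FALSE
  if (scenario %in% c("T1F", "T0")) {
    keep[all_crosses$male == all_crosses$male[v]] <- FALSE
  }
  if (scenario %in% c("T1M", "T0")) {
    keep[all_crosses$female == all_crosses$female[v]] <- FALSE
  }
  which(keep)
}

#' Prediction accuracy with heritability scaling
#'
#' Pearson correlation between predicted and observed values divided by the
#' square root of the entry-mean heritability.
#'
#' @param predicted,observed numeric vectors (length >= 3).
#' @param H2 entry-mean heritability in (0, 1].
#' @return scalar accuracy.
#' @export
accuracy <- function(predicted, observed, H2 = 1) {
  if (length(predicted) != length(observed) || length(predicted) < 3) {
    stop("predicted and observed must have equal length >= 3")
  }
  if (!is.numeric(H2) || length(H2) != 1 || H2 <= 0 || H2 > 1) {
    stop("H2 must be in (0, 1]")
  }
  if (sd(predicted) == 0 || sd(observed) == 0) {
    stop("zero variance in predicted or observed values: accuracy undefined")
  }
  cor(predicted, observed) / sqrt(H2)
}

#' Bootstrap standard error of a correlation
#'
#' Paired resampling with replacement, B times; the SE is the standard
#' deviation of the B resampled correlations. Degenerate resamples (zero
#' variance in either vector) are redrawn.
#'
#' @param predicted,observed paired numeric vectors (length >= 4).
#' @param B bootstrap resamples (default 200).
#' @param seed integer seed.
#' @return scalar bootstrap SE.
#' @export
bootstrap_se <- function(predicted, observed, B = 200, seed = 1L) {
  n <- length(predicted)
  if (n != length(observed) || n < 4) stop("need paired vectors of length >= 4")
  set.seed(derive_seed(seed, "bootstrap"))
  rs <- numeric(B)
  redraws <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (sd(predicted[idx]) > 0 && sd(observed[idx]) > 0) break
      redraws <- redraws + 1L
      if (redraws > 100 * B) stop("bootstrap: persistent degenerate resamples")
    }
    rs[b] <- cor(predicted[idx], observed[idx])
  }
  sd(rs)
}

#' Assemble the data bundle used by the cross-validation drivers
#'
#' Precomputes, over the realized cross list, the additive and dominance
#' relationship blocks that every fold's covariances are subset from.
#'
#' @param design cross list (`female`, `male`, optional `sc_family`).
#' @param blups data.frame `hybrid` ("female/male"), `blup`, `n_obs`:
#'   stage-1 single-cross BLUPs, the observed performance (y_t).
#' @param means optional data.frame like `blups` carrying weighted hybrid
#'   means; used as the response of the combining-ability methods 1a/1b
#'   (defaults to `blups`).
#' @param G_f,G_m additive relationship matrices.
#' @param components named vector `gca_f`, `gca_m`, `sca`, `sigma2_e` (model
#'   (2) estimates, or generating values in simulation studies).
#' @param H2 entry-mean heritability for accuracy scaling.
#' @return a `cv_bundle`.
#' @export
make_cv_bundle <- function(design, blups, means = NULL, G_f, G_m, components, H2) {
  ids <- paste(design$female, design$male, sep = "/")
  pos <- match(ids, blups$hybrid)
  if (anyNA(pos)) stop("blups do not cover all designed crosses")
  means <- means %||% blups
  pos2 <- match(ids, means$hybrid)
  if (anyNA(pos2)) stop("means do not cover all designed crosses")
  need <- c("gca_f", "gca_m", "sca", "sigma2_e")
  stopifnot(all(need %in% names(components)))
  structure(list(
    design = design, ids = ids,
    y_t = blups$blup[pos], n_obs = blups$n_obs[pos],
    y_1 = means$blup[pos2], n_obs_1 = means$n_obs[pos2],
    A_f = G_f[design$female, design$female, drop = FALSE],
    A_m = G_m[design$male, design$male, drop = FALSE],
    G_f = G_f, G_m = G_m,
    components = unlist(components[need]), H2 = H2
  ), class = "cv_bundle")
}

# per-fold covariance projection; returns predictions for crosses `u` from
# training crosses `t`. Methods 1a/1b use the full model-(2) covariance on
# the combining-ability response y_1; methods 2a/2b(-mod) use the Eq.(5)
# covariances on the stage-1 BLUPs y_t.
.cv_predict_fold <- function(bundle, method, t_idx, u_idx) {
  cm <- bundle$components
  s2F <- cm[["gca_f"]]; s2M <- cm[["gca_m"]]; s2S <- cm[["sca"]]; s2e <- cm[["sigma2_e"]]
  if (grepl("mod$", method)) s2F <- s2M <- (s2F + s2M) / 2
  Af_tt <- bundle$A_f[t_idx, t_idx]; Am_tt <- bundle$A_m[t_idx, t_idx]
  Af_ut <- bundle$A_f[u_idx, t_idx, drop = FALSE]
  Am_ut <- bundle$A_m[u_idx, t_idx, drop = FALSE]
  if (method %in% c("1a", "1b")) {
    V <- Af_tt * s2F + Am_tt * s2M + (Af_tt * Am_tt) * s2S
    diag(V) <- diag(V) + s2e / bundle$n_obs_1[t_idx]
    y <- bundle$y_1[t_idx]
    cu <- Af_ut * s2F + Am_ut * s2M
    if (method == "1b") cu <- cu + (Af_ut * Am_ut) * s2S
  } else {
    with_sca <- grepl("^2b", method)
    V <- Af_tt * s2F + Am_tt * s2M
    cu <- Af_ut * s2F + Am_ut * s2M
    if (with_sca) {
      V <- V + (Af_tt * Am_tt) * s2S
      cu <- cu + (Af_ut * Am_ut) * s2S
    }
    diag(V) <- diag(V) + s2e / bundle$n_obs[t_idx]
    y <- bundle$y_t[t_idx]
  }
  ch <- tryCatch(chol(V), error = function(e) chol(V + diag(1e-8, nrow(V))))
  Vi_y <- backsolve(ch, backsolve(ch, cbind(y, 1), transpose = TRUE))
  mu <- sum(Vi_y[, 2] * y) / sum(Vi_y[, 2])          # GLS grand mean
  w <- Vi_y[, 1] - Vi_y[, 2] * mu                    # V^-1 (y - mu)
  drop(cu %*% w) + mu
}

cv_methods <- c("1a", "1b", "2a", "2b", "2a-mod", "2b-mod")

#' Leave-one-individual-out cross-validation under a parent-testing scenario
#'
#' For each repetition and each hybrid, draws a training sample (default
#' 250) without replacement from the hybrid's scenario-eligible pool,
#' predicts the hybrid with the chosen method, integrates the predictions
#' into one vector, and computes the accuracy against the stage-1 BLUPs
#' scaled by sqrt(H2). With the full study design (312 hybrids) and 30
#' repetitions, 9360 training sets are drawn. Variance components are fixed
#' at the bundle's values across folds unless `refit = TRUE`, which
#' re-estimates them per training sample by REML at the entry-mean level.
#'
#' @param bundle a [make_cv_bundle()].
#' @param method one of "1a", "1b", "2a", "2b", "2a-mod", "2b-mod".
#' @param scenario "T2", "T1F", "T1M" or "T0".
#' @param train_size training-set size (default 250).
#' @param reps repetitions (default 30).
#' @param boot bootstrap resamples per repetition (default 200).
#' @param seed integer seed.
#' @param refit re-estimate components per training sample (slow).
#' @return a `cv_result`: list with `scenario`, `method`, `accuracy`
#'   (per-repetition), `mean_accuracy`, `mean_boot_se`, `n_training_sets`,
#'   `n_excluded` (infeasible hybrids).
#' @export
run_loocv <- function(bundle, method = "1a",
                      scenario = c("T2", "T1F", "T1M", "T0"),
                      train_size = 250, reps = 30, boot = 200, seed = 1L,
                      refit = FALSE) {
  scenario <- match.arg(scenario)
  method <- match.arg(method, cv_methods)
  stopifnot(inherits(bundle, "cv_bundle"), reps >= 1)
  n <- nrow(bundle$design)
  pools <- lapply(seq_len(n), scenario_training_pool,
                  all_crosses = bundle$design, scenario = scenario)
  # construction audit: the validation cross (and excluded parents) never
  # appear in any pool
  for (v in seq_len(n)) {
    p <- pools[[v]]
    stopifnot(!(v %in% p))
    if (scenario %in% c("T1F", "T0"))
      stopifnot(!any(bundle$design$male[p] == bundle$design$male[v]))
    if (scenario %in% c("T1M", "T0"))
      stopifnot(!any(bundle$design$female[p] == bundle$design$female[v]))
  }
  feasible <- which(lengths(pools) >= train_size)
  n_excl <- n - length(feasible)
  if (n_excl > 0) {
    warning(n_excl, " hybrid(s) infeasible under ", scenario,
            " with training size ", train_size, ": excluded")
  }
  if (length(feasible) < 3) stop("fewer than 3 feasible hybrids under ", scenario)
  acc <- se <- numeric(reps)
  n_draws <- 0L
  for (r in seq_len(reps)) {
    preds <- numeric(length(feasible))
    for (vi in seq_along(feasible)) {
      v <- feasible[vi]
      set.seed(derive_seed(seed, paste0("cv-", scenario), r * 1000L + v))
      t_idx <- sample(pools[[v]], train_size)
      n_draws <- n_draws + 1L
      if (refit) {
        b2 <- bundle
        b2$components <- .refit_components(bundle, t_idx)
        preds[vi] <- .cv_predict_fold(b2, method, t_idx, v)
      } else {
        preds[vi] <- .cv_predict_fold(bundle, method, t_idx, v)
      }
    }
    obs <- bundle$y_t[feasible]
    acc[r] <- accuracy(preds, obs, bundle$H2)
    se[r] <- bootstrap_se(preds, obs, B = boot,
                          seed = derive_seed(seed, "cv-boot", r))
  }
  structure(list(scenario = scenario, method = method, accuracy = acc,
                 mean_accuracy = mean(acc), mean_boot_se = mean(se),
                 n_training_sets = n_draws, n_excluded = n_excl),
            class = "cv_result")
}

.refit_components <- function(bundle, t_idx) {
  vals <- data.frame(female = bundle$design$female[t_idx],
                     male = bundle$design$male[t_idx],
                     y = bundle$y_1[t_idx], n_obs = bundle$n_obs_1[t_idx])
  uf <- unique(vals$female); um <- unique(vals$male)
  fit <- fit_gca_sca_means(vals,
                           G_f = bundle$G_f[uf, uf, drop = FALSE],
                           G_m = bundle$G_m[um, um, drop = FALSE])
  c(gca_f = unname(fit$theta["gca_f"]), gca_m = unname(fit$theta["gca_m"]),
    sca = unname(fit$theta["sca"]), sigma2_e = unname(fit$theta["sigma2_e"]))
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("CV %s / method %s: mean accuracy %.3f (boot SE %.3f, %d reps, %d training sets)\n",
              x$scenario, x$method, x$mean_accuracy, x$mean_boot_se,
              length(x$accuracy), x$n_training_sets))
  invisible(x)
}

#' Leave-one-family-out cross-validation
#'
#' Each single-cross family is the validation set in turn; the training set
#' is a sample of `train_size` crosses from the remaining families,
#' repeated `reps` times. Accuracy is computed per family and reported only
#' for families with at least `min_family` crosses (the six largest under
#' the reference design).
#'
#' @inheritParams run_loocv
#' @param min_family minimum validation-family size for reporting
#'   (default 25).
#' @return a `cv_family_result`: per-family mean accuracies and bootstrap
#'   SEs, plus per-repetition detail.
#' @export
run_leave_family_out <- function(bundle, method = "1a", train_size = 250,
                                 reps = 30, boot = 200, seed = 1L,
                                 min_family = 25) {
  method <- match.arg(method, cv_methods)
  if (is.null(bundle$design$sc_family)) stop("design carries no sc_family labels")
  fams <- sort(unique(bundle$design$sc_family))
  if (length(fams) < 2) stop("need at least 2 single-cross families")
  sizes <- table(bundle$design$sc_family)
  eval_fams <- names(sizes)[sizes >= min_family]
  if (!length(eval_fams)) stop("no family reaches the reporting threshold of ", min_family)
  acc <- se <- matrix(NA_real_, reps, length(eval_fams),
                      dimnames = list(NULL, eval_fams))
  for (fm in fams) {
    v_idx <- which(bundle$design$sc_family == fm)
    pool <- setdiff(seq_len(nrow(bundle$design)), v_idx)
    if (length(pool) < train_size) {
      warning("family ", fm, ": pool smaller than training size, skipped")
      next
    }
    report <- fm %in% eval_fams
    for (r in seq_len(reps)) {
      set.seed(derive_seed(seed, paste0("cv-family-", fm), r))
      t_idx <- sample(pool, train_size)
      if (!report) next     # still drawn for reproducibility parity
      preds <- .cv_predict_fold(bundle, method, t_idx, v_idx)
      obs <- bundle$y_t[v_idx]
      acc[r, fm] <- accuracy(preds, obs, bundle$H2)
      se[r, fm] <- bootstrap_se(preds, obs, B = boot,
                                seed = derive_seed(seed, paste0("boot-", fm), r))
    }
  }
  structure(list(method = method,
                 families = eval_fams,
                 family_sizes = as.integer(sizes[eval_fams]),
                 accuracy = acc,
                 mean_accuracy = colMeans(acc),
                 mean_boot_se = colMeans(se),
                 overall_mean = mean(colMeans(acc))),
            class = "cv_family_result")
}

#' @export
print.cv_family_result <- function(x, ...) {
  cat("Leave-one-family-out CV, method", x$method, "\n")
  print(data.frame(family = x$families, n = x$family_sizes,
                   mean_accuracy = round(x$mean_accuracy, 3),
                   mean_boot_se = round(x$mean_boot_se, 3)))
  invisible(x)
}
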