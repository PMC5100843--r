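ca_trial <- function(seed = 1, n_env = 3, reduced = TRUE) {
  w <- small_world()
  tr <- simulate_genetic_values(w$design, "mvn",
                                kinships = list(G_f = w$G_f, G_m = w$G_m, S = w$S),
                                seed = seed)
  fs <- field_spec(n_environments = n_env, n_replicates = 2,
                   incomplete_block_size = 12, var_block = 0.1, var_gxe = 0.3,
                   var_e = 1.5, dropout = 0.05)
  plots <- simulate_trials(tr, fs, seed = seed + 1)
  list(world = w, truth = tr, plots = plots,
       fit = fit_gca_sca(plots, w$G_f, w$G_m, S = w$S, reduced = reduced))
}

test_that("combining-ability fit recovers structure and covers untested parents", {
  ca <- ca_trial(seed = 5)
  fit <- ca$fit
  # every parent in the kinship matrices has a GCA prediction
  expect_setequal(names(fit$u$gca_f), rownames(ca$world$G_f))
  expect_setequal(names(fit$u$gca_m), rownames(ca$world$G_m))
  # fitted GCA BLUPs track the generating values
  expect_gt(cor(fit$u$gca_f, attr(ca$truth, "f_by_parent")[names(fit$u$gca_f)]), 0.4)
  expect_gt(cor(fit$u$gca_m, attr(ca$truth, "m_by_parent")[names(fit$u$gca_m)]), 0.4)
  # decomposition tracks stage-1 hybrid BLUPs
  tfit <- fit_trial_model(ca$plots)
  bl <- hybrid_blups(tfit)
  cross_ids <- paste(ca$world$design$female, ca$world$design$male, sep = "/")
  dec <- setNames(
    unname(fit$beta["(Intercept)"]) + unname(fit$u$gca_f[ca$world$design$female]) +
      unname(fit$u$gca_m[ca$world$design$male]) + unname(fit$u$sca[cross_ids]),
    cross_ids)
  expect_gt(cor(dec[bl$hybrid], bl$blup), 0.6)

  # and the agreement tightens as plot noise shrinks
  fs_low <- field_spec(n_environments = 3, n_replicates = 2,
                       incomplete_block_size = 12, var_block = 0.02,
                       var_gxe = 0.05, var_e = 0.15, dropout = 0.05)
  plots_low <- simulate_trials(ca$truth, fs_low, seed = 6)
  fit_low <- fit_gca_sca(plots_low, ca$world$G_f, ca$world$G_m,
                         S = ca$world$S, reduced = TRUE)
  bl_low <- hybrid_blups(fit_trial_model(plots_low))
  dec_low <- setNames(
    unname(fit_low$beta["(Intercept)"]) +
      unname(fit_low$u$gca_f[ca$world$design$female]) +
      unname(fit_low$u$gca_m[ca$world$design$male]) +
      unname(fit_low$u$sca[cross_ids]),
    cross_ids)
  expect_gt(cor(dec_low[bl_low$hybrid], bl_low$blup),
            cor(dec[bl$hybrid], bl$blup))
})

test_that("an inconsistent S matrix is rejected", {
  w <- small_world()
  tr <- simulate_genetic_values(w$design, "mvn", seed = 2)
  fs <- field_spec(n_environments = 2, n_replicates = 2, var_e = 1)
  plots <- simulate_trials(tr, fs, seed = 3)
  S_bad <- w$S
  S_bad[1, 2] <- S_bad[2, 1] <- S_bad[1, 2] + 0.2
  expect_error(fit_gca_sca(plots, w$G_f, w$G_m, S = S_bad, reduced = TRUE),
               "inconsistent")
})

test_that("identity kinships with no SCA reduce to independent GCA BLUPs", {
  d <- build_cross_design(crosses_per_family = matrix(6, 3, 3),
                          sss_sizes = c(4, 4, 4), nss_sizes = c(4, 4, 4), seed = 1)
  tr <- simulate_genetic_values(d, "mvn",
                                params = list(mu = 5, var_gca_f = 0.4,
                                              var_gca_m = 0.3, var_sca = 0),
                                seed = 2)
  obs <- mean_level_obs(tr, var_e = 1, n_obs = 10, seed = 3)
  vals <- data.frame(female = d$female, male = d$male,
                     y = obs$blup, n_obs = obs$n_obs)
  fems <- unique(d$female); mals <- unique(d$male)
  If <- diag(length(fems)); dimnames(If) <- list(fems, fems)
  Im <- diag(length(mals)); dimnames(Im) <- list(mals, mals)
  fit <- fit_gca_sca_means(vals, If, Im,
                           theta = c(0.4, 0.3, 1e-12, 1), include_sca = TRUE)
  # SCA BLUPs vanish as its variance goes to zero
  expect_lt(max(abs(fit$u$sca)), 1e-6)
  # and predictions equal the no-SCA fit
  fit0 <- fit_gca_sca_means(vals, If, Im, theta = c(0.4, 0.3, 1),
                            include_sca = FALSE)
  expect_equal(fit$u$gca_f, fit0$u$gca_f, tolerance = 1e-5)
})

test_that("sca_ratio reproduces the per-trait reported ratios", {
  expect_equal(sca_ratio(c(gca_f = 0.22, gca_m = 0.20, sca = 0.05)), 0.12)
  expect_equal(sca_ratio(c(gca_f = 28.66, gca_m = 34.48, sca = 2.6)), 0.04)
  expect_equal(sca_ratio(c(gca_f = 0.12, gca_m = 0.23, sca = 0.01)), 0.03)
  expect_equal(sca_ratio(c(gca_f = 0.22, gca_m = 0.20, sca = 0.05),
                         digits = NULL), 0.05 / 0.42, tolerance = 1e-12)
  expect_error(sca_ratio(c(gca_f = 0, gca_m = 0, sca = 0.1)), "zero GCA")
})

test_that("female/male exchangeability: transposing the design swaps GCA variances", {
  d <- build_cross_design(crosses_per_family = matrix(6, 3, 3),
                          sss_sizes = c(5, 5, 5), nss_sizes = c(5, 5, 5), seed = 3)
  tr <- simulate_genetic_values(d, "mvn",
                                params = list(mu = 0, var_gca_f = 0.5,
                                              var_gca_m = 0.1, var_sca = 0.05),
                                seed = 4)
  obs <- mean_level_obs(tr, var_e = 1, n_obs = 8, seed = 5)
  fems <- unique(d$female); mals <- unique(d$male)
  If <- diag(length(fems)); dimnames(If) <- list(fems, fems)
  Im <- diag(length(mals)); dimnames(Im) <- list(mals, mals)
  vals <- data.frame(female = d$female, male = d$male, y = obs$blup,
                     n_obs = obs$n_obs)
  fit <- fit_gca_sca_means(vals, If, Im)
  vals_t <- data.frame(female = d$male, male = d$female, y = obs$blup,
                       n_obs = obs$n_obs)
  fit_t <- fit_gca_sca_means(vals_t, Im, If)
  expect_equal(unname(fit$theta["gca_f"]), unname(fit_t$theta["gca_m"]),
               tolerance = 1e-5)
  expect_equal(unname(fit$theta["gca_m"]), unname(fit_t$theta["gca_f"]),
               tolerance = 1e-5)
  expect_equal(fit$u$gca_f, fit_t$u$gca_m, tolerance = 1e-5)
})

test_that("kinship propagates GCA to untested full sibs more than to unrelated lines", {
  # untested female that is a near-full-sib of tested females gets a larger
  # |GCA| than one unrelated to everything, on average over seeds
  n_rep <- 12
  diffs <- vapply(seq_len(n_rep), function(s) {
    ids <- c(sprintf("t%02d", 1:8), "sib", "stranger")
    G <- diag(10) * 0.4 + 0.6
    G[10, ] <- G[, 10] <- 0      # stranger unrelated
    G[10, 10] <- 1
    dimnames(G) <- list(ids, ids)
    mals <- sprintf("m%02d", 1:6)
    Im <- diag(6); dimnames(Im) <- list(mals, mals)
    set.seed(s)
    L <- t(chol(G * 0.4))
    f_true <- drop(L %*% rnorm(10))
    m_true <- rnorm(6, 0, sqrt(0.3))
    d <- expand.grid(female = ids[1:8], male = mals, stringsAsFactors = FALSE)
    vals <- data.frame(female = d$female, male = d$male,
                       y = f_true[match(d$female, ids)] +
                         m_true[match(d$male, mals)] + rnorm(nrow(d), 0, 0.5),
                       n_obs = 1)
    fit <- fit_gca_sca_means(vals, G, Im, theta = c(0.4, 0.3, 1e-10, 0.25),
                             include_sca = FALSE)
    abs(fit$u$gca_f["sib"]) - abs(fit$u$gca_f["stranger"])
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.7)
})

test_that("GCA standard errors fall as parents appear in more crosses", {
  # designs with k crosses per female: PEV-based SE(GCA) strictly decreasing
  mals <- sprintf("m%02d", 1:12)
  fems <- sprintf("f%02d", 1:4)
  If <- diag(4); dimnames(If) <- list(fems, fems)
  Im <- diag(12); dimnames(Im) <- list(mals, mals)
  mean_se <- vapply(c(1, 3, 6, 9), function(k) {
    d <- data.frame(female = rep(fems, each = k),
                    male = mals[((seq_len(4 * k) - 1) %% 12) + 1])
    set.seed(k)
    vals <- data.frame(female = d$female, male = d$male,
                       y = rnorm(nrow(d)), n_obs = 5)
    fit <- fit_gca_sca_means(vals, If, Im, theta = c(0.4, 0.3, 1e-10, 1),
                             include_sca = FALSE)
    mean(sqrt(prediction_error_variance(fit, "gca_f", fems)))
  }, numeric(1))
  expect_true(all(diff(mean_se) < 0))

  # duplicating every record strictly decreases the SEs
  w <- small_world()
  d <- w$design[1:30, ]
  vals <- data.frame(female = d$female, male = d$male,
                     y = rnorm(30), n_obs = 4)
  fit1 <- fit_gca_sca_means(vals, w$G_f, w$G_m,
                            theta = c(0.3, 0.3, 0.05, 1))
  vals2 <- vals; vals2$n_obs <- 8     # twice the information per cross
  fit2 <- fit_gca_sca_means(vals2, w$G_f, w$G_m,
                            theta = c(0.3, 0.3, 0.05, 1))
  ids <- unique(d$female)
  expect_true(all(prediction_error_variance(fit2, "gca_f", ids) <
                    prediction_error_variance(fit1, "gca_f", ids)))
})

test_that("gca_se_profile groups parents by representation", {
  ca <- ca_trial(seed = 9)
  prof <- gca_se_profile(ca$fit)
  expect_true(all(c("gca_f", "gca_m", "sca") %in% prof$term))
  expect_true(all(prof$mean_se > 0))
  # parents with zero crosses have SE at most the prior SD (shrinkage bound)
  zero_rows <- prof[prof$n_crosses == 0 & prof$term == "gca_f", ]
  if (nrow(zero_rows)) {
    expect_lte(zero_rows$mean_se[1],
               sqrt(ca$fit$theta[["gca_f"]]) + 1e-8)
  }
})
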