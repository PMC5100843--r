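# a small fitted combining-ability model on genomic kinships, shared here
pred_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      w <- small_world()
      tr <- simulate_genetic_values(w$design, "mvn",
                                    kinships = list(G_f = w$G_f, G_m = w$G_m,
                                                    S = w$S), seed = 31)
      obs <- mean_level_obs(tr, var_e = 1.5, n_obs = 9, seed = 32)
      vals <- data.frame(female = w$design$female, male = w$design$male,
                         y = obs$blup, n_obs = obs$n_obs)
      cache <<- list(world = w, truth = tr, vals = vals,
                     fit = fit_gca_sca_means(vals, w$G_f, w$G_m))
    }
    cache
  }
})

test_that("method 1a/1b predictions are the stated effect sums", {
  pf <- pred_fit()
  fit <- pf$fit
  crosses <- pf$world$design[1:10, ]
  p1a <- predict_1a(fit, crosses)
  p1b <- predict_1b(fit, crosses)
  mu <- unname(fit$beta["(Intercept)"])
  expect_equal(p1a$prediction,
               mu + unname(fit$u$gca_f[crosses$female]) +
                 unname(fit$u$gca_m[crosses$male]), tolerance = 1e-12)
  cid <- paste(crosses$female, crosses$male, sep = "/")
  expect_equal(p1b$prediction, p1a$prediction + unname(fit$u$sca[cid]),
               tolerance = 1e-12)
  expect_equal(unique(p1a$method), "1a")
  # duplicate pairs rejected
  expect_error(predict_1a(fit, crosses[c(1, 1), ]), "duplicate")
  expect_error(predict_1a(fit, data.frame(female = "ghost", male = crosses$male[1])),
               "unknown parent")
})

test_that("arithmetic example: mu 8.0, f 0.3, m -0.1, s 0.05", {
  # assembled directly from a stub fit object
  fit <- structure(list(
    beta = c(`(Intercept)` = 8.0),
    u = list(gca_f = c(F1 = 0.3), gca_m = c(M1 = -0.1), sca = c(`F1/M1` = 0.05)),
    G_f = matrix(1, 1, 1, dimnames = list("F1", "F1")),
    G_m = matrix(1, 1, 1, dimnames = list("M1", "M1")),
    S = matrix(1, 1, 1, dimnames = list("F1/M1", "F1/M1")),
    crosses = data.frame(female = "F1", male = "M1")),
    class = c("ca_fit", "reml_fit"))
  cr <- data.frame(female = "F1", male = "M1")
  expect_equal(predict_1a(fit, cr)$prediction, 8.2)
  expect_equal(predict_1b(fit, cr)$prediction, 8.25)
})

test_that("SCA propagation to unobserved crosses matches the dense conditional mean", {
  pf <- pred_fit()
  fit <- pf$fit
  w <- pf$world
  # build an unobserved cross list from parents present in the kinships
  all_pairs <- expand.grid(female = rownames(w$G_f), male = rownames(w$G_m),
                           stringsAsFactors = FALSE)
  obs_ids <- names(fit$u$sca)
  unobs <- all_pairs[!paste(all_pairs$female, all_pairs$male, sep = "/") %in%
                       obs_ids, ][1:15, ]
  s_hat <- predict_sca(fit, unobs)
  # dense oracle: S_uo S_oo^-1 s_o
  obs_f <- sub("/.*", "", obs_ids); obs_m <- sub(".*/", "", obs_ids)
  Suo <- w$G_f[unobs$female, obs_f] * w$G_m[unobs$male, obs_m]
  Soo <- w$G_f[obs_f, obs_f] * w$G_m[obs_m, obs_m]
  oracle <- drop(Suo %*% solve(Soo + diag(1e-10, length(obs_ids)), fit$u$sca))
  expect_equal(unname(s_hat), unname(oracle), tolerance = 1e-6)
  # observed crosses return their fitted BLUPs unchanged
  expect_equal(predict_sca(fit, w$design[3:5, ]),
               fit$u$sca[paste(w$design$female, w$design$male, sep = "/")[3:5]])
})

test_that("hybrid covariance elements follow the covariance element formulas", {
  G_f <- matrix(c(1, 0.8, 0.8, 1), 2, dimnames = list(c("f1", "f2"), c("f1", "f2")))
  G_m <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(c("m1", "m2"), c("m1", "m2")))
  comps <- c(gca_f = 0.22, gca_m = 0.20, sca = 0.05, sigma2_e = 1.5)
  tested <- data.frame(female = c("f1", "f2"), male = c("m1", "m2"),
                       n_obs = c(15, 10))
  untested <- data.frame(female = "f1", male = "m2")
  cv2b <- build_hybrid_covariances(G_f, G_m, comps, tested, untested,
                                   include_sca = TRUE)
  # off-diagonal: 0.8*0.22 + 0.5*0.20 + 0.4*0.05 = 0.296
  expect_equal(unname(cv2b$C_tt["f1/m1", "f2/m2"]), 0.296, tolerance = 1e-12)
  # diagonal adds sigma2_e / n_obs = 0.1
  expect_equal(unname(cv2b$C_tt["f1/m1", "f1/m1"]),
               0.22 + 0.20 + 0.05 + 1.5 / 15, tolerance = 1e-12)
  expect_equal(unname(cv2b$C_ut["f1/m2", "f2/m2"]),
               0.8 * 0.22 + 1 * 0.20 + 0.8 * 0.05, tolerance = 1e-12)
  expect_equal(cv2b$method, "2b")
  # 2a drops every SCA contribution
  cv2a <- build_hybrid_covariances(G_f, G_m, comps, tested, untested)
  expect_equal(unname(cv2a$C_tt["f1/m1", "f2/m2"]),
               0.8 * 0.22 + 0.5 * 0.20, tolerance = 1e-12)
  expect_equal(cv2a$method, "2a")
  # averaged mode replaces both GCA variances by their mean
  cvm <- build_hybrid_covariances(G_f, G_m, comps, tested, untested,
                                  variance_mode = "averaged")
  expect_equal(unname(cvm$C_tt["f1/m1", "f2/m2"]),
               0.8 * 0.21 + 0.5 * 0.21, tolerance = 1e-12)
  expect_equal(cvm$method, "2a-mod")
  # equal GCA variances make averaged and separate modes identical
  comps_eq <- c(gca_f = 0.21, gca_m = 0.21, sca = 0.05, sigma2_e = 1.5)
  a <- build_hybrid_covariances(G_f, G_m, comps_eq, tested, untested)
  b <- build_hybrid_covariances(G_f, G_m, comps_eq, tested, untested,
                                variance_mode = "averaged")
  expect_identical(a$C_tt, b$C_tt)
  expect_identical(a$C_ut, b$C_ut)
  # guards
  expect_error(build_hybrid_covariances(G_f + c(0, 0.1, 0, 0), G_m, comps,
                                        tested, untested), "symmetric")
  expect_error(build_hybrid_covariances(G_f, G_m, comps,
                                        transform(tested, n_obs = 0), untested),
               "n_obs")
})

test_that("covariance projection reproduces scalar and dense-oracle cases", {
  # scalar case: C_ut 0.2, C_tt 0.5, y_t - mu = 1 -> prediction mu + 0.4
  cov <- list(C_ut = matrix(0.2, 1, 1, dimnames = list("u", "t")),
              C_tt = matrix(0.5, 1, 1, dimnames = list("t", "t")),
              method = "2a",
              tested = data.frame(female = "ft", male = "mt"),
              untested = data.frame(female = "fu", male = "mu"))
  p <- predict_2(cov, y_t = 3.0, mu = 2.0)
  expect_equal(p$prediction, 2.0 + 0.4, tolerance = 1e-12)

  # zero covariance to every tested cross: prediction = mu
  cov0 <- cov; cov0$C_ut[] <- 0
  expect_equal(predict_2(cov0, y_t = 3.0, mu = 2.0)$prediction, 2.0)

  # 5 tested + 2 untested toy instance vs generic GLS/BLUP dense algebra
  set.seed(41)
  G_f <- crossprod(matrix(rnorm(49), 7)) / 7 + diag(7) * 0.3
  G_f <- G_f / mean(diag(G_f))
  G_m <- crossprod(matrix(rnorm(49), 7)) / 7 + diag(7) * 0.3
  G_m <- G_m / mean(diag(G_m))
  dimnames(G_f) <- list(sprintf("f%d", 1:7), sprintf("f%d", 1:7))
  dimnames(G_m) <- list(sprintf("m%d", 1:7), sprintf("m%d", 1:7))
  tested <- data.frame(female = sprintf("f%d", 1:5), male = sprintf("m%d", 1:5),
                       n_obs = c(3, 5, 4, 6, 2))
  untested <- data.frame(female = sprintf("f%d", 6:7), male = sprintf("m%d", 6:7))
  comps <- c(gca_f = 0.4, gca_m = 0.3, sca = 0.1, sigma2_e = 1.2)
  cov <- build_hybrid_covariances(G_f, G_m, comps, tested, untested,
                                  include_sca = TRUE)
  y_t <- c(1.2, -0.5, 0.3, 2.0, -1.1)
  mu <- 0.4
  p <- predict_2(cov, y_t, mu = mu)
  oracle <- mu + cov$C_ut %*% solve(cov$C_tt, y_t - mu)
  expect_equal(p$prediction, drop(oracle), tolerance = 1e-8, ignore_attr = TRUE)
  # permutation of tested crosses leaves predictions unchanged
  perm <- c(4, 2, 5, 1, 3)
  cov_p <- build_hybrid_covariances(G_f, G_m, comps, tested[perm, ], untested,
                                    include_sca = TRUE)
  expect_equal(predict_2(cov_p, y_t[perm], mu = mu)$prediction, p$prediction,
               tolerance = 1e-10)
})

test_that("method identities hold exactly", {
  pf <- pred_fit()
  w <- pf$world
  tested <- cbind(w$design[1:40, c("female", "male")], n_obs = 9)
  untested <- w$design[41:60, c("female", "male")]
  y_t <- pf$vals$y[1:40]
  comps0 <- c(gca_f = 0.25, gca_m = 0.22, sca = 0, sigma2_e = 1.5)
  # sca = 0: 2a and 2b agree entry-wise
  a <- predict_2(build_hybrid_covariances(w$G_f, w$G_m, comps0, tested,
                                          untested, include_sca = FALSE), y_t)
  b <- predict_2(build_hybrid_covariances(w$G_f, w$G_m, comps0, tested,
                                          untested, include_sca = TRUE), y_t)
  expect_equal(a$prediction, b$prediction, tolerance = 1e-10)
  # equal GCA variances: modified == original
  comps_eq <- c(gca_f = 0.2, gca_m = 0.2, sca = 0.05, sigma2_e = 1.5)
  for (sca_flag in c(FALSE, TRUE)) {
    orig <- predict_2(build_hybrid_covariances(w$G_f, w$G_m, comps_eq, tested,
                                               untested, include_sca = sca_flag),
                      y_t)
    mod <- predict_2(build_hybrid_covariances(w$G_f, w$G_m, comps_eq, tested,
                                              untested, include_sca = sca_flag,
                                              variance_mode = "averaged"), y_t)
    expect_equal(orig$prediction, mod$prediction, tolerance = 1e-10)
  }
  # sca variance ~0 in the fit: 1a == 1b
  fit0 <- fit_gca_sca_means(pf$vals, w$G_f, w$G_m,
                            theta = c(0.25, 0.22, 1e-12, 1.5))
  p1a <- predict_1a(fit0, untested)
  p1b <- predict_1b(fit0, untested)
  expect_equal(p1a$prediction, p1b$prediction, tolerance = 1e-6)
})

test_that("factorial prediction enumerates every parent pair", {
  pf <- pred_fit()
  fac <- predict_factorial(pf$fit, method = "1b", top_k = 20)
  n_f <- nrow(pf$world$G_f); n_m <- nrow(pf$world$G_m)
  expect_equal(nrow(fac$predictions), n_f * n_m)
  expect_equal(nrow(fac$top), 20)
  expect_true(all(diff(fac$top$prediction) <= 0))
  expect_lte(fac$n_tested_in_top, 20)
  # single pair
  fac1 <- predict_factorial(pf$fit, females = rownames(pf$world$G_f)[1],
                            males = rownames(pf$world$G_m)[1], method = "1a")
  expect_equal(nrow(fac1$predictions), 1)
  # rank correlation with the generating truth is positive
  tr <- pf$truth
  ids <- rownames(tr)
  pred_ids <- paste(fac$predictions$female, fac$predictions$male, sep = "/")
  common <- intersect(ids, pred_ids)
  expect_gt(cor(fac$predictions$prediction[match(common, pred_ids)],
                tr[common, "g"], method = "spearman"), 0.2)
})

test_that("methods 1a and 2a agree closely when parents are well tested", {
  # T2-like setting: predictions from the two method families correlate
  # strongly (comparable-accuracy regime), over several seeds
  w <- small_world()
  cors <- vapply(1:10, function(s) {
    tr <- simulate_genetic_values(w$design, "mvn",
                                  kinships = list(G_f = w$G_f, G_m = w$G_m,
                                                  S = w$S), seed = 200 + s)
    obs <- mean_level_obs(tr, var_e = 1.5, n_obs = 9, seed = 300 + s)
    vals <- data.frame(female = w$design$female, male = w$design$male,
                       y = obs$blup, n_obs = obs$n_obs)
    tested <- cbind(w$design[1:60, c("female", "male")], n_obs = 9)
    untested <- w$design[61:72, c("female", "male")]
    comps <- c(gca_f = 0.22, gca_m = 0.20, sca = 0.05, sigma2_e = 1.5)
    fit <- fit_gca_sca_means(vals[1:60, ], w$G_f, w$G_m, theta = comps)
    p1 <- predict_1a(fit, untested)$prediction
    p2 <- predict_2(build_hybrid_covariances(w$G_f, w$G_m, comps, tested,
                                             untested), vals$y[1:60],
                    mu = unname(fit$beta["(Intercept)"]))$prediction
    cor(p1, p2)
  }, numeric(1))
  expect_gt(mean(cors), 0.9)
})
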