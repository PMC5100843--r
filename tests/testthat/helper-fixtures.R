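# Shared fixtures, built in code at test time.

# small population + kinships + design, cached per session
small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- genome_spec(n_chromosomes = 3, chr_length = 120, n_markers = 400, seed = 2)
      pop <- simulate_population(g, sss_sizes = c(6L, 10L, 4L),
                                 nss_sizes = c(10L, 12L, 10L), seed = 3)
      gq <- apply_marker_filters(pop$genotypes, pop$group, verbose = FALSE)
      G_f <- additive_similarity(gq, pop$group, "F")
      G_m <- additive_similarity(gq, pop$group, "M")
      design <- build_cross_design(pop, crosses_per_family = matrix(8, 3, 3), seed = 4)
      S <- dominance_relationship(G_f, G_m, design)
      cache <<- list(pop = pop, geno = gq, G_f = G_f, G_m = G_m,
                     design = design, S = S)
    }
    cache
  }
})

# full-size design over abstract parent ids with identity kinships
table1_identity_bundle <- function(seed = 1, var_e = 3.2, n_obs = 14, H2 = 0.58,
                                   comps = c(gca_f = 0.22, gca_m = 0.20,
                                             sca = 0.05, sigma2_e = 3.2)) {
  d <- build_cross_design(crosses_per_family = "table1", seed = seed)
  tr <- simulate_genetic_values(d, "mvn", seed = seed)
  set.seed(derive_seed(seed, "helper-noise"))
  yt <- tr$g + rnorm(nrow(d), 0, sqrt(var_e / n_obs))
  blups <- data.frame(hybrid = rownames(tr), blup = yt, n_obs = n_obs)
  fems <- unique(d$female); mals <- unique(d$male)
  G_f <- diag(length(fems)); dimnames(G_f) <- list(fems, fems)
  G_m <- diag(length(mals)); dimnames(G_m) <- list(mals, mals)
  make_cv_bundle(d, blups, G_f = G_f, G_m = G_m, components = comps, H2 = H2)
}

# entry-mean level observed values from a truth record (two-stage emulation)
mean_level_obs <- function(truth, var_e = 3.2, n_obs = 14, seed = 1) {
  set.seed(derive_seed(seed, "mean-obs"))
  data.frame(hybrid = rownames(truth),
             blup = truth$g + rnorm(nrow(truth), 0, sqrt(var_e / n_obs)),
             n_obs = n_obs)
}

# tiny toy mixed-model data with one kinship term
toy_mixed <- function(n_levels = 5, reps = 4, theta = c(1, 0.8), seed = 1) {
  set.seed(seed)
  A <- crossprod(matrix(rnorm(n_levels^2), n_levels))
  A <- A / mean(diag(A))
  lv <- sprintf("L%02d", seq_len(n_levels))
  dimnames(A) <- list(lv, lv)
  fac <- rep(lv, each = reps)
  n <- length(fac)
  L <- t(chol(A * theta[1]))
  u <- drop(L %*% rnorm(n_levels))
  x <- rnorm(n)
  y <- 2 + 0.5 * x + u[match(fac, lv)] + rnorm(n, 0, sqrt(theta[2]))
  list(y = y, X = cbind(`(Intercept)` = 1, x = x), fac = fac, K = A, u = u)
}

# dense-algebra restricted log-likelihood oracle (explicit V, eigendecomposition)
dense_reml_oracle <- function(y, X, Zlist, Klist, theta) {
  n <- length(y)
  V <- diag(theta[length(theta)], n)
  for (c in seq_along(Zlist)) {
    V <- V + theta[c] * Zlist[[c]] %*% Klist[[c]] %*% t(Zlist[[c]])
  }
  eV <- eigen((V + t(V)) / 2, symmetric = TRUE)
  Vi <- eV$vectors %*% (t(eV$vectors) / eV$values)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX, t(X) %*% Vi)
  -0.5 * (sum(log(eV$values)) + determinant(XtViX)$modulus[1] +
            drop(t(y) %*% P %*% y))
}

# full-size world: study-scale population, QC'd kinships, table1 design,
# cached per session (used by combining-ability, evaluation and acceptance)
big_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      pop <- simulate_population(seed = 42)
      gq <- apply_marker_filters(pop$genotypes, pop$group, verbose = FALSE)
      G_f <- additive_similarity(gq, pop$group, "F")
      G_m <- additive_similarity(gq, pop$group, "M")
      design <- build_cross_design(pop, "table1", seed = 42)
      S <- dominance_relationship(G_f, G_m, design)
      cache <<- list(pop = pop, G_f = G_f, G_m = G_m, design = design, S = S)
    }
    cache
  }
})

# one simulated entry-mean dataset on the big world's kinships
big_world_dataset <- function(w, seed, truth = c(gca_f = 0.22, gca_m = 0.20,
                                                 sca = 0.05, sigma2_e = 1.0),
                              mu = 8.67) {
  tr <- simulate_genetic_values(
    w$design, "mvn",
    params = list(mu = mu, var_gca_f = truth[["gca_f"]],
                  var_gca_m = truth[["gca_m"]], var_sca = truth[["sca"]]),
    kinships = list(G_f = w$G_f, G_m = w$G_m, S = w$S), seed = seed)
  set.seed(derive_seed(seed, "dataset-noise"))
  nobs <- pmax(rbinom(nrow(w$design), 15, 0.94), 5)
  vals <- data.frame(female = w$design$female, male = w$design$male,
                     y = tr$g + rnorm(nrow(w$design),
                                      0, sqrt(truth[["sigma2_e"]] / nobs)),
                     n_obs = nobs)
  list(truth_record = tr, values = vals)
}
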