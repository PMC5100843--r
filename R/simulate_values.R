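#' Trait presets for the generator
#'
#' Combining-ability variances are the reference values used throughout for grain
#' yield, plant height and staygreen; the grand mean is the trait's
#' whole-population mean. The G x E and residual variances are chosen so
#' that, at the default field design (5 environments x 3 replicates, ~6%
#' plot dropout), the entry-mean heritability lands at the trait's
#' whole-population value (0.58 / 0.89 / 0.81).
#'
#' @param trait one of "gy" (grain yield, Mt/ha), "ph" (plant height, cm),
#'   "sg" (staygreen, 1-10 rating).
#' @return named list of generator parameters: `mu`, `var_gca_f`,
#'   `var_gca_m`, `var_sca`, `var_gxe`, `var_block`, `var_e`.
#' @export
trait_preset <- function(trait = c("gy", "ph", "sg")) {
  trait <- match.arg(trait)
  switch(trait,
    gy = list(mu = 8.67, var_gca_f = 0.22, var_gca_m = 0.20, var_sca = 0.05,
              var_gxe = 0.45, var_block = 0.15, var_e = 3.2),
    ph = list(mu = 210.1, var_gca_f = 28.66, var_gca_m = 34.48, var_sca = 2.6,
              var_gxe = 12, var_block = 6, var_e = 62),
    sg = list(mu = 6.79, var_gca_f = 0.12, var_gca_m = 0.23, var_sca = 0.01,
              var_gxe = 0.12, var_block = 0.05, var_e = 0.67))
}

# draw MVN(0, K * s2) via eigendecomposition with PSD jitter tolerance
.rmvn_kinship <- function(n_draws = 1, K, s2, jitter_tol = 1e-6) {
  q <- nrow(K)
  if (s2 == 0) return(matrix(0, q, n_draws))
  eg <- eigen((K + t(K)) / 2, symmetric = TRUE)
  lam <- eg$values
  if (min(lam) < -jitter_tol * max(abs(lam))) {
    stop("kinship matrix is not positive semidefinite beyond jitter tolerance (min eigenvalue ",
         signif(min(lam), 3), ")")
  }
  lam[lam < 0] <- 0
  L <- eg$vectors %*% (sqrt(lam * s2) * t(eg$vectors))
  L %*% matrix(rnorm(q * n_draws), q, n_draws)
}

#' Simulate true combining-ability values for a cross design
#'
#' Two generating modes. `"mvn"` draws GCA effects of females
#' f ~ MVN(0, G_f * var_gca_f), of males m ~ MVN(0, G_m * var_gca_m) and SCA
#' effects s ~ MVN(0, S * var_sca) — the distributional assumptions of the
#' combining-ability model. `"qtl"` assigns additive and dominance effects
#' to marker loci, scores every hybrid's genotypic value from its parents'
#' genotypes, and decomposes it into GCA/SCA by marginal means over the
#' realized design.
#'
#' @param design a [build_cross_design()] result.
#' @param mode "mvn" or "qtl".
#' @param params generator parameters ([trait_preset()] or a compatible
#'   list); `mu`, `var_gca_f`, `var_gca_m`, `var_sca` are used.
#' @param kinships list with `G_f`, `G_m` and optionally `S`
#'   (for `mode = "mvn"`); defaults to identity matrices over the design's
#'   parents. `S` defaults to the element-wise product implied by `G_f`,`G_m`.
#' @param genotypes inbred genotype matrix (for `mode = "qtl"`).
#' @param n_qtl,dominance_ratio QTL mode: number of causal loci and the
#'   ratio of dominance-to-additive effect scale.
#' @param seed integer seed.
#' @return A `truth_record`: data.frame (one row per cross) with `female`,
#'   `male`, `sc_family`, `f`, `m`, `s`, `g` (= mu + f + m + s); attributes
#'   `mu`, `params`, `f_by_parent`, `m_by_parent`.
#' @export
simulate_genetic_values <- function(design, mode = c("mvn", "qtl"),
                                    params = trait_preset("gy"),
                                    kinships = NULL, genotypes = NULL,
                                    n_qtl = 100, dominance_ratio = 0.5,
                                    seed = 1L) {
  mode <- match.arg(mode)
  assert_nonneg(c(params$var_gca_f, params$var_gca_m, params$var_sca), "variances")
  fem <- unique(design$female); mal <- unique(design$male)
  set.seed(derive_seed(seed, paste0("genetic-values-", mode)))
  if (mode == "mvn") {
    G_f <- kinships$G_f %||% diag(length(fem))
    G_m <- kinships$G_m %||% diag(length(mal))
    if (is.null(dimnames(G_f))) dimnames(G_f) <- list(fem, fem)
    if (is.null(dimnames(G_m))) dimnames(G_m) <- list(mal, mal)
    fem <- rownames(G_f); mal <- rownames(G_m)
    stopifnot(all(design$female %in% fem), all(design$male %in% mal))
    f <- setNames(drop(.rmvn_kinship(1, G_f, params$var_gca_f)), fem)
    m <- setNames(drop(.rmvn_kinship(1, G_m, params$var_gca_m)), mal)
    S <- kinships$S
    if (is.null(S)) {
      S <- G_f[design$female, design$female] * G_m[design$male, design$male]
    }
    s <- setNames(drop(.rmvn_kinship(1, S, params$var_sca)), cross_ids(design))
  } else {
    stopifnot(!is.null(genotypes))
    stopifnot(all(c(design$female, design$male) %in% rownames(genotypes)))
    M <- ncol(genotypes)
    qtl <- sample.int(M, min(n_qtl, M))
    a_eff <- rnorm(length(qtl)) * sqrt(params$var_gca_f + params$var_gca_m) / sqrt(length(qtl))
    d_eff <- abs(rnorm(length(qtl))) * dominance_ratio *
      sqrt(params$var_sca * 4) / sqrt(length(qtl))
    gf <- genotypes[design$female, qtl, drop = FALSE]
    gm <- genotypes[design$male, qtl, drop = FALSE]
    hyb_dose <- (gf + gm) / 2                  # 0, 1, 2 alternate-allele dose
    het <- (gf != gm) * 1
    g_raw <- drop((hyb_dose - 1) %*% a_eff + het %*% d_eff)
    names(g_raw) <- cross_ids(design)
    # decompose into GCA/SCA by marginal means over the realized design
    mu_dev <- mean(g_raw)
    f_all <- tapply(g_raw - mu_dev, design$female, mean)
    m_all <- tapply(g_raw - mu_dev, design$male, mean)
    f <- setNames(as.vector(f_all)[match(fem, names(f_all))], fem)
    m <- setNames(as.vector(m_all)[match(mal, names(m_all))], mal)
    s <- g_raw - mu_dev - f[design$female] - m[design$male]
    names(s) <- cross_ids(design)
  }
  out <- data.frame(
    female = design$female, male = design$male, sc_family = design$sc_family,
    f = as.vector(f[design$female]), m = as.vector(m[design$male]),
    s = as.vector(s[cross_ids(design)]),
    stringsAsFactors = FALSE)
  out$g <- params$mu + out$f + out$m + out$s
  rownames(out) <- cross_ids(design)
  structure(out, mu = params$mu, params = params,
            f_by_parent = f, m_by_parent = m,
            class = c("truth_record", "data.frame"))
}
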