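#' Predict hybrids from parental GCA (method 1a)
#'
#' y_hat = mu_hat + f_hat_i + m_hat_j. Parents with no performance data are
#' covered through their kinship-propagated GCA BLUPs in the fit.
#'
#' @param fit a `ca_fit` from [fit_gca_sca()] or [fit_gca_sca_means()].
#' @param crosses data.frame with `female`, `male` (no duplicate pairs).
#' @return data.frame `female`, `male`, `method`, `prediction`.
#' @export
predict_1a <- function(fit, crosses) {
  .predict_gca(fit, crosses, include_sca = FALSE)
}

#' Predict hybrids from parental GCA plus cross SCA (method 1b)
#'
#' y_hat = mu_hat + f_hat_i + m_hat_j + s_hat_ij, with SCA BLUPs of
#' unobserved crosses propagated through the dominance relationship matrix.
#'
#' @inheritParams predict_1a
#' @return data.frame `female`, `male`, `method`, `prediction`.
#' @export
predict_1b <- function(fit, crosses) {
  .predict_gca(fit, crosses, include_sca = TRUE)
}

.predict_gca <- function(fit, crosses, include_sca) {
  stopifnot(inherits(fit, "ca_fit"))
  if (anyDuplicated(paste(crosses$female, crosses$male))) {
    stop("duplicate (female, male) pairs in cross list")
  }
  bad_f <- setdiff(unique(crosses$female), names(fit$u$gca_f))
  bad_m <- setdiff(unique(crosses$male), names(fit$u$gca_m))
  if (length(bad_f) || length(bad_m)) {
    stop("unknown parent id(s): ", paste(c(bad_f, bad_m), collapse = ", "))
  }
  mu <- unname(fit$beta["(Intercept)"])
  pred <- mu + unname(fit$u$gca_f[crosses$female]) + unname(fit$u$gca_m[crosses$male])
  if (include_sca) pred <- pred + unname(predict_sca(fit, crosses))
  data.frame(female = crosses$female, male = crosses$male,
             method = if (include_sca) "1b" else "1a",
             prediction = pred, stringsAsFactors = FALSE)
}

#' Build the covariance matrices of the single-cross prediction methods
#'
#' For crosses (i x j) and (i' x j'), the genetic covariance used by the
#' covariance methods is (G_f)_ii' s2F + (G_m)_jj' s2M, plus
#' (G_f)_ii' (G_m)_jj' s2SCA when SCA is included (method 2b). Diagonals of
#' the tested-by-tested block add sigma2_Xbar = sigma2_e / n_obs for each
#' tested cross. The modified ("averaged") variants replace both s2F and
#' s2M by their average in every additive term.
#'
#' @param G_f,G_m additive relationship matrices.
#' @param components named vector with `gca_f`, `gca_m`, `sca`, `sigma2_e`.
#' @param tested data.frame `female`, `male`, `n_obs` of tested crosses.
#' @param untested data.frame `female`, `male` of crosses to predict.
#' @param include_sca include the dominance term (method 2b / 2b-mod).
#' @param variance_mode `"separate"` (2a/2b) or `"averaged"` (modified).
#' @return list with `C_ut`, `C_tt`, `method` tag, plus the input frames.
#' @export
build_hybrid_covariances <- function(G_f, G_m, components, tested, untested,
                                     include_sca = FALSE,
                                     variance_mode = c("separate", "averaged")) {
  variance_mode <- match.arg(variance_mode)
  if (max(abs(G_f - t(G_f))) > 1e-8 || max(abs(G_m - t(G_m))) > 1e-8) {
    stop("G_f and G_m must be symmetric")
  }
  need <- c("gca_f", "gca_m", "sca", "sigma2_e")
  stopifnot(all(need %in% names(components)))
  assert_nonneg(unlist(components[need]), "components")
  if (is.null(tested$n_obs) || any(tested$n_obs < 1)) {
    stop("tested crosses need n_obs >= 1")
  }
  s2F <- components[["gca_f"]]; s2M <- components[["gca_m"]]
  if (variance_mode == "averaged") s2F <- s2M <- (s2F + s2M) / 2
  s2S <- components[["sca"]]
  cov_block <- function(fa, ma, fb, mb) {
    out <- G_f[fa, fb, drop = FALSE] * s2F + G_m[ma, mb, drop = FALSE] * s2M
    if (include_sca) {
      out <- out + G_f[fa, fb, drop = FALSE] * G_m[ma, mb, drop = FALSE] * s2S
    }
    out
  }
  C_tt <- cov_block(tested$female, tested$male, tested$female, tested$male)
  diag(C_tt) <- diag(C_tt) + components[["sigma2_e"]] / tested$n_obs
  C_ut <- cov_block(untested$female, untested$male, tested$female, tested$male)
  tid <- paste(tested$female, tested$male, sep = "/")
  uid <- paste(untested$female, untested$male, sep = "/")
  dimnames(C_tt) <- list(tid, tid); dimnames(C_ut) <- list(uid, tid)
  method <- paste0(if (include_sca) "2b" else "2a",
                   if (variance_mode == "averaged") "-mod" else "")
  list(C_ut = C_ut, C_tt = C_tt, method = method,
       tested = tested, untested = untested)
}

#' Predict untested crosses by covariance projection (methods 2a/2b)
#'
#' y_hat_u = mu_hat + C_ut C_tt^-1 (y_t - mu_hat): the tested single-cross
#' BLUPs are centered by the grand mean, projected through the covariance
#' matrices, and the mean is added back. `center = FALSE` projects the raw
#' y_t (and reports C_ut C_tt^-1 y_t).
#'
#' @param cov a [build_hybrid_covariances()] result.
#' @param y_t tested single-cross values, aligned with `cov$tested` (vector,
#'   or a [hybrid_blups()] frame matched by "female/male" id).
#' @param mu grand mean used for centering; default `mean(y_t)`.
#' @param center center y_t by `mu` before projection.
#' @param jitter diagonal jitter added to C_tt if its Cholesky fails.
#' @return data.frame `female`, `male`, `method`, `prediction`.
#' @export
predict_2 <- function(cov, y_t, mu = NULL, center = TRUE, jitter = 1e-8) {
  if (is.data.frame(y_t)) {
    tid <- rownames(cov$C_tt)
    pos <- match(tid, y_t$hybrid)
    if (anyNA(pos)) stop("y_t does not cover all tested crosses")
    y_t <- y_t$blup[pos]
  }
  stopifnot(length(y_t) == nrow(cov$C_tt))
  mu <- mu %||% mean(y_t)
  rhs <- if (center) y_t - mu else y_t
  ch <- tryCatch(chol(cov$C_tt), error = function(e) NULL)
  if (is.null(ch)) {
    ch <- tryCatch(chol(cov$C_tt + diag(jitter, nrow(cov$C_tt))),
                   error = function(e) stop("C_tt is singular even after ",
                                            jitter, " jitter"))
    log_msg("C_tt jittered by ", jitter, " for inversion")
  }
  w <- backsolve(ch, backsolve(ch, rhs, transpose = TRUE))
  pred <- drop(cov$C_ut %*% w) + if (center) mu else 0
  data.frame(female = cov$untested$female, male = cov$untested$male,
             method = cov$method, prediction = unname(pred),
             stringsAsFactors = FALSE)
}

#' All-pairs factorial prediction
#'
#' Predicts every female x male combination with method 1a or 1b (46 x 171
#' parents in the default design gives 7866 crosses) and reports the top-k
#' crosses together with how many of them were actually tested.
#'
#' @param fit a `ca_fit`.
#' @param females,males parent id vectors; default all parents in the fit.
#' @param method "1a" or "1b".
#' @param top_k size of the ranked report (default 100).
#' @param chunk crosses per block for the SCA propagation.
#' @return list with `predictions` (data.frame over all pairs), `top`
#'   (top-k rows, ranked), `n_tested_in_top`.
#' @export
predict_factorial <- function(fit, females = NULL, males = NULL,
                              method = c("1a", "1b"), top_k = 100, chunk = 2000) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "ca_fit"))
  females <- females %||% names(fit$u$gca_f)
  males <- males %||% names(fit$u$gca_m)
  grid <- expand.grid(female = females, male = males,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mu <- unname(fit$beta["(Intercept)"])
  pred <- mu + unname(fit$u$gca_f[grid$female]) + unname(fit$u$gca_m[grid$male])
  if (method == "1b") pred <- pred + unname(predict_sca(fit, grid, chunk = chunk))
  out <- data.frame(female = grid$female, male = grid$male, method = method,
                    prediction = pred, stringsAsFactors = FALSE)
  ord <- order(out$prediction, decreasing = TRUE)
  top <- out[ord[seq_len(min(top_k, nrow(out)))], , drop = FALSE]
  tested_ids <- paste(fit$crosses$female, fit$crosses$male, sep = "/")
  n_tested <- sum(paste(top$female, top$male, sep = "/") %in% tested_ids)
  list(predictions = out, top = top, n_tested_in_top = n_tested)
}
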