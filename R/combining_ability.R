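#' Fit the combining-ability model with genomic covariances (stage 2)
#'
#' y = mu + f_i + m_j + s_ij + e_k + r_l(k) + b_q(kl) + (fe)_ik + (me)_jk +
#' (se)_ijk + eps, with f ~ MVN(0, G_f sigma2_GCA_F), m ~ MVN(0, G_m
#' sigma2_GCA_M), s ~ MVN(0, S sigma2_SCA). Environment and replicate are
#' fixed. Parents present in G_f / G_m but absent from the records are
#' carried as zero-record levels, so their GCA BLUPs are borrowed through
#' kinship. Interaction terms use the Kronecker product of the relationship
#' matrix with an identity over environments; `reduced = TRUE` drops them
#' (recommended for small synthetic designs, where they are weakly
#' identified and dominate the fitting cost).
#'
#' @param records plot records with `hybrid` (= "female/male"), `female`,
#'   `male`, `env`, `rep`, `iblock`, `y`.
#' @param G_f,G_m additive relationship matrices (dimnames = parent ids;
#'   may contain untested parents).
#' @param S optional dominance matrix over crosses ("female/male" ids); when
#'   supplied it is validated against the G_f/G_m element products; by
#'   default it is constructed from them.
#' @param reduced drop the (fe), (me), (se) interaction terms.
#' @param drop_blocks drop the incomplete-block term (for block-free data).
#' @param tol,max_iter passed to [fit_reml()].
#' @return a `ca_fit`: `reml_fit` plus `G_f`, `G_m`, `S`, `crosses`, and
#'   named components in `theta` (`gca_f`, `gca_m`, `sca`, ...).
#' @export
fit_gca_sca <- function(records, G_f, G_m, S = NULL, reduced = FALSE,
                        drop_blocks = FALSE, tol = 1e-8, max_iter = 200) {
  req <- c("female", "male", "env", "rep", "y")
  if (!all(req %in% names(records))) stop("records need columns ", paste(req, collapse = ", "))
  records <- records[!is.na(records$y), , drop = FALSE]
  miss <- setdiff(unique(records$female), rownames(G_f))
  if (length(miss)) stop("record females missing from G_f: ", paste(head(miss, 5), collapse = ", "))
  miss <- setdiff(unique(records$male), rownames(G_m))
  if (length(miss)) stop("record males missing from G_m: ", paste(head(miss, 5), collapse = ", "))
  crosses <- unique(records[, c("female", "male")])
  cid <- paste(crosses$female, crosses$male, sep = "/")
  S_check <- G_f[crosses$female, crosses$female, drop = FALSE] *
    G_m[crosses$male, crosses$male, drop = FALSE]
  dimnames(S_check) <- list(cid, cid)
  if (is.null(S)) {
    S <- S_check
  } else {
    if (!all(cid %in% rownames(S))) stop("S does not cover all observed crosses")
    if (max(abs(S[cid, cid] - S_check)) > 1e-8) {
      stop("S is inconsistent with the element-wise products of G_f and G_m")
    }
    S <- S[cid, cid, drop = FALSE]
  }
  rec_cid <- paste(records$female, records$male, sep = "/")
  one_env <- length(unique(records$env)) == 1
  rand <- list(
    random_term("gca_f", records$female, K = G_f),
    random_term("gca_m", records$male, K = G_m),
    random_term("sca", rec_cid, K = S))
  if (!reduced && !one_env) {
    envs <- sort(unique(records$env))
    kron_env <- function(K) {
      Ke <- kronecker(diag(length(envs)), K)
      lv <- as.vector(outer(rownames(K), envs, paste, sep = ":"))
      dimnames(Ke) <- list(lv, lv)
      Ke
    }
    rand <- c(rand, list(
      random_term("fe", paste(records$female, records$env, sep = ":"), K = kron_env(G_f)),
      random_term("me", paste(records$male, records$env, sep = ":"), K = kron_env(G_m)),
      random_term("se", paste(rec_cid, records$env, sep = ":"), K = kron_env(S))))
  }
  if (!drop_blocks && "iblock" %in% names(records) &&
      length(unique(records$iblock)) > 1) {
    rand <- c(rand, list(random_term("block", records$iblock)))
  }
  fixed <- if (one_env && length(unique(records$rep)) == 1) ~ 1 else
    if (one_env) ~ rep else ~ env + rep
  spec <- mixed_model_spec(records$y, fixed = fixed, data = records, random = rand)
  fit <- fit_reml(spec, tol = tol, max_iter = max_iter)
  fit$G_f <- G_f; fit$G_m <- G_m; fit$S <- S
  fit$crosses <- crosses
  fit$records <- records
  class(fit) <- c("ca_fit", class(fit))
  fit
}

#' Fit the combining-ability model to entry means (fast path)
#'
#' Weighted two-stage analogue of [fit_gca_sca()]: the response is one value
#' per hybrid (e.g. a weighted mean over plots or a stage-1 BLUP) with
#' residual variance sigma2_e / n_obs per hybrid. Used for repeated fits
#' inside cross-validation and simulation studies.
#'
#' @param values data.frame with `female`, `male`, `y`, `n_obs`.
#' @param G_f,G_m,S as in [fit_gca_sca()].
#' @param theta optional fixed components `c(gca_f, gca_m, sca, sigma2_e)`;
#'   when supplied, solves the MME without REML iteration.
#' @param include_sca include the SCA term.
#' @return a `ca_fit`.
#' @export
fit_gca_sca_means <- function(values, G_f, G_m, S = NULL, theta = NULL,
                              include_sca = TRUE) {
  cid <- paste(values$female, values$male, sep = "/")
  if (is.null(S) && include_sca) {
    S <- G_f[values$female, values$female, drop = FALSE] *
      G_m[values$male, values$male, drop = FALSE]
    dimnames(S) <- list(cid, cid)
  }
  rand <- list(random_term("gca_f", values$female, K = G_f),
               random_term("gca_m", values$male, K = G_m))
  if (include_sca) rand <- c(rand, list(random_term("sca", cid, K = S)))
  spec <- mixed_model_spec(values$y, fixed = NULL, random = rand,
                           weights = values$n_obs %||% rep(1, nrow(values)))
  if (!is.null(theta) && !include_sca && length(theta) == 4) {
    theta <- theta[-3]          # drop the sca slot when the term is absent
  }
  fit <- if (is.null(theta)) fit_reml(spec) else mme_fit(spec, theta)
  fit$G_f <- G_f; fit$G_m <- G_m; fit$S <- S
  fit$crosses <- values[, c("female", "male")]
  class(fit) <- c("ca_fit", class(fit))
  fit
}

#' SCA-to-GCA variance ratio
#'
#' sigma2_SCA / (sigma2_GCA_F + sigma2_GCA_M), the reported measure of the
#' relative weight of specific combining ability.
#'
#' @param fit a `ca_fit`, or a named numeric vector with `gca_f`, `gca_m`,
#'   `sca`.
#' @param digits rounding for reporting (default 2); `NULL` for no rounding.
#' @return scalar ratio.
#' @export
sca_ratio <- function(fit, digits = 2) {
  th <- if (inherits(fit, "reml_fit")) fit$theta else fit
  need <- c("gca_f", "gca_m", "sca")
  if (!all(need %in% names(th))) stop("need components gca_f, gca_m, sca")
  den <- th[["gca_f"]] + th[["gca_m"]]
  if (den <= 0) stop("zero GCA variance: ratio undefined")
  r <- th[["sca"]] / den
  if (is.null(digits)) r else round(r, digits)
}

#' SCA BLUPs for unobserved crosses by kinship propagation
#'
#' For crosses with no records, the SCA BLUP is the conditional prior mean
#' given the observed crosses' BLUPs: s_u = S_uo S_oo^-1 s_o, with S
#' entries built on demand from G_f and G_m (the all-pairs matrix is never
#' materialized; rows are processed in chunks).
#'
#' @param fit a `ca_fit`.
#' @param crosses data.frame with `female`, `male` of the target crosses.
#' @param chunk rows per chunk.
#' @return named vector of SCA BLUPs ("female/male" ids).
#' @export
predict_sca <- function(fit, crosses, chunk = 2000) {
  stopifnot(inherits(fit, "ca_fit"))
  s_o <- fit$u$sca
  obs <- names(s_o)
  cid <- paste(crosses$female, crosses$male, sep = "/")
  out <- setNames(numeric(length(cid)), cid)
  known <- cid %in% obs
  out[known] <- s_o[cid[known]]
  todo <- which(!known)
  if (length(todo)) {
    # S_oo^-1 s_o computed once
    ch <- chol(fit$S[obs, obs] + diag(1e-10, length(obs)))
    w <- backsolve(ch, backsolve(ch, s_o, transpose = TRUE))
    obs_f <- sub("/.*", "", obs); obs_m <- sub(".*/", "", obs)
    for (start in seq(1, length(todo), by = chunk)) {
      idx <- todo[start:min(start + chunk - 1, length(todo))]
      Suo <- fit$G_f[crosses$female[idx], obs_f, drop = FALSE] *
        fit$G_m[crosses$male[idx], obs_m, drop = FALSE]
      out[idx] <- drop(Suo %*% w)
    }
  }
  out
}

#' Standard errors of GCA/SCA predictions versus parent representation
#'
#' Groups parents by the number of single-cross combinations they appear in
#' within the fitted data and reports the mean SE (square root of the
#' prediction-error variance) of their GCA BLUPs per group, plus the mean
#' SE of SCA BLUPs grouped by the smaller of the two parents' counts. SEs
#' decrease as a parent is represented in more crosses.
#'
#' @param fit a `ca_fit` with stored crosses.
#' @return data.frame: `term` ("gca_f"/"gca_m"/"sca"), `n_crosses`,
#'   `n_levels`, `mean_se`.
#' @export
gca_se_profile <- function(fit) {
  stopifnot(inherits(fit, "ca_fit"))
  crosses <- fit$crosses
  fc <- table(crosses$female); mc <- table(crosses$male)
  count_of <- function(ids, tab) {
    n <- as.integer(tab[ids]); n[is.na(n)] <- 0L; n
  }
  rows <- list()
  for (tm in c("gca_f", "gca_m")) {
    ids <- names(fit$u[[tm]])
    cnt <- count_of(ids, if (tm == "gca_f") fc else mc)
    se <- sqrt(prediction_error_variance(fit, tm, ids))
    agg <- aggregate(se, list(n_crosses = cnt), mean)
    rows[[tm]] <- data.frame(term = tm, n_crosses = agg$n_crosses,
                             n_levels = as.vector(table(cnt)[as.character(agg$n_crosses)]),
                             mean_se = agg$x, stringsAsFactors = FALSE)
  }
  if ("sca" %in% names(fit$u)) {
    ids <- names(fit$u$sca)
    cnt <- pmin(count_of(sub("/.*", "", ids), fc), count_of(sub(".*/", "", ids), mc))
    se <- sqrt(prediction_error_variance(fit, "sca", ids))
    agg <- aggregate(se, list(n_crosses = cnt), mean)
    rows$sca <- data.frame(term = "sca", n_crosses = agg$n_crosses,
                           n_levels = as.vector(table(cnt)[as.character(agg$n_crosses)]),
                           mean_se = agg$x, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
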