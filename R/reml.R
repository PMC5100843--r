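#' Define a random term with an optional covariance matrix over its levels
#'
#' @param name term label.
#' @param levels_vec character vector, one level per record.
#' @param K covariance (relationship) matrix over levels, with dimnames.
#'   `NULL` means identity over the observed levels. Levels present in `K`
#'   but absent from the data are carried as zero-record levels, so their
#'   BLUPs are propagated purely through the covariance (e.g. untested
#'   parents).
#' @return a `random_term` list.
#' @export
random_term <- function(name, levels_vec, K = NULL) {
  levels_vec <- as.character(levels_vec)
  if (anyNA(levels_vec)) stop("random term '", name, "' has missing levels")
  if (!is.null(K)) {
    if (is.null(rownames(K))) stop("K for term '", name, "' needs dimnames")
    if (max(abs(K - t(K))) > 1e-8) stop("K for term '", name, "' is not symmetric")
    missing_lv <- setdiff(unique(levels_vec), rownames(K))
    if (length(missing_lv)) {
      stop("levels of term '", name, "' missing from K: ",
           paste(head(missing_lv, 5), collapse = ", "))
    }
  }
  structure(list(name = name, levels_vec = levels_vec, K = K),
            class = "random_term")
}

# inverse + log-determinant of a covariance matrix, with jitter escalation
.k_inverse <- function(K, name) {
  Ks <- (K + t(K)) / 2
  for (jit in c(0, 1e-8, 1e-6, 1e-4)) {
    Kj <- Ks + diag(jit * mean(diag(Ks)), nrow(Ks))
    ch <- tryCatch(chol(Kj), error = function(e) NULL)
    if (!is.null(ch)) {
      if (jit > 0) log_msg("term '", name, "': covariance jittered by ", jit,
                           " * mean(diag) for inversion")
      return(list(inv = chol2inv(ch), logdet = 2 * sum(log(diag(ch)))))
    }
  }
  stop("covariance of term '", name, "' is singular beyond jitter tolerance")
}

#' Assemble a mixed-model specification
#'
#' Linear mixed model y = X b + sum_c Z_c u_c + e with u_c ~ N(0, theta_c
#' K_c) and e ~ N(0, sigma2_e * diag(1/weights)). Fixed effects are given as
#' a formula over `data` (aliased columns dropped automatically) or as a
#' design matrix.
#'
#' @param y numeric response.
#' @param fixed formula (e.g. `~ env + rep`) or design matrix; `NULL` means
#'   intercept only.
#' @param data data.frame for the formula interface.
#' @param random list of [random_term()]s.
#' @param weights positive per-record residual weights (residual variance of
#'   record r is sigma2_e / weights\[r\]); default 1.
#' @return a `mixed_model_spec` with precomputed cross-products.
#' @export
mixed_model_spec <- function(y, fixed = NULL, data = NULL, random = list(),
                             weights = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (anyNA(y)) stop("response contains missing values")
  if (is.null(fixed)) {
    X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else if (inherits(fixed, "formula")) {
    X <- model.matrix(fixed, data)
  } else {
    X <- as.matrix(fixed)
  }
  if (nrow(X) != n) stop("fixed design and response lengths differ")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  weights <- weights %||% rep(1, n)
  if (any(weights <= 0) || length(weights) != n) stop("weights must be positive, length n")

  terms <- lapply(random, function(t) {
    stopifnot(inherits(t, "random_term"))
    if (length(t$levels_vec) != n) stop("term '", t$name, "' has wrong length")
    lv <- if (is.null(t$K)) sort(unique(t$levels_vec)) else rownames(t$K)
    Z <- Matrix::sparseMatrix(i = seq_len(n), j = match(t$levels_vec, lv),
                              x = 1, dims = c(n, length(lv)))
    if (is.null(t$K)) {
      kin <- list(inv = NULL, logdet = 0)       # identity
    } else {
      kin <- .k_inverse(t$K[lv, lv, drop = FALSE], t$name)
    }
    list(name = t$name, levels = lv, Z = Z, Kinv = kin$inv, logdetK = kin$logdet)
  })
  q_each <- vapply(terms, function(t) length(t$levels), integer(1))
  Zall <- if (length(terms)) do.call(cbind, lapply(terms, `[[`, "Z")) else
    Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0), dims = c(n, 0))
  W <- weights
  Xw <- X * W
  XtWX <- crossprod(X, Xw)
  XtWZ <- as.matrix(Matrix::crossprod(Xw, Zall))
  ZtWZ <- as.matrix(Matrix::crossprod(Zall, Zall * W))
  XtWy <- crossprod(Xw, y)
  ZtWy <- as.matrix(Matrix::crossprod(Zall, W * y))
  structure(list(
    y = y, X = X, n = n, p = ncol(X), terms = terms, q_each = q_each,
    weights = W, sum_log_w = sum(log(W)),
    XtWX = XtWX, XtWZ = XtWZ, ZtWZ = ZtWZ, XtWy = XtWy, ZtWy = ZtWy,
    ytWy = sum(y * W * y)
  ), class = "mixed_model_spec")
}

# Build and factor the MME coefficient matrix C0 (residual-variance-free
# scaling: R^{-1} = diag(w), G^{-1} = blockdiag(Kinv_c / gamma_c) with
# gamma_c = theta_c / sigma2_e). Returns chol factor, solutions and y'P0y.
.mme_solve <- function(spec, gamma) {
  p <- spec$p
  q <- sum(spec$q_each)
  C <- matrix(0, p + q, p + q)
  C[1:p, 1:p] <- spec$XtWX
  if (q) {
    C[1:p, p + 1:q] <- spec$XtWZ
    C[p + 1:q, 1:p] <- t(spec$XtWZ)
    C[p + 1:q, p + 1:q] <- spec$ZtWZ
    off <- p
    for (c in seq_along(spec$terms)) {
      qc <- spec$q_each[c]
      idx <- off + 1:qc
      if (is.null(spec$terms[[c]]$Kinv)) {
        C[cbind(idx, idx)] <- C[cbind(idx, idx)] + 1 / gamma[c]
      } else {
        C[idx, idx] <- C[idx, idx] + spec$terms[[c]]$Kinv / gamma[c]
      }
      off <- off + qc
    }
  }
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ch)) {
    kap <- tryCatch(kappa(C, exact = FALSE), error = function(e) NA_real_)
    stop("MME coefficient matrix is singular (condition number ~ ",
         signif(kap, 3), ")")
  }
  rhs <- c(spec$XtWy, spec$ZtWy)
  sol <- backsolve(ch, backsolve(ch, rhs, transpose = TRUE))
  yPy <- spec$ytWy - sum(sol * rhs)
  list(chol = ch, sol = sol, yPy = yPy, logdetC = 2 * sum(log(diag(ch))))
}

# -2 * restricted log-likelihood at full theta = (theta_1..theta_k, sigma2_e)
.minus2_reml <- function(theta, spec) {
  k <- length(spec$terms)
  stopifnot(length(theta) == k + 1)
  s2e <- theta[k + 1]
  gamma <- if (k) theta[1:k] / s2e else numeric(0)
  ms <- .mme_solve(spec, gamma)
  # log|V| + log|X'V^-1X| + y'Py with V = s2e*(W^-1 + Z Gamma Z'):
  #   = (n - p) log s2e - sum(log w) + sum_c(q_c log gamma_c + logdet K_c)
  #     + log|C0| + y'P0y / s2e
  ld <- (spec$n - spec$p) * log(s2e) - spec$sum_log_w + ms$logdetC
  if (k) ld <- ld + sum(spec$q_each * log(gamma)) +
      sum(vapply(spec$terms, `[[`, numeric(1), "logdetK"))
  ld + ms$yPy / s2e
}

#' Restricted log-likelihood of a variance-component vector
#'
#' Computes l_R(theta) = -1/2 (log|V| + log|X' V^-1 X| + y' P y) with
#' V = sum_c theta_c Z_c K_c Z_c' + sigma2_e diag(1/w), evaluated through
#' the mixed-model equations (no n x n matrix is formed).
#'
#' @param theta numeric vector: one variance per random term, in order,
#'   followed by the residual variance.
#' @param spec a [mixed_model_spec()].
#' @return scalar restricted log-likelihood.
#' @export
restricted_loglik <- function(theta, spec) {
  stopifnot(inherits(spec, "mixed_model_spec"))
  if (any(!is.finite(theta)) || any(theta[-length(theta)] < 0) ||
      theta[length(theta)] <= 0) {
    stop("theta must be non-negative with positive residual variance")
  }
  k <- length(spec$terms)
  if (k && any(theta[1:k] == 0)) {
    # exact-zero components: drop them from V (limit of the objective)
    keep <- which(theta[1:k] > 0)
    spec0 <- .drop_terms(spec, keep)
    return(unname(-0.5 * .minus2_reml(c(theta[keep], theta[k + 1]), spec0)))
  }
  unname(-0.5 * .minus2_reml(theta, spec))
}

# subset a spec to a subset of random terms (recompute index blocks only)
.drop_terms <- function(spec, keep) {
  off <- cumsum(c(0, spec$q_each))
  cols <- unlist(lapply(keep, function(c) off[c] + 1:spec$q_each[c]))
  spec2 <- spec
  spec2$terms <- spec$terms[keep]
  spec2$q_each <- spec$q_each[keep]
  spec2$XtWZ <- spec$XtWZ[, cols, drop = FALSE]
  spec2$ZtWZ <- spec$ZtWZ[cols, cols, drop = FALSE]
  spec2$ZtWy <- spec$ZtWy[cols, , drop = FALSE]
  spec2
}

#' Fit a mixed model by REML
#'
#' Maximizes the restricted log-likelihood over variance components using a
#' bounded quasi-Newton search on log variance ratios (theta_c / sigma2_e),
#' with the residual variance profiled out analytically. Components are
#' bounded below (ratio >= 1e-8); estimates at the bound are reported with a
#' boundary flag, not an error. BLUEs and BLUPs are the mixed-model-equation
#' solutions at the optimum.
#'
#' @param spec a [mixed_model_spec()].
#' @param tol relative-change convergence tolerance on the objective
#'   (default 1e-8).
#' @param max_iter maximum optimizer iterations.
#' @param init optional starting variances (length = #terms + 1).
#' @return a `reml_fit`: list with `theta` (named variances incl.
#'   `sigma2_e`), `beta` (fixed effects), `u` (list of named BLUP vectors
#'   per term), `loglik`, `trace` (objective per evaluation, best-so-far),
#'   `converged`, `boundary` (per-component flags), and internals for
#'   prediction-error variances.
#' @export
fit_reml <- function(spec, tol = 1e-8, max_iter = 200, init = NULL) {
  stopifnot(inherits(spec, "mixed_model_spec"))
  k <- length(spec$terms)
  if (spec$n < spec$p + 2) stop("need at least rank(X) + 2 records")
  vy <- var(spec$y)
  if (k == 0) {
    gamma_hat <- numeric(0)
  } else {
    g0 <- if (is.null(init)) rep(0.5, k) else pmax(init[1:k] / init[k + 1], 1e-6)
    eval_log <- new.env(); eval_log$vals <- numeric(0)
    obj <- function(lg) {
      gamma <- exp(lg)
      ms <- .mme_solve(spec, gamma)
      s2e <- ms$yPy / (spec$n - spec$p)
      v <- (spec$n - spec$p) * (log(s2e) + 1) - spec$sum_log_w + ms$logdetC +
        sum(spec$q_each * log(gamma)) +
        sum(vapply(spec$terms, `[[`, numeric(1), "logdetK"))
      eval_log$vals <- c(eval_log$vals, v)
      v
    }
    lb <- rep(log(1e-8), k); ub <- rep(log(1e8), k)
    opt <- optim(log(g0), obj, method = "L-BFGS-B", lower = lb, upper = ub,
                 control = list(maxit = max_iter, factr = tol / .Machine$double.eps))
    if (opt$convergence != 0 && opt$convergence != 52) {
      stop("REML did not converge (optim code ", opt$convergence, "): ",
           opt$message, "; trace length ", length(eval_log$vals))
    }
    gamma_hat <- exp(opt$par)
  }
  ms <- .mme_solve(spec, gamma_hat)
  s2e <- ms$yPy / (spec$n - spec$p)
  theta <- c(gamma_hat * s2e, s2e)
  names(theta) <- c(vapply(spec$terms, `[[`, character(1), "name"), "sigma2_e")
  boundary <- if (k) gamma_hat <= 1e-8 * 1.0001 else logical(0)
  if (any(boundary)) {
    log_msg("REML: component(s) at lower boundary: ",
            paste(names(theta)[which(boundary)], collapse = ", "))
  }
  beta <- setNames(ms$sol[seq_len(spec$p)], colnames(spec$X))
  u <- list(); off <- spec$p
  for (c in seq_along(spec$terms)) {
    qc <- spec$q_each[c]
    u[[spec$terms[[c]]$name]] <- setNames(ms$sol[off + 1:qc], spec$terms[[c]]$levels)
    off <- off + qc
  }
  trace <- if (k) cummin(eval_log$vals) * -0.5 else numeric(0)  # best-so-far loglik
  structure(list(
    theta = theta, beta = beta, u = u,
    loglik = restricted_loglik(theta, spec),
    trace = trace,
    converged = TRUE, boundary = setNames(boundary, names(theta)[seq_len(k)]),
    spec = spec, chol = ms$chol, sigma2_e = s2e
  ), class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("REML fit: n =", x$spec$n, " logLik =", format(x$loglik, digits = 6), "\n")
  cat("variance components:\n")
  print(signif(x$theta, 4))
  if (any(x$boundary)) cat("(boundary:", names(which(x$boundary)), ")\n")
  invisible(x)
}

#' Solve the mixed-model equations at fixed variance components
#'
#' BLUE/BLUP solutions (and optionally PEVs) at user-supplied theta, without
#' REML iteration. Used by prediction paths that reuse previously estimated
#' components.
#'
#' @param spec a [mixed_model_spec()].
#' @param theta variances (terms then residual), as in [restricted_loglik()].
#' @return a `reml_fit`-like object (no trace).
#' @export
mme_fit <- function(spec, theta) {
  k <- length(spec$terms)
  stopifnot(length(theta) == k + 1)
  s2e <- theta[k + 1]
  gamma <- if (k) pmax(theta[1:k], 1e-12 * s2e) / s2e else numeric(0)
  ms <- .mme_solve(spec, gamma)
  theta <- c(gamma * s2e, s2e)
  names(theta) <- c(vapply(spec$terms, `[[`, character(1), "name"), "sigma2_e")
  beta <- setNames(ms$sol[seq_len(spec$p)], colnames(spec$X))
  u <- list(); off <- spec$p
  for (c in seq_along(spec$terms)) {
    qc <- spec$q_each[c]
    u[[spec$terms[[c]]$name]] <- setNames(ms$sol[off + 1:qc], spec$terms[[c]]$levels)
    off <- off + qc
  }
  structure(list(theta = theta, beta = beta, u = u,
                 loglik = NA_real_, trace = numeric(0), converged = TRUE,
                 boundary = rep(FALSE, k), spec = spec, chol = ms$chol,
                 sigma2_e = s2e),
            class = "reml_fit")
}

#' Prediction-error variance of BLUPs
#'
#' PEV of the named levels of a random term, from the inverse of the MME
#' coefficient matrix at the fitted components: PEV = sigma2_e *
#' diag(C0^-1) over the term's block. SE(BLUP) = sqrt(PEV). A level with no
#' attached records and identity covariance has PEV equal to its prior
#' variance theta_c.
#'
#' @param fit a [fit_reml()] or [mme_fit()] result.
#' @param term term name.
#' @param level level id(s); default all levels of the term.
#' @return named numeric vector of PEVs.
#' @export
prediction_error_variance <- function(fit, term, level = NULL) {
  stopifnot(inherits(fit, "reml_fit"))
  cn <- vapply(fit$spec$terms, `[[`, character(1), "name")
  c_idx <- match(term, cn)
  if (is.na(c_idx)) stop("unknown random term '", term, "'")
  lv <- fit$spec$terms[[c_idx]]$levels
  level <- level %||% lv
  pos <- match(level, lv)
  if (anyNA(pos)) stop("unknown level(s) of term '", term, "': ",
                       paste(level[is.na(pos)], collapse = ", "))
  off <- fit$spec$p + sum(fit$spec$q_each[seq_len(c_idx - 1)])
  dimC <- nrow(fit$chol)
  out <- vapply(pos, function(j) {
    e <- numeric(dimC); e[off + j] <- 1
    x <- backsolve(fit$chol, backsolve(fit$chol, e, transpose = TRUE))
    x[off + j]
  }, numeric(1))
  setNames(out * fit$sigma2_e, level)
}

#' Likelihood-ratio test of one variance component
#'
#' Boundary-corrected test of H0: theta_c = 0 using the 0.5:0.5 mixture of
#' chi-square(0) and chi-square(1).
#'
#' @param spec a [mixed_model_spec()].
#' @param fit the full-model [fit_reml()] result.
#' @param term name of the component under test.
#' @return list with `lrt` statistic and `p_value`.
#' @export
lrt_component <- function(spec, fit, term) {
  cn <- vapply(spec$terms, `[[`, character(1), "name")
  c_idx <- match(term, cn)
  if (is.na(c_idx)) stop("unknown random term '", term, "'")
  spec0 <- .drop_terms(spec, setdiff(seq_along(spec$terms), c_idx))
  fit0 <- fit_reml(spec0)
  lrt <- max(0, 2 * (fit$loglik - fit0$loglik))
  list(lrt = lrt, p_value = 0.5 * pchisq(lrt, df = 1, lower.tail = FALSE))
}
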