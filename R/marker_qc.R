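#' Apply the marker filtering and imputation rules
#'
#' Steps, in fixed order: (1) heterozygous calls (coded 1) are set to
#' missing; (2) markers with more than `max_missing` missing values are
#' removed; (3) markers with minor allele frequency below `maf` (computed on
#' observed calls, both groups jointly) are removed; (4) markers that are
#' monomorphic within either heterotic group are removed; (5) remaining
#' missing values are replaced by the per-marker mean of observed coded
#' values (naive imputation). Markers entirely missing are removed with a
#' warning at step 2.
#'
#' @param genotypes inbred x marker matrix, values in \{0, 1, 2\} or `NA`.
#' @param group named character vector ("F"/"M") per inbred.
#' @param max_missing maximum per-marker missing fraction (default 0.20).
#' @param maf minimum minor allele frequency (default 0.05).
#' @param verbose log per-step marker counts.
#' @return filtered, imputed matrix (values in \[0, 2\]) with attribute
#'   `qc_log` (named integer vector of markers removed per step).
#' @examples
#' g <- rbind(a = c(0, 0, 2), b = c(2, 1, 2), c = c(0, 2, 0), d = c(2, 2, 0))
#' apply_marker_filters(g, c(a = "F", b = "F", c = "M", d = "M"), verbose = FALSE)
#' @export
apply_marker_filters <- function(genotypes, group, max_missing = 0.20,
                                 maf = 0.05, verbose = TRUE) {
  stopifnot(is.matrix(genotypes))
  # raw calls are 0/1/2/NA; fractional values in [0,2] (mean-imputed output
  # of a previous pass) are accepted unchanged, so filtering is idempotent
  bad <- (genotypes < 0 | genotypes > 2) & !is.na(genotypes)
  if (any(bad)) stop("genotype values must lie in [0,2] or be missing")
  group <- group[rownames(genotypes)]
  stopifnot(!anyNA(group), all(group %in% c("F", "M")))
  x <- genotypes
  x[x == 1] <- NA                                   # heterozygotes -> missing
  log <- c(all_missing = 0L, missingness = 0L, maf = 0L, group_monomorphic = 0L)

  miss <- colMeans(is.na(x))
  allm <- miss >= 1
  if (any(allm)) {
    warning(sum(allm), " marker(s) with all values missing removed")
    log["all_missing"] <- sum(allm)
  }
  drop1 <- miss > max_missing
  log["missingness"] <- sum(drop1 & !allm)
  x <- x[, !drop1, drop = FALSE]

  p <- colMeans(x, na.rm = TRUE) / 2                # alt-allele frequency, observed calls
  drop2 <- pmin(p, 1 - p) < maf
  log["maf"] <- sum(drop2)
  x <- x[, !drop2, drop = FALSE]

  poly_in <- function(g) {
    sub <- x[group == g, , drop = FALSE]
    apply(sub, 2, function(v) length(unique(v[!is.na(v)])) > 1)
  }
  keep <- poly_in("F") & poly_in("M")
  log["group_monomorphic"] <- sum(!keep)
  x <- x[, keep, drop = FALSE]

  cm <- colMeans(x, na.rm = TRUE)
  na_idx <- which(is.na(x), arr.ind = TRUE)
  if (nrow(na_idx)) x[na_idx] <- cm[na_idx[, 2]]
  log_msg("marker QC: ", ncol(genotypes), " -> ", ncol(x), " markers (removed: ",
          paste(names(log), log, sep = "=", collapse = ", "),
          "); MAF computed jointly across groups", verbose = verbose)
  attr(x, "qc_log") <- log
  x
}

#' Additive genomic relationship from simple marker similarity
#'
#' G\[i,j\] = mean over markers of 1 - |x_i - x_j| / 2: the average
#' allele-sharing of two inbreds, 1 for identical lines and 0 for opposite
#' homozygotes at every marker. Computed within one heterotic group at a
#' time; imputed fractional values participate unchanged.
#'
#' @param genotypes imputed inbred x marker matrix (no missing values).
#' @param group optional named group vector; with `which_group` selects the
#'   rows to use. If omitted, all rows are used.
#' @param which_group "F" or "M" when `group` is given.
#' @return symmetric similarity matrix with inbred ids as dimnames.
#' @export
additive_similarity <- function(genotypes, group = NULL, which_group = NULL) {
  if (!is.null(group)) {
    stopifnot(!is.null(which_group))
    genotypes <- genotypes[names(group)[group == which_group], , drop = FALSE]
  }
  if (anyNA(genotypes)) stop("genotypes must be imputed (no missing values)")
  M <- ncol(genotypes)
  if (M == 0) stop("zero markers: cannot compute similarity")
  n <- nrow(genotypes)
  # 1 - |xi - xj|/2 averaged over markers; via cross-products:
  # sum_k |xi - xj| has no bilinear form in general (fractional imputed
  # values), so compute directly but blockwise for memory safety.
  G <- matrix(0, n, n, dimnames = list(rownames(genotypes), rownames(genotypes)))
  for (i in seq_len(n)) {
    d <- abs(sweep(genotypes[i:n, , drop = FALSE], 2, genotypes[i, ]))
    G[i, i:n] <- 1 - rowSums(d) / (2 * M)
    G[i:n, i] <- G[i, i:n]
  }
  G
}

#' Dominance relationship among single crosses
#'
#' For crosses (i x j) and (i' x j'),
#' S\[(ij),(i'j')\] = G_f\[i,i'\] * G_m\[j,j'\]: the product of the parental
#' additive similarities, the classical dominance covariance structure for
#' hybrids of unrelated groups.
#'
#' @param G_f,G_m additive relationship matrices of the female and male
#'   parents (dimnames = parent ids).
#' @param crosses a `cross_design` (or data.frame with `female`, `male`).
#' @return symmetric matrix over crosses (dimnames = "female/male" ids).
#' @export
dominance_relationship <- function(G_f, G_m, crosses) {
  miss_f <- setdiff(unique(crosses$female), rownames(G_f))
  miss_m <- setdiff(unique(crosses$male), rownames(G_m))
  if (length(miss_f) || length(miss_m)) {
    stop("unknown parent id(s) in cross list: ",
         paste(c(miss_f, miss_m), collapse = ", "))
  }
  S <- G_f[crosses$female, crosses$female, drop = FALSE] *
    G_m[crosses$male, crosses$male, drop = FALSE]
  dimnames(S) <- list(paste(crosses$female, crosses$male, sep = "/"),
                      paste(crosses$female, crosses$male, sep = "/"))
  S
}
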