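#' Simulate the six founder inbreds of two heterotic groups
#'
#' Draws three fully homozygous founders per heterotic group (female = SSS
#' analogue, male = NSS analogue). Allele frequencies at each locus are
#' shifted between groups by `divergence`: at `divergence = 0` both groups
#' share one frequency; at `divergence = 1` every locus is fixed for
#' opposite alleles in the two groups. Genotypes are coded 0/2 (counts of
#' the alternate allele in a homozygous diploid).
#'
#' @param genome a [genome_spec()].
#' @param divergence between-group allele-frequency divergence in \[0, 1\].
#' @param n_per_group founders per group (default 3, as in a 3 x 3 SSS/NSS
#'   founder design).
#' @param seed integer seed.
#' @return A `founder_set`: list with `genotypes` (founder x marker matrix,
#'   values 0/2), `group` (named "F"/"M" per founder), `genome`.
#' @export
simulate_founders <- function(genome, divergence = 0.3, n_per_group = 3, seed = 1L) {
  if (!is.numeric(divergence) || length(divergence) != 1L || !is.finite(divergence) ||
      divergence < 0 || divergence > 1) {
    stop("`divergence` must be a single finite value in [0,1]")
  }
  stopifnot(inherits(genome, "genome_spec"), n_per_group >= 1)
  m <- length(genome$marker_ids)
  set.seed(derive_seed(seed, "founders"))
  p0 <- runif(m, 0.15, 0.85)          # shared base frequency per locus
  flip <- rbinom(m, 1, 0.5)           # which group carries the raised allele
  pF <- (1 - divergence) * p0 + divergence * flip
  pM <- (1 - divergence) * p0 + divergence * (1 - flip)
  draw <- function(p, n) {
    g <- matrix(rbinom(n * length(p), 1, rep(p, each = n)) * 2, nrow = n)
    g
  }
  gf <- draw(pF, n_per_group)
  gm <- draw(pM, n_per_group)
  genotypes <- rbind(gf, gm)
  ids <- c(sprintf("F_fnd%d", seq_len(n_per_group)),
           sprintf("M_fnd%d", seq_len(n_per_group)))
  dimnames(genotypes) <- list(ids, genome$marker_ids)
  structure(list(
    genotypes = genotypes,
    group = setNames(rep(c("F", "M"), each = n_per_group), ids),
    genome = genome
  ), class = "founder_set")
}

#' @export
print.founder_set <- function(x, ...) {
  cat("founder_set:", nrow(x$genotypes), "founders x",
      ncol(x$genotypes), "markers\n")
  invisible(x)
}

# one gamete from an F1 between two homozygous parents, as a 0/1 vector of
# "came from parent B" indicators per marker; Haldane model (Poisson
# crossovers, uniform breakpoints, no interference)
.f1_gamete_origin <- function(genome, map_expansion = 1) {
  unlist(lapply(seq_len(genome$n_chromosomes), function(c) {
    pos <- genome$marker_positions[[c]]
    if (!length(pos)) return(integer(0))
    L <- genome$chr_length[c] * map_expansion / 100  # Morgans
    n_co <- rpois(1, L)
    start <- rbinom(1, 1, 0.5)
    if (n_co == 0) return(rep.int(start, length(pos)))
    bp <- sort(runif(n_co, 0, genome$chr_length[c] * map_expansion))
    # phase switches at each breakpoint; marker positions scaled by expansion
    idx <- findInterval(pos * map_expansion, bp)
    (start + idx) %% 2L
  }), use.names = FALSE)
}

#' Simulate a biparental family of homozygous inbred progenies
#'
#' Doubled haploid (DH) progenies are doubled gametes of the F1 between two
#' fully homozygous founders: per chromosome, crossovers are Poisson with
#' mean chr_length/100 (Haldane, no interference) and breakpoints uniform.
#' Recombinant inbred lines (RILs, derived by repeated selfing) are
#' approximated as fully homozygous lines produced by the same mechanism on
#' a two-fold expanded map, reflecting the doubled recombination opportunity
#' of selfing series relative to one meiosis.
#'
#' @param founder_a,founder_b named genotype vectors (values 0/2) over the
#'   genome's markers.
#' @param n_progeny number of progenies.
#' @param line_type "DH" or "RIL".
#' @param genome a [genome_spec()].
#' @param seed integer seed.
#' @param family_id label stored on the progenies.
#' @return matrix (progeny x marker, values 0/2) with attributes
#'   `family_id`, `line_type`.
#' @export
simulate_biparental <- function(founder_a, founder_b, n_progeny, line_type = "DH",
                                genome, seed = 1L, family_id = "fam") {
  stopifnot(inherits(genome, "genome_spec"), n_progeny >= 1)
  line_type <- match.arg(line_type, c("DH", "RIL"))
  m <- length(genome$marker_ids)
  if (length(founder_a) != m || length(founder_b) != m)
    stop("founder genotype length does not match genome marker count")
  if (any(!founder_a %in% c(0, 2)) || any(!founder_b %in% c(0, 2)))
    stop("founders must be fully homozygous (all values in {0,2})")
  if (all(founder_a == founder_b))
    warning("founders are identical at every locus: family will be monomorphic")
  expansion <- if (line_type == "RIL") 2 else 1
  set.seed(derive_seed(seed, paste0("biparental-", family_id)))
  out <- matrix(0, nrow = n_progeny, ncol = m,
                dimnames = list(sprintf("%s_%s%03d", family_id, line_type, seq_len(n_progeny)),
                                genome$marker_ids))
  for (i in seq_len(n_progeny)) {
    origin <- .f1_gamete_origin(genome, expansion)
    out[i, ] <- ifelse(origin == 1L, founder_b, founder_a)
  }
  attr(out, "family_id") <- family_id
  attr(out, "line_type") <- line_type
  out
}

#' Simulate the full two-group inbred-progeny population
#'
#' Builds the three possible biparental crosses within each heterotic group
#' from simulated founders and generates the requested numbers of
#' homozygous progenies per family (a fraction of them RILs, the rest DH).
#'
#' @param genome a [genome_spec()].
#' @param sss_sizes,nss_sizes integer vectors of family sizes; defaults are
#'   the reference design's (8, 36, 2) and (35, 69, 67).
#' @param ril_fraction fraction of progenies per family simulated as RILs
#'   (default 0.1; the rest are DH).
#' @param divergence founder-group divergence passed to [simulate_founders()].
#' @param seed integer seed.
#' @return A `sim_population`: list with `genotypes` (all progenies x
#'   markers), `family` (named biparental-family label per progeny), `group`
#'   (named "F"/"M"), `founders`, `genome`, and `family_founders` (2-column
#'   matrix of founder ids per family).
#' @export
simulate_population <- function(genome = genome_spec(),
                                sss_sizes = c(8L, 36L, 2L),
                                nss_sizes = c(35L, 69L, 67L),
                                ril_fraction = 0.1,
                                divergence = 0.3,
                                seed = 1L) {
  stopifnot(length(sss_sizes) == 3L, length(nss_sizes) == 3L,
            all(sss_sizes >= 1), all(nss_sizes >= 1))
  assert_scalar_prob(ril_fraction, "ril_fraction")
  founders <- simulate_founders(genome, divergence = divergence, seed = seed)
  fnd <- founders$genotypes
  pairs_within <- combn(3, 2)                     # the three possible crosses
  fam_defs <- rbind(
    data.frame(fam = sprintf("SSS%d", 1:3), group = "F",
               a = rownames(fnd)[pairs_within[1, ]],
               b = rownames(fnd)[pairs_within[2, ]],
               n = as.integer(sss_sizes)),
    data.frame(fam = sprintf("NSS%d", 1:3), group = "M",
               a = rownames(fnd)[3 + pairs_within[1, ]],
               b = rownames(fnd)[3 + pairs_within[2, ]],
               n = as.integer(nss_sizes))
  )
  geno_list <- vector("list", nrow(fam_defs))
  fam_lab <- grp_lab <- character(0)
  set.seed(derive_seed(seed, "ril-assignment"))
  for (r in seq_len(nrow(fam_defs))) {
    n <- fam_defs$n[r]
    n_ril <- round(n * ril_fraction)
    types <- c(rep("RIL", n_ril), rep("DH", n - n_ril))
    parts <- list()
    if (n_ril > 0) {
      parts$ril <- simulate_biparental(fnd[fam_defs$a[r], ], fnd[fam_defs$b[r], ],
                                       n_ril, "RIL", genome, seed = seed,
                                       family_id = paste0(fam_defs$fam[r], "r"))
    }
    if (n - n_ril > 0) {
      parts$dh <- simulate_biparental(fnd[fam_defs$a[r], ], fnd[fam_defs$b[r], ],
                                      n - n_ril, "DH", genome, seed = seed,
                                      family_id = fam_defs$fam[r])
    }
    g <- do.call(rbind, parts)
    geno_list[[r]] <- g
    fam_lab <- c(fam_lab, rep(fam_defs$fam[r], n))
    grp_lab <- c(grp_lab, rep(fam_defs$group[r], n))
  }
  genotypes <- do.call(rbind, geno_list)
  structure(list(
    genotypes = genotypes,
    family = setNames(fam_lab, rownames(genotypes)),
    group = setNames(grp_lab, rownames(genotypes)),
    founders = founders,
    genome = genome,
    family_founders = structure(as.matrix(fam_defs[, c("a", "b")]),
                                dimnames = list(fam_defs$fam, c("a", "b")))
  ), class = "sim_population")
}

#' @export
print.sim_population <- function(x, ...) {
  cat("sim_population:", nrow(x$genotypes), "inbred progenies (",
      sum(x$group == "F"), "female-group /", sum(x$group == "M"),
      "male-group ) x", ncol(x$genotypes), "markers\n")
  invisible(x)
}
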