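#' Describe the marker genome used by the simulator
#'
#' A light container for chromosome count, genetic lengths and marker
#' positions. Marker positions are genetic (cM) coordinates; crossovers are
#' simulated under a no-interference (Haldane) model, so only genetic
#' distance matters.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chr_length genetic length per chromosome in cM (recycled to
#'   `n_chromosomes`).
#' @param n_markers total marker count; markers are spread over chromosomes
#'   as evenly as possible and placed uniformly at random along each
#'   chromosome (sorted), unless `marker_positions` is given.
#' @param marker_positions optional list (one numeric vector per chromosome)
#'   of strictly increasing cM positions; overrides `n_markers`.
#' @param seed seed for random marker placement.
#' @return An object of class `genome_spec` with elements `n_chromosomes`,
#'   `chr_length`, `marker_positions` (list), `marker_ids`, `marker_chr`.
#' @examples
#' g <- genome_spec(n_chromosomes = 10, chr_length = 150, n_markers = 2296)
#' length(unlist(g$marker_positions))
#' @export
genome_spec <- function(n_chromosomes = 10, chr_length = 150, n_markers = 2296,
                        marker_positions = NULL, seed = 1L) {
  stopifnot(n_chromosomes >= 1, all(chr_length >= 0))
  chr_length <- rep_len(chr_length, n_chromosomes)
  if (is.null(marker_positions)) {
    stopifnot(n_markers >= 1)
    per_chr <- diff(floor(seq(0, n_markers, length.out = n_chromosomes + 1)))
    # guarantee at least one marker per chromosome when feasible
    while (any(per_chr == 0) && n_markers >= n_chromosomes) {
      i <- which.max(per_chr); j <- which.min(per_chr)
      per_chr[i] <- per_chr[i] - 1L; per_chr[j] <- per_chr[j] + 1L
    }
    old <- .Random.seed_store()
    set.seed(derive_seed(seed, "marker-positions"))
    marker_positions <- lapply(seq_len(n_chromosomes), function(c) {
      if (per_chr[c] == 0) return(numeric(0))
      sort(runif(per_chr[c], 0, chr_length[c]))
    })
    .Random.seed_restore(old)
  }
  stopifnot(length(marker_positions) == n_chromosomes)
  for (c in seq_len(n_chromosomes)) {
    p <- marker_positions[[c]]
    if (length(p) && (is.unsorted(p, strictly = FALSE) || any(p < 0) ||
                      any(p > chr_length[c]))) {
      stop("marker positions must be non-decreasing within [0, chr_length]")
    }
  }
  m <- sum(lengths(marker_positions))
  structure(list(
    n_chromosomes = as.integer(n_chromosomes),
    chr_length = chr_length,
    marker_positions = marker_positions,
    marker_ids = sprintf("M%04d", seq_len(m)),
    marker_chr = rep(seq_len(n_chromosomes), lengths(marker_positions))
  ), class = "genome_spec")
}

#' @export
print.genome_spec <- function(x, ...) {
  cat("genome_spec:", x$n_chromosomes, "chromosomes,",
      length(x$marker_ids), "markers,",
      "total map", sum(x$chr_length), "cM\n")
  invisible(x)
}

# save/restore .Random.seed so spec constructors do not perturb the caller's RNG
.Random.seed_store <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
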