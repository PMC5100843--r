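#' Build a sparse factorial of single crosses between heterotic groups
#'
#' Samples parent pairs (female x male, one from each heterotic group)
#' without duplicates, cell by cell over the 3 x 3 grid of biparental-family
#' combinations. Each cell of the grid defines one single-cross family
#' (f1..f9 analogue). The `"table1"` preset reproduces the reference breeding design:
#' female families of sizes (8, 36, 2), male families of sizes (35, 69, 67),
#' and per-cell cross counts (27, 39, 33, 51, 49, 49, 21, 19, 24) for a
#' total of 312 single crosses.
#'
#' @param population a [simulate_population()] result, or `NULL` to build a
#'   design over abstract ids with `sss_sizes`/`nss_sizes`.
#' @param crosses_per_family either the string `"table1"` or a 3 x 3 numeric
#'   matrix (rows = female families, cols = male families) of cross counts.
#' @param sss_sizes,nss_sizes family sizes used when `population` is `NULL`.
#' @param seed integer seed for the within-cell sampling.
#' @return A `cross_design` data.frame with columns `female`, `male`,
#'   `sc_family`, plus attributes `females`, `males` (all parent ids per
#'   group) and `cell_counts`.
#' @examples
#' d <- build_cross_design(crosses_per_family = "table1", seed = 1)
#' nrow(d)  # 312
#' @export
build_cross_design <- function(population = NULL,
                               crosses_per_family = "table1",
                               sss_sizes = c(8L, 36L, 2L),
                               nss_sizes = c(35L, 69L, 67L),
                               seed = 1L) {
  if (identical(crosses_per_family, "table1")) {
    cells <- matrix(c(27, 39, 33, 51, 49, 49, 21, 19, 24), nrow = 3, byrow = TRUE)
    sss_sizes <- c(8L, 36L, 2L); nss_sizes <- c(35L, 69L, 67L)
  } else {
    cells <- as.matrix(crosses_per_family)
    if (!all(dim(cells) == c(3L, 3L))) stop("`crosses_per_family` must be 3 x 3 or \"table1\"")
  }
  if (!is.null(population)) {
    stopifnot(inherits(population, "sim_population"))
    fam <- population$family
    ffams <- unique(fam[population$group == "F"])
    mfams <- unique(fam[population$group == "M"])
    stopifnot(length(ffams) == 3L, length(mfams) == 3L)
    fem_by_fam <- lapply(ffams, function(f) names(fam)[fam == f])
    mal_by_fam <- lapply(mfams, function(f) names(fam)[fam == f])
  } else {
    fem_by_fam <- lapply(1:3, function(i) sprintf("SSS%d_L%03d", i, seq_len(sss_sizes[i])))
    mal_by_fam <- lapply(1:3, function(j) sprintf("NSS%d_L%03d", j, seq_len(nss_sizes[j])))
  }
  set.seed(derive_seed(seed, "cross-design"))
  rows <- list()
  for (i in 1:3) for (j in 1:3) {
    n_req <- cells[i, j]
    if (n_req == 0) next
    cap <- length(fem_by_fam[[i]]) * length(mal_by_fam[[j]])
    if (n_req > cap) {
      stop(sprintf(
        "infeasible cell (female family %d x male family %d): %d crosses requested, max %d",
        i, j, n_req, cap))
    }
    # sample pair indices without replacement over the full cell grid
    idx <- sample.int(cap, n_req)
    fi <- ((idx - 1L) %% length(fem_by_fam[[i]])) + 1L
    mj <- ((idx - 1L) %/% length(fem_by_fam[[i]])) + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      female = fem_by_fam[[i]][fi],
      male = mal_by_fam[[j]][mj],
      sc_family = sprintf("f%d", (i - 1L) * 3L + j),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  stopifnot(!anyDuplicated(paste(out$female, out$male)))
  structure(out,
            females = unlist(fem_by_fam), males = unlist(mal_by_fam),
            cell_counts = cells,
            class = c("cross_design", "data.frame"))
}

#' Cross ids ("female/male") for a design
#' @param design a `cross_design`.
#' @keywords internal
cross_ids <- function(design) paste(design$female, design$male, sep = "/")

#' Summarize a cross design as the 3 x 3 family table with margins
#' @param design a `cross_design`.
#' @return matrix of per-family cross counts with row/column totals.
#' @export
design_family_table <- function(design) {
  tab <- table(factor(design$sc_family, levels = sprintf("f%d", 1:9)))
  m <- matrix(as.integer(tab), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("F", 1:3), paste0("M", 1:3)))
  cbind(rbind(m, Total = colSums(m)), Total = c(rowSums(m), sum(m)))
}
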