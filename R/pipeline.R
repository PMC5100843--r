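#' Configuration for an end-to-end pipeline run
#'
#' Validated container of every stage's parameters. Unknown keys are
#' rejected so typos fail fast, before any compute.
#'
#' @param ... overrides of the defaults: `seed`, `trait` ("gy"/"ph"/"sg"),
#'   `design_preset` ("table1" or a 3x3 matrix), `n_markers`,
#'   `n_chromosomes`, `chr_length`, `divergence`, `ril_fraction`,
#'   `n_environments`, `n_replicates`, `incomplete_block_size`, `dropout`,
#'   `maf`, `max_missing`, `reduced` (drop G x E interaction terms in model
#'   (2)), `cv_scenarios`, `cv_methods`, `train_size`, `cv_reps`, `boot`,
#'   `top_k`, `out_dir` (NULL = no files written), `verbose`.
#' @return a `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L, trait = "gy", design_preset = "table1",
    n_markers = 2296, n_chromosomes = 10, chr_length = 150,
    divergence = 0.3, ril_fraction = 0.1,
    n_environments = 5, n_replicates = 3, incomplete_block_size = 26,
    dropout = 0.06,
    maf = 0.05, max_missing = 0.20,
    reduced = TRUE,
    cv_scenarios = c("T2", "T0"), cv_methods = "1a",
    train_size = 250, cv_reps = 3, boot = 200,
    top_k = 100, out_dir = NULL, verbose = TRUE)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  assert_scalar_prob(cfg$dropout, "dropout", upper_open = TRUE)
  assert_scalar_prob(cfg$maf, "maf"); assert_scalar_prob(cfg$max_missing, "max_missing")
  stopifnot(cfg$trait %in% c("gy", "ph", "sg"),
            cfg$train_size >= 3, cfg$cv_reps >= 1)
  bad <- setdiff(cfg$cv_methods, cv_methods)
  if (length(bad)) stop("unknown cv method(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(cfg$cv_scenarios, c("T2", "T1F", "T1M", "T0", "family"))
  if (length(bad)) stop("unknown cv scenario(s): ", paste(bad, collapse = ", "))
  structure(cfg, class = "run_config")
}

#' Run the full study pipeline on synthetic data
#'
#' simulate -> marker QC -> kinship -> trial model (1) -> combining-ability
#' model (2) -> factorial prediction -> cross-validation -> report. All
#' stage outputs are returned (and, when `out_dir` is set, persisted as
#' CSV/JSON via atomic writes).
#'
#' @param config a [run_config()].
#' @return a `run_report` list: `config`, `population` sizes, `qc_log`,
#'   `trial` (variance components, heritability), `family_table`,
#'   `combining_ability` (components, SCA ratio), `factorial` (top-k and
#'   tested-in-top count), `cv` (per scenario x method), plus intermediate
#'   objects in `$objects`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  v <- config$verbose
  t0 <- Sys.time()
  stage <- function(name, expr) {
    log_msg("[", name, "] ...", verbose = v)
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  genome <- genome_spec(n_chromosomes = config$n_chromosomes,
                        chr_length = config$chr_length,
                        n_markers = config$n_markers, seed = config$seed)
  pop <- stage("simulate", simulate_population(
    genome, divergence = config$divergence, ril_fraction = config$ril_fraction,
    seed = config$seed))
  design <- stage("design", build_cross_design(
    pop, crosses_per_family = config$design_preset, seed = config$seed))

  geno_qc <- stage("qc", apply_marker_filters(
    pop$genotypes, pop$group, max_missing = config$max_missing,
    maf = config$maf, verbose = v))
  G_f <- stage("kinship", additive_similarity(geno_qc, pop$group, "F"))
  G_m <- additive_similarity(geno_qc, pop$group, "M")
  S <- dominance_relationship(G_f, G_m, design)

  preset <- trait_preset(config$trait)
  truth <- stage("genetic-values", simulate_genetic_values(
    design, mode = "mvn", params = preset,
    kinships = list(G_f = G_f, G_m = G_m, S = S), seed = config$seed))
  # relatedness among parents makes the realized variance among crosses
  # smaller than the marginal sum of the combining-ability variances; scale
  # the noise layers accordingly so the entry-mean heritability stays at the
  # trait's whole-population value under the field design
  noise_scale <- var(truth$g) /
    (preset$var_gca_f + preset$var_gca_m + preset$var_sca)
  field <- field_spec(n_environments = config$n_environments,
                      n_replicates = config$n_replicates,
                      incomplete_block_size = config$incomplete_block_size,
                      var_block = preset$var_block * noise_scale,
                      var_gxe = preset$var_gxe * noise_scale,
                      var_e = preset$var_e * noise_scale,
                      dropout = config$dropout)
  plots <- stage("trials", simulate_trials(truth, field, seed = config$seed))

  tfit <- stage("fit-trial", fit_trial_model(plots))
  blups <- hybrid_blups(tfit)
  herit <- entry_mean_heritability(tfit)

  means_df <- stage("entry-means", {
    agg <- aggregate(plots$y, list(hybrid = plots$hybrid), mean)
    cnt <- table(plots$hybrid)
    data.frame(hybrid = agg$hybrid, blup = agg$x,
               n_obs = as.integer(cnt[agg$hybrid]))
  })

  cafit <- stage("fit-ca", fit_gca_sca(plots, G_f, G_m, S = S,
                                       reduced = config$reduced))
  comps <- c(gca_f = unname(cafit$theta["gca_f"]),
             gca_m = unname(cafit$theta["gca_m"]),
             sca = unname(cafit$theta["sca"]),
             sigma2_e = unname(cafit$theta["sigma2_e"]))

  fac <- stage("factorial", predict_factorial(cafit, method = "1b",
                                              top_k = config$top_k))

  bundle <- make_cv_bundle(design, blups, means = means_df, G_f = G_f,
                           G_m = G_m, components = comps, H2 = herit$H2)
  cv_out <- list()
  for (sc in config$cv_scenarios) for (me in config$cv_methods) {
    key <- paste(sc, me, sep = "_")
    cv_out[[key]] <- stage(paste0("cv-", key), {
      if (sc == "family") {
        run_leave_family_out(bundle, method = me, train_size = config$train_size,
                             reps = config$cv_reps, boot = config$boot,
                             seed = config$seed)
      } else {
        run_loocv(bundle, method = me, scenario = sc,
                  train_size = config$train_size, reps = config$cv_reps,
                  boot = config$boot, seed = config$seed)
      }
    })
  }

  report <- list(
    config = unclass(config),
    population = list(n_inbreds = nrow(pop$genotypes),
                      n_female = sum(pop$group == "F"),
                      n_male = sum(pop$group == "M"),
                      n_crosses = nrow(design),
                      family_table = design_family_table(design)),
    qc_log = attr(geno_qc, "qc_log"),
    n_markers_post_qc = ncol(geno_qc),
    trial = list(components = as.list(tfit$theta), H2 = herit$H2,
                 h_k = herit$h_k, h_t = herit$h_t),
    combining_ability = list(components = as.list(cafit$theta),
                             sca_ratio = sca_ratio(cafit)),
    factorial = list(n_predictions = nrow(fac$predictions),
                     n_tested_in_top = fac$n_tested_in_top,
                     top = fac$top),
    cv = lapply(cv_out, function(x) {
      if (inherits(x, "cv_result")) {
        list(scenario = x$scenario, method = x$method,
             mean_accuracy = x$mean_accuracy, mean_boot_se = x$mean_boot_se,
             n_training_sets = x$n_training_sets)
      } else {
        list(scenario = "family", method = x$method,
             mean_accuracy = unname(x$overall_mean),
             per_family = as.list(x$mean_accuracy))
      }
    }),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    objects = list(population = pop, design = design, G_f = G_f, G_m = G_m,
                   S = S, truth = truth, plots = plots, trial_fit = tfit,
                   blups = blups, ca_fit = cafit, bundle = bundle,
                   factorial = fac, cv = cv_out))
  class(report) <- "run_report"
  if (!is.null(config$out_dir)) write_run_report(report, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run (seed", x$config$seed, ", trait", x$config$trait, ")\n")
  cat(" crosses:", x$population$n_crosses,
      "| markers post-QC:", x$n_markers_post_qc, "\n")
  cat(" H2 =", round(x$trial$H2, 3),
      "| SCA ratio =", x$combining_ability$sca_ratio, "\n")
  for (k in names(x$cv)) {
    cat(sprintf("  CV %-10s mean accuracy %.3f\n", k, x$cv[[k]]$mean_accuracy))
  }
  invisible(x)
}

#' Persist pipeline outputs as CSV/JSON
#'
#' Writes genotypes, cross design, phenotypes, truth, relationship
#' matrices, BLUPs and the JSON report to `out_dir`, each via an atomic
#' temp-file rename. The layouts mirror the roles of a study's deposited
#' supplementary files, so real data can be swapped in path-for-path.
#'
#' @param report a [run_pipeline()] result.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ob <- report$objects
  write_genotype_csv(ob$population$genotypes, file.path(out_dir, "genotypes.csv"))
  atomic_write(function(p) write.csv(ob$design, p, row.names = FALSE),
               file.path(out_dir, "cross_design.csv"))
  atomic_write(function(p) write.csv(ob$plots, p, row.names = FALSE),
               file.path(out_dir, "phenotypes.csv"))
  atomic_write(function(p) write.csv(cbind(hybrid = rownames(ob$truth),
                                           as.data.frame(ob$truth)), p,
                                     row.names = FALSE),
               file.path(out_dir, "truth.csv"))
  write_relationship_csv(ob$G_f, file.path(out_dir, "G_f.csv"))
  write_relationship_csv(ob$G_m, file.path(out_dir, "G_m.csv"))
  write_relationship_csv(ob$S, file.path(out_dir, "S.csv"))
  atomic_write(function(p) write.csv(ob$blups, p, row.names = FALSE),
               file.path(out_dir, "hybrid_blups.csv"))
  payload <- report[setdiff(names(report), "objects")]
  atomic_write(function(p) jsonlite::write_json(payload, p, auto_unbox = TRUE,
                                                digits = NA, pretty = TRUE,
                                                force = TRUE),
               file.path(out_dir, "report.json"))
  invisible(out_dir)
}

#' Write / read a genotype matrix as CSV (rows = inbreds, columns = markers)
#' @param genotypes inbred x marker matrix.
#' @param path file path.
#' @export
write_genotype_csv <- function(genotypes, path) {
  atomic_write(function(p) {
    write.csv(data.frame(id = rownames(genotypes), genotypes,
                         check.names = FALSE), p, row.names = FALSE)
  }, path)
}

#' @rdname write_genotype_csv
#' @export
read_genotype_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write / read a relationship matrix as CSV (header and first column = ids)
#' @param G symmetric relationship matrix with dimnames.
#' @param path file path.
#' @export
write_relationship_csv <- function(G, path) {
  atomic_write(function(p) {
    write.csv(data.frame(id = rownames(G), G, check.names = FALSE), p,
              row.names = FALSE)
  }, path)
}

#' @rdname write_relationship_csv
#' @export
read_relationship_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  stopifnot(identical(rownames(m), colnames(m)))
  m
}

#' Read inbred genotypes from a VCF file
#'
#' Biallelic sites only; diploid GT fields are coded as alternate-allele
#' counts 0/1/2, heterozygous calls are treated as missing (to be handled by
#' [apply_marker_filters()], which also sets code 1 to missing).
#'
#' @param path VCF file (plain text or bgzipped).
#' @return inbred x marker matrix with values 0, 2 or NA.
#' @export
read_genotype_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  biallelic <- !grepl(",", vcfR::getFIX(v)[, "ALT"])
  gt <- vcfR::extract.gt(v[biallelic, ], element = "GT")
  code <- function(x) {
    x <- sub("\\|", "/", x)
    out <- rep(NA_real_, length(x))
    out[x %in% c("0/0", "0")] <- 0
    out[x %in% c("1/1", "1")] <- 2
    out[x %in% c("0/1", "1/0")] <- NA   # het -> missing
    out
  }
  m <- apply(gt, 2, code)
  rownames(m) <- rownames(gt)
  t(m)   # inbreds x markers
}
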