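#' Declarative configuration for the full PGIRS pipeline
#'
#' Bundles every stage parameter and seed so a run is fully reproducible:
#' simulation config, QC thresholds, clumping settings at both the main
#' (`P = 1e-5`) and sensitivity (`P = 0.05`) inclusion thresholds, the
#' covariate recipe, the secondary-trait construction, and the mediation /
#' cross-validation settings.
#'
#' @param sim A [simulation_config()].
#' @param qc A [qc_thresholds()].
#' @param p_thresholds Named numeric of clumping P thresholds; each entry
#'   yields a parallel clump/score/assoc output set.
#' @param window_bp,r2_threshold Clumping window and LD threshold.
#' @param covariates Covariate columns for residualization and association
#'   (an `age_sq` column is derived automatically when `age` is present).
#' @param secondary List: `share_main`, `share_interaction`,
#'   `trait_noise_sd` for the secondary trait.
#' @param mediation List: `n_boot` for the mediation stage.
#' @param cv_k Cross-validation fold count.
#' @param seed Master seed; stage seeds are derived from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            qc = qc_thresholds(),
                            p_thresholds = c(main = 1e-5,
                                             sensitivity = 0.05),
                            window_bp = 250000,
                            r2_threshold = 0.2,
                            covariates = c("age", "sex", "age_sq",
                                           paste0("PC", 1:10)),
                            secondary = list(share_main = 0,
                                             share_interaction = 1,
                                             trait_noise_sd = 1),
                            mediation = list(n_boot = 500),
                            cv_k = 5,
                            seed = sim$seed) {
  stopifnot(inherits(sim, "simulation_config"),
            inherits(qc, "qc_thresholds"))
  if (is.null(names(p_thresholds)) || any(names(p_thresholds) == "")) {
    stop_config("p_thresholds", "must be a named numeric vector")
  }
  structure(list(sim = sim, qc = qc, p_thresholds = p_thresholds,
                 window_bp = window_bp, r2_threshold = r2_threshold,
                 covariates = covariates, secondary = secondary,
                 mediation = mediation, cv_k = cv_k,
                 seed = check_count(seed, "seed", min = 0L)),
            class = "pipeline_config")
}

#' Run the full PGIRS pipeline
#'
#' Executes simulate -> QC -> scan -> clump -> score -> association ->
#' mediation -> cross-validation, writing each stage's outputs as plain TSV
#' under `out_dir` plus a `manifest.json` recording parameters, seeds, row
#' counts, and MD5 checksums of every output. Re-running the same
#' configuration reproduces every file byte-identically. Stage failures
#' halt the run with the stage name.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param verbose Emit stage-tagged progress messages to stderr.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- function(stage, ...) {
    if (verbose) message(sprintf("[%s] %s", stage, paste0(...)))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  manifest <- list(seed = config$seed, stages = list())
  outputs <- character(0)
  record <- function(stage, files, n_rows) {
    manifest$stages[[stage]] <<- list(outputs = basename(files),
                                      n_rows = n_rows)
    outputs <<- c(outputs, files)
  }
  pth <- function(...) file.path(out_dir, ...)
  exp_names <- names(config$sim$exposure_specs)

  ## 1. simulate -------------------------------------------------------
  cohort <- NULL
  run_stage("simulate", {
    log("simulate", sprintf("%d samples x %d SNPs", config$sim$n_samples,
                            config$sim$n_snps))
    cohort <- simulate_cohort(config$sim)
    sec <- simulate_correlated_trait(
      cohort, share_main = config$secondary$share_main,
      share_interaction = config$secondary$share_interaction,
      trait_noise_sd = config$secondary$trait_noise_sd,
      seed = config$seed + 4L)
    cohort$phenotype$secondary_trait <- unname(sec)
    write_cohort(cohort, out_dir)
    record("simulate",
           pth(c("genotypes.tsv", "genotypes.tsv.snps.tsv", "genotypes.vcf",
                 "exposures.tsv", "covariates.tsv", "phenotype.tsv",
                 "true_effects.tsv")),
           config$sim$n_samples)
  })

  ## 2. qc -------------------------------------------------------------
  qc_res <- NULL
  run_stage("qc", {
    qc_res <- apply_qc(cohort$genotypes, config$qc)
    utils::write.table(qc_res$report, pth("qc_report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    log("qc", sprintf("%d/%d SNPs kept", sum(qc_res$report$kept),
                      nrow(qc_res$report)))
    record("qc", pth("qc_report.tsv"), nrow(qc_res$report))
  })

  ## 3. gweis ----------------------------------------------------------
  scan <- NULL
  run_stage("gweis", {
    covs <- cohort$covariates
    if ("age" %in% names(covs) && "age_sq" %in% config$covariates) {
      covs$age_sq <- covs$age^2
    }
    use <- intersect(config$covariates, names(covs))
    y <- stats::setNames(cohort$phenotype$phenotype,
                         cohort$phenotype$sample_id)
    adj <- residualize(y, covs[use])
    scan <- gweis_scan(qc_res$panel, adj, cohort$exposures)
    write_gweis_summary(scan, pth("gweis.tsv"))
    log("gweis", sprintf("%d SNP x exposure fits", nrow(scan)))
    record("gweis", pth("gweis.tsv"), nrow(scan))
  })

  ## 4-6. clump / score / assoc per P threshold ------------------------
  for (lab in names(config$p_thresholds)) {
    pthr <- config$p_thresholds[[lab]]
    effects_main <- NULL
    effects_int <- NULL
    run_stage(paste0("clump_", lab), {
      effects_main <- ld_clump(
        gweis_candidates(scan, "main"), qc_res$panel,
        clump_params(pthr, config$window_bp, config$r2_threshold, "main"))
      effects_int <- lapply(exp_names, function(nm) {
        ld_clump(gweis_candidates(scan, "interaction", nm), qc_res$panel,
                 clump_params(pthr, config$window_bp, config$r2_threshold,
                              paste0("interaction:", nm)))
      })
      names(effects_int) <- exp_names
      files <- pth(sprintf("effects_%s_main.tsv", lab))
      write_effect_set(effects_main, files)
      for (nm in exp_names) {
        f <- pth(sprintf("effects_%s_interaction_%s.tsv", lab, nm))
        write_effect_set(effects_int[[nm]], f)
        files <- c(files, f)
      }
      log(paste0("clump_", lab),
          sprintf("main %d SNPs; %s", nrow(effects_main),
                  paste(sprintf("%s %d", exp_names,
                                vapply(effects_int, nrow, 1L)),
                        collapse = "; ")))
      record(paste0("clump_", lab), files,
             nrow(effects_main) + sum(vapply(effects_int, nrow, 1L)))
    })

    scores <- NULL
    run_stage(paste0("score_", lab), {
      scores <- compute_scores(qc_res$panel, effects_main, effects_int,
                                cohort$exposures)
      write_table(scores, pth(sprintf("scores_%s.tsv", lab)))
      record(paste0("score_", lab), pth(sprintf("scores_%s.tsv", lab)),
             nrow(scores))
    })

    run_stage(paste0("assoc_", lab), {
      data <- merge(merge(cohort$phenotype, cohort$exposures,
                          by = "sample_id"),
                    cohort$covariates, by = "sample_id")
      if ("age" %in% names(data) && "age_sq" %in% config$covariates) {
        data$age_sq <- data$age^2
      }
      strata <- if (length(exp_names) >= 2L) {
        default_strata(exp_names[1L], exp_names[2L])
      } else {
        list(stratum_spec("exposed",
                          function(d) d[[exp_names[1L]]] > 0),
             stratum_spec("unexposed",
                          function(d) d[[exp_names[1L]]] == 0))
      }
      assoc <- run_association_battery(
        scores, data,
        traits = c("phenotype", "secondary_trait"),
        strata = strata,
        covariates = intersect(config$covariates, names(data)))
      utils::write.table(
        cbind(assoc[c("score_name", "trait_name", "stratum")],
              beta = format_full(assoc$beta), se = format_full(assoc$se),
              p = format_full(assoc$p), fdr = format_full(assoc$fdr),
              n = assoc$n),
        pth(sprintf("assoc_%s.tsv", lab)), sep = "\t", quote = FALSE,
        row.names = FALSE)
      log(paste0("assoc_", lab), sprintf("%d tests", nrow(assoc)))
      record(paste0("assoc_", lab), pth(sprintf("assoc_%s.tsv", lab)),
             nrow(assoc))
    })

  }

  ## 7. mediate --------------------------------------------------------
  # analysis scores: the first threshold set whose PGIRS varies (a very
  # strict threshold can leave empty effect sets on small cohorts)
  analysis_scores <- pth(sprintf("scores_%s.tsv",
                                 names(config$p_thresholds)[1L]))
  for (lab in names(config$p_thresholds)) {
    f <- pth(sprintf("scores_%s.tsv", lab))
    if (stats::sd(read_table(f)$PGIRS) > 0) {
      analysis_scores <- f
      break
    }
  }
  manifest$analysis_scores <- basename(analysis_scores)
  run_stage("mediate", {
    scores <- read_table(analysis_scores)
    d <- merge(scores, cohort$phenotype, by = "sample_id")
    med <- mediate(d$PGIRS, d$phenotype, d$secondary_trait,
                   n_boot = config$mediation$n_boot,
                   seed = config$seed + 5L)
    out <- data.frame(a = med$a, b = med$b, direct = med$direct,
                      indirect = med$indirect, total = med$total,
                      ci_low = med$ci_low, ci_high = med$ci_high,
                      n = med$n, n_boot = med$n_boot)
    utils::write.table(out, pth("mediation.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    log("mediate", sprintf("indirect %.4g [%.4g, %.4g]", med$indirect,
                           med$ci_low, med$ci_high))
    record("mediate", pth("mediation.tsv"), 1L)
  })

  ## 8. cv -------------------------------------------------------------
  run_stage("cv", {
    scores <- read_table(analysis_scores)
    d <- merge(scores, cohort$phenotype, by = "sample_id")
    rows <- lapply(c("PRS", "PGIRS"), function(sc) {
      rep <- kfold_cv(d, sc, "secondary_trait", k = config$cv_k,
                      seed = config$seed + 6L)
      data.frame(score = sc, k = rep$k, rmse = rep$mean["rmse"],
                 mae = rep$mean["mae"], r2 = rep$mean["r2"])
    })
    cv_tab <- do.call(rbind, rows)
    utils::write.table(cv_tab, pth("cv.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    log("cv", sprintf("mean R2: %s",
                      paste(sprintf("%s %.3f", cv_tab$score, cv_tab$r2),
                            collapse = ", ")))
    record("cv", pth("cv.tsv"), nrow(cv_tab))
  })

  ## manifest ----------------------------------------------------------
  sums <- tools::md5sum(outputs)
  manifest$files <- data.frame(file = basename(outputs),
                               md5 = unname(sums),
                               stringsAsFactors = FALSE)
  manifest$params <- list(
    qc = unclass(config$qc),
    p_thresholds = as.list(config$p_thresholds),
    window_bp = config$window_bp, r2_threshold = config$r2_threshold,
    covariates = config$covariates, cv_k = config$cv_k)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
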