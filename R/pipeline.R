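# Config-driven orchestration: bidirectional screen -> univariable
# significance gate -> multivariable MR-BMA with one outlier-removal pass,
# with drop logs and a machine-readable run manifest.

#' Pipeline configuration
#'
#' Collects every tunable threshold of the workflow with its default:
#' genome-wide and lenient instrument p-value cutoffs (5e-8, 5e-6), clumping
#' window and r^2 (10000 kb, 0.001), heterogeneity threshold for IVW model
#' choice (0.05), the univariable IVW gate feeding MR-BMA (0.05, forward
#' direction only), the BMA prior inclusion probability (0.1) and prior
#' variance (0.25), and the outlier flag rules (Q > 10, Cd > 4/J). The full
#' parameter set is echoed into the run manifest.
#'
#' @param exposure_files,outcome_files Paths to summary-statistics files.
#' @param exposure_type,outcome_type Trait types for [read_gwas_table()].
#' @param column_map Optional column map shared by all inputs.
#' @param primary_p,lenient_p,min_snps,clump_kb,clump_r2 Instrument
#'   selection parameters.
#' @param het_p IVW heterogeneity threshold.
#' @param ivw_gate Forward IVW p-value below which an exposure enters the
#'   multivariable stage.
#' @param prior_inclusion,sigma2,q_flag,cd_rule,top_pp_threshold,permutations
#'   MR-BMA parameters (see [bma_config()]).
#' @param n_boot Weighted-median bootstrap replicates.
#' @param seed Integer seed governing every stochastic step.
#' @param out_dir Run directory for all outputs.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(exposure_files, outcome_files,
                            exposure_type = "quantitative",
                            outcome_type = "binary",
                            column_map = NULL,
                            primary_p = 5e-8, lenient_p = 5e-6, min_snps = 3L,
                            clump_kb = 10000L, clump_r2 = 0.001,
                            het_p = 0.05, ivw_gate = 0.05,
                            prior_inclusion = 0.1, sigma2 = 0.25,
                            q_flag = 10, cd_rule = "4/J",
                            top_pp_threshold = 0.01, permutations = 0L,
                            n_boot = 1000L, seed = 1L, out_dir) {
  assert_that(!missing(out_dir), "mrscreen_config_error", "out_dir is required")
  structure(list(exposure_files = exposure_files, outcome_files = outcome_files,
                 exposure_type = exposure_type, outcome_type = outcome_type,
                 column_map = column_map,
                 primary_p = primary_p, lenient_p = lenient_p,
                 min_snps = as.integer(min_snps),
                 clump_kb = as.integer(clump_kb), clump_r2 = clump_r2,
                 het_p = het_p, ivw_gate = ivw_gate,
                 prior_inclusion = prior_inclusion, sigma2 = sigma2,
                 q_flag = q_flag, cd_rule = cd_rule,
                 top_pp_threshold = top_pp_threshold,
                 permutations = as.integer(permutations),
                 n_boot = as.integer(n_boot), seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

# the named parameter echo written to the manifest
pipeline_parameters <- function(config) {
  config[c("primary_p", "lenient_p", "min_snps", "clump_kb", "clump_r2",
           "het_p", "ivw_gate", "prior_inclusion", "sigma2", "q_flag",
           "cd_rule")]
}

#' Run the full screen-then-BMA workflow
#'
#' Reads the inputs, runs the bidirectional univariable screen, then for each
#' outcome collects the exposures whose forward IVW p-value passes the gate,
#' builds the union-of-instruments multivariable dataset and runs MR-BMA with
#' one outlier-removal pass. Writes a screen table, leave-one-out and
#' scatter/funnel plot-data TSVs, per-outcome model/ranking/diagnostics
#' tables for both passes, drop logs with reason codes, and a JSON manifest
#' (parameter echo, seed, package version, input files) sufficient to rerun
#' bit-identically. Completion, not significance, determines success.
#'
#' @param config A [pipeline_config()].
#' @param exposures,outcomes Optional pre-loaded lists of [gwas_table()]s
#'   (bypassing the file reads; file lists may then be empty).
#' @return Invisibly, a list with the screen object, per-outcome BMA results,
#'   and the paths written.
#' @export
run_pipeline <- function(config, exposures = NULL, outcomes = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  exposures <- exposures %||% lapply(config$exposure_files, function(f)
    read_gwas_table(f, column_map = config$column_map,
                    trait_type = config$exposure_type, quiet = TRUE))
  outcomes <- outcomes %||% lapply(config$outcome_files, function(f)
    read_gwas_table(f, column_map = config$column_map,
                    trait_type = config$outcome_type, quiet = TRUE))

  message(sprintf("screen: %d exposures x %d outcomes, both directions",
                  length(exposures), length(outcomes)))
  screen <- bidirectional_screen(
    exposures, outcomes,
    primary_p = config$primary_p, lenient_p = config$lenient_p,
    min_snps = config$min_snps, clump_kb = config$clump_kb,
    clump_r2 = config$clump_r2, het_p = config$het_p,
    n_boot = config$n_boot, seed = config$seed)

  paths <- character(0)
  save <- function(df, name) {
    p <- file.path(config$out_dir, name)
    write_tsv(df, p)
    paths <<- c(paths, p)
  }
  save(screen$results, "screen.tsv")

  bind_details <- function(field, id_cols) {
    rows <- lapply(names(screen$details), function(key) {
      d <- screen$details[[key]][[field]]
      if (is.null(d)) return(NULL)
      parts <- strsplit(key, "|", fixed = TRUE)[[1]]
      cbind(data.frame(exposure = parts[1], outcome = parts[2],
                       direction = parts[3], stringsAsFactors = FALSE), d)
    })
    do.call(rbind, rows)
  }
  loo <- bind_details("leave_one_out")
  if (!is.null(loo)) save(loo, "leave_one_out.tsv")
  sc <- bind_details("scatter")
  if (!is.null(sc)) save(sc, "plot_scatter.tsv")
  fn <- bind_details("funnel")
  if (!is.null(fn)) save(fn, "plot_funnel.tsv")
  drops <- lapply(names(screen$details), function(key) {
    d <- screen$details[[key]]$harmonized$drops
    if (!nrow(d)) return(NULL)
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    cbind(data.frame(exposure = parts[1], outcome = parts[2],
                     direction = parts[3], stringsAsFactors = FALSE), d)
  })
  drops <- do.call(rbind, drops)
  save(drops %||% data.frame(exposure = character(), outcome = character(),
                             direction = character(), variant_id = character(),
                             reason = character()), "drop_log.tsv")

  # multivariable stage, forward direction only
  exp_names <- vapply(exposures, `[[`, "", "trait_name")
  bma_results <- list()
  bma_notes <- list()
  for (oc in outcomes) {
    res <- screen$results
    fwd <- res[res$direction == "forward" & res$outcome == oc$trait_name &
                 res$method %in% c("ivw_fixed", "ivw_random", "wald_ratio") &
                 res$status == "ok", , drop = FALSE]
    gated <- unique(fwd$exposure[fwd$pval < config$ivw_gate])
    note <- sprintf("%s: %d exposure(s) pass the IVW gate (p < %g)",
                    oc$trait_name, length(gated), config$ivw_gate)
    if (length(gated) < 2L) {
      bma_notes[[oc$trait_name]] <- paste(note, "- multivariable stage skipped")
      message(bma_notes[[oc$trait_name]])
      next
    }
    message(note)
    sets <- lapply(gated, function(nm) {
      screen$details[[paste(nm, oc$trait_name, "forward", sep = "|")]]$instruments
    })
    h <- harmonize(sets, oc, multivariable = TRUE,
                   exposure_tables = exposures[match(gated, exp_names)])
    cfg <- bma_config(prior_inclusion = config$prior_inclusion,
                      sigma2 = config$sigma2, q_flag = config$q_flag,
                      cd_flag_rule = config$cd_rule,
                      top_pp_threshold = config$top_pp_threshold,
                      permutations = config$permutations, seed = config$seed)
    fit <- tryCatch(bma_with_outlier_removal(h, cfg),
                    mrscreen_error = function(e) e)
    if (inherits(fit, "condition")) {
      bma_notes[[oc$trait_name]] <- paste(note, "- BMA failed:",
                                          conditionMessage(fit))
      message(bma_notes[[oc$trait_name]])
      next
    }
    bma_results[[oc$trait_name]] <- fit
    for (pass in c("pass1", "pass2")) {
      tag <- sprintf("bma_%s_%s", oc$trait_name, pass)
      save(fit[[pass]]$result$ranking, paste0(tag, "_ranking.tsv"))
      save(fit[[pass]]$result$models, paste0(tag, "_models.tsv"))
      save(fit[[pass]]$diagnostics$table, paste0(tag, "_diagnostics.tsv"))
    }
    save(data.frame(removed = fit$removed_ids %||% character()),
         sprintf("bma_%s_removed.tsv", oc$trait_name))
    if (nrow(h$drops))
      save(h$drops, sprintf("bma_%s_drop_log.tsv", oc$trait_name))
  }

  manifest <- list(
    tool = "mrscreen",
    version = as.character(utils::packageVersion("mrscreen")),
    seed = config$seed,
    parameters = pipeline_parameters(config),
    exposure_files = as.character(config$exposure_files),
    outcome_files = as.character(config$outcome_files),
    exposures = exp_names,
    outcomes = vapply(outcomes, `[[`, "", "trait_name"),
    bma_notes = unlist(bma_notes) %||% character(),
    outputs = basename(paths))
  mpath <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  paths <- c(paths, mpath)

  invisible(list(screen = screen, bma = bma_results, notes = bma_notes,
                 paths = paths, config = config))
}
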