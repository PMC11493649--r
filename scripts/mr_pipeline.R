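#!/usr/bin/env Rscript
# Thin command-line front end over the mrscreen package.
#
#   Rscript scripts/mr_pipeline.R simulate --config FILE --seed INT --out DIR
#   Rscript scripts/mr_pipeline.R screen   --exposure F [--exposure F ...]
#                                          --outcome F [...] --seed INT --out DIR
#   Rscript scripts/mr_pipeline.R bma      --harmonized FILE --prior-p 0.1
#                                          --sigma2 0.25 --q-flag 10 --seed INT --out DIR
#   Rscript scripts/mr_pipeline.R run      --config FILE [--seed INT] --out DIR
#
# Config files are YAML key: value maps of pipeline_config()/
# simulation_config() arguments.

suppressMessages({
  library(mrscreen)
})

`%||%` <- function(a, b) if (is.null(a)) b else a

argv <- commandArgs(trailingOnly = TRUE)
if (length(argv) < 1L) stop("subcommand required: simulate | screen | bma | run")
cmd <- argv[1]
argv <- argv[-1]

collect <- function(flag) {
  out <- character(0)
  i <- 1L
  while (i <= length(argv)) {
    if (argv[i] == flag && i < length(argv)) out <- c(out, argv[i + 1L])
    i <- i + 1L
  }
  out
}
get1 <- function(flag, default = NULL) {
  v <- collect(flag)
  if (length(v)) v[length(v)] else default
}

read_config_yaml <- function(path) {
  if (is.null(path)) return(list())
  yaml::read_yaml(path)
}

seed <- as.integer(get1("--seed", "1"))
out <- get1("--out", "mrscreen_run")

if (cmd == "simulate") {
  cfg_list <- read_config_yaml(get1("--config"))
  cfg_list$seed <- seed
  cfg <- do.call(simulation_config, cfg_list)
  sim <- simulate_gwas(cfg)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  for (tb in c(sim$exposures, sim$outcomes))
    write_gwas_table(tb, file.path(out, paste0(tb$trait_name, ".tsv")))
  if (!is.null(sim$ld))
    utils::write.csv(sim$ld, file.path(out, "ld.csv"))
  truth <- data.frame(variant_id = sim$truth$variant_id,
                      outlier = sim$truth$variant_id %in% sim$truth$outlier_ids)
  utils::write.table(cbind(truth, sim$truth$gamma), file.path(out, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote simulated tables to ", out)

} else if (cmd == "screen") {
  exposures <- lapply(collect("--exposure"), read_gwas_table,
                      trait_type = "quantitative")
  outcomes <- lapply(collect("--outcome"), read_gwas_table,
                     trait_type = "binary")
  sc <- bidirectional_screen(
    exposures, outcomes,
    primary_p = as.numeric(get1("--primary-p", "5e-8")),
    lenient_p = as.numeric(get1("--lenient-p", "5e-6")),
    min_snps = as.integer(get1("--min-snps", "3")),
    clump_kb = as.integer(get1("--clump-kb", "10000")),
    clump_r2 = as.numeric(get1("--clump-r2", "0.001")),
    n_boot = as.integer(get1("--n-boot", "1000")),
    seed = seed,
    reverse = is.null(get1("--forward-only")))
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(sc$results, file.path(out, "screen.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", file.path(out, "screen.tsv"))

} else if (cmd == "bma") {
  # harmonized TSV as written by write_harmonized: bx_*/sx_* columns + by/sy
  df <- utils::read.delim(get1("--harmonized"))
  bxc <- grep("^bx_", names(df), value = TRUE)
  sxc <- sub("^bx_", "sx_", bxc)
  h <- harmonized_dataset(as.matrix(df[bxc]), as.matrix(df[sxc]),
                          df$by, df$sy,
                          exposure_names = sub("^bx_", "", bxc),
                          variant_ids = df$variant_id)
  cfg <- bma_config(prior_inclusion = as.numeric(get1("--prior-p", "0.1")),
                    sigma2 = as.numeric(get1("--sigma2", "0.25")),
                    q_flag = as.numeric(get1("--q-flag", "10")),
                    cd_flag_rule = get1("--cd-rule", "4/J"),
                    permutations = as.integer(get1("--permutations", "0")),
                    seed = seed)
  fit <- bma_with_outlier_removal(h, cfg)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  for (pass in c("pass1", "pass2")) {
    utils::write.table(fit[[pass]]$result$ranking,
                       file.path(out, paste0("bma_", pass, "_ranking.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(fit[[pass]]$result$models,
                       file.path(out, paste0("bma_", pass, "_models.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  message("removed: ", paste(fit$removed_ids, collapse = ", "))

} else if (cmd == "run") {
  cfg_list <- read_config_yaml(get1("--config"))
  cfg_list$seed <- as.integer(get1("--seed", cfg_list$seed %||% 1L))
  cfg_list$out_dir <- out
  cfg <- do.call(pipeline_config, cfg_list)
  run_pipeline(cfg)
  message("run complete: ", out)

} else {
  stop("unknown subcommand: ", cmd)
}
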