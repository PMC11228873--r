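#!/usr/bin/env Rscript
# Thin command-line driver over phenomGP::run_pipeline(): simulate a
# preset-shaped trial and run stage-1 mixed models, FPCA, kernels and the
# requested cross-validation scenarios, writing stage tables and result
# CSVs to --out.
#
#   Rscript scripts/pipeline.R --preset pop1 --trait gy \
#       --models M1,M2,M4 --scenarios within,loeo --repeats 2 \
#       --seed 1 --out results/pipeline

suppressMessages(library(phenomGP))

args <- commandArgs(trailingOnly = TRUE)
opt <- list(preset = "pop1", trait = "gy", models = "M1,M2,M4",
            scenarios = "within,loeo", repeats = 2L, n_iter = 3000L,
            burn_in = 500L, seed = 1L, out = "results/pipeline")
i <- 1L
while (i <= length(args)) {
  key <- sub("^--", "", args[i])
  if (!key %in% names(opt)) stop("unknown flag: ", args[i])
  opt[[key]] <- if (is.numeric(opt[[key]]) || is.integer(opt[[key]]))
    as.integer(args[i + 1L]) else args[i + 1L]
  i <- i + 2L
}

res <- run_pipeline(
  preset_config(opt$preset, seed = opt$seed),
  trait = opt$trait,
  models = strsplit(opt$models, ",")[[1]],
  scenarios = strsplit(opt$scenarios, ",")[[1]],
  gibbs = gibbs_config(n_iter = opt$n_iter, burn_in = opt$burn_in,
                       seed = opt$seed),
  cv_repeats = opt$repeats, out_dir = opt$out, seed = opt$seed)

# run manifest: configuration and seed for byte-identical reruns
manifest <- list(preset = opt$preset, trait = opt$trait,
                 models = opt$models, scenarios = opt$scenarios,
                 repeats = opt$repeats, n_iter = opt$n_iter,
                 burn_in = opt$burn_in, seed = opt$seed,
                 package_version = as.character(utils::packageVersion("phenomGP")),
                 r_version = R.version.string)
jsonlite::write_json(manifest, file.path(opt$out, "manifest.json"),
                     auto_unbox = TRUE, pretty = TRUE)
print(res$cv_summary)
message("outputs written to ", opt$out)
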