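#!/usr/bin/env Rscript
# Thin shell entry point over lcintensity::run_pipeline().
# Usage: Rscript run_pipeline.R --config cfg.yaml [--mode simulate] \
#          [--out DIR] [--seed INT] [--min-targeted-frac F] [--min-area A] [-v]

suppressPackageStartupMessages({
  library(optparse)
  library(lcintensity)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL),
  make_option("--mode", type = "character", default = NULL,
              help = "rasters | matrices | simulate"),
  make_option("--out", type = "character", default = NULL),
  make_option("--seed", type = "integer", default = NULL),
  make_option("--min-targeted-frac", type = "double", default = NULL,
              dest = "min_targeted_frac"),
  make_option("--min-area", type = "double", default = NULL,
              dest = "min_area_km2"),
  make_option(c("-v", "--verbose"), action = "count", default = 0))))

cfg <- if (!is.null(opts$config)) read_run_config(opts$config) else list()
for (f in c("mode", "out", "seed", "min_targeted_frac", "min_area_km2"))
  if (!is.null(opts[[f]])) cfg[[f]] <- opts[[f]]

status <- tryCatch({
  fit <- run_pipeline(cfg)
  if (opts$verbose > 0) {
    message(sprintf("U = %.4f %%/yr over %d interval(s)",
                    fit$U, nrow(fit$intervals)))
    if (opts$verbose > 1) print(summary(fit))
  }
  0L
}, error = function(e) {
  message("error: ", conditionMessage(e))
  1L
})
quit(status = status)
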