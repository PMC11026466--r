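#!/usr/bin/env Rscript
# Thin command-line wrapper over singpref::run_pipeline(). Usage:
#   Rscript scripts/run_pipeline.R --seed 1 --design lab --out runs/lab1
#   Rscript scripts/run_pipeline.R --config config.yaml

suppressMessages({
  library(optparse)
  library(singpref)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL,
              help = "YAML/JSON pipeline config (overrides other options)"),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--design", type = "character", default = "lab",
              help = "lab or online"),
  make_option("--out", type = "character", default = NULL,
              help = "output directory for tables and summary JSON"),
  make_option("--participants", type = "integer", default = NULL),
  make_option("--no-extract", action = "store_true", default = FALSE,
              dest = "no_extract",
              help = "skip audio feature extraction (model on ground truth)"),
  make_option("--write-audio", action = "store_true", default = FALSE,
              dest = "write_audio", help = "write WAV + label tracks")
)))

cfg <- if (!is.null(opts$config)) {
  read_pipeline_config(opts$config)
} else {
  pipeline_config(seed = opts$seed, design = opts$design,
                  n_participants = opts$participants,
                  extract_features = !opts$no_extract,
                  write_audio = opts$write_audio, out_dir = opts$out)
}

res <- run_pipeline(cfg)
print(res)
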