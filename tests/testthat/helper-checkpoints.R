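# One trained checkpoint set (the standard study corpus: potentials from
# 200 natives, NNScorer from 30 targets x 8 models spanning noise 0-3 A,
# seed 7) shared across test files; trained once per session.

.bench_env <- new.env(parent = emptyenv())

bench_checkpoints <- function() {
  if (is.null(.bench_env$cp))
    .bench_env$cp <- train_checkpoints(seed = 7)
  .bench_env$cp
}

# a small scored scenario (native + templates + predictions + models)
# reused by pipeline/end-to-end tests
bench_scenario <- function() {
  if (is.null(.bench_env$scen)) {
    dir <- file.path(tempdir(), "discoqa_scenario")
    unlink(dir, recursive = TRUE)
    native <- make_native(36, seed = 991, id = "scen")
    tt <- make_templates_and_alignments(native, dir, seed = 992)
    pf <- make_predictor_files(native, dir, error_rate = 0.1, seed = 993)
    models <- make_models(native, c(0, 1, 2.5), seed = 994)
    .bench_env$scen <- list(native = native, dir = dir, a3m = tt$a3m,
                            template_dir = tt$template_dir,
                            ss2 = pf$ss2, acc = pf$acc, models = models)
  }
  .bench_env$scen
}
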