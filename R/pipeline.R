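# End-to-end orchestration: simulate (or load) -> stratified split ->
# p-value map on the TRAINING portion only (bag selection must not see the
# held-out subjects) -> bag construction -> train -> optional FSSA
# refinement -> evaluation on the held-out subjects. Reports are
# deterministic functions of (config, seed); logs carry no timestamps so
# reruns are byte-identical.

#' Default run configuration
#'
#' Returns the full nested configuration with the package's desk-scale
#' defaults. `proposal$k` and `proposal$W` are mandatory keys: they define
#' the bag and must be set consciously in any hand-written config.
#'
#' @return Nested named list.
#' @export
defaultRunConfig <- function() {
  list(
    seed = 1,
    out_dir = NULL,
    data = list(
      source = "synthetic",
      manifest = NULL,
      synthetic = list(shape = c(48, 48, 48), n_per_group = 60,
                       lesions = list(list(origin = c(24, 24, 24), width = 12)),
                       effect_size = 1.5, noise_sd = 0.1, smoothness = 4,
                       lesion_sign = -1)),
    proposal = list(k = 8, W = 12, statistic = "patch_mean"),
    split = list(fraction = 0.8, val_fraction = 0.2),
    model = list(channels = c(4, 8, 8, 8), att_hidden = 4,
                 shared_descriptor_mlp = TRUE, classifier_channels = c(8, 4),
                 flags = list()),
    train = list(lr = 1e-3, epochs = 40, batch_size = 8, patience = 10,
                 optimizer = "adam", class_weights = NULL),
    fssa = list(n_max = 20, n_min = 8, t_max = 40, c_max = 0.95, c_min = 0.05,
                radius = 0.5),
    evaluation = list(threshold = 0.5))
}

# strict schema: every key in cfg must exist in the template, recursively;
# lists-of-records (lesions, flags) are passed through opaque
validateConfigKeys <- function(cfg, template, path = "") {
  opaque <- c("data.synthetic.lesions", "model.flags", "train.class_weights")
  for (nm in names(cfg)) {
    here <- if (path == "") nm else paste(path, nm, sep = ".")
    if (!nm %in% names(template))
      stopf("unknown config key: %s", here)
    if (is.list(cfg[[nm]]) && is.list(template[[nm]]) && !(here %in% opaque))
      validateConfigKeys(cfg[[nm]], template[[nm]], here)
  }
  invisible(TRUE)
}

mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]) && !is.null(names(override[[nm]])))
      base[[nm]] <- mergeConfig(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read and validate a run configuration from YAML
#'
#' Unknown keys are rejected (strict schema); omitted keys take the
#' package defaults, except `proposal$k` and `proposal$W` which must be
#' stated explicitly.
#'
#' @param path YAML file.
#' @return Resolved config list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  resolveRunConfig(cfg)
}

#' @rdname readRunConfig
#' @param cfg partial config list (e.g. parsed YAML).
#' @export
resolveRunConfig <- function(cfg) {
  template <- defaultRunConfig()
  validateConfigKeys(cfg, template)
  if (is.null(cfg$proposal$k) || is.null(cfg$proposal$W))
    stopf("config must state proposal$k and proposal$W explicitly")
  mergeConfig(template, cfg)
}

#' Run the full pipeline
#'
#' @param cfg a resolved run configuration (see [resolveRunConfig()];
#'   partial lists are resolved automatically).
#' @param outDir output directory; overrides `cfg$out_dir`. NULL skips
#'   writing artifacts.
#' @return Invisibly, list(report, model, history, map, spec, refine,
#'   split, groundTruth).
#' @export
runPipeline <- function(cfg, outDir = NULL) {
  if (is.null(cfg$evaluation)) cfg <- resolveRunConfig(cfg)
  outDir <- outDir %||% cfg$out_dir
  logLines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    logLines <<- c(logLines, msg)
    message(msg)
  }
  seed <- as.integer(cfg$seed)

  # 1. data
  gt <- NULL
  if (identical(cfg$data$source, "synthetic")) {
    s <- cfg$data$synthetic
    scfg <- syntheticCohortConfig(shape = s$shape, nPerGroup = s$n_per_group,
                                  lesions = s$lesions, effectSize = s$effect_size,
                                  noiseSd = s$noise_sd, smoothness = s$smoothness,
                                  lesionSign = s$lesion_sign, seed = seed)
    coh <- generateCohort(scfg)
    volumes <- coh$volumes; labels <- coh$labels; gt <- coh$groundTruth
    say("stage data: simulated %d subjects of %s voxels (seed %d)",
        length(volumes), paste(scfg$shape, collapse = "x"), seed)
  } else if (identical(cfg$data$source, "manifest")) {
    m <- readManifest(cfg$data$manifest)
    volumes <- lapply(seq_len(nrow(m)), function(i) readVolume(m$path[i], m$subject_id[i]))
    labels <- as.integer(m$label)
    say("stage data: loaded %d subjects from %s", length(volumes), cfg$data$manifest)
  } else stopf("stage data: unknown source '%s'", cfg$data$source)

  # 2. split (stratified)
  sp <- splitHoldout(labels, fraction = cfg$split$fraction, seed = seed + 1L)
  say("stage split: %d train / %d held-out subjects", length(sp$train), length(sp$test))

  # 3. p-value map on training subjects only
  trA <- volumes[sp$train][labels[sp$train] == 0]
  trB <- volumes[sp$train][labels[sp$train] == 1]
  map <- groupTTestMap(trA, trB, W = cfg$proposal$W, statistic = cfg$proposal$statistic)
  spec <- selectBagLocations(map, cfg$proposal$k)
  say("stage proposal: %d locations tested, %d selected (min p = %.3g)",
      nrow(map@origins), cfg$proposal$k, min(map@pRaw))

  # 4. bags
  bags <- lapply(seq_along(volumes), function(i)
    buildBag(volumes[[i]], spec, label = labels[i]))

  # 5. inner train/val split for early stopping + refinement
  innerLabels <- labels[sp$train]
  spv <- splitHoldout(innerLabels, fraction = 1 - cfg$split$val_fraction, seed = seed + 2L)
  trainBags <- bags[sp$train][spv$train]
  valBags <- bags[sp$train][spv$test]

  flags <- unlist(cfg$model$flags)
  model <- newBagModel(k = cfg$proposal$k, W = cfg$proposal$W,
                       channels = cfg$model$channels,
                       attHidden = cfg$model$att_hidden,
                       sharedDescriptorMLP = cfg$model$shared_descriptor_mlp,
                       classifierChannels = cfg$model$classifier_channels,
                       flags = if (is.null(flags)) character(0) else flags,
                       seed = seed + 3L)
  tr <- trainBagModel(model, trainBags, valBags,
                      lr = cfg$train$lr, epochs = cfg$train$epochs,
                      batchSize = cfg$train$batch_size, patience = cfg$train$patience,
                      optimizer = cfg$train$optimizer,
                      classWeights = cfg$train$class_weights, seed = seed + 4L)
  model <- tr$model
  say("stage train: best validation loss %.4f at epoch %d",
      min(tr$history$val_loss), tr$bestEpoch)

  # 6. FSSA refinement of the global classifier
  refine <- NULL
  if (isTRUE(model@config$flags$no_fssa)) {
    say("stage refine: skipped (ablation flag no_fssa)")
  } else {
    fcfg <- fssaConfig(nMax = cfg$fssa$n_max, nMin = cfg$fssa$n_min,
                       TMax = cfg$fssa$t_max, cMax = cfg$fssa$c_max,
                       cMin = cfg$fssa$c_min, seed = seed + 5L)
    refine <- refineClassifier(model, valBags, cfg = fcfg,
                               radius = cfg$fssa$radius,
                               threshold = cfg$evaluation$threshold)
    model <- refine$model
    say("stage refine: validation accuracy %.3f -> %.3f",
        refine$accuracyBefore, refine$accuracyAfter)
  }

  # 7. held-out evaluation
  ev <- evaluateBags(model, bags[sp$test], threshold = cfg$evaluation$threshold)
  say("stage evaluate: ACC %.3f SEN %.3f SPE %.3f AUC %.3f on %d held-out subjects",
      ev$acc, ev$sen, ev$spe, ev$auc, ev$n)

  report <- list(acc = ev$acc, sen = ev$sen, spe = ev$spe, auc = ev$auc,
                 counts = ev$counts, n = ev$n, threshold = ev$threshold,
                 seed = seed)
  if (!is.null(gt)) {
    top1 <- attentionTopRate(ev, spec, gt, labels[sp$test])
    report$lesion_top_attention_rate <- top1
    say("stage evaluate: lesion gets top attention in %.0f%% of positive held-out bags",
        100 * top1)
  }

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write.csv(tr$history, file.path(outDir, "history.csv"), row.names = FALSE)
    writePValueMap(map, file.path(outDir, "pvalue_map.csv"))
    writeBagSpec(spec, file.path(outDir, "bag_spec.csv"))
    att <- ev$attention
    adf <- do.call(rbind, lapply(seq_len(ncol(att)), function(j)
      data.frame(subject_id = bags[sp$test][[j]]@subjectID,
                 rank = seq_len(nrow(att)),
                 ox = spec@origins[, 1], oy = spec@origins[, 2], oz = spec@origins[, 3],
                 weight = att[, j])))
    write.csv(adf, file.path(outDir, "attention.csv"), row.names = FALSE)
    yaml::write_yaml(cfg, file.path(outDir, "resolved_config.yaml"))
    writeLines(logLines, file.path(outDir, "run.log"))
  }

  invisible(list(report = report, model = model, history = tr$history,
                 map = map, spec = spec, refine = refine, split = sp,
                 groundTruth = gt))
}

# fraction of positive held-out bags whose largest attention weight sits on
# a ground-truth lesion location
attentionTopRate <- function(ev, spec, gt, testLabels) {
  pos <- which(testLabels == 1)
  if (!length(pos)) return(NA_real_)
  isLesion <- apply(spec@origins, 1, function(o)
    any(apply(gt@origins, 1, function(g) all(g == o))))
  if (!any(isLesion)) return(0)
  hits <- vapply(pos, function(j) {
    w <- ev$attention[, j]
    isLesion[which.max(w)]
  }, logical(1))
  mean(hits)
}
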