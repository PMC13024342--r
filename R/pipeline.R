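# End-to-end pipeline: align -> generate -> fuse -> evaluate, the ablation
# modes, and the stratified cross-validation protocol.

PIPELINE_MODES <- c("align", "align+noise", "flow-only", "latent-only",
                    "align+flow-concat", "align+flow+attention")

#' Pipeline configuration bundle
#'
#' @param alignment An [alignment_config()].
#' @param flow A [flow_config()].
#' @param fusion A [fusion_config()].
#' @param test_fraction Fraction of speech rows held out for testing when a
#'   cohort is split internally (default 0.3).
#' @param eeg_train_fraction EEG train share of the fixed train/validation
#'   split (default 0.8, i.e. 4:1).
#' @param seed Integer seed governing splits and model initialization.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(alignment = alignment_config(),
                            flow = flow_config(),
                            fusion = fusion_config(),
                            test_fraction = 0.3,
                            eeg_train_fraction = 0.8,
                            seed = 1) {
  structure(list(alignment = alignment, flow = flow, fusion = fusion,
                 test_fraction = test_fraction,
                 eeg_train_fraction = eeg_train_fraction, seed = seed),
            class = "pipeline_config")
}

# reseed every stage config from a master seed so folds/seeds are independent
reseed_config <- function(cfg, seed) {
  cfg$seed <- seed
  cfg$alignment$seed <- seed + 11L
  cfg$flow$seed <- seed + 23L
  cfg$fusion$seed <- seed + 37L
  cfg
}

# stratified split: returns index list(train, test)
stratified_split <- function(labels, test_fraction, seed) {
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  test <- unlist(lapply(split(seq_along(labels), labels), function(ii) {
    sample(ii, round(length(ii) * test_fraction))
  }), use.names = FALSE)
  list(train = setdiff(seq_along(labels), test), test = sort(test))
}

# stratified k folds: returns integer fold id per row
stratified_folds <- function(labels, k, seed) {
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  fold <- integer(length(labels))
  for (ii in split(seq_along(labels), labels)) {
    ii <- sample(ii)
    fold[ii] <- rep(seq_len(k), length.out = length(ii))[order(seq_along(ii))]
  }
  fold
}

# fusion-ready input tables for a given ablation mode
.mode_inputs <- function(mode, aligned_speech, generated, raw_speech, seed) {
  noise_like <- function(tbl) {
    fm <- feature_matrix(tbl)
    old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
    set.seed(seed + 101L)
    N <- matrix(stats::rnorm(length(fm$X)), nrow(fm$X), ncol(fm$X))
    colnames(N) <- paste0("N", seq_len(ncol(N)))
    dplyr::bind_cols(fm$meta, tibble::as_tibble(N))
  }
  switch(mode,
    "align" = list(x1 = aligned_speech, x2 = NULL, use_se = FALSE),
    "align+noise" = list(x1 = aligned_speech, x2 = noise_like(aligned_speech),
                         use_se = TRUE),
    "flow-only" = list(x1 = raw_speech, x2 = generated, use_se = TRUE),
    "latent-only" = list(x1 = generated, x2 = NULL, use_se = FALSE),
    "align+flow-concat" = list(x1 = aligned_speech, x2 = generated,
                               use_se = FALSE),
    "align+flow+attention" = list(x1 = aligned_speech, x2 = generated,
                                  use_se = TRUE),
    stop("unknown mode: ", mode, call. = FALSE))
}

#' Run the full pipeline on a synthetic cohort (or explicit tables)
#'
#' Splits the speech table into stratified train/test sets and the EEG table
#' into a fixed 4:1 train/validation split, standardizes each modality on
#' its training rows, trains the alignment network, trains the conditional
#' flow on the aligned latents, generates EEG-like latents for every speech
#' row, trains the fusion classifier for the requested ablation mode and
#' evaluates on the held-out speech rows.
#'
#' Modes: `"align"` (aligned speech only), `"align+noise"` (generated
#' latents replaced by standard-normal noise), `"flow-only"` (raw speech
#' features + generated latents), `"latent-only"` (generated latents only),
#' `"align+flow-concat"` (plain concatenation, no SE) and
#' `"align+flow+attention"` (the full model).
#'
#' @param cohort A `synthetic_cohort`, or a list with tibbles `speech` and
#'   `eeg` (labelled feature tables).
#' @param mode One of the six ablation modes.
#' @param cfg A [pipeline_config()].
#' @return A list of class `pipeline_result`: `metrics` (a
#'   [classification_metrics()] report on the test split), `mode`, the
#'   trained `alignment`, `flow` and `fusion` models and the split indices.
#' @export
run_pipeline <- function(cohort, mode = "align+flow+attention",
                         cfg = pipeline_config()) {
  mode <- match.arg(mode, PIPELINE_MODES)
  cfg <- reseed_config(cfg, cfg$seed)
  speech <- cohort$speech
  eeg <- cohort$eeg

  sp <- stratified_split(speech$label, cfg$test_fraction, cfg$seed)
  ee <- stratified_split(eeg$label, 1 - cfg$eeg_train_fraction, cfg$seed + 7L)
  sp_tr <- speech[sp$train, ]; sp_te <- speech[sp$test, ]
  ee_tr <- eeg[ee$train, ]
  stopifnot(length(intersect(sp_tr$subject_id, sp_te$subject_id)) == 0)

  # modality-wise standardization fitted on training rows only
  std_s <- fit_standardizer(sp_tr)
  std_e <- fit_standardizer(ee_tr)
  sp_tr_z <- predict(std_s, sp_tr); sp_te_z <- predict(std_s, sp_te)
  ee_tr_z <- predict(std_e, ee_tr)

  amodel <- train_alignment(sp_tr_z, ee_tr_z, cfg$alignment)
  al_tr <- align_encode(amodel, sp_tr_z, "speech")
  al_te <- align_encode(amodel, sp_te_z, "speech")
  al_ee <- align_encode(amodel, ee_tr_z, "eeg")

  fmodel <- NULL; gen_tr <- NULL; gen_te <- NULL
  if (mode %in% c("flow-only", "latent-only", "align+flow-concat",
                  "align+flow+attention")) {
    fmodel <- train_flow(al_tr, al_ee, cfg$flow)
    gen_tr <- flow_generate(fmodel, al_tr, seed = cfg$seed + 51L)
    gen_te <- flow_generate(fmodel, al_te, seed = cfg$seed + 52L)
  }

  inp_tr <- .mode_inputs(mode, al_tr, gen_tr, sp_tr_z, cfg$seed)
  inp_te <- .mode_inputs(mode, al_te, gen_te, sp_te_z, cfg$seed)
  fus <- fusion_fit(inp_tr$x1, inp_tr$x2, cfg$fusion, use_se = inp_tr$use_se)
  probs <- predict(fus, inp_te$x1, inp_te$x2, type = "prob")
  metrics <- classification_metrics(sp_te$label, probs = probs)

  structure(list(metrics = metrics, mode = mode, alignment = amodel,
                 flow = fmodel, fusion = fus,
                 split = list(speech = sp, eeg = ee)),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> mode = %s\n", x$mode))
  print(x$metrics)
  invisible(x)
}

#' Ablation study over modes and seeds
#'
#' Re-runs [run_pipeline()] for every mode/seed combination and collects the
#' headline metrics; the fold/seed structure matches the two-level
#' aggregation used for reporting (mean and SD over seeds).
#'
#' @param cohort Cohort passed to [run_pipeline()].
#' @param modes Subset of the six ablation modes.
#' @param seeds Integer vector of master seeds.
#' @param cfg A [pipeline_config()].
#' @return Tibble with one row per mode x seed (`mode`, `seed`, `accuracy`,
#'   `macro_f1`, `macro_auc`).
#' @export
ablation_study <- function(cohort,
                           modes = c("align", "align+noise",
                                     "align+flow+attention"),
                           seeds = 1:5, cfg = pipeline_config()) {
  res <- list()
  for (mode in modes) {
    for (s in seeds) {
      cfg_s <- cfg; cfg_s$seed <- as.integer(s)
      r <- run_pipeline(cohort, mode, cfg_s)
      res[[length(res) + 1]] <- tibble::tibble(
        mode = mode, seed = s, accuracy = r$metrics$accuracy,
        macro_f1 = r$metrics$macro_f1, macro_auc = r$metrics$macro_auc)
    }
  }
  dplyr::bind_rows(res)
}

#' Cross-validation protocol description
#'
#' @param n_folds Stratified folds on the speech training set (default 5).
#' @param eeg_train_fraction Fixed EEG train share (default 0.8, a 4:1
#'   split reused across folds).
#' @param seeds Random seeds for repetition (default 1:5).
#' @return A list of class `cv_protocol`.
#' @export
cv_protocol <- function(n_folds = 5, eeg_train_fraction = 0.8, seeds = 1:5) {
  structure(list(n_folds = n_folds, eeg_train_fraction = eeg_train_fraction,
                 seeds = seeds), class = "cv_protocol")
}

#' Stratified cross-validation of the full pipeline
#'
#' Stratifies the speech table into `n_folds` folds (class proportions
#' preserved within one sample per class); the EEG table keeps one fixed
#' 4:1 train/validation split across all folds.  For every fold the
#' alignment, flow and fusion models are trained from scratch on that
#' fold's training rows only (independent initialization per fold) and
#' evaluated on the fold's validation rows.  Training/validation subject
#' ids are asserted disjoint in every fold.
#'
#' @param speech_table,eeg_table Labelled feature tables.
#' @param protocol A [cv_protocol()].
#' @param cfg A [pipeline_config()].
#' @param mode Ablation mode (default the full model).
#' @return A list of class `cv_result`: `folds` (assignment tibble),
#'   `reports` (per seed x fold `metrics_report`s), `summary`
#'   (per-seed mean, then mean and SD over seeds), `aggregate`.
#' @export
cross_validate <- function(speech_table, eeg_table, protocol = cv_protocol(),
                           cfg = pipeline_config(),
                           mode = "align+flow+attention") {
  labels <- as.character(speech_table$label)
  if (any(table(labels) < protocol$n_folds)) {
    stop("a class has fewer training samples than folds", call. = FALSE)
  }
  ee <- stratified_split(eeg_table$label, 1 - protocol$eeg_train_fraction,
                         seed = 1003L)
  ee_tr <- eeg_table[ee$train, ]
  reports <- list(); fold_rows <- list(); per_seed <- list()
  param_hashes <- character(0)
  for (s in protocol$seeds) {
    fold_id <- stratified_folds(labels, protocol$n_folds, seed = s)
    fold_rows[[length(fold_rows) + 1]] <-
      tibble::tibble(seed = s, subject_id = speech_table$subject_id, fold = fold_id)
    seed_reports <- list()
    for (f in seq_len(protocol$n_folds)) {
      tr <- speech_table[fold_id != f, ]
      va <- speech_table[fold_id == f, ]
      stopifnot(length(intersect(tr$subject_id, va$subject_id)) == 0)
      cfg_f <- reseed_config(cfg, as.integer(s * 101L + f))
      std_s <- fit_standardizer(tr); std_e <- fit_standardizer(ee_tr)
      tr_z <- predict(std_s, tr); va_z <- predict(std_s, va)
      ee_z <- predict(std_e, ee_tr)
      amodel <- train_alignment(tr_z, ee_z, cfg_f$alignment)
      al_tr <- align_encode(amodel, tr_z, "speech")
      al_va <- align_encode(amodel, va_z, "speech")
      al_ee <- align_encode(amodel, ee_z, "eeg")
      fmodel <- train_flow(al_tr, al_ee, cfg_f$flow)
      gen_tr <- flow_generate(fmodel, al_tr, seed = cfg_f$seed + 51L)
      gen_va <- flow_generate(fmodel, al_va, seed = cfg_f$seed + 52L)
      inp_tr <- .mode_inputs(mode, al_tr, gen_tr, tr_z, cfg_f$seed)
      inp_va <- .mode_inputs(mode, al_va, gen_va, va_z, cfg_f$seed)
      fus <- fusion_fit(inp_tr$x1, inp_tr$x2, cfg_f$fusion, use_se = inp_tr$use_se)
      probs <- predict(fus, inp_va$x1, inp_va$x2, type = "prob")
      rep <- classification_metrics(va$label, probs = probs)
      reports[[length(reports) + 1]] <- list(seed = s, fold = f, report = rep)
      seed_reports[[f]] <- rep
      param_hashes <- c(param_hashes,
                        digest_params(nn_flatten(amodel$encoder_speech)))
    }
    agg <- aggregate_metrics(seed_reports)
    per_seed[[length(per_seed) + 1]] <-
      dplyr::mutate(agg, seed = s, .before = 1)
  }
  seed_means <- dplyr::bind_rows(per_seed)
  overall <- seed_means |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$mean), sd = stats::sd(.data$mean),
                     .groups = "drop")
  structure(list(folds = dplyr::bind_rows(fold_rows), reports = reports,
                 per_seed = seed_means, aggregate = overall,
                 param_hashes = param_hashes, protocol = protocol),
            class = "cv_result")
}

# cheap deterministic parameter fingerprint (fold-independence checks)
digest_params <- function(v) {
  paste(format(sum(v), digits = 15), format(sum(v^2), digits = 15),
        length(v), sep = "/")
}
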