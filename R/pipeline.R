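#' The four algorithm variants
#'
#' The pipeline variants differ only where stated: A1 skips the high-pass
#' filter and feeds spectrograms; A2 filters and feeds spectrograms; A3
#' and A4 filter, factorize each spectrogram with NNMF, and feed the basis
#' matrix `W` (A3) or the abundance matrix `H` (A4).
#'
#' @param id One of `"A1"`, `"A2"`, `"A3"`, `"A4"`.
#' @return A `fetmov_algorithm` list with `id`, `use_filter`, `feature`.
#' @export
#' @examples
#' algorithm_spec("A2")
algorithm_spec <- function(id = c("A2", "A1", "A3", "A4")) {
  id <- match.arg(id)
  structure(
    list(
      id = id,
      use_filter = id != "A1",
      feature = switch(id, A1 = "spectrogram", A2 = "spectrogram",
                       A3 = "nnmf_W", A4 = "nnmf_H")
    ),
    class = "fetmov_algorithm"
  )
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end pipeline in one serializable
#' object with a stable fingerprint, so that reports can state exactly
#' which configuration produced them and trained models can refuse
#' incompatible detection configs.
#'
#' @param filter A [filter_spec()].
#' @param search_back_s Annotation peak-search window, seconds.
#' @param threshold Application-mode amplitude threshold in AMU, or `NULL`
#'   for the adaptive per-session default.
#' @param min_separation Minimum peak separation, samples.
#' @param nnmf_rank,nnmf_max_iter,nnmf_tol NNMF settings for A3/A4.
#' @param cnn A [cnn_spec()].
#' @param train_frac Training fraction of the stratified split.
#' @return A `fetmov_config` list with a `fingerprint` string.
#' @export
pipeline_config <- function(filter = filter_spec(), search_back_s = 5,
                            threshold = NULL, min_separation = 200L,
                            nnmf_rank = 5L, nnmf_max_iter = 200L,
                            nnmf_tol = 1e-4, cnn = cnn_spec(),
                            train_frac = 0.8) {
  stopifnot(inherits(filter, "fetmov_filter_spec"), inherits(cnn, "fetmov_cnn_spec"))
  cfg <- list(filter = filter, search_back_s = search_back_s,
              threshold = threshold, min_separation = as.integer(min_separation),
              nnmf_rank = as.integer(nnmf_rank),
              nnmf_max_iter = as.integer(nnmf_max_iter), nnmf_tol = nnmf_tol,
              cnn = cnn, train_frac = train_frac)
  cfg$fingerprint <- config_fingerprint(cfg)
  structure(cfg, class = "fetmov_config")
}

# FNV-1a hash of the deterministic JSON serialization; good enough to
# detect config mismatches, no cryptographic ambition.
config_fingerprint <- function(cfg) {
  cfg$fingerprint <- NULL
  js <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
  bytes <- as.integer(charToRaw(as.character(js)))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Convert realizations into classifier feature arrays
#'
#' For the spectrogram variants each realization's 64 x 26 magnitude
#' spectrogram is rendered through the fixed colour table into a
#' 64 x 26 x 3 image. For A3/A4 the spectrogram is first factorized and
#' the basis (`W`, 64 x rank) or abundance (`H`, rank x 26) matrix is
#' rendered the same way. NNMF initializations are seeded per realization.
#'
#' @param realizations A `fetmov_realizations` tibble.
#' @param algo An [algorithm_spec()].
#' @param config A [pipeline_config()].
#' @param fs Sampling rate of the underlying traces.
#' @param seed Integer seed (drives the per-realization NNMF starts).
#' @return List with `X` (features as columns, flattened h-fastest),
#'   `input_shape`, and `labels`.
#' @export
featurize <- function(realizations, algo = algorithm_spec("A2"),
                      config = pipeline_config(), fs = 280, seed = 1L) {
  stopifnot(inherits(algo, "fetmov_algorithm"))
  n <- nrow(realizations)
  if (!n) abort("no realizations to featurize")
  feat_one <- function(i) {
    sp <- stft_magnitude(realizations$samples[[i]], fs = fs)
    M <- switch(algo$feature,
      spectrogram = sp$V,
      nnmf_W = nnmf_factorize(sp, rank = config$nnmf_rank,
                              seed = child_seed(seed, i),
                              max_iter = config$nnmf_max_iter,
                              tol = config$nnmf_tol)$W,
      nnmf_H = nnmf_factorize(sp, rank = config$nnmf_rank,
                              seed = child_seed(seed, i),
                              max_iter = config$nnmf_max_iter,
                              tol = config$nnmf_tol)$H
    )
    as.vector(render_rgb(M))
  }
  first <- stft_magnitude(realizations$samples[[1]], fs = fs)
  shape <- switch(algo$feature,
    spectrogram = c(dim(first$V), 3L),
    nnmf_W = c(nrow(first$V), config$nnmf_rank, 3L),
    nnmf_H = c(config$nnmf_rank, ncol(first$V), 3L)
  )
  X <- vapply(seq_len(n), feat_one, numeric(prod(shape)))
  list(X = X, input_shape = as.integer(shape), labels = realizations$label)
}

#' Run one algorithm variant end to end
#'
#' Executes the variant's stage order on a synthetic corpus:
#' (filter?) -> training-mode segmentation -> STFT -> (NNMF?) -> CNN
#' train/test -> evaluation, all deterministically derived from one seed.
#'
#' @param corpus A `fetmov_corpus` from [synth_dataset()].
#' @param algo An [algorithm_spec()] (or its id string).
#' @param config A [pipeline_config()].
#' @param seed Integer master seed for segmentation sampling, the split,
#'   initialization, and training shuffles.
#' @param keep_model Keep the trained model in the report (needed for
#'   [run_detection()]).
#' @param .realizations Precomputed segmentation output (internal; used to
#'   share segmentations across variants that use the same trace).
#' @return A `fetmov_eval` report: confusion matrix, per-class rates,
#'   config fingerprint, split sizes, and (optionally) the model.
#' @export
run_algorithm <- function(corpus, algo = algorithm_spec("A2"),
                          config = pipeline_config(), seed = 1L,
                          keep_model = TRUE, .realizations = NULL) {
  stopifnot(inherits(corpus, "fetmov_corpus"))
  if (is.character(algo)) algo <- algorithm_spec(algo)
  fs <- corpus$sessions$session[[1]]$fs
  reals <- .realizations %||% segment_corpus(corpus, algo, config, seed)
  fx <- featurize(reals, algo, config, fs = fs, seed = child_seed(seed, 77L))
  split <- stratified_split(fx$labels, config$train_frac,
                            seed = child_seed(seed, 202L))
  spec <- config$cnn
  spec$conv_kernels <- adapt_kernels(fx$input_shape, spec$conv_kernels)
  model <- build_cnn(spec, fx$input_shape, seed = child_seed(seed, 303L))
  model <- train_cnn(model, fx$X, fx$labels, train_idx = split$train_idx,
                     seed = child_seed(seed, 404L))
  model$fingerprint <- config$fingerprint
  model$algorithm <- algo$id
  pred <- predict(model, fx$X[, split$test_idx, drop = FALSE])
  truth <- factor(as.character(fx$labels[split$test_idx]),
                  levels = fm_classes())
  cm <- confusion_matrix3(truth, pred$labels)
  structure(
    list(algorithm = algo$id, cm = cm, rates = per_class_rates(cm),
         fingerprint = config$fingerprint, seed = as.integer(seed),
         n_train = length(split$train_idx), n_test = length(split$test_idx),
         class_counts = as.integer(table(fx$labels)[fm_classes()]),
         model = if (keep_model) model else NULL),
    class = "fetmov_eval"
  )
}

# Training-mode segmentation over a whole corpus, on the trace type the
# algorithm variant requires.
segment_corpus <- function(corpus, algo, config, seed) {
  traces <- lapply(corpus$sessions$session, function(s) {
    tr <- select_z_axis(s)
    if (algo$use_filter) highpass_filter(tr, structure(config$filter,
                                                       class = "fetmov_filter_spec"))
    else tr
  })
  n_resp <- corpus$sessions$n_respiratory %||% corpus$n_respiratory_per_session
  build_training_set(
    traces, corpus$sessions$session,
    search_back_s = config$search_back_s,
    n_respiratory_per_session = n_resp,
    seed = child_seed(seed, 101L),
    session_ids = corpus$sessions$session_id
  )
}

#' Serialize an evaluation report to JSON
#'
#' Writes the report's deterministic fields (no timings, no model) so that
#' identical runs produce byte-identical files.
#'
#' @param report A `fetmov_eval`.
#' @param path Output path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
eval_report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "fetmov_eval"))
  obj <- list(
    algorithm = report$algorithm,
    fingerprint = report$fingerprint,
    seed = report$seed,
    n_train = report$n_train,
    n_test = report$n_test,
    class_counts = report$class_counts,
    confusion = unclass(report$cm),
    rates = report$rates
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(as.character(js), path)
  invisible(js)
}

#' Compare algorithm variants on one corpus
#'
#' Runs each requested variant under a shared seed, so the variants see
#' identical splits and differ only where their definitions differ.
#' Segmentations are computed once per trace type (raw/filtered) and
#' shared. With `scope = "per_subject"` each variant is additionally
#' trained and tested within each subject (the local-training contrast);
#' subjects lacking at least two realizations of every class are skipped
#' with a warning.
#'
#' @param corpus A `fetmov_corpus`.
#' @param algo_ids Character vector among `"A1".."A4"`.
#' @param scope `"global"` or `"per_subject"`.
#' @param config A [pipeline_config()].
#' @param seed Shared integer seed.
#' @return A tibble with one row per run: `algorithm`, `subject_id`
#'   (`"all"` for global scope), accuracy, class-1 TPR/FPR, and the full
#'   report in a `report` list-column.
#' @export
compare_algorithms <- function(corpus, algo_ids = c("A1", "A2"),
                               scope = c("global", "per_subject"),
                               config = pipeline_config(), seed = 1L) {
  scope <- match.arg(scope)
  algos <- lapply(algo_ids, algorithm_spec)
  seg_cache <- list()
  seg_for <- function(cp, algo) {
    key <- if (algo$use_filter) "filtered" else "raw"
    key <- paste(key, cp$sessions$session_id[1], nrow(cp$sessions))
    if (is.null(seg_cache[[key]])) {
      seg_cache[[key]] <<- segment_corpus(cp, algo, config, seed)
    }
    seg_cache[[key]]
  }
  run_one <- function(cp, algo, subject_id) {
    rep <- run_algorithm(cp, algo, config, seed = seed, keep_model = FALSE,
                         .realizations = seg_for(cp, algo))
    dplyr::mutate(glance(rep), subject_id = subject_id, .after = 1) |>
      dplyr::mutate(report = list(rep))
  }
  if (scope == "global") {
    return(dplyr::bind_rows(lapply(algos, run_one, cp = corpus,
                                   subject_id = "all")))
  }
  if (dplyr::n_distinct(corpus$sessions$subject_id) < 2L) {
    abort("per_subject scope needs at least 2 subjects")
  }
  out <- list()
  for (sid in unique(corpus$sessions$subject_id)) {
    sub <- corpus
    sub$sessions <- corpus$sessions[corpus$sessions$subject_id == sid, ]
    counts <- tryCatch(
      table(seg_for(sub, algos[[1]])$label)[fm_classes()],
      error = function(e) NULL
    )
    if (is.null(counts) || any(is.na(counts)) || any(counts < 2L)) {
      warn(sprintf("subject %s lacks >= 2 realizations of every class; skipped", sid))
      next
    }
    for (algo in algos) out[[length(out) + 1L]] <- run_one(sub, algo, sid)
  }
  dplyr::bind_rows(out)
}

#' Detect fetal movements in a single session
#'
#' Application mode: segments the session by amplitude threshold, extracts
#' features for the model's algorithm variant, classifies every candidate
#' window, and reports the kick count (windows classified as fetal
#' movement) with their times. The model refuses to run under a
#' configuration other than the one it was trained with.
#'
#' @param session A [fm_session()].
#' @param model A trained `fetmov_cnn` from [run_algorithm()].
#' @param config The [pipeline_config()] used at training time.
#' @param seed Integer seed (NNMF starts for A3/A4 features).
#' @return List with `kick_count`, and `events`: a tibble of all candidate
#'   windows (`origin_idx`, `time_s`, `label`, `prob_fetal`).
#' @export
run_detection <- function(session, model, config = pipeline_config(),
                          seed = 1L) {
  stopifnot(inherits(session, "fetmov_session"), inherits(model, "fetmov_cnn"))
  if (is.null(model$fingerprint) || !identical(model$fingerprint,
                                               config$fingerprint)) {
    abort("config fingerprint does not match the one the model was trained with")
  }
  algo <- algorithm_spec(model$algorithm)
  tr <- select_z_axis(session)
  if (algo$use_filter) {
    tr <- highpass_filter(tr, structure(config$filter,
                                        class = "fetmov_filter_spec"))
  }
  peaks <- detect_candidate_peaks(tr, threshold = config$threshold,
                                  min_separation = config$min_separation)
  peaks <- peaks[peaks >= 101L & peaks <= length(tr$z) - 99L]
  if (!length(peaks)) {
    return(list(kick_count = 0L,
                events = tibble(origin_idx = integer(), time_s = numeric(),
                                label = factor(character(),
                                               levels = fm_classes()),
                                prob_fetal = numeric())))
  }
  reals <- dplyr::bind_rows(lapply(peaks, function(p) {
    extract_window(tr, p, "unlabeled")
  }))
  fx <- featurize(reals, algo, config, fs = session$fs, seed = seed)
  pred <- predict(model, fx$X)
  events <- tibble(
    origin_idx = reals$origin_idx,
    time_s = (reals$origin_idx - 1L) / session$fs,
    label = pred$labels,
    prob_fetal = pred$probs[, "fetal"]
  )
  list(kick_count = sum(events$label == "fetal"), events = events)
}
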