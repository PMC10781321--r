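#' Write an EEG record as a delimited text file
#'
#' Columns: `time_s`, `TP9`, `AF7`, `AF8`, `TP10`.
#'
#' @param record An [eeg_record()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "eeg_record"))
  S <- ncol(record$data)
  df <- data.frame(time_s = (seq_len(S) - 1) / record$sampling_rate)
  for (ch in eeg_channels()) df[[ch]] <- record$data[ch, ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an EEG record from a delimited text file
#'
#' Expects a header with `time_s` and the four channel columns in any
#' order; channels are mapped to canonical order by name. The sampling rate
#' is inferred from the time column and cross-checked against
#' `sampling_rate` when supplied (a mismatch above 0.1\% is an error).
#'
#' @param path CSV file.
#' @param sampling_rate Expected sampling rate in Hz (e.g. from a dataset
#'   manifest), or `NULL` to accept the inferred one.
#' @param label Optional class label to attach.
#' @return An [eeg_record()].
#' @export
read_record <- function(path, sampling_rate = NULL, label = NA_character_) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("time_s", eeg_channels())
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("file ", path, " is missing column(s): ", paste(miss, collapse = ", "))
  for (cl in need) {
    v <- df[[cl]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))[1L]
      stop("non-numeric value in column ", cl, " at data line ",
           if (is.na(bad)) "?" else bad, " of ", path)
    }
    if (anyNA(v)) stop("missing value in column ", cl, " at data line ",
                       which(is.na(v))[1L], " of ", path)
  }
  tt <- df$time_s
  if (nrow(df) < 2L) stop("record in ", path, " has fewer than 2 samples")
  dt <- diff(tt)
  if (any(dt <= 0))
    stop("non-monotone time column in ", path, " at data line ",
         which(dt <= 0)[1L] + 1L)
  sr_inferred <- 1 / stats::median(dt)
  if (!is.null(sampling_rate) &&
      abs(sr_inferred - sampling_rate) / sampling_rate > 1e-3)
    stop("sampling rate inferred from time column (", signif(sr_inferred, 6),
         " Hz) disagrees with the declared rate (", sampling_rate,
         " Hz) by more than 0.1%")
  eeg_record(t(as.matrix(df[eeg_channels()])),
             sampling_rate = sampling_rate %||% sr_inferred, label = label)
}

#' Write / read a dataset directory
#'
#' Each record becomes `rec_<i>.csv`; `manifest.json` stores the generation
#' parameters, sampling rate, seed and the file-to-label mapping.
#'
#' @param dataset An [eeg_dataset()].
#' @param dir Dataset directory.
#' @return `dir` (write) or an [eeg_dataset()] (read).
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "eeg_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(dataset$records)
  files <- sprintf("rec_%04d.csv", seq_len(n))
  for (i in seq_len(n))
    write_record(dataset$records[[i]], file.path(dir, files[i]))
  manifest <- dataset$manifest
  manifest$files <- stats::setNames(as.list(dataset_labels(dataset)), files)
  manifest$sampling_rate <- manifest$sampling_rate %||%
    (if (n) dataset$records[[1L]]$sampling_rate else NULL)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  files <- names(manifest$files)
  records <- lapply(files, function(f)
    read_record(file.path(dir, f), sampling_rate = manifest$sampling_rate,
                label = manifest$files[[f]]))
  manifest$files <- NULL
  eeg_dataset(records, manifest)
}

#' Pipeline configuration
#'
#' Bundles every stage's configuration. Per-stage seeds are derived from
#' `seed` by fixed offsets (generation: seed; autoencoder: seed + 1;
#' classifiers: seed + 2; split: seed + 3; workload: seed + 4) so each stage
#' is independently reproducible.
#'
#' @param out_dir Output directory for all artifacts.
#' @param synthetic A [synthetic_spec()] (set `NULL` and give `data_dir` to
#'   use on-disk data instead).
#' @param data_dir Existing dataset directory read with [read_dataset()].
#' @param filter A [filter_config()].
#' @param train A [train_config()] (its seed is overridden by `seed + 1`).
#' @param topology A [fog_topology()].
#' @param workload A [fog_workload()].
#' @param seed Global pipeline seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("fogbci_run_"),
                            synthetic = synthetic_spec(),
                            data_dir = NULL,
                            filter = filter_config(),
                            train = train_config(),
                            topology = default_fog_topology(),
                            workload = fog_workload(),
                            seed = 7L) {
  structure(list(out_dir = out_dir, synthetic = synthetic, data_dir = data_dir,
                 filter = filter, train = train, topology = topology,
                 workload = workload, seed = as.integer(seed)),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full decoding pipeline
#'
#' Executes, in order: synthetic generation (or dataset loading), band-pass
#' filtering and standardization, autoencoder training, dataset encoding,
#' the four-classifier benchmark, latent-space analysis, and the fog versus
#' cloud latency simulation. Artifacts are written under `config$out_dir`
#' together with a `run_manifest.json` recording the seeds and parameters
#' actually used; a stage failure aborts with that stage's name while
#' preserving completed artifacts.
#'
#' @param config A [pipeline_config()].
#' @param verbose Print stage progress.
#' @return A `pipeline_report`: list with the fitted `autoencoder`, the
#'   `benchmark` result, the `latent` analysis, the `latency` comparison
#'   and the output paths.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(...)

  say("* stage: generate")
  dataset <- .stage("generate", {
    if (!is.null(config$data_dir)) read_dataset(config$data_dir)
    else {
      spec <- config$synthetic
      spec$seed <- config$seed
      ds <- generate_dataset(spec)
      write_dataset(ds, file.path(config$out_dir, "data"))
      ds
    }
  })

  say("* stage: train-autoencoder")
  ae <- .stage("train-autoencoder", {
    cfg <- config$train
    cfg$seed <- config$seed + 1L
    train_autoencoder(dataset, cfg, preprocess = TRUE, filter = config$filter)
  })
  .stage("train-autoencoder", save_autoencoder(ae, file.path(config$out_dir, "model")))

  say("* stage: encode")
  enc <- .stage("encode", encode_dataset(ae$encoder, dataset,
                                         preprocess = TRUE, filter = config$filter))
  .stage("encode", utils::write.table(
    enc$features, file.path(config$out_dir, "latent_features.tsv"),
    sep = "\t", row.names = FALSE, col.names = FALSE))

  say("* stage: benchmark")
  bench <- .stage("benchmark", evaluate_suite(
    dataset, ae$encoder, default_classifier_specs(seed = config$seed + 2L),
    split_seed = config$seed + 3L, filter = config$filter))
  .stage("benchmark", write_benchmark(bench, file.path(config$out_dir, "benchmark")))

  say("* stage: analyze-latent")
  rf_model <- .stage("analyze-latent", train_classifier(
    classifier_spec("RF", seed = config$seed + 2L),
    enc$features[bench$split$train, , drop = FALSE],
    enc$labels[bench$split$train]))
  latent <- .stage("analyze-latent", analyze_latent(
    enc$features, enc$labels, model = rf_model,
    out_dir = file.path(config$out_dir, "latent")))

  say("* stage: simulate-fog")
  wl <- config$workload
  wl$seed <- config$seed + 4L
  latency <- .stage("simulate-fog", compare_architectures(config$topology, wl))
  .stage("simulate-fog", write_latency_results(
    list(fog = latency$fog, cloud = latency$cloud),
    file.path(config$out_dir, "latency")))

  manifest <- list(
    package_version = as.character(utils::packageVersion("fogbci")),
    seed = config$seed,
    stage_seeds = list(generate = config$seed, autoencoder = config$seed + 1L,
                       classifiers = config$seed + 2L, split = config$seed + 3L,
                       workload = config$seed + 4L),
    n_records = length(dataset$records),
    sampling_rate = dataset$records[[1L]]$sampling_rate,
    synthetic = if (is.null(config$data_dir))
      unclass(config$synthetic)[c("n_records", "sampling_rate", "duration",
                                  "noise_exponent", "base_amplitude",
                                  "separation", "osc_amplitude")],
    workload = unclass(config$workload),
    filter = unclass(config$filter), train = unclass(config$train),
    accuracy = as.list(bench$accuracy),
    fog_mean_ms = latency$fog_mean_ms, cloud_mean_ms = latency$cloud_mean_ms)
  jsonlite::write_json(manifest, file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  structure(list(autoencoder = ae, benchmark = bench, latent = latent,
                 latency = latency, dataset = dataset,
                 out_dir = config$out_dir, manifest = manifest),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("fogbci pipeline run ->", x$out_dir, "\n")
  cat("Held-out accuracy:\n")
  print(round(x$benchmark$accuracy, 3))
  cat(sprintf("Latency: fog %.2f ms vs cloud %.2f ms (ratio %.2f)\n",
              x$latency$fog_mean_ms, x$latency$cloud_mean_ms, x$latency$ratio))
  invisible(x)
}
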