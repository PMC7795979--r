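#' Default run configuration
#'
#' All parameters of an end-to-end run, as a flat named list. Every source
#' of randomness has an explicit seed; nothing is seeded from the clock.
#'
#' @return Named list of defaults: the Z1 design (200 frames per class at
#'   15 m/s), 640 x 360 frames, 5 x 5 Kirsch kernels, 8 grey levels at
#'   distance 1, one hidden-size candidate (23), the BP50 + CG257
#'   training schedule, and fixed seeds for generation, splitting and
#'   weight initialisation.
#' @export
default_run_config <- function() {
  list(set = "Z1", n_per_class = NA_real_, width = 640, height = 360,
       seed_count = 12, noise_sd = 1.0, blur_k = 0.4,
       kirsch_size = 5, levels = 8, distance = 1,
       hidden = 23, bp_epochs = 50, bp_learning_rate = 0.2,
       cg_max_iter = 257,
       seed_generate = 101, seed_split = 202, seed_init = 303,
       write_frames = FALSE, out_dir = "seedtex_run")
}

#' Read a run configuration from a key = value text file
#'
#' Lines are `key = value`; blank lines and lines starting with `#` are
#' ignored. Comma-separated values become numeric vectors (e.g.
#' `hidden = 6, 23`); `true`/`false` become logicals. Unknown keys are an
#' error; missing keys take their defaults from [default_run_config()].
#'
#' @param path config file path.
#' @return Named list, as [default_run_config()].
#' @export
read_run_config <- function(path) {
  cfg <- default_run_config()
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    if (!key %in% names(cfg)) stop("unknown config key: ", key, call. = FALSE)
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    cfg[[key]] <- if (!anyNA(num)) num
      else if (length(parts) == 1L && tolower(parts) %in% c("true", "false"))
        tolower(parts) == "true"
      else val
  }
  cfg
}

config_counts <- function(config) {
  if (!is.na(config$n_per_class[1])) {
    design <- set_design(config$set)
    design$n_frames <- as.integer(config$n_per_class)
    design
  } else {
    set_design(config$set)
  }
}

config_text <- function(config) {
  vals <- vapply(config, function(v) paste(format(v, digits = 15),
                                           collapse = ", "), character(1))
  paste0(names(config), " = ", vals, collapse = "\n")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(config_text(config), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline: generate, preprocess, extract, split, train, stats
#'
#' Executes all stages in order and writes every artifact to the run
#' directory: `features.csv`, `split.csv`, `model.json`, `report.json`,
#' `correlation.csv`, `pca.csv` and `manifest.json` (plus the generated
#' frames and ground truth when `write_frames` is on, and a `run.log` with
#' per-stage timings). Rerunning with the same configuration reproduces all
#' CSV/JSON artifacts byte-identically.
#'
#' @param config a configuration list from [default_run_config()] or
#'   [read_run_config()].
#' @return The run directory path, invisibly; the manifest as attribute
#'   `manifest`.
#' @export
run_experiment <- function(config = default_run_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$out_dir, "run.log")
  cat("", file = logf)
  t_all <- proc.time()[3]
  stage <- function(name, code) {
    t0 <- proc.time()[3]
    out <- tryCatch(force(code), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    cat(sprintf("%-10s %8.2f s\n", name, proc.time()[3] - t0),
        file = logf, append = TRUE)
    out
  }

  counts <- config_counts(config)
  params <- generator_params(noise_sd = config$noise_sd,
                             blur_k = config$blur_k)

  dataset <- stage("generate", generate_dataset(
    counts, rng_seed = config$seed_generate, params = params,
    seed_count = config$seed_count, width = config$width,
    height = config$height))
  if (isTRUE(config$write_frames)) {
    stage("frames", write_dataset(dataset, file.path(config$out_dir, "frames")))
  }

  table <- stage("build", {
    tab <- build_table(dataset, name = config$set,
                       kirsch_size = config$kirsch_size,
                       levels = config$levels, distance = config$distance)
    if (nrow(tab) == 0L) stop("no training cases were produced")
    tab
  })
  write_feature_csv(table, file.path(config$out_dir, "features.csv"))

  split <- stage("split", split_2_1_1(table, config$seed_split))
  write_feature_csv(split, file.path(config$out_dir, "split.csv"))

  best <- stage("train", {
    candidates <- lapply(seq_along(config$hidden), function(i) {
      mlp_train(mlp_init(config$hidden[i],
                         rng_seed = config$seed_init + i - 1L),
                split, bp_epochs = config$bp_epochs,
                bp_learning_rate = config$bp_learning_rate,
                cg_max_iter = config$cg_max_iter)
    })
    select_best(candidates)
  })
  mlp_to_json(best$model, file.path(config$out_dir, "model.json"))
  jsonlite::write_json(best$report, file.path(config$out_dir, "report.json"),
                       digits = NA, auto_unbox = TRUE)

  st <- stage("stats", stats_summary(table))
  write.csv(as.data.frame(unclass(st$correlation)),
            file.path(config$out_dir, "correlation.csv"))
  pca_df <- data.frame(component = paste0("PC", seq_along(st$pca$eigenvalues)),
                       variance = st$pca$eigenvalues,
                       pct_var = st$pca$pct_var,
                       cum_pct_var = st$pca$cum_pct_var)
  write.csv(pca_df, file.path(config$out_dir, "pca.csv"), row.names = FALSE)

  manifest <- list(
    config = config, config_hash = config_hash(config),
    n_cases = nrow(table),
    split_sizes = c(train = nrow(split$train),
                    validation = nrow(split$validation),
                    test = nrow(split$test)),
    selected_hidden = best$model$hidden,
    quality_test = best$report$quality_test,
    rms_validation = best$report$rms_validation,
    kaiser = st$kaiser, strongest_variable = st$strongest$variable)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  cat(sprintf("%-10s %8.2f s\n", "total", proc.time()[3] - t_all),
      file = logf, append = TRUE)
  structure(invisible(config$out_dir), manifest = manifest)
}
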