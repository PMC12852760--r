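## Format round-tripping (NIfTI, TIFF, delimited, shape text), YAML run
## configuration and the pipeline entry points tying the modules together.

#' Write and read image stacks
#'
#' Stacks are stored time-last (rows x cols x time) in NIfTI; the package's
#' in-memory convention is time x rows x cols. The TIFF writer stores one
#' 32-bit float page per time point, rescaled to `[0, 1]` with the affine
#' rescaling recorded in a JSON sidecar (`<path>.json`) so the roundtrip is
#' lossless to float precision.
#'
#' @param stack numeric 3-D array, time x rows x cols.
#' @param path output path (`.nii`/`.nii.gz`, or `.tif`).
#' @return `write_*` return `path` invisibly; `read_*` return the stack as
#'   time x rows x cols.
#' @export
write_stack_nifti <- function(stack, path) {
  arr <- aperm(stack, c(2, 3, 1))
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}

#' @rdname write_stack_nifti
#' @export
read_stack_nifti <- function(path) {
  if (!file.exists(path)) stop("read_stack_nifti: file not found: ", path)
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) == 2) arr <- array(arr, c(dim(arr), 1))
  aperm(arr, c(3, 1, 2))
}

#' @rdname write_stack_nifti
#' @export
write_stack_tiff <- function(stack, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("write_stack_tiff: the 'tiff' package is required")
  lo <- min(stack); hi <- max(stack)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(stack)[1]),
                  function(i) (stack[i, , ] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  jsonlite::write_json(list(offset = lo, scale = scale, n_time = dim(stack)[1]),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack_nifti
#' @export
read_stack_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("read_stack_tiff: the 'tiff' package is required")
  if (!file.exists(path)) stop("read_stack_tiff: file not found: ", path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, c(length(pages), dim(pages[[1]])[1], dim(pages[[1]])[2]))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]] * meta$scale + meta$offset
  arr
}

#' Load an artifact by format
#'
#' Uniform loader over the package's artifact formats, used for round-trip
#' checks: `"NIfTI"` and `"TIFF"` return stacks (time x rows x cols),
#' `"shape-text"` returns an [rf_shape()], `"delimited"` returns a tibble.
#'
#' @param path file to read.
#' @param format one of `"NIfTI"`, `"TIFF"`, `"shape-text"`, `"delimited"`.
#' @return The loaded object.
#' @export
load_artifact <- function(path, format = c("NIfTI", "TIFF", "shape-text", "delimited")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("load_artifact: file not found: ", path)
  switch(format,
         "NIfTI" = read_stack_nifti(path),
         "TIFF" = read_stack_tiff(path),
         "shape-text" = read_shape(path),
         "delimited" = tibble::as_tibble(
           utils::read.delim(path, comment.char = "#")))
}

## ---------------------------------------------------------------------------
## Run configuration

pipeline_commands <- c("simulate-table", "export-shapes", "make-phantom",
                       "fit-maps", "contrast-report")

#' Read and validate a pipeline run configuration
#'
#' Configurations are YAML with top-level fields `command` (one of
#' `simulate-table`, `export-shapes`, `make-phantom`, `fit-maps`,
#' `contrast-report`), `seed` (integer), `output_dir` and an optional
#' `parameters` mapping of stage-specific settings.
#'
#' @param path YAML file path.
#' @return A validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("read_run_config: file not found: ", path)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg a config list (as from [read_run_config()] or built in code).
#' @export
validate_run_config <- function(cfg) {
  if (is.null(cfg$command) || !cfg$command %in% pipeline_commands)
    stop("run config: unknown or missing command '", cfg$command %||% "",
         "'; expected one of ", paste(pipeline_commands, collapse = ", "))
  if (is.null(cfg$output_dir)) stop("run config: output_dir is required")
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$parameters <- cfg$parameters %||% list()
  class(cfg) <- "run_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_sidecar <- function(dir, cfg, extra = list()) {
  side <- c(list(command = cfg$command, seed = cfg$seed,
                 parameters = cfg$parameters,
                 package = "raffsim",
                 version = as.character(utils::packageVersion("raffsim"))),
            extra)
  jsonlite::write_json(side, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Execute a pipeline stage
#'
#' Runs the stage named in the configuration and writes its artifacts plus a
#' deterministic provenance sidecar (`provenance.json`: config echo, seed,
#' package version) into `output_dir`. Identical configuration and seed give
#' byte-identical artifacts.
#'
#' Stages: `simulate-table` (method x scenario R/SS table, `table.tsv`);
#' `export-shapes` (RF shape files per method); `make-phantom` (phantom
#' series as NIfTI plus region masks and ground truth); `fit-maps`
#' (pixel-wise relaxation and SS maps from a `make-phantom` directory);
#' `contrast-report` (ROI means and RRTD from a `fit-maps` directory).
#'
#' @param cfg a `run_config` (or plain list validated on entry).
#' @return Invisibly, a character vector of written artifact paths.
#' @export
run_config <- function(cfg) {
  cfg <- validate_run_config(unclass(cfg))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  p <- cfg$parameters
  out <- switch(cfg$command,
    "simulate-table" = {
      tab <- simulate_relaxation_table(
        scenarios = p$scenarios %||% c("Fn1 healthy", "Fn1 upregulated"),
        methods = p$methods %||% raff_methods(),
        max_packets = p$max_packets %||% 64,
        n_timepoints = p$n_timepoints %||% 33,
        signal = p$signal %||% "magnitude",
        n_samples = p$n_samples %||% 128)
      # one row per method, scenarios spread into R_*/SS_* columns
      wide <- tidyr::pivot_wider(tab, id_cols = "method",
                                 names_from = "scenario",
                                 values_from = c("R", "SS"))
      write_tsv(wide, file.path(cfg$output_dir, "table.tsv"))
    },
    "export-shapes" = {
      methods <- p$methods %||% raff_methods()
      dialect <- p$dialect %||% "plain"
      paths <- character(0)
      for (m in methods) {
        pk <- method_packet(m, n_samples = p$n_samples %||% 128)
        f <- file.path(cfg$output_dir,
                       paste0(gsub("[^A-Za-z0-9.]+", "_", m), ".shape"))
        export_shape(pk$shape, f, dialect = dialect)
        paths <- c(paths, f)
      }
      paths
    },
    "make-phantom" = {
      spec <- phantom_spec(
        grid = unlist(p$grid %||% c(192, 192)),
        noise_sigma = p$noise_sigma %||% 0.01,
        noise_model = p$noise_model %||% "gaussian",
        region_params = if (!is.null(p$region_params))
          dplyr::bind_rows(p$region_params) else default_region_params(
            t_remote = p$t_remote %||% 0.045,
            mi_ratio = p$mi_ratio %||% 1.182),
        seed = cfg$seed)
      times <- p$times %||% seq(0, 0.07232, length.out = 9)
      ser <- synthesize_series(spec, times, polarity = "both")
      paths <- c(
        write_stack_nifti(ser$plus, file.path(cfg$output_dir, "phantom_plus.nii.gz")),
        write_stack_nifti(ser$minus, file.path(cfg$output_dir, "phantom_minus.nii.gz")))
      for (rg in names(ser$mask)) {
        f <- file.path(cfg$output_dir, paste0("mask_", rg, ".nii.gz"))
        write_stack_nifti(array(ser$mask[[rg]] * 1,
                                c(1, dim(ser$mask[[rg]]))), f)
        paths <- c(paths, f)
      }
      truth <- tibble::tibble(region = c("MI", "remote", "healthy"))
      truth <- dplyr::left_join(truth, spec$region_params, by = "region")
      paths <- c(paths,
                 write_tsv(truth, file.path(cfg$output_dir, "truth.tsv")))
      attr(paths, "times") <- times
      paths
    },
    "fit-maps" = {
      input <- p$input %||% stop("fit-maps: parameters$input directory required")
      side <- jsonlite::read_json(file.path(input, "provenance.json"),
                                  simplifyVector = TRUE)
      times <- as.numeric(side$times)
      plus <- read_stack_nifti(file.path(input, "phantom_plus.nii.gz"))
      minus <- read_stack_nifti(file.path(input, "phantom_minus.nii.gz"))
      myo <- read_stack_nifti(file.path(input, "mask_myocardium.nii.gz"))[1, , ] > 0.5
      mp <- fit_map(plus, times, model = p$model %||% "ss_model", mask = myo,
                    paired_stack = minus, method_label = p$method_label %||% "phantom")
      paths <- write_stack_nifti(array(mp$values, c(1, dim(mp$values))),
                                 file.path(cfg$output_dir, "map_T.nii.gz"))
      if (!is.null(mp$ss))
        paths <- c(paths, write_stack_nifti(array(mp$ss, c(1, dim(mp$ss))),
                                            file.path(cfg$output_dir, "map_SS.nii.gz")))
      attr(paths, "times") <- times
      paths
    },
    "contrast-report" = {
      input <- p$input %||% stop("contrast-report: parameters$input (fit-maps dir) required")
      masks_dir <- p$masks %||% input
      Tmap <- read_stack_nifti(file.path(input, "map_T.nii.gz"))[1, , ]
      mask <- list(
        MI = read_stack_nifti(file.path(masks_dir, "mask_MI.nii.gz"))[1, , ] > 0.5,
        remote = read_stack_nifti(file.path(masks_dir, "mask_remote.nii.gz"))[1, , ] > 0.5)
      mp <- new_relax_map(Tmap, NULL, NULL, is.finite(Tmap),
                          p$method_label %||% "map", "s")
      rep <- contrast_report(stats::setNames(list(mp), mp$method_label), mask)
      write_tsv(rep, file.path(cfg$output_dir, "contrast_report.tsv"))
    })
  extra <- list()
  if (!is.null(attr(out, "times"))) extra$times <- attr(out, "times")
  write_sidecar(cfg$output_dir, cfg, extra)
  invisible(c(out, file.path(cfg$output_dir, "provenance.json")))
}

#' @rdname run_config
#' @param path YAML config path.
#' @export
run_pipeline_file <- function(path) {
  run_config(read_run_config(path))
}
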