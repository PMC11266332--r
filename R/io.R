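#' Load a study configuration from YAML
#'
#' Reads a YAML configuration, fills documented defaults (grid
#' reductions 0/17/33/50/67%, penalisation factors 150/300/450/600,
#' score threshold 2, detectability threshold 90%, PET/MR-like acquisition,
#' seed 1) and validates it. Unknown keys are rejected with their path.
#'
#' @param path Path to a YAML file; an empty file yields all defaults.
#' @return A `study_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  defaults <- list(
    seed = 1L,
    betas = c(150, 300, 450, 600),
    reductions = c(0, 0.17, 0.33, 0.50, 0.67),
    score_threshold = 2,
    detectability_threshold = 90,
    sigma_ref_mm = 3,
    phantom = list(ratio = "4:1"),
    acquisition = list(
      time_per_bed_s = 180,
      sensitivity_cps_per_kBq = 21,
      psf_fwhm_mm = 4.2,
      voxel_size_mm = c(2.34, 2.34, 2.78),
      matrix = c(256, 256),
      half_life_min = 67.71
    ),
    output_dir = "."
  )
  check_keys <- function(x, allowed, prefix = "") {
    extra <- setdiff(names(x), allowed)
    if (length(extra)) {
      stop("unknown config key: ", prefix, extra[1], call. = FALSE)
    }
  }
  check_keys(raw, names(defaults))
  check_keys(raw$phantom %||% list(), names(defaults$phantom), "phantom.")
  check_keys(raw$acquisition %||% list(), names(defaults$acquisition),
             "acquisition.")
  cfg <- utils::modifyList(defaults, raw)

  if (any(cfg$reductions < 0 | cfg$reductions >= 1)) {
    stop("invalid config field reductions: must be in [0, 1)", call. = FALSE)
  }
  if (any(cfg$betas < 0)) {
    stop("invalid config field betas: must be >= 0", call. = FALSE)
  }
  for (f in c("time_per_bed_s", "sensitivity_cps_per_kBq", "half_life_min")) {
    if (any(cfg$acquisition[[f]] <= 0)) {
      stop("invalid config field acquisition.", f, ": must be > 0", call. = FALSE)
    }
  }
  if (any(cfg$acquisition$voxel_size_mm <= 0)) {
    stop("invalid config field acquisition.voxel_size_mm: must be > 0",
         call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "study_config")
}

format_numeric_cols <- function(df) {
  df[] <- lapply(df, function(col) {
    if (is.double(col)) sprintf("%.10g", col) else col
  })
  df
}

#' Write study reports
#'
#' Writes the long metric table and the selection result as RFC-4180 CSV
#' (fixed `%.10g` numeric precision, so write/read/write round-trips are
#' byte-identical) plus a machine-readable JSON summary.
#'
#' @param grid A `phantom_grid` or `patient_grid` tibble (or any metric
#'   tibble).
#' @param selection Optional [select_optimal_beta()] result.
#' @param dir Output directory, created if needed.
#' @return Named character vector of the files written, invisibly.
#' @export
write_report <- function(grid, selection = NULL, dir = ".") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(records = file.path(dir, "iq_records.csv"))
  utils::write.csv(format_numeric_cols(as.data.frame(grid)),
                   files[["records"]], row.names = FALSE, quote = FALSE)
  report <- list(n_records = nrow(grid))
  if (!is.null(selection)) {
    files[["selection"]] <- file.path(dir, "selection.csv")
    utils::write.csv(format_numeric_cols(as.data.frame(selection$optimal)),
                     files[["selection"]], row.names = FALSE, quote = FALSE)
    report$optimal <- selection$optimal
    report$thresholds <- attr(selection, "thresholds")
    report$reference <- attr(selection, "reference")
  }
  files[["report"]] <- file.path(dir, "report.json")
  jsonlite::write_json(report, files[["report"]], auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(files)
}

#' Read a metric table written by [write_report()]
#'
#' @param path Path to the CSV file.
#' @return A tibble.
#' @export
read_iq_records <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}
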