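#' Batch-run configuration
#'
#' Collects everything a batch quantification run needs: the input images,
#' the calibration pair, the kernel, acquisition magnification and output
#' location. Can be built in code or read from a YAML file.
#'
#' @param images Character vector of image paths, or a glob pattern.
#' @param brightfield,darkfield Calibration image paths (required for the
#'   stain assays, ignored by confluency and LIVE/DEAD).
#' @param kernel A `stain_kernel`, a preset name (see [kernel_preset()]),
#'   or a kernel YAML path.
#' @param magnification 10 or 20 (sets the adaptive region size).
#' @param min_area Minimum dead-cell component area (px).
#' @param offset Confluency threshold offset.
#' @param out_dir Output directory for CSV/log/manifest.
#' @param seed Integer seed recorded in the manifest.
#' @param filename_template Template for parsing metadata out of file
#'   names, e.g. `"{donor}_{condition}_{system}_{day}"`.
#' @return List of class `run_config`.
#' @export
run_config <- function(images, brightfield = NULL, darkfield = NULL,
                       kernel = NULL, magnification = 10, min_area = 10L,
                       offset = 0.07, out_dir = tempdir(), seed = 1,
                       filename_template = "{donor}_{condition}_{system}_{day}") {
  if (length(images) == 1L && grepl("[*?]", images)) images <- Sys.glob(images)
  structure(list(images = images, brightfield = brightfield,
                 darkfield = darkfield, kernel = kernel,
                 magnification = magnification, min_area = as.integer(min_area),
                 offset = offset, out_dir = out_dir, seed = as.integer(seed),
                 filename_template = filename_template),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML config path.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

resolve_kernel <- function(kernel) {
  if (is.null(kernel)) return(NULL)
  if (inherits(kernel, "stain_kernel")) return(kernel)
  if (is.character(kernel)) {
    if (file.exists(kernel)) return(read_kernel(kernel))
    return(kernel_preset(kernel))
  }
  stop("kernel must be a stain_kernel, preset name, or kernel file path")
}

#' Parse donor/condition/system/day metadata from file names
#'
#' The template's `{field}` placeholders are turned into a regular
#' expression matched against the file base name (underscore-free fields).
#' Unmatched files get `NA` metadata.
#'
#' @param paths File paths.
#' @param template Template string, default
#'   `"{donor}_{condition}_{system}_{day}"`.
#' @return Tibble with `file` and one column per template field.
#' @export
parse_filename_metadata <- function(paths,
                                    template = "{donor}_{condition}_{system}_{day}") {
  fields <- regmatches(template, gregexpr("\\{[a-z_]+\\}", template))[[1]]
  fields <- gsub("[{}]", "", fields)
  rx <- gsub("\\{[a-z_]+\\}", "([^_]+)", template)
  rx <- paste0("^", rx, "$")
  base <- tools::file_path_sans_ext(basename(paths))
  m <- regmatches(base, regexec(rx, base))
  out <- tibble::tibble(file = paths)
  for (i in seq_along(fields))
    out[[fields[i]]] <- vapply(m, function(g)
      if (length(g) > i) g[i + 1] else NA_character_, character(1))
  out
}

#' Run one assay over a batch of images
#'
#' Applies the assay's quantification to every image in the config,
#' writing a tidy per-image results CSV, a run log (every skipped file and
#' warning), and a JSON manifest (config echo, seed, package version).
#' Unreadable or mis-shaped images are skipped with a logged error and the
#' run continues; an empty input set is an error.
#'
#' @param config A [run_config()].
#' @param assay One of `"adipogenic"`, `"chondrogenic"`, `"osteogenic"`,
#'   `"confluency"`, `"livedead"`.
#' @return Tibble of per-image results (also written to
#'   `<out_dir>/<assay>_results.csv`).
#' @export
run_assay <- function(config,
                      assay = c("adipogenic", "chondrogenic", "osteogenic",
                                "confluency", "livedead")) {
  assay <- match.arg(assay)
  if (!length(config$images)) stop("empty input set")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, paste0(...))
  needs_calib <- assay %in% c("adipogenic", "chondrogenic", "osteogenic")
  bf <- df_ <- NULL
  if (needs_calib) {
    if (is.null(config$brightfield) || is.null(config$darkfield))
      stop(assay, " assay requires brightfield and darkfield calibration images")
    bf <- read_image(config$brightfield)
    df_ <- read_image(config$darkfield)
  }
  kern <- resolve_kernel(config$kernel)
  if (is.null(kern) && assay == "adipogenic") kern <- kernel_preset("oilredo_hematoxylin")
  if (is.null(kern) && assay == "chondrogenic") kern <- kernel_preset("alcianblue_nfr")
  params <- adaptive_params(magnification = config$magnification)
  meta <- parse_filename_metadata(config$images, config$filename_template)
  rows <- list()
  for (i in seq_along(config$images)) {
    path <- config$images[i]
    row <- tryCatch({
      img <- read_image(path)
      withCallingHandlers(
        switch(assay,
          adipogenic = adipogenic_metrics(img, bf, df_, kern, params),
          chondrogenic = chondrogenic_metrics(img, bf, df_, kern),
          osteogenic = osteogenic_score(img, bf, df_),
          confluency = confluency(img, offset = config$offset),
          livedead = count_dead_cells(
            if (n_channels(img) == 3L) img[, , 1] else img,
            min_area = config$min_area)),
        warning = function(w) {
          note("warning [", basename(path), "]: ", conditionMessage(w))
          invokeRestart("muffleWarning")
        })
    }, error = function(e) {
      note("skipped [", basename(path), "]: ", conditionMessage(e))
      NULL
    })
    if (!is.null(row)) rows[[length(rows) + 1]] <- dplyr::bind_cols(meta[i, ], row)
  }
  out <- dplyr::bind_rows(rows)
  csv_path <- file.path(config$out_dir, paste0(assay, "_results.csv"))
  write.csv(out, csv_path, row.names = FALSE)
  writeLines(log_lines, file.path(config$out_dir, paste0(assay, "_run.log")))
  manifest <- list(assay = assay, seed = config$seed,
                   n_images = length(config$images), n_results = nrow(out),
                   magnification = config$magnification,
                   package_version = as.character(utils::packageVersion("stainquant")))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, paste0(assay, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE)
  out
}

#' Statistics stage of a batch run
#'
#' Takes one or more per-image results CSVs (or an in-memory tibble) with
#' donor/condition/day metadata, runs the Friedman/Wilcoxon battery on the
#' chosen metric, and optionally writes the test table and boxplot figure.
#'
#' @param results Tibble, or character vector of CSV paths from
#'   [run_assay()].
#' @param metric Column to analyze (e.g. `"dye_ratio"`, `"score"`,
#'   `"dead_count"`).
#' @param out_dir Output directory; `NULL` skips writing.
#' @param control Control condition label.
#' @param ... Passed to [cohort_tests()].
#' @return Tibble of test results.
#' @export
run_stats <- function(results, metric, out_dir = NULL, control = "control", ...) {
  if (is.character(results))
    results <- dplyr::bind_rows(lapply(results, function(p)
      utils::read.csv(p, stringsAsFactors = FALSE)))
  results <- tibble::as_tibble(results)
  if (!metric %in% names(results)) stop("no column '", metric, "' in results")
  if (all(is.na(results[[metric]]))) stop("metric column '", metric, "' is empty")
  if (!"culture_system" %in% names(results) && "system" %in% names(results))
    results$culture_system <- results$system
  if (!"day" %in% names(results)) results$day <- 1
  tests <- cohort_tests(results, value_col = metric, control = control, ...)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(tests, file.path(out_dir, paste0("stats_", metric, ".csv")),
              row.names = FALSE)
    p <- plot_cohort_boxplots(results, value_col = metric)
    ggplot2::ggsave(file.path(out_dir, paste0("boxplot_", metric, ".png")),
                    p, width = 8, height = 6, dpi = 120)
  }
  tests
}
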