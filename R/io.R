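## Dataset and configuration I/O. Datasets travel as CSV with an `x,y`
## header and a comment line carrying the generating spec as JSON;
## run configurations are YAML.

#' Write a dataset as CSV
#'
#' Writes `x,y` rows preceded by a `# spec: {...}` comment line holding
#' the generating [synth_spec()] as JSON, so a dataset file is
#' self-describing and round-trips through [read_dataset()].
#'
#' @param dataset a `kin_dataset`
#' @param path output file
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "kin_dataset"))
  spec <- dataset$spec
  spec_json <- jsonlite::toJSON(
    list(kind = spec$kind, true_params = spec$true_params,
         noise_sd = spec$noise_sd, noise_type = spec$noise_type,
         seed = spec$seed),
    auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# spec: ", spec_json), con)
  writeLines("x,y", con)
  writeLines(sprintf("%.15g,%.15g", dataset$x, dataset$y), con)
  invisible(path)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param path CSV file with optional `# spec:` header comment
#' @return a `kin_dataset` (spec reconstructed when present)
#' @export
read_dataset <- function(path) {
  lines <- readLines(path)
  spec <- NULL
  spec_line <- grep("^# spec:", lines, value = TRUE)
  if (length(spec_line)) {
    parsed <- jsonlite::fromJSON(sub("^# spec:\\s*", "", spec_line[1]),
                                 simplifyVector = TRUE)
    spec <- synth_spec(parsed$kind,
                       true_params = as.list(parsed$true_params),
                       grid = 1,  # placeholder, replaced below
                       noise_sd = parsed$noise_sd,
                       noise_type = parsed$noise_type,
                       seed = parsed$seed)
  }
  dat <- utils::read.csv(text = lines[!startsWith(lines, "#")])
  if (is.null(spec))
    spec <- synth_spec("actin_titration",
                       true_params = list(basal = 0, kcat = 1, KM = 1),
                       grid = dat$x)
  spec$grid <- dat$x
  structure(list(x = dat$x, y = dat$y, spec = spec),
            class = "kin_dataset")
}

#' Read a run configuration
#'
#' Run configurations are YAML with top-level keys `seed`, `output_dir`,
#' `tolerances` and an `experiments` list; see the file
#' `system.file("extdata", "default_config.yaml", package = "actokin")`
#' for the layout.
#'
#' @param path YAML file
#' @return the configuration as a nested list, validated
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop("missing input file: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  cfg$seed <- cfg$seed %||% 1L
  cfg$experiments <- cfg$experiments %||% list()
  cfg$tolerances <- cfg$tolerances %||% list(default = 0.1)
  tolv <- unlist(cfg$tolerances)
  if (any(tolv <= 0)) stop("tolerances must be > 0", call. = FALSE)
  cfg
}

#' Default run configuration
#'
#' The configuration shipped with the package: one experiment per
#' reference constant, at the module default grids and noise levels.
#'
#' @return parsed configuration list
#' @export
default_run_config <- function() {
  read_run_config(system.file("extdata", "default_config.yaml",
                              package = "actokin", mustWork = TRUE))
}
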