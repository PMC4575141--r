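# Reading and writing plate datasets and configurations.
#
# Datasets travel as long-format CSV with the fixed header
# plate_id,well,construct,condition,rlu (UTF-8, comma delimiter, "." decimal):
# every computation keys on (plate, construct, condition), so a tidy layout is
# the natural interchange format and a 96-well grid importer is out of scope.

#' Read a plate dataset from long-format CSV
#'
#' @param path Path to a CSV file with header
#'   `plate_id,well,construct,condition,rlu`. Extra columns are ignored with
#'   a warning. `condition` must contain only the literal strings
#'   `BASELINE` or `FORSKOLIN`.
#' @return A data frame of well measurements, one row per well.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path))
    stop("dataset file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  missing <- setdiff(DATASET_COLUMNS, names(df))
  if (length(missing))
    stop("dataset is missing required column(s): ",
         paste(missing, collapse = ", "))
  extra <- setdiff(names(df), DATASET_COLUMNS)
  if (length(extra))
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "))
  df <- df[DATASET_COLUMNS]

  rlu <- suppressWarnings(as.numeric(df$rlu))
  bad <- which(is.na(rlu) & !is.na(df$rlu) | is.na(df$rlu))
  if (length(bad))
    stop("non-numeric rlu at data line(s): ",
         paste(bad + 1L, collapse = ", "))  # +1 for the header line
  negv <- which(rlu < 0)
  if (length(negv))
    stop("negative rlu at data line(s): ", paste(negv + 1L, collapse = ", "))
  df$rlu <- rlu

  bad_cond <- which(!df$condition %in% CONDITIONS)
  if (length(bad_cond))
    stop("condition must be BASELINE or FORSKOLIN; offending line(s): ",
         paste(bad_cond + 1L, collapse = ", "))
  df
}

#' Write a plate dataset to long-format CSV
#'
#' Rows are emitted in a deterministic order (plate, construct, condition,
#' well) so that datasets compare byte-for-byte regardless of in-memory
#' ordering.
#'
#' @param wells A non-empty data frame of well measurements.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(wells, path) {
  check_wells(wells)
  if (nrow(wells) == 0L)
    stop("refusing to write an empty dataset")
  ord <- order(wells$plate_id, wells$construct, wells$condition, wells$well,
               method = "radix")
  out <- wells[ord, DATASET_COLUMNS]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a classifier/simulation configuration file
#'
#' Accepts a flat YAML or JSON mapping. Any missing key takes its documented
#' default (the published study's values: stimulation threshold +2.0,
#' inhibition thresholds -0.40, alpha 0.05, forskolin:baseline control ratio
#' 5.0). Unknown keys are an error so that misspelled settings cannot be
#' silently dropped.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file. An empty file yields
#'   all defaults.
#' @return A list with elements `classifier` (a [classifier_config()]),
#'   `simulation` (a [simulation_config()]) and `anova`
#'   (list with `error_term`).
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    if (!nzchar(trimws(txt))) list() else jsonlite::fromJSON(txt, simplifyVector = TRUE)
  } else {
    out <- yaml::read_yaml(path)
    if (is.null(out)) list() else out
  }
  if (!is.list(raw))
    stop("config must be a mapping of option names to values")
  build_config(raw)
}

CLASSIFIER_KEYS <- c("stimulation_threshold", "baseline_inhibition_threshold",
                     "forskolin_inhibition_threshold", "alpha",
                     "stimulation_as_fold")
SIMULATION_KEYS <- c("baseline_mean_rlu", "forskolin_ratio", "plate_effect_sd",
                     "well_noise_cv", "n_plates", "seed", "effect_jitter_sd")
ANOVA_KEYS <- c("error_term")

build_config <- function(raw) {
  valid <- c(CLASSIFIER_KEYS, SIMULATION_KEYS, ANOVA_KEYS)
  unknown <- setdiff(names(raw), valid)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "; valid keys are: ", paste(valid, collapse = ", "))
  cls <- raw[intersect(names(raw), CLASSIFIER_KEYS)]
  sim <- raw[intersect(names(raw), SIMULATION_KEYS)]
  anv <- raw[intersect(names(raw), ANOVA_KEYS)]
  list(
    classifier = do.call(classifier_config, cls),
    simulation = do.call(simulation_config, sim),
    anova = list(error_term = if (length(anv)) match.arg(anv$error_term,
                 c("residual", "interaction")) else "residual")
  )
}
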