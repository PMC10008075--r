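# Domain types, CSV readers/writers with schema validation, run configuration.
#
# A cohort bundles three tables:
#   responses:    long format, one row per (participant, descriptor) with a
#                 four-level classification
#   descriptors:  one row per named odor with its semantic variables
#   participants: one row per patient with clinical covariates
#
# Missing numeric cells are written as empty strings; "NA" is also accepted
# on read. Descriptor and participant order is the order of first appearance
# in their files and is preserved through the whole pipeline.

#' Response vocabulary of the odor-classification questionnaire
#'
#' Patients classify each named odor as smelling like it always does
#' (`normal`), smelling distorted (`qualitatively_different`), evoking no
#' smell at all (`odorless`), or being unfamiliar (`unknown`). Unknown
#' responses are treated as missing downstream.
#'
#' @return character vector of the four admissible response strings.
#' @export
response_categories <- function() {
  c("normal", "qualitatively_different", "odorless", "unknown")
}

# Declared scales for validation; NULL bound = unbounded.
.descriptor_ranges <- list(
  oai = c(-Inf, Inf), osi = c(-Inf, Inf),
  valence = c(1, 9), arousal = c(1, 9),
  olfactory = c(0, 5), gustatory = c(0, 5)
)

.participant_ranges <- list(
  age = c(0, 120), bmi = c(5, 100), tdi = c(0, 48), threshold = c(0, 17),
  duration_months = c(0, Inf), parosmia_intensity = c(0, 10),
  parosmia_consequences = c(0, 1), parosmia_valence = c(-5, 5),
  subjective_impairment = c(0, 10), importance_olfaction = c(0, Inf),
  depression_adsl = c(0, 60)
)

.participant_numeric <- names(.participant_ranges)

#' Construct a validated cohort object
#'
#' @param responses data frame with columns `participant_id`,
#'   `descriptor_id`, `response`.
#' @param descriptors data frame with columns `descriptor_id`, `label`,
#'   `oai`, `osi`, `valence`, `arousal`, `olfactory`, `gustatory`.
#' @param participants data frame with the participant covariates (see
#'   [load_cohort()] for the column list).
#' @return an object of class `parosim_cohort`: a list with the three
#'   validated tables. Row order of `descriptors` and `participants` defines
#'   the canonical descriptor/participant order everywhere downstream.
#' @export
new_cohort <- function(responses, descriptors, participants) {
  responses <- validate_responses(responses)
  descriptors <- validate_descriptors(descriptors)
  participants <- validate_participants(participants)

  bad_d <- !(responses$descriptor_id %in% descriptors$descriptor_id)
  if (any(bad_d)) {
    abort_validation(
      sprintf("response descriptor_id '%s' not present in descriptor table",
              responses$descriptor_id[which(bad_d)[1L]]),
      row = which(bad_d)[1L]
    )
  }
  bad_p <- !(responses$participant_id %in% participants$participant_id)
  if (any(bad_p)) {
    abort_validation(
      sprintf("response participant_id '%s' not present in participant table",
              responses$participant_id[which(bad_p)[1L]]),
      row = which(bad_p)[1L]
    )
  }
  key <- paste(responses$participant_id, responses$descriptor_id, sep = "\r")
  if (anyDuplicated(key)) {
    abort_validation(
      "duplicate (participant_id, descriptor_id) pair in responses",
      row = which(duplicated(key))[1L]
    )
  }
  structure(
    list(responses = responses, descriptors = descriptors,
         participants = participants),
    class = "parosim_cohort"
  )
}

#' @export
print.parosim_cohort <- function(x, ...) {
  cat(sprintf(
    "parosim cohort: %d participants x %d descriptors, %d responses\n",
    nrow(x$participants), nrow(x$descriptors), nrow(x$responses)
  ))
  tab <- table(factor(x$responses$response, levels = response_categories()))
  cat("  responses:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

validate_responses <- function(df, file = NULL) {
  need <- c("participant_id", "descriptor_id", "response")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort_validation(sprintf("responses table lacks column(s): %s",
                             paste(miss, collapse = ", ")), file = file)
  }
  df <- df[need]
  for (col in c("participant_id", "descriptor_id")) {
    df[[col]] <- as.character(df[[col]])
    bad <- is.na(df[[col]]) | !nzchar(df[[col]])
    if (any(bad)) {
      abort_validation(sprintf("empty %s in responses", col),
                       file = file, row = which(bad)[1L])
    }
  }
  df$response <- as.character(df$response)
  bad <- !(df$response %in% response_categories())
  if (any(bad)) {
    abort_validation(
      sprintf("response value '%s' is not one of {%s}",
              df$response[which(bad)[1L]],
              paste(response_categories(), collapse = ", ")),
      file = file, row = which(bad)[1L]
    )
  }
  rownames(df) <- NULL
  df
}

validate_descriptors <- function(df, file = NULL) {
  need <- c("descriptor_id", "label", names(.descriptor_ranges))
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort_validation(sprintf("descriptor table lacks column(s): %s",
                             paste(miss, collapse = ", ")), file = file)
  }
  df <- df[need]
  df$descriptor_id <- as.character(df$descriptor_id)
  bad <- is.na(df$descriptor_id) | !nzchar(df$descriptor_id)
  if (any(bad)) {
    abort_validation("empty descriptor_id", file = file, row = which(bad)[1L])
  }
  if (anyDuplicated(df$descriptor_id)) {
    abort_validation("duplicate descriptor_id",
                     file = file,
                     row = which(duplicated(df$descriptor_id))[1L])
  }
  df$label <- as.character(df$label)
  for (col in names(.descriptor_ranges)) {
    df[[col]] <- validate_numeric_column(df[[col]], col,
                                         .descriptor_ranges[[col]], file)
  }
  rownames(df) <- NULL
  df
}

validate_participants <- function(df, file = NULL) {
  need <- c("participant_id", "age", "sex", "bmi", "tdi", "threshold",
            "duration_months", "parosmia_intensity", "parosmia_frequency",
            "parosmia_consequences", "parosmia_valence",
            "subjective_impairment", "importance_olfaction",
            "depression_adsl")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort_validation(sprintf("participant table lacks column(s): %s",
                             paste(miss, collapse = ", ")), file = file)
  }
  df <- df[need]
  df$participant_id <- as.character(df$participant_id)
  bad <- is.na(df$participant_id) | !nzchar(df$participant_id)
  if (any(bad)) {
    abort_validation("empty participant_id", file = file, row = which(bad)[1L])
  }
  if (anyDuplicated(df$participant_id)) {
    abort_validation("duplicate participant_id", file = file,
                     row = which(duplicated(df$participant_id))[1L])
  }
  df$sex <- as.character(df$sex)
  bad <- !is.na(df$sex) & !(df$sex %in% c("F", "M"))
  if (any(bad)) {
    abort_validation(sprintf("sex value '%s' is not 'F' or 'M'",
                             df$sex[which(bad)[1L]]),
                     file = file, row = which(bad)[1L])
  }
  df$parosmia_frequency <- as.character(df$parosmia_frequency)
  bad <- !is.na(df$parosmia_frequency) &
    !(df$parosmia_frequency %in% c("daily", "not_daily"))
  if (any(bad)) {
    abort_validation(
      sprintf("parosmia_frequency value '%s' is not 'daily' or 'not_daily'",
              df$parosmia_frequency[which(bad)[1L]]),
      file = file, row = which(bad)[1L]
    )
  }
  for (col in .participant_numeric) {
    df[[col]] <- validate_numeric_column(df[[col]], col,
                                         .participant_ranges[[col]], file)
  }
  rownames(df) <- NULL
  df
}

validate_numeric_column <- function(x, col, range, file = NULL) {
  if (is.character(x)) {
    x[!is.na(x) & (x == "" | x == "NA")] <- NA_character_
    num <- suppressWarnings(as.numeric(x))
    bad <- !is.na(x) & is.na(num)
    if (any(bad)) {
      abort_validation(sprintf("column '%s': value '%s' is not numeric",
                               col, x[which(bad)[1L]]),
                       file = file, row = which(bad)[1L])
    }
    x <- num
  }
  x <- as.numeric(x)
  bad <- !is.na(x) & (x < range[1] | x > range[2])
  if (any(bad)) {
    abort_validation(
      sprintf("column '%s': value %s outside declared range [%s, %s]",
              col, format(x[which(bad)[1L]]), range[1], range[2]),
      file = file, row = which(bad)[1L]
    )
  }
  x
}

read_table_csv <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("input file '%s' does not exist", path), call. = FALSE)
  }
  utils::read.csv(path, colClasses = "character", na.strings = c("", "NA"),
                  check.names = FALSE)
}

#' Load and validate a cohort from three CSV files
#'
#' Reads the long-format response table, the descriptor semantic-variable
#' table, and the participant covariate table, validating each against its
#' schema (see the package README for the column lists). Validation errors
#' name the offending file, row, and rule; nothing is silently coerced.
#'
#' @param responses_path,descriptors_path,participants_path CSV paths.
#' @return a [new_cohort()] object.
#' @export
load_cohort <- function(responses_path, descriptors_path, participants_path) {
  responses <- validate_responses(read_table_csv(responses_path),
                                  file = responses_path)
  descriptors <- validate_descriptors(read_table_csv(descriptors_path),
                                      file = descriptors_path)
  participants <- validate_participants(read_table_csv(participants_path),
                                        file = participants_path)
  new_cohort(responses, descriptors, participants)
}

#' Write a cohort to three CSV files
#'
#' Inverse of [load_cohort()]: writes `responses.csv`, `descriptors.csv`,
#' and `participants.csv` into `dir`. Missing numeric cells are written as
#' empty strings.
#'
#' @param cohort a `parosim_cohort`.
#' @param dir output directory (created if absent).
#' @return named character vector of the three written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "parosim_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    responses = file.path(dir, "responses.csv"),
    descriptors = file.path(dir, "descriptors.csv"),
    participants = file.path(dir, "participants.csv")
  )
  write_csv_na(cohort$responses, paths[["responses"]])
  write_csv_na(cohort$descriptors, paths[["descriptors"]])
  write_csv_na(cohort$participants, paths[["participants"]])
  invisible(paths)
}

write_csv_na <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
}

#' Convert a wide response sheet to the long format
#'
#' Clinics often record one row per patient with one column per named odor.
#' This helper melts such a sheet into the long `(participant_id,
#' descriptor_id, response)` format expected by [load_cohort()]. Empty cells
#' become `unknown` when `empty_as_unknown` is `TRUE`, otherwise they error.
#'
#' @param wide data frame whose first column is `participant_id` and whose
#'   remaining column names are descriptor ids.
#' @param empty_as_unknown treat empty/NA cells as `unknown` responses.
#' @return long-format response data frame.
#' @export
wide_to_long <- function(wide, empty_as_unknown = TRUE) {
  if (!"participant_id" %in% names(wide)) {
    abort_validation("wide table lacks a participant_id column")
  }
  desc_cols <- setdiff(names(wide), "participant_id")
  if (!length(desc_cols)) abort_validation("wide table has no descriptor columns")
  long <- data.frame(
    participant_id = rep(as.character(wide$participant_id),
                         times = length(desc_cols)),
    descriptor_id = rep(desc_cols, each = nrow(wide)),
    response = as.character(unlist(wide[desc_cols], use.names = FALSE)),
    stringsAsFactors = FALSE
  )
  blank <- is.na(long$response) | long$response == ""
  if (any(blank)) {
    if (!empty_as_unknown) {
      abort_validation("empty response cell in wide table",
                       row = which(blank)[1L])
    }
    long$response[blank] <- "unknown"
  }
  validate_responses(long)
}

#' Write a results bundle to CSV files plus a run-metadata JSON
#'
#' Each table in `bundle` (any subset of descriptor summaries, correlation
#' tables, model tables, weight tables, severity scores, imputation reports)
#' is written as `<name>.csv`; a `run.json` records the configuration echo,
#' seed, package version, and the file manifest.
#'
#' @param bundle named list of data frames.
#' @param out_dir output directory (created if absent).
#' @param config optional configuration list echoed into `run.json`.
#' @param seed optional seed echoed into `run.json`.
#' @return character vector of written paths (CSV files then `run.json`).
#' @export
write_results <- function(bundle, out_dir, config = NULL, seed = NULL) {
  stopifnot(is.list(bundle))
  if (length(bundle) && is.null(names(bundle))) {
    stop("bundle must be a named list of data frames", call. = FALSE)
  }
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create output directory '%s'", out_dir),
                  call. = FALSE)
  }
  paths <- character(0)
  for (nm in names(bundle)) {
    stopifnot(is.data.frame(bundle[[nm]]))
    p <- file.path(out_dir, paste0(nm, ".csv"))
    write_csv_na(bundle[[nm]], p)
    paths <- c(paths, p)
  }
  meta <- list(
    package = "parosim",
    version = as.character(utils::packageVersion("parosim")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    config = config,
    tables = as.list(names(bundle))
  )
  run_path <- file.path(out_dir, "run.json")
  jsonlite::write_json(meta, run_path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  c(paths, run_path)
}

#' Default run configuration
#'
#' @return a list with the analysis defaults: `n_pcs = 3` retained principal
#'   components, `n_boot_impute = 10` bootstrap samples for imputation,
#'   `ci_level = 0.95`, a `seed`, and the simulator parameter block
#'   ([sim_config()]).
#' @export
default_config <- function() {
  list(
    n_pcs = 3L,
    n_boot_impute = 10L,
    ci_level = 0.95,
    seed = 1L,
    simulator = unclass(sim_config())
  )
}

#' Read or write a run configuration as YAML
#'
#' Configurations round-trip unchanged: `read_config(write_config(cfg, f))`
#' equals `cfg`. Matrices in the simulator block are stored as row lists.
#'
#' @param config configuration list as from [default_config()].
#' @param path YAML file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns the
#'   configuration list with the semantic-correlation matrix restored.
#' @export
write_config <- function(config, path) {
  cfg <- config
  if (!is.null(cfg$simulator$semantic_correlation)) {
    m <- cfg$simulator$semantic_correlation
    cfg$simulator$semantic_correlation <-
      lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))
    cfg$simulator$semantic_correlation_names <- colnames(m)
  }
  # named atomic vectors must become maps, or YAML drops their names
  listify <- function(x) {
    if (is.list(x)) {
      lapply(x, listify)
    } else if (is.atomic(x) && !is.null(names(x))) {
      as.list(x)
    } else {
      x
    }
  }
  cfg$simulator <- listify(cfg$simulator)
  yaml::write_yaml(cfg, path, precision = 15L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$simulator$semantic_correlation)) {
    rows <- cfg$simulator$semantic_correlation
    m <- do.call(rbind, lapply(rows, as.numeric))
    nms <- cfg$simulator$semantic_correlation_names
    if (!is.null(nms)) dimnames(m) <- list(unlist(nms), unlist(nms))
    cfg$simulator$semantic_correlation <- m
    cfg$simulator$semantic_correlation_names <- NULL
  }
  for (f in c("n_pcs", "n_boot_impute", "seed")) {
    if (!is.null(cfg[[f]])) cfg[[f]] <- as.integer(cfg[[f]])
  }
  if (!is.null(cfg$simulator)) {
    cfg$simulator <- do.call(sim_config, cfg$simulator)
    cfg$simulator <- unclass(cfg$simulator)
  }
  cfg
}
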