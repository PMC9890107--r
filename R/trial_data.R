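#' Trial tables
#'
#' A trial table is a data frame with one row per guessing trial and a
#' canonical schema, ordered by `deposit_order` (the authoritative
#' chronology of a born-open stream; timestamps are only present as opaque
#' hashes) with ties broken by `(session_id, trial_index)`. Required
#' columns:
#'
#' `session_id`, `participant_id`, `lab_id`, `experimenter_id` (character),
#' `trial_index` (1--36 within session), `trial_type` ("erotic" /
#' "nonerotic"), `guessed_side`, `target_side` ("left" / "right"),
#' `success` (logical, must equal `guessed_side == target_side`),
#' `deposit_order` (non-negative integer, global), `timestamp_hash`
#' (character). Optional: `experimenter_asgs`, `sitepi_asgs` (0--36),
#' `esp_belief`, `sensation_seeking` (1--5), any of which may be NA.
#'
#' Provenance (source name, parsed and excluded row counts) is carried in
#' attributes `source` and `excluded`.
#'
#' @param df data frame holding at least the required columns.
#' @param source label recorded in provenance.
#' @param excluded count of rows dropped during validation upstream.
#' @return the validated table, class `trial_table`.
#' @export
trial_table <- function(df, source = "in-memory", excluded = 0L) {
  req <- c("session_id", "participant_id", "lab_id", "experimenter_id",
           "trial_index", "trial_type", "guessed_side", "target_side",
           "success", "deposit_order", "timestamp_hash")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  opt <- c("experimenter_asgs", "sitepi_asgs", "esp_belief", "sensation_seeking")
  for (col in opt) if (!col %in% names(df)) df[[col]] <- NA_integer_
  df <- df[c(req, opt)]
  if (nrow(df)) {
    bad <- which(df$success != (df$guessed_side == df$target_side))
    if (length(bad)) {
      stop("success flag inconsistent with sides at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
    ord <- order(df$deposit_order, df$session_id, df$trial_index)
    df <- df[ord, , drop = FALSE]
    rownames(df) <- NULL
  }
  structure(df, class = c("trial_table", "data.frame"),
            source = source, excluded = as.integer(excluded))
}

#' @export
print.trial_table <- function(x, ...) {
  cat(sprintf("<trial_table> %d trials (%d erotic), %d excluded on read, source: %s\n",
              nrow(x), sum(x$trial_type == "erotic"),
              attr(x, "excluded"), attr(x, "source")))
  NextMethod()
}

#' Read a trial-level CSV into a trial table
#'
#' Parses an RFC-4180 CSV with a header row. Column names in the file are
#' mapped onto the canonical schema through `column_map` (canonical name ->
#' source header); canonical headers need no map. Rows with an unparseable
#' `trial_type`, `guessed_side` or `target_side`, or an inconsistent
#' `success` flag, are excluded and counted in provenance — never repaired.
#' When the file lacks a `deposit_order` column, file row order defines it.
#'
#' @param path CSV file path.
#' @param column_map named character vector, canonical field -> source column.
#' @return a [trial_table()] with provenance attributes; excluded row
#'   numbers (file order) in attribute `excluded_rows`.
#' @export
read_trials <- function(path, column_map = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  canonical <- c("session_id", "participant_id", "lab_id", "experimenter_id",
                 "trial_index", "trial_type", "guessed_side", "target_side",
                 "success", "deposit_order", "timestamp_hash",
                 "experimenter_asgs", "sitepi_asgs", "esp_belief",
                 "sensation_seeking")
  src_of <- function(field) {
    if (!is.null(column_map) && field %in% names(column_map)) column_map[[field]] else field
  }
  required <- canonical[1:9]  # deposit_order/timestamp_hash may be absent
  for (field in required) {
    if (!src_of(field) %in% names(raw)) {
      stop("required column '", field, "' not found in file (looked for '",
           src_of(field), "')", call. = FALSE)
    }
  }
  df <- data.frame(row_number = seq_len(nrow(raw)))
  for (field in canonical) {
    src <- src_of(field)
    df[[field]] <- if (src %in% names(raw)) raw[[src]] else NA_character_
  }
  if (all(is.na(df$deposit_order))) df$deposit_order <- as.character(df$row_number - 1L)

  norm_enum <- function(x, levels) {
    x <- tolower(trimws(x))
    ifelse(x %in% levels, x, NA_character_)
  }
  df$trial_type <- norm_enum(df$trial_type, c("erotic", "nonerotic"))
  df$guessed_side <- norm_enum(df$guessed_side, c("left", "right"))
  df$target_side <- norm_enum(df$target_side, c("left", "right"))
  suc <- tolower(trimws(df$success))
  df$success <- ifelse(suc %in% c("true", "t", "1", "yes"), TRUE,
                       ifelse(suc %in% c("false", "f", "0", "no"), FALSE, NA))
  df$trial_index <- suppressWarnings(as.integer(df$trial_index))
  df$deposit_order <- suppressWarnings(as.numeric(df$deposit_order))
  for (col in c("experimenter_asgs", "sitepi_asgs", "esp_belief", "sensation_seeking")) {
    df[[col]] <- suppressWarnings(as.integer(df[[col]]))
  }

  ok <- !is.na(df$trial_type) & !is.na(df$guessed_side) & !is.na(df$target_side) &
    !is.na(df$success) & !is.na(df$trial_index) & !is.na(df$deposit_order) &
    df$success == (df$guessed_side == df$target_side)
  excluded_rows <- df$row_number[!ok]
  kept <- df[ok, setdiff(names(df), "row_number"), drop = FALSE]
  kept$timestamp_hash[is.na(kept$timestamp_hash)] <- ""
  tab <- trial_table(kept, source = path, excluded = length(excluded_rows))
  attr(tab, "excluded_rows") <- excluded_rows
  tab
}

#' Read an inclusion configuration file
#'
#' YAML file holding the read/inclusion settings: `column_map` (canonical
#' field -> source column), `test_experimenter_ids`, and `analysis_point`
#' (or null for no truncation). Fields may be omitted; defaults are an
#' identity map, no test accounts and no truncation.
#'
#' @param path YAML file path.
#' @return list with `column_map` (named character vector or `NULL`),
#'   `test_experimenter_ids` (character), `analysis_point` (integer or
#'   `NULL`).
#' @export
read_inclusion_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading config files requires the 'yaml' package", call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  list(
    column_map = if (length(raw$column_map)) unlist(raw$column_map),
    test_experimenter_ids = as.character(unlist(raw$test_experimenter_ids)),
    analysis_point = if (!is.null(raw$analysis_point)) as.integer(raw$analysis_point)
  )
}

#' Write a trial table as fixed-size born-open batches
#'
#' Emulates batched public deposition: the table is split, in deposit
#' order, into consecutive CSV files of `batch_size` rows (the last batch
#' may be short). Concatenating the batches in filename order reproduces
#' the table's content.
#'
#' @param table a [trial_table()].
#' @param batch_size rows per deposited file (default 200).
#' @param sink existing writable directory.
#' @param prefix filename prefix.
#' @return character vector of written file paths, in deposit order.
#' @export
write_born_open_batches <- function(table, batch_size = 200L, sink,
                                    prefix = "batch") {
  stopifnot(inherits(table, "trial_table"), batch_size >= 1)
  if (!dir.exists(sink)) stop("sink directory does not exist: ", sink, call. = FALSE)
  n <- nrow(table)
  n_batches <- max(1L, ceiling(n / batch_size))
  paths <- character(0)
  for (i in seq_len(n_batches)) {
    rows <- seq.int((i - 1L) * batch_size + 1L, min(i * batch_size, n))
    if (n == 0L && i == 1L) rows <- integer(0)
    path <- file.path(sink, sprintf("%s_%05d.csv", prefix, i))
    utils::write.csv(as.data.frame(table)[rows, , drop = FALSE], path,
                     row.names = FALSE, quote = TRUE)
    paths <- c(paths, path)
  }
  paths
}

#' Apply the preregistered inclusion and truncation rules
#'
#' Reduces a raw deposited stream to the confirmatory analysis set:
#' keeps only erotic trials, drops everything produced by test-account
#' experimenters, and — when an analysis point is given — cuts the stream
#' strictly after the analysis-point-th retained erotic trial in deposit
#' order, so sessions still in progress contribute their completed trials
#' up to the cut. Completed erotic trials of terminated (partial) sessions
#' are always retained. Idempotent.
#'
#' @param table a [trial_table()].
#' @param test_experimenter_ids experimenter ids whose trials are
#'   system-test data, excluded wholesale.
#' @param analysis_point number of erotic trials to retain, or `NULL` for
#'   all; errors if the stream has fewer retained erotic trials.
#' @return the filtered [trial_table()].
#' @export
filter_confirmatory <- function(table, test_experimenter_ids = character(0),
                                analysis_point = NULL) {
  stopifnot(inherits(table, "trial_table"))
  keep <- table$trial_type == "erotic" &
    !(table$experimenter_id %in% test_experimenter_ids)
  out <- as.data.frame(table)[keep, , drop = FALSE]
  if (!is.null(analysis_point)) {
    if (nrow(out) < analysis_point) {
      stop("analysis point not reached: ", analysis_point,
           " erotic trials required, ", nrow(out), " available", call. = FALSE)
    }
    out <- out[seq_len(analysis_point), , drop = FALSE]
  }
  trial_table(out, source = attr(table, "source"), excluded = attr(table, "excluded"))
}

#' Pooled success counts over a confirmatory trial table
#'
#' @param table a confirmatory-filtered [trial_table()].
#' @return named numeric vector `c(k = successes, n = trials)`.
#' @export
pooled_success_counts <- function(table) {
  stopifnot(inherits(table, "trial_table"))
  c(k = sum(table$success), n = nrow(table))
}

#' Per-participant success rates for complete participants
#'
#' Restricts to participants contributing exactly `required_trials`
#' retained erotic trials (the rule used by the distributional exploratory
#' analysis) and returns their success rates.
#'
#' @param table a confirmatory-filtered [trial_table()].
#' @param required_trials exact per-participant trial count (default 18).
#' @return named numeric vector, participant id -> success rate.
#' @export
participant_success_rates <- function(table, required_trials = 18L) {
  stopifnot(inherits(table, "trial_table"), required_trials >= 1)
  if (!nrow(table)) return(stats::setNames(numeric(0), character(0)))
  n_i <- table(table$participant_id)
  complete <- names(n_i)[n_i == required_trials]
  sub <- table[table$participant_id %in% complete, , drop = FALSE]
  if (!nrow(sub)) return(stats::setNames(numeric(0), character(0)))
  rates <- tapply(sub$success, sub$participant_id, mean)
  stats::setNames(as.numeric(rates), names(rates))
}
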