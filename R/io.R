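# Canonical delimited table schemas and provenance-carrying readers/writers.
# Tables are plain delimited text (comma default, tab accepted), UTF-8,
# one header row; lines starting with '#' are provenance comments.

CELL_REQUIRED <- c("cell_id", "well_id", "condition", "fixation_time_h",
                   "cfz_flag", "chx_flag", "dna", "geminin", "size_se")
CELL_NUMERIC <- c("fixation_time_h", "dna", "geminin", "size_se",
                  "aha", "k48", "mv151", "ell", "ell_dist", "chase_time_h")
TRACK_REQUIRED <- c("track_id", "time_h", "nuclear_area", "geminin",
                    "birth_time_h", "g1s_time_h", "division_time_h",
                    "complete")
TRACK_NUMERIC <- c("time_h", "nuclear_area", "geminin", "birth_time_h",
                   "g1s_time_h", "division_time_h")
BULK_REQUIRED <- c("time_h", "cell_count", "mean_size")
BULK_NUMERIC <- BULK_REQUIRED

read_delim_auto <- function(path) {
  lines <- readLines(path, n = 50, encoding = "UTF-8")
  header <- lines[!startsWith(lines, "#")][1]
  if (is.na(header)) stop_field(sprintf("'%s': no header row found", path))
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    fileEncoding = "UTF-8")
}

check_columns <- function(df, required, numeric_cols, path) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_field(sprintf("'%s': missing required column(s): %s",
                       path, paste(missing, collapse = ", ")))
  for (col in intersect(numeric_cols, names(df))) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      coerced <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(coerced) & !is.na(v) & v != "NA")
      if (length(bad))
        stop_field(sprintf("'%s': non-numeric value in column '%s' at row %d",
                           path, col, bad[1]))
      df[[col]] <- coerced
    }
  }
  df
}

as_flag <- function(x) {
  if (is.logical(x)) return(x)
  tolower(as.character(x)) %in% c("true", "t", "1", "yes")
}

#' Read a per-cell feature table
#'
#' Delimited text (comma default, tab accepted) with one row per cell.
#' Required columns: cell_id, well_id, condition, fixation_time_h,
#' cfz_flag, chx_flag, dna, geminin, size_se; optional: aha, k48, mv151,
#' stage, ell and ground-truth (`true_*`) columns. Each well must map to
#' exactly one (condition, cfz_flag, chx_flag, fixation_time_h).
#'
#' @param path file path
#' @return validated data.frame
#' @export
read_cells <- function(path) {
  df <- read_delim_auto(path)
  df <- check_columns(df, CELL_REQUIRED, CELL_NUMERIC, path)
  df$cfz_flag <- as_flag(df$cfz_flag)
  df$chx_flag <- as_flag(df$chx_flag)
  meta <- unique(df[, c("well_id", "condition", "cfz_flag", "chx_flag",
                        "fixation_time_h")])
  dup <- meta$well_id[duplicated(meta$well_id)]
  if (length(dup))
    stop_field(sprintf("'%s': well(s) map to more than one condition/flag/time: %s",
                       path, paste(unique(dup), collapse = ", ")))
  if ("stage" %in% names(df))
    df$stage <- factor(df$stage, levels = STAGE_LEVELS)
  df
}

#' Read a time-lapse track table
#'
#' Long format: one row per (track, frame) with landmark times repeated
#' per row (birth_time_h, g1s_time_h, division_time_h) and a `complete`
#' flag.
#'
#' @param path file path
#' @return validated data.frame
#' @export
read_tracks <- function(path) {
  df <- read_delim_auto(path)
  df <- check_columns(df, TRACK_REQUIRED, TRACK_NUMERIC, path)
  df$complete <- as_flag(df$complete)
  df
}

#' Read a bulk time-course table
#'
#' @param path file path
#' @return validated data.frame with time_h, cell_count, mean_size
#' @export
read_bulk <- function(path) {
  df <- read_delim_auto(path)
  df <- check_columns(df, BULK_REQUIRED, BULK_NUMERIC, path)
  if (any(df$cell_count <= 0))
    stop_field(sprintf("'%s': cell_count must be positive", path))
  df
}

# Deterministic short hash for provenance headers.
hash_of <- function(x) {
  sprintf("%08x", derive_seed(7L, paste(deparse(x), collapse = "")))
}

#' Write a results table with a provenance header
#'
#' Prepends '#' comment lines (package version, config hash, seed) so every
#' output records how to reproduce it; the body is plain CSV readable by
#' the `read_*` functions.
#'
#' @param df data.frame
#' @param path output path
#' @param config optional configuration list (hashed into the header)
#' @param seed optional seed to record
#' @export
write_table <- function(df, path, config = NULL, seed = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# compgrowth %s",
                     as.character(utils::packageVersion("compgrowth"))), con)
  if (!is.null(config))
    writeLines(sprintf("# config_hash: %s", hash_of(config)), con)
  if (!is.null(seed))
    writeLines(sprintf("# seed: %s", format(seed)), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, qmethod = "double")
  invisible(path)
}
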