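## Shared delimited-text readers/writers.

#' Read a comma- or tab-delimited file, auto-detecting the delimiter
#' @noRd
read_delimited <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  read.csv(path, sep = sep, stringsAsFactors = FALSE, strip.white = TRUE)
}

#' Read a phenotype table
#'
#' Delimited text (comma or tab auto-detected) with header columns `id`,
#' `day`, `fanning_s` and optional trailing columns `condition`,
#' `clutch_size`, `patch`. `fanning_s` must lie within [0, 300] seconds
#' (the observation-window length); `day` must be one of the observation-day
#' labels (`ED1`, `ED3`, `ED5`, `FD1`, `FD3`, `FD5`) or numeric.
#'
#' @param path file path.
#' @return Validated phenotype data frame.
#' @export
read_phenotypes <- function(path) {
  df <- read_delimited(path)
  names(df) <- tolower(names(df))
  need <- c("id", "day", "fanning_s")
  if (!all(need %in% names(df))) {
    stop("phenotype file must have columns id, day, fanning_s", call. = FALSE)
  }
  df$fanning_s <- as.numeric(df$fanning_s)
  bad <- which(is.na(df$fanning_s) | df$fanning_s < 0 | df$fanning_s > 300)
  if (length(bad) > 0) {
    stop("fanning_s outside [0, 300] (or missing) in row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  day_num <- suppressWarnings(as.numeric(as.character(df$day)))
  labelled <- is.na(day_num)
  unknown <- labelled & !(as.character(df$day) %in% names(day_codes()))
  if (any(unknown)) {
    stop("unknown day label(s): ",
         paste(unique(as.character(df$day)[unknown]), collapse = ", "), call. = FALSE)
  }
  df
}

#' Write a phenotype table as CSV
#'
#' @param phenotypes phenotype data frame.
#' @param path output path.
#' @export
write_phenotypes <- function(phenotypes, path) {
  write.csv(as.data.frame(phenotypes), path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write / read stored MCMC samples as CSV
#'
#' One column per parameter, one row per stored sample.
#'
#' @param chains an `fh_chains` object (or samples matrix).
#' @param path file path.
#' @export
write_chains <- function(chains, path) {
  s <- if (inherits(chains, "fh_chains")) chains$samples else as.matrix(chains)
  write.csv(as.data.frame(s, check.names = FALSE), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_chains
#' @export
read_chains <- function(path) {
  as.matrix(read.csv(path, check.names = FALSE))
}
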