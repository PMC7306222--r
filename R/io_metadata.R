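#' Permitted specimen label levels
#'
#' The study design covers two ontogenetic stages, three host-attachment
#' sites and two pereopod appendages.
#' @name specimen-levels
#' @keywords internal
NULL

specimen_levels <- list(
  stage = c("immature", "adult"),
  site = c("mouth", "gill", "external"),
  appendage = c("P1", "P6")
)

#' Read a specimen metadata table
#'
#' Reads a delimited table with columns `specimen_id`, `species`, `stage`,
#' `site`, `appendage` (case-insensitive header; comma- or tab-separated
#' inferred from the file). Label values are validated against the
#' permitted levels: stage in {immature, adult}, site in
#' {mouth, gill, external}, appendage in {P1, P6}.
#'
#' @param path file path.
#' @return data frame of specimen records with validated label columns;
#'   `specimen_id` is the join key for linking shapes.
#' @export
read_specimen_metadata <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, strip.white = TRUE)
  names(df) <- tolower(names(df))
  validate_specimen_metadata(df)
}

#' Validate a specimen metadata data frame
#'
#' @param df data frame with columns `specimen_id`, `species`, `stage`,
#'   `site`, `appendage`.
#' @return the validated data frame (columns reordered, labels as character).
#' @export
validate_specimen_metadata <- function(df) {
  names(df) <- tolower(names(df))
  need <- c("specimen_id", "species", "stage", "site", "appendage")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  }
  df <- df[, need]
  for (col in c("stage", "site", "appendage")) {
    vals <- as.character(df[[col]])
    bad <- setdiff(unique(vals), specimen_levels[[col]])
    if (length(bad)) {
      stop(sprintf("unknown %s value(s) %s; permitted: %s",
                   col, paste(sQuote(bad), collapse = ", "),
                   paste(specimen_levels[[col]], collapse = ", ")))
    }
    df[[col]] <- vals
  }
  df$specimen_id <- as.character(df$specimen_id)
  dup <- df$specimen_id[duplicated(df$specimen_id)]
  if (length(dup)) {
    stop("duplicate specimen_id: ", paste(unique(dup), collapse = ", "))
  }
  rownames(df) <- NULL
  df
}

#' Write a specimen metadata table
#' @param df validated metadata data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_specimen_metadata <- function(df, path) {
  utils::write.csv(validate_specimen_metadata(df), path, row.names = FALSE)
  invisible(path)
}
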