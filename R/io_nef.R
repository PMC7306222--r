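#' Read normalized elliptic Fourier coefficients from a `.nef` file
#'
#' Record-oriented text dialect: per record a name line, a line giving the
#' harmonic count N, then N lines each holding four reals `a_n b_n c_n d_n`.
#' Lines starting with `#` are comments when `permissive = TRUE`.
#'
#' @param path file path or character vector of lines.
#' @param permissive allow `#` comment lines.
#' @param check verify the normalization invariants of each record
#'   (`a1 = 1`, `b1 = c1 = 0` within `tol`).
#' @param tol invariant tolerance used when `check = TRUE`.
#' @return named list of `normalized_efd` objects, names taken from the
#'   record name lines, preserved in file order.
#' @export
read_nef <- function(path, permissive = TRUE, check = TRUE, tol = 1e-6) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  if (permissive) lines <- lines[!grepl("^\\s*#", lines)]
  lines <- trimws(lines)
  lines <- lines[lines != ""]
  i <- 1L
  out <- list()
  nm <- character(0)
  n <- length(lines)
  while (i <= n) {
    name <- lines[i]
    if (i + 1L > n) stop(sprintf("record '%s': missing harmonic count", name))
    N <- suppressWarnings(as.integer(lines[i + 1L]))
    if (is.na(N) || N < 1L) stop(sprintf("record '%s': bad harmonic count", name))
    if (i + 1L + N > n) stop(sprintf("record '%s': truncated coefficient block", name))
    rows <- lines[(i + 2L):(i + 1L + N)]
    mat <- matrix(NA_real_, N, 4L)
    for (r in seq_len(N)) {
      vals <- suppressWarnings(as.numeric(strsplit(rows[r], "\\s+")[[1L]]))
      if (length(vals) != 4L || any(is.na(vals))) {
        stop(sprintf("record '%s': ragged coefficient row %d", name, r))
      }
      mat[r, ] <- vals
    }
    out[[length(out) + 1L]] <- as_normalized_efd(mat, check = check, tol = tol)
    nm <- c(nm, name)
    i <- i + 2L + N
  }
  names(out) <- nm
  out
}

#' Write normalized elliptic Fourier coefficients to a `.nef` file
#'
#' Inverse of [read_nef()]; coefficients are written with 10 significant
#' digits so a write/read round trip reproduces them to at least 6
#' significant digits.
#'
#' @param efds named list of `normalized_efd` (or `efd`) objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_nef <- function(efds, path) {
  nm <- names(efds)
  if (is.null(nm) || any(nm == "")) stop("efds must be a fully named list")
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(efds)) {
    e <- efds[[k]]
    writeLines(nm[k], con)
    writeLines(as.character(e$n_harmonics), con)
    writeLines(apply(e$coef, 1L, function(r) paste(sprintf("%.10g", r), collapse = " ")),
               con)
  }
  invisible(path)
}

#' Read an outline from a two-column CSV
#'
#' @param path CSV file with header columns `x`, `y` (case-insensitive).
#' @return an [outline].
#' @export
read_outline_csv <- function(path) {
  df <- utils::read.csv(path)
  names(df) <- tolower(names(df))
  if (!all(c("x", "y") %in% names(df))) stop("outline CSV needs columns x, y")
  outline(cbind(df$x, df$y), min_points = 3L)
}

#' Write an outline to a two-column CSV
#' @param x an [outline].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_outline_csv <- function(x, path) {
  utils::write.csv(data.frame(x = unclass(x)[, 1L], y = unclass(x)[, 2L]),
                   path, row.names = FALSE)
  invisible(path)
}
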