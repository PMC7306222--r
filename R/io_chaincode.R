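#' Freeman chain code of a digitized outline
#'
#' A chain code records a pixel-boundary walk as a start pixel plus a
#' sequence of 8-connectivity direction codes 0..7 (0 = +x, codes increase
#' counterclockwise in the mathematical convention, so 2 = -y in image
#' coordinates where y grows downward). The walk must return exactly to the
#' start pixel.
#'
#' @param name record identifier.
#' @param start integer pixel coordinate pair (x, y), image convention
#'   (y down), 0-based.
#' @param codes integer vector of direction codes in 0..7, length >= 4.
#' @return a `chain_code` object.
#' @export
chain_code <- function(name, start, codes) {
  codes <- as.integer(codes)
  start <- as.integer(start)
  if (length(start) != 2L) stop("start must be a coordinate pair")
  if (any(codes < 0L | codes > 7L)) {
    stop(sprintf("chain '%s': code outside 0..7", name))
  }
  if (length(codes) < 1L) stop(sprintf("chain '%s': empty code sequence", name))
  st <- freeman_steps(codes)
  if (sum(st[, 1L]) != 0L || sum(st[, 2L]) != 0L) {
    stop(sprintf("chain '%s': chain not closed", name))
  }
  if (length(codes) < 4L) stop(sprintf("chain '%s': fewer than 4 codes", name))
  structure(list(name = as.character(name), start = start, codes = codes),
            class = "chain_code")
}

# code -> (dx, dy) in y-up mathematical convention
freeman_steps <- function(codes) {
  dx <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
  dy <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  cbind(dx[codes + 1L], dy[codes + 1L])
}

#' @export
print.chain_code <- function(x, ...) {
  cat(sprintf("<chain_code> '%s' start (%d,%d), %d codes\n",
              x$name, x$start[1L], x$start[2L], length(x$codes)))
  invisible(x)
}

#' Read chain-code records from a `.chc` file
#'
#' Record-oriented text dialect: per record a name line, a start-coordinate
#' line `x y` (image coordinates, y down, 0-based), then whitespace-separated
#' codes over one or more lines, terminated by the sentinel `-1`. Lines
#' starting with `#` are treated as comments when `permissive = TRUE`.
#'
#' @param path file path or character vector of lines.
#' @param permissive allow `#` comment lines (default TRUE).
#' @return list of [chain_code] objects in file order.
#' @export
read_chc <- function(path, permissive = TRUE) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  if (permissive) lines <- lines[!grepl("^\\s*#", lines)]
  lines_trim <- trimws(lines)
  i <- 1L
  out <- list()
  n <- length(lines_trim)
  while (i <= n) {
    if (lines_trim[i] == "") { i <- i + 1L; next }
    name <- lines_trim[i]
    if (i + 1L > n) stop(sprintf("record '%s': missing start coordinates", name))
    start <- suppressWarnings(as.integer(strsplit(lines_trim[i + 1L], "\\s+")[[1L]]))
    if (length(start) != 2L || any(is.na(start))) {
      stop(sprintf("record '%s': malformed start line at line %d", name, i + 1L))
    }
    i <- i + 2L
    codes <- integer(0)
    found_sentinel <- FALSE
    while (i <= n) {
      toks <- strsplit(lines_trim[i], "\\s+")[[1L]]
      toks <- toks[toks != ""]
      vals <- suppressWarnings(as.integer(toks))
      if (any(is.na(vals))) {
        stop(sprintf("record '%s': non-numeric code token at line %d", name, i))
      }
      sent <- which(vals == -1L)
      if (length(sent)) {
        codes <- c(codes, vals[seq_len(sent[1L] - 1L)])
        found_sentinel <- TRUE
        i <- i + 1L
        break
      }
      if (any(vals < 0L | vals > 7L)) {
        stop(sprintf("record '%s': code outside 0..7 at line %d", name, i))
      }
      codes <- c(codes, vals)
      i <- i + 1L
    }
    if (!found_sentinel) stop(sprintf("record '%s': missing -1 sentinel", name))
    if (any(codes < 0L | codes > 7L)) {
      stop(sprintf("record '%s': code outside 0..7", name))
    }
    out[[length(out) + 1L]] <- chain_code(name, start, codes)
  }
  out
}

#' Write chain-code records to a `.chc` file
#'
#' @param chains list of [chain_code] objects.
#' @param path output file path.
#' @param width maximum codes per line.
#' @return `path`, invisibly.
#' @export
write_chc <- function(chains, path, width = 30L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in chains) {
    writeLines(ch$name, con)
    writeLines(sprintf("%d %d", ch$start[1L], ch$start[2L]), con)
    codes <- c(ch$codes, -1L)
    idx <- split(codes, ceiling(seq_along(codes) / width))
    writeLines(vapply(idx, paste, "", collapse = " "), con)
  }
  invisible(path)
}

#' Convert a chain code to an outline
#'
#' Traces the pixel path in y-up mathematical coordinates (the image y axis
#' is negated), dropping the duplicate terminal vertex. Orientation is left
#' as traced.
#'
#' @param chain a [chain_code].
#' @return an [outline].
#' @export
chain_to_outline <- function(chain) {
  st <- freeman_steps(chain$codes)
  x0 <- chain$start[1L]
  y0 <- -chain$start[2L]   # image y (down) -> mathematical y (up)
  xs <- x0 + cumsum(c(0L, st[-nrow(st), 1L]))
  ys <- y0 + cumsum(c(0L, st[-nrow(st), 2L]))
  outline(cbind(xs, ys), min_points = 3L)
}

#' Convert a pixel-grid outline back to a chain code
#'
#' Inverse of [chain_to_outline()] for outlines whose consecutive vertices
#' are unit or diagonal pixel steps.
#'
#' @param x an [outline] on the integer pixel grid.
#' @param name record identifier.
#' @return a [chain_code].
#' @export
outline_to_chain <- function(x, name = "outline") {
  p <- round(unclass(x))
  d <- edge_vectors(p)
  if (any(abs(d) > 1)) stop("outline steps exceed one pixel; not a chain path")
  codes <- integer(nrow(d))
  dx <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
  dy <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  key <- paste(d[, 1L], d[, 2L])
  lut <- stats::setNames(0:7, paste(dx, dy))
  codes <- lut[key]
  if (any(is.na(codes))) stop("outline contains a zero-length step")
  chain_code(name, c(p[1L, 1L], -p[1L, 2L]), unname(codes))
}
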