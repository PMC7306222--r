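#' Trace the outer boundary of a binary mask
#'
#' Moore-neighbor boundary tracing with Jacob's stopping criterion: starting
#' from the lowest-leftmost foreground pixel (scanning rows bottom-up in the
#' y-up convention), the tracer walks the 8-connected outer boundary and
#' stops when it re-enters the start pixel from the original entry
#' direction. The mask must contain exactly one 8-connected foreground
#' component, with background grid borders.
#'
#' The returned outline is the sequence of boundary pixel centers in y-up
#' mathematical coordinates (row 1 of the matrix is the top image row, so
#' image row r maps to y = -(r - 1)), counterclockwise.
#'
#' @param mask logical or 0/1 matrix; rows are image rows top-to-bottom.
#' @return a closed [outline] of boundary pixel centers.
#' @export
trace_boundary <- function(mask) {
  m <- as.matrix(mask)
  m <- matrix(as.logical(m), nrow(m), ncol(m))
  m[is.na(m)] <- FALSE
  ncomp <- count_components(m)
  if (ncomp == 0L) stop("no foreground component")
  if (ncomp > 1L) stop(sprintf("expected 1 foreground component, found %d", ncomp))
  if (any(m[1L, ]) || any(m[nrow(m), ]) || any(m[, 1L]) || any(m[, ncol(m)])) {
    stop("foreground touches the grid border; pad the mask")
  }
  nr <- nrow(m)
  # start pixel: bottom-most image row containing foreground (min y-up),
  # then left-most column; entered from the pixel below (outside)
  rows_with <- which(apply(m, 1L, any))
  r0 <- max(rows_with)                 # bottom-most image row
  c0 <- min(which(m[r0, ]))
  # Moore neighborhood in (dr, dc), clockwise in image coords starting from
  # "below" = (+1, 0); clockwise image order is counterclockwise in y-up
  nbr <- rbind(c(1L, 0L), c(1L, -1L), c(0L, -1L), c(-1L, -1L),
               c(-1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L))
  cur <- c(r0, c0)
  backtrack_idx <- 1L                  # came from below (background by choice of start)
  path <- matrix(0L, 0L, 2L)
  # Jacob's stopping criterion, state form: stop when a (pixel, entry
  # direction) state repeats, i.e. the start pixel is about to be left the
  # same way twice. Each pixel has at most 8 entry states, so the walk
  # terminates.
  seen <- new.env(parent = emptyenv())
  repeat {
    key <- sprintf("%d,%d,%d", cur[1L], cur[2L], backtrack_idx)
    if (!is.null(seen[[key]])) break
    seen[[key]] <- TRUE
    path <- rbind(path, cur)
    found <- FALSE
    for (k in 0:7) {
      idx <- ((backtrack_idx - 1L + k) %% 8L) + 1L
      cand <- cur + nbr[idx, ]
      if (cand[1L] >= 1L && cand[1L] <= nr && cand[2L] >= 1L &&
          cand[2L] <= ncol(m) && m[cand[1L], cand[2L]]) {
        # next backtrack: the neighbor index just before the found pixel
        prev_idx <- ((idx - 2L) %% 8L) + 1L
        back_cell <- cur + nbr[prev_idx, ]
        cur <- cand
        # index of back_cell relative to the new current pixel
        rel <- back_cell - cur
        backtrack_idx <- which(nbr[, 1L] == rel[1L] & nbr[, 2L] == rel[2L])
        found <- TRUE
        break
      }
    }
    if (!found) break   # isolated pixel (cannot happen for >= 8 boundary px)
  }
  # the walk may append the start pixel again just before the state repeat
  if (nrow(path) > 1L && all(path[nrow(path), ] == path[1L, ])) {
    path <- path[-nrow(path), , drop = FALSE]
  }
  if (nrow(path) < 3L) stop("boundary too short to form an outline")
  # image (row, col) -> mathematical (x, y): x = col - 1, y = -(row - 1)
  pts <- cbind(path[, 2L] - 1L, -(path[, 1L] - 1L))
  out <- outline(pts, min_points = 3L)
  if (!is_ccw(out)) {
    out <- outline(unclass(out)[nrow(out):1L, , drop = FALSE], min_points = 3L)
  }
  out
}

# count 8-connected foreground components by flood fill
count_components <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  comp <- 0L
  idx <- which(m)
  for (i in idx) {
    if (lab[i] > 0L) next
    comp <- comp + 1L
    stack <- i
    lab[i] <- comp
    while (length(stack)) {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- ((j - 1L) %% nr) + 1L
      cl <- ((j - 1L) %/% nr) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- cl + dc
        if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc) {
          k <- (cc - 1L) * nr + rr
          if (m[k] && lab[k] == 0L) {
            lab[k] <- comp
            stack <- c(stack, k)
          }
        }
      }
    }
  }
  comp
}

#' Rasterize a closed outline to a binary mask
#'
#' Point-in-polygon scan over pixel centers; used to digitize
#' vector-generated hooks the way a drawing would be scanned.
#'
#' @param x an [outline].
#' @param height target mask height in pixels (the outline is scaled to fit
#'   with a margin of `pad` background pixels).
#' @param pad margin of background pixels on each side.
#' @return binary matrix (image convention, rows top-to-bottom).
#' @export
rasterize_outline <- function(x, height = 200L, pad = 2L) {
  p <- unclass(x)
  rngx <- range(p[, 1L]); rngy <- range(p[, 2L])
  scale <- (height - 1L - 2L * pad) / diff(rngy)
  px <- (p[, 1L] - rngx[1L]) * scale + pad
  py <- (p[, 2L] - rngy[1L]) * scale + pad
  width <- ceiling(max(px)) + pad + 1L
  nr <- as.integer(height)
  nc <- as.integer(width)
  # pixel centers: x = col-1, y-up = height-row ; inside test via even-odd rule
  m <- matrix(FALSE, nr, nc)
  cx <- 0:(nc - 1L)
  n <- length(px)
  xj <- px; yj <- py
  xk <- c(px[-1L], px[1L]); yk <- c(py[-1L], py[1L])
  for (r in seq_len(nr)) {
    y0 <- nr - r   # y-up coordinate of this image row
    crosses <- ((yj > y0) != (yk > y0))
    if (!any(crosses)) next
    xi <- xj[crosses] + (y0 - yj[crosses]) / (yk[crosses] - yj[crosses]) *
      (xk[crosses] - xj[crosses])
    xi <- sort(xi)
    inside <- rep(FALSE, nc)
    for (s in seq(1L, length(xi) - 1L, by = 2L)) {
      inside <- inside | (cx >= xi[s] & cx <= xi[s + 1L])
    }
    m[r, ] <- inside
  }
  m
}

#' Read a binary mask from a plain text grid, PNG or TIFF
#'
#' Text grids hold one row per line of 0/1 characters (optionally
#' whitespace-separated). PNG/TIFF images are thresholded at 0.5 on the
#' first channel (requires the png or tiff package).
#'
#' @param path input file.
#' @return binary matrix in image convention.
#' @export
read_mask <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) stop("png package not available")
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    return(img > 0.5)
  }
  if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) stop("tiff package not available")
    img <- tiff::readTIFF(path)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    return(img > 0.5)
  }
  lines <- readLines(path)
  lines <- lines[trimws(lines) != ""]
  rows <- lapply(lines, function(l) {
    l <- gsub("\\s", "", l)
    as.integer(strsplit(l, "")[[1L]])
  })
  len <- unique(lengths(rows))
  if (length(len) != 1L) stop("ragged mask rows")
  matrix(unlist(rows) == 1L, nrow = length(rows), byrow = TRUE)
}
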