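#' Contours and Freeman chain codes
#'
#' A contour is a two-column numeric matrix (columns `x`, `y`) of ordered
#' vertices of a closed polygon in mathematical coordinates (y increases
#' upward). Closure is implicit: the first vertex is not repeated at the end.
#' A chain code encodes an 8-connected pixel boundary as a start coordinate
#' plus a sequence of Freeman direction symbols 0-7 (0 = east, 2 = north,
#' 4 = west, 6 = south, odd symbols are the diagonals in between).
#'
#' @name contour
NULL

# Freeman 8-direction steps, code k -> (dx, dy) in y-up coordinates
.freeman_dx <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
.freeman_dy <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)

#' Coerce to a contour matrix
#'
#' Validates and normalizes a set of polygon vertices: drops a repeated
#' closing vertex and consecutive duplicates, and optionally re-orients the
#' polygon counter-clockwise.
#'
#' @param x Two-column matrix or data frame of vertices (`x`, `y`).
#' @param ccw Re-orient counter-clockwise (positive signed area)? Default `TRUE`.
#' @return Numeric matrix with columns `x`, `y`.
#' @export
as_contour <- function(x, ccw = TRUE) {
  m <- as.matrix(x)
  if (ncol(m) != 2 || !is.numeric(m)) {
    stop("a contour must be a two-column numeric matrix of (x, y) vertices", call. = FALSE)
  }
  colnames(m) <- c("x", "y")
  n <- nrow(m)
  if (n > 1 && all(m[1, ] == m[n, ])) m <- m[-n, , drop = FALSE]
  dup <- c(FALSE, rowSums(abs(diff(m))) == 0)
  if (any(dup)) m <- m[!dup, , drop = FALSE]
  if (nrow(m) < 3) stop("a contour needs at least 3 distinct vertices", call. = FALSE)
  if (ccw && contour_area(m, signed = TRUE) < 0) m <- m[nrow(m):1, , drop = FALSE]
  m
}

#' Polygon area by the shoelace formula
#'
#' @param contour Contour matrix (see [as_contour()]).
#' @param signed Return the signed area (positive = counter-clockwise)?
#' @return Area in squared contour units.
#' @export
contour_area <- function(contour, signed = FALSE) {
  x <- contour[, 1]; y <- contour[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  a <- sum(x * yn - xn * y) / 2
  if (signed) a else abs(a)
}

#' Polygon perimeter
#' @inheritParams contour_area
#' @return Perimeter in contour units.
#' @export
contour_perimeter <- function(contour) {
  d <- diff(rbind(contour, contour[1, , drop = FALSE]))
  sum(sqrt(rowSums(d^2)))
}

#' Area centroid of a simple polygon
#' @inheritParams contour_area
#' @return Length-2 numeric vector (x, y).
#' @export
contour_centroid <- function(contour) {
  x <- contour[, 1]; y <- contour[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(colMeans(contour))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

#' Encode a pixel contour as a Freeman chain code
#'
#' Consecutive contour vertices must differ by a single king move (both
#' coordinate differences in -1, 0, 1 and not both zero), as produced by
#' [extract_contour()].
#'
#' @param contour Contour matrix of integer pixel coordinates.
#' @return A `chain_code` object: list with `start` (first vertex) and
#'   `codes` (integer vector of Freeman symbols, one per boundary step,
#'   including the closing step back to `start`).
#' @export
contour_to_chain_code <- function(contour) {
  contour <- as_contour(contour, ccw = FALSE)
  p <- rbind(contour, contour[1, , drop = FALSE])
  dx <- round(diff(p[, 1])); dy <- round(diff(p[, 2]))
  if (any(abs(dx) > 1 | abs(dy) > 1 | (dx == 0 & dy == 0))) {
    stop("consecutive contour points must differ by one king move; ",
         "not an 8-connected pixel path", call. = FALSE)
  }
  codes <- match(paste(dx, dy), paste(.freeman_dx, .freeman_dy)) - 1L
  structure(list(start = c(x = contour[1, 1], y = contour[1, 2]),
                 codes = as.integer(codes)),
            class = "chain_code")
}

#' Decode a Freeman chain code back to a contour
#'
#' @param cc A `chain_code` object (see [contour_to_chain_code()]).
#' @return Contour matrix. Errors if the code does not return to its start.
#' @export
chain_code_to_contour <- function(cc) {
  stopifnot(inherits(cc, "chain_code"))
  k <- cc$codes + 1L
  x <- cc$start[[1]] + cumsum(.freeman_dx[k])
  y <- cc$start[[2]] + cumsum(.freeman_dy[k])
  n <- length(k)
  if (x[n] != cc$start[[1]] || y[n] != cc$start[[2]]) {
    stop("chain code does not close back to its start point", call. = FALSE)
  }
  cbind(x = c(cc$start[[1]], x[-n]), y = c(cc$start[[2]], y[-n]))
}

#' @export
print.chain_code <- function(x, ...) {
  cat("Freeman chain code: start (", x$start[[1]], ", ", x$start[[2]], "), ",
      length(x$codes), " steps\n", sep = "")
  invisible(x)
}

#' Write / read chain codes as plain text
#'
#' One outline per line: `name,x0,y0,code0code1...` where the codes are the
#' concatenated Freeman digits.
#'
#' @param codes Named list of `chain_code` objects.
#' @param path Output file path.
#' @return `write_chain_codes()` returns `path` invisibly;
#'   `read_chain_codes()` a named list of `chain_code` objects.
#' @export
write_chain_codes <- function(codes, path) {
  stopifnot(is.list(codes), !is.null(names(codes)))
  lines <- vapply(names(codes), function(nm) {
    cc <- codes[[nm]]
    paste(nm, cc$start[[1]], cc$start[[2]], paste(cc$codes, collapse = ""), sep = ",")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_chain_codes
#' @export
read_chain_codes <- function(path) {
  lines <- readLines(path)
  out <- lapply(lines, function(ln) {
    f <- strsplit(ln, ",", fixed = TRUE)[[1]]
    if (length(f) != 4) stop("malformed chain-code line: ", ln, call. = FALSE)
    structure(list(start = c(x = as.numeric(f[2]), y = as.numeric(f[3])),
                   codes = as.integer(strsplit(f[4], "")[[1]])),
              class = "chain_code")
  })
  names(out) <- vapply(strsplit(lines, ",", fixed = TRUE), `[[`, character(1), 1)
  out
}

#' Export / import contours as CSV
#'
#' Long format with columns `name,point_index,x,y`.
#'
#' @param contours Named list of contour matrices.
#' @param path File path.
#' @return `write_contours_csv()` returns `path` invisibly;
#'   `read_contours_csv()` a named list of contour matrices.
#' @export
write_contours_csv <- function(contours, path) {
  stopifnot(is.list(contours), !is.null(names(contours)))
  tbl <- purrr::imap_dfr(contours, function(m, nm) {
    tibble::tibble(name = nm, point_index = seq_len(nrow(m)),
                   x = m[, 1], y = m[, 2])
  })
  readr::write_csv(tbl, path)
  invisible(path)
}

#' @rdname write_contours_csv
#' @export
read_contours_csv <- function(path) {
  tbl <- readr::read_csv(path, col_types = readr::cols(
    name = "c", point_index = "i", x = "d", y = "d"))
  split(tbl, tbl$name) |>
    lapply(function(d) cbind(x = d$x[order(d$point_index)],
                             y = d$y[order(d$point_index)]))
}

# Simplicity check: TRUE iff no two non-adjacent edges intersect.
# Bounding-box prefilter keeps the pairwise test tractable for outline sizes
# used here (a few hundred vertices).
contour_is_simple <- function(contour) {
  p <- rbind(contour, contour[1, , drop = FALSE])
  n <- nrow(contour)
  x1 <- p[-nrow(p), 1]; y1 <- p[-nrow(p), 2]
  x2 <- p[-1, 1]; y2 <- p[-1, 2]
  idx <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  adj <- (j - i == 1) | (i == 1 & j == n)
  i <- i[!adj]; j <- j[!adj]
  bb <- pmin(x1, x2)[i] <= pmax(x1, x2)[j] & pmax(x1, x2)[i] >= pmin(x1, x2)[j] &
    pmin(y1, y2)[i] <= pmax(y1, y2)[j] & pmax(y1, y2)[i] >= pmin(y1, y2)[j]
  i <- i[bb]; j <- j[bb]
  if (!length(i)) return(TRUE)
  cross <- function(ax, ay, bx, by) ax * by - ay * bx
  d1 <- cross(x2[i] - x1[i], y2[i] - y1[i], x1[j] - x1[i], y1[j] - y1[i])
  d2 <- cross(x2[i] - x1[i], y2[i] - y1[i], x2[j] - x1[i], y2[j] - y1[i])
  d3 <- cross(x2[j] - x1[j], y2[j] - y1[j], x1[i] - x1[j], y1[i] - y1[j])
  d4 <- cross(x2[j] - x1[j], y2[j] - y1[j], x2[i] - x1[j], y2[i] - y1[j])
  !any(d1 * d2 < 0 & d3 * d4 < 0)
}
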