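#' Load a binary leaf silhouette
#'
#' Reads a PNG or TIFF mask image (one leaf per image), binarizes grayscale
#' input at 50%, selects the largest 8-connected foreground component, and
#' returns it as a logical matrix in image convention (row 1 = top of image)
#' with the scan resolution attached.
#'
#' @param path Path to a PNG or TIFF file.
#' @param dpi Scan resolution in pixels per inch (> 0).
#' @param foreground Which pixel value is leaf: `"nonzero"` (default; bright
#'   pixels are leaf) or `"zero"` (dark pixels are leaf).
#' @return Logical matrix (`TRUE` = leaf) with attribute `dpi`.
#'   Errors on an empty foreground, or when a second connected component
#'   exceeds 1% of the largest (more than scanner dust); smaller extra
#'   components are dropped with a warning.
#' @export
load_mask <- function(path, dpi, foreground = c("nonzero", "zero")) {
  foreground <- match.arg(foreground)
  if (!is.numeric(dpi) || length(dpi) != 1 || dpi <= 0) {
    stop("`dpi` must be a single positive number", call. = FALSE)
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '", ext, "' (PNG or TIFF expected)", call. = FALSE)
  )
  if (length(dim(img)) == 3) {
    nch <- min(dim(img)[3], 3L)
    img <- apply(img[, , seq_len(nch), drop = FALSE], c(1, 2), mean)
  }
  fg <- if (foreground == "nonzero") img > 0.5 else img <= 0.5
  fg <- keep_largest_component(fg)
  attr(fg, "dpi") <- dpi
  fg
}

# Largest 8-connected component selection with the dust-tolerance rule.
keep_largest_component <- function(fg) {
  if (!any(fg)) stop("empty foreground: mask contains no leaf pixels", call. = FALSE)
  lab <- label_components(fg)
  sizes <- tabulate(lab)
  if (length(sizes) > 1) {
    ord <- order(sizes, decreasing = TRUE)
    if (sizes[ord[2]] > 0.01 * sizes[ord[1]]) {
      n_big <- sum(sizes > 0.01 * sizes[ord[1]])
      stop("mask contains ", n_big,
           " foreground components of comparable size; expected one leaf",
           call. = FALSE)
    }
    warning("dropping ", length(sizes) - 1L,
            " small extra foreground component(s) (scanner dust)", call. = FALSE)
    fg <- lab == ord[1]
  }
  fg
}

#' Label 8-connected foreground components
#'
#' Breadth-first frontier labeling over the foreground pixels; diagonal
#' neighbours connect.
#'
#' @param fg Logical matrix.
#' @return Integer matrix of component labels (0 = background).
#' @export
label_components <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- fg
  np <- nr + 2L
  off <- c(-1L, 1L, -np, np, -np - 1L, -np + 1L, np - 1L, np + 1L)
  lab <- integer(length(pad))
  padv <- as.vector(pad)
  cur <- 0L
  for (s in which(padv)) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    lab[s] <- cur
    frontier <- s
    while (length(frontier)) {
      nb <- unique(as.vector(outer(frontier, off, `+`)))
      nb <- nb[padv[nb] & lab[nb] == 0L]
      lab[nb] <- cur
      frontier <- nb
    }
  }
  matrix(lab, np)[2:(nr + 1L), 2:(nc + 1L)]
}

#' Extract the outer boundary of a leaf mask
#'
#' Traces the outer boundary of the largest foreground component with
#' Moore-neighbour tracing (Jacob's stopping criterion), converts it to
#' mathematical coordinates (0-based, y up, pixel centers at integers) and
#' orients it counter-clockwise. Interior holes are ignored.
#'
#' @param mask Logical matrix as returned by [load_mask()] or
#'   [rasterize_outline()].
#' @return Contour matrix (columns `x`, `y`) of 8-connected pixel centers.
#'   Errors if the component has fewer than 8 pixels or touches the image
#'   border (clipped leaf).
#' @export
extract_contour <- function(mask) {
  fg <- keep_largest_component(mask)
  if (sum(fg) < 8) stop("component too small: fewer than 8 foreground pixels", call. = FALSE)
  nr <- nrow(fg); nc <- ncol(fg)
  if (any(fg[1, ]) || any(fg[nr, ]) || any(fg[, 1]) || any(fg[, nc])) {
    stop("foreground touches the image border; leaf appears clipped", call. = FALSE)
  }
  path_rc <- moore_trace(fg)
  contour <- cbind(x = path_rc[, 2] - 1, y = nr - path_rc[, 1])
  as_contour(contour, ccw = TRUE)
}

# Moore-neighbour boundary tracing in matrix (row, col) coordinates.
# Returns the clockwise (image convention) boundary pixel path.
moore_trace <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  # first foreground pixel in raster order (row by row, left to right)
  start <- NULL
  for (r in seq_len(nr)) {
    cc <- which(fg[r, ])
    if (length(cc)) { start <- c(r, cc[1]); break }
  }
  # clockwise Moore neighbourhood (image convention, row grows downward)
  nbr <- matrix(c(-1L, 0L, -1L, 1L, 0L, 1L, 1L, 1L, 1L, 0L, 1L, -1L, 0L, -1L, -1L, -1L),
                ncol = 2, byrow = TRUE) # N NE E SE S SW W NW
  b0 <- start + c(0L, -1L) # entered from the west during the raster scan
  p <- start; b <- b0
  path <- matrix(0L, 4L * sum(fg) + 8L, 2)
  path[1, ] <- start
  n_pts <- 1L
  repeat {
    # index of b in the neighbourhood of p
    db <- b - p
    k <- which(nbr[, 1] == db[1] & nbr[, 2] == db[2])
    found <- FALSE
    for (s in seq_len(8)) {
      k2 <- ((k + s - 1L) %% 8L) + 1L
      q <- p + nbr[k2, ]
      if (q[1] >= 1 && q[1] <= nr && q[2] >= 1 && q[2] <= nc && fg[q[1], q[2]]) {
        b <- p + nbr[((k + s - 2L) %% 8L) + 1L, ]
        p <- q
        found <- TRUE
        break
      }
    }
    if (!found) break # isolated pixel
    if (all(p == start) && all(b == b0)) break # Jacob's criterion
    n_pts <- n_pts + 1L
    if (n_pts > nrow(path)) stop("boundary trace failed to terminate", call. = FALSE)
    path[n_pts, ] <- p
  }
  path[seq_len(n_pts), , drop = FALSE]
}

#' Leaf area from a mask
#'
#' Foreground pixel count converted to square centimeters:
#' `count * (2.54 / dpi)^2`.
#'
#' @param mask Logical matrix (leaf = `TRUE`).
#' @param dpi Pixels per inch; defaults to the mask's `dpi` attribute.
#' @return Area in cm^2.
#' @export
compute_area_cm2 <- function(mask, dpi = attr(mask, "dpi")) {
  if (is.null(dpi) || !is.numeric(dpi) || dpi <= 0) {
    stop("`dpi` must be a positive number", call. = FALSE)
  }
  sum(mask) * (2.54 / dpi)^2
}

#' Parse and format node labels
#'
#' Node position is counted from the shoot apex; node 1 (label "i") is the
#' node closest to the apex. Labels are lowercase roman numerals i-xvi or
#' arabic integer strings.
#'
#' @param label Character vector of node labels.
#' @return `parse_node_label()`: integer vector in 1-16.
#'   `node_to_roman()`: lowercase roman labels.
#' @examples
#' parse_node_label(c("i", "iv", "xvi", "7"))
#' node_to_roman(1:4)
#' @export
parse_node_label <- function(label) {
  label <- trimws(as.character(label))
  out <- rep(NA_integer_, length(label))
  arabic <- grepl("^[0-9]+$", label)
  out[arabic] <- as.integer(label[arabic])
  roman <- !arabic & grepl("^[ivxIVX]+$", label)
  out[roman] <- suppressWarnings(as.integer(utils::as.roman(toupper(label[roman]))))
  bad <- is.na(out) | out < 1L | out > 16L
  if (any(bad)) {
    stop("invalid node label(s): ", paste(unique(label[bad]), collapse = ", "),
         "; accepted forms are lowercase roman numerals i-xvi or integers 1-16",
         call. = FALSE)
  }
  out
}

#' @rdname parse_node_label
#' @param node Integer vector of node positions (1-16).
#' @export
node_to_roman <- function(node) {
  stopifnot(all(node >= 1 & node <= 16))
  tolower(as.character(utils::as.roman(node)))
}

#' Read a leaf-scan metadata table
#'
#' Expects a CSV with header `file,shoot_id,node,phyllotaxy,side,dpi`.
#' `node` accepts roman or arabic labels; `phyllotaxy` is `CL` (clockwise) or
#' `CC` (counter-clockwise); `side` is `ab_top` (abaxial surface scanned face
#' up) or `ad_bottom` (adaxial surface).
#'
#' @param path CSV path.
#' @return Tibble with columns `file`, `shoot_id`, `node` (integer),
#'   `phyllotaxy`, `side`, `dpi`.
#' @export
read_leaf_metadata <- function(path) {
  tbl <- readr::read_csv(path, col_types = readr::cols(
    file = "c", shoot_id = "c", node = "c", phyllotaxy = "c", side = "c", dpi = "d"))
  need <- c("file", "shoot_id", "node", "phyllotaxy", "side", "dpi")
  miss <- setdiff(need, names(tbl))
  if (length(miss)) stop("metadata is missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (!all(tbl$phyllotaxy %in% c("CL", "CC"))) {
    stop("`phyllotaxy` must be 'CL' or 'CC'", call. = FALSE)
  }
  if (!all(tbl$side %in% c("ab_top", "ad_bottom"))) {
    stop("`side` must be 'ab_top' or 'ad_bottom'", call. = FALSE)
  }
  dplyr::mutate(tbl, node = parse_node_label(.data$node))
}

#' Load a full leaf dataset (masks + metadata) into a tibble
#'
#' Reads every mask listed in a metadata table, extracts contours and areas,
#' and validates the record structure: exactly one `ab_top` and at most one
#' `ad_bottom` scan per (shoot, node).
#'
#' @param metadata Path to a metadata CSV (see [read_leaf_metadata()]) or an
#'   equivalent tibble.
#' @param image_dir Directory holding the mask images; defaults to the
#'   metadata file's directory.
#' @param foreground Passed to [load_mask()].
#' @return Tibble with one row per scanned leaf side: `shoot_id`, `node`,
#'   `phyllotaxy`, `side`, `dpi`, `area_cm2`, and a `contour` list-column.
#' @export
read_leaf_dataset <- function(metadata, image_dir = NULL, foreground = "nonzero") {
  if (is.character(metadata)) {
    if (is.null(image_dir)) image_dir <- dirname(metadata)
    metadata <- read_leaf_metadata(metadata)
  } else if (is.null(image_dir)) {
    image_dir <- "."
  }
  validate_leaf_records(metadata)
  rows <- purrr::pmap(metadata, function(file, shoot_id, node, phyllotaxy, side, dpi, ...) {
    mask <- load_mask(file.path(image_dir, file), dpi = dpi, foreground = foreground)
    tibble::tibble(shoot_id = shoot_id, node = node, phyllotaxy = phyllotaxy,
                   side = side, dpi = dpi,
                   area_cm2 = compute_area_cm2(mask),
                   contour = list(extract_contour(mask)))
  })
  dplyr::bind_rows(rows)
}

# shared record-structure invariant
validate_leaf_records <- function(tbl) {
  counts <- dplyr::count(tbl, .data$shoot_id, .data$node, .data$side)
  if (any(counts$n > 1)) stop("duplicate (shoot_id, node, side) records", call. = FALSE)
  wide <- dplyr::count(dplyr::filter(tbl, .data$side == "ab_top"),
                       .data$shoot_id, .data$node)
  all_keys <- dplyr::distinct(tbl, .data$shoot_id, .data$node)
  if (nrow(wide) != nrow(all_keys)) {
    stop("every (shoot_id, node) needs exactly one ab_top record", call. = FALSE)
  }
  invisible(tbl)
}
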