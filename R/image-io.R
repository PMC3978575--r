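#' Read a greyscale mammogram image
#'
#' Reads an 8- or 16-bit greyscale PNG, TIFF or PGM file at its native bit
#' depth. Colour (RGB) inputs are rejected: digitised film mammograms are
#' single-channel and silent channel collapsing would corrupt intensities.
#'
#' @param path Path to a `.png`, `.tif`/`.tiff`, or `.pgm` file.
#' @param source_id Identifier stored on the image; defaults to the file
#'   name without extension.
#' @return A [grey_image].
#' @export
read_image <- function(path, source_id = NULL) {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  if (is.null(source_id))
    source_id <- tools::file_path_sans_ext(basename(path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    depth <- .png_bit_depth(path)
    arr <- png::readPNG(path)
    if (length(dim(arr)) == 3L) {
      if (dim(arr)[3] >= 3L)
        stop("unsupported format: '", path, "' is a colour (RGB) image")
      arr <- arr[, , 1L]  # greyscale + alpha: keep the grey channel
    }
    px <- round(arr * (2^depth - 1))
  } else if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
    depth <- attr(arr, "bits.per.sample")
    if (is.null(depth)) depth <- if (max(arr) > 255) 16L else 8L
    if (length(dim(arr)) == 3L) {
      if (dim(arr)[3] >= 3L)
        stop("unsupported format: '", path, "' is a colour (RGB) image")
      arr <- arr[, , 1L]
    }
    px <- arr
  } else if (ext == "pgm") {
    pgm <- .read_pgm(path)
    px <- pgm$pixels
    depth <- pgm$bit_depth
  } else {
    stop("unsupported format: '", path, "' (expected PNG, TIFF or PGM)")
  }
  grey_image(px, bit_depth = as.integer(depth), source_id = source_id)
}

#' Write a greyscale image
#'
#' Writes at native bit depth. PNG output is 8-bit only (16-bit images go to
#' TIFF or PGM); TIFF and PGM support both depths.
#'
#' @param image A [grey_image].
#' @param path Output path; format chosen by extension (`.png`, `.tif`,
#'   `.tiff`, `.pgm`).
#' @return Invisibly, `path`.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "grey_image"))
  ext <- tolower(tools::file_ext(path))
  maxv <- .max_intensity(image)
  if (ext == "png") {
    if (image$bit_depth != 8L)
      stop("PNG output supports 8-bit only; use TIFF or PGM for 16-bit")
    png::writePNG(image$pixels / maxv, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(image$pixels / maxv, path,
                    bits.per.sample = image$bit_depth)
  } else if (ext == "pgm") {
    .write_pgm(image$pixels, maxv, path)
  } else {
    stop("unsupported output format: '", path, "'")
  }
  invisible(path)
}

# Bit depth from the PNG IHDR chunk (byte 25 of the file: 8-byte signature,
# 4-byte length, "IHDR", width, height, then bit depth).
.png_bit_depth <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 25L)
  if (length(hdr) < 25L) stop("cannot read image file: ", path)
  as.integer(hdr[25L])
}

# --- PGM (portable greymap), P2 ascii and P5 binary -------------------------

.read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2L))
  if (!magic %in% c("P2", "P5")) stop("cannot read image file: ", path)
  # header tokens (width, height, maxval) with '#' comments allowed
  tokens <- integer(0)
  buf <- character(0)
  while (length(tokens) < 3L) {
    ch <- rawToChar(readBin(con, "raw", 1L))
    if (length(ch) == 0L || ch == "") stop("truncated PGM header: ", path)
    if (ch == "#") {
      repeat {
        ch <- rawToChar(readBin(con, "raw", 1L))
        if (ch %in% c("\n", "\r") || ch == "") break
      }
      ch <- " "
    }
    if (grepl("[0-9]", ch)) {
      buf <- c(buf, ch)
    } else if (length(buf)) {
      tokens <- c(tokens, as.integer(paste(buf, collapse = "")))
      buf <- character(0)
    }
  }
  w <- tokens[1]; h <- tokens[2]; maxval <- tokens[3]
  depth <- if (maxval > 255L) 16L else 8L
  n <- w * h
  if (magic == "P5") {
    size <- if (maxval > 255L) 2L else 1L
    vals <- readBin(con, "integer", n = n, size = size, signed = FALSE,
                    endian = "big")
  } else {
    txt <- readChar(con, nchars = file.size(path), useBytes = TRUE)
    vals <- as.integer(strsplit(trimws(txt), "[[:space:]]+")[[1]])[seq_len(n)]
  }
  if (length(vals) < n || anyNA(vals)) stop("truncated PGM data: ", path)
  list(pixels = matrix(vals, nrow = h, ncol = w, byrow = TRUE),
       bit_depth = depth)
}

.write_pgm <- function(pixels, maxval, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(sprintf("P5\n%d %d\n%d\n", ncol(pixels), nrow(pixels),
                             maxval)), con)
  vals <- as.integer(t(pixels))
  if (maxval > 255L) {
    writeBin(vals, con, size = 2L, endian = "big", useBytes = TRUE)
  } else {
    writeBin(as.raw(vals), con)
  }
  invisible(path)
}

# --- masks and overlays -----------------------------------------------------

#' Write a binary mask image
#'
#' Mask pixels are written at full intensity, background at 0, as an 8-bit
#' image so masks round-trip byte-identically through any supported format.
#'
#' @param mask A `breast_mask`, `dense_mask`, or logical matrix.
#' @param path Output path (`.png`, `.tif`, `.tiff` or `.pgm`).
#' @return Invisibly, `path`.
#' @export
write_mask <- function(mask, path) {
  px <- if (is.matrix(mask)) mask else mask$pixels
  img <- grey_image(matrix(ifelse(px, 255L, 0L), nrow(px), ncol(px)),
                    bit_depth = 8L, source_id = "mask")
  write_image(img, path)
}

# Boundary of a binary mask: mask pixels with at least one 4-neighbour
# outside the mask (or on the image edge).
.mask_boundary <- function(px) {
  nr <- nrow(px); nc <- ncol(px)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- px
  inner <- pad[2:(nr + 1L), 2:(nc + 1L)] &
    pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
    pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
  px & !inner
}

#' Write segmentation overlay images
#'
#' Produces the two mark-up images reported for each mammogram: an outline
#' overlay with the breast boundary burned in at mid-grey and the dense-area
#' boundary at maximum intensity, and a binary dense-area mask image.
#'
#' @param image The original [grey_image].
#' @param breast A `breast_mask` sharing the image dimensions.
#' @param dense A `dense_mask` sharing the image dimensions.
#' @param outline_path,mask_path Output paths. 16-bit sources must use TIFF
#'   or PGM for the outline overlay.
#' @return Invisibly, `c(outline_path, mask_path)`.
#' @export
write_overlay <- function(image, breast, dense, outline_path, mask_path) {
  stopifnot(inherits(image, "grey_image"))
  bpx <- breast$pixels; dpx <- dense$pixels
  if (!identical(dim(bpx), dim(image$pixels)) ||
      !identical(dim(dpx), dim(image$pixels)))
    stop("mask dimensions do not match image dimensions")
  maxv <- .max_intensity(image)
  out <- image$pixels
  out[.mask_boundary(bpx)] <- as.integer(maxv %/% 2L)  # breast: mid-grey
  out[.mask_boundary(dpx)] <- maxv                     # dense: maximum
  write_image(grey_image(out, image$bit_depth,
                         paste0(image$source_id, "_outline")), outline_path)
  write_mask(dpx, mask_path)
  invisible(c(outline_path, mask_path))
}

# --- results table ----------------------------------------------------------

#' Assemble a results table from per-image density results
#'
#' @param results A list of `density_result` objects (see [process_image]).
#' @return A data frame with columns `source_id`, `status`,
#'   `breast_area_px`, `dense_area_px`, `percent_density`, `threshold`; one
#'   row per input in input order. Failed rows carry their failure reason in
#'   `status` and `NA` numeric fields.
#' @export
results_table <- function(results) {
  stopifnot(is.list(results))
  rows <- lapply(results, function(r) {
    if (identical(r$status, "success")) {
      data.frame(source_id = r$source_id, status = "OK",
                 breast_area_px = r$breast_area_px,
                 dense_area_px = r$dense_area_px,
                 percent_density = r$percent_density,
                 threshold = r$threshold, stringsAsFactors = FALSE)
    } else {
      data.frame(source_id = r$source_id, status = r$reason,
                 breast_area_px = NA_integer_, dense_area_px = NA_integer_,
                 percent_density = NA_real_, threshold = NA_real_,
                 stringsAsFactors = FALSE)
    }
  })
  if (length(rows) == 0L)
    return(data.frame(source_id = character(), status = character(),
                      breast_area_px = integer(), dense_area_px = integer(),
                      percent_density = numeric(), threshold = numeric(),
                      stringsAsFactors = FALSE))
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (anyDuplicated(tab$source_id))
    warning("duplicate source_id values in results table")
  tab
}

#' Write the indexed results table as CSV
#'
#' Comma-separated, UTF-8, `.` decimal. `percent_density` is rendered with
#' two decimals; failed rows leave numeric fields empty.
#'
#' @param table Data frame from [results_table].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_results <- function(table, path) {
  out <- table
  out$percent_density <- ifelse(is.na(table$percent_density), "",
                                sprintf("%.2f", table$percent_density))
  for (col in c("breast_area_px", "dense_area_px", "threshold"))
    out[[col]] <- ifelse(is.na(table[[col]]), "",
                         format(table[[col]], trim = TRUE, scientific = FALSE))
  write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a results table CSV written by [write_results]
#' @param path CSV path.
#' @return Data frame with the canonical column types.
#' @export
read_results <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(source_id = "character"))
  need <- c("source_id", "status", "breast_area_px", "dense_area_px",
            "percent_density", "threshold")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("results CSV is missing column(s): ", paste(missing, collapse = ", "))
  for (col in c("breast_area_px", "dense_area_px", "percent_density",
                "threshold"))
    tab[[col]] <- suppressWarnings(as.numeric(tab[[col]]))
  tab
}
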