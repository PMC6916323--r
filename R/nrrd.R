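# Minimal NRRD0004 attached-header raw-encoding reader/writer.
# Axis order on disk is (col, row, slice) with col fastest, matching the
# usual x-fastest NRRD layout; space is LPS ("left-posterior-superior").

.nrrd_types <- c(uint8 = 1L, int16 = 2L, float64 = 8L, double = 8L)

.write_nrrd <- function(path, arr, origin, spacing, direction, type) {
  dims <- dim(arr)   # (slice, row, col)
  dir_cols <- direction %*% diag(spacing)   # columns: slice, row, col axes
  fmt_vec <- function(v) sprintf("(%.10g,%.10g,%.10g)", v[1], v[2], v[3])
  hdr <- c(
    "NRRD0004",
    paste0("type: ", type),
    "dimension: 3",
    paste0("sizes: ", dims[3], " ", dims[2], " ", dims[1]),
    "encoding: raw",
    "endian: little",
    "space: left-posterior-superior",
    paste0("space directions: ", fmt_vec(dir_cols[, 3]), " ",
           fmt_vec(dir_cols[, 2]), " ", fmt_vec(dir_cols[, 1])),
    paste0("space origin: ", fmt_vec(origin)),
    "", "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste(hdr, collapse = "\n")), con)
  flat <- as.vector(aperm(arr, c(3, 2, 1)))   # col fastest
  if (type == "uint8") writeBin(as.raw(flat), con)
  else if (type == "int16") writeBin(as.integer(flat), con, size = 2L,
                                     endian = "little")
  else writeBin(as.numeric(flat), con, size = 8L, endian = "little")
  invisible(path)
}

.read_nrrd <- function(path) {
  raw <- readBin(path, raw(), file.size(path))
  # header ends at the first blank line
  nl <- which(raw == as.raw(10L))
  hdr_end <- NA
  prev <- 0L
  for (p in nl) {
    if (p == prev + 1L) { hdr_end <- p; break }
    prev <- p
  }
  if (is.na(hdr_end)) stop("malformed NRRD header (no blank line): ", path)
  lines <- strsplit(rawToChar(raw[1:(hdr_end - 2L)]), "\n")[[1]]
  if (!grepl("^NRRD000[1-5]$", lines[1])) stop("not an NRRD file: ", path)
  fields <- list()
  for (ln in lines[-1]) {
    if (grepl("^#", ln) || !grepl(":", ln)) next
    kv <- regmatches(ln, regexpr(": *", ln), invert = TRUE)[[1]]
    fields[[tolower(kv[1])]] <- kv[2]
  }
  type <- fields[["type"]]
  if (!type %in% names(.nrrd_types)) stop("unsupported NRRD type: ", type)
  if (!identical(fields[["encoding"]], "raw"))
    stop("only raw encoding supported")
  sizes <- as.integer(strsplit(fields[["sizes"]], " +")[[1]])
  stopifnot(length(sizes) == 3L)
  n <- prod(sizes)
  bytes <- raw[(hdr_end + 1L):length(raw)]
  vals <- if (type == "uint8") as.integer(bytes[seq_len(n)])
          else if (type == "int16") readBin(bytes, integer(), n, size = 2L,
                                            signed = TRUE, endian = "little")
          else readBin(bytes, numeric(), n, size = 8L, endian = "little")
  arr <- aperm(array(vals, dim = sizes), c(3, 2, 1))  # back to (slice,row,col)

  parse_vecs <- function(s) {
    m <- gregexpr("\\(([^)]*)\\)", s)[[1]]
    vecs <- regmatches(s, gregexpr("\\(([^)]*)\\)", s))[[1]]
    lapply(vecs, function(v)
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]))
  }
  origin <- c(0, 0, 0); spacing <- c(1, 1, 1); direction <- NULL
  if (!is.null(fields[["space origin"]]))
    origin <- parse_vecs(fields[["space origin"]])[[1]]
  if (!is.null(fields[["space directions"]])) {
    dirs <- parse_vecs(fields[["space directions"]])  # (col, row, slice) axes
    spacing <- c(sqrt(sum(dirs[[3]]^2)), sqrt(sum(dirs[[2]]^2)),
                 sqrt(sum(dirs[[1]]^2)))
    direction <- cbind(dirs[[3]] / spacing[1], dirs[[2]] / spacing[2],
                       dirs[[1]] / spacing[3])
  }
  if (is.null(direction)) direction <- cbind(c(0, 0, 1), c(0, 1, 0), c(1, 0, 0))
  list(arr = arr, origin = origin, spacing = spacing, direction = direction)
}

#' Write a binary mask as an NRRD file
#'
#' Values are `{0,1}` uint8; space directions and origin reproduce the mask's
#' grid geometry.
#'
#' @param m a [binary_mask()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_mask_nrrd <- function(m, path) {
  stopifnot(inherits(m, "binary_mask"))
  arr <- array(as.integer(m$bits), dim = dim(m$bits))
  .write_nrrd(path, arr, m$origin, m$spacing, m$direction, "uint8")
  invisible(path)
}

#' Read a mask from NRRD
#'
#' @param path NRRD file with `{0,1}` values
#' @param roi_name name to attach to the mask
#' @return a [binary_mask()]
#' @export
read_mask_nrrd <- function(path, roi_name = basename(path)) {
  x <- .read_nrrd(path)
  binary_mask(x$arr != 0, roi_name, x$origin, x$spacing, x$direction)
}

#' Write an image volume as NRRD
#'
#' @param vol an [image_volume()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_volume_nrrd <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  .write_nrrd(path, vol$voxels, vol$origin, vol$spacing, vol$direction,
              "double")
  invisible(path)
}

#' Read an image volume from NRRD (the pre-gridded bypass path)
#'
#' @param path NRRD scalar volume
#' @param modality,patient_id metadata to attach
#' @return an [image_volume()]
#' @export
read_volume_nrrd <- function(path, modality = "CT", patient_id = "") {
  x <- .read_nrrd(path)
  image_volume(x$arr, x$origin, x$spacing, x$direction,
               modality = modality, patient_id = patient_id)
}
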