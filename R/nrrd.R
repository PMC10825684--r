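#' Read and write voxel grids as ASCII NRRD
#'
#' Minimal, spacing-aware NRRD I/O for 3-D masks and dose grids.  Only the
#' subset of the format the package emits is supported: `dimension: 3`,
#' `encoding: ascii`, `sizes`, `spacings` and an optional `axis mins` line
#' recording the physical coordinate of the first voxel center.  Data are in
#' NRRD order (first axis fastest), which matches R's column-major arrays.
#'
#' @param x a [voxel_mask()] or [dose_grid()].
#' @param path file path (conventionally `.nrrd`).
#' @return `write_nrrd()` returns `path` invisibly; `read_nrrd()` returns a
#'   `voxel_mask` (when the stored type is `uchar`) or a `dose_grid`.
#' @examples
#' ph <- generate_phantom_pair(dim = c(8, 8, 8), radius = 3)
#' f <- tempfile(fileext = ".nrrd")
#' write_nrrd(ph$mask_a, f)
#' m <- read_nrrd(f)
#' identical(m$grid, ph$mask_a$grid)
#' @export
write_nrrd <- function(x, path) {
  is_mask <- inherits(x, "voxel_mask")
  if (!is_mask && !inherits(x, "dose_grid"))
    stop("'x' must be a voxel_mask or dose_grid")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("NRRD0004",
               sprintf("type: %s", if (is_mask) "uchar" else "double"),
               "dimension: 3",
               sprintf("sizes: %s", paste(dim(x$grid), collapse = " ")),
               sprintf("spacings: %s",
                       paste(format(x$spacing, digits = 17), collapse = " ")),
               sprintf("axis mins: %s",
                       paste(format(x$origin, digits = 17), collapse = " ")),
               "encoding: ascii",
               ""), con)
  vals <- if (is_mask) as.integer(x$grid) else as.vector(x$grid)
  writeLines(paste(format(vals, digits = 17, trim = TRUE, scientific = FALSE),
                   collapse = " "), con)
  invisible(path)
}

#' @rdname write_nrrd
#' @export
read_nrrd <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "NRRD")) stop("not an NRRD file: ", path)
  blank <- which(lines == "")[1]
  if (is.na(blank)) stop("malformed NRRD: missing blank line before data")
  hdr <- lines[2:(blank - 1)]
  hdr <- hdr[!startsWith(hdr, "#")]
  kv <- strsplit(hdr, ": ", fixed = TRUE)
  keys <- vapply(kv, `[[`, character(1), 1L)
  vals <- vapply(kv, function(z) paste(z[-1], collapse = ": "), character(1))
  field <- function(k, default = NULL) {
    i <- match(k, keys)
    if (is.na(i)) default else vals[i]
  }
  if (field("dimension") != "3") stop("only 3-D NRRD grids are supported")
  if (tolower(field("encoding", "")) != "ascii")
    stop("only ascii-encoded NRRD is supported")
  sizes <- as.integer(strsplit(field("sizes"), "\\s+")[[1]])
  spacing <- as.numeric(strsplit(field("spacings", "1 1 1"), "\\s+")[[1]])
  origin <- as.numeric(strsplit(field("axis mins", "0 0 0"), "\\s+")[[1]])
  data <- scan(text = paste(lines[(blank + 1):length(lines)], collapse = " "),
               quiet = TRUE)
  if (length(data) != prod(sizes))
    stop(sprintf("NRRD data length %d does not match sizes (%s)",
                 length(data), paste(sizes, collapse = "x")))
  arr <- array(data, dim = sizes)
  if (field("type") %in% c("uchar", "uint8", "int", "uint"))
    voxel_mask(arr != 0, spacing, origin)
  else dose_grid(arr, spacing, origin)
}
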