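#' Cubic density maps
#'
#' A \code{density_map} is a cubic \code{n x n x n} array of finite real
#' voxel values (arbitrary density units, possibly negative) plus a voxel
#' size in Angstrom per voxel.  The physical center of the grid is the
#' voxel at 0-based index \code{n \%/\% 2} along each axis (1-based index
#' \code{n \%/\% 2 + 1}); all rotations, reflections and reported shifts
#' use this origin, matching the zero-frequency-centered Fourier
#' convention for both even and odd \code{n}.
#'
#' @param data numeric 3D array with equal dimensions.
#' @param voxel_size voxel edge length in Angstrom (default 1).
#' @return an object of class \code{density_map}.
#' @export
density_map <- function(data, voxel_size = 1) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("'data' must be a 3D array", call. = FALSE)
  }
  d <- dim(data)
  if (d[1L] != d[2L] || d[2L] != d[3L]) {
    stop("density map must be cubic; got ", paste(d, collapse = "x"),
         call. = FALSE)
  }
  if (anyNA(data) || any(!is.finite(data))) {
    stop("density map contains non-finite values", call. = FALSE)
  }
  stopifnot(is.numeric(voxel_size), length(voxel_size) == 1L,
            is.finite(voxel_size), voxel_size > 0)
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 n = d[1L]),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("density_map: %d^3 voxels, %.4g A/voxel, range [%.4g, %.4g]\n",
              x$n, x$voxel_size, min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.density_map <- function(x) dim(x$data)

.as_map <- function(x) {
  if (inherits(x, "density_map")) return(x)
  if (is.array(x) && length(dim(x)) == 3L) return(density_map(x))
  stop("expected a density_map or a cubic 3D array", call. = FALSE)
}

# MRC2014 / CCP4 volume format, mode 2 (32-bit IEEE float), little-endian.
# Header is 1024 bytes of 4-byte words; only the words needed to round-trip
# cubic mode-2 volumes are interpreted.

#' Read a density map from an MRC/CCP4 file
#'
#' Supports MRC2014 mode 2 (32-bit float) volumes on cubic grids.  The
#' voxel size is taken as \code{CELLA / MX} from the header.  Extended
#' headers (\code{NSYMBT > 0}) are skipped.
#'
#' @param path path to an existing \code{.mrc}/\code{.map} file.
#' @return a \code{\link{density_map}}.
#' @export
read_mrc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 256L, size = 4L, endian = "little")
  if (length(hdr_int) < 256L) stop("corrupt MRC header (short file)", call. = FALSE)
  nx <- hdr_int[1L]; ny <- hdr_int[2L]; nz <- hdr_int[3L]
  mode <- hdr_int[4L]
  mx <- hdr_int[8L]
  nsymbt <- hdr_int[24L]
  if (any(c(nx, ny, nz) <= 0L) || any(c(nx, ny, nz) > 4096L)) {
    stop("corrupt MRC header (implausible dimensions)", call. = FALSE)
  }
  if (mode != 2L) {
    stop("unsupported MRC mode ", mode, " (only mode 2, 32-bit float)",
         call. = FALSE)
  }
  if (nx != ny || ny != nz) {
    stop("non-cubic volume (", nx, "x", ny, "x", nz,
         "); only cubic maps are supported", call. = FALSE)
  }
  # reread cell dimensions as floats (words 11-13)
  seek(con, 40L)
  cella <- readBin(con, "double", n = 3L, size = 4L, endian = "little")
  voxel <- if (mx > 0L && cella[1L] > 0) cella[1L] / mx else 1
  seek(con, 1024L + max(0L, nsymbt))
  vals <- readBin(con, "double", n = nx * ny * nz, size = 4L,
                  endian = "little")
  if (length(vals) < nx * ny * nz) stop("corrupt MRC file (truncated data)",
                                        call. = FALSE)
  density_map(array(vals, dim = c(nx, ny, nz)), voxel_size = voxel)
}

#' Write a density map to an MRC/CCP4 file
#'
#' Writes MRC2014 mode 2 (32-bit float, little-endian).  Voxel data and
#' voxel size round-trip exactly at 32-bit precision through
#' \code{\link{read_mrc}}.
#'
#' @param map a \code{\link{density_map}} (or cubic 3D array).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_mrc <- function(map, path) {
  map <- .as_map(map)
  n <- map$n
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  v <- as.numeric(map$data)
  wi(c(n, n, n))          # NX NY NZ
  wi(2L)                  # MODE 2 = float32
  wi(c(0L, 0L, 0L))       # NXSTART..
  wi(c(n, n, n))          # MX MY MZ
  wf(rep(n * map$voxel_size, 3L))  # CELLA
  wf(c(90, 90, 90))       # CELLB
  wi(c(1L, 2L, 3L))       # MAPC MAPR MAPS
  wf(c(min(v), max(v), mean(v)))   # DMIN DMAX DMEAN
  wi(1L)                  # ISPG (volume)
  wi(0L)                  # NSYMBT
  wi(rep(0L, 25L))        # EXTRA (words 26-50)
  wf(c(0, 0, 0))          # ORIGIN (words 50-52 in MRC2014)
  writeBin(charToRaw("MAP "), con)                 # word 53
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con) # machine stamp, LE
  wf(stats::sd(v))        # RMS
  wi(0L)                  # NLABL
  writeBin(raw(800L), con)  # labels
  writeBin(v, con, size = 4L, endian = "little")
  invisible(path)
}
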