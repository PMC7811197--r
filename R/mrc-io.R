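#' Read and write volumes in MRC2014 format
#'
#' `write_volume()` stores a [voxel_grid()] as a 32-bit float MRC2014 file
#' (mode 2, little-endian), recording the voxel size in the header cell
#' parameters. `read_volume()` reads it back; the round trip preserves the
#' density array bit-exactly and the voxel size to 32-bit float precision.
#'
#' The pipeline assumes isotropic voxels: files whose header implies
#' different spacings along the three axes are rejected, as are non-3-D
#' files and modes other than 32-bit float.
#'
#' @param path file path.
#' @param grid a [voxel_grid()].
#' @return `read_volume()` returns a [voxel_grid()]; `write_volume()`
#'   returns `path` invisibly.
#' @examples
#' g <- voxel_grid(array(rnorm(4 * 4 * 4), c(4, 4, 4)), voxel_size_nm = 0.7)
#' f <- tempfile(fileext = ".mrc")
#' write_volume(g, f)
#' g2 <- read_volume(f)
#' stopifnot(identical(dim(g2$data), dim(g$data)))
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  h_int <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nx <- h_int[1]; ny <- h_int[2]; nz <- h_int[3]; mode <- h_int[4]
  mx <- h_int[8]; my <- h_int[9]; mz <- h_int[10]
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  if (any(c(nx, ny, nz) <= 0)) {
    stop("malformed MRC header: non-positive dimension (nx/ny/nz)", call. = FALSE)
  }
  if (min(nx, ny, nz) == 1L) {
    stop("not a 3-D volume: one of nx/ny/nz is 1", call. = FALSE)
  }
  if (mode != 2L) {
    stop("unsupported MRC mode ", mode, " (only mode 2, 32-bit float)", call. = FALSE)
  }
  if (any(c(mx, my, mz) <= 0) || any(cella <= 0)) {
    stop("malformed MRC header: non-positive sampling (mx/my/mz) or cell (cella)",
         call. = FALSE)
  }
  # cella is in Angstrom per MRC2014; voxel size nm = cella / (10 * m)
  vox <- cella / c(mx, my, mz) / 10
  if (max(vox) / min(vox) > 1 + 1e-4) {
    stop("anisotropic voxel size in header cella: ",
         paste(signif(vox, 6), collapse = ", "),
         " nm; the pipeline assumes isotropic voxels", call. = FALSE)
  }
  seek(con, 23 * 4)
  nsymbt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  seek(con, 1024 + nsymbt)
  n <- nx * ny * nz
  vals <- readBin(con, "numeric", n = n, size = 4, endian = "little")
  if (length(vals) != n) stop("truncated MRC data section", call. = FALSE)
  voxel_grid(array(vals, c(nx, ny, nz)), voxel_size_nm = mean(vox))
}

#' @rdname read_volume
#' @export
write_volume <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  d <- dim(grid$data)
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  vox_ang <- grid$voxel_size_nm * 10
  writeBin(as.integer(c(d, 2L)), con, size = 4, endian = "little")   # nx ny nz mode
  writeBin(integer(3), con, size = 4, endian = "little")             # nxstart..
  writeBin(as.integer(d), con, size = 4, endian = "little")          # mx my mz
  writeBin(as.numeric(d * vox_ang), con, size = 4, endian = "little")  # cella
  writeBin(c(90, 90, 90), con, size = 4, endian = "little")          # cellb
  writeBin(1:3, con, size = 4, endian = "little")                    # mapc/r/s
  writeBin(as.numeric(c(min(grid$data), max(grid$data), mean(grid$data))),
           con, size = 4, endian = "little")                         # dmin/max/mean
  writeBin(c(1L, 0L), con, size = 4, endian = "little")              # ispg, nsymbt
  writeBin(raw(25 * 4), con)                                         # extra
  writeBin(numeric(3), con, size = 4, endian = "little")             # origin
  writeBin(charToRaw("MAP "), con)                                   # word 53
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)                   # machine stamp LE
  writeBin(as.numeric(stats::sd(grid$data)), con, size = 4, endian = "little")
  writeBin(0L, con, size = 4, endian = "little")                     # nlabl
  writeBin(raw(800), con)                                            # labels
  writeBin(as.numeric(grid$data), con, size = 4, endian = "little")
  invisible(path)
}
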