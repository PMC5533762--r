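# Minimal LAS 1.2 reader/writer, point data record format 1 (XYZ as scaled
# int32, return flags, classification, GPS time). Enough for interchange with
# standard LiDAR tooling; the CSV dialect remains the canonical format.

.las_header_size <- 227L
.las_point_len <- 28L

read_las <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  sig <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(sig, "LASF")) stop("not a LAS file: ", path, call. = FALSE)
  invisible(readBin(con, "raw", 20L))              # source id .. GUID
  ver <- readBin(con, "integer", 2L, size = 1L, signed = FALSE)
  if (ver[1] != 1L)
    stop("unsupported LAS major version ", ver[1], call. = FALSE)
  invisible(readBin(con, "raw", 68L))              # sysid, software, dates
  header_size <- readBin(con, "integer", 1L, size = 2L, signed = FALSE)
  point_offset <- readBin(con, "integer", 1L, size = 4L)
  invisible(readBin(con, "integer", 1L, size = 4L))  # VLR count
  fmt <- readBin(con, "integer", 1L, size = 1L, signed = FALSE)
  if (!fmt %in% c(1L, 3L))
    stop("unsupported LAS point format ", fmt, " (need GPS time)", call. = FALSE)
  rec_len <- readBin(con, "integer", 1L, size = 2L, signed = FALSE)
  n_points <- readBin(con, "integer", 1L, size = 4L)
  invisible(readBin(con, "integer", 5L, size = 4L))  # points by return
  scales <- readBin(con, "double", 3L)
  offsets <- readBin(con, "double", 3L)
  invisible(readBin(con, "double", 6L))              # min/max
  seek(con, point_offset)
  raw <- readBin(con, "raw", n_points * rec_len)
  stride <- rec_len
  at <- function(start, n) {  # column of n bytes from each record
    idx <- rep(seq(0L, by = stride, length.out = n_points), each = n) +
      rep(seq(start, length.out = n), n_points)
    raw[idx]
  }
  xi <- readBin(at(1L, 4L), "integer", n_points, size = 4L)
  yi <- readBin(at(5L, 4L), "integer", n_points, size = 4L)
  zi <- readBin(at(9L, 4L), "integer", n_points, size = 4L)
  flags <- as.integer(at(15L, 1L))
  cls <- as.integer(at(16L, 1L))
  gps <- readBin(at(21L, 8L), "double", n_points)
  dt <- data.table(
    x = xi * scales[1] + offsets[1],
    y = yi * scales[2] + offsets[2],
    z = zi * scales[3] + offsets[3],
    return_number = bitwAnd(flags, 7L),
    number_of_returns = bitwAnd(bitwShiftR(flags, 3L), 7L),
    pulse_id = gps,
    point_class = ifelse(cls == 2L, "ground", "vegetation"))
  point_cloud(dt, height_mode = "elevation")
}

write_las <- function(cloud, path) {
  dt <- as.data.table(cloud)
  n <- nrow(dt)
  scale <- 0.001
  off <- c(min(dt$x), min(dt$y), min(dt$z))
  pulse_num <- as.numeric(as.integer(factor(dt$pulse_id,
                                            levels = unique(dt$pulse_id))))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("LASF", con, 4L, eos = NULL)
  writeBin(raw(20L), con)                                  # source id + GUID
  writeBin(as.raw(c(1L, 2L)), con)                         # version 1.2
  writeBin(raw(64L), con)                                  # sysid + software
  writeBin(as.integer(c(1L, 2026L)), con, size = 2L)       # day, year
  writeBin(.las_header_size, con, size = 2L)
  writeBin(.las_header_size, con, size = 4L)               # point data offset
  writeBin(0L, con, size = 4L)                             # no VLRs
  writeBin(as.raw(1L), con)                                # point format 1
  writeBin(.las_point_len, con, size = 2L)
  writeBin(n, con, size = 4L)
  by_ret <- vapply(1:5, function(r) sum(dt$return_number == r), integer(1))
  writeBin(by_ret, con, size = 4L)
  writeBin(rep(scale, 3L), con)
  writeBin(off, con)
  writeBin(as.double(rbind(apply(dt[, .(x, y, z)], 2L, max),
                           apply(dt[, .(x, y, z)], 2L, min))), con)
  flags <- as.raw(bitwOr(dt$return_number,
                         bitwShiftL(dt$number_of_returns, 3L)))
  cls <- as.raw(ifelse(dt$point_class == "ground", 2L, 5L))
  rec <- vector("list", n)
  ints <- cbind(as.integer(round((dt$x - off[1]) / scale)),
                as.integer(round((dt$y - off[2]) / scale)),
                as.integer(round((dt$z - off[3]) / scale)))
  body <- raw(n * .las_point_len)
  for (i in seq_len(n)) {
    base <- (i - 1L) * .las_point_len
    body[base + 1:12] <- writeBin(ints[i, ], raw(), size = 4L)
    # intensity (2 bytes) left zero at base+13:14
    body[base + 15L] <- flags[i]
    body[base + 16L] <- cls[i]
    # scan angle, user data, point source id zero at base+17:20
    body[base + 21:28] <- writeBin(pulse_num[i], raw())
  }
  writeBin(body, con)
  invisible(path)
}
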