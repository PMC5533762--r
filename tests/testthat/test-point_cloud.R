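test_that("CSV round-trip and parsing honour the dialect", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("x,y,z,return_number,number_of_returns,pulse_id,point_class",
               "0,0,100,1,2,7,vegetation",
               "0,0,95,2,2,7,vegetation",
               "1,1,90,1,1,8,ground"), f)
  cl <- read_point_table(f)
  expect_s3_class(cl, "lidar_cloud")
  expect_equal(nrow(cl), 3L)
  expect_equal(data.table::uniqueN(cl$pulse_id), 2L)
  expect_identical(cloud_height_mode(cl), "elevation")

  out <- tempfile(fileext = ".csv")
  write_point_table(cl, out)
  back <- read_point_table(out)
  expect_equal(as.data.frame(back), as.data.frame(cl))
})

test_that("invalid return numbering and missing columns are rejected", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("x,y,z,return_number,number_of_returns,pulse_id,point_class",
               "0,0,100,3,2,7,vegetation"), f)
  expect_error(read_point_table(f), "return_number")

  f2 <- tempfile(fileext = ".csv")
  writeLines(c("x,y,z,return_number,pulse_id",
               "0,0,100,1,7"), f2)
  expect_error(read_point_table(f2), "lacks column")

  dt <- make_points(0, 0, 1)
  dt2 <- rbind(dt, dt)            # duplicate return slot in one pulse
  dt2$pulse_id <- c(1L, 1L)
  expect_error(point_cloud(dt2), "bookkeeping")
})

test_that("LAS 1.2 write/read round-trips coordinates within precision", {
  set.seed(3)
  dt <- make_points(runif(50, 0, 30), runif(50, 0, 30), runif(50, 90, 130))
  dt$return_number <- rep(1:2, 25)
  dt$number_of_returns <- 2L
  dt$pulse_id <- rep(1:25, each = 2L)
  dt$point_class[1:5] <- "ground"
  cl <- point_cloud(dt)
  f <- tempfile(fileext = ".las")
  write_point_table(cl, f, format = "las")
  back <- read_point_table(f)
  expect_equal(back$x, cl$x, tolerance = 1e-3)
  expect_equal(back$y, cl$y, tolerance = 1e-3)
  expect_equal(back$z, cl$z, tolerance = 1e-3)
  expect_identical(back$return_number, cl$return_number)
  expect_identical(back$number_of_returns, cl$number_of_returns)
  expect_identical(back$point_class, cl$point_class)
})

test_that("build_dem recovers constant and planar ground", {
  set.seed(1)
  g <- make_points(runif(200, 0, 10), runif(200, 0, 10), rep(100, 200),
                   class = "ground")
  dem <- build_dem(point_cloud(g))
  expect_true(all(abs(dem$values - 100) < 1e-12))

  # planar ground z = 0.1 x: cell means lie within 0.1 * cell_size of plane
  set.seed(2)
  xs <- runif(5000, 0, 20); ys <- runif(5000, 0, 20)
  dem2 <- build_dem(point_cloud(make_points(xs, ys, 0.1 * xs,
                                            class = "ground")))
  centers_x <- dem2$origin[1] + (seq_len(nrow(dem2$values)) - 0.5) *
    dem2$cell_size
  plane <- matrix(0.1 * centers_x, nrow(dem2$values), ncol(dem2$values))
  expect_lt(max(abs(dem2$values - plane)), 0.1 * dem2$cell_size)

  expect_error(build_dem(point_cloud(make_points(1, 1, 1, class = "ground"))),
               "3 ground points")
})

test_that("DEM void cells are filled from neighbours", {
  # ground only at two elevations on either side of a gap
  g <- make_points(c(0.5, 0.5, 2.5, 2.5, 4.5, 4.5),
                   c(0.5, 2.5, 0.5, 4.5, 0.5, 2.5),
                   c(10, 10, 10, 10, 20, 20), class = "ground")
  dem <- build_dem(point_cloud(g), cell_size = 1)
  expect_false(anyNA(dem$values))
  expect_true(all(dem$values %in% c(10, 20)))
})

test_that("normalize_heights subtracts DEM, drops ground, clamps", {
  g <- make_points(rep(seq(0.5, 9.5), each = 10),
                   rep(seq(0.5, 9.5), times = 10), rep(100, 100),
                   class = "ground")
  veg <- make_points(c(5, 6, 7), c(5, 6, 7), c(105, 99.5, 112),
                     pulse_id = 200 + 1:3)
  cl <- point_cloud(rbind(g, veg))
  dem <- build_dem(cl)
  norm <- normalize_heights(cl, dem)
  expect_identical(cloud_height_mode(norm), "above_ground")
  expect_equal(nrow(norm), 3L)                     # ground points removed
  expect_equal(sort(norm$z), c(0, 5, 12))          # clamped at 0
  expect_error(normalize_heights(norm, dem), "already")
})

test_that("clip_circular retains, buffers and drops correctly", {
  dt <- make_points(c(14.9, 16.0, 20.0), c(0, 0, 0), c(1, 2, 3))
  cl <- point_cloud(dt)
  out <- clip_circular(cl, c(0, 0), radius = 15, buffer = 4.7)
  expect_equal(nrow(out), 2L)                      # 20 > 19.7 dropped
  expect_identical(out$in_buffer, c(FALSE, TRUE))
  expect_equal(cloud_area(out), pi * 15^2)
  # buffered clip is a superset of the unbuffered clip
  plain <- clip_circular(cl, c(0, 0), radius = 15)
  expect_true(all(plain$x %in% out$x))
})

test_that("point_density counts per area with first-return variant", {
  dt <- make_points(runif(400), runif(400), runif(400))
  cl <- point_cloud(dt, area = 100)
  expect_equal(point_density(cl), 4.0)
  expect_equal(point_density(point_cloud(dt[0], area = 100)), 0)
  expect_error(point_density(point_cloud(dt)), "area")
  dt2 <- copy(dt)
  dt2$return_number[1:100] <- 2L
  dt2$number_of_returns <- ifelse(seq_len(400) <= 200, 2L, 1L)
  dt2$pulse_id <- c(1:100, 1:100, 201:400)
  cl2 <- point_cloud(dt2, area = 100)
  expect_equal(point_density(cl2, first_return_only = TRUE), 3.0)
})
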