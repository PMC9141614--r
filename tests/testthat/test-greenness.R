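test_that("label image validates raster values against the palette", {
  expect_error(label_image(matrix(9L, 2, 2), default_palette()), "not in palette")
  img <- uniform_label_image(10, 10, class_id = 3L)  # tree
  expect_s3_class(img, "label_image")
  expect_error(label_image(matrix(integer(0), 0, 0), default_palette()), "at least one pixel")
})

test_that("green_fraction counts vegetation classes case-insensitively", {
  expect_equal(unname(green_fraction(uniform_label_image(10, 10, 3L))), c(100, 100))
  expect_equal(unname(green_fraction(uniform_label_image(10, 10, 1L))), c(0, 100))
  # constructed fixture with a known green count
  m <- matrix(0L, 100, 100)
  m[seq_len(1234)] <- 4L  # grass
  expect_equal(unname(green_fraction(label_image(m, default_palette()))), c(1234, 10000))
  # palette name case does not matter
  pal <- c(`0` = "Sky", `1` = "TREE")
  img <- label_image(matrix(c(0L, 1L, 1L, 1L), 2, 2), pal)
  expect_equal(unname(green_fraction(img)), c(3, 4))
})

test_that("HSV classifier is exact on constructed pure-color fixtures", {
  mk <- function(r, g, b, h = 10, w = 10) {
    a <- array(0, c(h, w, 3)); a[, , 1] <- r; a[, , 2] <- g; a[, , 3] <- b; a
  }
  expect_equal(unname(green_fraction(classify_green(mk(0, 255, 0)))), c(100, 100))
  expect_equal(unname(green_fraction(classify_green(mk(128, 128, 128)))), c(0, 100))
  # 30% pure-green on gray
  a <- mk(128, 128, 128, 10, 10)
  idx <- seq_len(30)
  red <- a[, , 1]; grn <- a[, , 2]; blu <- a[, , 3]
  red[idx] <- 0; grn[idx] <- 255; blu[idx] <- 0
  a[, , 1] <- red; a[, , 2] <- grn; a[, , 3] <- blu
  expect_equal(unname(green_fraction(classify_green(a))), c(30, 100))
  expect_error(classify_green(matrix(1, 5, 5)), "3-channel")
})

test_that("point GVI is the ratio of sums over views", {
  pal <- c(`0` = "background", `1` = "green")
  frac_img <- function(f, h, w) {
    m <- matrix(0L, h, w); m[seq_len(round(f * h * w))] <- 1L
    label_image(m, pal, green_classes = "green")
  }
  # equal sizes: ratio of sums = mean of ratios
  views <- lapply(c(0.1, 0.2, 0.3, 0.4), frac_img, h = 20, w = 20)
  expect_equal(point_gvi(views), 0.25)
  # hand-summed counts on 640x480 views: 107520 / 1228800
  counts <- c(30720, 61440, 0, 15360)
  views2 <- lapply(counts / (640 * 480), frac_img, h = 640, w = 480)
  expect_equal(point_gvi(views2), 0.0875)
  # unequal sizes discriminate ratio-of-sums from mean-of-ratios
  views3 <- list(frac_img(1, 10, 10), frac_img(0, 10, 30))
  expect_equal(point_gvi(views3), 0.25)  # 100 / 400, not 0.5
  # order invariance
  expect_equal(point_gvi(rev(views2)), point_gvi(views2))
  expect_error(point_gvi(list()), "at least one view")
})

test_that("point GVI recovers planted fractions from rendered views to quantization", {
  shape <- c(37, 23)  # deliberately awkward sizes
  npx <- 4 * prod(shape)
  for (f in c(0.03, 0.31, 0.774)) {
    v <- render_views(f, shape, 4, seed = 13)
    expect_lt(abs(point_gvi(v) - f), 1 / npx)
  }
  # exact when the planted count is integral
  v <- render_views(0.25, c(10, 10), 4, seed = 2)
  expect_identical(point_gvi(v), 0.25)
})

test_that("QC applies the exclusion list and the minimum-view rule", {
  mk_point <- function(id, n_views) {
    list(id = id, x = id, y = 0,
         views = replicate(n_views, uniform_label_image(5, 5, 3L), simplify = FALSE))
  }
  pts <- list(mk_point(1, 4), mk_point(2, 4), mk_point(3, 3))
  out <- apply_qc(pts, exclusion_list = 2, min_views = 4)
  expect_equal(vapply(out, `[[`, "", "qc_status"), c("kept", "excluded", "excluded"))
  expect_equal(out[[1]]$gvi, 1)
  expect_true(is.na(out[[2]]$gvi))
  # all kept with empty list and enough views
  out2 <- apply_qc(pts[1:2], min_views = 4)
  expect_true(all(vapply(out2, `[[`, "", "qc_status") == "kept"))
  tab <- points_table(out)
  expect_equal(tab$qc_status, c("kept", "excluded", "excluded"))
  expect_true(all(is.na(tab$gvi[2:3])))
})

test_that("label images round-trip through PNG + palette sidecar", {
  v <- render_views(0.4, c(16, 12), 1, seed = 8)[[1]]
  path <- file.path(withr::local_tempdir(), "view.png")
  write_label_image(v, path)
  back <- read_label_image(path)
  expect_identical(back$classes, v$classes)
  expect_identical(unname(back$palette), unname(v$palette))
  expect_identical(green_fraction(back), green_fraction(v))
})
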