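test_that("square stimulus geometry: perimeter count, polarity, inward normals", {
  st <- make_square_stimulus(64, 20, polarity = "light-on-dark")
  # perimeter of an s x s square has 4s - 4 pixels
  expect_equal(nrow(st$boundary), 4 * 20 - 4)
  expect_equal(sum(st$boundary_mask), 4 * 20 - 4)
  expect_true(all(st$pixels %in% c(0.25, 0.75)))

  # top edge points downward (toward the interior)
  top <- st$boundary[st$boundary$row == min(st$boundary$row) &
                       !(st$boundary$col %in% range(st$boundary$col)), ]
  expect_true(all(top$angle == 3 * pi / 2))

  # every perimeter normal points strictly inside: positive dot product with
  # the pixel-to-center vector (row axis points down, so dy = -d_row)
  ctr <- c(32.5, 32.5)
  dx <- ctr[2] - st$boundary$col
  dy <- st$boundary$row - ctr[1]  # y is up, rows grow downward
  dot <- cos(st$boundary$angle) * dx + sin(st$boundary$angle) * dy
  expect_true(all(dot > 0))

  # dark-on-light polarity: figure darker than background, exact inversion
  std <- make_square_stimulus(64, 20, polarity = "dark-on-light")
  expect_lt(std$pixels[32, 32], std$pixels[1, 1])
  expect_equal(std$pixels, 1 - st$pixels)
})

test_that("square outside the image is rejected", {
  expect_error(make_square_stimulus(64, 40, center = c(10, 32)), "outside")
  expect_error(make_square_stimulus(8, 4), "at least 16")
})

test_that("simulated cell responses are reproducible and exact at zero noise", {
  ref <- tibble::tibble(scene_point_id = paste0("p", 1:6),
                        bos = c(0.9, -0.4, 0.2, 0.8, -0.1, 0.5))
  r0 <- simulate_cell_responses(ref, gain = 1.5, noise_sd = 0, n_repeats = 3, seed = 7)
  expect_equal(r0$bos, rep(1.5 * ref$bos, each = 3))

  ra <- simulate_cell_responses(ref, gain = 2, noise_sd = 0.3, n_repeats = 5, seed = 11)
  rb <- simulate_cell_responses(ref, gain = 2, noise_sd = 0.3, n_repeats = 5, seed = 11)
  expect_identical(ra, rb)
  rc <- simulate_cell_responses(ref, gain = 2, noise_sd = 0.3, n_repeats = 5, seed = 12)
  expect_false(identical(ra$bos, rc$bos))

  expect_error(simulate_cell_responses(ref, n_repeats = 1, seed = 1), "repeats")
  expect_error(simulate_cell_responses(ref, noise_sd = -1, seed = 1), "non-negative")
})

test_that("sample means of simulated responses concentrate at gain x reference", {
  # CLT bound: with sd 0.1 and 50 repeats, each per-point mean lies within
  # 3 * 0.1 / sqrt(50) of 2 x reference (checked at a fixed seed)
  ref <- tibble::tibble(scene_point_id = paste0("p", 1:20),
                        bos = seq(-1, 1, length.out = 20))
  r <- simulate_cell_responses(ref, gain = 2, noise_sd = 0.1, n_repeats = 50, seed = 42)
  means <- tapply(r$bos, r$scene_point_id, mean)[ref$scene_point_id]
  expect_true(all(abs(means - 2 * ref$bos) < 3 * 0.1 / sqrt(50)))
})

test_that("image and annotation round trips preserve content", {
  # PNG round trip through the reader: values rescaled to [0, 1]
  px <- matrix(seq(0, 1, length.out = 24 * 24), 24, 24)
  tmp <- withr::local_tempfile(fileext = ".png")
  EBImage::writeImage(EBImage::Image(t(px)), tmp)
  img <- read_image(tmp)
  expect_s3_class(img, "annotated_image")
  expect_true(max(img$pixels) <= 1 && min(img$pixels) >= 0)
  expect_lt(max(abs(img$pixels - px)), 1 / 255)
  expect_null(img$boundary)

  expect_error(read_image(file.path(tempdir(), "nope.png")), "exist")

  st <- make_square_stimulus(32, 10)
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  write_boundary_annotation(st$boundary, tmp2)
  back <- read_boundary_annotation(tmp2)
  expect_equal(back$row, st$boundary$row)
  expect_equal(back$angle, st$boundary$angle)

  tmp3 <- withr::local_tempfile(fileext = ".csv")
  resp <- simulate_cell_responses(
    tibble::tibble(scene_point_id = c("a", "b"), bos = c(1, -1)),
    noise_sd = 0.1, n_repeats = 2, seed = 3)
  write_scene_points(resp, tmp3)
  expect_equal(read_scene_points(tmp3)$bos, resp$bos)
})

test_that("pixel bounds are enforced", {
  expect_error(annotated_image(matrix(2, 20, 20)), "\\[0, 1\\]")
  expect_error(annotated_image(matrix(-0.1, 20, 20)), "\\[0, 1\\]")
})
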