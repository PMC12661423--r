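test_that("binarisation recovers painted-pixel counts and symmetries", {
  img <- matrix(0, 40, 40)
  img[1:10, ] <- 1          # 400 known white pixels
  lab <- binarize_image(img, threshold = 0.5)
  expect_equal(sum(lab == 1), 400)
  expect_equal(sum(lab == 0), 1200)
  # all-white image: every seed pixel white (degenerate histogram)
  lab1 <- binarize_image(matrix(1, 10, 10), threshold = 0.5)
  expect_true(all(lab1 == 1))
  # inverting the image swaps the labels (fixed threshold)
  lab_inv <- binarize_image(1 - img, threshold = 0.5)
  expect_true(all(lab_inv == 1 - lab))
  # crop excludes background from the counts
  labc <- binarize_image(img, threshold = 0.5, crop = c(1, 20, 1, 40))
  expect_equal(sum(!is.na(labc)), 800)
  expect_error(binarize_image(matrix(numeric(0), 0, 0)), "non-empty")
  # Otsu lands between the two modes of a bimodal image
  thr <- attr(binarize_image(img), "threshold")
  expect_true(thr > 0 && thr < 1)
})

test_that("grid fractions partition the frame exactly", {
  img <- matrix(0, 100, 100); img[, 41:100] <- 1   # left 2/5 black
  lab <- binarize_image(img, threshold = 0.5)
  g <- grid_fractions(lab, grid = 5)
  expect_equal(nrow(g), 25)
  expect_equal(sum(g$n_pixels), 100 * 100)           # partition-exact
  expect_true(all(g$x_white %in% c(0, 1)))           # grid-aligned halves
  expect_equal(attr(g, "x_bar"), 0.6)
  # uniform random labels: every cell fraction near the overall mean
  lab_r <- withr::with_seed(1, matrix(rbinom(4e4, 1, 0.5), 200, 200))
  gr <- grid_fractions(lab_r, grid = 5)
  expect_true(all(abs(gr$x_white - 0.5) < 0.05))     # binomial, n = 1600/cell
  expect_error(grid_fractions(lab, grid = 1), ">= 2")
})

test_that("mixing entropy hits its analytic anchors", {
  # fully mixed: every cell at the overall fraction
  chess <- matrix(rep(c(0L, 1L), 50), 100, 100)      # alternating rows
  expect_equal(mixing_entropy(grid_fractions(chess, 5)), 1, tolerance = 1e-12)
  # fully segregated: every cell pure
  img <- matrix(0L, 100, 100); img[, 41:100] <- 1L
  expect_equal(mixing_entropy(grid_fractions(img, 5)), 0)
  # two-cell hand evaluation: s(0.25)/s(0.5) = 0.562.../0.693...
  g2 <- tibble::tibble(row = 1, col = 1:2, n_pixels = c(100L, 100L),
                       x_white = c(0.25, 0.75))
  expect_equal(mixing_entropy(g2, x_bar = 0.5), 0.811278124459133,
               tolerance = 1e-9)
  # undefined for a single-colour bed
  expect_error(mixing_entropy(grid_fractions(matrix(1L, 10, 10), 2)),
               "one colour")
})

test_that("entropy is bounded, colour-symmetric and grid-monotone", {
  lab <- withr::with_seed(8, {
    m <- matrix(0L, 120, 120)
    m[, 1:60] <- rbinom(120 * 60, 1, 0.25)
    m[, 61:120] <- rbinom(120 * 60, 1, 0.75)
    m
  })
  s <- mixing_entropy(grid_fractions(lab, 4))
  expect_true(s >= 0 && s <= 1)
  # relabelling colours leaves S unchanged
  expect_equal(mixing_entropy(grid_fractions(1L - lab, 4)), s, tolerance = 1e-12)
  # refining the grid never increases S (entropy is concave)
  s_coarse <- mixing_entropy(grid_fractions(lab, 2))
  s_mid <- mixing_entropy(grid_fractions(lab, 4))
  s_fine <- mixing_entropy(grid_fractions(lab, 8))
  expect_gte(s_coarse, s_mid)
  expect_gte(s_mid, s_fine)
})

test_that("image time series tracks a bed that homogenises", {
  dir <- withr::local_tempdir()
  sidecar <- gen_mixing_sequence(dir, n = 6, size = 100, seed = 2)
  ts <- entropy_timeseries(dir, times = sidecar)
  expect_equal(nrow(ts), 6)
  expect_true(!is.unsorted(ts$entropy))        # segregated -> mixed
  expect_equal(ts$entropy[1], 0)
  expect_gt(dplyr::last(ts$entropy), 0.95)
  # repeated identical image: constant S
  f <- file.path(dir, "bed_0003.png")
  ts2 <- entropy_timeseries(c(f, f, f),
                            times = tibble::tibble(filename = "bed_0003.png",
                                                   time_s = 0))
  expect_equal(length(unique(round(ts2$entropy, 12))), 1)
  # shuffled input order with explicit timestamps sorts identically
  files <- list.files(dir, full.names = TRUE)
  ts3 <- entropy_timeseries(rev(files), times = sidecar)
  expect_equal(ts3$entropy, ts$entropy)
  # unreadable file: warned and skipped
  bad <- file.path(dir, "bed_9999.png")
  writeLines("not a png", bad)
  expect_warning(ts4 <- entropy_timeseries(c(files[1], bad)), "Skipping")
  expect_equal(nrow(ts4), 1)
})

test_that("mixedness sweep produces monotone entropy", {
  ss <- vapply(c(0.1, 0.4, 0.7, 1.0), function(p) {
    f <- gen_mixing_image(withr::local_tempfile(fileext = ".png"),
                          "intermediate", mix = p, size = 150, seed = 11)
    mixing_entropy(grid_fractions(binarize_image(as.character(f), 0.5), 5))
  }, numeric(1))
  expect_true(all(diff(ss) > 0))
  expect_gt(ss[4], 0.95)   # Bernoulli(0.5) everywhere: near fully mixed
})
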