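test_that("preprocessing flattens illumination and keeps cell amplitude", {
  uniform <- matrix(80, 128, 128)
  out <- preprocess_image(uniform)
  expect_lt(max(out), 2)   # top-hat removes constant background

  sim <- simulate_fluorescence_image(12, c(256, 256), 6, 180, 40,
                                     illumination_gradient = 0.5, seed = 6)
  pre <- preprocess_image(sim$image)
  # illumination unevenness (corner-to-corner background difference) is
  # flattened from ~16 intensity units to < 5
  lo <- function(m) median(m[1:56, 1:56])
  hi <- function(m) median(m[200:256, 200:256])
  expect_gt(hi(sim$image) - lo(sim$image), 10)
  expect_lt(abs(hi(pre) - lo(pre)), 5)
  # disc peaks retain most of their amplitude
  peaks <- vapply(seq_len(nrow(sim$centroids)), function(i) {
    pre[round(sim$centroids$x[i]), round(sim$centroids$y[i])]
  }, numeric(1))
  expect_gt(min(peaks), 0.8 * (180 - 40))

  # isolated max-value pixels are removed by the median filter
  salt <- matrix(0, 64, 64)
  salt[cbind(c(10, 30, 50), c(12, 33, 55))] <- 255
  expect_lt(max(preprocess_image(salt, tophat_radius = 7)), 10)
  expect_warning(preprocess_image(uniform, tophat_radius = 3,
                                  cell_radius = 6), "attenuated")
})

test_that("segmentation counts discs and splits touching pairs", {
  dark <- matrix(20, 64, 64)
  expect_equal(segment_nuclei(dark)$count, 0)

  sim <- simulate_fluorescence_image(20, c(256, 256), 6, 200, 10,
                                     overlap_fraction = 0, seed = 7)
  seg <- segment_nuclei(preprocess_image(sim$image))
  expect_equal(seg$count, 20)

  # two discs overlapping by ~30% of a radius split into 2 by watershed
  img <- matrix(0, 80, 80)
  for (ctr in list(c(40, 35), c(40, 35 + 1.7 * 6))) {
    d2 <- (row(img) - ctr[1])^2 + (col(img) - ctr[2])^2
    img[d2 <= 36] <- 200
  }
  expect_equal(segment_nuclei(img)$count, 2)
  expect_error(segment_nuclei(img, threshold = 300), "\\[0, 255\\]")
})

test_that("counting is accurate and illumination-invariant", {
  rec <- prec <- numeric(3)
  for (i in 1:3) {
    sim <- simulate_fluorescence_image(25, c(256, 256), 6, 160, 30,
                                       illumination_gradient = 0.4,
                                       overlap_fraction = 0.08,
                                       seed = 100 + i)   # SNR > 4
    seg <- segment_nuclei(preprocess_image(sim$image))
    m <- match_centroids(seg$centroids, sim$centroids, max_dist = 6)
    rec[i] <- m$recall; prec[i] <- m$precision
  }
  expect_gte(mean(rec), 0.95)
  expect_gte(mean(prec), 0.95)

  # identical layout with and without gradient: counts differ by <= 2%
  flat <- simulate_fluorescence_image(30, c(256, 256), 6, 160, 30,
                                      illumination_gradient = 0,
                                      overlap_fraction = 0.1, seed = 55)
  grad <- simulate_fluorescence_image(30, c(256, 256), 6, 160, 30,
                                      illumination_gradient = 0.5,
                                      overlap_fraction = 0.1, seed = 55)
  c1 <- segment_nuclei(preprocess_image(flat$image))$count
  c2 <- segment_nuclei(preprocess_image(grad$image))$count
  expect_lte(abs(c1 - c2) / c1, 0.02)
})

test_that("densities pool sections and scale correctly", {
  d <- compute_density(100, mask_areas_px = 1e6, pixel_size_um = 10,
                       thickness_um = 1)  # 0.1 mm^3
  expect_equal(d$density, 1000)
  # doubling counts and volume leaves density unchanged
  d2 <- compute_density(c(100, 100), c(1e6, 1e6), 10, 1)
  expect_equal(d2$density, d$density)
  # multi-section sums equal the pooled computation
  d3 <- compute_density(c(40, 60), c(4e5, 6e5), 10, 1)
  expect_equal(d3$density, compute_density(100, 1e6, 10, 1)$density)
  expect_error(compute_density(5, 0, 10, 1), "zero")
})

test_that("fold induction is anchored at the baseline group", {
  an <- data.frame(animal = 1:6,
                   condition = rep(c("No Stim", "USV"), each = 3),
                   density_a1 = c(8, 10, 12, 20, 19, 21),
                   density_s1 = c(10, 10, 10, 10, 10, 10))
  fi <- fold_induction(an)
  base <- fi$per_condition[fi$per_condition$condition == "No Stim", ]
  expect_identical(base$mean_fold, 1)   # exactly, by construction
  expect_equal(fi$per_condition$mean_fold[
    fi$per_condition$condition == "USV"], 2)

  flat <- data.frame(animal = 1:4, condition = rep(c("No Stim", "x"), 2),
                     density_a1 = 7, density_s1 = 7)
  expect_true(all(fold_induction(flat)$per_animal$fold == 1))

  z <- an; z$density_s1[5] <- 0
  expect_warning(fz <- fold_induction(z), "zero S1")
  expect_equal(nrow(fz$per_animal), 5)
  expect_error(fold_induction(an[an$condition != "No Stim", ]), "baseline")
})
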