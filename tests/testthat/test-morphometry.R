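test_that("binarization separates a two-level image exactly", {
  px <- matrix(0.1, 40, 40)
  px[10:20, 15:25] <- 0.9
  mask <- binarize(micrograph(px), method = "otsu")
  expect_identical(as.vector(mask), as.vector(px == 0.9))

  empty <- binarize(micrograph(px), method = "fixed", level = 1.0)
  expect_false(any(empty))
  expect_error(binarize(micrograph(matrix(0.5, 5, 5))), "constant")
})

test_that("otsu masks a noisy phantom with high Jaccard overlap", {
  ph <- generate_phantom(
    n_fibers = 5, width = 160, height = 160, noise_sd = 0.05, seed = 2
  )
  mask <- binarize(ph$image, method = "otsu")
  truth <- ph$truth$label_map > 0
  jaccard <- sum(mask & truth) / sum(mask | truth)
  expect_gt(jaccard, 0.95)
})

test_that("disjoint rectangles are labeled and measured exactly", {
  m <- matrix(FALSE, 30, 30)
  m[2:5, 2:7] <- TRUE # 4 x 6 = 24 px
  m[10:14, 20:22] <- TRUE # 5 x 3 = 15 px
  m[25:26, 10:10] <- TRUE # 2 x 1 = 2 px
  seg <- label_components(m, pixel_size = 10)
  expect_equal(seg$n_components, 3)
  expect_setequal(seg$components$area_nm2, c(24, 15, 2) * 100)
})

test_that("connectivity semantics split or join diagonal chains", {
  m <- matrix(FALSE, 10, 10)
  for (i in 1:6) m[i, i] <- TRUE
  expect_equal(label_components(m, connectivity = 8)$n_components, 1)
  expect_equal(label_components(m, connectivity = 4)$n_components, 6)
})

test_that("labels are permutation stable and contiguous", {
  set.seed(5)
  m <- matrix(runif(400) > 0.7, 20, 20)
  seg <- label_components(m)
  expect_equal(sort(unique(as.vector(seg$label_map[seg$label_map > 0]))),
    seq_len(seg$n_components))
  # transposing the mask permutes components but preserves the area multiset
  seg_t <- label_components(t(m))
  expect_setequal(seg$components$area_nm2, seg_t$components$area_nm2)
})

test_that("zero-noise phantoms are segmented exactly", {
  ph <- generate_phantom(
    n_fibers = 12, n_spheres = 2, width = 256, height = 256,
    noise_sd = 0, seed = 4
  )
  mask <- binarize(ph$image, method = "fixed", level = 0.5)
  seg <- label_components(mask, pixel_size = ph$image$pixel_size)
  expect_equal(seg$n_components, ph$truth$n_components)
  expect_setequal(seg$components$n_pixels, ph$truth$components$n_pixels)
  expect_equal(
    sort(seg$components$length_nm),
    sort(ph$truth$components$length_nm),
    tolerance = 1e-12
  )
})

test_that("pixel-size equivariance scales lengths by k and areas by k^2", {
  ph <- generate_phantom(n_fibers = 6, width = 128, height = 128, seed = 9)
  mask <- ph$truth$label_map > 0
  k <- 3.7
  s1 <- label_components(mask, pixel_size = 2)
  s2 <- label_components(mask, pixel_size = 2 * k)
  expect_equal(s2$components$length_nm, k * s1$components$length_nm)
  expect_equal(s2$components$area_nm2, k^2 * s1$components$area_nm2)
})

test_that("canny edges trace a sharp disc boundary", {
  px <- matrix(0, 80, 80)
  ctr <- 40
  for (r in 1:80) for (cc in 1:80) {
    if ((r - ctr)^2 + (cc - ctr)^2 <= 20^2) px[r, cc] <- 1
  }
  img <- micrograph(px)
  mask <- px > 0.5
  cmp <- canny_compare(img, mask, sigma = 1)
  expect_false(cmp$undefined)
  expect_gt(cmp$overlap_fraction, 0.9)

  # edge pixels stay within 2 px of the true boundary for >= 90% of them
  boundary <- protact:::mask_boundary(mask)
  near_boundary <- protact:::dilate_mask(boundary, 2)
  edge_px <- which(cmp$edge_map)
  expect_gt(mean(near_boundary[edge_px]), 0.9)
})

test_that("a blank image yields zero edges with the undefined flag", {
  img <- micrograph(matrix(0, 30, 30))
  cmp <- canny_compare(img, matrix(FALSE, 30, 30))
  expect_true(cmp$undefined)
  expect_equal(cmp$overlap_fraction, 0)
  expect_equal(cmp$n_edges, 0)
})

test_that("morphometry summary follows the documented sd conventions", {
  seg <- structure(
    list(
      label_map = matrix(0L, 1, 1), n_components = 2,
      components = tibble::tibble(
        label = 1:2, n_pixels = c(10, 30),
        area_nm2 = c(1000, 3000), length_nm = c(100, 300)
      ),
      pixel_size = 10
    ),
    class = "segmentation_result"
  )
  pop <- morphometry_summary(seg)
  expect_equal(pop$stats$mean_length, 200)
  expect_equal(pop$stats$sd_length, 100) # population: sqrt(mean((x - m)^2))
  smp <- morphometry_summary(seg, sd_type = "sample")
  expect_equal(smp$stats$sd_length, sqrt(2) * 100, tolerance = 1e-12)
  expect_equal(sum(pop$histogram$count), 2)

  single <- seg
  single$components <- single$components[1, ]
  expect_equal(morphometry_summary(single)$stats$sd_length, 0)
  empty <- seg
  empty$components <- seg$components[0, ]
  expect_error(morphometry_summary(empty), "empty")
})

test_that("pipeline recovers phantom ground truth statistics", {
  for (seed in 1:3) {
    ph <- generate_phantom(
      n_fibers = 8, width = 192, height = 192, noise_sd = 0, seed = seed
    )
    mask <- binarize(ph$image, method = "fixed", level = 0.5)
    seg <- label_components(mask, pixel_size = ph$image$pixel_size)
    got <- morphometry_summary(seg)$stats
    want <- morphometry_summary(ph$truth)$stats
    expect_equal(got$mean_length, want$mean_length, tolerance = 0.05)
    expect_equal(got$mean_area, want$mean_area, tolerance = 0.05)
  }
})

test_that("phantoms are reproducible and reject overcrowded geometry", {
  a <- generate_phantom(n_fibers = 4, width = 96, height = 96, seed = 3)
  b <- generate_phantom(n_fibers = 4, width = 96, height = 96, seed = 3)
  expect_identical(a$image$pixels, b$image$pixels)

  expect_error(
    generate_phantom(
      n_spheres = 50, sphere_radius = 20, width = 64, height = 64,
      seed = 1, max_tries = 5
    ),
    "overcrowded"
  )
})

test_that("a lone disc phantom is recovered as one component", {
  ph <- generate_phantom(
    n_fibers = 0, n_spheres = 1, width = 96, height = 96,
    sphere_radius = 15, noise_sd = 0, seed = 6
  )
  mask <- binarize(ph$image, method = "fixed", level = 0.5)
  seg <- label_components(mask, pixel_size = ph$image$pixel_size)
  expect_equal(seg$n_components, 1)
  expect_equal(
    seg$components$n_pixels,
    ph$truth$components$n_pixels
  )
})
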