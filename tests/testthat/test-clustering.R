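test_that("k-means closed-form cases: K = 1 and K = n", {
  set.seed(1)
  x <- matrix(rnorm(20), 10, 2)
  m1 <- fit_kmeans(x, 1, seed = 0, n_restarts = 3)
  expect_equal(m1$centroids[1, ], colMeans(x))
  expect_equal(m1$final_sse, sum(sweep(x, 2, colMeans(x))^2))
  mn <- fit_kmeans(x, nrow(x), seed = 0, n_restarts = 3)
  expect_equal(mn$final_sse, 0)
  expect_error(fit_kmeans(x, 11, seed = 0), "distinct")
  expect_error(fit_kmeans(x[0, , drop = FALSE], 1), "no pixels")
})

test_that("k-means matches the exhaustive-partition optimum on small instances", {
  set.seed(2)
  x <- matrix(rnorm(12), 6, 2)
  m <- fit_kmeans(x, 2, seed = 0, n_restarts = 25)
  expect_equal(m$final_sse, kmeans_brute_force_sse(x, 2), tolerance = 1e-9)
  # and never beats stats::kmeans badly nor the optimum at all
  skm <- stats::kmeans(x, 2, nstart = 25)
  expect_lte(m$final_sse, skm$tot.withinss + 1e-9)
})

test_that("SSE trace is non-increasing and fits are deterministic in the seed", {
  set.seed(3)
  for (rep in 1:5) {
    x <- matrix(runif(8 * 3), 8, 3)
    m <- fit_kmeans(x, 3, seed = rep, n_restarts = 5)
    expect_true(all(diff(m$sse_trace) <= 1e-9))
  }
  x <- matrix(runif(60), 20, 3)
  expect_identical(fit_kmeans(x, 4, seed = 9), fit_kmeans(x, 4, seed = 9))
})

test_that("pixel assignment is nearest-centroid with lowest-id tie-breaking", {
  wl <- c(500, 600)
  ctr <- matrix(c(0, 0, 1, 1, 2, 2, 4, 4, 6, 6), 5, 2, byrow = TRUE)
  model <- structure(list(K = 5L, centroids = ctr, wavelengths = wl),
                     class = "cluster_model")
  vals <- array(0, c(1, 3, 2))
  vals[1, 1, ] <- c(2, 2)   # equals centroid 3
  vals[1, 2, ] <- c(5, 5)   # equidistant to centroids 4 (id 4) and 5 (id 5)
  vals[1, 3, ] <- c(0.1, 0.1)
  cube <- spectral_cube(vals, wl, "assign")
  lab <- assign_pixels(model, cube)
  expect_equal(lab[1, 1], 3)
  expect_equal(lab[1, 2], 4)  # tie broken to the lower id
  expect_equal(lab[1, 3], 1)
  bad <- spectral_cube(vals, c(510, 610), "assign")
  expect_error(assign_pixels(model, bad), "grid")
})

test_that("assigning the training pixels reproduces the converged labelling", {
  set.seed(4)
  x <- matrix(runif(40 * 3), 40, 3)
  m <- fit_kmeans(x, 3, seed = 1, n_restarts = 10)
  vals <- array(0, c(8, 5, 3))
  for (r in 1:8) for (cc in 1:5) vals[r, cc, ] <- x[(r - 1) * 5 + cc, ]
  cube <- spectral_cube(vals, c(500, 600, 700), "train")
  # one Lloyd step from the converged centroids does not move them
  lab <- as.vector(t(assign_pixels(m, cube)))
  px <- as_pixel_matrix(cube)
  for (j in 1:3)
    expect_equal(colMeans(px[lab == j, , drop = FALSE]), m$centroids[j, ],
                 tolerance = 1e-6)
})

test_that("thrombus cluster identification follows override and similarity rules", {
  b <- toy_basis(20)
  ctr <- rbind(b$components$rbc,
               b$components$filter,
               0.6 * b$components$rbc + 0.4 * b$components$plasma,
               b$components$ice)
  model <- structure(list(K = 4L, centroids = ctr, wavelengths = b$wavelengths),
                     class = "cluster_model")
  expect_identical(identify_thrombus_clusters(model, b, override = c(9, 11) - 7L),
                   c(2L, 4L))
  expect_error(identify_thrombus_clusters(model, b, override = 9), "out of range")
  ids <- identify_thrombus_clusters(model, b)
  expect_true(1 %in% ids)       # pure RBC centroid: similarity 1
  expect_true(3 %in% ids)       # RBC/plasma mixture
  expect_false(2 %in% ids)      # filter centroid excluded
  expect_false(4 %in% ids)      # ice centroid excluded
  # nothing matching -> warning and empty result
  flat <- structure(list(K = 1L,
                         centroids = matrix(b$components$filter, 1),
                         wavelengths = b$wavelengths),
                    class = "cluster_model")
  expect_warning(ids2 <- identify_thrombus_clusters(flat, b), "no cluster")
  expect_length(ids2, 0)
})

test_that("masking and area fraction are exact counts", {
  lab <- matrix(c(1, 2, 2, 3), 2, 2)
  expect_equal(mask_thrombus(lab, 1:3), matrix(TRUE, 2, 2))
  expect_equal(mask_thrombus(lab, integer(0)), matrix(FALSE, 2, 2))
  expect_equal(sum(mask_thrombus(lab, 2)), sum(lab == 2))
  expect_equal(thrombus_area_fraction(matrix(TRUE, 5, 5)), 1)
  expect_equal(thrombus_area_fraction(matrix(FALSE, 5, 5)), 0)
  expect_equal(thrombus_area_fraction(matrix(rep(c(TRUE, FALSE), c(30, 70)),
                                             10, 10)), 0.30)
  expect_error(thrombus_area_fraction(logical(0)), "empty")
})

test_that("k-fraction profiles are compositional and relabelling-invariant", {
  b <- toy_basis(16)
  wl <- b$wavelengths
  # two equal-size, spectrally distinct thrombus sub-regions
  h <- 8; w <- 8
  vals <- array(rep(b$components$filter, each = h * w), c(h, w, 16))
  for (r in 1:4) for (cc in 1:w) vals[r, cc, ] <- b$components$rbc
  for (r in 5:8) for (cc in 1:w) vals[r, cc, ] <- b$components$plasma
  cube <- spectral_cube(vals, wl, "two-region")
  mask <- matrix(TRUE, h, w)
  prof <- kfractions(cube, mask, K2 = 2, seed = 0, n_restarts = 5)
  expect_equal(sort(prof$fractions), c(0.5, 0.5))
  expect_equal(sum(prof$fractions), 1, tolerance = 1e-9)
  expect_equal(prof$area_fraction, 1)
  expect_false(prof$degenerate)

  # all-identical thrombus pixels: one fraction 1 (via a 1-cluster model)
  vals1 <- array(rep(b$components$rbc, each = h * w), c(h, w, 16))
  cube1 <- spectral_cube(vals1, wl, "uniform")
  prof1 <- kfractions(cube1, mask, K2 = 1, seed = 0, n_restarts = 2)
  expect_equal(prof1$fractions, 1)

  # degenerate when fewer thrombus pixels than K2
  small_mask <- matrix(FALSE, h, w); small_mask[1, 1:3] <- TRUE
  profd <- kfractions(cube, small_mask, K2 = 7)
  expect_true(profd$degenerate)
  expect_true(all(is.na(profd$fractions)))
  expect_equal(profd$n_thrombus_pixels, 3)

  # permuting cluster ids permutes the fractions (multiset preserved)
  model <- fit_kmeans(as_pixel_matrix(cube), 2, seed = 0, n_restarts = 5,
                      wavelengths = wl)
  perm_model <- model
  perm_model$centroids <- model$centroids[c(2, 1), ]
  p1 <- kfractions(cube, mask, model = model)
  p2 <- kfractions(cube, mask, model = perm_model)
  expect_equal(sort(p1$fractions), sort(p2$fractions))
  expect_equal(p1$fractions, p2$fractions[c(2, 1)])
})

test_that("pooled fitting yields one shared centroid set across samples", {
  b <- toy_basis(10)
  mk <- function(seed) make_cube(demo_scene(12, 12, noise_sd = 0.01,
                                            seed = seed), b)$cube
  cubes <- list(mk(1), mk(2))
  pooled <- do.call(rbind, lapply(cubes, as_pixel_matrix))
  model <- fit_kmeans(pooled, 4, seed = 0, n_restarts = 5,
                      wavelengths = b$wavelengths)
  labs <- lapply(cubes, assign_pixels, model = model)
  # per-sample labels are drawn from the one pooled centroid set, and
  # concatenating them reproduces the pooled assignment
  flat <- unlist(lapply(labs, function(l) as.vector(t(l))))
  pooled_lab <- as.vector(apply(pooled, 1, function(p)
    which.min(colSums((t(model$centroids) - p)^2))))
  expect_equal(flat, pooled_lab)
})

test_that("false-colour rendering maps clusters to distinct colours", {
  lab <- matrix(c(0L, 1L, 2L, 3L), 2, 2)
  attr(lab, "K") <- 3L
  img <- render_false_colour(lab)
  expect_equal(dim(img), c(2, 2, 3))
  expect_equal(img[1, 1, ], c(0, 0, 0))        # masked pixel is black
  cols <- apply(matrix(img, 4, 3), 1, paste, collapse = ",")
  expect_equal(length(unique(cols)), 4)        # 3 clusters + black
  expect_error(render_false_colour(lab, palette = c("red", "blue")),
               "palette")
})
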