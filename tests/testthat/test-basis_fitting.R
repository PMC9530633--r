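test_that("exact members and mixtures are recovered with zero chi2", {
  b <- toy_basis(20)
  for (mode in c("ols", "nnls")) {
    fit <- fit_pixel(b$components$rbc, b, mode)
    expect_equal(unname(fit$coefficients),
                 c(0, 0, 1, 0, 0), tolerance = 1e-8)
    expect_lt(fit$chi2, 1e-16)
    expect_equal(fit$dof, 15)

    mix <- 0.5 * b$components$plasma + 0.5 * b$components$ice + 0.1
    fit2 <- fit_pixel(mix, b, mode)
    expect_equal(unname(fit2$coefficients),
                 c(0.1, 0.5, 0, 0, 0.5), tolerance = 1e-8)
    expect_lt(fit2$chi2, 1e-16)
  }
})

test_that("OLS agrees with an independent normal-equations oracle", {
  b <- toy_basis(6)
  X <- cbind(1, b$components$plasma, b$components$rbc,
             b$components$filter, b$components$ice)
  set.seed(10)
  for (i in 1:5) {
    y <- runif(6)
    fit <- fit_pixel(y, b, "ols")
    expect_equal(unname(fit$coefficients), ols_normal_equations(X, y),
                 tolerance = 1e-8)
    expect_equal(fit$chi2, sum((y - X %*% ols_normal_equations(X, y))^2),
                 tolerance = 1e-10)
  }
})

test_that("NNLS constrains components and never beats OLS", {
  b <- toy_basis(20)
  set.seed(11)
  for (i in 1:10) {
    y <- pmax(rnorm(20, mean = 0.3, sd = 0.3), 0)
    f_ols <- fit_pixel(y, b, "ols")
    f_nnls <- fit_pixel(y, b, "nnls")
    expect_true(all(f_nnls$coefficients[-1] >= 0))
    expect_lte(f_ols$chi2, f_nnls$chi2 + 1e-10)
  }
})

test_that("OLS coefficients scale inversely with the basis spectra", {
  b <- toy_basis(20)
  set.seed(12)
  y <- runif(20)
  s <- 3.7
  b_scaled <- basis_spectra(b$wavelengths, lapply(b$components, `*`, s))
  f1 <- fit_pixel(y, b, "ols")
  f2 <- fit_pixel(y, b_scaled, "ols")
  expect_equal(unname(f2$coefficients[-1]), unname(f1$coefficients[-1]) / s,
               tolerance = 1e-8)
  expect_equal(f2$coefficients[["c0"]], f1$coefficients[["c0"]],
               tolerance = 1e-8)
  expect_equal(f2$chi2, f1$chi2, tolerance = 1e-10)
})

test_that("rank-deficient designs are flagged, not fatal", {
  b <- toy_basis(20)
  comps <- b$components
  comps$ice <- 2 * comps$filter       # proportional spectra
  b_bad <- basis_spectra(b$wavelengths, comps)
  expect_warning(fit <- fit_pixel(runif(20), b_bad, "ols"), "rank-deficient")
  expect_true(fit$rank_deficient)
  expect_true(all(is.finite(fit$coefficients)))
})

test_that("cube-level chi2 matches the noise variance on noisy mixtures", {
  # Monte-Carlo residual check: spectra are exact mixtures plus N(0, sigma^2)
  # noise (no truncation: signal level keeps draws positive), so mean
  # chi2/dof estimates sigma^2.
  b <- make_basis_spectra(seed = 3)
  B <- length(b$wavelengths)
  sigma <- 0.01
  n_px <- 1000
  set.seed(13)
  w <- rdir <- matrix(rgamma(n_px * 4, 1), n_px, 4); w <- w / rowSums(w)
  S <- cbind(b$components$plasma, b$components$rbc,
             b$components$filter, b$components$ice)
  clean <- w %*% t(S)
  noisy <- clean + rnorm(length(clean), sd = sigma)
  h <- 25; wd <- 40
  vals <- array(0, c(h, wd, B))
  for (bb in seq_len(B)) vals[, , bb] <- matrix(noisy[, bb], h, wd, byrow = TRUE)
  cube <- spectral_cube(pmax(vals, 0), b$wavelengths, "mc")
  cm <- fit_cube(cube, b, mode = "ols")
  expect_equal(mean(cm$maps$chi2) / cm$dof, sigma^2, tolerance = 0.1)
})

test_that("coefficient map rendering preserves shape and handles constants", {
  maps <- list(a = matrix(0.5, 3, 4), b = matrix(runif(12), 3, 4))
  imgs <- render_coefficient_maps(maps)
  expect_named(imgs, c("a", "b"))
  expect_equal(dim(imgs$a), c(3, 4, 3))
  # constant map renders uniformly (single colour)
  expect_equal(nrow(unique(matrix(imgs$a, 12, 3))), 1)
  # full fit_cube output renders one raster per coefficient plus chi2
  b <- toy_basis(8)
  cube <- make_cube(demo_scene(6, 6, seed = 1), b)$cube
  cm <- fit_cube(cube, b, "ols")
  imgs2 <- render_coefficient_maps(cm, shared_scale = TRUE)
  expect_length(imgs2, 6)
  expect_named(imgs2, c("c0", "plasma", "rbc", "filter", "ice", "chi2"))
})
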