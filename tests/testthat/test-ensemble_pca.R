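# Superposition, ensemble construction and covariance PCA.

test_that("kabsch_superpose undoes an arbitrary rigid transform exactly", {
  m <- random_calpha(12, seed = 21)
  R <- rotation_about_axis(c(1, 2, 3), 40)
  moved <- calpha_model(m$residues, sweep(m$xyz %*% R, 2, c(5, -3, 8), `+`))
  fit <- kabsch_superpose(moved, m)
  expect_lt(fit$rmsd_all, 1e-9)
  expect_lt(fit$rmsd_mask, 1e-9)
  expect_equal(det(fit$R), 1, tolerance = 1e-10)
  expect_equal(fit$R %*% t(fit$R), diag(3), tolerance = 1e-10)
})

test_that("scaffold-masked superposition leaves a known residual rmsd", {
  # scaffold untouched, 4 of 10 residues displaced by d along z:
  # scaffold fit is the identity, so rmsd_all = d * sqrt(4/10)
  m <- random_calpha(10, seed = 22)
  d <- 5
  shifted <- m$xyz
  shifted[7:10, 3] <- shifted[7:10, 3] + d
  mask <- c(rep(TRUE, 6), rep(FALSE, 4))
  fit <- kabsch_superpose(calpha_model(m$residues, shifted), m, mask)
  expect_equal(fit$rmsd_mask, 0, tolerance = 1e-10)
  expect_equal(fit$rmsd_all, d * sqrt(4 / 10), tolerance = 1e-10)
})

test_that("superposition never applies a reflection", {
  m <- random_calpha(10, seed = 23)
  mirrored <- calpha_model(m$residues, m$xyz %*% diag(c(-1, 1, 1)))
  fit <- kabsch_superpose(mirrored, m)
  expect_equal(det(fit$R), 1, tolerance = 1e-10)
  expect_gt(fit$rmsd_all, 0.5)
})

test_that("degenerate fit masks are rejected", {
  m <- random_calpha(6, seed = 24)
  expect_error(kabsch_superpose(m, m, c(TRUE, TRUE, rep(FALSE, 4))),
               class = "elevator_degenerate")
  line <- calpha_model(m$residues,
                       cbind(seq_len(6) * 3.8, 0, 0))
  expect_error(kabsch_superpose(line, line), class = "elevator_degenerate")
})

test_that("build_ensemble validates inputs and reports fit statistics", {
  m <- random_calpha(20, seed = 25)
  models <- list(a = m,
                 b = calpha_model(m$residues, m$xyz + 0.1),
                 c = calpha_model(m$residues, m$xyz - 0.1))
  expect_error(build_ensemble(unname(models), reference_id = "a"),
               class = "elevator_schema")
  expect_error(build_ensemble(models, reference_id = "zz"),
               class = "elevator_validation")
  short <- c(models, list(d = random_calpha(5, seed = 1)))
  expect_error(build_ensemble(short, reference_id = "a"),
               class = "elevator_validation")
  ens <- build_ensemble(models, reference_id = "a")
  expect_equal(dim(ens$coords), c(3, 20, 3))
  # pure translations are removed by the fit
  expect_lt(ens$mean_fit_rmsd, 1e-9)
})

test_that("fit rmsd of an isotropically perturbed ensemble matches theory", {
  # each coordinate gets N(0, sigma^2) noise; before fitting the expected
  # rmsd to the reference is sigma * sqrt(3), and the rigid fit can only
  # reduce it (by ~6 of 3M degrees of freedom)
  sigma <- 0.5
  m <- random_calpha(200, seed = 26, spread = 40)
  models <- with_seed(27, {
    out <- list(ref = m)
    for (i in 1:10)
      out[[paste0("s", i)]] <-
        calpha_model(m$residues, m$xyz + rnorm(600, sd = sigma))
    out
  })
  ens <- build_ensemble(models, reference_id = "ref")
  r <- ens$fit_rmsd[-1]
  expect_equal(mean(r), sigma * sqrt(3), tolerance = 0.1)
  expect_true(all(r < sigma * sqrt(3) * 1.2))
})

test_that("covariance_pca matches a direct eigendecomposition oracle", {
  m <- random_calpha(6, seed = 28)
  models <- with_seed(29, {
    out <- list()
    for (i in 1:8)
      out[[paste0("s", i)]] <-
        calpha_model(m$residues, m$xyz + rnorm(18, sd = 0.8))
    out
  })
  ens <- build_ensemble(models, reference_id = "s1")
  basis <- covariance_pca(ens)
  # oracle: explicit 3M x 3M covariance with 1/N normalization
  X <- t(vapply(1:8, function(i) as.vector(t(ens$coords[i, , ])),
                numeric(18)))
  Xc <- sweep(X, 2, colMeans(X))
  C <- crossprod(Xc) / 8
  eig <- eigen(C, symmetric = TRUE)
  K <- length(basis$values)
  expect_equal(K, 7)  # at most N - 1 nonzero components
  expect_equal(basis$values, eig$values[1:K], tolerance = 1e-9)
  for (k in 1:K)
    expect_equal(abs(sum(basis$vectors[k, ] * eig$vectors[, k])), 1,
                 tolerance = 1e-8)
  # rows are orthonormal; variance fractions derive from the full trace
  G <- basis$vectors %*% t(basis$vectors)
  expect_equal(G, diag(K), tolerance = 1e-10)
  expect_equal(basis$varfrac, basis$values / sum(diag(C)), tolerance = 1e-10)
  expect_lte(sum(basis$varfrac), 1 + 1e-12)
})

test_that("a two-state ensemble yields PC1 along the known axis", {
  m <- random_calpha(30, seed = 30)
  # core-only z-shift: residues 16-30 move +z, scaffold 1-15 stays
  d <- numeric(90); d[seq(3, 90, 3)[16:30]] <- 1
  models <- list()
  for (i in 1:4) models[[paste0("in", i)]] <- m
  for (i in 1:4) models[[paste0("out", i)]] <-
    calpha_model(m$residues, m$xyz + 4 * matrix(d, ncol = 3, byrow = TRUE))
  mask <- c(rep(TRUE, 15), rep(FALSE, 15))
  ens <- build_ensemble(models, reference_id = "in1", fit_mask = mask)
  basis <- covariance_pca(ens, calibrate_id = "out1")
  expect_gt(basis$varfrac[1], 0.999)
  expect_gt(abs(sum(basis$vectors[1, ] * d / sqrt(sum(d^2)))), 0.999)
  # sign calibration: the designated outward structure projects positive
  p <- project(ens$coords["out1", , ], basis, components = 1)
  expect_gt(p, 0)
  expect_equal(unname(p), 4 * sqrt(15), tolerance = 1e-9)
})

test_that("projections are displacement dot products with guard rails", {
  m <- random_calpha(8, seed = 31)
  models <- with_seed(32, {
    out <- list()
    for (i in 1:5)
      out[[paste0("s", i)]] <- calpha_model(m$residues,
                                            m$xyz + rnorm(24, sd = 1))
    out
  })
  ens <- build_ensemble(models, reference_id = "s1")
  basis <- covariance_pca(ens)
  # reference projects to zero on every axis
  expect_equal(max(abs(project(ens$coords["s1", , ], basis))), 0,
               tolerance = 1e-10)
  # hand oracle for one structure and axis
  Tvec <- as.vector(t(ens$coords["s3", , ])) - basis$reference_coords
  expect_equal(unname(project(ens$coords["s3", , ], basis, components = 2)),
               sum(Tvec * basis$vectors[2, ]), tolerance = 1e-12)
  # size mismatch and frame guard
  expect_error(project(random_calpha(5), basis), class = "elevator_consistency")
  far <- calpha_model(m$residues, ens$coords["s1", , ] + 50)
  expect_error(project(far, basis, max_frame_rmsd = 1),
               class = "elevator_frame")
  tab <- projection_table(ens, basis, components = 1:2)
  expect_equal(tab$PC1[tab$id == "s3"],
               unname(project(ens$coords["s3", , ], basis, components = 1)))
})

test_that("pc_interpolate frames project back to their amplitudes", {
  m <- random_calpha(10, seed = 33)
  models <- with_seed(34, {
    out <- list()
    for (i in 1:6)
      out[[paste0("s", i)]] <- calpha_model(m$residues,
                                            m$xyz + rnorm(30, sd = 1))
    out
  })
  ens <- build_ensemble(models, reference_id = "s1")
  basis <- covariance_pca(ens)
  amps <- c(-3, 0, 2.5)
  frames <- pc_interpolate(basis, ens$residues, k = 1, amplitudes = amps)
  got <- vapply(frames, function(f)
    unname(project(f, basis, reference = basis$mean, components = 1)), 0)
  expect_equal(got, amps, tolerance = 1e-9)
})
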