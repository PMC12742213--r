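test_that("elementary matrices match their defining blocks", {
  t <- c(0.2, -0.1, 0.05)
  Tm <- translation_matrix(t)$mat
  expect_equal(Tm[1:3, 4], t)
  expect_equal(Tm[1:3, 1:3], diag(3))
  expect_equal(translation_matrix(c(0, 0, 0))$mat, diag(4))

  # rotation about x by pi/2: cos = 0, sin = 1 in the x-axis block
  Rx <- rotation_matrix(c(pi / 2, 0, 0))$mat
  expect_equal(Rx[2:3, 2:3], matrix(c(0, 1, -1, 0), 2), tolerance = 1e-12)
  expect_equal(Rx[1, 1:3], c(1, 0, 0))
  expect_equal(rotation_matrix(c(0, 0, 0))$mat, diag(4))

  s <- c(1.2, 0.8, 1.05)
  expect_equal(scaling_matrix(s)$mat, diag(c(s, 1)))
  expect_equal(det(scaling_matrix(s)$mat[1:3, 1:3]), prod(s))

  h <- c(0.3, -0.2, 0.15)
  Hm <- shearing_matrix(h)$mat
  expect_equal(Hm[1, 2], h[1])
  expect_equal(Hm[1, 3], h[2])
  expect_equal(Hm[2, 3], h[3])
  expect_equal(diag(Hm), rep(1, 4))
  expect_equal(shearing_matrix(c(0, 0, 0))$mat, diag(4))
})

test_that("out-of-range parameters are rejected, not wrapped", {
  expect_error(rotation_matrix(c(4, 0, 0)), "rotation")
  expect_error(scaling_matrix(c(2, 1, 1)), "scaling")
  expect_error(scaling_matrix(c(0.2, 1, 1)), "scaling")
  expect_error(shearing_matrix(c(0, 4, 0)), "shear")
  expect_error(geometric_params(t = c(0.7, 0, 0)), "translation")
})

test_that("rotation linear blocks are orthonormal with determinant one", {
  for (seed in 1:20) {
    set.seed(seed)
    r <- runif(3, -pi, pi)
    R3 <- rotation_matrix(r)$mat[1:3, 1:3]
    expect_lt(max(abs(t(R3) %*% R3 - diag(3))), 1e-10)
    expect_equal(det(R3), 1, tolerance = 1e-12)
  }
})

test_that("composition is the ordered product T R S H about a pivot", {
  p <- random_inrange_params(3)
  # about the origin the four separately built factors multiply directly
  bf <- translation_matrix(unclass(p)[1:3])$mat %*%
    rotation_matrix(unclass(p)[4:6])$mat %*%
    scaling_matrix(unclass(p)[7:9])$mat %*%
    shearing_matrix(unclass(p)[10:12])$mat
  expect_equal(compose_affine(p)$mat, bf, tolerance = 1e-12)

  # conjugation: R, S, H act about the pivot
  ctr <- c(0.2, -0.1, 0.3)
  Cm <- diag(4); Cm[1:3, 4] <- ctr
  Ci <- diag(4); Ci[1:3, 4] <- -ctr
  man <- translation_matrix(unclass(p)[1:3])$mat %*% Cm %*%
    rotation_matrix(unclass(p)[4:6])$mat %*%
    scaling_matrix(unclass(p)[7:9])$mat %*%
    shearing_matrix(unclass(p)[10:12])$mat %*% Ci
  expect_equal(compose_affine(p, ctr)$mat, man, tolerance = 1e-12)

  # identity params give the identity for any pivot; pure translation is
  # pivot independent
  expect_equal(compose_affine(geometric_params(), ctr)$mat, diag(4))
  pt <- geometric_params(t = c(0.1, 0.2, -0.3))
  expect_equal(compose_affine(pt, ctr)$mat, translation_matrix(c(0.1, 0.2, -0.3))$mat)

  # in-range parameters never produce a reflection
  for (seed in 1:25) {
    pr <- random_inrange_params(seed)
    expect_gt(det(compose_affine(pr, ctr)$mat[1:3, 1:3]), 0)
  }

  # translation inverse pair cancels
  acc <- accumulate_transforms(list(translation_matrix(c(0.5, 0, 0)),
                                    translation_matrix(c(-0.5, 0, 0))))
  expect_equal(acc$mat, diag(4))
})

test_that("tanh squashing maps any raw vector into the admissible ranges", {
  expect_equal(unclass(constrain_params(rep(0, 12))),
               unclass(geometric_params()), ignore_attr = TRUE)
  hi <- constrain_params(c(rep(0, 6), rep(50, 3), rep(0, 3)))
  lo <- constrain_params(c(rep(0, 6), rep(-50, 3), rep(0, 3)))
  expect_equal(unname(unclass(hi)[7:9]), rep(1.5, 3), tolerance = 1e-12)
  expect_equal(unname(unclass(lo)[7:9]), rep(0.5, 3), tolerance = 1e-12)

  set.seed(11)
  raws <- matrix(rnorm(1e5 * 12, sd = 5), ncol = 12)
  th <- tanh(raws)
  out <- cbind(0.5 * th[, 1:3], pi * th[, 4:6], 1 + 0.5 * th[, 7:9],
               pi * th[, 10:12])
  # the vectorized mapping above mirrors constrain_params; spot-check rows
  for (i in sample(nrow(raws), 50))
    expect_equal(unname(unclass(constrain_params(raws[i, ]))), out[i, ])
  expect_true(all(abs(out[, 1:3]) <= 0.5))
  expect_true(all(abs(out[, 4:6]) <= pi))
  expect_true(all(out[, 7:9] >= 0.5 & out[, 7:9] <= 1.5))
  expect_true(all(abs(out[, 10:12]) <= pi))

  # monotone per component
  grid <- seq(-4, 4, length.out = 41)
  for (k in c(1, 5, 8, 12)) {
    vals <- vapply(grid, function(g) {
      raw <- rep(0, 12); raw[k] <- g
      unclass(constrain_params(raw))[k]
    }, 0)
    expect_true(all(diff(vals) > 0))
  }
})

test_that("centre of mass matches direct summation", {
  v <- array(0, c(7, 8, 9))
  v[3, 5, 2] <- 2.5
  expect_equal(center_of_mass(v), c(2, 4, 1))

  ones <- array(1, c(6, 6, 6))
  expect_equal(center_of_mass(ones), rep(2.5, 3))

  set.seed(4)
  v <- array(runif(5 * 6 * 4), c(5, 6, 4))
  acc <- c(0, 0, 0); tot <- 0
  for (i in 1:5) for (j in 1:6) for (k in 1:4) {
    acc <- acc + c(i - 1, j - 1, k - 1) * v[i, j, k]
    tot <- tot + v[i, j, k]
  }
  expect_equal(center_of_mass(v), acc / tot, tolerance = 1e-9)

  expect_error(center_of_mass(array(0, c(4, 4, 4))), "degenerate")
})

test_that("centre-of-mass alignment brings the centres together", {
  ph <- generate_phantom(2, c(32, 32, 32), 4)
  f <- ph$intensity
  expect_equal(com_align(f, f)$mat, diag(4))

  # content shifted by +3 voxels along x: the sampling matrix carries +3
  # voxels (normalized), i.e. a forward motion of -3 voxels
  m <- array(0, dim(f)); m[4:32, , ] <- f[1:29, , ]
  al <- com_align(f, m)
  vox3 <- 2 * 3 / (dim(f)[1] - 1)
  expect_equal(al$mat[1, 4], vox3, tolerance = 0.05)
  w <- warp_volume(m, al)
  expect_lt(max(abs(center_of_mass(f) - center_of_mass(w))), 0.5)
})

test_that("stage accumulation equals the ordered matrix product", {
  a1 <- compose_affine(random_inrange_params(1, mild = TRUE))
  a2 <- compose_affine(random_inrange_params(2, mild = TRUE))
  a3 <- compose_affine(random_inrange_params(3, mild = TRUE))
  expect_equal(accumulate_transforms(list(a1))$mat, a1$mat)
  expect_lt(max(abs(accumulate_transforms(list(a1, invert_transform(a1)))$mat -
                      diag(4))), 1e-10)
  expect_equal(accumulate_transforms(list(a1, a2, a3))$mat,
               a1$mat %*% a2$mat %*% a3$mat)
  # associativity
  expect_equal(accumulate_transforms(list(accumulate_transforms(list(a1, a2)), a3))$mat,
               accumulate_transforms(list(a1, accumulate_transforms(list(a2, a3))))$mat)
  expect_error(accumulate_transforms(list()), "empty")
})

test_that("affine matrices and parameter sidecars round-trip through disk", {
  p <- random_inrange_params(9, mild = TRUE)
  a <- compose_affine(p, center = c(0.1, 0, -0.2))
  path <- tempfile(fileext = ".mat")
  write_affine(a, path, params = p)
  b <- read_affine(path)
  expect_equal(b$mat, a$mat, tolerance = 1e-9)
  expect_equal(b$convention, "normalized")
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(unlist(side$params), unclass(p), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_lt(max(abs(b$mat %*% solve(a$mat) - diag(4))), 1e-8)
})

test_that("voxel- and world-space conversions agree with the normalized map", {
  a <- compose_affine(random_inrange_params(6, mild = TRUE))
  shape <- c(9, 7, 5)
  spacing <- c(0.3, 0.3, 0.4)
  av <- convert_affine(a, shape)
  aw <- convert_affine(a, shape, spacing, to = "world")
  expect_equal(av$convention, "voxel")
  set.seed(6)
  for (i in 1:10) {
    v <- runif(3, 0, shape - 1)
    x <- c(2 * v / (shape - 1) - 1, 1)            # normalized coordinate
    src_norm <- (a$mat %*% x)[1:3]
    src_vox <- (av$mat %*% c(v, 1))[1:3]
    expect_equal((src_norm + 1) * (shape - 1) / 2, src_vox, tolerance = 1e-9)
    src_world <- (aw$mat %*% c(v * spacing, 1))[1:3]
    expect_equal(src_vox * spacing, src_world, tolerance = 1e-9)
  }
})

test_that("affine decomposition inverts the composition", {
  for (seed in c(1, 5, 9)) {
    p <- random_inrange_params(seed, mild = TRUE)
    ctr <- c(0.15, -0.05, 0.1)
    dec <- decompose_affine(compose_affine(p, ctr), ctr)
    expect_equal(dec$t, unname(unclass(p)[1:3]), tolerance = 1e-9)
    expect_equal(dec$r, unname(unclass(p)[4:6]), tolerance = 1e-9)
    expect_equal(dec$s, unname(unclass(p)[7:9]), tolerance = 1e-9)
    expect_equal(dec$h, unname(unclass(p)[10:12]), tolerance = 1e-9)
  }
})
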