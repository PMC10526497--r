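test_that("normalize_hom divides by the projective coordinate", {
  expect_vec_equal(normalize_hom(c(2, 4, 2)), c(1, 2, 1))
  expect_vec_equal(normalize_hom(c(1, 2, 1)), c(1, 2, 1))
  # component-wise division oracle
  p <- c(0.3, -0.6, 0.3)
  expect_vec_equal(normalize_hom(p), p / p[3])
  expect_vec_equal(normalize_hom(p), c(1, -2, 1))
  expect_error(normalize_hom(c(1, 1, 0)), "infinity")
})

test_that("scale-then-normalize is the identity on normalized points", {
  set.seed(1)
  for (i in 1:25) {
    p <- c(stats::runif(2, -5, 5), 1)
    cc <- stats::runif(1, -3, 3)
    if (abs(cc) < 1e-3) cc <- 1
    expect_vec_equal(normalize_hom(cc * p), p)
  }
})

test_that("make_rototranslation matches the explicit matrix product", {
  expect_equal(make_rototranslation(0, 0, 0), diag(3))
  expect_vec_equal(apply_transform(make_rototranslation(pi / 2), c(1, 0, 1)),
                   c(0, 1, 1), tol = 1e-12)
  # explicit 3x3 product oracle: rotation %*% translation
  theta <- pi / 2; lx <- 1; ly <- 2
  rot <- matrix(c(cos(theta), sin(theta), 0,
                  -sin(theta), cos(theta), 0, 0, 0, 1), 3, 3)
  trn <- matrix(c(1, 0, 0, 0, 1, 0, lx, ly, 1), 3, 3)
  expect_equal(make_rototranslation(theta, lx, ly), rot %*% trn)
  expect_vec_equal(apply_transform(make_rototranslation(theta, lx, ly),
                                   c(0, 0, 1)), c(-2, 1, 1), tol = 1e-12)
  # printed closed form of the composite action
  set.seed(2)
  for (i in 1:10) {
    th <- stats::runif(1, -pi, pi); l <- stats::runif(2, -2, 2)
    p <- c(stats::runif(2, -3, 3), 1)
    out <- apply_transform(make_rototranslation(th, l[1], l[2]), p)
    expect_vec_equal(out, c(cos(th) * (p[1] + l[1]) - sin(th) * (p[2] + l[2]),
                            sin(th) * (p[1] + l[1]) + cos(th) * (p[2] + l[2]), 1))
  }
})

test_that("rotation composition adds angles", {
  set.seed(3)
  for (i in 1:10) {
    th <- stats::runif(2, -pi, pi)
    expect_equal(make_rototranslation(th[1]) %*% make_rototranslation(th[2]),
                 make_rototranslation(th[1] + th[2]), tolerance = 1e-12)
  }
})

test_that("make_eye_transform matches its printed matrix", {
  expect_equal(make_eye_transform(0, 0), diag(3))
  # matrix substitution oracle
  eye_mat <- function(th, l)
    matrix(c(cos(th), sin(th), -l * sin(th),
             -sin(th), cos(th), -l * cos(th),
             0, 0, 1), 3, 3, byrow = TRUE)
  expect_equal(make_eye_transform(0.7, -0.5), eye_mat(0.7, -0.5))
  expect_vec_equal(apply_transform(make_eye_transform(0, 0.5), c(2, 0.3, 1)),
                   c(2, -0.2, 1))
  expect_vec_equal(apply_transform(make_eye_transform(pi / 2, 1), c(2, 3, 1)),
                   c(2, -2, 1), tol = 1e-12)
  # affine invariants: last row, orthogonal rotation block
  Tm <- make_eye_transform(0.3, 0.5)
  expect_vec_equal(Tm[3, ], c(0, 0, 1))
  R <- Tm[1:2, 1:2]
  expect_equal(crossprod(R), diag(2), tolerance = 1e-12)
  expect_equal(det(R), 1, tolerance = 1e-12)
})

test_that("apply_transform composes associatively and projects per Eq-style maps", {
  p <- c(2, 3, 1)
  proj <- matrix(c(1, 0, 1, 0, 1, 0, 0, 0, 1), 3, 3)  # (zx, zy) = (1, 0)
  expect_vec_equal(apply_transform(proj, p), c(2, 3, 3))
  set.seed(4)
  T1 <- matrix(stats::rnorm(9), 3, 3)
  T2 <- matrix(stats::rnorm(9), 3, 3)
  expect_vec_equal(apply_transform(T1, apply_transform(T2, p)),
                   apply_transform(T1 %*% T2, p), tol = 1e-12)
})

test_that("project_to_camera maps (x, y, 1) to (1, f*y/x)", {
  expect_vec_equal(project_to_camera(c(5, 0, 1), 2), c(1, 0))
  expect_vec_equal(project_to_camera(c(2, 1, 1), 1), c(1, 0.5))
  expect_vec_equal(project_to_camera(c(4, -1, 1), 2), c(1, -0.5))
  expect_error(project_to_camera(c(0, 1, 1), 1), "zero depth")
})

test_that("backprop operations match central-difference derivatives", {
  set.seed(5)
  for (i in 1:100) {
    Tm <- matrix(stats::rnorm(9), 3, 3)
    err <- stats::rnorm(3)
    p <- stats::rnorm(3)
    # gradient of err' T p wrt p is t(T) err
    g <- num_grad(function(x) sum(err * apply_transform(Tm, x)), p)
    expect_equal(backprop_point(Tm, err), g, tolerance = 1e-6)
  }
  expect_vec_equal(backprop_point(diag(3), c(1, 2, 3)), c(1, 2, 3))
  expect_vec_equal(backprop_point(matrix(stats::rnorm(9), 3, 3), c(0, 0, 0)),
                   c(0, 0, 0))
})

test_that("backprop_param equals the derivative wrt the eye angle", {
  set.seed(6)
  for (i in 1:100) {
    th <- stats::runif(1, -1.2, 1.2)
    l <- stats::runif(1, -1, 1)
    err <- stats::rnorm(3)
    mu_r <- c(stats::runif(1, 1, 5), stats::runif(1, -2, 2), 1)
    fd <- num_grad(function(x)
      sum(err * apply_transform(make_eye_transform(x, l), mu_r)), th)
    got <- backprop_param(depthsim:::deye_dtheta(th, l), err, mu_r)
    expect_equal(got, as.numeric(fd), tolerance = 1e-6 * max(1, abs(fd)))
  }
  expect_equal(backprop_param(depthsim:::deye_dtheta(0.3, 0.5), c(0, 0, 0),
                              c(1, 2, 1)), 0)
  expect_equal(backprop_param(matrix(0, 3, 3), c(1, 2, 3), c(1, 2, 1)), 0)
})

test_that("backprop_projection matches finite differences of the projection", {
  expect_vec_equal(backprop_projection(c(1, 0, 1), 1, 0), c(0, 0))
  expect_vec_equal(backprop_projection(c(1, 0, 1), 1, 1), c(0, 1))
  set.seed(7)
  for (i in 1:100) {
    r <- c(stats::runif(1, 0.5, 5), stats::runif(1, -3, 3), 1)
    f <- stats::runif(1, 0.5, 3)
    err <- stats::rnorm(1)
    fd <- num_grad(function(x)
      err * project_to_camera(c(x, 1), f)[2], r[1:2])
    expect_equal(backprop_projection(r, f, err), as.numeric(fd),
                 tolerance = 1e-6 * max(1, max(abs(fd))))
  }
})

test_that("parallel-eye triangulation closed form inverts the projections", {
  set.seed(8)
  for (i in 1:20) {
    x <- stats::runif(1, 1.5, 6); y <- stats::runif(1, -2, 2)
    f <- stats::runif(1, 0.5, 3); L <- stats::runif(1, 0.2, 1)
    l <- c(-L, L)
    cs <- vapply(1:2, function(k) {
      r <- apply_transform(make_eye_transform(0, l[k]), c(x, y, 1))
      project_to_camera(r, f)[2]
    }, numeric(1))
    expect_vec_equal(triangulate_parallel(cs[1], cs[2], f, L), c(x, y),
                     tol = 1e-9)
    expect_equal(x, 2 * f * L / (cs[1] - cs[2]), tolerance = 1e-9)
  }
})
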