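test_that("circle and torus targets have the documented geometry", {
  tg <- circle_target(11)
  expect_identical(dim(tg$T), c(11L, 2L))
  expect_equal(sum(tg$T^2), 11)                 # ||T||^2 = M
  expect_equal(rowSums(tg$T^2), rep(1, 11))     # unit rows
  expect_error(circle_target(2), ">= 3")

  tt <- torus_target(4, 5)
  expect_identical(dim(tt$T), c(20L, 4L))
  expect_equal(rowSums(tt$T^2), rep(2, 20))     # rows have norm sqrt(2)
  expect_equal(sum(tt$T^2), 2 * 20)
  # row-major over the (a, b) grid: first m2 rows share the first angle
  expect_equal(tt$angles[1:5, 1], rep(0, 5))
  expect_error(torus_target(2, 5), ">= 3")
})

test_that("torus_target_for picks near-square factorizations", {
  expect_identical(torus_target_for(16)$shape, c(4L, 4L))
  expect_identical(torus_target_for(12)$shape, c(3L, 4L))
  expect_warning(out <- torus_target_for(13), "factorization")
  expect_identical(nrow(out$T), 13L)
})

test_that("match_geometry exactly recovers a permuted noiseless circle", {
  M <- 16
  tg <- circle_target(M)
  set.seed(3)
  perm_true <- sample.int(M)
  # embed the permuted circle in 5 dimensions through a random linear map
  Q <- qr.Q(qr(matrix(rnorm(5 * 5), 5, 5)))[, 1:2] %*% diag(c(2, 0.5))
  Z <- tg$T[perm_true, ] %*% t(Q)
  mt <- match_geometry(Z, tg, seed = 1)
  expect_lt(mt$loss, 1e-10)
  expect_equal(mt$r2, 1, tolerance = 1e-10)
  # the recovered cyclic ordering matches the planted one exactly (up to
  # the unidentifiable rotation/reflection of the circle)
  expect_equal(circular_agreement(perm_true[mt$perm]), 1)
})

test_that("matching loss is invariant to rotations of the embedding", {
  set.seed(5)
  Z <- matrix(rnorm(12 * 4), 12, 4)
  tg <- circle_target(12)
  Q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  m1 <- match_geometry(Z, tg, n_restarts = 20, seed = 2)
  m2 <- match_geometry(Z %*% Q, tg, n_restarts = 20, seed = 2)
  expect_equal(m1$loss, m2$loss, tolerance = 1e-6)
})

test_that("best-of-restarts equals exhaustive search for small M", {
  set.seed(123)
  for (inst in 1:4) {
    M <- sample(4:6, 1); D <- sample(2:4, 1)
    Z <- matrix(rnorm(M * D), M, D)
    tg <- circle_target(M)
    mt <- match_geometry(Z, tg, n_restarts = 20, seed = inst)
    P <- perms_of(M)
    best <- Inf
    for (r in seq_len(nrow(P))) {
      p <- P[r, ]
      Pp <- ctembed:::ls_projection(Z[p, , drop = FALSE], tg$T)
      best <- min(best, sum((tg$T - Z[p, , drop = FALSE] %*% Pp)^2))
    }
    expect_equal(mt$loss, best, tolerance = 1e-8)
  }
})

test_that("fixed_P skips the projection update", {
  set.seed(1)
  Z <- matrix(rnorm(8 * 3), 8, 3)
  tg <- circle_target(8)
  # an all-zero projection leaves the full target mass unexplained
  m0 <- match_geometry(Z, tg, fixed_P = matrix(0, 3, 2))
  expect_equal(m0$loss, sum(tg$T^2))
  expect_equal(m0$r2, 0)
  expect_identical(m0$n_restarts, 1L)
  expect_error(match_geometry(Z, tg, fixed_P = matrix(0, 2, 2)), "3 x 2")
})

test_that("match_geometry validates shapes and warns on low D", {
  tg <- circle_target(6)
  expect_error(match_geometry(matrix(0, 5, 3), tg), "6 points")
  expect_warning(match_geometry(matrix(rnorm(6), 6, 1), tg), "full rank")
})

test_that("circularity p-values use the upper tail of a Gaussian null", {
  null <- list(values = NULL, mean = 0.9, sd = 0.02, M = 16, D = 5)
  pv <- circularity_pvalue(c(0.9, 0.99), null = null)
  expect_equal(pv$p[1], 0.5)
  expect_equal(pv$p[2], pnorm(0.99, 0.9, 0.02, lower.tail = FALSE))
  expect_equal(pv$p_lower, 1 - pv$p)
  expect_identical(nrow(pv), 2L)
  expect_error(circularity_pvalue(0.5), "supply M and D")
})

test_that("circularity_null is seeded and summarizes its draws", {
  n1 <- circularity_null(8, 3, n_null = 5, seed = 2, n_restarts = 3)
  n2 <- circularity_null(8, 3, n_null = 5, seed = 2, n_restarts = 3)
  expect_identical(n1$values, n2$values)
  expect_equal(n1$mean, mean(n1$values))
  expect_equal(n1$sd, sd(n1$values))
  expect_error(circularity_null(8, 3, n_null = 1), "n_null")
})

test_that("assign_angles reads angles off a 2-column projection", {
  tg <- circle_target(8)
  ang <- assign_angles(tg$T, diag(2))
  expect_equal(ang, tg$angles)
  expect_error(assign_angles(tg$T, diag(1)), "2 columns")
  Z <- rbind(c(0, 0), c(1, 0))
  expect_warning(a2 <- assign_angles(Z, diag(2)), "project to zero")
  expect_true(is.na(a2[1]))
  expect_identical(angle_order(a2), c(2L, 1L))
})

test_that("screen_types ranks a structured type above the null", {
  gen <- make_ring_connectome(ring_circuit_spec(
    n_per_type = c(A = 16, B = 16), seed = 7))
  fit <- fit_embedding(gen$cx, D = 5,
                       config = train_config(n_steps = 1500, seed = 1))
  tab <- screen_types(fit, min_size = 10, n_null = 40, seed = 3)
  expect_identical(nrow(tab), 2L)
  expect_true(all(tab$p_value < 0.05))
  expect_true(all(diff(tab$r2) <= 0))  # sorted decreasing
  # min_size excludes small types entirely
  tab2 <- screen_types(fit, min_size = 17, n_null = 2)
  expect_identical(nrow(tab2), 0L)
})

test_that("sort_by_shared_projection orders all types by one plane", {
  gen <- make_ring_connectome(ring_circuit_spec(
    n_per_type = c(A = 10, B = 10), seed = 7, noise = "none"))
  # use ground-truth-like embeddings: each type on the same circle
  th <- gen$theta
  Z <- cbind(cos(th), sin(th), 0 * th)
  fit <- list(model = toy_model(Z, types = gen$cx$types,
                                type_names = gen$cx$type_names))
  out <- sort_by_shared_projection(gen$cx, fit, cbind(c(1, 0, 0), c(0, 1, 0)))
  # already sorted by angle, so nothing moves
  expect_equal(out$cx$W, gen$cx$W)
  expect_identical(out$orderings$A, seq_len(10L))
  expect_equal(out$theta, th)
})

test_that("circularity_coefficient separates rings from noise", {
  th <- 2 * pi * (0:11) / 12
  ring <- cbind(cos(th), sin(th), matrix(0, 12, 2))
  r2_ring <- as.numeric(circularity_coefficient(ring, seed = 1))
  expect_equal(r2_ring, 1, tolerance = 1e-8)
  set.seed(9)
  r2_noise <- as.numeric(circularity_coefficient(
    matrix(rnorm(12 * 4), 12, 4), seed = 1))
  expect_lt(r2_noise, r2_ring)
  expect_s3_class(attr(circularity_coefficient(ring, seed = 1), "match"),
                  "geometry_match")
})
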