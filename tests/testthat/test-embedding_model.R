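test_that("softplus and wrap_angle closed forms", {
  expect_equal(softplus(0), log(2))
  expect_equal(softplus(1), log(1 + exp(1)))
  expect_equal(softplus(1), 1.31326168752, tolerance = 1e-10)
  # large-argument stability: softplus(x) -> x without overflow
  expect_equal(softplus(1000), 1000)
  expect_equal(softplus(-1000), 0)
  expect_equal(wrap_angle(0), 0)
  expect_equal(wrap_angle(pi), -pi)      # [-pi, pi) convention
  expect_equal(wrap_angle(3 * pi / 2), -pi / 2)
  expect_equal(wrap_angle(-3 * pi / 2), pi / 2)
  expect_equal(wrap_angle(2 * pi), 0)
})

test_that("per-pair NLL closed forms", {
  # Poisson at What = W = 1: 1 - 1*log(1) + lgamma(2) = 1
  expect_equal(ctembed:::nll_matrix(matrix(1), matrix(1), "poisson"),
               matrix(1))
  # Poisson at What = 2, W = 0: 2 - 0 + lgamma(1) = 2
  expect_equal(ctembed:::nll_matrix(matrix(2), matrix(0), "poisson"),
               matrix(2))
  # Gaussian at W = What = 0: v = 1, 0.5*log(2*pi)
  expect_equal(ctembed:::nll_matrix(matrix(0), matrix(0), "gaussian"),
               matrix(0.5 * log(2 * pi)))
  # Gaussian general: v = 1 + What^2
  What <- 2; W <- 3.5; v <- 1 + What^2
  expect_equal(
    ctembed:::nll_matrix(matrix(What), matrix(W), "gaussian"),
    matrix(0.5 * log(2 * pi * v) + (W - What)^2 / (2 * v)))
})

test_that("Poisson NLL is minimized at the observed count", {
  # brute force over integer observations: argmin over What grid is near W
  for (W in c(1, 5, 17)) {
    grid <- seq(0.2, 50, by = 0.05)
    nll <- grid - W * log(grid) + lgamma(W + 1)
    expect_equal(grid[which.min(nll)], W, tolerance = 0.051)
  }
})

test_that("predict_mean matches the closed-form mean", {
  # zero embeddings, A = 1, B = 0, C = 1: What = softplus(1) off-diagonal
  m <- toy_model(matrix(0, 3, 2))
  What <- predict_mean(m)
  off <- !(diag(3) > 0)
  expect_true(all(abs(What[off] - softplus(1)) < 1e-12))
  # distances enter through exp(-d^2 / C^2)
  Z <- rbind(c(0, 0), c(1, 0))
  m2 <- toy_model(Z, A = 2, B = 0.5)
  expect_equal(predict_mean(m2)[1, 2], softplus(2 * exp(-1) + 0.5))
})

test_that("embedding_loss adds the documented ridge penalty", {
  m <- toy_model(matrix(1, 2, 5))            # ||Z||^2 = 10, N*D = 10
  W <- matrix(c(0, 1, 1, 0), 2, 2)
  nll <- embedding_nll(m, W)
  loss <- ctembed:::embedding_loss(m, W)
  expect_equal(loss - nll$total, 0.1 * (1 / 10) * 10)  # lambda = 0.1
  expect_identical(nll$n_pairs, 2L)
})

test_that("analytic gradients match directional finite differences", {
  gen <- make_ring_connectome(ring_circuit_spec(
    n_per_type = c(A = 6, B = 5), seed = 3))
  N <- n_neurons(gen$cx)
  mk_par <- function(rotations, type_aware, D) {
    set.seed(7)
    k <- if (type_aware) 2 else 1
    list(Z = matrix(rnorm(N * D, 0, 0.5), N, D),
         A = matrix(rnorm(k * k, 1, 0.2), k, k),
         B = matrix(rnorm(k * k, 0.5, 0.2), k, k),
         C_raw = matrix(rnorm(k * k, 0.5, 0.2), k, k),
         G = if (rotations)
           lapply(seq_len(k * k), function(i) {
             S <- matrix(rnorm(D * D, 0, 0.3), D, D); S - t(S)
           }) else NULL)
  }
  cases <- list(
    list(rot = FALSE, aware = TRUE,  lik = "poisson"),
    list(rot = FALSE, aware = TRUE,  lik = "gaussian"),
    list(rot = TRUE,  aware = TRUE,  lik = "poisson"),
    list(rot = TRUE,  aware = FALSE, lik = "gaussian")
  )
  for (cs in cases) {
    W <- gen$cx$W
    if (cs$lik == "gaussian") W <- W + 0.3
    static <- make_static(W, gen$cx$types, 2L, cs$lik, cs$aware, D = 3L)
    par <- mk_par(cs$rot, cs$aware, D = 3L)
    err <- grad_check_max_err(par, static)
    expect_lt(err, 1e-4)
  }
})

test_that("fit_embedding with n_steps = 0 returns the documented init", {
  gen <- make_ring_connectome(ring_circuit_spec(
    n_per_type = c(A = 5, B = 5), seed = 1))
  fit <- fit_embedding(gen$cx, D = 4,
                       config = train_config(n_steps = 0, seed = 9))
  expect_length(fit$loss_trace, 1)
  expect_identical(fit$n_steps_run, 0L)
  expect_true(all(fit$model$A == 1))
  expect_true(all(fit$model$B == 1))
  # C_raw inits so that the effective width C = 1
  C <- 1e-3 + log1p(exp(fit$model$C_raw))
  expect_equal(max(abs(C - 1)), 0, tolerance = 1e-12)
  # Z ~ N(0, 1/D): sd of the init is sqrt(1/D) (loose MC check)
  expect_equal(sd(fit$model$Z), sqrt(1 / 4), tolerance = 0.2)
})

test_that("fitting is deterministic given the seed and reduces the loss", {
  gen <- make_ring_connectome(ring_circuit_spec(
    n_per_type = c(A = 8, B = 8), seed = 2))
  cfg <- train_config(n_steps = 120, seed = 4)
  f1 <- fit_embedding(gen$cx, D = 3, config = cfg)
  f2 <- fit_embedding(gen$cx, D = 3, config = cfg)
  expect_identical(f1$model$Z, f2$model$Z)
  expect_identical(f1$loss_trace, f2$loss_trace)
  expect_lt(tail(f1$loss_trace, 1), f1$loss_trace[1])
  expect_length(f1$loss_trace, 121)  # init + one per step
})

test_that("holdout masks partition the off-diagonal pairs", {
  gen <- make_ring_connectome(ring_circuit_spec(
    n_per_type = c(A = 8, B = 8), seed = 2))
  N <- n_neurons(gen$cx)
  fit <- fit_embedding(gen$cx, D = 3,
                       config = train_config(n_steps = 5, seed = 1,
                                             holdout_fraction = 0.2))
  offdiag <- !(diag(N) > 0)
  expect_true(!any(fit$train_mask & fit$test_mask))
  expect_equal(fit$train_mask | fit$test_mask, offdiag)
  expect_equal(sum(fit$train_mask), round(0.8 * N * (N - 1)))
  expect_false(is.na(fit$test_nll_per_pair))
  ev <- evaluate_heldout(fit)
  expect_equal(ev$test_nll_per_pair, fit$test_nll_per_pair)

  fit0 <- fit_embedding(gen$cx, D = 3,
                        config = train_config(n_steps = 2, seed = 1))
  expect_error(evaluate_heldout(fit0), "empty held-out mask")
})

test_that("Poisson likelihood rejects non-integer counts", {
  W <- matrix(c(0, 0.5, 1, 0), 2, 2)
  cx <- connectome(W, types = c("a", "a"))
  expect_error(fit_embedding(cx, D = 2,
                             config = train_config(n_steps = 1)),
               "integer counts")
  # but the same data fits under the Gaussian likelihood
  expect_s3_class(fit_embedding(cx, D = 2, likelihood = "gaussian",
                                config = train_config(n_steps = 1)),
                  "embedding_fit")
})

test_that("rotation-augmented fits keep R exactly unitary", {
  gen <- make_ring_connectome(ring_circuit_spec(
    n_per_type = c(A = 6, B = 6), seed = 5))
  fit <- fit_embedding(gen$cx, D = 2, rotations = TRUE,
                       config = train_config(n_steps = 150, seed = 2))
  Rs <- ctembed:::materialize_rotations(fit$model)
  for (R in Rs) {
    expect_lt(max(abs(crossprod(R) - diag(2))), 1e-8)
    # generators stay exactly skew under Adam
  }
  for (G in fit$model$G) expect_equal(G, -t(G))
})

test_that("type-aware parameter shapes follow the flag", {
  gen <- make_ring_connectome(ring_circuit_spec(
    n_per_type = c(A = 5, B = 5), seed = 1))
  f1 <- fit_embedding(gen$cx, D = 2, config = train_config(n_steps = 2))
  expect_identical(dim(f1$model$A), c(2L, 2L))
  f0 <- fit_embedding(gen$cx, D = 2, type_aware = FALSE,
                      config = train_config(n_steps = 2))
  expect_identical(dim(f0$model$A), c(1L, 1L))
})

test_that("sample_adjacency draws from the fitted observation model", {
  m <- toy_model(matrix(0, 30, 2), A = 3, B = 1)
  What <- predict_mean(m)
  S1 <- sample_adjacency(m, seed = 11)
  S2 <- sample_adjacency(m, seed = 11)
  expect_identical(S1, S2)
  expect_true(all(diag(S1) == 0))
  expect_true(all(S1 == round(S1)))  # Poisson counts
  off <- !(diag(30) > 0)
  expect_equal(mean(S1[off]), mean(What[off]), tolerance = 0.05)
  m$likelihood <- "gaussian"
  Sg <- sample_adjacency(m, seed = 3)
  expect_false(all(Sg == round(Sg)))
})

test_that("fit serialization and tidy/glance accessors round trip", {
  gen <- make_ring_connectome(ring_circuit_spec(
    n_per_type = c(A = 5, B = 5), seed = 1))
  fit <- fit_embedding(gen$cx, D = 2, config = train_config(n_steps = 10))
  td <- withr::local_tempdir()
  p <- file.path(td, "fit.rds")
  write_embedding_fit(fit, p)
  fit2 <- read_embedding_fit(p)
  expect_equal(fit2$model$Z, fit$model$Z)
  expect_error(read_embedding_fit(file.path(td, "nope.rds")),
               "no fitted model")

  tb <- tidy(fit)
  expect_identical(names(tb)[1:2], c("neuron_id", "type"))
  expect_identical(nrow(tb), 10L)
  gl <- glance(fit)
  expect_identical(gl$n_neurons, 10L)
  expect_identical(gl$D, 2L)
  expect_equal(gl$loss_final, tail(fit$loss_trace, 1))
  expect_s3_class(autoplot(fit), "ggplot")

  ep <- file.path(td, "emb.tsv")
  write_embeddings_tsv(fit, ep)
  back <- read.delim(ep)
  expect_identical(nrow(back), 10L)
  expect_true(all(c("z_1", "z_2") %in% names(back)))
})

test_that("predict on a fit equals predict_mean of its model", {
  gen <- make_ring_connectome(ring_circuit_spec(
    n_per_type = c(A = 5, B = 5), seed = 1))
  fit <- fit_embedding(gen$cx, D = 2, config = train_config(n_steps = 3))
  expect_equal(predict(fit), predict_mean(fit$model))
})
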