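# Cell-type-aware latent embedding model.
#
# Each neuron i carries a latent vector Z_i in R^D. The predicted mean weight
# from neuron i to neuron j is
#
#   What_ij = softplus( A[ci,cj] * exp(-d(Z_i, Z_j)^2 / C[ci,cj]^2) + B[ci,cj] )
#
# with d the Euclidean distance, or d(Z_i, Z_j; R) = ||Z_i - R[ci,cj] Z_j||
# when per-type-pair unitary rotations are enabled (phase-shift detection).
# Edges are modelled as independent Poisson (synapse counts) or Gaussian with
# variance 1 + What^2 (continuous strengths). The loss is the negative log
# likelihood over off-diagonal pairs plus a ridge penalty
# lambda/(N*D) * ||Z||_F^2, minimized with Adam using analytic gradients.

#' Training configuration for the embedding model
#'
#' @param learning_rate Adam step size (default 0.01).
#' @param n_steps Maximum number of optimization steps (default 5000).
#' @param seed Integer seed controlling initialization and the held-out mask.
#' @param holdout_fraction Fraction of directed off-diagonal pairs held out
#'   for evaluation, in `[0, 1)` (default 0: train on all pairs).
#' @param tol Early-stopping tolerance: stop when the relative loss change
#'   over 100 steps falls below `tol` (default 1e-6).
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.01, n_steps = 5000, seed = 1,
                         holdout_fraction = 0, tol = 1e-6) {
  if (n_steps < 0) stop("n_steps must be >= 0")
  if (holdout_fraction < 0 || holdout_fraction >= 1)
    stop("holdout_fraction must be in [0, 1)")
  structure(list(learning_rate = learning_rate, n_steps = as.integer(n_steps),
                 seed = as.integer(seed),
                 holdout_fraction = holdout_fraction, tol = tol),
            class = "train_config")
}

# ---- parameter plumbing ----

# C is reparameterized as C = eps + softplus(C_raw) so the division in the
# kernel is always well-posed.
C_EPS <- 1e-3

c_raw_init <- function() log(expm1(1 - C_EPS))  # softplus(C_raw) = 1 - eps

expm_mat <- function(M) as.matrix(Matrix::expm(Matrix::Matrix(M)))

# Adjoint (vector-Jacobian product) of the matrix exponential: given the
# gradient Rbar = dL/d expm(G), returns dL/dG via the Frechet derivative of
# expm at t(G), computed with the 2D x 2D block-matrix identity.
expm_frechet_adjoint <- function(G, Rbar) {
  d <- nrow(G)
  blk <- rbind(cbind(t(G), Rbar), cbind(matrix(0, d, d), t(G)))
  E <- expm_mat(blk)
  E[seq_len(d), d + seq_len(d), drop = FALSE]
}

materialize_rotations <- function(model) {
  lapply(model$G, expm_mat)
}

pair_index_matrix <- function(ci, ntype, type_aware) {
  if (!type_aware) return(matrix(1L, length(ci), length(ci)))
  outer(ci, ci, function(a, b) a + (b - 1L) * ntype)
}

pack_par <- function(par) {
  c(as.numeric(par$Z), as.numeric(par$A), as.numeric(par$B),
    as.numeric(par$C_raw),
    if (!is.null(par$G)) unlist(lapply(par$G, as.numeric)) else numeric(0))
}

unpack_par <- function(vec, template) {
  out <- template
  pos <- 0L
  take <- function(n) {
    v <- vec[pos + seq_len(n)]
    pos <<- pos + n
    v
  }
  out$Z <- matrix(take(length(template$Z)), nrow(template$Z))
  out$A <- matrix(take(length(template$A)), nrow(template$A))
  out$B <- matrix(take(length(template$B)), nrow(template$B))
  out$C_raw <- matrix(take(length(template$C_raw)), nrow(template$C_raw))
  if (!is.null(template$G)) {
    d <- nrow(template$G[[1]])
    out$G <- lapply(template$G, function(g) matrix(take(d * d), d))
  }
  out
}

# ---- forward pass ----

# Squared-distance matrix, optionally with per-type-pair rotations.
compute_D2 <- function(Z, ci, R = NULL, ntype = 1L, idx = NULL) {
  if (is.null(R)) return(cross_dist2(Z, Z))
  N <- nrow(Z)
  D2 <- matrix(0, N, N)
  for (m in seq_len(ntype)) {
    for (n in seq_len(ntype)) {
      p <- pair_lin(m, n, ntype, length(R))
      im <- idx[[m]]; jn <- idx[[n]]
      if (length(im) == 0 || length(jn) == 0) next
      ZnR <- Z[jn, , drop = FALSE] %*% t(R[[p]])
      D2[im, jn] <- cross_dist2(Z[im, , drop = FALSE], ZnR)
    }
  }
  D2
}

pair_lin <- function(m, n, ntype, npair) {
  if (npair == 1L) 1L else m + (n - 1L) * ntype
}

#' Predicted mean adjacency of an embedding model
#'
#' Evaluates `softplus(A[ci,cj] * exp(-d_ij^2 / C[ci,cj]^2) + B[ci,cj])` for
#' every directed pair. The diagonal is computed like any other entry but is
#' excluded from all likelihood sums in the package.
#'
#' @param model An `embedding_model` (e.g. `fit$model` from
#'   [fit_embedding()]).
#' @param types Optional type labels overriding the ones stored in the model.
#' @return `N x N` matrix of strictly positive predicted means.
#' @export
predict_mean <- function(model, types = NULL) {
  ci <- if (is.null(types)) model$types else as.integer(types)
  N <- length(ci)
  if (nrow(model$Z) != N) stop("model dimensions inconsistent with labels")
  Cm <- C_EPS + softplus(model$C_raw)
  if (any(Cm == 0)) stop("C entry equal to 0")
  PIdx <- pair_index_matrix(ci, model$ntype, model$type_aware)
  idx <- lapply(seq_len(model$ntype), function(m) which(ci == m))
  R <- if (model$rotations) materialize_rotations(model) else NULL
  D2 <- compute_D2(model$Z, ci, R,
                   ntype = if (model$rotations) model$ntype else 1L,
                   idx = idx)
  Af <- matrix(model$A[PIdx], N, N)
  Bf <- matrix(model$B[PIdx], N, N)
  Cf <- matrix(Cm[PIdx], N, N)
  softplus(Af * exp(-D2 / Cf^2) + Bf)
}

# ---- likelihoods ----

nll_matrix <- function(What, W, likelihood) {
  What <- pmax(What, 1e-300)
  if (likelihood == "poisson") {
    What - W * log(What) + lgamma(W + 1)
  } else {
    v <- 1 + What^2
    0.5 * log(2 * pi * v) + (W - What)^2 / (2 * v)
  }
}

check_poisson_counts <- function(W, mask) {
  w <- W[mask]
  if (any(w != round(w)))
    stop("Poisson likelihood requires integer counts on the evaluated pairs")
}

#' Negative log likelihood of a model on a set of directed pairs
#'
#' Poisson: `sum(What - W*log(What) + log(W!))`; Gaussian:
#' `sum(0.5*log(2*pi*(1+What^2)) + (W-What)^2 / (2*(1+What^2)))`. The
#' `log(W!)` term is constant in the parameters but is included so reported
#' values are absolute.
#'
#' @param model An `embedding_model`.
#' @param W Observed adjacency matrix.
#' @param mask Logical `N x N` matrix selecting off-diagonal directed pairs;
#'   defaults to all off-diagonal pairs.
#' @return List with `total` (sum over the mask), `per_pair` (mean) and
#'   `n_pairs`.
#' @export
embedding_nll <- function(model, W, mask = NULL) {
  N <- nrow(W)
  if (is.null(mask)) mask <- !diag(N) > 0
  if (any(mask & diag(N) > 0)) stop("mask must exclude the diagonal")
  if (model$likelihood == "poisson") check_poisson_counts(W, mask)
  What <- predict_mean(model)
  nm <- nll_matrix(What, W, model$likelihood)
  tot <- sum(nm[mask])
  list(total = tot, per_pair = tot / sum(mask), n_pairs = sum(mask))
}

#' Training loss (regularized negative log likelihood)
#'
#' `embedding_nll(...)$total + lambda/(N*D) * ||Z||_F^2`.
#'
#' @inheritParams embedding_nll
#' @return Scalar loss.
#' @export
embedding_loss <- function(model, W, mask = NULL) {
  nll <- embedding_nll(model, W, mask)$total
  N <- nrow(model$Z)
  nll + model$lambda / (N * model$D) * sum(model$Z^2)
}

# ---- loss + analytic gradient ----

# par: list(Z, A, B, C_raw, G); static: precomputed problem description.
embedding_loss_grad <- function(par, static) {
  N <- static$N; D <- static$D
  W <- static$W; mask <- static$mask
  Cm <- C_EPS + softplus(par$C_raw)
  rot <- !is.null(par$G)
  R <- if (rot) lapply(par$G, expm_mat) else NULL
  D2 <- compute_D2(par$Z, static$ci, R,
                   ntype = if (rot) static$ntype else 1L, idx = static$idx)

  Af <- matrix(par$A[static$PIdx], N, N)
  Bf <- matrix(par$B[static$PIdx], N, N)
  Cf <- matrix(Cm[static$PIdx], N, N)
  E <- exp(-D2 / Cf^2)
  u <- Af * E + Bf
  What <- pmax(softplus(u), 1e-300)

  if (static$likelihood == "poisson") {
    nllm <- What - W * log(What) + static$lgammaW
    dWhat <- 1 - W / What
  } else {
    v <- 1 + What^2
    resid <- W - What
    nllm <- 0.5 * log(2 * pi * v) + resid^2 / (2 * v)
    dWhat <- What / v - resid / v - What * resid^2 / v^2
  }
  nll_sum <- sum(nllm[mask])
  loss <- nll_sum + static$lambda / (N * D) * sum(par$Z^2)

  g <- dWhat * sigmoid(u)
  g[!mask] <- 0

  GE <- g * E
  dC_mat <- GE * Af * (2 * D2 / Cf^3)
  H <- GE * Af * (-1 / Cf^2)  # dL/d(d^2)

  if (static$type_aware) {
    nt <- static$ntype
    gA <- gB <- gC <- matrix(0, nt, nt)
    for (m in seq_len(nt)) {
      im <- static$idx[[m]]
      if (length(im) == 0) next
      for (n in seq_len(nt)) {
        jn <- static$idx[[n]]
        if (length(jn) == 0) next
        gA[m, n] <- sum(GE[im, jn])
        gB[m, n] <- sum(g[im, jn])
        gC[m, n] <- sum(dC_mat[im, jn])
      }
    }
  } else {
    gA <- matrix(sum(GE), 1, 1)
    gB <- matrix(sum(g), 1, 1)
    gC <- matrix(sum(dC_mat), 1, 1)
  }
  gC_raw <- gC * sigmoid(par$C_raw)

  if (!rot) {
    S <- H + t(H)
    gZ <- 2 * (rowSums(S) * par$Z - S %*% par$Z)
    gG <- NULL
  } else {
    gZ <- matrix(0, N, D)
    gG <- lapply(par$G, function(gm) matrix(0, D, D))
    for (m in seq_len(static$ntype)) {
      im <- static$idx[[m]]
      if (length(im) == 0) next
      Zm <- par$Z[im, , drop = FALSE]
      for (n in seq_len(static$ntype)) {
        jn <- static$idx[[n]]
        if (length(jn) == 0) next
        p <- pair_lin(m, n, static$ntype, length(par$G))
        Rp <- R[[p]]
        Zn <- par$Z[jn, , drop = FALSE]
        Hb <- H[im, jn, drop = FALSE]
        ZnR <- Zn %*% t(Rp)
        rs <- rowSums(Hb)
        cs <- colSums(Hb)
        gZ[im, ] <- gZ[im, ] + 2 * (rs * Zm - Hb %*% ZnR)
        Y <- crossprod(Hb, Zm) - cs * ZnR
        gZ[jn, ] <- gZ[jn, ] - 2 * (Y %*% Rp)
        gR <- -2 * (crossprod(Zm, Hb %*% Zn) - Rp %*% crossprod(Zn, cs * Zn))
        full <- expm_frechet_adjoint(par$G[[p]], gR)
        gG[[p]] <- gG[[p]] + (full - t(full)) / 2  # project onto skew space
      }
    }
  }
  gZ <- gZ + 2 * static$lambda / (N * D) * par$Z

  list(loss = loss, nll_sum = nll_sum,
       grads = list(Z = gZ, A = gA, B = gB, C_raw = gC_raw, G = gG))
}

# ---- fitting ----

#' Fit the cell-type-aware embedding model
#'
#' Learns latent vectors `Z` (one per neuron) and type-pair parameters
#' `A, B, C` (and optionally unitary rotations `R`) by minimizing the
#' regularized negative log likelihood with Adam. `Z` is initialized i.i.d.
#' `N(0, 1/D)`; `A`, `B`, `C` start at 1; rotation generators start at 0
#' (`R = I`). The same seed always produces a bit-identical run.
#'
#' @param cx A [connectome()].
#' @param D Embedding dimension (default 5).
#' @param likelihood `"poisson"` for integer synapse counts or `"gaussian"`
#'   (variance `1 + What^2`) for continuous strengths.
#' @param type_aware When `FALSE`, `A`, `B`, `C` are scalars shared by all
#'   type pairs (the baseline model); when `TRUE` (default) they are
#'   `N_type x N_type` matrices.
#' @param rotations When `TRUE`, the distance is
#'   `||Z_i - R[ci,cj] Z_j||` with one unitary `R` per ordered type pair,
#'   parameterized as the matrix exponential of a trainable skew-symmetric
#'   generator (unitary by construction).
#' @param lambda Ridge weight on `Z` (default 0.1).
#' @param config A [train_config()].
#' @param verbose Log the loss every 100 steps via `message()`.
#' @return An object of class `embedding_fit` with fields `model`,
#'   `loss_trace` (loss at initialization, then after each step),
#'   `n_steps_run`, `train_mask`, `test_mask`, `train_nll_per_pair`,
#'   `test_nll_per_pair`, `W`, `config`.
#' @export
fit_embedding <- function(cx, D = 5, likelihood = c("poisson", "gaussian"),
                          type_aware = TRUE, rotations = FALSE, lambda = 0.1,
                          config = train_config(), verbose = FALSE) {
  likelihood <- match.arg(likelihood)
  W <- cx$W
  N <- nrow(W)
  if (D < 1) stop("D must be >= 1")
  ci <- cx$types
  ntype <- length(cx$type_names)

  offdiag <- !(diag(N) > 0)
  if (likelihood == "poisson") check_poisson_counts(W, offdiag)

  set.seed(config$seed)
  if (config$holdout_fraction > 0) {
    od_idx <- which(offdiag)
    n_train <- round((1 - config$holdout_fraction) * N * (N - 1))
    train_idx <- sample(od_idx, n_train)
    train_mask <- matrix(FALSE, N, N)
    train_mask[train_idx] <- TRUE
    test_mask <- offdiag & !train_mask
  } else {
    train_mask <- offdiag
    test_mask <- matrix(FALSE, N, N)
  }
  if (!any(train_mask)) stop("training mask is empty")

  npair_rot <- if (type_aware) ntype * ntype else 1L
  par <- list(
    Z = matrix(rnorm(N * D, 0, sqrt(1 / D)), N, D),
    A = matrix(1, if (type_aware) ntype else 1, if (type_aware) ntype else 1),
    B = matrix(1, if (type_aware) ntype else 1, if (type_aware) ntype else 1),
    C_raw = matrix(c_raw_init(), if (type_aware) ntype else 1,
                   if (type_aware) ntype else 1),
    G = if (rotations) replicate(npair_rot, matrix(0, D, D),
                                 simplify = FALSE) else NULL
  )

  static <- list(
    W = W, mask = train_mask, ci = ci,
    PIdx = pair_index_matrix(ci, ntype, type_aware),
    idx = lapply(seq_len(ntype), function(m) which(ci == m)),
    likelihood = likelihood, type_aware = type_aware,
    lambda = lambda, N = N, D = D, ntype = ntype,
    lgammaW = if (likelihood == "poisson") lgamma(W + 1) else NULL
  )

  # Adam state on the packed parameter vector
  theta <- pack_par(par)
  mstate <- numeric(length(theta))
  vstate <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; aeps <- 1e-8
  lr <- config$learning_rate

  trace <- numeric(0)
  steps_run <- 0L
  for (t in seq_len(config$n_steps)) {
    lg <- embedding_loss_grad(par, static)
    if (!is.finite(lg$loss))
      stop("optimization diverged (non-finite loss) at step ", t)
    trace <- c(trace, lg$loss)
    gvec <- pack_par(lg$grads)
    mstate <- b1 * mstate + (1 - b1) * gvec
    vstate <- b2 * vstate + (1 - b2) * gvec^2
    mh <- mstate / (1 - b1^t)
    vh <- vstate / (1 - b2^t)
    theta <- theta - lr * mh / (sqrt(vh) + aeps)
    par <- unpack_par(theta, par)
    steps_run <- t
    if (verbose && t %% 100 == 0)
      message("step ", t, " loss ", format(lg$loss))
    if (t > 100) {
      prev <- trace[t - 100]
      if (abs(trace[t] - prev) / (abs(prev) + 1e-12) < config$tol) break
    }
  }
  final <- embedding_loss_grad(par, static)
  if (!is.finite(final$loss))
    stop("optimization diverged (non-finite loss) at final evaluation")
  loss_trace <- c(trace, final$loss)

  model <- structure(
    list(Z = par$Z, A = par$A, B = par$B, C_raw = par$C_raw, G = par$G,
         D = D, ntype = ntype, likelihood = likelihood,
         type_aware = type_aware, rotations = rotations, lambda = lambda,
         types = ci, type_names = cx$type_names,
         neuron_ids = cx$neuron_ids),
    class = "embedding_model")

  fit <- structure(
    list(model = model, loss_trace = loss_trace, n_steps_run = steps_run,
         train_mask = train_mask, test_mask = test_mask, W = W,
         config = config),
    class = "embedding_fit")
  ev <- evaluate_heldout(fit, require_test = FALSE)
  fit$train_nll_per_pair <- ev$train_nll_per_pair
  fit$test_nll_per_pair <- ev$test_nll_per_pair
  fit
}

#' Per-pair negative log likelihood on the train and held-out masks
#'
#' @param fit An `embedding_fit`.
#' @param W Adjacency to evaluate on; defaults to the training matrix.
#' @param require_test Error when the fit has no held-out pairs
#'   (default TRUE).
#' @return List with `train_nll_per_pair` and `test_nll_per_pair` (the latter
#'   `NA` when no pairs were held out and `require_test = FALSE`).
#' @export
evaluate_heldout <- function(fit, W = NULL, require_test = TRUE) {
  if (is.null(W)) W <- fit$W
  has_test <- any(fit$test_mask)
  if (!has_test && require_test) stop("fit has an empty held-out mask")
  tr <- embedding_nll(fit$model, W, fit$train_mask)
  te <- if (has_test) embedding_nll(fit$model, W, fit$test_mask) else NULL
  list(train_nll_per_pair = tr$per_pair,
       test_nll_per_pair = if (has_test) te$per_pair else NA_real_)
}

#' Sample an adjacency matrix from a fitted model
#'
#' Draws each off-diagonal entry independently: Poisson with mean `What_ij`,
#' or Gaussian with mean `What_ij` and variance `1 + What_ij^2`. The diagonal
#' is set to 0.
#'
#' @param model An `embedding_model`.
#' @param seed Integer seed.
#' @return `N x N` matrix.
#' @export
sample_adjacency <- function(model, seed = 1) {
  What <- predict_mean(model)
  N <- nrow(What)
  set.seed(seed)
  if (model$likelihood == "poisson") {
    S <- matrix(rpois(N * N, lambda = What), N, N)
  } else {
    S <- matrix(rnorm(N * N, mean = What, sd = sqrt(1 + What^2)), N, N)
  }
  diag(S) <- 0
  S
}

#' @export
predict.embedding_fit <- function(object, ...) predict_mean(object$model)

#' @export
print.embedding_fit <- function(x, ...) {
  cat("<embedding_fit> N=", nrow(x$model$Z), " D=", x$model$D,
      " likelihood=", x$model$likelihood,
      " type_aware=", x$model$type_aware,
      " rotations=", x$model$rotations, "\n", sep = "")
  cat("  steps run: ", x$n_steps_run,
      "; train NLL/pair: ", format(x$train_nll_per_pair), sep = "")
  if (!is.na(x$test_nll_per_pair))
    cat("; test NLL/pair: ", format(x$test_nll_per_pair), sep = "")
  cat("\n")
  invisible(x)
}

#' @export
#' @method tidy embedding_fit
tidy.embedding_fit <- function(x, ...) {
  Z <- x$model$Z
  colnames(Z) <- paste0("z_", seq_len(ncol(Z)))
  dplyr::bind_cols(
    tibble::tibble(neuron_id = x$model$neuron_ids,
                   type = x$model$type_names[x$model$types]),
    tibble::as_tibble(Z)
  )
}

#' @export
#' @method glance embedding_fit
glance.embedding_fit <- function(x, ...) {
  tibble::tibble(
    n_neurons = nrow(x$model$Z),
    n_types = x$model$ntype,
    D = as.integer(x$model$D),
    likelihood = x$model$likelihood,
    type_aware = x$model$type_aware,
    rotations = x$model$rotations,
    n_steps_run = x$n_steps_run,
    loss_final = x$loss_trace[length(x$loss_trace)],
    train_nll_per_pair = x$train_nll_per_pair,
    test_nll_per_pair = x$test_nll_per_pair
  )
}

#' @export
#' @method autoplot embedding_fit
autoplot.embedding_fit <- function(object, ...) {
  Z <- object$model$Z
  pc <- prcomp(Z, center = TRUE)
  df <- tibble::tibble(
    pc1 = pc$x[, 1],
    pc2 = if (ncol(pc$x) > 1) pc$x[, 2] else 0,
    type = object$model$type_names[object$model$types]
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pc1, y = .data$pc2,
                                   colour = .data$type)) +
    ggplot2::geom_point() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "embedding PC1", y = "embedding PC2",
                  title = "Latent embeddings (top principal components)")
}

# ---- serialization ----

#' Save / load a fitted embedding
#'
#' The archive stores `Z`, `A`, `B`, `C`, rotation generators, configuration
#' and the train/test masks in a single RDS file.
#'
#' @param fit An `embedding_fit`.
#' @param path Output path.
#' @return `path`, invisibly (writer); an `embedding_fit` (reader).
#' @export
write_embedding_fit <- function(fit, path) {
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname write_embedding_fit
#' @export
read_embedding_fit <- function(path) {
  if (!file.exists(path)) stop("no fitted model at '", path, "'")
  readRDS(path)
}

#' Export embeddings as TSV (neuron_id, type, z_1..z_D)
#'
#' @param fit An `embedding_fit`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_embeddings_tsv <- function(fit, path) {
  write.table(as.data.frame(tidy(fit)), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
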