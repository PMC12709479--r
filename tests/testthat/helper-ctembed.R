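# Shared test helpers.

# 2-D rotation matrix
rot2 <- function(a) matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)

# Maximal circular agreement between a recovered ordering and ground truth.
# `o` lists the neurons in recovered order around the circle; ground truth is
# the identity sequence 1..M. The maximum over cyclic rotations and the
# reflection of the fraction of sequence positions that match.
circular_agreement <- function(o, M = length(o)) {
  max(circular_agreement_oriented(o, M),
      circular_agreement_oriented(rev(o), M))
}

# As above, but over cyclic rotations only (reflection-sensitive); used to
# detect which orientation a recovered ring has.
circular_agreement_oriented <- function(o, M = length(o)) {
  best <- 0
  for (r in 0:(M - 1)) {
    best <- max(best, mean(o[((seq_len(M) - 1 + r) %% M) + 1] == seq_len(M)))
  }
  best
}

# All permutations of 1..M (M small), one per row
perms_of <- function(M) {
  if (M == 1) return(matrix(1L, 1, 1))
  sub <- perms_of(M - 1)
  do.call(rbind, lapply(seq_len(M), function(k) cbind(k, sub + (sub >= k))))
}

# Align recovered angles (radians, [0, 2*pi)) to ground-truth angles that
# are sorted increasing: picks the reflection with the better cyclic-order
# agreement (the circle's orientation is not identifiable from the weights
# alone), then rotates by the circular mean offset so aligned angles track
# the truth. Returns the aligned angles.
align_to_truth <- function(theta_rec, theta_true) {
  cand <- list(theta_rec, (2 * pi - theta_rec) %% (2 * pi))
  ag <- vapply(cand, function(th) circular_agreement_oriented(order(th)),
               numeric(1))
  th <- cand[[which.max(ag)]]
  off <- atan2(mean(sin(theta_true - th)), mean(cos(theta_true - th)))
  (th + off) %% (2 * pi)
}

# Numerical directional-derivative check of the packed analytic gradient.
# Returns the max relative error over `ndir` random skew-respecting
# directions.
grad_check_max_err <- function(par, static, ndir = 6, h = 1e-5, seed = 1) {
  lg <- ctembed:::embedding_loss_grad(par, static)
  gvec <- ctembed:::pack_par(lg$grads)
  th0 <- ctembed:::pack_par(par)
  set.seed(seed)
  errs <- vapply(seq_len(ndir), function(k) {
    dir <- rnorm(length(th0))
    tmp <- ctembed:::unpack_par(dir, par)
    if (!is.null(tmp$G)) tmp$G <- lapply(tmp$G, function(g) (g - t(g)) / 2)
    dir <- ctembed:::pack_par(tmp)
    lp <- ctembed:::embedding_loss_grad(
      ctembed:::unpack_par(th0 + h * dir, par), static)$loss
    lm_ <- ctembed:::embedding_loss_grad(
      ctembed:::unpack_par(th0 - h * dir, par), static)$loss
    num <- (lp - lm_) / (2 * h)
    ana <- sum(gvec * dir)
    abs(num - ana) / max(abs(num), 1e-8)
  }, numeric(1))
  max(errs)
}

# Static environment for embedding_loss_grad built from a connectome
make_static <- function(W, ci, ntype, likelihood, type_aware, D,
                        lambda = 0.1) {
  N <- nrow(W)
  list(W = W, mask = !(diag(N) > 0), ci = ci,
       PIdx = ctembed:::pair_index_matrix(ci, ntype, type_aware),
       idx = lapply(seq_len(ntype), function(m) which(ci == m)),
       likelihood = likelihood, type_aware = type_aware,
       lambda = lambda, N = N, D = D, ntype = ntype,
       lgammaW = if (likelihood == "poisson") lgamma(W + 1) else NULL)
}

# Minimal hand-built embedding model
toy_model <- function(Z, A = 1, B = 0, likelihood = "poisson",
                      types = NULL, type_names = NULL) {
  N <- nrow(Z)
  if (is.null(types)) types <- rep(1L, N)
  ntype <- max(types)
  if (is.null(type_names)) type_names <- paste0("t", seq_len(ntype))
  k <- if (ntype > 1) ntype else 1
  structure(list(
    Z = Z,
    A = matrix(A, k, k), B = matrix(B, k, k),
    C_raw = matrix(ctembed:::c_raw_init(), k, k),
    G = NULL, D = ncol(Z), ntype = ntype, likelihood = likelihood,
    type_aware = ntype > 1, rotations = FALSE, lambda = 0.1,
    types = types, type_names = type_names,
    neuron_ids = as.character(seq_len(N) - 1)), class = "embedding_model")
}
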