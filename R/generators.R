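# Synthetic connectome generators carrying ground-truth latent variables:
# block-circulant ring circuits (heading-direction analogue), the toroidal
# excitatory/inhibitory grid-cell sheet, and retinotopic projections.

#' Ring-circuit specification
#'
#' Describes a multi-type ring circuit: neurons of each type get evenly
#' spaced preferred angles, and the mean weight from neuron i (type m, angle
#' `th_i`) to neuron j (type n, angle `th_j`) is a Gaussian bump over the
#' wrapped angular offset,
#' `a_mn * exp(-wrap(th_j - th_i - dtheta_mn)^2 / sigma_mn^2) + b_mn`,
#' with `a_mn = 0` for unstructured pairs. With equal type sizes and no
#' noise every type-to-type block is exactly circulant. The defaults give a
#' 3-type circuit (16 neurons each, gain 10) in which the first two types
#' exchange a reciprocal 2*pi/8 phase offset, the structure the heading
#' direction circuit uses for angular-velocity integration.
#'
#' @param n_per_type Named integer vector of neuron counts per type, each at
#'   least 3.
#' @param gain,baseline,sigma Scalars or `N_type x N_type` matrices: bump
#'   gain `a_mn` (>= 0), baseline rate `b_mn` (>= 0), tuning width
#'   `sigma_mn` in radians (> 0).
#' @param offset Scalar or matrix of phase offsets `dtheta_mn` in
#'   `[0, 2*pi)`; defaults to 0 everywhere except the reciprocal 2*pi/8
#'   shift between the first two types.
#' @param structured Logical scalar/matrix; unstructured pairs get gain 0.
#' @param noise `"poisson"` (weights drawn around the mean) or `"none"`
#'   (means used directly).
#' @param seed Integer seed for the Poisson draws.
#' @return A list of class `ring_circuit_spec`.
#' @export
ring_circuit_spec <- function(n_per_type = c(R1 = 16, R2 = 16, R3 = 16),
                              gain = 10, baseline = 0.1, sigma = 0.8,
                              offset = NULL, structured = TRUE,
                              noise = c("poisson", "none"), seed = 1) {
  noise <- match.arg(noise)
  nt <- length(n_per_type)
  if (is.null(names(n_per_type)))
    names(n_per_type) <- paste0("T", seq_len(nt))
  if (any(n_per_type < 3)) stop("each type needs >= 3 neurons")
  as_mat <- function(x, what) {
    if (length(x) == 1) x <- matrix(x, nt, nt)
    x <- as.matrix(x)
    if (!all(dim(x) == c(nt, nt))) stop(what, " must be scalar or ",
                                        nt, " x ", nt)
    x
  }
  gain <- as_mat(gain, "gain")
  baseline <- as_mat(baseline, "baseline")
  sigma <- as_mat(sigma, "sigma")
  if (is.null(offset)) {
    offset <- matrix(0, nt, nt)
    if (nt >= 2) {
      offset[1, 2] <- 2 * pi / 8
      offset[2, 1] <- 2 * pi - 2 * pi / 8
    }
  } else {
    offset <- as_mat(offset, "offset")
  }
  structured <- as_mat(structured + 0, "structured") > 0
  gain[!structured] <- 0
  if (any(gain < 0) || any(baseline < 0) || any(sigma <= 0) ||
      any(offset < 0) || any(offset >= 2 * pi))
    stop("invalid ring-circuit parameters")
  structure(list(n_per_type = n_per_type, gain = gain, baseline = baseline,
                 sigma = sigma, offset = offset, structured = structured,
                 noise = noise, seed = as.integer(seed)),
            class = "ring_circuit_spec")
}

#' Generate a ring-circuit connectome
#'
#' @param spec A [ring_circuit_spec()].
#' @return List with `cx` (a [connectome()]), `theta` (ground-truth angle per
#'   neuron, in `[0, 2*pi)`), `mean` (the noiseless mean matrix) and `spec`.
#' @export
make_ring_connectome <- function(spec) {
  stopifnot(inherits(spec, "ring_circuit_spec"))
  nt <- length(spec$n_per_type)
  theta <- unlist(lapply(spec$n_per_type,
                         function(n) 2 * pi * (seq_len(n) - 1) / n),
                  use.names = FALSE)
  types <- rep(seq_len(nt), times = spec$n_per_type)
  N <- length(theta)
  mu <- matrix(0, N, N)
  for (m in seq_len(nt)) {
    im <- which(types == m)
    for (n in seq_len(nt)) {
      jn <- which(types == n)
      off <- outer(theta[im], theta[jn],
                   function(ti, tj) wrap_angle(tj - ti - spec$offset[m, n]))
      mu[im, jn] <- spec$gain[m, n] * exp(-off^2 / spec$sigma[m, n]^2) +
        spec$baseline[m, n]
    }
  }
  diag(mu) <- 0
  if (spec$noise == "poisson") {
    set.seed(spec$seed)
    W <- matrix(rpois(N * N, mu), N, N)
    diag(W) <- 0
  } else {
    W <- mu
  }
  cx <- connectome(W, types = types, type_names = names(spec$n_per_type))
  list(cx = cx, theta = theta, mean = mu, spec = spec)
}

#' Grid-cell circuit specification
#'
#' An excitatory/inhibitory grid-cell sheet: `n_E^2` excitatory neurons at
#' unit spacing and `n_I^2` inhibitory neurons at spacing `n_E/n_I` on a
#' periodic square sheet of side `n_E`. Connection strengths depend on the
#' geodesic (wrapped Euclidean) distance:
#' `W_EE = exp(-gamma*d^2) - I`, `W_EI = exp(-(beta/2)*d^2)`, and the I->E
#' weights are the negative transpose of E->I (effective lateral inhibition;
#' the adjacency stores magnitudes, the inhibitory sign travels as neuron
#' metadata). There are no I->I connections. The assembled matrix is rescaled
#' so its maximum element equals `w_max`. Unless overridden, the kernel
#' parameters follow `lambda_net = 13*n_E/128`, `beta = 3/lambda_net^2`,
#' `gamma = 1.05*beta`.
#'
#' @param n_E Excitatory lattice side length.
#' @param n_I Inhibitory lattice side length (`n_E > n_I >= 2`).
#' @param w_max Target maximum adjacency element (default 100).
#' @param beta,gamma Optional kernel overrides.
#' @return A list of class `grid_circuit_spec` (with derived `lambda_net`,
#'   `beta`, `gamma`).
#' @export
grid_circuit_spec <- function(n_E = 12, n_I = 8, w_max = 100, beta = NULL,
                              gamma = NULL) {
  if (!(n_E > n_I && n_I >= 2)) stop("need n_E > n_I >= 2")
  lambda_net <- 13 * n_E / 128
  beta <- beta %||% (3 / lambda_net^2)
  gamma <- gamma %||% (1.05 * beta)
  structure(list(n_E = as.integer(n_E), n_I = as.integer(n_I), w_max = w_max,
                 lambda_net = lambda_net, beta = beta, gamma = gamma),
            class = "grid_circuit_spec")
}

# wrapped squared Euclidean distance between rows of 2-column position
# matrices on a periodic sheet of side L
torus_dist2 <- function(X, Y, L) {
  d2 <- matrix(0, nrow(X), nrow(Y))
  for (k in 1:2) {
    dd <- abs(outer(X[, k], Y[, k], "-")) %% L
    dd <- pmin(dd, L - dd)
    d2 <- d2 + dd^2
  }
  d2
}

#' Generate the grid-cell connectome
#'
#' Deterministic (the construction has no noise); the connectome has types
#' `"E"` and `"I"`, a metadata column `sign` (-1 for inhibitory neurons,
#' applied to their outgoing weights when interpreting the circuit), and
#' sheet positions in metadata columns `sx`, `sy`.
#'
#' @param spec A [grid_circuit_spec()].
#' @return List with `cx` (a [connectome()]), `positions` (tibble
#'   `neuron_id`, `type`, `sx`, `sy`) and `spec`.
#' @export
make_grid_connectome <- function(spec) {
  stopifnot(inherits(spec, "grid_circuit_spec"))
  nE <- spec$n_E; nI <- spec$n_I
  gE <- -nE / 2 + seq_len(nE) - 1          # unit spacing
  gI <- -nE / 2 + (seq_len(nI) - 1) * (nE / nI)
  xE <- cbind(rep(gE, each = nE), rep(gE, times = nE))
  xI <- cbind(rep(gI, each = nI), rep(gI, times = nI))
  dEE <- torus_dist2(xE, xE, nE)
  dEI <- torus_dist2(xE, xI, nE)
  WEE <- exp(-spec$gamma * dEE) - diag(nE * nE)
  WEI <- exp(-(spec$beta / 2) * dEI)
  # I->E magnitudes are the transpose of E->I (the sign is metadata)
  W <- rbind(cbind(WEE, WEI),
             cbind(t(WEI), matrix(0, nI * nI, nI * nI)))
  W <- (W / max(W)) * spec$w_max
  types <- c(rep(1L, nE * nE), rep(2L, nI * nI))
  pos <- rbind(xE, xI)
  meta <- data.frame(sign = ifelse(types == 1L, 1, -1),
                     sx = pos[, 1], sy = pos[, 2])
  cx <- connectome(W, types = types, type_names = c("E", "I"), meta = meta)
  positions <- tibble::tibble(neuron_id = cx$neuron_ids,
                              type = c("E", "I")[types],
                              sx = pos[, 1], sy = pos[, 2])
  list(cx = cx, positions = positions, spec = spec)
}

#' Retinotopic-circuit specification
#'
#' One source population of visual projection neurons with receptive-field
#' (RF) centers on a regular grid in the unit square, plus two downstream
#' populations: `"sel"` neurons with Gaussian selectivity over RF space
#' (`gain * exp(-||rf_i - center_t||^2 / width^2) + baseline`) and `"nonsel"`
#' neurons receiving spatially uniform input
#' (`gain * uniform_level + baseline`). Recurrent source-type connectivity is
#' retinotopically organized with its own Gaussian kernel over RF distance.
#'
#' @param n_source Number of source neurons (a perfect square; default 64).
#' @param n_sel,n_uni Numbers of selective and uniform target neurons.
#' @param gain,baseline Feedforward bump gain and baseline mean synapse
#'   count.
#' @param width RF width of selective targets (unit-square units).
#' @param uniform_level Constant in `[0, 1]` setting the uniform targets'
#'   drive.
#' @param recurrent_gain,recurrent_width Recurrent source-source kernel.
#' @param noise `"poisson"` or `"none"`.
#' @param seed Integer seed.
#' @return A list of class `retino_circuit_spec`.
#' @export
retino_circuit_spec <- function(n_source = 64, n_sel = 8, n_uni = 8,
                                gain = 30, baseline = 0.2, width = 0.25,
                                uniform_level = 0.4, recurrent_gain = 20,
                                recurrent_width = 0.2,
                                noise = c("poisson", "none"), seed = 1) {
  noise <- match.arg(noise)
  s <- round(sqrt(n_source))
  if (s * s != n_source) stop("n_source must be a perfect square")
  if (width <= 0 || recurrent_width <= 0) stop("widths must be > 0")
  structure(list(n_source = as.integer(n_source), n_sel = as.integer(n_sel),
                 n_uni = as.integer(n_uni), gain = gain, baseline = baseline,
                 width = width, uniform_level = uniform_level,
                 recurrent_gain = recurrent_gain,
                 recurrent_width = recurrent_width, noise = noise,
                 seed = as.integer(seed)),
            class = "retino_circuit_spec")
}

#' Generate a retinotopic projection connectome
#'
#' @param spec A [retino_circuit_spec()].
#' @return List with `cx` (types `"VPN"`, `"sel"`, `"nonsel"`), `rf` (tibble
#'   `neuron_id`, `rf_x`, `rf_y`; RF centers of the source neurons),
#'   `centers` (selective-target RF centers), `mean` and `spec`.
#' @export
make_retinotopic_connectome <- function(spec) {
  stopifnot(inherits(spec, "retino_circuit_spec"))
  s <- round(sqrt(spec$n_source))
  g <- (seq_len(s) - 0.5) / s
  rf <- cbind(rep(g, each = s), rep(g, times = s))
  # selective-target centers evenly spread over the unit square
  ts <- ceiling(sqrt(spec$n_sel))
  gt <- (seq_len(ts) - 0.5) / ts
  centers <- cbind(rep(gt, each = ts), rep(gt, times = ts))[seq_len(spec$n_sel), , drop = FALSE]

  n_src <- spec$n_source
  N <- n_src + spec$n_sel + spec$n_uni
  mu <- matrix(0, N, N)
  # recurrent retinotopic source connectivity
  d2 <- cross_dist2(rf, rf)
  mu[seq_len(n_src), seq_len(n_src)] <-
    spec$recurrent_gain * exp(-d2 / spec$recurrent_width^2) + spec$baseline
  # feedforward to selective targets
  jsel <- n_src + seq_len(spec$n_sel)
  d2t <- cross_dist2(rf, centers)
  mu[seq_len(n_src), jsel] <-
    spec$gain * exp(-d2t / spec$width^2) + spec$baseline
  # feedforward to uniform targets
  juni <- n_src + spec$n_sel + seq_len(spec$n_uni)
  mu[seq_len(n_src), juni] <- spec$gain * spec$uniform_level + spec$baseline
  diag(mu) <- 0

  if (spec$noise == "poisson") {
    set.seed(spec$seed)
    W <- matrix(rpois(N * N, mu), N, N)
    diag(W) <- 0
  } else {
    W <- mu
  }
  types <- c(rep(1L, n_src), rep(2L, spec$n_sel), rep(3L, spec$n_uni))
  cx <- connectome(W, types = types, type_names = c("VPN", "sel", "nonsel"))
  rf_tb <- tibble::tibble(neuron_id = cx$neuron_ids[seq_len(n_src)],
                          rf_x = rf[, 1], rf_y = rf[, 2])
  list(cx = cx, rf = rf_tb, centers = centers, mean = mu, spec = spec)
}

#' Shuffle neuron order within each type
#'
#' Applies an independent uniform permutation to the neurons of each type
#' (rows and columns together), destroying any informative ordering while
#' preserving type membership; returns the permutations so recovery can be
#' scored.
#'
#' @param cx A [connectome()].
#' @param seed Integer seed.
#' @return List with `cx` (shuffled) and `perms` (named list of within-type
#'   permutations; applying `lapply(perms, order)` with [sort_connectome()]
#'   undoes the shuffle).
#' @export
shuffle_within_types <- function(cx, seed = 1) {
  set.seed(seed)
  part <- type_partition(cx)
  perms <- lapply(part, function(idx) sample.int(length(idx)))
  list(cx = sort_connectome(cx, perms), perms = perms)
}
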