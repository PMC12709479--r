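# Geometry matching: fit a target geometry (circle, Clifford torus) to a set
# of embeddings by minimizing ||T - Pi Z P||_F^2 over permutations Pi and
# projections P, alternating an exact linear assignment step (Pi) with a
# closed-form least-squares step (P).

#' Circle target geometry
#'
#' `M` evenly spaced unit-norm points: row i is
#' `(cos(2*pi*i/M), sin(2*pi*i/M))`. The squared Frobenius norm of the target
#' equals `M`.
#'
#' @param M Number of points (>= 3).
#' @return Object of class `target_geometry` with fields `T`, `kind`,
#'   `shape`.
#' @export
circle_target <- function(M) {
  if (M < 3) stop("a circle target needs M >= 3 points")
  th <- 2 * pi * (seq_len(M) - 1) / M
  structure(list(T = cbind(cos(th), sin(th)), kind = "circle",
                 shape = M, angles = th),
            class = "target_geometry")
}

#' Clifford torus target geometry
#'
#' `m1 * m2` points in 4-D, row-major over the `(a, b)` grid:
#' `(cos(2*pi*a/m1), sin(2*pi*a/m1), cos(2*pi*b/m2), sin(2*pi*b/m2))`. Every
#' row has norm `sqrt(2)`, so the squared Frobenius norm is `2*m1*m2`.
#'
#' @param m1,m2 Grid side lengths (each >= 3).
#' @return Object of class `target_geometry`.
#' @export
torus_target <- function(m1, m2) {
  if (m1 < 3 || m2 < 3) stop("a torus target needs m1, m2 >= 3")
  a <- rep(seq_len(m1) - 1, each = m2)
  b <- rep(seq_len(m2) - 1, times = m1)
  t1 <- 2 * pi * a / m1
  t2 <- 2 * pi * b / m2
  structure(list(T = cbind(cos(t1), sin(t1), cos(t2), sin(t2)),
                 kind = "torus", shape = as.integer(c(m1, m2)),
                 angles = cbind(t1, t2)),
            class = "target_geometry")
}

# Torus target sized for M points: perfect square -> sqrt(M) x sqrt(M);
# otherwise the divisor pair closest to square; if M is prime, the first M
# row-major points of the ceiling(sqrt(M))^2 grid (with a warning).
torus_target_for <- function(M) {
  s <- round(sqrt(M))
  if (s * s == M && s >= 3) return(torus_target(s, s))
  divs <- which(M %% seq_len(floor(sqrt(M))) == 0)
  divs <- divs[divs >= 3 & (M / divs) >= 3]
  if (length(divs) > 0) {
    d <- max(divs)
    return(torus_target(d, M / d))
  }
  warning("no near-square factorization of M = ", M,
          "; matching to the first ", M, " points of a ",
          ceiling(sqrt(M)), "^2 torus grid")
  full <- torus_target(ceiling(sqrt(M)), ceiling(sqrt(M)))
  full$T <- full$T[seq_len(M), , drop = FALSE]
  full$angles <- full$angles[seq_len(M), , drop = FALSE]
  full$shape <- as.integer(c(ceiling(sqrt(M)), ceiling(sqrt(M)), M))
  full
}

ls_projection <- function(Zp, T) {
  # closed-form least-squares P minimizing ||T - Zp P||^2; pseudoinverse
  # handles rank deficiency
  MASS::ginv(Zp) %*% T
}

#' Match embeddings to a target geometry
#'
#' Minimizes `||T - Pi Z P||_F^2` by coordinate descent: the permutation step
#' is solved exactly as a linear assignment problem (squared-Euclidean cost,
#' Jonker-Volgenant solver), the projection step in closed form by least
#' squares. The loss is non-increasing within a restart; the best of
#' `n_restarts` random initializations is returned. When `fixed_P` is given
#' only the permutation is optimized (used, e.g., to transfer the projection
#' learned on one population to another sharing the same torus).
#'
#' @param Z `M x D` embedding matrix for the neurons of one type.
#' @param target A [circle_target()] or [torus_target()] with `M` rows.
#' @param n_restarts Number of random restarts (default 10).
#' @param seed Integer seed for restart initialization.
#' @param fixed_P Optional `D x K` projection to hold fixed.
#' @param max_iter Iteration cap per restart (default 200); each restart also
#'   stops as soon as the permutation is unchanged.
#' @return Object of class `geometry_match`: `perm` (for target row `a`,
#'   `perm[a]` is the matched embedding row), `P`, `loss`, `r2`
#'   (`1 - loss/||T||^2`), `angles` (per-neuron angles in `[0, 2*pi)`; one
#'   column per circle factor), `n_restarts`, `best_restart`, `target`.
#' @export
match_geometry <- function(Z, target, n_restarts = 10, seed = 1,
                           fixed_P = NULL, max_iter = 200) {
  Z <- as.matrix(Z)
  T <- target$T
  M <- nrow(T)
  if (nrow(Z) != M)
    stop("Z has ", nrow(Z), " rows but the target has ", M, " points")
  D <- ncol(Z)
  K <- ncol(T)
  if (D < K)
    warning("embedding dimension D = ", D, " is below the target dimension ",
            K, "; the projection cannot be full rank")
  Tnorm2 <- sum(T^2)

  best <- NULL
  if (!is.null(fixed_P)) {
    if (!all(dim(fixed_P) == c(D, K)))
      stop("fixed_P must be ", D, " x ", K)
    ZP <- Z %*% fixed_P
    perm <- lap_solve(cross_dist2(T, ZP))
    loss <- sum((T - ZP[perm, , drop = FALSE])^2)
    best <- list(perm = perm, P = fixed_P, loss = loss, restart = 1L)
  } else {
    # Restart 1 is deterministic: seed the permutation from the top
    # principal components of Z (the plane a near-circular / near-toroidal
    # embedding occupies), which routinely lands the coordinate descent in a
    # far better basin than a random permutation. Remaining restarts are
    # uniform-random. Both descend the same objective; the best loss wins.
    pca_perm <- NULL
    if (D >= 2 && M > 2) {
      pc <- stats::prcomp(Z, center = TRUE, scale. = FALSE)
      if (target$kind == "circle") {
        pca_perm <- order(atan2(pc$x[, 2], pc$x[, 1]))
      } else if (ncol(pc$x) >= K) {
        Zp <- pc$x[, seq_len(K), drop = FALSE]
        Zp <- Zp * sqrt(sum(T^2) / max(sum(Zp^2), 1e-12))
        pca_perm <- lap_solve(cross_dist2(T, Zp))
      }
    }
    set.seed(seed)
    for (r in seq_len(n_restarts)) {
      perm <- if (r == 1 && !is.null(pca_perm)) pca_perm else sample.int(M)
      loss_prev <- Inf
      for (it in seq_len(max_iter)) {
        P <- ls_projection(Z[perm, , drop = FALSE], T)
        ZP <- Z %*% P
        loss_p <- sum((T - ZP[perm, , drop = FALSE])^2)
        new_perm <- lap_solve(cross_dist2(T, ZP))
        loss <- sum((T - ZP[new_perm, , drop = FALSE])^2)
        if (loss > loss_p + 1e-9 * (1 + loss_p))
          stop("coordinate-descent loss increased; this should not happen")
        if (identical(new_perm, perm) || loss >= loss_prev - 1e-12) {
          perm <- new_perm
          break
        }
        perm <- new_perm
        loss_prev <- loss
      }
      P <- ls_projection(Z[perm, , drop = FALSE], T)
      loss <- sum((T - Z[perm, , drop = FALSE] %*% P)^2)
      if (is.null(best) || loss < best$loss)
        best <- list(perm = perm, P = P, loss = loss, restart = r)
    }
  }

  ang <- if (target$kind == "circle") {
    assign_angles(Z, best$P)
  } else {
    cbind(assign_angles(Z, best$P[, 1:2, drop = FALSE]),
          assign_angles(Z, best$P[, 3:4, drop = FALSE]))
  }
  structure(
    list(perm = best$perm, P = best$P, loss = best$loss,
         r2 = 1 - best$loss / Tnorm2, angles = ang,
         n_restarts = if (is.null(fixed_P)) n_restarts else 1L,
         best_restart = best$restart, target = target),
    class = "geometry_match")
}

#' @export
print.geometry_match <- function(x, ...) {
  cat("<geometry_match> kind=", x$target$kind, " M=", nrow(x$target$T),
      " loss=", format(x$loss), " r2=", format(x$r2), "\n", sep = "")
  invisible(x)
}

#' @export
#' @method tidy geometry_match
tidy.geometry_match <- function(x, ...) {
  ang <- x$angles
  if (is.null(dim(ang))) ang <- matrix(ang, ncol = 1)
  colnames(ang) <- paste0("theta_", seq_len(ncol(ang)))
  out <- tibble::as_tibble(ang)
  out$row <- seq_len(nrow(out))
  # rank of each embedding row along the target ordering
  rank <- integer(nrow(out))
  rank[x$perm] <- seq_along(x$perm)
  out$target_rank <- rank
  dplyr::relocate(out, "row")
}

#' @export
#' @method autoplot geometry_match
autoplot.geometry_match <- function(object, ...) {
  Z <- NULL
  proj <- tidy(object)
  df <- tibble::tibble(theta = proj$theta_1,
                       rank = proj$target_rank)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$theta)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "matched target rank", y = "assigned angle (rad)",
                  title = "Geometry match: assigned angles vs target order")
}

#' Circularity (or toroidal) coefficient
#'
#' `r2 = 1 - L(T, Z) / ||T||^2`, the fraction of target-geometry variance
#' explained after the optimal permutation and projection. Values near 1
#' indicate that the embeddings lie close to the target geometry; i.i.d.
#' Gaussian embeddings give intermediate values that define the null
#' distribution for significance testing.
#'
#' @param Z `M x D` embeddings of one type.
#' @param target Target geometry; defaults to the `M`-point circle.
#' @inheritParams match_geometry
#' @return Scalar `r2` with the full [match_geometry()] result attached as
#'   attribute `"match"`.
#' @export
circularity_coefficient <- function(Z, target = NULL, n_restarts = 10,
                                    seed = 1) {
  if (is.null(target)) target <- circle_target(nrow(Z))
  m <- match_geometry(Z, target, n_restarts = n_restarts, seed = seed)
  structure(m$r2, match = m)
}

#' Null distribution of the circularity coefficient
#'
#' Draws `n_null` sets of `M x D` i.i.d. standard-Gaussian embeddings and
#' computes each set's circularity coefficient; the null is summarized as a
#' 1-D Gaussian fitted to these values.
#'
#' @param M,D Embedding set shape.
#' @param n_null Number of null draws (default 100).
#' @param seed Integer seed.
#' @param n_restarts Restarts per match (default 10).
#' @param target Optional target geometry (default: `M`-point circle).
#' @return List with `values`, `mean`, `sd`, `M`, `D`.
#' @export
circularity_null <- function(M, D, n_null = 100, seed = 1, n_restarts = 10,
                             target = NULL) {
  if (n_null < 2) stop("n_null must be >= 2")
  if (is.null(target)) target <- circle_target(M)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max / 2, n_null)
  zs <- lapply(seq_len(n_null),
               function(k) matrix(rnorm(M * D), M, D))
  vals <- vapply(seq_len(n_null), function(k) {
    as.numeric(circularity_coefficient(zs[[k]], target = target,
                                       n_restarts = n_restarts,
                                       seed = seeds[k]))
  }, numeric(1))
  list(values = vals, mean = mean(vals), sd = sd(vals), M = M, D = D)
}

#' Significance of a circularity coefficient
#'
#' Fits a 1-D Gaussian to the null circularity coefficients of i.i.d.
#' Gaussian embeddings of the same shape and returns the upper-tail
#' probability `P(null >= r2_obs)` as the primary p-value (`p`); the
#' lower-tail value is surfaced as `p_lower` (the two tails are not
#' interchangeable; the upper tail asks whether the observed coefficient
#' beats unstructured embeddings).
#'
#' @param r2_obs Observed coefficient(s); vectorized.
#' @param M,D Embedding set shape (ignored when `null` is supplied).
#' @param n_null Number of null draws (default 100).
#' @param seed Integer seed for the null draws.
#' @param null Optional precomputed [circularity_null()].
#' @param n_restarts Restarts per null match.
#' @return Tibble with columns `r2_obs`, `p`, `p_lower`, `null_mean`,
#'   `null_sd`.
#' @export
circularity_pvalue <- function(r2_obs, M = NULL, D = NULL, n_null = 100,
                               seed = 1, null = NULL, n_restarts = 10) {
  if (is.null(null)) {
    if (is.null(M) || is.null(D)) stop("supply M and D (or a null object)")
    null <- circularity_null(M, D, n_null = n_null, seed = seed,
                             n_restarts = n_restarts)
  }
  tibble::tibble(
    r2_obs = as.numeric(r2_obs),
    p = pnorm(as.numeric(r2_obs), null$mean, null$sd, lower.tail = FALSE),
    p_lower = pnorm(as.numeric(r2_obs), null$mean, null$sd),
    null_mean = null$mean,
    null_sd = null$sd
  )
}

#' Assign per-neuron angles from a 2-column projection
#'
#' Projects each embedding onto the two columns of `P` and takes the
#' `atan2` angle, shifted to `[0, 2*pi)`. Neurons whose projection is
#' (numerically) zero get an undefined angle (`NA`), are placed last by
#' [angle_order()], and trigger a warning.
#'
#' @param Z `M x D` embeddings.
#' @param P `D x 2` projection matrix.
#' @return Numeric vector of angles in `[0, 2*pi)` (`NA` where undefined).
#' @export
assign_angles <- function(Z, P) {
  if (ncol(P) != 2) stop("P must have exactly 2 columns")
  proj <- as.matrix(Z) %*% P
  r <- sqrt(rowSums(proj^2))
  th <- atan2(proj[, 2], proj[, 1]) %% (2 * pi)
  zero <- r < 1e-12
  if (any(zero)) {
    warning(sum(zero), " neuron(s) project to zero; angle undefined")
    th[zero] <- NA_real_
  }
  th
}

#' Ordering by angle (undefined angles last)
#' @param theta Angles from [assign_angles()].
#' @return Integer permutation.
#' @export
angle_order <- function(theta) order(theta, na.last = TRUE)

#' Screen cell types for circular (or toroidal) embedding structure
#'
#' Computes, for every cell type with at least `min_size` neurons, the
#' circularity (or toroidal) coefficient of its embeddings and a Gaussian
#' null p-value, and ranks types by the coefficient. Null distributions are
#' computed once per distinct (M, D) shape and reused.
#'
#' @param fit An `embedding_fit`.
#' @param target_kind `"circle"` (default) or `"torus"`.
#' @param min_size Smallest type screened (default 10).
#' @param n_null Null draws per (M, D) shape.
#' @param n_restarts Restarts per match.
#' @param seed Integer seed.
#' @return Tibble `type`, `n_neurons`, `r2`, `p_value`, `p_lower`, sorted by
#'   decreasing `r2`.
#' @export
screen_types <- function(fit, target_kind = c("circle", "torus"),
                         min_size = 10, n_null = 100, n_restarts = 10,
                         seed = 1) {
  target_kind <- match.arg(target_kind)
  model <- fit$model
  sizes <- tabulate(model$types, nbins = model$ntype)
  keep <- which(sizes >= min_size)
  nulls <- list()
  rows <- lapply(keep, function(m) {
    idx <- which(model$types == m)
    M <- length(idx)
    target <- if (target_kind == "circle") circle_target(M)
              else torus_target_for(M)
    r2 <- as.numeric(circularity_coefficient(model$Z[idx, , drop = FALSE],
                                             target = target,
                                             n_restarts = n_restarts,
                                             seed = seed))
    key <- paste0(M, "_", model$D)
    if (is.null(nulls[[key]]))
      nulls[[key]] <<- circularity_null(M, model$D, n_null = n_null,
                                        seed = seed, n_restarts = n_restarts,
                                        target = target)
    pv <- circularity_pvalue(r2, null = nulls[[key]])
    tibble::tibble(type = model$type_names[m], n_neurons = M, r2 = r2,
                   p_value = pv$p, p_lower = pv$p_lower)
  })
  if (length(rows) == 0)
    return(tibble::tibble(type = character(), n_neurons = integer(),
                          r2 = numeric(), p_value = numeric(),
                          p_lower = numeric()))
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, dplyr::desc(.data$r2))
}

#' Sort a connectome by angles from a shared projection
#'
#' Computes every neuron's angle from a single shared `D x 2` projection of
#' the embeddings (so the sort is consistent across cell types, as required
#' when different types encode the same circular variable) and reorders each
#' type by angle.
#'
#' @param cx A [connectome()].
#' @param fit An `embedding_fit` on `cx`.
#' @param P `D x 2` projection (e.g. from the [match_geometry()] of one
#'   type).
#' @return List with `cx` (sorted connectome), `theta` (angles in the sorted
#'   order), `orderings` (per-type permutations applied).
#' @export
sort_by_shared_projection <- function(cx, fit, P) {
  theta <- assign_angles(fit$model$Z, P)
  part <- type_partition(cx)
  orderings <- lapply(part, function(idx) angle_order(theta[idx]))
  sorted <- sort_connectome(cx, orderings)
  perm <- seq_len(n_neurons(cx))
  for (nm in names(orderings)) {
    idx <- part[[nm]]
    perm[idx] <- idx[orderings[[nm]]]
  }
  list(cx = sorted, theta = theta[perm], orderings = orderings)
}
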