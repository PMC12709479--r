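# Phase-shift detection: quantify how much relative rotation the fitted
# unitary matrices apply between the embedding subspaces of two cell types,
# and estimate connectivity tuning curves along direct and multi-step paths.

check_unitary <- function(R, tol = 1e-6, arg = "R") {
  R <- as.matrix(R)
  if (nrow(R) != ncol(R)) stop(arg, " must be square")
  dev <- max(abs(crossprod(R) - diag(nrow(R))))
  if (dev > tol)
    stop(arg, " is not unitary (||R'R - I||_inf = ", format(dev), ")")
  R
}

# Principal matrix logarithm of a rotation (normal matrix with unit-modulus
# eigenvalues) via complex eigendecomposition. Rotation angles within 1e-6 of
# pi make the principal branch ill-conditioned; such inputs are flagged with
# a warning and attribute "flagged".
logm_rotation <- function(R) {
  e <- eigen(R)
  ang <- Arg(e$values)
  flagged <- any(abs(abs(ang) - pi) < 1e-6)
  if (flagged)
    warning("rotation angle within 1e-6 of pi; principal log is ill-conditioned")
  L <- Re(e$vectors %*% diag(log(e$values + 0i), nrow(R)) %*% solve(e$vectors))
  structure(L, flagged = flagged)
}

#' Rotation magnitude between two unitary matrices (degrees)
#'
#' `(180 / (2*pi)) * ||log R_mn + log R_nm||_F` with principal matrix
#' logarithms. The statistic is symmetric in its arguments and is 0 when both
#' rotations are the identity (or exact inverses of each other): it measures
#' the net rotation applied around the m -> n -> m loop, i.e. the magnitude
#' of `R_mn R_nm`.
#'
#' @param R_mn,R_nm `D x D` unitary matrices (checked to tolerance 1e-6).
#' @return Rotation magnitude in degrees; attribute `"flagged"` is `TRUE`
#'   when either principal log was ill-conditioned (angle at pi).
#' @export
rotation_magnitude <- function(R_mn, R_nm) {
  R_mn <- check_unitary(R_mn, arg = "R_mn")
  R_nm <- check_unitary(R_nm, arg = "R_nm")
  L1 <- logm_rotation(R_mn)
  L2 <- logm_rotation(R_nm)
  val <- (180 / (2 * pi)) * norm(L1 + L2, type = "F")
  structure(val,
            flagged = isTRUE(attr(L1, "flagged")) ||
              isTRUE(attr(L2, "flagged")))
}

#' Type-pair rotation report for a rotation-augmented fit
#'
#' Entry `(m, n)` is [rotation_magnitude()] of the fitted `R_mn` and `R_nm`;
#' the diagonal uses `R_mm` twice. Large entries indicate phase-shifted
#' connectivity between the two types.
#'
#' @param fit An `embedding_fit` trained with `rotations = TRUE`.
#' @return Object of class `rotation_report`: `stat` (named
#'   `N_type x N_type` matrix, degrees), `logs` (principal logs of each `R`),
#'   `R` (the materialized rotations).
#' @export
rotation_report <- function(fit) {
  model <- fit$model
  if (!isTRUE(model$rotations) || is.null(model$G))
    stop("model was fitted without rotations")
  nt <- if (model$type_aware) model$ntype else 1L
  R <- materialize_rotations(model)
  logs <- lapply(R, logm_rotation)
  stat <- matrix(0, nt, nt,
                 dimnames = if (model$type_aware)
                   list(model$type_names, model$type_names) else NULL)
  for (m in seq_len(nt)) {
    for (n in seq_len(nt)) {
      p_mn <- pair_lin(m, n, nt, length(R))
      p_nm <- pair_lin(n, m, nt, length(R))
      stat[m, n] <- (180 / (2 * pi)) *
        norm(logs[[p_mn]] + logs[[p_nm]], type = "F")
    }
  }
  structure(list(stat = stat, logs = logs, R = R), class = "rotation_report")
}

#' @export
print.rotation_report <- function(x, ...) {
  cat("<rotation_report> rotation magnitudes (degrees):\n")
  print(round(x$stat, 2))
  invisible(x)
}

#' @export
#' @method tidy rotation_report
tidy.rotation_report <- function(x, ...) {
  nt <- nrow(x$stat)
  nms <- rownames(x$stat) %||% as.character(seq_len(nt))
  tibble::tibble(
    source = rep(nms, times = nt),
    target = rep(nms, each = nt),
    rotation_deg = as.numeric(x$stat)
  )
}

#' Write a rotation report as a square CSV matrix with type-name headers
#' @param x A `rotation_report`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_rotation_report <- function(x, path) {
  utils::write.csv(as.data.frame(x$stat), path, row.names = TRUE)
  invisible(path)
}

#' Effective weights along a multi-step path
#'
#' Multiplies the type-to-type adjacency blocks in order; e.g. the
#' EPG -> PEN -> EPG effective weight is `W_ep %*% W_pe`. A single block is
#' returned unchanged.
#'
#' @param blocks List of weight submatrices with compatible inner dimensions.
#' @return The matrix product.
#' @export
effective_weight <- function(blocks) {
  if (length(blocks) == 0) stop("need at least one block")
  for (k in seq_len(length(blocks) - 1)) {
    if (ncol(blocks[[k]]) != nrow(blocks[[k + 1]]))
      stop("block ", k, " has ", ncol(blocks[[k]]),
           " columns but block ", k + 1, " has ", nrow(blocks[[k + 1]]),
           " rows")
  }
  Reduce(`%*%`, blocks)
}

#' Connectivity tuning curve over angular offset
#'
#' For every ordered pair (i, j), i != j, accumulates `W_eff[i, j]` into the
#' bin of the wrapped offset `theta_j - theta_i` and reports the per-bin mean
#' weight. Bin centers lie on the regular grid `k * 2*pi/n_bins` wrapped to
#' `[-pi, pi)`, so offsets that are exact multiples of the bin width map to a
#' bin center exactly. A symmetric (no phase shift) profile peaks at 0; a
#' phase-shifted projection peaks at its offset.
#'
#' @param W_eff `M x M` (effective) weight matrix among neurons with angles.
#' @param theta Length-M angles in `[0, 2*pi)` (recovered by geometry
#'   matching in pipeline use; ground truth accepted for testing).
#' @param n_bins Number of bins; default `min(M, 32)`.
#' @return Object of class `tuning_curve`: a tibble with `bin`, `offset`
#'   (bin center, radians in `[-pi, pi)`), `mean_weight` (`NA` for empty
#'   bins) and `n_pairs`; attribute `"peak_offset"` is the center of the
#'   maximal bin.
#' @export
tuning_curve <- function(W_eff, theta, n_bins = NULL) {
  M <- length(theta)
  if (!all(dim(W_eff) == c(M, M)))
    stop("W_eff must be ", M, " x ", M)
  if (any(theta < 0 | theta >= 2 * pi))
    stop("angles must lie in [0, 2*pi)")
  if (is.null(n_bins)) n_bins <- min(M, 32L)
  w <- 2 * pi / n_bins
  ii <- rep(seq_len(M), times = M)
  jj <- rep(seq_len(M), each = M)
  keep <- ii != jj
  dth <- wrap_angle(theta[jj[keep]] - theta[ii[keep]])
  val <- as.numeric(W_eff)[keep]
  k <- (round(dth / w)) %% n_bins  # 0 .. n_bins-1, centers at k*w
  centers <- wrap_angle(seq_len(n_bins) * w - w)  # for k = 0..n_bins-1
  cnt <- tabulate(k + 1L, nbins = n_bins)
  sums <- vapply(seq_len(n_bins) - 1L,
                 function(b) sum(val[k == b]), numeric(1))
  means <- ifelse(cnt > 0, sums / cnt, NA_real_)
  tb <- tibble::tibble(bin = seq_len(n_bins), offset = centers,
                       mean_weight = means, n_pairs = cnt)
  tb <- dplyr::arrange(tb, .data$offset)
  peak <- tb$offset[which.max(tb$mean_weight)]
  structure(tb, peak_offset = peak, class = c("tuning_curve", class(tb)))
}

#' @export
#' @method autoplot tuning_curve
autoplot.tuning_curve <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset, y = .data$mean_weight)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = attr(object, "peak_offset"),
                        linetype = "dashed") +
    ggplot2::labs(x = "angular offset (rad)", y = "mean effective weight",
                  title = "Connectivity tuning curve")
}
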