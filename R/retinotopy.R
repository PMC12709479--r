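# Retinotopy: do the embeddings of a visual projection neuron type encode its
# 2-D receptive-field coordinates, and how strongly is each type-to-type
# projection organized by them?

#' Estimate putative receptive fields from synapse locations
#'
#' For each neuron, pools its synapses flagged as lying in the source region
#' (e.g. the optic lobe) and takes their centroid; the centroids of all
#' usable neurons are then projected onto their top-2 principal-component
#' plane. By convention the longer (first) axis is labeled D-V and the second
#' A-P. Neurons without flagged synapses are excluded and counted.
#'
#' @param synapses Data frame with columns `neuron_id`, `x`, `y`, `z`,
#'   `in_region` (0/1 or logical).
#' @return Object of class `rf_map`: `coords` (tibble `neuron_id`, `dv`,
#'   `ap`), `centroids`, `basis` (3 x 2), `var_fraction` (variance captured
#'   by the plane), `excluded` (neuron ids without flagged synapses).
#' @export
receptive_field_map <- function(synapses) {
  synapses <- as.data.frame(synapses)
  need <- c("neuron_id", "x", "y", "z", "in_region")
  if (!all(need %in% names(synapses)))
    stop("synapse table needs columns ", paste(need, collapse = ", "))
  flagged <- synapses[as.logical(synapses$in_region), , drop = FALSE]
  all_ids <- unique(as.character(synapses$neuron_id))
  cen <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(flagged),
                    neuron_id = as.character(.data$neuron_id)),
    x = mean(.data$x), y = mean(.data$y), z = mean(.data$z),
    .groups = "drop")
  excluded <- setdiff(all_ids, cen$neuron_id)
  if (nrow(cen) < 3)
    stop("need at least 3 neurons with in-region synapses (found ",
         nrow(cen), ")")
  X <- as.matrix(cen[, c("x", "y", "z")])
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  var_fraction <- sum(pc$sdev[1:2]^2) / sum(pc$sdev^2)
  coords <- tibble::tibble(neuron_id = cen$neuron_id,
                           dv = pc$x[, 1], ap = pc$x[, 2])
  structure(list(coords = coords, centroids = cen,
                 basis = pc$rotation[, 1:2, drop = FALSE],
                 var_fraction = var_fraction, excluded = excluded),
            class = "rf_map")
}

#' @export
print.rf_map <- function(x, ...) {
  cat("<rf_map> ", nrow(x$coords), " neurons mapped, ",
      length(x$excluded), " excluded; plane captures ",
      round(100 * x$var_fraction, 1), "% of centroid variance\n", sep = "")
  invisible(x)
}

#' @export
#' @method tidy rf_map
tidy.rf_map <- function(x, ...) x$coords

#' Linear decodability of a coordinate from embeddings
#'
#' Ordinary least squares of the coordinate on the embedding columns plus an
#' intercept; returns the coefficient of determination of the fit. With
#' `M <= D + 1` the fit is saturated and flagged unreliable (attribute
#' `"unreliable"`), but still computed.
#'
#' @param Z `M x D` embeddings.
#' @param coords Length-M coordinate (e.g. the D-V or A-P receptive-field
#'   coordinate).
#' @return Scalar `r2`.
#' @export
coordinate_decoding_r2 <- function(Z, coords) {
  Z <- as.matrix(Z)
  if (length(coords) != nrow(Z)) stop("coords must match rows of Z")
  if (sd(coords) == 0) {
    warning("constant coordinates; r2 defined as 0")
    return(0)
  }
  fit <- lm(coords ~ Z)
  r2 <- summary(fit)$r.squared
  if (nrow(Z) <= ncol(Z) + 1) attr(r2, "unreliable") <- TRUE
  r2
}

#' Directional retinotopy profile
#'
#' Projects the 2-D receptive-field coordinates onto the direction
#' `(cos(phi), sin(phi))` for each angle and computes
#' [coordinate_decoding_r2()]. Directions are unsigned, so the profile has
#' period 180 degrees; the minimum over directions is the statistic used for
#' the full-field retinotopy inclusion rule (threshold 0.5).
#'
#' @param Z `M x D` embeddings.
#' @param coords2d `M x 2` receptive-field coordinates (D-V, A-P).
#' @param angles Direction angles in degrees, in `[0, 180)`; default every 5
#'   degrees.
#' @return Tibble `angle_deg`, `r2`; attribute `"min_r2"` is the profile
#'   minimum.
#' @export
directional_retinotopy <- function(Z, coords2d, angles = seq(0, 175, by = 5)) {
  coords2d <- as.matrix(coords2d)
  if (ncol(coords2d) != 2) stop("coords2d must have 2 columns")
  if (any(angles < 0 | angles >= 180))
    stop("angles must lie in [0, 180) degrees")
  r2 <- vapply(angles, function(phi) {
    u <- c(cos(phi * pi / 180), sin(phi * pi / 180))
    as.numeric(coordinate_decoding_r2(Z, as.numeric(coords2d %*% u)))
  }, numeric(1))
  out <- tibble::tibble(angle_deg = angles, r2 = r2)
  attr(out, "min_r2") <- min(r2)
  out
}

#' Goodness-of-fit of the model for one projection block
#'
#' The coefficient of determination `1 - SS_res/SS_tot` between the observed
#' block `W^{m->n}` and the model prediction, with `SS_tot` taken around the
#' block mean. Can be negative (model worse than the block mean); a constant
#' observed block makes it undefined (`NA`). The raw ratio `SS_res/SS_tot`
#' is attached as attribute `"ss_ratio"`.
#'
#' @param W_block Observed `N_m x N_n` submatrix.
#' @param What_block Model-predicted submatrix of the same shape.
#' @return Scalar `r2` (or `NA`).
#' @export
projection_r2 <- function(W_block, What_block) {
  W_block <- as.matrix(W_block)
  What_block <- as.matrix(What_block)
  if (!all(dim(W_block) == dim(What_block)))
    stop("blocks must have identical shapes")
  ss_res <- sum((W_block - What_block)^2)
  ss_tot <- sum((W_block - mean(W_block))^2)
  if (ss_tot == 0) {
    warning("constant observed block; projection r2 undefined")
    return(structure(NA_real_, ss_ratio = NA_real_))
  }
  structure(1 - ss_res / ss_tot, ss_ratio = ss_res / ss_tot)
}

#' Rank type-to-type projections by model goodness-of-fit
#'
#' Scores every (source, target) projection by [projection_r2()] between the
#' observed block and the fitted model's predicted block. Projections with
#' mean weight below `min_mean` (fewer than one synapse per pair of neurons,
#' by default) are flagged excluded for lack of statistical power; the
#' exclusion depends only on the observed block. Included projections are
#' sorted by decreasing `r2`.
#'
#' @param fit An `embedding_fit`.
#' @param sources,targets Type names (defaults: all types).
#' @param min_mean Minimum mean block weight for inclusion (default 1).
#' @return Tibble `source`, `target`, `mean_weight`, `r2`, `ss_ratio`,
#'   `included`; included rows first, each group sorted by decreasing `r2`.
#' @export
rank_projections <- function(fit, sources = NULL, targets = NULL,
                             min_mean = 1) {
  model <- fit$model
  W <- fit$W
  What <- predict_mean(model)
  nms <- model$type_names
  sources <- sources %||% nms
  targets <- targets %||% nms
  rows <- list()
  for (s in sources) {
    m <- match(s, nms)
    if (is.na(m)) stop("unknown source type '", s, "'")
    im <- which(model$types == m)
    for (t in targets) {
      n <- match(t, nms)
      if (is.na(n)) stop("unknown target type '", t, "'")
      jn <- which(model$types == n)
      Wb <- W[im, jn, drop = FALSE]
      Hb <- What[im, jn, drop = FALSE]
      if (s == t) {
        # exclude the diagonal, as in every likelihood sum
        off <- !diag(length(im)) > 0
        wvec <- Wb[off]; hvec <- Hb[off]
        mw <- mean(wvec)
        ss_res <- sum((wvec - hvec)^2)
        ss_tot <- sum((wvec - mean(wvec))^2)
      } else {
        mw <- mean(Wb)
        ss_res <- sum((Wb - Hb)^2)
        ss_tot <- sum((Wb - mean(Wb))^2)
      }
      r2 <- if (ss_tot == 0) NA_real_ else 1 - ss_res / ss_tot
      rows[[length(rows) + 1]] <- tibble::tibble(
        source = s, target = t, mean_weight = mw, r2 = r2,
        ss_ratio = if (ss_tot == 0) NA_real_ else ss_res / ss_tot,
        included = mw >= min_mean)
    }
  }
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, dplyr::desc(.data$included), dplyr::desc(.data$r2))
}
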