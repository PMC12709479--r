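# Connectome container: weighted directed adjacency plus per-neuron cell types.
#
# Convention: W[i, j] is the synapse count (or continuous strength) FROM
# neuron i TO neuron j. Diagonal entries are stored but excluded from every
# likelihood sum in the package.

#' Construct a connectome
#'
#' Bundles an N x N nonnegative weight matrix with per-neuron cell-type
#' labels and optional metadata. `W[i, j]` is the connection from neuron `i`
#' to neuron `j` (synapse count for the Poisson likelihood, or a continuous
#' strength for the Gaussian one).
#'
#' @param W Square numeric matrix with nonnegative entries.
#' @param types Cell-type label per neuron: a character/factor vector, or an
#'   integer vector indexing `type_names`.
#' @param type_names Optional character vector of unique type names; derived
#'   from `types` when those are character or factor.
#' @param meta Optional data frame of per-neuron annotations (e.g. a
#'   `hemisphere` column with values "L"/"R", or `x`,`y`,`z` synapse
#'   centroids); one row per neuron.
#' @param neuron_ids Optional character vector of neuron identifiers.
#' @return An object of class `connectome` with fields `W`, `types`
#'   (integer), `type_names`, `meta`, `neuron_ids`.
#' @export
connectome <- function(W, types, type_names = NULL, meta = NULL,
                       neuron_ids = NULL) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop("W must be square")
  n <- nrow(W)
  if (anyNA(W) || any(W < 0)) stop("W entries must be nonnegative and finite")
  if (length(types) != n) stop("need one type label per neuron")

  if (is.factor(types) || is.character(types)) {
    types <- as.character(types)
    if (is.null(type_names)) type_names <- unique(types)
    ci <- match(types, type_names)
    if (anyNA(ci)) stop("type label not found in type_names")
  } else {
    ci <- as.integer(types)
    if (is.null(type_names)) type_names <- paste0("type", seq_len(max(ci)))
  }
  if (anyDuplicated(type_names)) stop("type_names must be unique")
  if (any(ci < 1L) || any(ci > length(type_names)))
    stop("type index out of range")
  if (!is.null(meta)) {
    meta <- as.data.frame(meta)
    if (nrow(meta) != n) stop("meta must have one row per neuron")
  }
  if (is.null(neuron_ids)) neuron_ids <- as.character(seq_len(n) - 1L)
  neuron_ids <- as.character(neuron_ids)
  if (length(neuron_ids) != n) stop("need one neuron_id per neuron")

  structure(
    list(W = W, types = ci, type_names = as.character(type_names),
         meta = meta, neuron_ids = neuron_ids),
    class = "connectome"
  )
}

#' @export
print.connectome <- function(x, ...) {
  cat("<connectome> ", n_neurons(x), " neurons, ",
      length(x$type_names), " types, ",
      sum(x$W != 0), " nonzero edges, total weight ",
      format(sum(x$W)), "\n", sep = "")
  sz <- type_sizes(x)
  cat("  types:", paste0(names(sz), " (", sz, ")", collapse = ", "), "\n")
  invisible(x)
}

#' Number of neurons in a connectome
#' @param cx A `connectome`.
#' @return Integer neuron count.
#' @export
n_neurons <- function(cx) nrow(cx$W)

#' Per-type neuron counts
#' @param cx A `connectome`.
#' @return Named integer vector of type sizes (all types, including empty).
#' @export
type_sizes <- function(cx) {
  sz <- tabulate(cx$types, nbins = length(cx$type_names))
  setNames(sz, cx$type_names)
}

#' Per-type neuron index lists
#'
#' Disjoint index lists covering all neurons, one per cell type.
#'
#' @param cx A `connectome`.
#' @return Named list of integer vectors of neuron indices.
#' @export
type_partition <- function(cx) {
  out <- lapply(seq_along(cx$type_names), function(m) which(cx$types == m))
  setNames(out, cx$type_names)
}

#' Neuron metadata as a tibble
#' @param cx A `connectome`.
#' @return Tibble with `neuron_id`, `type` and any metadata columns.
#' @export
neuron_table <- function(cx) {
  tb <- tibble::tibble(neuron_id = cx$neuron_ids,
                       type = cx$type_names[cx$types])
  if (!is.null(cx$meta)) tb <- dplyr::bind_cols(tb, tibble::as_tibble(cx$meta))
  tb
}

# ---- I/O ----

#' Read a connectome from an edge file plus a neuron metadata table
#'
#' `edges` is either a Matrix Market coordinate file (`.mtx`, standard
#' 1-based indices) or a 3-column TSV edge list with header `from`, `to`,
#' `weight` where `from`/`to` are 0-based row indices into the neuron table.
#' Duplicate edges are summed (synapse-count semantics). Neurons absent from
#' the edge list get all-zero rows and columns.
#'
#' `neurons` is a TSV with a header containing at least `neuron_id` and
#' `type`; optional columns (`hemisphere`, `x`, `y`, `z`, ...) become
#' metadata.
#'
#' @param edges Path to the edge file.
#' @param neurons Path to the neuron table TSV.
#' @return A [connectome()].
#' @export
read_connectome <- function(edges, neurons) {
  nt <- tryCatch(read.delim(neurons, sep = "\t", stringsAsFactors = FALSE,
                            check.names = FALSE),
                 error = function(e) stop("failed to parse neuron table '",
                                          neurons, "': ", conditionMessage(e)))
  if (!all(c("neuron_id", "type") %in% names(nt)))
    stop("neuron table must have 'neuron_id' and 'type' columns")
  n <- nrow(nt)

  if (grepl("\\.mtx$", edges, ignore.case = TRUE)) {
    M <- tryCatch(Matrix::readMM(edges),
                  error = function(e) stop("failed to parse Matrix Market file '",
                                           edges, "': ", conditionMessage(e)))
    if (nrow(M) > n || ncol(M) > n)
      stop("edge index out of range: matrix is ", nrow(M), "x", ncol(M),
           " but neuron table has ", n, " rows")
    W <- matrix(0, n, n)
    M <- methods::as(M, "TsparseMatrix")
    if (length(M@x) > 0) {
      if (any(M@x < 0)) stop("negative weight in edge file")
      # duplicate (i, j) triplets sum
      ij <- cbind(M@i + 1L, M@j + 1L)
      for (k in seq_along(M@x)) W[ij[k, 1], ij[k, 2]] <- W[ij[k, 1], ij[k, 2]] + M@x[k]
    }
  } else {
    el <- tryCatch(read.delim(edges, sep = "\t", stringsAsFactors = FALSE),
                   error = function(e) stop("failed to parse edge list '",
                                            edges, "': ", conditionMessage(e)))
    if (ncol(el) < 3) stop("edge list needs columns from, to, weight")
    from <- as.integer(el[[1]]) + 1L  # 0-based on disk
    to <- as.integer(el[[2]]) + 1L
    w <- as.numeric(el[[3]])
    bad <- which(is.na(from) | is.na(to) | from < 1L | from > n |
                   to < 1L | to > n)
    if (length(bad) > 0)
      stop("edge index out of range at edge-list line ", bad[1] + 1L)
    if (anyNA(w) || any(w < 0))
      stop("negative or missing weight in edge list")
    W <- matrix(0, n, n)
    for (k in seq_along(w)) W[from[k], to[k]] <- W[from[k], to[k]] + w[k]
  }

  extra <- setdiff(names(nt), c("neuron_id", "type"))
  meta <- if (length(extra) > 0) nt[extra] else NULL
  connectome(W, types = as.character(nt$type), meta = meta,
             neuron_ids = as.character(nt$neuron_id))
}

#' Write a connectome to disk
#'
#' Writes the adjacency as a Matrix Market coordinate file (1-based) or a
#' 0-based TSV edge list (chosen by the `edges` extension), the neuron table
#' as TSV, and a sidecar JSON provenance record (`<edges>.prov.json`) naming
#' the inputs, seed and package version.
#'
#' @param cx A [connectome()].
#' @param edges Output path for the adjacency (`.mtx` or `.tsv`).
#' @param neurons Output path for the neuron table TSV.
#' @param seed Optional seed recorded in the provenance sidecar.
#' @return Invisibly, the edge path.
#' @export
write_connectome <- function(cx, edges, neurons, seed = NULL) {
  nt <- neuron_table(cx)
  write.table(nt, neurons, sep = "\t", quote = FALSE, row.names = FALSE)
  if (grepl("\\.mtx$", edges, ignore.case = TRUE)) {
    Matrix::writeMM(methods::as(Matrix::Matrix(cx$W, sparse = TRUE),
                                "generalMatrix"), edges)
  } else {
    idx <- which(cx$W != 0, arr.ind = TRUE)
    el <- data.frame(from = idx[, 1] - 1L, to = idx[, 2] - 1L,
                     weight = cx$W[idx])
    el <- el[order(el$from, el$to), , drop = FALSE]
    write.table(el, edges, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_provenance(paste0(edges, ".prov.json"),
                   inputs = list(edges = edges, neurons = neurons),
                   seed = seed)
  invisible(edges)
}

write_provenance <- function(path, inputs, seed = NULL, extra = NULL) {
  rec <- list(
    package = "ctembed",
    version = as.character(utils::packageVersion("ctembed")),
    inputs = inputs,
    seed = seed
  )
  if (!is.null(extra)) rec <- c(rec, extra)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}

# ---- views and transforms ----

#' Drop cell types with too few neurons
#'
#' Restricts the connectome to neurons whose type has at least `min_size`
#' members; low-dimensional structure is hard to discern with too few points
#' per type. Type labels are re-indexed densely, preserving the original
#' order of the retained types.
#'
#' @param cx A [connectome()].
#' @param min_size Minimum type size to keep (default 10).
#' @return A filtered [connectome()].
#' @export
filter_types <- function(cx, min_size = 10) {
  if (min_size < 1) stop("min_size must be >= 1")
  sz <- type_sizes(cx)
  keep_types <- which(sz >= min_size)
  if (length(keep_types) == 0)
    stop("all cell types have fewer than ", min_size, " neurons")
  keep <- cx$types %in% keep_types
  new_types <- match(cx$types[keep], keep_types)
  connectome(cx$W[keep, keep, drop = FALSE],
             types = new_types,
             type_names = cx$type_names[keep_types],
             meta = if (is.null(cx$meta)) NULL else cx$meta[keep, , drop = FALSE],
             neuron_ids = cx$neuron_ids[keep])
}

#' Split every cell type by hemisphere
#'
#' Each original type `m` becomes up to two types `m_L` and `m_R` according
#' to the per-neuron side labels; the adjacency is unchanged. Phase shifts
#' often differ between the two sides of the brain, so splitting lets the
#' rotation-augmented model fit them separately.
#'
#' @param cx A [connectome()].
#' @param side Length-N character vector with values "L"/"R"; defaults to
#'   `cx$meta$hemisphere`.
#' @return A [connectome()] with per-hemisphere types.
#' @export
split_by_hemisphere <- function(cx, side = NULL) {
  if (is.null(side)) side <- cx$meta$hemisphere
  if (is.null(side) || length(side) != n_neurons(cx) || anyNA(side))
    stop("need a non-missing L/R side label for every neuron")
  side <- as.character(side)
  if (!all(side %in% c("L", "R"))) stop("side labels must be 'L' or 'R'")
  lab <- paste0(cx$type_names[cx$types], "_", side)
  # order new types by original type then L before R
  cand <- as.vector(t(outer(cx$type_names, c("L", "R"), paste, sep = "_")))
  new_names <- cand[cand %in% unique(lab)]
  connectome(cx$W, types = lab, type_names = new_names, meta = cx$meta,
             neuron_ids = cx$neuron_ids)
}

#' Extract the type-to-type block of the adjacency
#'
#' Rows are the source-type neurons, columns the target-type neurons, in
#' stored order: `W^{m->n}`.
#'
#' @param cx A [connectome()].
#' @param from,to Type name or index.
#' @return `N_m x N_n` numeric matrix.
#' @export
type_block <- function(cx, from, to) {
  m <- resolve_type(cx, from)
  n <- resolve_type(cx, to)
  cx$W[cx$types == m, cx$types == n, drop = FALSE]
}

resolve_type <- function(cx, t) {
  if (is.character(t)) {
    m <- match(t, cx$type_names)
    if (is.na(m)) stop("unknown cell type '", t, "'")
    m
  } else {
    t <- as.integer(t)
    if (t < 1L || t > length(cx$type_names)) stop("unknown cell type ", t)
    t
  }
}

#' Reorder neurons within each type
#'
#' Applies a within-type permutation to rows and columns simultaneously, so
#' the weight multiset is preserved; used to sort the adjacency by recovered
#' angles and reveal banded (circulant-like) structure.
#'
#' @param cx A [connectome()].
#' @param orderings Named list (by type name) of permutations; each element
#'   is a permutation of `1..N_m` giving the new within-type order. Types not
#'   named keep their order.
#' @return A reordered [connectome()].
#' @export
sort_connectome <- function(cx, orderings) {
  part <- type_partition(cx)
  perm <- seq_len(n_neurons(cx))
  for (nm in names(orderings)) {
    idx <- part[[nm]]
    if (is.null(idx)) stop("unknown cell type '", nm, "'")
    ord <- orderings[[nm]]
    if (length(ord) != length(idx) || !setequal(ord, seq_along(idx)))
      stop("ordering for type '", nm, "' is not a permutation of 1..",
           length(idx))
    perm[idx] <- idx[ord]
  }
  connectome(cx$W[perm, perm, drop = FALSE],
             types = cx$types[perm],
             type_names = cx$type_names,
             meta = if (is.null(cx$meta)) NULL else cx$meta[perm, , drop = FALSE],
             neuron_ids = cx$neuron_ids[perm])
}
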