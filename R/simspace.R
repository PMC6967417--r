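# Similarity analyses of embedding spaces: cosine nearest neighbors and
# low-dimensional projections colored by physicochemical properties.

#' Cosine distance between two vectors
#'
#' `1 - cos(u, v)`, in [0, 2]; 0 for parallel, 1 for orthogonal, 2 for
#' anti-parallel vectors. Scale-invariant for positive rescalings of either
#' argument.
#'
#' @param u,v nonzero numeric vectors of equal length.
#' @return a single number in [0, 2].
#' @export
cosineDistance <- function(u, v) {
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine distance undefined for zero vectors")
  1 - sum(u * v) / (nu * nv)
}

#' Top-k cosine nearest neighbors of a record
#'
#' Exact brute-force search over a feature block: returns the `k` records
#' closest to the query in cosine distance, ascending, ties broken by id;
#' the query itself is excluded.
#'
#' @param block a [FeatureBlock-class].
#' @param queryId id of the query record (must be in the block).
#' @param k number of neighbors (default 10; must be < number of records).
#' @return data.frame `rank`, `id`, `cosine_distance`.
#' @export
topKNeighbors <- function(block, queryId, k = 10L) {
  ids <- block@ids
  qi <- match(queryId, ids)
  if (is.na(qi)) stop("unknown query id: ", queryId)
  if (k >= length(ids)) stop("k must be smaller than the number of records")
  q <- block@mat[qi, ]
  d <- vapply(seq_along(ids), function(i)
    if (i == qi) Inf else cosineDistance(q, block@mat[i, ]), numeric(1))
  ord <- order(d, ids, method = "radix")
  take <- ord[seq_len(k)]
  data.frame(rank = seq_len(k), id = ids[take], cosine_distance = d[take])
}

#' Project a feature block to 2-D or 3-D with t-SNE
#'
#' Exact t-distributed stochastic neighbor embedding (see [tsne()]) of the
#' block's rows. The perplexity is capped at `(n - 1) / 3` for small inputs;
#' the projection is deterministic given the seed.
#'
#' @param block a [FeatureBlock-class].
#' @param outDim 2 (default) or 3.
#' @param seed RNG seed for the initialization.
#' @param perplexity target perplexity (default 30, capped for small n).
#' @param maxIter gradient-descent iterations (default 500).
#' @return a [ProjectedCloud-class].
#' @export
projectEmbedding <- function(block, outDim = 2L, seed = 1L, perplexity = 30,
                             maxIter = 500L) {
  stopifnot(outDim %in% c(2L, 3L))
  n <- nrow(block@mat)
  perplexity <- min(perplexity, (n - 1) / 3)
  if (n <= 3 * perplexity && n < 10)
    stop("too few points to project")
  coords <- tsne(block@mat, outDim = outDim, perplexity = perplexity,
                 seed = seed, maxIter = maxIter)
  new("ProjectedCloud", ids = block@ids, coords = coords, color = numeric())
}

#' Attach a min-max-normalized color scalar to a projection
#'
#' Values are normalized to [0, 1] by the min-max rule; a constant input maps
#' every point to 0.5. Normalization is invariant to affine transforms of the
#' values (with positive slope).
#'
#' @param cloud a [ProjectedCloud-class].
#' @param values one numeric value per point (e.g. a property from
#'   [propertyProfile()]).
#' @return the cloud with its `color` slot filled.
#' @export
colorByProperty <- function(cloud, values) {
  if (length(values) != length(cloud@ids))
    stop(sprintf("need one value per point: %d values for %d points",
                 length(values), length(cloud@ids)))
  rng <- range(values)
  color <- if (rng[1] == rng[2]) rep(0.5, length(values)) else
    (values - rng[1]) / (rng[2] - rng[1])
  initialize(cloud, color = color)
}
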