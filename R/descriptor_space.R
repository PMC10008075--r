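# Even-dispersion descriptor subset selection in an embedding space.

#' Read descriptor embedding vectors from CSV
#'
#' Expects a header `descriptor_id,e1,...,eD`. Vectors are unit-normalized
#' on load (cosine geometry); zero vectors and ragged or non-numeric rows
#' are rejected.
#'
#' @param path CSV path.
#' @param normalize unit-normalize rows (default TRUE).
#' @return numeric matrix with descriptor ids as rownames.
#' @export
read_embeddings <- function(path, normalize = TRUE) {
  df <- read_table_csv(path)
  if (!"descriptor_id" %in% names(df) || ncol(df) < 2) {
    abort_validation("embeddings file needs descriptor_id plus vector columns",
                     file = path)
  }
  ids <- as.character(df$descriptor_id)
  if (anyDuplicated(ids)) {
    abort_validation("duplicate descriptor_id in embeddings", file = path,
                     row = which(duplicated(ids))[1L])
  }
  vec_cols <- setdiff(names(df), "descriptor_id")
  m <- matrix(NA_real_, nrow(df), length(vec_cols),
              dimnames = list(ids, vec_cols))
  for (j in seq_along(vec_cols)) {
    m[, j] <- validate_numeric_column(df[[vec_cols[j]]], vec_cols[j],
                                      c(-Inf, Inf), file = path)
  }
  if (anyNA(m)) {
    abort_validation("missing value in embedding vector", file = path,
                     row = which(rowSums(is.na(m)) > 0)[1L])
  }
  if (normalize) {
    nrm <- sqrt(rowSums(m^2))
    if (any(nrm == 0)) {
      abort_validation("zero embedding vector", file = path,
                       row = which(nrm == 0)[1L])
    }
    m <- m / nrm
  }
  m
}

#' Greedy maximin (farthest-point) descriptor selection
#'
#' Selects `k` descriptors that are evenly dispersed across the embedding
#' space: the first two are the pair at maximum distance; each further
#' descriptor maximizes its minimum distance to the already-selected set.
#' This is the classical 2-approximation to the k-center dispersion optimum.
#' Ties are broken by input order, making the selection deterministic.
#'
#' @param embeddings numeric matrix with descriptor ids as rownames (e.g.
#'   from [read_embeddings()]), or a data frame with a `descriptor_id`
#'   column.
#' @param k subset size, `1 <= k <= n`.
#' @param distance `"cosine"` (default; vectors are unit-normalized first)
#'   or `"euclidean"`.
#' @param seed accepted for interface stability; the procedure is
#'   deterministic and the seed is unused.
#' @return character vector of `k` selected descriptor ids, in selection
#'   order.
#' @export
select_dispersed <- function(embeddings, k,
                             distance = c("cosine", "euclidean"),
                             seed = NULL) {
  distance <- match.arg(distance)
  if (is.data.frame(embeddings)) {
    ids <- as.character(embeddings$descriptor_id)
    m <- as.matrix(embeddings[setdiff(names(embeddings), "descriptor_id")])
    rownames(m) <- ids
    embeddings <- m
  }
  stopifnot(is.matrix(embeddings), is.numeric(embeddings))
  n <- nrow(embeddings)
  ids <- rownames(embeddings) %||% as.character(seq_len(n))
  k <- as.integer(k)
  if (k < 1 || k > n) {
    stop(sprintf("k must be in [1, %d], got %d", n, k), call. = FALSE)
  }

  if (distance == "cosine") {
    nrm <- sqrt(rowSums(embeddings^2))
    if (any(nrm == 0)) stop("zero embedding vector", call. = FALSE)
    x <- embeddings / nrm
    d <- 1 - tcrossprod(x)
  } else {
    sq <- rowSums(embeddings^2)
    d <- sqrt(pmax(outer(sq, sq, `+`) - 2 * tcrossprod(embeddings), 0))
  }
  diag(d) <- 0

  # seed pair: maximum distance, first such pair in row-major input order
  best <- which(d == max(d), arr.ind = TRUE)
  best <- best[best[, 1] < best[, 2], , drop = FALSE]
  if (nrow(best) == 0) best <- matrix(c(1L, 2L), 1)  # all points coincide
  first <- best[order(best[, 1], best[, 2])[1L], ]
  sel <- if (k == 1L) first[1L] else c(first[1L], first[2L])

  while (length(sel) < k) {
    min_d <- apply(d[, sel, drop = FALSE], 1, min)
    min_d[sel] <- -Inf
    sel <- c(sel, which.max(min_d))  # which.max breaks ties by input order
  }
  ids[sel]
}
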