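# Vector-space comparison of transcriptomic population signatures.
# Each population is a point in gene-attribute space (one coordinate per
# gene, value = differential-expression level); similarity is measured by
# Euclidean distance and by the absolute cosine of the angle between the
# vectors, and populations are ordered by average-linkage clustering on the
# distance matrix.

# coerce a profiles table (gene column + one numeric column per population)
# or a genes x populations matrix into a named numeric matrix
.as_profile_matrix <- function(profiles) {
  if (is.matrix(profiles)) {
    if (is.null(rownames(profiles)) || is.null(colnames(profiles))) {
      abort("A profile matrix needs gene rownames and population colnames.")
    }
    m <- profiles
  } else if (is.data.frame(profiles)) {
    gene_col <- if ("gene" %in% names(profiles)) "gene" else names(profiles)[1]
    genes <- as.character(profiles[[gene_col]])
    m <- as.matrix(profiles[setdiff(names(profiles), gene_col)])
    rownames(m) <- genes
  } else {
    abort("`profiles` must be a data frame (gene column + populations) or a matrix.")
  }
  if (anyDuplicated(rownames(m))) abort("Duplicate gene identifiers.")
  if (anyDuplicated(colnames(m))) abort("Duplicate population labels.")
  if (ncol(m) < 2) abort("At least 2 populations are required.")
  storage.mode(m) <- "double"
  m
}

#' Restrict profiles to the genes shared by all populations
#'
#' Keeps the genes with a finite value in every population (intersection
#' matching); the number of dropped genes is reported as an attribute and
#' a message. Intersection is preferred to zero-filling because imputed
#' zeros bias the cosine correlation toward zero.
#'
#' @param profiles Tibble with a `gene` column and one numeric column per
#'   population, or a genes x populations matrix.
#' @return Tibble of the same shape restricted to shared genes, with
#'   attribute `n_dropped`.
#' @export
align_genes <- function(profiles) {
  m <- .as_profile_matrix(profiles)
  keep <- rowSums(!is.finite(m)) == 0
  if (!any(keep)) abort("No gene has finite values in all populations.")
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    inform(sprintf("align_genes: dropped %d gene(s) missing in at least one population.",
                   n_dropped))
  }
  out <- dplyr::bind_cols(tibble(gene = rownames(m)[keep]),
                          as_tibble(m[keep, , drop = FALSE]))
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Euclidean distance between two attribute vectors
#'
#' \eqn{d_{i,j} = \sqrt{\sum_k (v_k^i - v_k^j)^2}}; the smaller the
#' distance, the more similar the populations.
#'
#' @param v,w Numeric vectors of equal length (>= 1).
#' @return Non-negative distance.
#' @examples
#' euclidean_distance(c(0, 0), c(3, 4))  # 5
#' @export
euclidean_distance <- function(v, w) {
  if (length(v) != length(w) || length(v) < 1) {
    abort("`v` and `w` must have the same positive length.")
  }
  sqrt(sum((v - w)^2))
}

#' Absolute-cosine correlation between two attribute vectors
#'
#' \eqn{C_{i,j} = |\cos\theta| = |v \cdot w| / (\lVert v\rVert \lVert w\rVert)}
#' in `[0, 1]`: 0 means the vectors are perpendicular in attribute space
#' (independent populations), 1 means they are linearly dependent
#' (equivalent populations). The absolute value makes sign-flipped
#' signatures equivalent.
#'
#' @inheritParams euclidean_distance
#' @examples
#' cosine_correlation(c(1, 2, 2), c(2, 1, 2))  # 8/9
#' @export
cosine_correlation <- function(v, w) {
  if (length(v) != length(w) || length(v) < 1) {
    abort("`v` and `w` must have the same positive length.")
  }
  nv <- sqrt(sum(v^2)); nw <- sqrt(sum(w^2))
  if (nv < 1e-300 || nw < 1e-300) {
    abort("Cosine correlation is undefined for a zero vector.")
  }
  min(1, abs(sum(v * w)) / (nv * nw))
}

#' Pairwise similarity of population signatures
#'
#' Computes all pairwise Euclidean distances and absolute-cosine
#' correlations between population attribute vectors, and orders the
#' populations by agglomerative clustering on the distance matrix
#' (average linkage by default). Populations whose vector is entirely zero
#' are excluded with a warning. Gene alignment ([align_genes()]) is applied
#' first.
#'
#' @inheritParams align_genes
#' @param standardize If `TRUE`, z-score each population vector across
#'   genes before comparison (off by default).
#' @param linkage Agglomeration method passed to [stats::hclust()]
#'   (default `"average"`).
#' @return A `similarity_result`: list with `labels`, `distance` and
#'   `correlation` (symmetric matrices), `n_genes_used`, `cluster_order`
#'   (labels permuted by the dendrogram), `hclust`, `dropped_populations`.
#'   Has [tidy()], [glance()] and [autoplot()] methods.
#' @export
similarity_matrix <- function(profiles, standardize = FALSE,
                              linkage = "average") {
  aligned <- align_genes(profiles)
  m <- .as_profile_matrix(aligned)
  if (standardize) m <- scale(m)
  norms <- sqrt(colSums(m^2))
  dropped <- colnames(m)[norms < 1e-300]
  if (length(dropped)) {
    warn(sprintf("Excluding zero-vector population(s): %s",
                 paste(dropped, collapse = ", ")))
    m <- m[, norms >= 1e-300, drop = FALSE]
  }
  if (ncol(m) < 2) abort("Fewer than 2 usable populations after exclusions.")
  labels <- colnames(m)
  p <- ncol(m)
  D <- matrix(0, p, p, dimnames = list(labels, labels))
  C <- diag(1, p); dimnames(C) <- list(labels, labels)
  for (i in seq_len(p - 1)) {
    for (j in seq(i + 1, p)) {
      D[i, j] <- D[j, i] <- euclidean_distance(m[, i], m[, j])
      C[i, j] <- C[j, i] <- cosine_correlation(m[, i], m[, j])
    }
  }
  hc <- hclust(as.dist(D), method = linkage)
  structure(
    list(labels = labels, distance = D, correlation = C,
         n_genes_used = nrow(m), cluster_order = labels[hc$order],
         hclust = hc, dropped_populations = dropped,
         n_genes_dropped = attr(aligned, "n_dropped")),
    class = "similarity_result"
  )
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf("Signature similarity over %d populations, %d shared genes\n",
              length(x$labels), x$n_genes_used))
  cat("  cluster order:", paste(x$cluster_order, collapse = " | "), "\n")
  cat("  correlation matrix (|cos theta|):\n")
  print(round(x$correlation, 3))
  invisible(x)
}

#' @export
tidy.similarity_result <- function(x, ...) {
  p <- length(x$labels)
  idx <- which(upper.tri(x$distance), arr.ind = TRUE)
  tibble(pop1 = x$labels[idx[, 1]], pop2 = x$labels[idx[, 2]],
         distance = x$distance[idx],
         correlation = x$correlation[idx])
}

#' @export
glance.similarity_result <- function(x, ...) {
  off <- x$correlation[upper.tri(x$correlation)]
  tibble(n_populations = length(x$labels), n_genes_used = x$n_genes_used,
         n_genes_dropped = x$n_genes_dropped %||% 0L,
         mean_correlation = mean(off), max_correlation = max(off),
         min_distance = min(x$distance[upper.tri(x$distance)]))
}
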