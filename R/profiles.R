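## Reactivity-profile similarity: sample- and allergen-level profile
## matrices, principal component analysis and clustered-heatmap ordering.

#' Sample-by-peptide profile matrix
#'
#' Restricts the log2 layer to a peptide subset, observations in rows.
#' Samples missing any subset peptide are flagged in attribute
#' `incomplete_samples`.
#'
#' @param rmat a [reactivity_matrix()].
#' @param peptides character vector of unique peptide sequences; `NULL`
#'   (default) keeps all peptides of the matrix.
#' @return Numeric matrix (samples x peptides) of log2 intensities.
#' @export
sample_profile_matrix <- function(rmat, peptides = NULL) {
  stopifnot(inherits(rmat, "reactivity_matrix"))
  if (is.null(peptides)) peptides <- rmat$peptides
  if (length(peptides) == 0L) stop("empty peptide subset")
  unknown <- setdiff(peptides, rmat$peptides)
  if (length(unknown) > 0L)
    stop("peptides absent from the matrix: ",
         paste(utils::head(unknown, 3L), collapse = ", "),
         if (length(unknown) > 3L) " ...")
  m <- rmat$log2[, peptides, drop = FALSE]
  incomplete <- rownames(m)[rowSums(is.na(m)) > 0L]
  attr(m, "incomplete_samples") <- incomplete
  m
}

#' Allergen-by-(sample, aligned start) profile matrix
#'
#' Compares reactivity profiles across allergens: for each allergen the
#' feature vector holds, per sample and aligned tile start in
#' `aligned_range`, the log2 signal of the allergen's tile starting at that
#' alignment column. Cells where an allergen carries no tile at a start
#' (gap) are missing, and features (sample x start columns) with any
#' missing value are dropped so every allergen is compared on the same
#' basis.
#'
#' @param rmat a [reactivity_matrix()].
#' @param index the matching [build_peptide_index()]; occurrences must
#'   carry aligned starts.
#' @param aligned_range length-2 integer vector of aligned tile-start
#'   bounds, default `c(9, 95)`.
#' @param alignment optional [master_alignment] used only to validate the
#'   range.
#' @return Numeric matrix (allergens x features); feature names are
#'   `"<sample_id>|<aligned_start>"`. Attribute `dropped_features` counts
#'   columns removed for missingness.
#' @export
allergen_profile_matrix <- function(rmat, index, aligned_range = c(9L, 95L),
                                    alignment = NULL) {
  stopifnot(inherits(rmat, "reactivity_matrix"),
            inherits(index, "peptide_index"))
  aligned_range <- as.integer(aligned_range)
  stopifnot(length(aligned_range) == 2L, aligned_range[1] <= aligned_range[2])
  if (!is.null(alignment) && aligned_range[2] > alignment$column_count)
    stop("aligned_range extends beyond the alignment (",
         alignment$column_count, " columns)")
  occ <- index$occurrences[!is.na(index$occurrences$start_aligned), ]
  occ <- occ[occ$start_aligned >= aligned_range[1] &
               occ$start_aligned <= aligned_range[2], ]
  if (nrow(occ) == 0L) stop("no tiles with aligned starts in the range")
  allergens <- sort(unique(occ$allergen_id))
  starts <- seq.int(aligned_range[1], aligned_range[2])
  samples <- rownames(rmat$log2)
  feat <- as.data.table(expand.grid(sample_id = samples,
                                    start_aligned = starts,
                                    stringsAsFactors = FALSE))
  m <- matrix(NA_real_, length(allergens), nrow(feat),
              dimnames = list(allergens,
                              paste(feat$sample_id, feat$start_aligned,
                                    sep = "|")))
  for (a in allergens) {
    oa <- occ[occ$allergen_id == a, ]
    hit <- match(feat$start_aligned, oa$start_aligned)
    pep <- oa$sequence[hit]
    vals <- rmat$log2[cbind(match(feat$sample_id, samples),
                            match(pep, colnames(rmat$log2)))]
    m[a, ] <- vals
  }
  keep <- colSums(is.na(m)) == 0L
  dropped <- sum(!keep)
  m <- m[, keep, drop = FALSE]
  attr(m, "dropped_features") <- dropped
  m
}

#' Principal component analysis of a profile matrix
#'
#' Column-centres the matrix and factors it by singular value
#' decomposition. Scores are the projections of the observations, loadings
#' the right singular vectors, and explained variance fractions come from
#' the squared singular values. The sign of each component is fixed so that
#' its largest-magnitude loading is positive, making results deterministic.
#'
#' @param x numeric matrix, observations in rows (at least 2 rows and 2
#'   columns).
#' @return Object of class `profile_pca`: list with `scores`
#'   (observations x components), `loadings` (features x components),
#'   `explained_variance` (fractions, non-increasing), `center`.
#' @export
profile_pca <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("need at least 2 observations and 2 features")
  if (anyNA(x)) stop("profile matrix contains missing values")
  ctr <- colMeans(x)
  xc <- sweep(x, 2L, ctr)
  if (sum(xc^2) == 0)
    stop("constant matrix: zero variance, PCA undefined")
  sv <- svd(xc)
  ncomp <- sum(sv$d > sv$d[1] * 1e-12)
  d <- sv$d[seq_len(ncomp)]
  u <- sv$u[, seq_len(ncomp), drop = FALSE]
  v <- sv$v[, seq_len(ncomp), drop = FALSE]
  ## sign convention: largest-|loading| entry of each component positive
  for (j in seq_len(ncomp)) {
    piv <- which.max(abs(v[, j]))
    if (v[piv, j] < 0) { v[, j] <- -v[, j]; u[, j] <- -u[, j] }
  }
  scores <- u %*% diag(d, ncomp)
  dimnames(scores) <- list(rownames(x), paste0("PC", seq_len(ncomp)))
  dimnames(v) <- list(colnames(x), paste0("PC", seq_len(ncomp)))
  structure(list(scores = scores, loadings = v,
                 explained_variance = d^2 / sum(sv$d^2), center = ctr),
            class = "profile_pca")
}

#' @export
print.profile_pca <- function(x, ...) {
  ev <- round(100 * x$explained_variance[seq_len(min(3, length(x$explained_variance)))], 1)
  cat(sprintf("profile_pca: %d observations, %d components (top: %s%%)\n",
              nrow(x$scores), ncol(x$scores), paste(ev, collapse = ", ")))
  invisible(x)
}

#' Heatmap ordering by per-sample hierarchical clustering
#'
#' Clusters samples (rows) by agglomerative hierarchical clustering and
#' records the resulting leaf order; columns (peptides) are deliberately
#' left in their linear tiling order, never clustered, so per-position
#' structure stays readable. Defaults match the pheatmap conventions:
#' Euclidean distance, complete linkage.
#'
#' @param x numeric matrix, samples in rows, peptides in tiling order in
#'   columns.
#' @param distance distance measure passed to [stats::dist()] (default
#'   `"euclidean"`).
#' @param linkage agglomeration method passed to [stats::hclust()]
#'   (default `"complete"`).
#' @return Object of class `heatmap_spec`: list with `row_order`
#'   (sample names, dendrogram leaf order), `col_order` (unchanged column
#'   names), `values` (the input matrix), `tree` (the `hclust` object),
#'   `distance`, `linkage`.
#' @export
cluster_order <- function(x, distance = "euclidean", linkage = "complete") {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 samples to cluster")
  d <- dist(x, method = distance)
  tree <- hclust(d, method = linkage)
  structure(list(row_order = rownames(x)[tree$order],
                 col_order = colnames(x),
                 values = x, tree = tree,
                 distance = distance, linkage = linkage),
            class = "heatmap_spec")
}

#' @export
print.heatmap_spec <- function(x, ...) {
  cat(sprintf("heatmap_spec: %d samples (%s/%s), %d columns in tiling order\n",
              length(x$row_order), x$distance, x$linkage,
              length(x$col_order)))
  invisible(x)
}
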