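#' Paired-sample trans feature block
#'
#' Concatenates the two samples' expression over a fixed, ordered RBP gene
#' list: \code{[expr_a over rbp_list, expr_b over rbp_list]}.  Genes missing
#' from a sample contribute 0 with a warning.  With the full 1499-RBP
#' registry the block has length 2998.
#'
#' @param expr_a,expr_b named numeric vectors of per-gene expression
#'   (TPM-like) for samples A and B.
#' @param rbp_list ordered character vector of RBP gene symbols, fixed at
#'   model-build time.
#' @return named numeric vector of length \code{2 * length(rbp_list)} with
#'   names \code{<gene>_a}, \code{<gene>_b}.
#' @export
transBlock <- function(expr_a, expr_b, rbp_list) {
  if (!length(rbp_list)) stop("empty rbp_list")
  pick <- function(e, tag) {
    v <- e[rbp_list]
    miss <- is.na(v)
    if (any(miss)) {
      warning(sum(miss), " RBP gene(s) missing from sample ", tag,
              "; set to 0")
      v[miss] <- 0
    }
    stats::setNames(as.numeric(v), paste0(rbp_list, "_", tag))
  }
  c(pick(expr_a, "a"), pick(expr_b, "b"))
}

#' Assemble the model input rows for one sample comparison
#'
#' Binds every event's cis feature vector to the pair's trans block
#' \code{[trans(sample_a), trans(sample_b)]}.
#'
#' @param cis_mat numeric matrix, events x cis features (already
#'   normalized).
#' @param trans_mat numeric matrix, samples x trans features (per-sample
#'   half blocks, already normalized), rownames = sample ids.
#' @param sample_a,sample_b sample ids (rows of \code{trans_mat}).
#' @return matrix, events x (cis + 2 * trans) features.
#' @export
pairFeatures <- function(cis_mat, trans_mat, sample_a, sample_b) {
  cis_mat <- as.matrix(cis_mat)
  ta <- trans_mat[sample_a, ]; tb <- trans_mat[sample_b, ]
  n <- nrow(cis_mat)
  out <- cbind(cis_mat,
               matrix(ta, n, length(ta), byrow = TRUE),
               matrix(tb, n, length(tb), byrow = TRUE))
  colnames(out) <- c(colnames(cis_mat),
                     paste0(colnames(trans_mat), "_a"),
                     paste0(colnames(trans_mat), "_b"))
  rownames(out) <- rownames(cis_mat)
  out
}

#' Fit a max-abs normalizer on a training feature table
#'
#' Stores the per-column maximum absolute value of the training table.
#' Columns with maximum 0 are flagged constant and map to 0.
#'
#' @param x numeric matrix (rows = training instances) with column names.
#' @return a \code{\link{MaxAbsNormalizer-class}} object.
#' @export
fitMaxAbsNormalizer <- function(x) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) stop("feature table must have column names")
  mx <- apply(abs(x), 2L, max)
  new("MaxAbsNormalizer", max_abs = mx,
      constant = stats::setNames(mx == 0, names(mx)))
}

#' Apply a max-abs normalizer
#'
#' Divides each feature by its stored training maximum; values exceeding 1
#' in magnitude after scaling (possible only on data unseen at fit time) are
#' clipped back to +/-1 when \code{clip = TRUE}.  Constant features map
#' to 0.
#'
#' @param norm a \code{MaxAbsNormalizer}.
#' @param x named numeric vector or matrix whose (column) names match the
#'   normalizer.
#' @param clip clip scaled magnitudes above 1 (default TRUE).
#' @return normalized vector/matrix of the same shape.
#' @export
applyNormalizer <- function(norm, x, clip = TRUE) {
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, 1L, dimnames = list(NULL, names(x))) else as.matrix(x)
  if (!identical(colnames(m), names(norm@max_abs)))
    stop("feature names do not match the normalizer")
  sc <- norm@max_abs
  sc[norm@constant] <- 1          # constant columns: anything/1 * 0 below
  out <- sweep(m, 2L, sc, "/")
  out[, norm@constant] <- 0
  if (clip) out <- pmin(pmax(out, -1), 1)
  if (vec) out[1L, ] else out
}
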