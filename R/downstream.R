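#' @importFrom stats phyper pnorm coef predict
NULL

#' circRNA index from a unit-vs-panel prediction triple
#'
#' \code{index = (1 - p_unchanged) * (p_region - p_panel)}, where the three
#' probabilities come from comparing the circRNA's junction ratio in one
#' region/spot against the whole panel.  Lies in [-1, 1]; exchanging the
#' region and panel probabilities flips the sign exactly.
#'
#' @param p numeric vector \code{(p_unchanged, p_region, p_panel)} or a
#'   matrix with those three columns (rows must sum to 1 within 1e-6).
#' @return numeric index value(s).
#' @export
circIndex <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, 1L)
  if (ncol(p) != 3L) stop("need three probabilities per row")
  if (any(abs(rowSums(p) - 1) > 1e-6))
    stop("probability triples must sum to 1")
  as.numeric((1 - p[, 1L]) * (p[, 2L] - p[, 3L]))
}

#' Tissue-specificity tau of a circRNA
#'
#' \code{tau = sum(1 - x_i) / (N - 1)} over junction ratios normalised by
#' their maximum; 1 = expressed in a single tissue, 0 = uniform.
#'
#' @param ratios numeric vector of junction ratios over N >= 2 tissues, or
#'   a matrix (rows = circRNAs).
#' @return tau value(s) in [0,1]; \code{NA} (with a warning) when all
#'   ratios are zero.
#' @export
tauSpecificity <- function(ratios) {
  if (!is.null(dim(ratios)))
    return(apply(ratios, 1L, tauSpecificity))
  n <- length(ratios)
  if (n < 2L) stop("tau needs at least two tissues")
  mx <- max(ratios)
  if (mx <= 0) {
    warning("all ratios zero; tau undefined")
    return(NA_real_)
  }
  sum(1 - ratios / mx) / (n - 1)
}

#' Consistent regulation calls across sample pairs
#'
#' Per pair, an event is labeled up when the probability attached to the
#' case sample exceeds \code{p_thr} and down when the control-side
#' probability does.  Per event, the call is consistently up (down) when
#' the corresponding fraction of pairs strictly exceeds \code{frac_thr};
#' when both fractions qualify the larger wins (ties give none).
#'
#' @param p_case,p_control numeric matrices (events x pairs) of the
#'   higher-in-case and higher-in-control probabilities.
#' @param p_thr per-pair probability threshold (default 0.35).
#' @param frac_thr fraction-of-pairs threshold (default 0.35, strict).
#' @return data.frame: frac_up, frac_down, call (up/down/none).
#' @export
consistentRegulation <- function(p_case, p_control, p_thr = 0.35,
                                 frac_thr = 0.35) {
  p_case <- as.matrix(p_case); p_control <- as.matrix(p_control)
  if (!identical(dim(p_case), dim(p_control)))
    stop("p_case and p_control must have identical dimensions")
  if (ncol(p_case) == 0L) stop("zero sample pairs")
  frac_up <- rowMeans(p_case > p_thr)
  frac_down <- rowMeans(p_control > p_thr)
  call <- rep("none", nrow(p_case))
  call[frac_up > frac_thr & frac_up > frac_down] <- "up"
  call[frac_down > frac_thr & frac_down > frac_up] <- "down"
  data.frame(frac_up = frac_up, frac_down = frac_down, call = call,
             row.names = rownames(p_case), stringsAsFactors = FALSE)
}

#' Enrichment of a predicted set in a reference set
#'
#' One-sided Fisher's exact test (hypergeometric upper tail) on the 2x2
#' membership table over the universe, plus the sample odds ratio
#' (0.5 continuity correction, flagged, when any cell is zero).
#'
#' @param predicted,reference character vectors, subsets of
#'   \code{universe}.
#' @param universe character vector of all testable items.
#' @return list: \code{table} (a, b, c, d), \code{odds_ratio},
#'   \code{or_corrected} (logical), \code{p_value}.
#' @export
enrichmentTest <- function(predicted, reference, universe) {
  if (!length(universe)) stop("empty universe")
  predicted <- unique(predicted); reference <- unique(reference)
  if (!all(predicted %in% universe) || !all(reference %in% universe))
    stop("predicted and reference must be subsets of the universe")
  a <- length(intersect(predicted, reference))
  b <- length(setdiff(predicted, reference))
  cc <- length(setdiff(reference, predicted))
  d <- length(universe) - a - b - cc
  if (!length(predicted)) {
    return(list(table = c(a = a, b = b, c = cc, d = d),
                odds_ratio = NA_real_, or_corrected = FALSE, p_value = 1))
  }
  corrected <- any(c(a, b, cc, d) == 0L)
  orv <- if (corrected) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
  else (a * d) / (b * cc)
  p <- phyper(a - 1L, length(reference),
              length(universe) - length(reference), length(predicted),
              lower.tail = FALSE)
  list(table = c(a = a, b = b, c = cc, d = d), odds_ratio = orv,
       or_corrected = corrected, p_value = p)
}

#' One-sided Wilcoxon rank-sum test with an exact small-sample path
#'
#' Tests whether values in \code{x} are stochastically greater than in
#' \code{y}.  For pooled n <= \code{exact_max} the p-value is the exact
#' permutation tail of the midrank sum (valid under ties, computed by
#' dynamic programming over the midrank multiset); larger samples use the
#' normal approximation with tie correction and continuity correction.
#'
#' @param x,y numeric samples.
#' @param exact_max largest pooled size for the exact path (default 25).
#' @return list: \code{statistic} (rank sum of \code{x}), \code{p_value},
#'   \code{exact} (logical).
#' @export
wilcoxRankSum <- function(x, y, exact_max = 25L) {
  nx <- length(x); ny <- length(y); n <- nx + ny
  if (nx == 0L || ny == 0L) stop("both samples must be non-empty")
  r <- rank(c(x, y))
  rx <- sum(r[seq_len(nx)])
  if (n <= exact_max) {
    r2 <- as.integer(round(2 * r))          # midranks doubled -> integers
    smax <- sum(sort(r2, decreasing = TRUE)[seq_len(nx)])
    # dp[j+1, s+1] = number of size-j subsets of the midrank multiset
    # with doubled-rank sum s
    dp <- matrix(0, nx + 1L, smax + 1L)
    dp[1L, 1L] <- 1
    for (v in r2) {
      jmax <- nx
      for (j in jmax:1) {
        nz <- which(dp[j, ] > 0)
        nz <- nz[nz + v <= smax + 1L]
        if (length(nz)) dp[j + 1L, nz + v] <- dp[j + 1L, nz + v] + dp[j, nz]
      }
    }
    counts <- dp[nx + 1L, ]
    obs <- as.integer(round(2 * rx))
    p <- sum(counts[(obs + 1L):(smax + 1L)]) / choose(n, nx)
    list(statistic = rx, p_value = p, exact = TRUE)
  } else {
    mu <- nx * (n + 1) / 2
    ties <- table(r)
    sig2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (rx - mu - 0.5) / sqrt(sig2)
    list(statistic = rx, p_value = pnorm(z, lower.tail = FALSE),
         exact = FALSE)
  }
}

#' Cell-type marker criteria for one circRNA
#'
#' A cell type hosts the circRNA as a marker when all three hold:
#' strictly more than \code{min_cells} cells of the type express it
#' (BSJ > 0); the mean junction ratio over expressing cells of the type
#' exceeds \code{min_ratio}; and a one-sided Wilcoxon rank-sum test of the
#' type's expressing-cell ratios against all other expressing cells gives
#' p < \code{alpha} (raw, no multiple-testing correction).
#'
#' @param type character/factor of cell types, one per cell.
#' @param bsj,fsj per-cell junction counts for the circRNA.
#' @param min_cells strict expressing-cell threshold (default 5).
#' @param min_ratio mean junction-ratio threshold (default 0.05).
#' @param alpha Wilcoxon significance level (default 0.05).
#' @param c junction-ratio convention (default 2).
#' @return data.frame per cell type: n_expressing, mean_ratio, p_wilcox,
#'   marker.  \code{NULL} (with a warning) when no cell expresses the
#'   circRNA.
#' @export
markerCriteria <- function(type, bsj, fsj, min_cells = 5L,
                           min_ratio = 0.05, alpha = 0.05, c = 2) {
  expressing <- bsj > 0
  if (!any(expressing)) {
    warning("circRNA not expressed in any cell; no call")
    return(NULL)
  }
  ratio <- junctionRatio(bsj, fsj, c = c)
  types <- unique(as.character(type))
  out <- do.call(rbind, lapply(types, function(tt) {
    inx <- expressing & type == tt
    outx <- expressing & type != tt
    n_ex <- sum(inx)
    mr <- if (n_ex) mean(ratio[inx]) else NA_real_
    pw <- if (n_ex && sum(outx))
      wilcoxRankSum(ratio[inx], ratio[outx])$p_value else NA_real_
    data.frame(cell_type = tt, n_expressing = n_ex, mean_ratio = mr,
               p_wilcox = pw,
               marker = isTRUE(n_ex > min_cells) && isTRUE(mr > min_ratio) &&
                 isTRUE(pw < alpha),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Accuracy of cell-type specificity predictions
#'
#' \code{(TP + TN) / N} over cell types: TP = truth types predicted
#' specific (probability of higher junction ratio in the type >
#' \code{p_thr}), TN = non-truth types predicted non-specific.
#'
#' @param prob_higher named numeric vector: per cell type, the predicted
#'   probability of a higher junction ratio in that type.
#' @param truth_types character vector of truly specific cell types.
#' @param p_thr decision threshold (default 0.35).
#' @return accuracy in [0,1].
#' @export
markerAccuracy <- function(prob_higher, truth_types, p_thr = 0.35) {
  n <- length(prob_higher)
  if (n == 0L) stop("no cell types")
  pred <- prob_higher > p_thr
  truth <- names(prob_higher) %in% truth_types
  (sum(pred & truth) + sum(!pred & !truth)) / n
}

#' Sparse-regression cell-type proportions
#'
#' One LASSO model per cell type, fitted on spot-level probability features
#' by coordinate descent over a logarithmic lambda grid with internal
#' 10-fold cross-validation (\code{glmnet::cv.glmnet}); the lambda
#' minimising the mean CV error is used.  Fitted proportions are returned
#' as fitted (unclipped).
#'
#' @param x numeric matrix, spots x features (e.g. higher-in-spot /
#'   higher-in-panel probabilities of the selected circRNAs).
#' @param y numeric matrix (spots x cell types) or vector of target
#'   proportions in [0,1].
#' @param folds CV folds (default 10; must not exceed the number of
#'   spots).
#' @param seed seed controlling the CV fold assignment.
#' @return named list per cell type: \code{coef} (named, incl. intercept),
#'   \code{lambda}, \code{fitted}, \code{support} (features with non-zero
#'   coefficients).
#' @export
lassoProportions <- function(x, y, folds = 10L, seed = 1L) {
  x <- as.matrix(x)
  if (is.null(dim(y))) y <- matrix(y, ncol = 1L,
                                   dimnames = list(NULL, "target"))
  y <- as.matrix(y)
  if (folds > nrow(x)) stop("folds exceed the number of spots")
  if (any(y < 0 | y > 1, na.rm = TRUE))
    stop("target proportions must be in [0,1]")
  set.seed(seed)
  out <- list()
  for (tt in colnames(y)) {
    yy <- y[, tt]
    if (all(apply(x, 2L, function(col) length(unique(col)) == 1L))) {
      # degenerate design: intercept-only model
      cf <- stats::setNames(c(mean(yy), numeric(ncol(x))),
                            c("(Intercept)", colnames(x)))
      out[[tt]] <- list(coef = cf, lambda = Inf,
                        fitted = rep(mean(yy), nrow(x)),
                        support = character())
      next
    }
    foldid <- sample(rep_len(seq_len(folds), nrow(x)))
    cv <- glmnet::cv.glmnet(x, yy, foldid = foldid)
    cf <- as.matrix(coef(cv, s = "lambda.min"))[, 1L]
    out[[tt]] <- list(coef = cf, lambda = cv$lambda.min,
                      fitted = as.numeric(predict(cv, x, s = "lambda.min")),
                      support = setdiff(names(cf)[cf != 0], "(Intercept)"))
  }
  out
}

#' Select specific, mutually uncorrelated circRNAs
#'
#' Orders candidates by specificity tau (descending, above
#' \code{tau_thr}) and greedily keeps a candidate when the absolute
#' Pearson correlation of its prediction-probability profile with every
#' already-kept candidate stays below \code{r_max}.
#'
#' @param tau named numeric vector of tau values per circRNA.
#' @param probs numeric matrix, units (spots/regions) x circRNAs, of
#'   prediction probabilities (columns named as \code{tau}).
#' @param tau_thr specificity threshold (default 0.75, strict).
#' @param r_max correlation cutoff (default 0.5).
#' @param k optional cap on the number selected.
#' @return character vector of selected circRNA ids.
#' @export
selectSpecificCircs <- function(tau, probs, tau_thr = 0.75, r_max = 0.5,
                                k = Inf) {
  cand <- names(sort(tau[tau > tau_thr], decreasing = TRUE))
  kept <- character()
  for (id in cand) {
    if (length(kept) >= k) break
    if (!length(kept)) { kept <- id; next }
    rr <- abs(stats::cor(probs[, id], probs[, kept, drop = FALSE]))
    if (all(rr < r_max)) kept <- c(kept, id)
  }
  kept
}
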