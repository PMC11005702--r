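#' @importFrom stats median
NULL

# differential score used for AUROC-based interpretation
.diffScore <- function(model, x) {
  p <- predictModel(model, x)
  if (model@config$head == "binary") p else 1 - p[, "unchanged"]
}

#' Group permutation importance as AUROC loss
#'
#' For each feature group, the group's columns are jointly permuted across
#' the evaluation instances (trans groups: across samples; cis groups:
#' across circRNAs -- both amount to shuffling the rows of the column block
#' in an instance-level evaluation matrix), predictions recomputed, and the
#' relative AUROC loss reported:
#' \code{(AUROC - AUROC_i) / AUROC * 100}.
#'
#' @param model a \code{DenseCircModel}.
#' @param x evaluation feature matrix.
#' @param labels positive/negative (or logical) evaluation labels.
#' @param groups named list of column indices or column names; every group
#'   must be non-empty.
#' @param seed RNG seed for the permutations.
#' @param n_perm number of permutations to average per group (default 1).
#' @return data.frame: group, auroc_base, auroc_perm, loss_pct.
#' @export
permutationImportance <- function(model, x, labels, groups, seed = 1L,
                                  n_perm = 1L) {
  x <- as.matrix(x)
  if (!length(groups) || is.null(names(groups)))
    stop("groups must be a non-empty named list")
  labels <- if (is.logical(labels)) labels else
    as.character(labels) %in% c("positive", "higher_in_A", "higher_in_B",
                                "1", "TRUE")
  base <- aurocScore(.diffScore(model, x), labels)
  set.seed(seed)
  out <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    if (is.character(idx)) idx <- match(idx, colnames(x))
    if (!length(idx) || anyNA(idx) || any(idx < 1 | idx > ncol(x)))
      stop("empty or out-of-range feature group: ", g)
    auc_i <- mean(vapply(seq_len(n_perm), function(k) {
      xp <- x
      xp[, idx] <- x[sample(nrow(x)), idx, drop = FALSE]
      aurocScore(.diffScore(model, xp), labels)
    }, numeric(1)))
    data.frame(group = g, auroc_base = base, auroc_perm = auc_i,
               loss_pct = (base - auc_i) / base * 100,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Relative AUROC loss
#'
#' \code{(auroc - auroc_perm) / auroc * 100}, the percentage of the model's
#' discrimination destroyed by permuting a feature group.
#'
#' @param auroc,auroc_perm AUROC before/after permutation.
#' @return loss in percent.
#' @export
aurocLoss <- function(auroc, auroc_perm) (auroc - auroc_perm) / auroc * 100

#' Integrated gradients along the linear path
#'
#' Approximates, per feature j,
#' \code{(x_j - x'_j) * integral_0^1 dF/dx_j (x' + a (x - x')) da}
#' by a midpoint Riemann sum over \code{steps} interior points.  Gradients
#' are taken in inference mode (no dropout).  The completeness residual
#' \code{|sum(IG) - (F(x) - F(x'))|} is always reported.
#'
#' @param model a \code{DenseCircModel}, or a plain function
#'   \code{f(x) -> scalar} (gradient by central finite differences, or an
#'   exact gradient supplied as \code{attr(f, "gradient")}).
#' @param x,baseline named numeric vectors conforming to the model registry.
#' @param steps number of path points (>= 2, default 100).
#' @param class,value forwarded to \code{\link{inputGradients}} /
#'   \code{\link{modelValue}} for \code{DenseCircModel}s.
#' @return list: \code{ig} (named signed per-feature values),
#'   \code{residual}, \code{fx}, \code{fbaseline}, \code{degenerate}
#'   (TRUE when \code{x == baseline}).
#' @export
integratedGradients <- function(model, x, baseline, steps = 100L,
                                class = 2L, value = "default") {
  if (steps < 2L) stop("steps must be >= 2")
  x <- as.numeric(x); xb <- as.numeric(baseline)
  if (length(x) != length(xb)) stop("x and baseline lengths differ")
  d <- length(x)
  if (isTRUE(all.equal(x, xb, tolerance = 0))) {
    return(list(ig = stats::setNames(numeric(d), names(baseline)),
                residual = 0, fx = NA_real_, fbaseline = NA_real_,
                degenerate = TRUE))
  }
  alphas <- (seq_len(steps) - 0.5) / steps
  path <- matrix(rep(xb, each = steps), steps, d) +
    alphas %o% (x - xb)
  if (is(model, "DenseCircModel")) {
    colnames(path) <- model@feature_names
    G <- inputGradients(model, path, class = class, value = value)
    fx <- modelValue(model, matrix(x, 1L), class = class, value = value)
    fb <- modelValue(model, matrix(xb, 1L), class = class, value = value)
  } else if (is.function(model)) {
    gradf <- attr(model, "gradient")
    if (is.null(gradf)) {
      h <- 1e-5
      gradf <- function(z) vapply(seq_along(z), function(j) {
        zp <- z; zm <- z; zp[j] <- z[j] + h; zm[j] <- z[j] - h
        (model(zp) - model(zm)) / (2 * h)
      }, numeric(1))
    }
    G <- t(apply(path, 1L, gradf))
    fx <- model(x); fb <- model(xb)
  } else stop("model must be a DenseCircModel or a function")
  ig <- (x - xb) * colMeans(G)
  names(ig) <- if (!is.null(names(x))) names(x) else
    if (is(model, "DenseCircModel")) model@feature_names else NULL
  list(ig = ig, residual = abs(sum(ig) - (fx - fb)),
       fx = fx, fbaseline = fb, degenerate = FALSE)
}

# pick the n baseline rows closest (Euclidean) to the coordinate-wise
# median of the baseline class over the columns in block; ties broken by
# row order (event id order)
.nearestToMedian <- function(mat, rows, block, n) {
  sub <- mat[rows, block, drop = FALSE]
  med <- apply(sub, 2L, median)
  d2 <- rowSums(sweep(sub, 2L, med)^2)
  rows[order(d2)[seq_len(n)]]
}

#' Adapted integrated gradients: cis protocol
#'
#' Each trial fixes a sample comparison (one sample from the target group,
#' one from outside), so the trans block is constant and its IG is exactly
#' zero.  Target events are those with junction ratio > \code{hi} in the
#' target sample and < \code{lo} in the other; baseline events have ratio <
#' \code{lo} in both.  The baseline class is represented by the
#' \code{n_baseline} events nearest (Euclidean, on the cis block) to its
#' coordinate-wise median, ties broken by event order.  IG is computed for
#' every target against each representative baseline and the mean absolute
#' IG per cis feature over all trials is returned.
#'
#' @param model a \code{DenseCircModel} trained on
#'   \code{[cis, trans_a, trans_b]} feature rows.
#' @param cis_mat normalized cis feature matrix (events x cis features).
#' @param trans_mat normalized per-sample trans half-block matrix
#'   (samples x RBP features).
#' @param ratios junction-ratio matrix (events x samples).
#' @param organs character/factor of group labels, one per sample (named or
#'   ordered as \code{colnames(ratios)}).
#' @param target_organ the group whose specific events are interrogated.
#' @param hi,lo ratio thresholds (defaults 0.5 and 0.1).
#' @param n_baseline baseline representatives per trial (default 3).
#' @param steps IG path points.
#' @param max_targets cap on targets per trial (keeps trials cheap; the
#'   first \code{max_targets} in event order are used).
#' @return list: \code{values} (mean |IG| per cis feature),
#'   \code{n_trials}, \code{n_skipped}, \code{max_trans_ig} (largest |IG|
#'   seen on any trans feature; identically 0).
#' @export
aigCis <- function(model, cis_mat, trans_mat, ratios, organs, target_organ,
                   hi = 0.5, lo = 0.1, n_baseline = 3L, steps = 100L,
                   max_targets = 20L) {
  samples <- colnames(ratios)
  organs <- rep_len(as.character(organs), length(samples))
  in_t <- samples[organs == target_organ]
  out_t <- samples[organs != target_organ]
  if (!length(in_t) || !length(out_t))
    stop("need samples inside and outside the target group")
  n_cis <- ncol(cis_mat)
  acc <- numeric(n_cis); n_ig <- 0L
  n_trials <- 0L; n_skip <- 0L; max_trans <- 0
  for (st in in_t) for (so in out_t) {
    rt <- ratios[, st]; ro <- ratios[, so]
    targets <- which(!is.na(rt) & !is.na(ro) & rt > hi & ro < lo)
    basel <- which(!is.na(rt) & !is.na(ro) & rt < lo & ro < lo)
    if (length(targets) < 1L || length(basel) < n_baseline) {
      warning("trial ", st, " vs ", so, " skipped: ", length(targets),
              " target(s), ", length(basel), " baseline candidate(s)")
      n_skip <- n_skip + 1L
      next
    }
    n_trials <- n_trials + 1L
    targets <- targets[seq_len(min(length(targets), max_targets))]
    X <- pairFeatures(cis_mat, trans_mat, st, so)
    reps <- .nearestToMedian(cis_mat, basel, seq_len(n_cis), n_baseline)
    for (tg in targets) for (bl in reps) {
      igr <- integratedGradients(model, X[tg, ], X[bl, ], steps = steps,
                                 class = 2L)
      acc <- acc + abs(igr$ig[seq_len(n_cis)])
      max_trans <- max(max_trans, max(abs(igr$ig[-seq_len(n_cis)])))
      n_ig <- n_ig + 1L
    }
  }
  if (n_ig == 0L) {
    warning("no qualifying trials; empty report")
    return(list(values = stats::setNames(numeric(n_cis), colnames(cis_mat)),
                n_trials = 0L, n_skipped = n_skip, max_trans_ig = 0))
  }
  list(values = stats::setNames(acc / n_ig, colnames(cis_mat)),
       n_trials = n_trials, n_skipped = n_skip, max_trans_ig = max_trans)
}

#' Adapted integrated gradients: trans protocol
#'
#' Mirror of \code{\link{aigCis}} with the roles of the blocks swapped:
#' each trial fixes one circRNA (ratio > \code{hi} in every sample of the
#' target group), so the cis block is constant and its IG is exactly zero.
#' Target instances are comparisons (target-group sample, outside sample)
#' where the circRNA is differentially spliced (ratio > \code{hi} vs <
#' \code{lo}); baseline instances are comparisons of two outside samples
#' with ratio < \code{lo} in both.  Baselines are represented by the
#' \code{n_baseline} comparisons nearest to the baseline median on the
#' trans block.  Returns the mean absolute IG per trans feature.
#'
#' @inheritParams aigCis
#' @param max_circs cap on interrogated circRNAs.
#' @return list as for \code{aigCis}, with \code{values} over trans
#'   features and \code{max_cis_ig} identically 0.
#' @export
aigTrans <- function(model, cis_mat, trans_mat, ratios, organs,
                     target_organ, hi = 0.5, lo = 0.1, n_baseline = 3L,
                     steps = 100L, max_circs = 10L) {
  samples <- colnames(ratios)
  organs <- rep_len(as.character(organs), length(samples))
  in_t <- samples[organs == target_organ]
  out_t <- samples[organs != target_organ]
  if (!length(out_t) || !length(in_t)) {
    warning("only one group present; no qualifying comparisons")
    nt <- 2L * ncol(trans_mat)
    return(list(values = numeric(0), n_trials = 0L, n_skipped = 0L,
                max_cis_ig = 0))
  }
  n_cis <- ncol(cis_mat)
  trans_cols <- (n_cis + 1L):(n_cis + 2L * ncol(trans_mat))
  circs <- which(apply(ratios[, in_t, drop = FALSE] > hi, 1L,
                       function(z) all(!is.na(z) & z)))
  circs <- circs[seq_len(min(length(circs), max_circs))]
  acc <- numeric(length(trans_cols)); n_ig <- 0L
  n_trials <- 0L; n_skip <- 0L; max_cis <- 0
  for (e in circs) {
    tpairs <- list(); bpairs <- list()
    for (st in in_t) for (so in out_t)
      if (!is.na(ratios[e, st]) && !is.na(ratios[e, so]) &&
          ratios[e, st] > hi && ratios[e, so] < lo)
        tpairs[[length(tpairs) + 1L]] <- c(st, so)
    for (s1 in out_t) for (s2 in out_t)
      if (s1 != s2 && !is.na(ratios[e, s1]) && !is.na(ratios[e, s2]) &&
          ratios[e, s1] < lo && ratios[e, s2] < lo)
        bpairs[[length(bpairs) + 1L]] <- c(s1, s2)
    if (length(tpairs) < 1L || length(bpairs) < n_baseline) {
      warning("circRNA ", rownames(ratios)[e], " skipped: ",
              length(tpairs), " target / ", length(bpairs),
              " baseline comparison(s)")
      n_skip <- n_skip + 1L
      next
    }
    n_trials <- n_trials + 1L
    mk <- function(p) pairFeatures(cis_mat[e, , drop = FALSE], trans_mat,
                                   p[1L], p[2L])[1L, ]
    tvecs <- do.call(rbind, lapply(tpairs, mk))
    bvecs <- do.call(rbind, lapply(bpairs, mk))
    reps <- .nearestToMedian(bvecs, seq_len(nrow(bvecs)),
                             trans_cols, n_baseline)
    for (ti in seq_len(nrow(tvecs))) for (bi in reps) {
      igr <- integratedGradients(model, tvecs[ti, ], bvecs[bi, ],
                                 steps = steps, class = 2L)
      acc <- acc + abs(igr$ig[trans_cols])
      max_cis <- max(max_cis, max(abs(igr$ig[seq_len(n_cis)])))
      n_ig <- n_ig + 1L
    }
  }
  if (n_ig == 0L) {
    warning("no qualifying trials; empty report")
    return(list(values = numeric(0), n_trials = 0L, n_skipped = n_skip,
                max_cis_ig = 0))
  }
  vals <- acc / n_ig
  names(vals) <- colnames(pairFeatures(cis_mat[1L, , drop = FALSE],
                                       trans_mat, rownames(trans_mat)[1L],
                                       rownames(trans_mat)[1L]))[trans_cols]
  list(values = vals, n_trials = n_trials, n_skipped = n_skip,
       max_cis_ig = max_cis)
}
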