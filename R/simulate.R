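#' @importFrom stats rnorm rpois rbinom plogis
NULL

#' Configuration for the synthetic corpus generator
#'
#' The generator emulates the statistical structure the predictor assumes:
#' per-event cis feature vectors, per-sample RBP expression, latent junction
#' ratios tied to planted feature-expression effects, and binomial BSJ/FSJ
#' counts at a configurable depth.  Defaults give 2000 events x 20 sample
#' pairs = 40000 candidate labeled events.
#'
#' The latent model is
#' \code{logit(psi[e,s]) = beta0 + cis main effects + RBP main effects +
#' cis x RBP interactions + noise}; totals are Poisson(\code{depth_mean})
#' and BSJ counts Binomial with the success probability implied by the
#' ratio convention \code{c}.  Samples belong to two groups ("organs") and
#' the planted RBPs are shifted between groups, so events driven by the
#' planted interaction become group-specific.
#'
#' @param n_events,n_samples,n_rbps,n_cis corpus dimensions.
#' @param planted_cis,cis_weights indices and weights of cis main effects.
#' @param planted_rbps,rbp_weights indices and weights of RBP main effects
#'   (on the per-gene z-scale of log expression).
#' @param interactions data.frame with columns \code{cis}, \code{rbp},
#'   \code{w}: planted cis x trans interaction terms.
#' @param cis_active_frac fraction of events carrying a non-zero value of
#'   each planted cis feature (planted columns are zero-inflated
#'   half-normal: most events have no binding element for a given
#'   regulator, responsive events a strong one).
#' @param organ_shift additive log-expression shift of planted RBPs in the
#'   first sample group.
#' @param beta0 latent intercept; \code{noise_sd} event x sample logit
#'   noise.
#' @param noise_sd standard deviation of the event x sample logit noise.
#' @param depth_mean mean total junction reads per event and sample.
#' @param c junction-ratio convention (1 or 2).
#' @param seed RNG seed; the whole corpus is a deterministic function of
#'   the config.
#' @return config list for \code{\link{simulateCorpus}}.
#' @export
simConfig <- function(n_events = 2000L, n_samples = 40L, n_rbps = 50L,
                      n_cis = 30L,
                      planted_cis = c(1L, 2L), cis_weights = c(0.4, 0.4),
                      planted_rbps = c(1L, 2L), rbp_weights = c(0.15, 0.1),
                      interactions = data.frame(cis = c(1L, 2L),
                                                rbp = c(1L, 2L),
                                                w = c(3, 2)),
                      cis_active_frac = 0.2,
                      organ_shift = 2.5, beta0 = -2.5, noise_sd = 0.08,
                      depth_mean = 800, c = 2, seed = 1L) {
  stopifnot(all(planted_cis <= n_cis), all(planted_rbps <= n_rbps),
            all(interactions$cis <= n_cis), all(interactions$rbp <= n_rbps),
            depth_mean > 0, n_samples %% 2L == 0L)
  list(n_events = n_events, n_samples = n_samples, n_rbps = n_rbps,
       n_cis = n_cis, planted_cis = planted_cis, cis_weights = cis_weights,
       planted_rbps = planted_rbps, rbp_weights = rbp_weights,
       interactions = interactions, cis_active_frac = cis_active_frac,
       organ_shift = organ_shift,
       beta0 = beta0, noise_sd = noise_sd, depth_mean = depth_mean,
       c = c, seed = as.integer(seed))
}

#' Simulate a synthetic circRNA corpus with planted signal
#'
#' @param config list from \code{\link{simConfig}}.
#' @return list with elements \code{config}; \code{cis} (raw event
#'   features), \code{cis_norm} and \code{cis_normalizer}; \code{expr}
#'   (TPM-like RBP x sample matrix), \code{trans_mat} (normalized
#'   per-sample half blocks) and \code{trans_normalizer}; \code{organs};
#'   \code{pairs} (2 x n_pairs sample-id matrix); \code{counts} (list of
#'   \code{bsj}, \code{fsj} event x sample matrices); \code{psi} (latent
#'   junction ratios); \code{ratios} (observed); \code{truth} (planted
#'   parameters and latent state).
#' @export
simulateCorpus <- function(config = simConfig()) {
  cf <- config
  set.seed(cf$seed)
  ev <- sprintf("ev%04d", seq_len(cf$n_events))
  sm <- sprintf("S%02d", seq_len(cf$n_samples))
  rbp <- sprintf("RBP%03d", seq_len(cf$n_rbps))
  cis_names <- sprintf("cis%02d", seq_len(cf$n_cis))
  organs <- rep(c("O1", "O2"), length.out = cf$n_samples)

  cis <- matrix(rnorm(cf$n_events * cf$n_cis), cf$n_events, cf$n_cis,
                dimnames = list(ev, cis_names))
  # planted cis features are zero-inflated half-normal: most events carry
  # no binding element for a given RBP, responsive events a strong one
  for (j in cf$planted_cis)
    cis[, j] <- (stats::runif(cf$n_events) < cf$cis_active_frac) *
      abs(rnorm(cf$n_events, 1.5, 0.5))
  mu_g <- rnorm(cf$n_rbps, 3, 0.5)
  sd_g <- rep(0.4, cf$n_rbps)
  log_e <- matrix(rnorm(cf$n_rbps * cf$n_samples, mu_g, sd_g),
                  cf$n_rbps, cf$n_samples, dimnames = list(rbp, sm))
  log_e[cf$planted_rbps, organs == "O1"] <-
    log_e[cf$planted_rbps, organs == "O1"] + cf$organ_shift
  expr <- exp(log_e)
  z <- t(scale(t(log_e)))                     # per-gene z across samples

  eta <- matrix(cf$beta0, cf$n_events, cf$n_samples,
                dimnames = list(ev, sm))
  for (k in seq_along(cf$planted_cis))
    eta <- eta + cf$cis_weights[k] * cis[, cf$planted_cis[k]]
  for (k in seq_along(cf$planted_rbps))
    eta <- eta + matrix(cf$rbp_weights[k] * z[cf$planted_rbps[k], ],
                        cf$n_events, cf$n_samples, byrow = TRUE)
  if (nrow(cf$interactions))
    for (k in seq_len(nrow(cf$interactions)))
      eta <- eta + cf$interactions$w[k] *
        outer(cis[, cf$interactions$cis[k]], z[cf$interactions$rbp[k], ])
  eta <- eta + matrix(rnorm(length(eta), 0, cf$noise_sd), nrow(eta))
  psi <- plogis(eta)

  totals <- matrix(rpois(length(psi), cf$depth_mean), nrow(psi),
                   dimnames = dimnames(psi))
  q <- .psiToSuccess(psi, cf$c)
  bsj <- matrix(rbinom(length(psi), as.vector(totals), as.vector(q)),
                nrow(psi), dimnames = dimnames(psi))
  fsj <- totals - bsj

  pairs <- matrix(sm[sample(cf$n_samples)], nrow = 2L)
  rownames(pairs) <- c("sample_a", "sample_b")
  colnames(pairs) <- sprintf("pair%02d", seq_len(ncol(pairs)))

  cis_normalizer <- fitMaxAbsNormalizer(cis)
  cis_norm <- applyNormalizer(cis_normalizer, cis, clip = FALSE)
  trans_raw <- t(expr)                        # samples x genes
  trans_normalizer <- fitMaxAbsNormalizer(trans_raw)
  trans_mat <- applyNormalizer(trans_normalizer, trans_raw, clip = FALSE)

  list(config = cf, cis = cis, cis_norm = cis_norm,
       cis_normalizer = cis_normalizer, expr = expr,
       trans_mat = trans_mat, trans_normalizer = trans_normalizer,
       organs = stats::setNames(organs, sm), pairs = pairs,
       counts = list(bsj = bsj, fsj = fsj), psi = psi,
       ratios = junctionRatio(bsj, fsj, c = cf$c),
       truth = list(psi = psi, eta = eta, z = z,
                    planted_cis = cf$planted_cis,
                    planted_rbps = cf$planted_rbps,
                    interactions = cf$interactions))
}

#' Assemble labeled training data from a corpus
#'
#' Runs the count filters and the flat-prior test on every sample pair,
#' keeps confidently labeled events, and binds their feature rows
#' \code{[cis, trans_a, trans_b]}.
#'
#' @param corpus output of \code{\link{simulateCorpus}}.
#' @param head \code{"binary"} or \code{"three_class"}.
#' @param symmetrize also emit the mirrored orientation of every pair
#'   (default TRUE for the three-class head), swapping the trans halves and
#'   the direction labels.
#' @param pairs optional subset of pair columns to use.
#' @param grid quadrature resolution for labeling.
#' @return list: \code{x} (feature matrix), \code{y} (labels), \code{meta}
#'   (data.frame event_id, pair, sample_a, sample_b, p_diff, true_delta).
#' @export
pairTrainingData <- function(corpus, head = c("binary", "three_class"),
                             symmetrize = NULL, pairs = NULL, grid = 201) {
  head <- match.arg(head)
  if (is.null(symmetrize)) symmetrize <- head == "three_class"
  if (is.null(pairs)) pairs <- seq_len(ncol(corpus$pairs))
  bsj <- corpus$counts$bsj; fsj <- corpus$counts$fsj
  xs <- list(); ys <- list(); metas <- list()
  for (p in pairs) {
    sa <- corpus$pairs[1L, p]; sb <- corpus$pairs[2L, p]
    orient <- list(c(sa, sb))
    if (symmetrize) orient <- c(orient, list(c(sb, sa)))
    for (o in orient) {
      lab <- makeTrainingLabels(bsj[, o[1L]], fsj[, o[1L]],
                                bsj[, o[2L]], fsj[, o[2L]],
                                event_id = rownames(bsj), grid = grid)
      keep <- which(lab$kept & lab$label %in% c("positive", "negative"))
      if (!length(keep)) next
      X <- pairFeatures(corpus$cis_norm[keep, , drop = FALSE],
                        corpus$trans_mat, o[1L], o[2L])
      y <- if (head == "binary") lab$label[keep] else lab$class3[keep]
      y[y == "positive"] <- "positive"; y[y == "negative"] <- "negative"
      xs[[length(xs) + 1L]] <- X
      ys[[length(ys) + 1L]] <- y
      metas[[length(metas) + 1L]] <- data.frame(
        event_id = lab$event_id[keep],
        pair = colnames(corpus$pairs)[p],
        sample_a = o[1L], sample_b = o[2L],
        p_diff = lab$p_diff[keep],
        true_delta = corpus$psi[keep, o[1L]] - corpus$psi[keep, o[2L]],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(xs)) stop("no labeled events survive the filters")
  list(x = do.call(rbind, xs), y = unlist(ys),
       meta = do.call(rbind, metas))
}

#' Binomially thin junction counts
#'
#' Each read is retained independently with probability \code{factor}
#' (BSJ and FSJ thinned separately), emulating shallow resequencing.
#'
#' @param counts list with integer matrices \code{bsj} and \code{fsj}.
#' @param factor retention probability in (0, 1].
#' @param seed RNG seed.
#' @return list of thinned \code{bsj}, \code{fsj} matrices.
#' @export
downsampleCounts <- function(counts, factor, seed = 1L) {
  if (factor <= 0 || factor > 1) stop("factor must be in (0, 1]")
  if (factor == 1) return(counts)
  set.seed(seed)
  thin <- function(m) {
    out <- m
    out[] <- rbinom(length(m), as.vector(m), factor)
    out
  }
  list(bsj = thin(counts$bsj), fsj = thin(counts$fsj))
}

#' Flat vs informative inference on thinned counts
#'
#' Thins the corpus counts to \code{factor} of their depth (\code{reps}
#' seeded thinning replicates) and, for every (replicate, pair) comparison,
#' scores each event with the flat-prior posterior and with the informative
#' posterior whose prior is the model's differential probability, then
#' evaluates both against the latent truth |delta psi| > C by AUROC.  With
#' the defaults this yields \code{reps * length(pairs) = 50} replicate
#' comparisons.
#'
#' @param corpus output of \code{\link{simulateCorpus}}.
#' @param model a binary-head \code{DenseCircModel} trained on the corpus
#'   features.
#' @param factor depth retention (default 0.05).
#' @param reps number of seeded thinning replicates (default 10).
#' @param pairs pair columns to evaluate; \code{NULL} (default) picks the
#'   first \code{n_pairs} pairs whose latent truth contains both classes
#'   (AUROC is undefined for a comparison with no true DSC events).
#' @param n_pairs number of pairs when \code{pairs} is NULL (default 5).
#' @param C junction-ratio difference threshold.
#' @param grid,refine quadrature resolution; bulk scoring defaults to a
#'   lighter refinement than single-event testing because AUROC depends
#'   only on the score ordering.
#' @param seed base seed; replicate r uses \code{seed + r}.
#' @return data.frame, one row per (replicate, pair) comparison:
#'   \code{rep}, \code{pair}, \code{auroc_flat}, \code{auroc_info}.
#' @export
lowDepthBenchmark <- function(corpus, model, factor = 0.05, reps = 10L,
                              pairs = NULL, n_pairs = 5L, C = 0.05,
                              grid = 201, refine = 2L, seed = 1L) {
  cfc <- corpus$config$c
  if (is.null(pairs)) {
    ok <- which(vapply(seq_len(ncol(corpus$pairs)), function(p) {
      tr <- abs(corpus$psi[, corpus$pairs[1L, p]] -
                  corpus$psi[, corpus$pairs[2L, p]]) > C
      any(tr) && !all(tr)
    }, logical(1)))
    if (length(ok) < n_pairs)
      stop("fewer than ", n_pairs, " evaluable pairs in the corpus")
    pairs <- ok[seq_len(n_pairs)]
  }
  # per-pair model priors and truth labels are depth-independent
  qs <- list(); truths <- list()
  for (p in pairs) {
    sa <- corpus$pairs[1L, p]; sb <- corpus$pairs[2L, p]
    X <- pairFeatures(corpus$cis_norm, corpus$trans_mat, sa, sb)
    qs[[as.character(p)]] <- predictModel(model, X)
    truths[[as.character(p)]] <-
      abs(corpus$psi[, sa] - corpus$psi[, sb]) > C
  }
  out <- expand.grid(rep = seq_len(reps), pair = pairs)
  out$auroc_flat <- NA_real_; out$auroc_info <- NA_real_
  for (r in seq_len(reps)) {
    thin <- downsampleCounts(corpus$counts, factor, seed = seed + r)
    for (p in pairs) {
      sa <- corpus$pairs[1L, p]; sb <- corpus$pairs[2L, p]
      fl <- bhtFlat(thin$bsj[, sa], thin$fsj[, sa],
                    thin$bsj[, sb], thin$fsj[, sb], C = C, c = cfc,
                    grid = grid, refine = refine)
      inf <- bhtInfo(thin$bsj[, sa], thin$fsj[, sa],
                     thin$bsj[, sb], thin$fsj[, sb],
                     prior_q = qs[[as.character(p)]], C = C, c = cfc,
                     grid = grid, refine = refine)
      row <- which(out$rep == r & out$pair == p)
      tr <- truths[[as.character(p)]]
      out$auroc_flat[row] <- aurocScore(fl$p_diff, tr)
      out$auroc_info[row] <- aurocScore(inf$p_diff, tr)
    }
  }
  out
}
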