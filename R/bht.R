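#' @importFrom stats dbinom
NULL

# success probability of a BSJ read among total junction reads implied by a
# junction ratio psi under ratio convention c:  psi = c q / (c q + 1 - q)
.psiToSuccess <- function(psi, c) psi / (c - (c - 1) * psi)

# F_B evaluated at every node shifted by +/- C, linearly interpolated
# between cells; cumB is the per-column cumulative mass, B the cell masses.
# t: length-m vector of positions in cell units.  Returns an m x n matrix.
.cdfShift <- function(cumB, B, t, m) {
  j <- floor(t)
  frac <- t - j
  base_idx <- pmax(pmin(j, m), 0L)
  base <- rbind(0, cumB)[base_idx + 1L, , drop = FALSE]
  dens_row <- pmin(pmax(j + 1L, 1L), m)
  valid <- as.numeric(j + 1L >= 1L & j + 1L <= m)
  base + (frac * valid) * B[dens_row, , drop = FALSE]
}

# core quadrature, vectorised over events.
# bA, nA, bB, nB: integer vectors (BSJ and total counts per sample).
# prior_q: NULL for the flat model, else vector in [0,1].
# The likelihoods are evaluated on refine x m nodes so that posteriors
# narrower than one nominal grid cell are still resolved.
.bhtCore <- function(bA, nA, bB, nB, C, c, m, prior_q = NULL,
                     refine = 10L) {
  nev <- length(bA)
  mm <- as.integer(m * refine)
  psis <- (seq_len(mm) - 0.5) / mm
  q <- .psiToSuccess(psis, c)
  logA <- matrix(dbinom(rep(bA, each = mm), rep(nA, each = mm), q,
                        log = TRUE), mm, nev)
  logB <- matrix(dbinom(rep(bB, each = mm), rep(nB, each = mm), q,
                        log = TRUE), mm, nev)
  A <- exp(sweep(logA, 2L, apply(logA, 2L, max)))
  B <- exp(sweep(logB, 2L, apply(logB, 2L, max)))
  # P(|psi_A - psi_B| > C) = int L_A(a) [F_B(a - C) + 1 - F_B(a + C)] da /
  # (int L_A)(int L_B): one-dimensional quadrature against the cumulative
  # mass of psi_B, linearly interpolated between grid cells.
  cumB <- apply(B, 2L, cumsum)
  if (is.null(dim(cumB))) cumB <- matrix(cumB, nrow = mm)
  totA <- colSums(A); totB <- cumB[mm, ]
  nodes <- seq_len(mm) - 0.5
  F_lo <- .cdfShift(cumB, B, nodes - C * mm, mm)
  F_hi <- .cdfShift(cumB, B, nodes + C * mm, mm)
  S_D <- colSums(A * (F_lo + rep(totB, each = mm) - F_hi))
  S_tot <- totA * totB
  S_U <- pmax(S_tot - S_D, 0)
  # prior areas of the two regions are exact under uniform (psi_A, psi_B)
  N_D <- (1 - C)^2
  N_U <- 1 - N_D
  if (is.null(prior_q)) {
    p <- S_D / S_tot
  } else {
    num <- prior_q * S_D / N_D
    den <- num + (1 - prior_q) * S_U / N_U
    p <- num / den
  }
  defined <- (nA + nB) > 0
  # with no reads the posterior equals the prior; report it but flag it
  if (any(!defined)) {
    p[!defined] <- if (is.null(prior_q)) N_D else prior_q[!defined]
  }
  psiA <- ifelse(nA > 0, c * bA / (c * bA + (nA - bA)), NA_real_)
  psiB <- ifelse(nB > 0, c * bB / (c * bB + (nB - bB)), NA_real_)
  delta <- psiA - psiB
  dir <- rep("none", nev)
  dir[!is.na(delta) & delta > 0] <- "higher_in_A"
  dir[!is.na(delta) & delta < 0] <- "higher_in_B"
  data.frame(p_diff = p, mle_delta = delta, direction = dir,
             defined = defined, stringsAsFactors = FALSE)
}

#' Flat-prior Bayesian hypothesis test on junction counts
#'
#' Posterior probability that the junction-ratio difference between two
#' samples exceeds \code{C} in magnitude.  The likelihood treats each
#' sample's BSJ count as Binomial(BSJ+FSJ, q(psi)) with
#' \code{q(psi) = psi/(c - (c-1) psi)} (the count-space success probability
#' implied by the ratio convention \code{c}); the prior is independent
#' Uniform(0,1) on each sample's psi.  The posterior integral is evaluated
#' by midpoint quadrature on a uniform \code{grid x grid} mesh, accumulated
#' in likelihood space after per-event log-scale normalisation.
#'
#' Events with zero total reads in both samples are flagged
#' \code{defined = FALSE}; their reported \code{p_diff} is the prior mass of
#' the differential region.
#'
#' @param bsj_a,fsj_a,bsj_b,fsj_b integer count vectors (one entry per
#'   event) for samples A and B.
#' @param C junction-ratio difference threshold (default 0.05).
#' @param c ratio convention weight (default 2; see
#'   \code{\link{junctionRatio}}).
#' @param grid number of quadrature cells per axis (default 201).
#' @param refine internal likelihood-resolution factor: the marginal
#'   likelihoods are evaluated on \code{refine * grid} nodes so that
#'   posteriors narrower than one nominal cell stay resolved (default 10).
#' @return data.frame: \code{p_diff}, \code{mle_delta} (plug-in ratio
#'   difference A - B), \code{direction}, \code{defined}.
#' @export
bhtFlat <- function(bsj_a, fsj_a, bsj_b, fsj_b, C = 0.05, c = 2,
                    grid = 201, refine = 10L) {
  stopifnot(all(bsj_a >= 0), all(fsj_a >= 0), all(bsj_b >= 0),
            all(fsj_b >= 0))
  .bhtCore(bsj_a, bsj_a + fsj_a, bsj_b, bsj_b + fsj_b, C, c, grid,
           refine = refine)
}

#' Informative-prior Bayesian hypothesis test
#'
#' Same likelihood and quadrature as \code{\link{bhtFlat}}, but the prior on
#' (psi_A, psi_B) is a two-component mixture driven by an external
#' differential probability \code{prior_q} (typically the network's
#' prediction for the event): with probability \code{prior_q} the pair is
#' uniform over the differential region \{|psi_A - psi_B| > C\}, with
#' probability \code{1 - prior_q} uniform over its complement.  At
#' \code{prior_q = 0.5} the posterior ordering over events reduces to the
#' flat model's ordering; \code{p_diff} is monotone increasing in
#' \code{prior_q}.
#'
#' @inheritParams bhtFlat
#' @param prior_q vector of prior differential probabilities in [0,1].
#' @return data.frame as for \code{bhtFlat}.
#' @export
bhtInfo <- function(bsj_a, fsj_a, bsj_b, fsj_b, prior_q, C = 0.05, c = 2,
                    grid = 201, refine = 10L) {
  stopifnot(all(bsj_a >= 0), all(fsj_a >= 0), all(bsj_b >= 0),
            all(fsj_b >= 0))
  prior_q <- rep_len(prior_q, length(bsj_a))
  if (any(prior_q < 0 | prior_q > 1)) stop("prior_q must be in [0,1]")
  .bhtCore(bsj_a, bsj_a + fsj_a, bsj_b, bsj_b + fsj_b, C, c, grid, prior_q,
           refine = refine)
}

#' Generate training labels for one sample pair
#'
#' Applies the count filters (BSJ > \code{min_bsj}, FSJ > \code{min_fsj} and
#' BSJ + FSJ > \code{min_total}, in both samples), runs the flat-prior test,
#' and labels survivors positive when
#' \code{p(|delta ratio| > C) > pos_thr}, negative when \code{< neg_thr};
#' events between the cuts are kept out of training (label
#' \code{"ambiguous"}).  Positives carry a three-class sub-label
#' (\code{higher_in_A} / \code{higher_in_B}) from the sign of the plug-in
#' ratio difference.
#'
#' @inheritParams bhtFlat
#' @param event_id optional event identifiers.
#' @param pos_thr,neg_thr posterior cuts (defaults 0.9 and 0.1).
#' @param min_bsj,min_fsj,min_total strict count filters (defaults 2, 2,
#'   20).
#' @param refine likelihood-resolution factor; labeling uses a lighter
#'   default than single-event testing (posteriors at the 0.9/0.1 cuts are
#'   insensitive to the extra resolution).
#' @return data.frame with one row per input event: \code{event_id},
#'   \code{kept} (passed the count filter), \code{p_diff},
#'   \code{mle_delta}, \code{label} (positive/negative/ambiguous, NA when
#'   dropped) and \code{class3} (unchanged/higher_in_A/higher_in_B).
#' @export
makeTrainingLabels <- function(bsj_a, fsj_a, bsj_b, fsj_b, event_id = NULL,
                               C = 0.05, pos_thr = 0.9, neg_thr = 0.1,
                               min_bsj = 2, min_fsj = 2, min_total = 20,
                               c = 2, grid = 201, refine = 2L) {
  n <- length(bsj_a)
  if (is.null(event_id)) event_id <- as.character(seq_len(n))
  kept <- bsj_a > min_bsj & fsj_a > min_fsj & (bsj_a + fsj_a) > min_total &
    bsj_b > min_bsj & fsj_b > min_fsj & (bsj_b + fsj_b) > min_total
  out <- data.frame(event_id = event_id, kept = kept,
                    p_diff = NA_real_, mle_delta = NA_real_,
                    label = NA_character_, class3 = NA_character_,
                    stringsAsFactors = FALSE)
  if (any(kept)) {
    res <- bhtFlat(bsj_a[kept], fsj_a[kept], bsj_b[kept], fsj_b[kept],
                   C = C, c = c, grid = grid, refine = refine)
    out$p_diff[kept] <- res$p_diff
    out$mle_delta[kept] <- res$mle_delta
    lab <- rep("ambiguous", nrow(res))
    lab[res$p_diff > pos_thr] <- "positive"
    lab[res$p_diff < neg_thr] <- "negative"
    out$label[kept] <- lab
    cls <- rep(NA_character_, nrow(res))
    cls[lab == "negative"] <- "unchanged"
    cls[lab == "positive"] <- res$direction[lab == "positive"]
    out$class3[kept] <- cls
  }
  out
}
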