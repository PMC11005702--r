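#' @importFrom stats rnorm runif
NULL

#' Model configuration for the dense-block network
#'
#' Four dense blocks (linear -> batch normalization -> ReLU -> dropout) of
#' widths 1200/500/300/200 with dropout rates 0.5/0.3/0.2/0.1, a sigmoid
#' output for the binary head and a softmax for the three-class head.
#' Training uses balanced mini-batches of 512 (half positive, half
#' negative), binary or categorical cross-entropy, the Adam optimizer, and
#' 8 (binary) or 7 (three-class) epochs with a balanced 1\% held-out split
#' scored by AUROC after each epoch; the best-epoch weights are kept.
#'
#' @param head \code{"binary"} or \code{"three_class"}.
#' @param widths output widths of the four dense blocks.
#' @param dropout dropout rates per block, in [0,1).
#' @param batch_size mini-batch size (default 512).
#' @param epochs training epochs (default 8 binary / 7 three-class).
#' @param lr Adam learning rate (default 1e-3).
#' @param test_frac held-out fraction (default 0.01, balanced).
#' @param seed RNG seed controlling init, batching and the held-out split.
#' @return a config list for \code{\link{trainDenseModel}}.
#' @export
modelConfig <- function(head = c("binary", "three_class"),
                        widths = c(1200L, 500L, 300L, 200L),
                        dropout = c(0.5, 0.3, 0.2, 0.1),
                        batch_size = 512L,
                        epochs = NULL, lr = 1e-3, test_frac = 0.01,
                        seed = 1L) {
  head <- match.arg(head)
  if (length(widths) != length(dropout))
    stop("widths and dropout must have equal length")
  if (any(dropout < 0 | dropout >= 1)) stop("dropout rates must be in [0,1)")
  if (is.null(epochs)) epochs <- if (head == "binary") 8L else 7L
  list(head = head, widths = as.integer(widths), dropout = dropout,
       batch_size = as.integer(batch_size), epochs = as.integer(epochs),
       lr = lr, test_frac = test_frac, seed = as.integer(seed),
       bn_eps = 1e-5, bn_momentum = 0.9,
       adam_beta1 = 0.9, adam_beta2 = 0.999, adam_eps = 1e-8)
}

.initParams <- function(d_in, cfg) {
  widths <- cfg$widths
  n_out <- if (cfg$head == "binary") 1L else 3L
  dims <- c(d_in, widths)
  blocks <- vector("list", length(widths))
  for (l in seq_along(widths)) {
    blocks[[l]] <- list(
      W = matrix(rnorm(dims[l] * dims[l + 1L], sd = sqrt(2 / dims[l])),
                 dims[l], dims[l + 1L]),
      gamma = rep(1, dims[l + 1L]), beta = rep(0, dims[l + 1L]),
      run_mean = rep(0, dims[l + 1L]), run_var = rep(1, dims[l + 1L]))
  }
  out <- list(W = matrix(rnorm(dims[length(dims)] * n_out,
                               sd = sqrt(1 / dims[length(dims)])),
                         dims[length(dims)], n_out),
              b = rep(0, n_out))
  list(blocks = blocks, out = out)
}

.softmaxRows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# training-mode forward pass; returns cache for backprop
.forwardTrain <- function(params, X, cfg) {
  caches <- vector("list", length(params$blocks))
  H <- X
  for (l in seq_along(params$blocks)) {
    bl <- params$blocks[[l]]
    Z <- H %*% bl$W
    mu <- colMeans(Z)
    v <- colMeans(Z^2) - mu^2
    inv_sd <- 1 / sqrt(v + cfg$bn_eps)
    xhat <- sweep(sweep(Z, 2L, mu), 2L, inv_sd, "*")
    A <- sweep(sweep(xhat, 2L, bl$gamma, "*"), 2L, bl$beta, "+")
    M <- A > 0
    Hr <- A * M
    p <- cfg$dropout[l]
    D <- if (p > 0)
      matrix((runif(length(Hr)) >= p) / (1 - p), nrow(Hr), ncol(Hr))
    else NULL
    Hout <- if (is.null(D)) Hr else Hr * D
    caches[[l]] <- list(H_in = H, xhat = xhat, inv_sd = inv_sd, M = M,
                        D = D, mu = mu, v = v)
    H <- Hout
  }
  logits <- sweep(H %*% params$out$W, 2L, params$out$b, "+")
  list(H_last = H, logits = logits, caches = caches)
}

# inference-mode forward pass (running stats, no dropout); optionally keeps
# the per-layer cache needed for input gradients
.forwardInfer <- function(params, X, cfg, keep_cache = FALSE) {
  caches <- if (keep_cache) vector("list", length(params$blocks)) else NULL
  H <- X
  for (l in seq_along(params$blocks)) {
    bl <- params$blocks[[l]]
    Z <- H %*% bl$W
    inv_sd <- 1 / sqrt(bl$run_var + cfg$bn_eps)
    A <- sweep(sweep(Z, 2L, bl$run_mean), 2L, bl$gamma * inv_sd, "*")
    A <- sweep(A, 2L, bl$beta, "+")
    M <- A > 0
    if (keep_cache) caches[[l]] <- list(M = M, scale = bl$gamma * inv_sd)
    H <- A * M
  }
  logits <- sweep(H %*% params$out$W, 2L, params$out$b, "+")
  list(logits = logits, caches = caches)
}

# backprop from dlogits through the training-mode network; returns gradients
.backward <- function(params, fw, dlogits, cfg) {
  g <- list(blocks = vector("list", length(params$blocks)), out = NULL)
  g$out <- list(W = crossprod(fw$H_last, dlogits), b = colSums(dlogits))
  dH <- tcrossprod(dlogits, params$out$W)
  B <- nrow(dlogits)
  for (l in rev(seq_along(params$blocks))) {
    cc <- fw$caches[[l]]
    if (!is.null(cc$D)) dH <- dH * cc$D
    dA <- dH * cc$M
    dgamma <- colSums(dA * cc$xhat)
    dbeta <- colSums(dA)
    dxhat <- sweep(dA, 2L, params$blocks[[l]]$gamma, "*")
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * cc$xhat)
    # dZ = inv_sd/B * (B*dxhat - s1 - xhat*s2)
    dZ <- sweep(B * dxhat, 2L, s1) - sweep(cc$xhat, 2L, s2, "*")
    dZ <- sweep(dZ, 2L, cc$inv_sd / B, "*")
    g$blocks[[l]] <- list(W = crossprod(cc$H_in, dZ),
                          gamma = dgamma, beta = dbeta)
    dH <- tcrossprod(dZ, params$blocks[[l]]$W)
  }
  g
}

.adamInit <- function(params) {
  rapply(params, function(x) x * 0, how = "replace")
}

.adamStep <- function(params, grads, m, v, t, cfg) {
  b1 <- cfg$adam_beta1; b2 <- cfg$adam_beta2; eps <- cfg$adam_eps
  upd <- function(p, g, mm, vv) {
    mm <- b1 * mm + (1 - b1) * g
    vv <- b2 * vv + (1 - b2) * g^2
    mhat <- mm / (1 - b1^t)
    vhat <- vv / (1 - b2^t)
    list(p = p - cfg$lr * mhat / (sqrt(vhat) + eps), m = mm, v = vv)
  }
  for (l in seq_along(params$blocks)) {
    for (nm in c("W", "gamma", "beta")) {
      r <- upd(params$blocks[[l]][[nm]], grads$blocks[[l]][[nm]],
               m$blocks[[l]][[nm]], v$blocks[[l]][[nm]])
      params$blocks[[l]][[nm]] <- r$p
      m$blocks[[l]][[nm]] <- r$m
      v$blocks[[l]][[nm]] <- r$v
    }
  }
  for (nm in c("W", "b")) {
    r <- upd(params$out[[nm]], grads$out[[nm]], m$out[[nm]], v$out[[nm]])
    params$out[[nm]] <- r$p; m$out[[nm]] <- r$m; v$out[[nm]] <- r$v
  }
  list(params = params, m = m, v = v)
}

.classCodes <- function(y, head) {
  if (head == "binary") {
    lv <- c("negative", "positive")
    if (is.logical(y)) y <- lv[y + 1L]
    if (is.numeric(y)) y <- lv[(y > 0) + 1L]
    y <- as.character(y)
    if (!all(y %in% lv)) stop("binary labels must be negative/positive")
    miss <- setdiff(lv, unique(y))
    if (length(miss)) stop("class absent from training data: ", miss[1L])
    match(y, lv) - 1L                       # 0 = negative, 1 = positive
  } else {
    lv <- c("unchanged", "higher_in_A", "higher_in_B")
    y <- as.character(y)
    if (!all(y %in% lv))
      stop("three-class labels must be unchanged/higher_in_A/higher_in_B")
    miss <- setdiff(lv, unique(y))
    if (length(miss)) stop("class absent from training data: ", miss[1L])
    match(y, lv)                            # 1..3
  }
}

# index stream of length need drawn from pool: without replacement when the
# pool suffices, minority oversampling with replacement otherwise
.classStream <- function(pool, need) {
  if (length(pool) >= need) sample(pool)[seq_len(need)]
  else sample(pool, need, replace = TRUE)
}

#' Train the dense-block network
#'
#' Balanced mini-batch training: each batch holds \code{batch_size/2}
#' negative (unchanged) and \code{batch_size/2} positive (either direction)
#' instances; the minority class is oversampled with replacement per epoch.
#' A balanced held-out split (\code{test_frac} of the data, equal classes)
#' is scored by AUROC after each epoch and the best-epoch weights are
#' returned.  Fully deterministic given \code{config$seed}.
#'
#' @param x numeric feature matrix (instances x features), normalized,
#'   with column names.
#' @param y labels: \code{negative}/\code{positive} (binary head) or
#'   \code{unchanged}/\code{higher_in_A}/\code{higher_in_B} (three-class).
#' @param config list from \code{\link{modelConfig}}.
#' @param batch_log when TRUE, the per-batch class compositions are kept in
#'   the model history attribute \code{"batch_composition"}.
#' @return a \code{\link{DenseCircModel-class}} object.
#' @export
trainDenseModel <- function(x, y, config = modelConfig(), batch_log = FALSE) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  cfg <- config
  codes <- .classCodes(y, cfg$head)
  pos_is <- if (cfg$head == "binary") codes == 1L else codes > 1L
  set.seed(cfg$seed)
  n <- nrow(x)
  n_test_half <- max(1L, round(cfg$test_frac * n / 2))
  test_idx <- c(.classStream(which(!pos_is), n_test_half)[seq_len(
    min(n_test_half, sum(!pos_is)))],
    .classStream(which(pos_is), n_test_half)[seq_len(
      min(n_test_half, sum(pos_is)))])
  test_idx <- unique(test_idx)
  tr_idx <- setdiff(seq_len(n), test_idx)
  xt <- x[test_idx, , drop = FALSE]
  yt_pos <- pos_is[test_idx]

  params <- .initParams(ncol(x), cfg)
  m_st <- .adamInit(params); v_st <- .adamInit(params)
  half <- cfg$batch_size %/% 2L
  neg_pool <- tr_idx[!pos_is[tr_idx]]
  pos_pool <- tr_idx[pos_is[tr_idx]]
  if (!length(neg_pool) || !length(pos_pool))
    stop("training data must contain both classes")
  hist <- data.frame(epoch = integer(), loss = numeric(),
                     test_auroc = numeric())
  comp <- if (batch_log) list() else NULL
  best <- list(auroc = -Inf, params = params)
  t_step <- 0L

  for (ep in seq_len(cfg$epochs)) {
    n_steps <- max(1L, floor(max(length(neg_pool), length(pos_pool)) / half))
    neg_s <- .classStream(neg_pool, n_steps * half)
    pos_s <- .classStream(pos_pool, n_steps * half)
    losses <- numeric(n_steps)
    for (s in seq_len(n_steps)) {
      take <- ((s - 1L) * half + 1L):(s * half)
      idx <- c(neg_s[take], pos_s[take])
      xb <- x[idx, , drop = FALSE]
      fw <- .forwardTrain(params, xb, cfg)
      if (cfg$head == "binary") {
        yb <- as.numeric(codes[idx])
        p <- 1 / (1 + exp(-fw$logits[, 1L]))
        p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
        losses[s] <- -mean(yb * log(p) + (1 - yb) * log(1 - p))
        dlogits <- matrix((p - yb) / length(yb), ncol = 1L)
      } else {
        P <- .softmaxRows(fw$logits)
        Y <- matrix(0, nrow(P), 3L)
        Y[cbind(seq_len(nrow(P)), codes[idx])] <- 1
        losses[s] <- -mean(log(pmax(P[Y == 1], 1e-12)))
        dlogits <- (P - Y) / nrow(P)
      }
      if (batch_log)
        comp[[length(comp) + 1L]] <- c(epoch = ep, neg = sum(!pos_is[idx]),
                                       pos = sum(pos_is[idx]))
      grads <- .backward(params, fw, dlogits, cfg)
      t_step <- t_step + 1L
      # update batch-norm running statistics
      Bn <- nrow(xb)
      for (l in seq_along(params$blocks)) {
        cc <- fw$caches[[l]]
        mom <- cfg$bn_momentum
        params$blocks[[l]]$run_mean <-
          mom * params$blocks[[l]]$run_mean + (1 - mom) * cc$mu
        params$blocks[[l]]$run_var <-
          mom * params$blocks[[l]]$run_var +
          (1 - mom) * cc$v * Bn / max(Bn - 1L, 1L)
      }
      st <- .adamStep(params, grads, m_st, v_st, t_step, cfg)
      params <- st$params; m_st <- st$m; v_st <- st$v
    }
    sc <- .predictCore(params, xt, cfg)
    score <- if (cfg$head == "binary") sc[, 1L] else 1 - sc[, 1L]
    auc <- aurocScore(score, yt_pos)
    hist <- rbind(hist, data.frame(epoch = ep, loss = mean(losses),
                                   test_auroc = auc))
    if (auc > best$auroc) best <- list(auroc = auc, params = params)
  }
  if (batch_log) attr(hist, "batch_composition") <- do.call(rbind, comp)
  new("DenseCircModel", config = cfg, params = best$params,
      feature_names = colnames(x), history = hist)
}

# chunked inference returning probabilities (matrix: 1 col binary, 3 cols
# three-class)
.predictCore <- function(params, x, cfg, chunk = 4096L) {
  n <- nrow(x)
  n_out <- if (cfg$head == "binary") 1L else 3L
  out <- matrix(NA_real_, n, n_out)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    lg <- .forwardInfer(params, x[s:e, , drop = FALSE], cfg)$logits
    out[s:e, ] <- if (cfg$head == "binary") 1 / (1 + exp(-lg))
    else .softmaxRows(lg)
  }
  out
}

#' Predict differential probabilities
#'
#' Deterministic inference (running batch-norm statistics, no dropout).
#'
#' @param model a \code{DenseCircModel}.
#' @param x feature matrix or single named vector conforming to the model's
#'   registry.
#' @return binary head: numeric vector of differential probabilities;
#'   three-class head: matrix with columns \code{unchanged},
#'   \code{higher_in_A}, \code{higher_in_B} (rows sum to 1).
#' @export
predictModel <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, 1L, dimnames = list(NULL, names(x)))
  x <- as.matrix(x)
  if (ncol(x) != length(model@feature_names))
    stop("feature length mismatch: got ", ncol(x), ", model expects ",
         length(model@feature_names))
  if (!is.null(colnames(x)) &&
      !identical(colnames(x), model@feature_names))
    stop("feature names do not match the model registry")
  p <- .predictCore(model@params, x, model@config)
  if (model@config$head == "binary") p[, 1L]
  else {
    colnames(p) <- c("unchanged", "higher_in_A", "higher_in_B")
    p
  }
}

#' Gradient of the model output with respect to the input
#'
#' Backpropagates through the inference-mode network (batch norm as a fixed
#' affine map, no dropout).  For the three-class head the differentiated
#' quantity is by default the pre-softmax logit of \code{class}, for the
#' binary head the sigmoid probability (or the logit).
#'
#' @param model a \code{DenseCircModel}.
#' @param x feature matrix (rows = instances).
#' @param class for the three-class head: 1 = unchanged, 2 = higher_in_A,
#'   3 = higher_in_B.
#' @param value \code{"logit"} or \code{"prob"}.
#' @return matrix of the same shape as \code{x}.
#' @export
inputGradients <- function(model, x, class = 2L,
                           value = c("default", "logit", "prob")) {
  value <- match.arg(value)
  if (is.null(dim(x))) x <- matrix(x, 1L, dimnames = list(NULL, names(x)))
  x <- as.matrix(x)
  cfg <- model@config
  params <- model@params
  fw <- .forwardInfer(params, x, cfg, keep_cache = TRUE)
  n <- nrow(x)
  if (cfg$head == "binary") {
    if (value == "default") value <- "prob"
    dlog <- if (value == "prob") {
      p <- 1 / (1 + exp(-fw$logits[, 1L]))
      matrix(p * (1 - p), ncol = 1L)
    } else matrix(1, n, 1L)
  } else {
    if (value == "default") value <- "logit"
    if (value == "logit") {
      dlog <- matrix(0, n, 3L); dlog[, class] <- 1
    } else {
      P <- .softmaxRows(fw$logits)
      dlog <- -P * P[, class]
      dlog[, class] <- dlog[, class] + P[, class]
    }
  }
  dH <- tcrossprod(dlog, params$out$W)
  for (l in rev(seq_along(params$blocks))) {
    cc <- fw$caches[[l]]
    dA <- dH * cc$M
    dZ <- sweep(dA, 2L, cc$scale, "*")
    dH <- tcrossprod(dZ, params$blocks[[l]]$W)
  }
  dimnames(dH) <- dimnames(x)
  dH
}

#' Model output as a scalar function
#'
#' Convenience wrapper returning F(x) as used in attribution: the
#' differential probability (binary head) or the chosen class's logit or
#' probability (three-class head).
#'
#' @inheritParams inputGradients
#' @return numeric vector, one value per row of \code{x}.
#' @export
modelValue <- function(model, x, class = 2L,
                       value = c("default", "logit", "prob")) {
  value <- match.arg(value)
  if (is.null(dim(x))) x <- matrix(x, 1L, dimnames = list(NULL, names(x)))
  cfg <- model@config
  lg <- .forwardInfer(model@params, as.matrix(x), cfg)$logits
  if (cfg$head == "binary") {
    if (value == "logit") lg[, 1L] else 1 / (1 + exp(-lg[, 1L]))
  } else {
    if (value == "default") value <- "logit"
    if (value == "logit") lg[, class] else .softmaxRows(lg)[, class]
  }
}

#' Area under the ROC curve
#'
#' Mann-Whitney U statistic normalised by the number of
#' positive x negative pairs; ties contribute 1/2 (midranks).
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels logical or 0/1 class labels.
#' @return AUROC in [0,1].
#' @export
aurocScore <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("AUROC needs at least one positive and one negative")
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
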