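# Network: multi-kernel 1-D convolution over one-hot residues with one-max
# pooling, a linear embedding projected onto the unit hypersphere, and one
# MLP classifier branch per hierarchy level.
#
# Because inputs are one-hot, the convolution response of all filters of
# kernel size k at all positions reduces to one dense product
#   M = E %*% W   (E: stacked one-hot rows, W: 20 x (k*F))
# followed by k shifted additions, so the whole forward/backward runs on
# BLAS-backed GEMMs with no deep-learning framework.

#' Model configuration
#'
#' Architecture hyperparameters. Defaults are the full-scale reference
#' configuration: kernel sizes 8..36, 256 filters per kernel size (2048
#' pooled features), a 30-dimensional embedding and 15 hidden units per
#' classifier branch.
#'
#' @param kernel_sizes Integer vector of convolution kernel sizes.
#' @param filters_per_kernel Filters per kernel size.
#' @param embed_dim Embedding dimension d.
#' @param classifier_hidden Hidden units in each classifier branch.
#' @param classifier_l2 L2 penalty weight on classifier-branch weight
#'   matrices (biases and all other layers are unpenalized).
#' @param max_len Fixed encoded sequence length.
#' @param embed_bias Whether the embedding linear layer carries a bias term.
#' @param branches `"all"` for the three-branch model, `"subsubfamily"` for
#'   the single-branch ablation.
#' @return Object of class `hier_model_config`.
#' @export
model_config <- function(kernel_sizes = c(8L, 12L, 16L, 20L, 24L, 28L, 32L, 36L),
                         filters_per_kernel = 256L,
                         embed_dim = 30L,
                         classifier_hidden = 15L,
                         classifier_l2 = 5e-4,
                         max_len = 1000L,
                         embed_bias = TRUE,
                         branches = c("all", "subsubfamily")) {
  branches <- match.arg(branches)
  kernel_sizes <- as.integer(kernel_sizes)
  stopifnot(length(kernel_sizes) >= 1L, all(kernel_sizes >= 1L),
            filters_per_kernel >= 1L, embed_dim >= 1L,
            classifier_hidden >= 1L, classifier_l2 >= 0, max_len >= 1L)
  if (max(kernel_sizes) > max_len) {
    stop("largest kernel size (", max(kernel_sizes),
         ") exceeds encoded length (", max_len, ")")
  }
  structure(
    list(kernel_sizes = kernel_sizes,
         filters_per_kernel = as.integer(filters_per_kernel),
         embed_dim = as.integer(embed_dim),
         classifier_hidden = as.integer(classifier_hidden),
         classifier_l2 = classifier_l2,
         max_len = as.integer(max_len),
         embed_bias = isTRUE(embed_bias),
         branches = branches),
    class = "hier_model_config"
  )
}

#' Number of pooled features produced by the extractor
#' @param config A `hier_model_config`.
#' @return Integer: `filters_per_kernel * length(kernel_sizes)`.
#' @export
n_features <- function(config) {
  config$filters_per_kernel * length(config$kernel_sizes)
}

hier_levels <- function() c("family", "subfamily", "subsubfamily")

active_levels <- function(config) {
  if (config$branches == "all") hier_levels() else "subsubfamily"
}

#' Initialize a model against a label hierarchy
#'
#' He-style Gaussian initialization for convolution and ReLU layers, zero
#' biases; deterministic given `seed`.
#'
#' @param config A `hier_model_config`.
#' @param hierarchy A `hier_table` defining class counts per level.
#' @param seed Integer seed for weight initialization.
#' @return Object of class `hier_model` (config, hierarchy, flat parameter
#'   list).
#' @export
build_model <- function(config, hierarchy, seed = 1L) {
  stopifnot(inherits(config, "hier_model_config"), inherits(hierarchy, "hier_table"))
  FF <- config$filters_per_kernel
  d <- config$embed_dim
  nf <- n_features(config)
  params <- withr::with_seed(seed, {
    p <- list()
    for (k in config$kernel_sizes) {
      p[[paste0("conv_W_k", k)]] <-
        matrix(stats::rnorm(20 * k * FF, sd = sqrt(2 / (k * 20))), nrow = 20)
      p[[paste0("conv_b_k", k)]] <- numeric(FF)
    }
    p$embed_W <- matrix(stats::rnorm(nf * d, sd = sqrt(1 / nf)), nrow = nf)
    p$embed_b <- numeric(d)
    for (lvl in active_levels(config)) {
      C <- length(level_classes(hierarchy, lvl))
      h <- config$classifier_hidden
      p[[paste0("cls_", lvl, "_W1")]] <-
        matrix(stats::rnorm(d * h, sd = sqrt(2 / d)), nrow = d)
      p[[paste0("cls_", lvl, "_b1")]] <- numeric(h)
      p[[paste0("cls_", lvl, "_W2")]] <-
        matrix(stats::rnorm(h * C, sd = sqrt(2 / h)), nrow = h)
      p[[paste0("cls_", lvl, "_b2")]] <- numeric(C)
    }
    p
  })
  structure(list(config = config, hierarchy = hierarchy, params = params),
            class = "hier_model")
}

#' @export
print.hier_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<hier_model> kernels {%s} x %d filters -> %d features -> d=%d, branches: %s\n",
              paste(cfg$kernel_sizes, collapse = ","), cfg$filters_per_kernel,
              n_features(cfg), cfg$embed_dim,
              paste(active_levels(cfg), collapse = "/")))
  invisible(x)
}

# ---- input handling -------------------------------------------------------

# Accepts an integer index matrix (B x L), a single one-hot matrix (L x 20)
# or a list of one-hot matrices; returns a B x L integer index matrix.
as_index_matrix <- function(x, config) {
  L <- config$max_len
  onehot_to_idx <- function(m) {
    stopifnot(ncol(m) == 20L)
    if (nrow(m) != L) stop("encoded length ", nrow(m), " does not match config max_len ", L)
    idx <- max.col(m, ties.method = "first")
    idx[rowSums(m) == 0] <- 0L
    as.integer(idx)
  }
  if (is.list(x)) {
    out <- do.call(rbind, lapply(x, onehot_to_idx))
  } else if (is.matrix(x) && ncol(x) == 20L && !is.integer(x)) {
    out <- matrix(onehot_to_idx(x), nrow = 1L)
  } else {
    out <- x
    if (!is.matrix(out)) out <- matrix(as.integer(out), nrow = 1L)
    if (ncol(out) != L) stop("index matrix has ", ncol(out), " columns; config max_len is ", L)
    storage.mode(out) <- "integer"
  }
  out
}

# Stacked one-hot matrix: row (b-1)*L + p is the one-hot vector of
# position p of sequence b.
onehot_stack <- function(idx) {
  B <- nrow(idx); L <- ncol(idx)
  E <- matrix(0, nrow = B * L, ncol = 20L)
  v <- as.vector(t(idx))   # position-major within each sequence
  nz <- which(v > 0L)
  E[cbind(nz, v[nz])] <- 1
  E
}

# ---- forward --------------------------------------------------------------

# Convolution + ReLU + one-max pooling for one kernel size.
# Returns pooled (B x F) and, when cache=TRUE, what backward needs.
conv_pool_k <- function(W, b, E, B, L, k, cache = FALSE) {
  FF <- length(b)
  M <- E %*% W                               # (B*L) x (k*F)
  total <- B * L
  C <- M[, seq_len(FF), drop = FALSE]
  if (k > 1L) {
    for (j in 2:k) {
      cols <- ((j - 1L) * FF + 1L):(j * FF)
      C[1:(total - j + 1L), ] <- C[1:(total - j + 1L), , drop = FALSE] +
        M[j:total, cols, drop = FALSE]
    }
  }
  P <- L - k + 1L
  valid <- as.vector(outer(seq_len(P), (seq_len(B) - 1L) * L, "+"))
  A <- C[valid, , drop = FALSE] + rep(b, each = length(valid))
  A[A < 0] <- 0                              # ReLU
  # one-max pool over positions: reshape to (B*F) x P
  Dm <- matrix(aperm(array(A, dim = c(P, B, FF)), c(2, 3, 1)), nrow = B * FF)
  mi <- max.col(Dm, ties.method = "first")
  pooled_v <- Dm[cbind(seq_len(B * FF), mi)]
  pooled <- matrix(pooled_v, nrow = B, ncol = FF)
  if (!cache) return(list(pooled = pooled))
  list(pooled = pooled, argmax = mi, P = P, valid = valid)
}

conv_pool_backward_k <- function(W, E, cache, dpooled, B, L, k) {
  FF <- ncol(dpooled)
  P <- cache$P
  total <- B * L
  rbf <- seq_len(B * FF)
  bvec <- ((rbf - 1L) %% B) + 1L
  fvec <- ((rbf - 1L) %/% B) + 1L
  # gradient reaches the pre-ReLU response only where the pooled value is
  # strictly positive (subgradient 0 at exact zero)
  contrib <- as.vector(dpooled) * (as.vector(cache$pooled) > 0)
  dA <- matrix(0, nrow = P * B, ncol = FF)
  dA[cbind(cache$argmax + (bvec - 1L) * P, fvec)] <- contrib
  db <- colSums(dA)
  dC <- matrix(0, nrow = total, ncol = FF)
  dC[cache$valid, ] <- dA
  dM <- matrix(0, nrow = total, ncol = k * FF)
  dM[, seq_len(FF)] <- dC
  if (k > 1L) {
    for (j in 2:k) {
      cols <- ((j - 1L) * FF + 1L):(j * FF)
      dM[j:total, cols] <- dC[1:(total - j + 1L), , drop = FALSE]
    }
  }
  dW <- crossprod(E, dM)
  list(dW = dW, db = db)
}

#' Extract pooled motif features for a batch of encoded sequences
#'
#' For every filter, the output is the maximum over all valid positions of
#' the ReLU-activated convolution response (one-max pooling), concatenated
#' across kernel sizes in the order of `config$kernel_sizes`.
#'
#' @param model A `hier_model`.
#' @param x Encoded input: integer index matrix from [encode_dataset()], a
#'   one-hot matrix from [one_hot_encode()], or a list of one-hot matrices.
#' @return Numeric matrix, one row per sequence, `n_features(config)`
#'   columns, all entries non-negative.
#' @export
extract_features <- function(model, x) {
  stopifnot(inherits(model, "hier_model"))
  idx <- as_index_matrix(x, model$config)
  B <- nrow(idx); L <- ncol(idx)
  E <- onehot_stack(idx)
  blocks <- lapply(model$config$kernel_sizes, function(k) {
    conv_pool_k(model$params[[paste0("conv_W_k", k)]],
                model$params[[paste0("conv_b_k", k)]],
                E, B, L, k)$pooled
  })
  do.call(cbind, blocks)
}

#' Project features onto the unit hypersphere
#'
#' Linear projection to `embed_dim` dimensions followed by L2 normalization,
#' so every embedding has Euclidean norm 1.
#'
#' @param model A `hier_model`.
#' @param features Feature matrix from [extract_features()].
#' @return Matrix of unit-norm embeddings (rows).
#' @export
embed_features <- function(model, features) {
  stopifnot(inherits(model, "hier_model"))
  features <- matrix(features, ncol = n_features(model$config))
  Z0 <- features %*% model$params$embed_W
  if (model$config$embed_bias) Z0 <- sweep(Z0, 2L, model$params$embed_b, "+")
  nrm <- sqrt(rowSums(Z0^2))
  if (any(nrm < 1e-12)) {
    stop("degenerate embedding: pre-normalization norm below 1e-12 for row(s) ",
         paste(which(nrm < 1e-12), collapse = ", "))
  }
  Z0 / nrm
}

#' Classifier-branch logits at one hierarchy level
#'
#' @param model A `hier_model`.
#' @param embeddings Unit-norm embedding matrix.
#' @param level `"family"`, `"subfamily"` or `"subsubfamily"`.
#' @return Logit matrix, one column per class at `level` (columns named).
#' @export
classify <- function(model, embeddings, level) {
  level <- match.arg(level, hier_levels())
  if (!level %in% active_levels(model$config)) {
    stop("branch not present: ", level)
  }
  p <- model$params
  H <- embeddings %*% p[[paste0("cls_", level, "_W1")]]
  H <- sweep(H, 2L, p[[paste0("cls_", level, "_b1")]], "+")
  H[H < 0] <- 0
  logits <- H %*% p[[paste0("cls_", level, "_W2")]]
  logits <- sweep(logits, 2L, p[[paste0("cls_", level, "_b2")]], "+")
  colnames(logits) <- level_classes(model$hierarchy, level)
  logits
}

#' Full forward pass
#'
#' @param model A `hier_model`.
#' @param x Encoded input (see [extract_features()]).
#' @return List with `features`, unit-norm `embeddings`, and `logits` (named
#'   list over the configured branches).
#' @export
forward_model <- function(model, x) {
  feat <- extract_features(model, x)
  Z <- embed_features(model, feat)
  logits <- lapply(stats::setNames(nm = active_levels(model$config)),
                   function(lvl) classify(model, Z, lvl))
  list(features = feat, embeddings = Z, logits = logits)
}

#' Embed a dataset in evaluation mode
#'
#' @param model A `hier_model`.
#' @param dataset A `hier_dataset`, named character vector of sequences, or
#'   a pre-encoded integer index matrix.
#' @param chunk Sequences per forward chunk (memory bound).
#' @return Unit-norm embedding matrix with ids as rownames.
#' @export
embed_dataset <- function(model, dataset, chunk = 256L) {
  idx <- if (is.matrix(dataset) && is.integer(dataset)) dataset
         else encode_dataset(dataset, model$config$max_len)
  B <- nrow(idx)
  out <- matrix(0, nrow = B, ncol = model$config$embed_dim,
                dimnames = list(rownames(idx), NULL))
  for (s in seq(1L, B, by = chunk)) {
    e <- min(B, s + chunk - 1L)
    out[s:e, ] <- embed_features(model, extract_features(model, idx[s:e, , drop = FALSE]))
  }
  out
}

# ---- cached forward/backward for training ---------------------------------

model_forward_cached <- function(model, idx) {
  cfg <- model$config
  B <- nrow(idx); L <- ncol(idx)
  E <- onehot_stack(idx)
  caches <- list()
  blocks <- list()
  for (k in cfg$kernel_sizes) {
    cp <- conv_pool_k(model$params[[paste0("conv_W_k", k)]],
                      model$params[[paste0("conv_b_k", k)]],
                      E, B, L, k, cache = TRUE)
    caches[[as.character(k)]] <- cp
    blocks[[as.character(k)]] <- cp$pooled
  }
  feat <- do.call(cbind, blocks)
  Z0 <- feat %*% model$params$embed_W
  if (cfg$embed_bias) Z0 <- sweep(Z0, 2L, model$params$embed_b, "+")
  nrm <- sqrt(rowSums(Z0^2))
  if (any(nrm < 1e-12)) stop("degenerate embedding during training")
  Z <- Z0 / nrm
  hs <- list(); logits <- list()
  for (lvl in active_levels(cfg)) {
    p <- model$params
    H0 <- sweep(Z %*% p[[paste0("cls_", lvl, "_W1")]], 2L,
                p[[paste0("cls_", lvl, "_b1")]], "+")
    H <- H0; H[H < 0] <- 0
    lg <- sweep(H %*% p[[paste0("cls_", lvl, "_W2")]], 2L,
                p[[paste0("cls_", lvl, "_b2")]], "+")
    hs[[lvl]] <- H
    logits[[lvl]] <- lg
  }
  list(E = E, B = B, L = L, conv = caches, features = feat,
       Z = Z, nrm = nrm, H = hs, logits = logits)
}

# dlogits: named list of already-weighted upstream gradients per level (may
# omit levels); dZ_extra: additional gradient on the normalized embeddings
# (e.g. weighted center-loss term). Returns a flat gradient list aligned
# with model$params.
model_backward <- function(model, cache, dlogits = list(), dZ_extra = NULL) {
  cfg <- model$config
  p <- model$params
  B <- cache$B
  dZ <- if (is.null(dZ_extra)) matrix(0, B, cfg$embed_dim) else dZ_extra
  grads <- list()
  for (lvl in names(dlogits)) {
    dlg <- dlogits[[lvl]]
    H <- cache$H[[lvl]]
    W2 <- p[[paste0("cls_", lvl, "_W2")]]
    grads[[paste0("cls_", lvl, "_W2")]] <- crossprod(H, dlg)
    grads[[paste0("cls_", lvl, "_b2")]] <- colSums(dlg)
    dH <- dlg %*% t(W2)
    dH[H <= 0] <- 0
    W1 <- p[[paste0("cls_", lvl, "_W1")]]
    grads[[paste0("cls_", lvl, "_W1")]] <- crossprod(cache$Z, dH)
    grads[[paste0("cls_", lvl, "_b1")]] <- colSums(dH)
    dZ <- dZ + dH %*% t(W1)
  }
  # through L2 normalization: z = z0/||z0||
  Z <- cache$Z
  dZ0 <- (dZ - Z * rowSums(dZ * Z)) / cache$nrm
  grads$embed_W <- crossprod(cache$features, dZ0)
  if (cfg$embed_bias) grads$embed_b <- colSums(dZ0)
  dFeat <- dZ0 %*% t(p$embed_W)
  FF <- cfg$filters_per_kernel
  for (i in seq_along(cfg$kernel_sizes)) {
    k <- cfg$kernel_sizes[i]
    cols <- ((i - 1L) * FF + 1L):(i * FF)
    cb <- conv_pool_backward_k(p[[paste0("conv_W_k", k)]], cache$E,
                               cache$conv[[as.character(k)]],
                               dFeat[, cols, drop = FALSE],
                               cache$B, cache$L, k)
    grads[[paste0("conv_W_k", k)]] <- cb$dW
    grads[[paste0("conv_b_k", k)]] <- cb$db
  }
  grads
}
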