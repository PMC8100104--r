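# Training objective: per-level softmax cross-entropy plus per-level center
# loss, combined as a weighted sum
#   L = sum_i w_S[i] * L_S[i] + lambda_C * sum_i w_C[i] * L_C[i]
# over the three hierarchy levels. Cross-entropy is averaged over the batch;
# center loss is the batch *sum* of squared Euclidean distances between each
# embedding and its class's mean embedding, with class means recomputed from
# the whole training set (not mini-batches) and treated as constants inside
# a batch.

softmax_rows <- function(logits) {
  m <- apply(logits, 1L, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

#' Softmax cross-entropy at one hierarchy level
#'
#' Mean over the batch of the negative log softmax probability of the true
#' class.
#'
#' @param logits Numeric matrix, one row per item, one column per class.
#' @param labels Integer class indices (1-based) or character class names
#'   matching `colnames(logits)`.
#' @return Non-negative scalar.
#' @export
cross_entropy_level <- function(logits, labels) {
  logits <- as.matrix(logits)
  if (is.character(labels) || is.factor(labels)) {
    labels <- match(as.character(labels), colnames(logits))
    if (anyNA(labels)) stop("label not among logit columns")
  }
  labels <- as.integer(labels)
  if (length(labels) != nrow(logits)) stop("logits and labels differ in batch size")
  if (any(labels < 1L | labels > ncol(logits))) {
    stop("label index out of range 1..", ncol(logits))
  }
  P <- softmax_rows(logits)
  -mean(log(P[cbind(seq_len(nrow(P)), labels)]))
}

# gradient of batch-mean cross-entropy w.r.t. logits
cross_entropy_grad <- function(logits, labels) {
  P <- softmax_rows(as.matrix(logits))
  P[cbind(seq_len(nrow(P)), as.integer(labels))] <-
    P[cbind(seq_len(nrow(P)), as.integer(labels))] - 1
  P / nrow(P)
}

#' Center loss at one hierarchy level
#'
#' Sum over the batch of the squared Euclidean distance between each
#' embedding and the center (mean embedding) of its class:
#' `sum_i || z_i - mu_{y_i} ||^2`.
#'
#' @param embeddings Embedding matrix, one row per item.
#' @param labels Character class names (or factor) at this level.
#' @param centers Numeric matrix of class centers with rownames naming the
#'   classes, same number of columns as `embeddings`.
#' @return Non-negative scalar; zero iff every embedding equals its center.
#' @export
center_loss_level <- function(embeddings, labels, centers) {
  embeddings <- as.matrix(embeddings)
  labels <- as.character(labels)
  if (length(labels) != nrow(embeddings)) stop("embeddings and labels differ in batch size")
  missing <- setdiff(unique(labels), rownames(centers))
  if (length(missing) > 0L) {
    stop("no center for class(es): ", paste(missing, collapse = ", "))
  }
  diff <- embeddings - centers[labels, , drop = FALSE]
  sum(diff^2)
}

# gradient of center loss w.r.t. embeddings: 2 (z - mu)
center_loss_grad <- function(embeddings, labels, centers) {
  2 * (as.matrix(embeddings) - centers[as.character(labels), , drop = FALSE])
}

#' Per-phase loss weights
#'
#' One curriculum phase: the center-loss balance `lambda_c` and the
#' per-level weights on cross-entropy (`w_s`) and center loss (`w_c`), plus
#' an epoch budget.
#'
#' @param name Phase name (the level it emphasizes).
#' @param lambda_c Weight on the summed center-loss term.
#' @param w_s,w_c Named numeric vectors with entries `family`, `subfamily`,
#'   `subsubfamily`; all weights must be non-negative.
#' @param epochs Epoch budget for this phase (>= 0).
#' @return Object of class `phase_config`.
#' @export
phase_config <- function(name, lambda_c, w_s, w_c, epochs) {
  lv <- hier_levels()
  stopifnot(lambda_c >= 0, epochs >= 0,
            all(lv %in% names(w_s)), all(lv %in% names(w_c)),
            all(w_s >= 0), all(w_c >= 0))
  structure(list(name = name, lambda_c = lambda_c,
                 w_s = w_s[lv], w_c = w_c[lv], epochs = as.integer(epochs)),
            class = "phase_config")
}

#' Default three-phase curriculum weights
#'
#' The reference schedule: phase 1 emphasizes the family level, phase 2 the
#' subfamily level, phase 3 the sub-subfamily level, with the center-loss
#' balance growing 0.01 -> 0.3 -> 0.5 as training moves to finer classes.
#'
#' @param epochs Integer vector of per-phase epoch budgets (default
#'   `c(30, 30, 40)`).
#' @return List of three `phase_config` objects, ordered family ->
#'   subfamily -> sub-subfamily.
#' @export
default_phase_configs <- function(epochs = c(30L, 30L, 40L)) {
  stopifnot(length(epochs) == 3L)
  lv <- hier_levels()
  list(
    phase_config("family", 0.01,
                 w_s = stats::setNames(c(0.8, 0.15, 0.05), lv),
                 w_c = stats::setNames(c(0.8, 0.15, 0.05), lv),
                 epochs = epochs[1]),
    phase_config("subfamily", 0.3,
                 w_s = stats::setNames(c(0.1, 0.8, 0.1), lv),
                 w_c = stats::setNames(c(0.1, 0.8, 0.1), lv),
                 epochs = epochs[2]),
    phase_config("subsubfamily", 0.5,
                 w_s = stats::setNames(c(0.1, 0.25, 0.65), lv),
                 w_c = stats::setNames(c(0.1, 0.15, 0.75), lv),
                 epochs = epochs[3])
  )
}

#' Weighted total loss
#'
#' `L = sum_i w_s[i] * ls[i] + lambda_c * sum_i w_c[i] * lc[i]`, linear in
#' every component. With `lambda_c = 0` this is the no-center-loss ablation.
#'
#' @param ls Named numeric vector of per-level cross-entropy losses.
#' @param lc Named numeric vector of per-level center losses.
#' @param phase A `phase_config`.
#' @return Scalar total loss.
#' @export
total_loss <- function(ls, lc, phase) {
  stopifnot(inherits(phase, "phase_config"))
  lv <- hier_levels()
  ls <- ls[lv]; lc <- lc[lv]
  if (anyNA(ls) || anyNA(lc) || any(!is.finite(c(ls, lc)))) {
    stop("all six component losses must be finite")
  }
  if (any(c(ls, lc) < 0)) stop("negative component loss")
  sum(phase$w_s * ls) + phase$lambda_c * sum(phase$w_c * lc)
}

#' Recompute class centers from the whole training set
#'
#' Runs the model in evaluation mode over every training sequence and
#' returns, for each hierarchy level, the arithmetic mean embedding of every
#' class.
#'
#' @param model A `hier_model`.
#' @param idx Encoded training set (integer index matrix with ids as
#'   rownames) or a `hier_dataset`.
#' @param labels Data frame with columns `family`, `subfamily`,
#'   `subsubfamily` aligned to the rows of `idx`; taken from the dataset if
#'   `idx` is a `hier_dataset`.
#' @return Named list over levels; each element a class-by-`embed_dim`
#'   matrix with class rownames.
#' @export
update_centers <- function(model, idx, labels = NULL) {
  if (inherits(idx, "hier_dataset")) {
    labels <- idx$labels
    idx <- encode_dataset(idx, model$config$max_len)
  }
  stopifnot(!is.null(labels), nrow(labels) == nrow(idx))
  Z <- embed_dataset(model, idx)
  centers_from_embeddings(Z, labels)
}

#' Group-mean centers from precomputed embeddings
#'
#' @param embeddings Embedding matrix, one row per item.
#' @param labels Data frame with the three level columns.
#' @return As [update_centers()].
#' @export
centers_from_embeddings <- function(embeddings, labels) {
  out <- list()
  for (lvl in hier_levels()) {
    f <- factor(labels[[lvl]])
    if (any(table(f) == 0L)) stop("class with zero members at level ", lvl)
    M <- rowsum(embeddings, f) / as.vector(table(f))
    out[[lvl]] <- M
  }
  out
}
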