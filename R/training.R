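# Three-phase curriculum training. Each phase uses its own loss weights;
# class centers are initialized from a full forward pass before the first
# phase and recomputed from the whole training set after every epoch (they
# are constants within a batch: no gradient flows into the centers).

#' Stratified train/validation/test split
#'
#' Splits sequence ids within every subfamily class using the given ratios.
#' Within a class, counts are `floor(n * ratio)` with remaining items
#' assigned by largest fractional remainder (ties resolved in
#' train/validation/test order), so a class of 10 splits 8/1/1 under the
#' default ratios. Deterministic given `seed`.
#'
#' @param dataset A labeled `hier_dataset`.
#' @param ratios Length-3 numeric vector summing to 1 (train, validation,
#'   test).
#' @param seed Integer seed.
#' @return Named list of three `hier_dataset`s: `train`, `validation`,
#'   `test` (pairwise disjoint, jointly exhaustive).
#' @export
split_dataset <- function(dataset, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(inherits(dataset, "hier_dataset"), !is.null(dataset$labels),
            length(ratios) == 3L, all(ratios >= 0),
            abs(sum(ratios) - 1) < 1e-8)
  labels <- dataset$labels
  parts <- list(train = character(0), validation = character(0), test = character(0))
  withr::with_seed(seed, {
    for (cls in sort(unique(labels$subfamily))) {
      ids <- labels$id[labels$subfamily == cls]
      n <- length(ids)
      base <- floor(n * ratios)
      rem <- n - sum(base)
      if (rem > 0L) {
        frac <- n * ratios - base
        extra <- order(frac, decreasing = TRUE)[seq_len(rem)]
        base[extra] <- base[extra] + 1L
      }
      if (any(base == 0L & ratios > 0)) {
        stop("subfamily class too small to populate every split: ", cls,
             " (n = ", n, ")")
      }
      ids <- sample(ids)
      cut <- cumsum(base)
      parts$train <- c(parts$train, ids[seq_len(cut[1])])
      parts$validation <- c(parts$validation,
                            if (base[2] > 0) ids[(cut[1] + 1L):cut[2]] else character(0))
      parts$test <- c(parts$test,
                      if (base[3] > 0) ids[(cut[2] + 1L):cut[3]] else character(0))
    }
  })
  lapply(parts, function(ids) subset_dataset(dataset, ids))
}

# ---- Adam optimizer -------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

# ---- training -------------------------------------------------------------

label_indices <- function(labels, hierarchy) {
  lapply(stats::setNames(nm = hier_levels()), function(lvl) {
    cls <- level_classes(hierarchy, lvl)
    i <- match(labels[[lvl]], cls)
    if (anyNA(i)) stop("label outside training hierarchy at level ", lvl)
    i
  })
}

eval_accuracy_idx <- function(model, idx, lab_idx, level) {
  Z <- embed_dataset(model, idx)
  lg <- classify(model, Z, level)
  mean(max.col(lg, ties.method = "first") == lab_idx[[level]])
}

#' Train the hierarchical embedding model
#'
#' Runs the three curriculum phases in order (family -> subfamily ->
#' sub-subfamily), each phase weighting the per-level cross-entropy and
#' center losses by its `phase_config`. Class centers are initialized from a
#' full forward pass before phase 1 and recomputed from the whole training
#' set after every epoch. The returned model is the checkpoint with the best
#' validation sub-subfamily accuracy (the final parameters if no validation
#' set is given). Fully deterministic given `seed` on a fixed platform.
#'
#' @param train A labeled `hier_dataset` (training split).
#' @param validation Optional labeled `hier_dataset` for checkpoint
#'   selection; its labels must be classes of the training hierarchy.
#' @param config A `hier_model_config`.
#' @param phases List of `phase_config`s, ordered family -> subfamily ->
#'   sub-subfamily (see [default_phase_configs()]).
#' @param lr Adam learning rate.
#' @param batch_size Mini-batch size.
#' @param seed Integer seed (weights and batch shuffling).
#' @param no_center_loss Ablation: train with the center-loss weight
#'   `lambda_c` forced to 0 in every phase.
#' @param single_branch Ablation: keep only the sub-subfamily classifier
#'   branch (all three center-loss terms are retained).
#' @param center_batch_mean If `TRUE` (default) the center-loss terms are
#'   averaged over the batch inside the training objective, putting them on
#'   the same per-sequence scale as the cross-entropy terms so the reference
#'   phase weights balance the two as intended; [center_loss_level()] itself
#'   remains a batch sum. Set `FALSE` to optimize the raw batch-sum.
#' @return Object of class `hier_train`: `model` (best checkpoint),
#'   `final_model`, `report` (per-epoch data frame of loss components and
#'   validation accuracies), `best` (phase/epoch/accuracy of the selected
#'   checkpoint) and `centers` (class centers of the final model).
#' @export
train_model <- function(train, validation = NULL,
                        config = model_config(),
                        phases = default_phase_configs(),
                        lr = 0.001, batch_size = 64L, seed = 1L,
                        no_center_loss = FALSE, single_branch = FALSE,
                        center_batch_mean = TRUE) {
  stopifnot(inherits(train, "hier_dataset"), !is.null(train$labels))
  if (is.null(phases) || length(phases) == 0L) stop("no training phases given")
  stopifnot(all(vapply(phases, inherits, logical(1), "phase_config")))
  if (single_branch) config$branches <- "subsubfamily"

  hierarchy <- train$hierarchy
  idx_tr <- encode_dataset(train, config$max_len)
  lab_tr <- label_indices(train$labels, hierarchy)
  lab_tr_chr <- lapply(stats::setNames(nm = hier_levels()),
                       function(lvl) train$labels[[lvl]])
  has_val <- !is.null(validation)
  if (has_val) {
    idx_va <- encode_dataset(validation, config$max_len)
    lab_va <- label_indices(validation$labels, hierarchy)
  }

  model <- build_model(config, hierarchy, seed)
  opt <- adam_init(model$params)
  lv <- hier_levels()
  act <- active_levels(config)
  B <- nrow(idx_tr)

  centers <- update_centers(model, idx_tr, train$labels)
  best <- list(acc = -Inf, params = model$params, phase = NA_character_,
               epoch = NA_integer_)
  rows <- list()

  withr::with_seed(seed + 1L, {
    for (phase in phases) {
      lambda_eff <- if (no_center_loss) 0 else phase$lambda_c
      eff <- phase; eff$lambda_c <- lambda_eff
      if (phase$epochs == 0L) next
      for (epoch in seq_len(phase$epochs)) {
        ord <- sample.int(B)
        starts <- seq(1L, B, by = batch_size)
        tot_acc <- 0; ls_acc <- stats::setNames(numeric(3), lv)
        lc_acc <- stats::setNames(numeric(3), lv)
        for (s in starts) {
          rows_b <- ord[s:min(B, s + batch_size - 1L)]
          fwd <- model_forward_cached(model, idx_tr[rows_b, , drop = FALSE])
          ls <- stats::setNames(numeric(3), lv)
          dlogits <- list()
          for (l in act) {
            ls[[l]] <- cross_entropy_level(fwd$logits[[l]], lab_tr[[l]][rows_b])
            if (eff$w_s[[l]] > 0) {
              dlogits[[l]] <- eff$w_s[[l]] *
                cross_entropy_grad(fwd$logits[[l]], lab_tr[[l]][rows_b])
            }
          }
          lc <- stats::setNames(numeric(3), lv)
          dZ_extra <- NULL
          nB <- length(rows_b)
          cscale <- if (center_batch_mean) 1 / nB else 1
          for (l in lv) {
            lc[[l]] <- cscale * center_loss_level(fwd$Z, lab_tr_chr[[l]][rows_b],
                                                  centers[[l]])
          }
          if (lambda_eff > 0) {
            dZ_extra <- matrix(0, nrow(fwd$Z), ncol(fwd$Z))
            for (l in lv) {
              if (eff$w_c[[l]] > 0) {
                dZ_extra <- dZ_extra + (lambda_eff * eff$w_c[[l]] * cscale) *
                  center_loss_grad(fwd$Z, lab_tr_chr[[l]][rows_b], centers[[l]])
              }
            }
          }
          tot <- total_loss(ls, lc, eff)
          if (!is.finite(tot)) {
            stop("non-finite training loss at phase ", phase$name, " epoch ",
                 epoch, " (ce = ", paste(signif(ls, 4), collapse = "/"),
                 ", center = ", paste(signif(lc, 4), collapse = "/"), ")")
          }
          grads <- model_backward(model, fwd, dlogits, dZ_extra)
          if (config$classifier_l2 > 0) {
            for (l in names(dlogits)) {
              for (w in c("_W1", "_W2")) {
                nm <- paste0("cls_", l, w)
                grads[[nm]] <- grads[[nm]] + 2 * config$classifier_l2 * model$params[[nm]]
              }
            }
          }
          upd <- adam_step(model$params, grads, opt, lr)
          model$params <- upd$params
          opt <- upd$state
          w <- length(rows_b) / B
          tot_acc <- tot_acc + tot * w
          ls_acc <- ls_acc + ls * w
          lc_acc <- lc_acc + lc * w
        }
        centers <- update_centers(model, idx_tr, train$labels)
        rec <- as.list(c(total_loss = tot_acc,
                         stats::setNames(ls_acc, paste0("ce_", lv)),
                         stats::setNames(lc_acc, paste0("center_", lv))))
        rec <- c(list(phase = phase$name, epoch = epoch), rec)
        if (has_val) {
          for (l in act) {
            rec[[paste0("val_acc_", l)]] <- eval_accuracy_idx(model, idx_va, lab_va, l)
          }
          acc_sel <- rec[["val_acc_subsubfamily"]]
          # ties resolve to the most recent epoch: later checkpoints have
          # more compact class geometry under the center loss
          if (!is.null(acc_sel) && acc_sel >= best$acc) {
            best <- list(acc = acc_sel, params = model$params,
                         phase = phase$name, epoch = epoch)
          }
        }
        rows[[length(rows) + 1L]] <- rec
      }
    }
  })

  report <- if (length(rows) > 0L) {
    do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  } else {
    data.frame()
  }
  final_model <- model
  if (has_val && is.finite(best$acc)) {
    model$params <- best$params
  }
  structure(
    list(model = model, final_model = final_model, report = report,
         best = if (has_val) best[c("acc", "phase", "epoch")] else NULL,
         centers = centers),
    class = "hier_train"
  )
}

#' @export
print.hier_train <- function(x, ...) {
  cat(sprintf("<hier_train> %d epochs run%s\n", nrow(x$report),
              if (!is.null(x$best) && is.finite(x$best$acc)) {
                sprintf("; best val sub-subfamily accuracy %.3f (phase %s, epoch %d)",
                        x$best$acc, x$best$phase, x$best$epoch)
              } else ""))
  invisible(x)
}

#' Classification accuracy of a model at one hierarchy level
#'
#' Fraction of sequences whose argmax logit matches the true class.
#'
#' @param model A `hier_model`.
#' @param dataset A labeled `hier_dataset`.
#' @param level `"family"`, `"subfamily"` or `"subsubfamily"`.
#' @return Fraction in `[0, 1]`.
#' @export
evaluate_accuracy <- function(model, dataset, level) {
  stopifnot(inherits(dataset, "hier_dataset"), !is.null(dataset$labels))
  if (length(dataset) == 0L) stop("empty dataset")
  level <- match.arg(level, hier_levels())
  Z <- embed_dataset(model, dataset)
  lg <- classify(model, Z, level)
  pred <- colnames(lg)[max.col(lg, ties.method = "first")]
  mean(pred == dataset$labels[[level]])
}
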