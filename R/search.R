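# Similarity search: the training set is embedded once into a database of
# unit-norm vectors; queries are embedded with the same model and answered
# by exact nearest-neighbor retrieval under Euclidean distance (no
# approximate index — distances are cheap in the low-dimensional space).

model_fingerprint <- function(model) {
  # a deserialized checkpoint carries the fingerprint it was saved with
  if (!is.null(model$fingerprint)) return(model$fingerprint)
  rlang::hash(list(config = model$config, params = model$params))
}

#' Build an embedding database from a trained model
#'
#' Embeds every (labeled) sequence once in evaluation mode and stores the
#' model fingerprint so queries can verify they are embedded by the same
#' checkpoint.
#'
#' @param model A trained `hier_model`.
#' @param dataset A labeled `hier_dataset` (typically the training split).
#' @return Object of class `embed_db`: `ids`, unit-norm `embeddings`
#'   matrix, `labels` data frame, `fingerprint`.
#' @export
build_database <- function(model, dataset) {
  stopifnot(inherits(model, "hier_model"), inherits(dataset, "hier_dataset"))
  if (is.null(dataset$labels)) stop("database sequences must be labeled")
  Z <- embed_dataset(model, dataset)
  structure(
    list(ids = names(dataset$sequences), embeddings = Z,
         labels = dataset$labels, fingerprint = model_fingerprint(model)),
    class = "embed_db"
  )
}

#' @export
print.embed_db <- function(x, ...) {
  cat(sprintf("<embed_db> %d sequences, d = %d\n", length(x$ids),
              ncol(x$embeddings)))
  invisible(x)
}

#' Save an embedding database as plain text
#'
#' Writes `embeddings.tsv`, `labels.tsv` and `meta.json` (fingerprint and
#' dimensions) into `dir`.
#'
#' @param db An `embed_db`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_database <- function(db, dir) {
  stopifnot(inherits(db, "embed_db"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_embeddings(db$ids, db$embeddings, file.path(dir, "embeddings.tsv"))
  utils::write.table(db$labels, file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(fingerprint = db$fingerprint, n = length(db$ids),
         d = ncol(db$embeddings)),
    file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Load an embedding database saved by [save_database()]
#'
#' @param dir Directory written by [save_database()].
#' @return An `embed_db`.
#' @export
load_database <- function(dir) {
  Z <- read_embeddings(file.path(dir, "embeddings.tsv"))
  labels <- utils::read.delim(file.path(dir, "labels.tsv"),
                              colClasses = "character")
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  structure(
    list(ids = rownames(Z), embeddings = Z, labels = labels,
         fingerprint = meta$fingerprint),
    class = "embed_db"
  )
}

# Squared Euclidean distances between rows of Q and rows of X.
cross_distances <- function(Q, X) {
  d2 <- outer(rowSums(Q^2), rowSums(X^2), "+") - 2 * tcrossprod(Q, X)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' Nearest-neighbor query against an embedding database
#'
#' Embeds the query sequences with `model` (whose fingerprint must match the
#' database) and returns the `k` nearest database entries per query by
#' Euclidean distance, ties broken by database id order.
#'
#' @param db An `embed_db`.
#' @param model The `hier_model` that built the database.
#' @param queries Named character vector of sequences or a `hier_dataset`.
#' @param k Number of hits per query (capped at the database size).
#' @return Data frame with columns `query_id`, `rank`, `hit_id`,
#'   `distance`, `family`, `subfamily`, `subsubfamily`.
#' @export
query_database <- function(db, model, queries, k = 5L) {
  stopifnot(inherits(db, "embed_db"), k >= 1L)
  if (!identical(model_fingerprint(model), db$fingerprint)) {
    stop("model fingerprint does not match the database")
  }
  if (inherits(queries, "hier_dataset")) queries <- queries$sequences
  Zq <- embed_dataset(model, queries)
  k <- min(k, length(db$ids))
  D <- cross_distances(Zq, db$embeddings)
  lab <- db$labels[match(db$ids, db$labels$id), , drop = FALSE]
  out <- vector("list", nrow(D))
  for (i in seq_len(nrow(D))) {
    o <- order(D[i, ], seq_along(db$ids))[seq_len(k)]
    out[[i]] <- data.frame(
      query_id = names(queries)[i], rank = seq_len(k), hit_id = db$ids[o],
      distance = D[i, o], family = lab$family[o], subfamily = lab$subfamily[o],
      subsubfamily = lab$subsubfamily[o], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-level retrieval accuracy by nearest-neighbor label transfer
#'
#' For each labeled query, the label of the rank-1 hit (or, with `k > 1` and
#' `vote = TRUE`, the majority label among the top k hits) is compared with
#' the query's true class at `level`.
#'
#' @param db An `embed_db`.
#' @param model The `hier_model` that built the database.
#' @param queries A labeled `hier_dataset`, disjoint from the database.
#' @param level `"family"`, `"subfamily"` or `"subsubfamily"`.
#' @param k Hits considered per query (default 1: plain label transfer).
#' @param vote If `TRUE`, use majority vote over the top `k` hits (ties go
#'   to the nearer hit).
#' @return Fraction in `[0, 1]`.
#' @export
retrieval_accuracy <- function(db, model, queries, level, k = 1L, vote = FALSE) {
  stopifnot(inherits(queries, "hier_dataset"), !is.null(queries$labels))
  if (length(queries) == 0L) stop("empty query set")
  level <- match.arg(level, hier_levels())
  hits <- query_database(db, model, queries, k = k)
  truth <- stats::setNames(queries$labels[[level]], queries$labels$id)
  pred <- vapply(split(hits, hits$query_id), function(h) {
    h <- h[order(h$rank), , drop = FALSE]
    if (!vote || nrow(h) == 1L) return(h[[level]][1])
    tab <- table(h[[level]])
    winners <- names(tab)[tab == max(tab)]
    h[[level]][h[[level]] %in% winners][1]
  }, character(1))
  mean(pred == truth[names(pred)])
}
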