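#' Standard amino-acid alphabet used for one-hot encoding
#'
#' The 20 standard amino acids in fixed alphabetical one-letter order.
#' Column `j` of every one-hot matrix produced by [one_hot_encode()]
#' corresponds to `aa_alphabet()[j]`.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() {
  strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
}

#' Read protein sequences from a FASTA file
#'
#' Reads amino-acid FASTA via Biostrings. The header token before the first
#' whitespace becomes the sequence id. Ids must be unique and every record
#' must have at least one residue.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of residue strings (names are ids), in
#'   file order. An empty file yields `character(0)`.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) return(stats::setNames(character(0), character(0)))
  ids <- sub("\\s.*$", "", names(set))
  widths <- Biostrings::width(set)
  if (any(widths == 0L)) {
    stop("FASTA record with empty sequence: ",
         paste(ids[widths == 0L], collapse = ", "))
  }
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate sequence id(s) in FASTA: ", paste(unique(dup), collapse = ", "))
  }
  stats::setNames(as.character(set), ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of residue strings.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# ---- hierarchy table ------------------------------------------------------

#' Build and validate a three-level hierarchy table
#'
#' Constructs the global label tree from per-sequence label triples and
#' checks parent consistency: every sub-subfamily must map to exactly one
#' subfamily, and every subfamily to exactly one family.
#'
#' @param labels Data frame with columns `family`, `subfamily`,
#'   `subsubfamily` (one row per sequence; an `id` column is allowed and
#'   ignored here).
#' @return Object of class `hier_table` with per-level class vectors,
#'   child-to-parent maps and per-sub-subfamily sequence counts.
#' @export
hier_table <- function(labels) {
  req <- c("family", "subfamily", "subsubfamily")
  if (!all(req %in% names(labels))) {
    stop("label table must have columns family, subfamily, subsubfamily")
  }
  if (nrow(labels) == 0L) stop("empty label set")
  labels[req] <- lapply(labels[req], as.character)
  if (anyNA(labels[req]) || any(unlist(labels[req]) == "")) {
    stop("all three hierarchy levels must be present for every sequence")
  }

  pair_ss <- unique(labels[c("subsubfamily", "subfamily")])
  bad <- pair_ss$subsubfamily[duplicated(pair_ss$subsubfamily)]
  if (length(bad) > 0L) {
    stop("sub-subfamily assigned to more than one subfamily: ",
         paste(unique(bad), collapse = ", "))
  }
  pair_sf <- unique(labels[c("subfamily", "family")])
  bad <- pair_sf$subfamily[duplicated(pair_sf$subfamily)]
  if (length(bad) > 0L) {
    stop("subfamily assigned to more than one family: ",
         paste(unique(bad), collapse = ", "))
  }

  subsub <- sort(unique(labels$subsubfamily))
  subfam <- sort(unique(labels$subfamily))
  fam <- sort(unique(labels$family))
  parent_subfamily <- stats::setNames(pair_ss$subfamily, pair_ss$subsubfamily)[subsub]
  parent_family <- stats::setNames(pair_sf$family, pair_sf$subfamily)[subfam]
  counts <- table(factor(labels$subsubfamily, levels = subsub))

  structure(
    list(
      families = fam,
      subfamilies = subfam,
      subsubfamilies = subsub,
      parent_subfamily = parent_subfamily,
      parent_family = parent_family,
      counts = stats::setNames(as.integer(counts), subsub)
    ),
    class = "hier_table"
  )
}

#' @export
print.hier_table <- function(x, ...) {
  cat(sprintf("<hier_table> %d families / %d subfamilies / %d sub-subfamilies, %d sequences\n",
              length(x$families), length(x$subfamilies), length(x$subsubfamilies),
              sum(x$counts)))
  invisible(x)
}

#' Classes available at a hierarchy level
#'
#' @param hierarchy A `hier_table`.
#' @param level One of `"family"`, `"subfamily"`, `"subsubfamily"`.
#' @return Character vector of class names at that level.
#' @export
level_classes <- function(hierarchy, level) {
  level <- match.arg(level, c("family", "subfamily", "subsubfamily"))
  switch(level,
         family = hierarchy$families,
         subfamily = hierarchy$subfamilies,
         subsubfamily = hierarchy$subsubfamilies)
}

# ---- labeled dataset ------------------------------------------------------

#' Construct a labeled hierarchical sequence dataset
#'
#' @param seqs Named character vector of residue strings.
#' @param labels Data frame with columns `id`, `family`, `subfamily`,
#'   `subsubfamily`, or `NULL` for an unlabeled set.
#' @return Object of class `hier_dataset`: sequences, label table aligned to
#'   sequence order, and a validated `hier_table` (both `NULL` if unlabeled).
#' @export
hier_dataset <- function(seqs, labels = NULL) {
  ids <- names(seqs)
  if (is.null(ids) || any(ids == "") || anyNA(ids)) stop("sequences must be named by id")
  if (anyDuplicated(ids)) stop("duplicate sequence ids")
  if (any(nchar(seqs) == 0L)) stop("zero-length sequence present")
  hierarchy <- NULL
  if (!is.null(labels)) {
    if (!"id" %in% names(labels)) stop("label table must have an id column")
    labels$id <- as.character(labels$id)
    missing <- setdiff(ids, labels$id)
    if (length(missing) > 0L) {
      stop("sequence id(s) missing from label table: ",
           paste(missing, collapse = ", "))
    }
    labels <- labels[match(ids, labels$id), c("id", "family", "subfamily", "subsubfamily")]
    rownames(labels) <- NULL
    hierarchy <- hier_table(labels)
  }
  structure(list(sequences = seqs, labels = labels, hierarchy = hierarchy),
            class = "hier_dataset")
}

#' @export
print.hier_dataset <- function(x, ...) {
  cat(sprintf("<hier_dataset> %d sequences (%s)\n", length(x$sequences),
              if (is.null(x$labels)) "unlabeled" else "labeled"))
  if (!is.null(x$hierarchy)) print(x$hierarchy)
  invisible(x)
}

#' @export
length.hier_dataset <- function(x) length(x$sequences)

#' Subset a dataset by sequence id
#'
#' @param dataset A `hier_dataset`.
#' @param ids Character vector of ids to keep (order preserved).
#' @return A `hier_dataset` restricted to `ids`, hierarchy rebuilt.
#' @export
subset_dataset <- function(dataset, ids) {
  stopifnot(inherits(dataset, "hier_dataset"))
  missing <- setdiff(ids, names(dataset$sequences))
  if (length(missing) > 0L) stop("unknown id(s): ", paste(missing, collapse = ", "))
  seqs <- dataset$sequences[ids]
  labels <- if (is.null(dataset$labels)) NULL else
    dataset$labels[match(ids, dataset$labels$id), , drop = FALSE]
  hier_dataset(seqs, labels)
}

#' Read a hierarchical label table and attach it to sequences
#'
#' The label file is tab-separated with a header row and columns
#' `id`, `family`, `subfamily`, `subsubfamily`. Ids must exactly match the
#' FASTA ids; rows for ids not present in `seqs` are ignored.
#'
#' @param path Path to the label TSV.
#' @param seqs Named character vector from [read_fasta()].
#' @return A labeled `hier_dataset` with a validated hierarchy.
#' @export
read_labels <- function(path, seqs) {
  stopifnot(file.exists(path))
  tab <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  req <- c("id", "family", "subfamily", "subsubfamily")
  if (!all(req %in% names(tab))) {
    stop("label TSV must have columns: ", paste(req, collapse = ", "))
  }
  hier_dataset(seqs, tab[req])
}

#' Write a dataset's label table as TSV
#'
#' @param dataset A labeled `hier_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(dataset, path) {
  stopifnot(inherits(dataset, "hier_dataset"), !is.null(dataset$labels))
  utils::write.table(dataset$labels, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Remove sub-subfamily classes with too few sequences
#'
#' Drops every sequence whose sub-subfamily has fewer than `min_count`
#' members and rebuilds the hierarchy, so subfamilies or families left
#' without children disappear. Applying the filter twice is a no-op.
#'
#' @param dataset A labeled `hier_dataset`.
#' @param min_count Minimum class size to keep (default 10, the standard
#'   small-class cutoff for hierarchical family benchmarks).
#' @return Filtered `hier_dataset`.
#' @export
filter_small_classes <- function(dataset, min_count = 10L) {
  stopifnot(inherits(dataset, "hier_dataset"), !is.null(dataset$labels),
            min_count >= 1L)
  counts <- dataset$hierarchy$counts
  keep_classes <- names(counts)[counts >= min_count]
  keep <- dataset$labels$subsubfamily %in% keep_classes
  if (!any(keep)) stop("no class has at least ", min_count, " sequences")
  hier_dataset(dataset$sequences[keep], dataset$labels[keep, , drop = FALSE])
}

# ---- encoding -------------------------------------------------------------

#' Encode residues as integer alphabet indices
#'
#' Internal fast path equivalent to the one-hot representation: position i
#' holds the 1-based index of residue i in [aa_alphabet()], 0 for padding or
#' non-standard residues.
#'
#' @param residues Residue string.
#' @param max_len Fixed encoded length.
#' @return Integer vector of length `max_len`.
#' @keywords internal
encode_indices <- function(residues, max_len) {
  chars <- strsplit(residues, "")[[1]]
  if (length(chars) > max_len) {
    warning("sequence of length ", length(chars), " truncated to ", max_len)
    chars <- chars[seq_len(max_len)]
  }
  idx <- match(chars, aa_alphabet())
  idx[is.na(idx)] <- 0L
  out <- integer(max_len)
  out[seq_along(idx)] <- idx
  out
}

#' One-hot encode a protein sequence
#'
#' Produces the fixed-size binary matrix fed to the feature extractor: row i
#' is the one-hot vector of residue i over [aa_alphabet()]; rows past the
#' sequence end are zero (padding), as are rows for non-standard residues
#' (B, J, O, U, X, Z). Sequences longer than `max_len` are truncated with a
#' warning.
#'
#' @param residues Residue string (or a single-element named vector).
#' @param max_len Fixed encoded length (default 1000).
#' @return `max_len` x 20 matrix of 0/1 with columns named by the alphabet.
#' @export
#' @examples
#' m <- one_hot_encode("ACDW", max_len = 10)
#' sum(m) # 4
one_hot_encode <- function(residues, max_len = 1000L) {
  stopifnot(max_len >= 1L)
  idx <- encode_indices(as.character(residues)[1], max_len)
  m <- matrix(0, nrow = max_len, ncol = 20L,
              dimnames = list(NULL, aa_alphabet()))
  nz <- which(idx > 0L)
  m[cbind(nz, idx[nz])] <- 1
  m
}

#' Decode a one-hot matrix back to a residue string
#'
#' Trailing all-zero rows are treated as padding; interior all-zero rows
#' decode to `"X"` (unknown residue).
#'
#' @param m One-hot matrix as produced by [one_hot_encode()].
#' @return Residue string.
#' @export
decode_one_hot <- function(m) {
  hit <- max.col(m, ties.method = "first")
  present <- rowSums(m) > 0
  if (!any(present)) return("")
  last <- max(which(present))
  chars <- ifelse(present[seq_len(last)], aa_alphabet()[hit[seq_len(last)]], "X")
  paste(chars, collapse = "")
}

#' Encode every sequence of a dataset as an index matrix
#'
#' @param dataset A `hier_dataset` (or named character vector).
#' @param max_len Fixed encoded length.
#' @return Integer matrix, one row per sequence (rownames = ids), entries in
#'   0..20 with 0 meaning padding/unknown.
#' @export
encode_dataset <- function(dataset, max_len = 1000L) {
  seqs <- if (inherits(dataset, "hier_dataset")) dataset$sequences else dataset
  out <- matrix(0L, nrow = length(seqs), ncol = max_len,
                dimnames = list(names(seqs), NULL))
  for (i in seq_along(seqs)) out[i, ] <- encode_indices(seqs[[i]], max_len)
  out
}

# ---- embedding I/O --------------------------------------------------------

#' Write embeddings as a tab-separated text table
#'
#' One row per sequence: id followed by the embedding coordinates at 12
#' significant digits (round-trips well below 1e-9).
#'
#' @param ids Character vector of ids.
#' @param embeddings Numeric matrix with `length(ids)` rows.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(ids, embeddings, path) {
  embeddings <- as.matrix(embeddings)
  if (length(ids) != nrow(embeddings)) {
    stop("number of ids (", length(ids), ") does not match embedding rows (",
         nrow(embeddings), ")")
  }
  d <- ncol(embeddings)
  header <- paste(c("id", paste0("E", seq_len(d))), collapse = "\t")
  lines <- header
  if (nrow(embeddings) > 0L) {
    body <- vapply(seq_len(nrow(embeddings)), function(i) {
      paste(c(ids[i], sprintf("%.12g", embeddings[i, ])), collapse = "\t")
    }, character(1))
    lines <- c(header, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read embeddings written by [write_embeddings()]
#'
#' @param path Path to the embedding TSV.
#' @return Numeric matrix with ids as rownames (0-row matrix for a
#'   header-only file).
#' @export
read_embeddings <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  if (nrow(tab) == 0L) {
    return(matrix(numeric(0), nrow = 0, ncol = ncol(tab) - 1L,
                  dimnames = list(NULL, names(tab)[-1])))
  }
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab$id)
  m
}
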