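# Synthetic hierarchical families: every node of a strict 3-level class tree
# contributes one conserved motif to all sequences below it, over an i.i.d.
# background. This is the structure the embedding model is designed to
# exploit (level-specific conserved regions), reduced to its essentials.

#' Build a specification for a synthetic 3-level family tree
#'
#' Assigns one distinct random motif to every node of a
#' `n_fam x n_subfam_per x n_subsub_per` tree. Family motifs use
#' `motif_lengths[1]`, subfamily motifs `motif_lengths[2]`, sub-subfamily
#' motifs `motif_lengths[3]`. Deterministic given `seed`.
#'
#' @param n_fam Number of families.
#' @param n_subfam_per Subfamilies per family.
#' @param n_subsub_per Sub-subfamilies per subfamily.
#' @param motif_lengths Length-3 integer vector of motif lengths per level
#'   (all at least 3).
#' @param background Residue sampling probabilities over [aa_alphabet()]
#'   (default uniform).
#' @param seed Integer seed.
#' @return Object of class `family_spec`: leaf table (family / subfamily /
#'   sub-subfamily names), named motif list (one per tree node), background,
#'   motif lengths and seed.
#' @export
build_family_spec <- function(n_fam, n_subfam_per, n_subsub_per,
                              motif_lengths = c(8L, 6L, 5L),
                              background = rep(1 / 20, 20),
                              seed = 1L) {
  stopifnot(n_fam >= 1L, n_subfam_per >= 1L, n_subsub_per >= 1L,
            length(motif_lengths) == 3L, all(motif_lengths >= 3L),
            length(background) == 20L, all(background >= 0),
            sum(background) > 0)
  background <- background / sum(background)

  fams <- paste0("F", seq_len(n_fam))
  leaf <- expand.grid(g = seq_len(n_subsub_per), s = seq_len(n_subfam_per),
                      f = seq_len(n_fam))
  tree <- data.frame(
    family = paste0("F", leaf$f),
    subfamily = paste0("F", leaf$f, "S", leaf$s),
    subsubfamily = paste0("F", leaf$f, "S", leaf$s, "G", leaf$g),
    stringsAsFactors = FALSE
  )
  tree <- tree[order(tree$subsubfamily), , drop = FALSE]
  rownames(tree) <- NULL

  nodes <- c(unique(tree$family), unique(tree$subfamily), tree$subsubfamily)
  node_level <- c(rep(1L, length(unique(tree$family))),
                  rep(2L, length(unique(tree$subfamily))),
                  rep(3L, nrow(tree)))
  # capacity guard: distinct strings of each length must exist
  for (l in 1:3) {
    n_need <- sum(node_level == l)
    if (n_need > 20^motif_lengths[l]) {
      stop("cannot draw ", n_need, " distinct motifs of length ", motif_lengths[l])
    }
  }

  motifs <- withr::with_seed(seed, {
    out <- character(length(nodes))
    seen <- character(0)
    for (i in seq_along(nodes)) {
      len <- motif_lengths[node_level[i]]
      for (try in 1:1000) {
        m <- paste(sample(aa_alphabet(), len, replace = TRUE, prob = background),
                   collapse = "")
        if (!m %in% seen) break
        if (try == 1000) stop("failed to draw distinct motifs")
      }
      out[i] <- m
      seen <- c(seen, m)
    }
    stats::setNames(out, nodes)
  })

  structure(
    list(tree = tree, motifs = motifs, motif_lengths = as.integer(motif_lengths),
         background = background, seed = as.integer(seed)),
    class = "family_spec"
  )
}

#' @export
print.family_spec <- function(x, ...) {
  cat(sprintf("<family_spec> %d families / %d subfamilies / %d sub-subfamilies, motif lengths %s\n",
              length(unique(x$tree$family)), length(unique(x$tree$subfamily)),
              nrow(x$tree), paste(x$motif_lengths, collapse = "/")))
  invisible(x)
}

#' Simulate sequences from a synthetic family specification
#'
#' Each sequence is drawn i.i.d. from the background distribution, then its
#' family, subfamily and sub-subfamily motifs are planted at random positions
#' inside the first, second and third thirds of the sequence respectively
#' (which keeps them non-overlapping by construction). Each planted motif
#' position is then independently substituted with probability
#' `mutation_rate` by a uniformly chosen *different* residue. Deterministic
#' given `seed`.
#'
#' @param spec A `family_spec`.
#' @param n_per_class Sequences per sub-subfamily.
#' @param length Sequence length (must exceed the summed motif lengths).
#' @param mutation_rate Per-motif-position substitution probability in
#'   `[0, 1)`.
#' @param seed Integer seed.
#' @param length_jitter If `TRUE`, lengths vary uniformly within +/-10% to
#'   exercise padding.
#' @return A labeled `hier_dataset`. Ids are `<subsubfamily>_<index>`. The
#'   `"planted"` attribute records, per sequence and level, the motif and the
#'   position where it was planted (before mutation).
#' @export
simulate_sequences <- function(spec, n_per_class = 40L, length = 200L,
                               mutation_rate = 0.05, seed = 1L,
                               length_jitter = FALSE) {
  stopifnot(inherits(spec, "family_spec"), n_per_class >= 1L,
            mutation_rate >= 0, mutation_rate < 1)
  if (length <= sum(spec$motif_lengths)) {
    stop("sequence length must exceed total motif length ",
         sum(spec$motif_lengths))
  }
  alpha <- aa_alphabet()
  min_len <- if (length_jitter) floor(length * 0.9) else length
  # each third must hold its level's motif even at the shortest length
  windows_ok <- floor(min_len / 3) >= max(spec$motif_lengths)
  if (!windows_ok) {
    stop("placement windows (thirds of length ", min_len,
         ") cannot hold a motif of length ", max(spec$motif_lengths))
  }

  n_leaf <- nrow(spec$tree)
  withr::with_seed(seed, {
    seqs <- character(n_leaf * n_per_class)
    ids <- character(n_leaf * n_per_class)
    planted <- vector("list", n_leaf * n_per_class)
    lab <- spec$tree[rep(seq_len(n_leaf), each = n_per_class), , drop = FALSE]
    k <- 0L
    for (leaf in seq_len(n_leaf)) {
      node_names <- c(spec$tree$family[leaf], spec$tree$subfamily[leaf],
                      spec$tree$subsubfamily[leaf])
      motifs <- spec$motifs[node_names]
      for (r in seq_len(n_per_class)) {
        k <- k + 1L
        L <- if (length_jitter) {
          sample(seq(floor(length * 0.9), ceiling(length * 1.1)), 1L)
        } else length
        res <- sample(alpha, L, replace = TRUE, prob = spec$background)
        third <- floor(L / 3)
        starts <- integer(3)
        for (lvl in 1:3) {
          m <- strsplit(motifs[[lvl]], "")[[1]]
          lo <- (lvl - 1L) * third + 1L
          hi <- min(lvl * third, L) - length(m) + 1L
          start <- if (hi > lo) sample(lo:hi, 1L) else lo
          starts[lvl] <- start
          mut <- stats::runif(length(m)) < mutation_rate
          if (any(mut)) {
            m[mut] <- vapply(m[mut], function(a) {
              sample(setdiff(alpha, a), 1L)
            }, character(1))
          }
          res[start:(start + length(m) - 1L)] <- m
        }
        seqs[k] <- paste(res, collapse = "")
        ids[k] <- sprintf("%s_%03d", spec$tree$subsubfamily[leaf], r)
        planted[[k]] <- data.frame(
          id = ids[k], level = c("family", "subfamily", "subsubfamily"),
          node = node_names, start = starts,
          motif = unname(motifs), stringsAsFactors = FALSE)
      }
    }
    labels <- data.frame(id = ids, family = lab$family, subfamily = lab$subfamily,
                         subsubfamily = lab$subsubfamily, stringsAsFactors = FALSE)
    out <- hier_dataset(stats::setNames(seqs, ids), labels)
    # provenance: where each (possibly mutated) motif was planted
    attr(out, "planted") <- do.call(rbind, planted)
    out
  })
}

#' Write a synthetic dataset as FASTA plus label TSV
#'
#' @param dataset A labeled `hier_dataset`.
#' @param dir Output directory (created if needed); writes
#'   `sequences.fasta` and `labels.tsv`.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "hier_dataset"), !is.null(dataset$labels))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(dataset$sequences, file.path(dir, "sequences.fasta"))
  write_labels(dataset, file.path(dir, "labels.tsv"))
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory containing `sequences.fasta` and `labels.tsv`.
#' @return A labeled `hier_dataset`.
#' @export
read_dataset <- function(dir) {
  seqs <- read_fasta(file.path(dir, "sequences.fasta"))
  read_labels(file.path(dir, "labels.tsv"), seqs)
}
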