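test_that("pairwise distances form a valid Euclidean metric matrix", {
  set.seed(51)
  Z <- matrix(rnorm(10 * 4), nrow = 10,
              dimnames = list(paste0("s", 1:10), NULL))
  Z[2, ] <- Z[1, ]                      # duplicate vectors
  D <- pairwise_distances(Z)
  expect_identical(dim(D), c(10L, 10L))
  expect_equal(D, t(D), tolerance = 1e-12)
  expect_equal(unname(diag(D)), rep(0, 10))
  expect_equal(D["s1", "s2"], 0)
  # brute-force double-loop oracle
  for (i in 1:10) for (j in 1:10) {
    expect_equal(D[i, j], sqrt(sum((Z[i, ] - Z[j, ])^2)), tolerance = 1e-9)
  }
  # antipodal unit vectors attain the sphere diameter
  U <- rbind(c(1, 0), c(-1, 0), c(0, 1))
  expect_equal(pairwise_distances(U)[1, 2], 2, tolerance = 1e-12)
  expect_error(pairwise_distances(Z[1, , drop = FALSE]), "at least 2")
})

test_that("silhouette against true labels matches a hand-rolled oracle", {
  set.seed(52)
  # two tight, well-separated clusters score near 1
  Z <- rbind(matrix(rnorm(40, 0, 0.05), 20), matrix(rnorm(40, 5, 0.05), 20))
  labs <- data.frame(family = rep(c("a", "b"), each = 20),
                     subfamily = rep(c("a1", "b1"), each = 20),
                     subsubfamily = rep(c("a1x", "b1x"), each = 20))
  s <- silhouette_by_level(Z, labs)
  expect_true(all(s > 0.9))
  expect_named(s, c("family", "subfamily", "subsubfamily"))

  # random labels on one isotropic cloud sit at chance level
  Zr <- matrix(rnorm(300 * 3), nrow = 300)
  lr <- sample(c("u", "v"), 300, TRUE)
  labr <- data.frame(family = lr, subfamily = lr, subsubfamily = lr)
  expect_lt(abs(silhouette_by_level(Zr, labr)[["family"]]), 0.1)

  # 12-point instance vs a from-scratch a/b computation
  Z12 <- matrix(rnorm(12 * 2), nrow = 12)
  l12 <- rep(c("p", "q", "r"), each = 4)
  D <- as.matrix(dist(Z12))
  sil <- vapply(1:12, function(i) {
    own <- which(l12 == l12[i] & seq_len(12) != i)
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(l12), l12[i]),
                    function(cl) mean(D[i, l12 == cl]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  got <- silhouette_by_level(Z12, data.frame(family = l12, subfamily = l12,
                                             subsubfamily = l12))
  expect_equal(got[["family"]], mean(sil), tolerance = 1e-9)

  # undefined for a single class
  lab1 <- data.frame(family = rep("a", 12), subfamily = l12, subsubfamily = l12)
  expect_error(silhouette_by_level(Z12, lab1), "one class")

  # all-singleton classes score 0 by the singleton convention
  ls1 <- paste0("c", 1:12)
  labs1 <- data.frame(family = l12, subfamily = ls1, subsubfamily = ls1)
  expect_equal(unname(silhouette_by_level(Z12, labs1)[["subsubfamily"]]), 0)
})

test_that("ward clustering honors k and recovers separated blobs", {
  set.seed(53)
  Z <- rbind(matrix(rnorm(30, 0, 0.1), 15), matrix(rnorm(30, 10, 0.1), 15))
  expect_length(unique(agglomerative_ward(Z, 30)), 30L)   # singletons
  expect_length(unique(agglomerative_ward(Z, 1)), 1L)
  cl <- agglomerative_ward(Z, 2)
  truth <- rep(1:2, each = 15)
  expect_true(all(table(cl, truth) %in% c(0L, 15L)))      # exact partition match
  expect_error(agglomerative_ward(Z, 31), "k must be")
})

test_that("adjusted mutual information matches the reference implementation", {
  # expected values computed once with scikit-learn adjusted_mutual_info_score
  expect_equal(adjusted_mutual_information(c(1, 1, 1, 2, 2, 2, 3, 3, 3, 3),
                                           c(1, 1, 2, 2, 2, 3, 3, 3, 3, 3)),
               0.4666567782822789, tolerance = 1e-9)
  i <- 0:29
  expect_equal(adjusted_mutual_information((i * 7) %% 4, (i * 5) %% 3),
               -0.08848049382178357, tolerance = 1e-9)
  # identical partitions score 1, including the trivial single-cluster case
  expect_equal(adjusted_mutual_information(c(0, 0, 1, 1, 2, 2),
                                           c(0, 0, 1, 1, 2, 2)), 1)
  expect_equal(adjusted_mutual_information(rep(1, 8), rep("a", 8)), 1)
  # permutation of cluster names is irrelevant
  expect_equal(adjusted_mutual_information(c(1, 1, 2, 2), c("b", "b", "a", "a")), 1)
  expect_error(adjusted_mutual_information(1:3, 1:4), "differ in length")
})

test_that("AMI of random partitions is centered at zero", {
  set.seed(54)
  vals <- replicate(50, {
    adjusted_mutual_information(sample(1:4, 200, TRUE), sample(1:5, 200, TRUE))
  })
  expect_lt(abs(mean(vals)), 0.05)
})

test_that("the AMI curve scans the documented k grid and peaks at true structure", {
  set.seed(55)
  # n = 120 supports the full default grid 2, 5, ..., 98 (33 values)
  Z <- matrix(rnorm(120 * 3), nrow = 120)
  l <- sample(c("a", "b", "c"), 120, TRUE)
  labs <- data.frame(family = l, subfamily = l, subsubfamily = l)
  curve <- ami_curve(Z, labs)
  expect_equal(sort(unique(curve$k)), seq(2, 98, by = 3))
  expect_equal(nrow(curve), 3L * 33L)
  expect_true(all(curve$ami <= 1 + 1e-12))

  # three well-separated blobs: AMI is 1 exactly at k = true count
  Zb <- rbind(matrix(rnorm(40, 0, 0.1), 20), matrix(rnorm(40, 8, 0.1), 20),
              matrix(rnorm(40, -8, 0.1), 20))
  lb <- rep(c("a", "b", "c"), each = 20)
  cb <- ami_curve(Zb, data.frame(family = lb, subfamily = lb, subsubfamily = lb),
                  k_from = 3, k_to = 9, step = 3)
  expect_equal(cb$ami[cb$level == "family" & cb$k == 3], 1, tolerance = 1e-9)
  expect_equal(unname(ami_argmax(cb)[["family"]]), 3)

  expect_warning(ami_curve(matrix(rnorm(20), 10), labs[1:10, ]), "truncating")
  expect_error(ami_curve(Z, labs[0, ]), "empty")
})

test_that("neighbor joining recovers additive trees exactly", {
  # 3 taxa: closed-form pendant lengths a, b, c
  a <- 0.7; b <- 1.3; c <- 0.4
  D3 <- matrix(c(0, a + b, a + c,
                 a + b, 0, b + c,
                 a + c, b + c, 0), nrow = 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- neighbor_joining(D3)
  expect_s3_class(t3, "phylo")
  expect_equal(sort(t3$edge.length), sort(c(a, b, c)), tolerance = 1e-9)

  # 5-taxon tree with stated branch lengths: recovered topology and lengths
  # (checked through the induced tree metric)
  tr <- ape::read.tree(text = "((A:0.3,B:0.6):0.5,(C:0.2,D:0.9):0.4,E:1.1);")
  D5 <- cophenetic(tr)
  rec <- neighbor_joining(D5)
  expect_lt(max(abs(cophenetic(rec)[rownames(D5), colnames(D5)] - D5)), 1e-9)
  expect_equal(ape::dist.topo(ape::unroot(tr), rec), structure(0, Nnode = NULL),
               ignore_attr = TRUE)

  # identical rows form a cherry with zero-length pendant edges
  Dd <- cophenetic(ape::read.tree(text = "((A:0,B:0):0.5,(C:0.4,D:0.7):0.2);"))
  td <- neighbor_joining(Dd)
  tipA <- which(td$tip.label == "A")
  tipB <- which(td$tip.label == "B")
  lenA <- td$edge.length[td$edge[, 2] == tipA]
  lenB <- td$edge.length[td$edge[, 2] == tipB]
  expect_equal(lenA, 0, tolerance = 1e-9)
  expect_equal(lenB, 0, tolerance = 1e-9)

  expect_error(neighbor_joining(D3[1:2, 1:2]), "at least 3")
  asym <- D3; asym[1, 2] <- 99
  expect_error(neighbor_joining(asym), "symmetric")
})

test_that("negative NJ branch estimates are clamped and flagged", {
  # a non-additive matrix known to produce a negative NJ branch estimate
  D <- matrix(c(0, 2, 2, 2,
                2, 0, 0.1, 2,
                2, 0.1, 0, 0.1,
                2, 2, 0.1, 0), nrow = 4,
              dimnames = list(letters[1:4], letters[1:4]))
  t4 <- neighbor_joining(D)
  expect_true(all(t4$edge.length >= 0))
  expect_true(is.numeric(attr(t4, "clamped")))
})

test_that("UPGMA is exact on ultrametric input and equivariant to permutation", {
  set.seed(56)
  tr <- ape::rcoal(8)                    # coalescent trees are ultrametric
  D <- cophenetic(tr)
  up <- upgma_order(D)
  # cophenetic distances of the UPGMA dendrogram reproduce the input
  merge_heights <- cophenetic(up$hclust)
  expect_lt(max(abs(as.matrix(merge_heights)[rownames(D), colnames(D)] - D)),
            1e-9)
  expect_setequal(up$order, rownames(D))

  # 4-point hand matrix: closest pair (a,b) merges first at height 0.2,
  # then c joins at mean distance, then d
  Dh <- matrix(c(0, 0.2, 0.6, 1.0,
                 0.2, 0, 0.6, 1.0,
                 0.6, 0.6, 0, 1.0,
                 1.0, 1.0, 1.0, 0), nrow = 4,
               dimnames = list(letters[1:4], letters[1:4]))
  uh <- upgma_order(Dh)
  expect_equal(uh$hclust$height, c(0.2, 0.6, 1.0), tolerance = 1e-12)
  expect_identical(uh$hclust$merge[1, ], c(-1L, -2L))

  perm <- c(3, 1, 4, 2)
  up2 <- upgma_order(Dh[perm, perm])
  expect_equal(sort(up2$hclust$height), sort(uh$hclust$height), tolerance = 1e-12)
  expect_identical(sort(up2$order), sort(uh$order))
})

test_that("per-cluster FASTA export preserves ids and planted motifs", {
  spec <- tiny_spec()
  ds <- simulate_sequences(spec, n_per_class = 3, length = 150,
                           mutation_rate = 0, seed = 8)
  dir <- withr::local_tempdir()
  # cluster = true sub-subfamily
  paths <- export_clusters_fasta(ds, ds$labels$subsubfamily, dir)
  expect_length(paths, 12L)
  one <- read_fasta(paths[["F2S1G1"]])
  expect_length(one, 3L)
  expect_true(all(names(one) %in% names(ds$sequences)))
  # the cluster's planted motif appears verbatim in every exported record
  expect_true(all(grepl(spec$motifs[["F2S1G1"]], one, fixed = TRUE)))
  # sizes 3 and 5 example with an arbitrary clustering
  cl <- c(rep(1, 3), rep(2, 5), rep(1, length(ds) - 8))
  p2 <- export_clusters_fasta(ds, cl, withr::local_tempdir())
  expect_length(read_fasta(p2[["2"]]), 5L)
})
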