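test_that("cross-entropy matches closed forms and hand arithmetic", {
  # uniform logits over k classes -> ln(k)
  for (k in c(2, 5, 12)) {
    lg <- matrix(1.7, nrow = 3, ncol = k)
    expect_equal(cross_entropy_level(lg, c(1, k, 1)), log(k), tolerance = 1e-12)
  }
  # loss decreases monotonically as the correct-class margin grows
  losses <- vapply(c(1, 10, 100), function(margin) {
    lg <- matrix(0, nrow = 1, ncol = 4); lg[1, 2] <- margin
    cross_entropy_level(lg, 2L)
  }, numeric(1))
  expect_true(all(diff(losses) < 0))
  # independent hand computation: 3-class batch of 2
  lg <- rbind(c(2, 1, 0), c(0, 0, 3))
  labels <- c(1L, 3L)
  p1 <- exp(2) / (exp(2) + exp(1) + exp(0))
  p2 <- exp(3) / (exp(0) + exp(0) + exp(3))
  expect_equal(cross_entropy_level(lg, labels),
               mean(-log(c(p1, p2))), tolerance = 1e-12)
  # named labels resolve against logit columns
  colnames(lg) <- c("a", "b", "c")
  expect_equal(cross_entropy_level(lg, c("a", "c")),
               mean(-log(c(p1, p2))), tolerance = 1e-12)
  expect_error(cross_entropy_level(lg, c(1L, 4L)), "out of range")
})

test_that("center loss follows the squared-distance definition", {
  centers <- rbind(X = c(0.5, 0.5), Y = c(0, 0))
  # worked instance: two points at (1,0), (0,1) with center (0.5, 0.5)
  Z <- rbind(c(1, 0), c(0, 1))
  expect_identical(center_loss_level(Z, c("X", "X"), centers), 1.0)
  # zero iff every embedding equals its center
  expect_identical(center_loss_level(rbind(c(0.5, 0.5)), "X", centers), 0)
  # quadratic homogeneity: doubling deviations quadruples the loss
  base <- center_loss_level(Z, c("X", "X"), centers)
  Z2 <- sweep((Z - rep(1, 2) %o% centers["X", ]) * 2, 2, centers["X", ], "+")
  expect_equal(center_loss_level(Z2, c("X", "X"), centers), 4 * base,
               tolerance = 1e-12)
  expect_error(center_loss_level(Z, c("X", "Q"), centers), "no center.*Q")
})

test_that("center-loss gradient matches finite differences", {
  set.seed(31)
  centers <- matrix(rnorm(6), nrow = 3,
                    dimnames = list(c("a", "b", "c"), NULL))
  Z <- matrix(rnorm(10), nrow = 5)
  labs <- c("a", "b", "b", "c", "a")
  g <- hierembed:::center_loss_grad(Z, labs, centers)
  eps <- 1e-6
  for (i in sample(length(Z), 6)) {
    Zp <- Z; Zp[i] <- Zp[i] + eps
    Zm <- Z; Zm[i] <- Zm[i] - eps
    num <- (center_loss_level(Zp, labs, centers) -
            center_loss_level(Zm, labs, centers)) / (2 * eps)
    expect_lt(abs(num - g[i]) / max(abs(num), 1e-8), 1e-4)
  }
})

test_that("center loss at the true means equals the summed within-class scatter", {
  set.seed(32)
  labs <- rep(c("u", "v"), each = 25)
  Z <- rbind(matrix(rnorm(50, 1, 0.3), 25), matrix(rnorm(50, -1, 0.5), 25))
  centers <- hierembed::centers_from_embeddings(
    Z, data.frame(family = labs, subfamily = labs, subsubfamily = labs))$family
  scatter <- sum(vapply(c("u", "v"), function(cl) {
    M <- Z[labs == cl, , drop = FALSE]
    sum(sweep(M, 2, colMeans(M))^2)
  }, numeric(1)))
  expect_equal(center_loss_level(Z, labs, centers), scatter, tolerance = 1e-9)
})

test_that("total loss is the exact weighted combination and linear", {
  lv <- c("family", "subfamily", "subsubfamily")
  phases <- default_phase_configs()
  ones <- stats::setNames(rep(1, 3), lv)
  # phase-1 weights with all six unit components: 1.0 + 0.01 * 1.0
  expect_equal(total_loss(ones, ones, phases[[1]]), 1.01, tolerance = 1e-12)
  # lambda_c = 0 reduces to the weighted cross-entropy alone
  p0 <- phases[[2]]; p0$lambda_c <- 0
  ls <- stats::setNames(c(0.3, 0.7, 1.1), lv)
  lc <- stats::setNames(c(5, 6, 7), lv)
  expect_equal(total_loss(ls, lc, p0), sum(p0$w_s * ls), tolerance = 1e-12)
  # annihilation at zero weights
  pz <- phase_config("z", 0, stats::setNames(rep(0, 3), lv),
                     stats::setNames(rep(0, 3), lv), 1)
  expect_identical(total_loss(ls, lc, pz), 0)
  # positive homogeneity in the components
  for (alpha in c(0, 0.5, 3)) {
    expect_equal(total_loss(alpha * ls, alpha * lc, phases[[3]]),
                 alpha * total_loss(ls, lc, phases[[3]]), tolerance = 1e-12)
  }
  expect_error(total_loss(stats::setNames(c(-1, 0, 0), lv), lc, phases[[1]]),
               "negative")
  expect_error(total_loss(stats::setNames(c(NaN, 0, 0), lv), lc, phases[[1]]),
               "finite")
})

test_that("default curriculum weights are the reference three-phase schedule", {
  ph <- default_phase_configs()
  expect_equal(vapply(ph, `[[`, numeric(1), "lambda_c"), c(0.01, 0.3, 0.5))
  expect_equal(unname(ph[[1]]$w_s), c(0.8, 0.15, 0.05))
  expect_equal(unname(ph[[2]]$w_s), c(0.1, 0.8, 0.1))
  expect_equal(unname(ph[[3]]$w_s), c(0.1, 0.25, 0.65))
  expect_equal(unname(ph[[1]]$w_c), c(0.8, 0.15, 0.05))
  expect_equal(unname(ph[[2]]$w_c), c(0.1, 0.8, 0.1))
  expect_equal(unname(ph[[3]]$w_c), c(0.1, 0.15, 0.75))
  # every column sums to one
  for (p in ph) {
    expect_equal(sum(p$w_s), 1)
    expect_equal(sum(p$w_c), 1)
  }
})

test_that("class centers are whole-dataset group means", {
  # one class holding (1,0) and (0,1) -> center (0.5, 0.5)
  lab2 <- data.frame(family = c("f", "f"), subfamily = c("s", "s"),
                     subsubfamily = c("g", "g"))
  cen <- centers_from_embeddings(rbind(c(1, 0), c(0, 1)), lab2)
  expect_equal(unname(cen$family["f", ]), c(0.5, 0.5))
  # singleton class: center equals the embedding, its center loss is zero
  lab1 <- data.frame(family = "f", subfamily = "s", subsubfamily = "g")
  z <- matrix(c(0.2, -0.4), nrow = 1)
  cen1 <- centers_from_embeddings(z, lab1)
  expect_equal(unname(cen1$subsubfamily["g", ]), c(0.2, -0.4))
  expect_equal(center_loss_level(z, "g", cen1$subsubfamily), 0)
  # random 20-item set vs an explicit group-by-mean oracle
  set.seed(33)
  Z <- matrix(rnorm(20 * 4), nrow = 20)
  labs <- data.frame(family = sample(c("A", "B"), 20, TRUE),
                     subfamily = sample(c("x", "y", "z"), 20, TRUE),
                     subsubfamily = sample(letters[1:5], 20, TRUE))
  cen <- centers_from_embeddings(Z, labs)
  for (lvl in c("family", "subfamily", "subsubfamily")) {
    for (cl in unique(labs[[lvl]])) {
      expect_equal(unname(cen[[lvl]][cl, ]),
                   unname(colMeans(Z[labs[[lvl]] == cl, , drop = FALSE])),
                   tolerance = 1e-9)
    }
  }
})

test_that("model-wide update_centers agrees with centers from embed_dataset", {
  ds <- tiny_dataset(n_per_class = 3)
  m <- tiny_model(ds)
  cen <- update_centers(m, ds)
  Z <- embed_dataset(m, ds)
  oracle <- centers_from_embeddings(Z, ds$labels)
  expect_equal(cen, oracle, tolerance = 1e-12)
  expect_identical(nrow(cen$subsubfamily), 12L)
  expect_identical(ncol(cen$family), m$config$embed_dim)
})
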