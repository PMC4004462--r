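# Predictor evaluation, the squash bridge, the convex stage-1 solver
# against an independent QP reference, and the stage-2 descent properties.

test_that("squash and classify implement the documented bridge", {
  expect_equal(squash(c(-2, -1, 0, 1, 2)), c(0, 0, 0.5, 1, 1))
  expect_identical(classify(c(0.2, -0.2, 0)), c(1L, -1L, -1L))
  expect_equal(hinge_loss(1, 2), 0)
  expect_equal(hinge_loss(1, 0), 1)
  expect_equal(hinge_loss(-1, 0.5), 1.5)
  expect_error(hinge_loss(0, 1), "labels")
})

test_that("predict_margins is the representer-form expansion", {
  set.seed(41)
  g <- random_gram(6)
  basis <- canonical_pairs(as.data.frame(t(utils::combn(rownames(g), 2))))
  basis <- basis[sample(nrow(basis), 5), ]
  K <- pairwise_gram(g, basis)
  m <- mlpip:::new_predictor("protein", basis, K, g)
  # w = 0: all margins zero
  expect_equal(unname(predict_margins(m)), rep(0, 5))
  m$w <- rnorm(5)
  # matches an explicit loop over the expansion
  q <- data.frame(id_a = c("x1", "x2"), id_b = c("x4", "x6"))
  got <- predict_margins(m, q)
  for (i in seq_len(nrow(q))) {
    expected <- sum(vapply(seq_len(nrow(basis)), function(j)
      m$w[j] * pairwise_gram(g, q[i, ], basis[j, ])[1, 1], numeric(1)))
    expect_equal(unname(got[i]), expected)
  }
  # symmetric in pair member order
  qr <- data.frame(id_a = q$id_b, id_b = q$id_a)
  expect_equal(unname(predict_margins(m, qr)), unname(got))
  # representer consistency on the training index: margins equal K w
  expect_equal(unname(predict_margins(m)), unname(drop(K %*% m$w)))
})

test_that("stage-1 solution matches an independent QP reference solver", {
  set.seed(42)
  cfg <- train_config(lambda_r = 0.1)
  for (rep in 1:10) {
    n_obj <- 8
    g <- random_gram(n_obj, rank = sample(3:n_obj, 1))
    pairs <- canonical_pairs(as.data.frame(t(utils::combn(rownames(g), 2))))
    pairs <- pairs[sample(nrow(pairs), 20), ]
    K <- pairwise_gram(g, pairs)
    labeled <- sample(nrow(pairs), 20)
    y <- sample(c(-1, 1), 20, replace = TRUE)
    w <- stage1_fit(K, labeled, y, cfg)
    wr <- reference_stage1(K, labeled, y, cfg$lambda_r)
    expect_equal(drop(K %*% w), drop(K %*% wr), tolerance = 1e-3)
  }
})

test_that("stage-1 separates well-separated labeled pairs", {
  # two orthogonal object groups: the pairwise kernel separates the pairs
  f <- rbind(a1 = c(1, 0, 0, 0), a2 = c(1, 0.1, 0, 0),
             b1 = c(0, 0, 1, 0), b2 = c(0, 0, 1, 0.1))
  g <- linear_gram(f)
  pairs <- data.frame(id_a = c("a1", "b1"), id_b = c("a2", "b2"))
  K <- pairwise_gram(g, pairs)
  w <- stage1_fit(K, 1:2, c(1, -1), train_config())
  m <- drop(K %*% w)
  expect_gt(m[1], 0)
  expect_lt(m[2], 0)
})

test_that("doubling lambda_r never increases the solution norm", {
  set.seed(43)
  g <- random_gram(7)
  pairs <- canonical_pairs(as.data.frame(t(utils::combn(rownames(g), 2))))
  pairs <- pairs[sample(nrow(pairs), 12), ]
  K <- pairwise_gram(g, pairs)
  y <- sample(c(-1, 1), 12, replace = TRUE)
  norms <- vapply(c(0.05, 0.1, 0.2, 0.4, 0.8), function(lr) {
    w <- stage1_fit(K, 1:12, y, train_config(lambda_r = lr))
    sqrt(drop(w %*% K %*% w))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-6))
})

test_that("stage1_fit refuses an unlabeled level", {
  K <- diag(3)
  expect_error(stage1_fit(K, integer(), numeric(), train_config()),
               "supply labels or skip")
})

make_toy_fit <- function(seed = 44, rules = "full", lambda_c = 1,
                         max_iters = 120, noise = 0.2, n_prot = 8,
                         clamped = NULL, use_exists_n = FALSE) {
  p <- synth_params(n_prot, seed = seed, noise_sigma = noise,
                    domains_per_protein = c(1, 2),
                    residues_per_domain = c(2, 3), interface_size = 2,
                    protein_interaction_rate = 0.25)
  d <- suppressWarnings(generate(p))   # tiny instances may cap negatives
  grams <- lapply(d$features, linear_gram)
  cfg <- train_config(lambda_c = lambda_c, max_iters = max_iters)
  list(d = d, grams = grams,
       t = fit(d$hierarchy, grams, d$gold, rules, cfg, clamped = clamped,
               use_exists_n = use_exists_n))
}

test_that("objective breakdown adds up and switches off correctly", {
  x <- make_toy_fit(rules = "P<->D")
  ob <- objective(x$t)
  expect_equal(ob$total, ob$regularizer + ob$loss +
                 x$t$cfg$lambda_c * ob$penalty, tolerance = 1e-9)
  # w = 0 with no constraints: total equals the number of labeled pairs
  t0 <- x$t
  for (lv in names(t0$models)) t0$models[[lv]]$w[] <- 0
  t0$compiled <- list()
  ob0 <- objective(t0)
  expect_equal(ob0$regularizer, 0)
  expect_equal(ob0$penalty, 0)
  n_labeled <- sum(vapply(t0$labels_idx, function(l) length(l$idx),
                          integer(1)))
  expect_equal(ob0$total, n_labeled)
  # lambda_r = lambda_c = 0: total is the loss alone
  obl <- objective(x$t, train_config(lambda_r = 0, lambda_c = 0))
  expect_equal(obl$total, obl$loss)
})

test_that("stage 2 is a no-op when the penalty is off", {
  x0 <- make_toy_fit(rules = "full", lambda_c = 0)
  xi <- make_toy_fit(rules = "independent")
  for (lv in names(x0$t$models))
    expect_identical(x0$t$models[[lv]]$w, xi$t$models[[lv]]$w)
})

test_that("stage 2 decreases the objective and the penalty", {
  x <- make_toy_fit(rules = "full", lambda_c = 10, noise = 0.5)
  tr <- x$t$optim_trace
  expect_true(all(diff(tr) < 0))            # accepted steps only improve
  # penalty strictly improved relative to the stage-1 start
  t1 <- x$t
  for (lv in names(t1$models)) t1$models[[lv]]$w <- stage1_fit(
    t1$models[[lv]]$K, t1$labels_idx[[lv]]$idx, t1$labels_idx[[lv]]$y,
    t1$cfg)
  expect_lt(objective(x$t)$penalty, objective(t1)$penalty)
  expect_lte(tail(tr, 1), tr[1])
})

test_that("a supervised protein pair drags its unsupervised domain pair up", {
  # two proteins, one domain each; protein pair supervised bound, the only
  # domain pair unsupervised: P->D must raise its squashed output
  h <- hierarchy(parent_pd = c(d1 = "p1", d2 = "p2"))
  set.seed(45)
  fp <- matrix(rnorm(8), 2, 4, dimnames = list(c("p1", "p2"), NULL))
  fd <- matrix(rnorm(8), 2, 4, dimnames = list(c("d1", "d2"), NULL))
  grams <- list(protein = linear_gram(fp), domain = linear_gram(fd))
  labels <- list(protein = labeled_pairs(
    data.frame(id_a = "p1", id_b = "p2", label = 1L), "protein", h))
  cfg <- train_config(lambda_c = 5, max_iters = 200)
  t <- fit(h, grams, labels, "P->D", cfg)
  m_stage1 <- 0  # domain level has no labels: stage-1 weights are zero
  expect_gt(unname(t$margins$domain["d1|d2"]), m_stage1)
})

test_that("fit with the same config is bit-identical across runs", {
  x1 <- make_toy_fit(seed = 46)
  x2 <- make_toy_fit(seed = 46)
  for (lv in names(x1$t$models))
    expect_identical(x1$t$models[[lv]]$w, x2$t$models[[lv]]$w)
})

test_that("with no constraints the fit is convex: stage 1 is the optimum", {
  x <- make_toy_fit(rules = "independent")
  ob <- objective(x$t)
  # perturbing any level's weights does not lower the objective
  set.seed(47)
  for (rep in 1:5) {
    t2 <- x$t
    lv <- sample(names(t2$models), 1)
    t2$models[[lv]]$w <- t2$models[[lv]]$w +
      rnorm(length(t2$models[[lv]]$w), sd = 0.01)
    expect_gte(objective(t2)$total, ob$total - 1e-6)
  }
})

test_that("model checkpoints round-trip through JSON", {
  x <- make_toy_fit(seed = 48, rules = "independent", n_prot = 5)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "model.json")
  write_model(x$t, path)
  t2 <- read_model(path, x$grams)
  for (lv in names(x$t$models)) {
    expect_equal(t2$models[[lv]]$w, x$t$models[[lv]]$w)
    expect_equal(t2$margins[[lv]], x$t$margins[[lv]])
  }
})
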