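test_that("generated datasets satisfy every consistency rule", {
  for (s in 1:3) {
    p <- synth_params(8, seed = s, domains_per_protein = c(1, 2),
                      residues_per_domain = c(2, 4), interface_size = 2,
                      protein_interaction_rate = 0.3)
    d <- generate(p)
    expect_true(verify_consistency(d))
  }
})

test_that("every bound domain pair hosts exactly interface_size residue
          pairs", {
  p <- synth_params(8, seed = 51, residues_per_domain = c(5, 6),
                    interface_size = 5, protein_interaction_rate = 0.3)
  d <- generate(p)
  if (nrow(d$planted$domain)) {
    rkey <- pair_key(d$planted$residue$id_a, d$planted$residue$id_b)
    for (i in seq_len(nrow(d$planted$domain))) {
      dd <- d$planted$domain[i, ]
      cross <- child_pairs(d$hierarchy, dd, "domain")
      n_bound <- sum(pair_key(cross$id_a, cross$id_b) %in% rkey)
      expect_identical(n_bound, 5L)
    }
  }
})

test_that("flipping planted facts breaks consistency", {
  p <- synth_params(8, seed = 52, domains_per_protein = c(1, 2),
                    residues_per_domain = c(2, 3), interface_size = 2,
                    protein_interaction_rate = 0.3)
  d <- generate(p)
  expect_gt(nrow(d$planted$domain), 0)
  # delete a bound domain pair while its proteins stay bound: P->D fails
  d2 <- d
  d2$planted$domain <- d2$planted$domain[-1, , drop = FALSE]
  expect_false(verify_consistency(d2))
  # delete one residue pair of an interface: the n-existential drops
  d3 <- d
  dd <- d3$planted$domain[1, ]
  cross <- child_pairs(d3$hierarchy, dd, "domain")
  ckeys <- pair_key(cross$id_a, cross$id_b)
  rk <- pair_key(d3$planted$residue$id_a, d3$planted$residue$id_b)
  victim <- which(rk %in% ckeys)[1]
  d3$planted$residue <- d3$planted$residue[-victim, , drop = FALSE]
  expect_false(verify_consistency(d3))
})

test_that("labels are balanced, canonical and exclude intra-protein pairs", {
  p <- synth_params(10, seed = 53, protein_interaction_rate = 0.3,
                    domains_per_protein = c(2, 2),
                    residues_per_domain = c(2, 3), interface_size = 2)
  d <- generate(p)
  h <- d$hierarchy
  for (lv in c("protein", "domain", "residue")) {
    g <- d$gold[[lv]]
    expect_identical(sum(g$label == 1), sum(g$label == -1))
    expect_true(all(g$id_a < g$id_b))
    if (lv == "domain")
      expect_true(all(h$parent_pd[g$id_a] != h$parent_pd[g$id_b]))
    if (lv == "residue")
      expect_true(all(h$parent_pr[g$id_a] != h$parent_pr[g$id_b]))
  }
  # unbalanced option uses the negative ratio
  p2 <- synth_params(24, seed = 53, protein_interaction_rate = 0.05,
                     domains_per_protein = c(1, 1),
                     residues_per_domain = c(2, 3), interface_size = 2,
                     balanced_negatives = FALSE, negative_ratio = 2)
  d2 <- generate(p2)
  g2 <- d2$gold$protein
  expect_identical(sum(g2$label == -1), 2L * sum(g2$label == 1))
})

test_that("generation is deterministic given the seed", {
  p <- synth_params(8, seed = 54, protein_interaction_rate = 0.3)
  expect_identical(generate(p), generate(p))
  p2 <- synth_params(8, seed = 55, protein_interaction_rate = 0.3)
  expect_false(identical(generate(p)$features, generate(p2)$features))
})

test_that("dropout thins gold positives but not the planted truth", {
  p <- synth_params(12, seed = 56, protein_interaction_rate = 0.4,
                    domains_per_protein = c(1, 2),
                    residues_per_domain = c(3, 4), interface_size = 3,
                    dropout = 0.5)
  d <- generate(p)
  expect_lt(sum(d$gold$residue$label == 1), nrow(d$planted$residue))
  expect_true(verify_consistency(d))
})

test_that("datasets round-trip through the plain-text directory format", {
  p <- synth_params(6, seed = 57, protein_interaction_rate = 0.3,
                    domains_per_protein = c(1, 2),
                    residues_per_domain = c(2, 3), interface_size = 2)
  d <- generate(p)
  dir <- withr::local_tempdir()
  write_dataset(d, dir)
  d2 <- load_dataset(dir)
  expect_identical(d2$hierarchy, d$hierarchy)
  expect_equal(d2$features, d$features, tolerance = 0)
  expect_identical(d2$gold, d$gold)
  expect_identical(d2$planted, d$planted)
  expect_equal(unclass(d2$params), unclass(d$params))
})

test_that("infeasible parameters are rejected", {
  expect_error(synth_params(1), "two proteins")
  expect_error(synth_params(5, interface_size = 0), "interface_size")
  expect_error(synth_params(5, residues_per_domain = c(2, 3),
                            interface_size = 4), "residues_per_domain")
  expect_error(synth_params(5, protein_interaction_rate = 1.5),
               "probability")
  expect_error(synth_params(5, noise_sigma = c(foo = 1)), "noise_sigma")
})

test_that("stage-1 training AUC is perfect on noiseless data", {
  p <- synth_params(20, seed = 58, noise_sigma = 0,
                    protein_interaction_rate = 0.3,
                    domains_per_protein = c(1, 2),
                    residues_per_domain = c(2, 3), interface_size = 2)
  d <- generate(p)
  g <- linear_gram(d$features$protein)
  lab <- d$gold$protein
  K <- pairwise_gram(g, lab[, 1:2])
  w <- stage1_fit(K, seq_len(nrow(lab)), lab$label, train_config())
  expect_equal(auc(drop(K %*% w), lab$label), 1)
})

test_that("held-out accuracy degrades monotonically with noise", {
  # mean stage-1 protein AUC on a held-out third, 5 seeds per noise level
  mean_auc <- vapply(c(0, 0.5, 1, 2), function(ns) {
    mean(vapply(1:5, function(s) {
      p <- synth_params(20, seed = 60 + s, noise_sigma = ns,
                        protein_interaction_rate = 0.25,
                        domains_per_protein = c(1, 2),
                        residues_per_domain = c(2, 3), interface_size = 2)
      d <- generate(p)
      g <- linear_gram(d$features$protein)
      lab <- d$gold$protein
      K <- pairwise_gram(g, lab[, 1:2])
      n <- nrow(lab)
      te <- mlpip:::with_seed(70 + s, sample(n, round(n / 3)))
      tr <- setdiff(seq_len(n), te)
      w <- stage1_fit(K, tr, lab$label[tr], train_config())
      m <- drop(K %*% w)
      auc(m[te], lab$label[te])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_auc) <= 0.02))
})
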