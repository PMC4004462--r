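# t-norm algebra, formula evaluation against the classical oracle, the
# quantifier relaxations, and subgradient correctness.

test_that("t-norm operations satisfy their defining identities", {
  expect_equal(t_and(0.5, 1), 0.5)          # neutral element
  expect_equal(t_and(1, 1), 1)
  expect_equal(t_and(0.3, 0.4), 0.12)
  expect_equal(t_or(0, 0), 0)
  expect_equal(t_or(1, 0.7), 1)
  expect_equal(t_or(0.3, 0.4), 0.58)
  expect_equal(t_not(0), 1)
  expect_equal(t_not(1), 0)
  expect_equal(t_not(0.25), 0.75)
  expect_equal(t_implies(0.2, 0.7), 1)      # residuum: satisfied branch
  expect_equal(t_implies(0.7, 0.2), 0.2)    # residuum: consequent value
  expect_equal(t_implies(1, 0), 0)          # crisp modus ponens
  expect_error(t_and(1.2, 0.5), "out-of-range")
  expect_error(t_not(-0.1), "out-of-range")
})

test_that("t_and is commutative, associative, monotone, with neutral 1", {
  set.seed(21)
  a <- runif(200); b <- runif(200); c <- runif(200)
  expect_equal(t_and(a, b), t_and(b, a))
  expect_equal(t_and(t_and(a, b), c), t_and(a, t_and(b, c)))
  expect_equal(t_and(a, 1), a)
  # monotone in each argument
  d <- pmin(1, b + runif(200, 0, 0.2))
  expect_true(all(t_and(a, d) >= t_and(a, b)))
  # De Morgan under product semantics: or(a,b) = not(and(not a, not b))
  expect_equal(t_or(a, b), t_not(t_and(t_not(a), t_not(b))))
})

test_that("formula values follow the t-norm composition", {
  h <- tiny_hierarchy()
  a <- truth_assignment(h, boundp = c("p1|p2" = 0.9),
                        boundd = c("d1|d2" = 0.8))
  f <- fol_and(fol_atom("boundp", "x", "y"), fol_atom("boundd", "u", "v"))
  env <- list(x = "p1", y = "p2", u = "d1", v = "d2")
  expect_equal(formula_value(f, a, env = env), 0.72)
  expect_equal(formula_value(fol_not(fol_atom("boundp", "x", "y")), a,
                             env = env), 0.1)
  expect_equal(formula_value(
    fol_implies(fol_atom("boundp", "x", "y"),
                fol_atom("boundd", "u", "v")), a, env = env), 0.8)
  expect_error(formula_value(fol_atom("boundp", "x", "z"), a, env = env),
               "unbound")
})

test_that("quantifier values use max / n-th largest / min", {
  h <- hierarchy(parent_pd = c(d1 = "p1", d2 = "p1", d3 = "p2"))
  vals <- c(0.2, 0.9)
  a <- truth_assignment(h, boundd = stats::setNames(vals,
                                                    c("d1|d3", "d2|d3")))
  g <- list("u,v" = grounding_table(
    data.frame(u = c("d1", "d2"), v = c("d3", "d3")), c("u", "v")))
  body <- fol_atom("boundd", "u", "v")
  expect_equal(formula_value(fol_exists(c("u", "v"), body), a, g), 0.9)
  expect_equal(formula_value(fol_forall(c("u", "v"), body), a, g), 0.2)
  expect_equal(formula_value(fol_exists_n(2, c("u", "v"), body), a, g), 0.2)
  expect_equal(formula_value(fol_exists_n(3, c("u", "v"), body), a, g), 0)
  # 5th largest of six body values
  h6 <- hierarchy(parent_pd = stats::setNames(rep(c("p1", "p2"), each = 3),
                                              paste0("d", 1:6)))
  keys <- pair_key(paste0("d", 1:3)[c(1, 1, 2, 2, 3, 3)],
                   paste0("d", 4:6)[c(1, 2, 1, 2, 1, 2)])
  a6 <- truth_assignment(h6, boundd = stats::setNames(
    c(0.9, 0.8, 0.7, 0.6, 0.5, 0.1), keys))
  g6 <- list("u,v" = grounding_table(
    data.frame(u = paste0("d", c(1, 1, 2, 2, 3, 3)),
               v = paste0("d", c(4, 5, 4, 5, 4, 5))), c("u", "v")))
  expect_equal(formula_value(fol_exists_n(5, c("u", "v"), body), a6, g6),
               0.5)
})

test_that("constraint violations sum, minimize or top-n as specified", {
  h <- hierarchy(parent_pd = c(d1 = "p1", d2 = "p1", d3 = "p2", d4 = "p2"))
  g <- list("u,v" = grounding_table(
    data.frame(u = c("d1", "d2", "d3"), v = c("d4", "d4", "d4"))[1:2, ],
    c("u", "v")))
  mk <- function(vals, keys = c("d1|d4", "d2|d4")) {
    truth_assignment(h, boundd = stats::setNames(vals, keys))
  }
  body <- fol_atom("boundd", "u", "v")
  forall_c <- constraint("t", fol_forall(c("u", "v"), body), g)
  expect_equal(constraint_violation(forall_c, mk(c(1, 1))), 0)
  expect_equal(constraint_violation(forall_c, mk(c(1, 0.6))), 0.4)
  # top-level exists_n: sum of the n smallest violations
  g3 <- list("u,v" = grounding_table(
    data.frame(u = c("d1", "d2", "d3"), v = "d4"), c("u", "v")))
  en <- constraint("t2", fol_exists_n(2, c("u", "v"), body), g3)
  a3 <- truth_assignment(h, boundd = stats::setNames(
    c(1.0, 0.7, 0.1), c("d1|d4", "d2|d4", "d3|d4")))
  expect_equal(constraint_violation(en, a3), 0.3)
  ex <- constraint("t3", fol_exists(c("u", "v"), body), g3)
  expect_equal(constraint_violation(ex, a3), 0)
  # empty universal grounding set: vacuous truth
  g0 <- list("u,v" = grounding_table(
    data.frame(u = character(), v = character()), c("u", "v")))
  expect_equal(constraint_violation(
    constraint("t4", fol_forall(c("u", "v"), body), g0), a3), 0)
})

test_that("top-level exists_n reduces to exists at n=1 and forall at n=|S|", {
  h <- hierarchy(parent_pd = stats::setNames(rep(c("p1", "p2"), each = 4),
                                             paste0("d", 1:8)))
  set.seed(22)
  for (rep in 1:100) {
    k <- sample(2:8, 1)
    u <- paste0("d", sample(1:4, k, replace = TRUE))
    v <- paste0("d", sample(5:8, k, replace = TRUE))
    df <- unique(data.frame(u = u, v = v, stringsAsFactors = FALSE))
    keys <- pair_key(df$u, df$v)
    vals <- stats::setNames(runif(length(keys)), keys)
    a <- truth_assignment(h, boundd = vals)
    g <- list("u,v" = grounding_table(df, c("u", "v")))
    body <- fol_atom("boundd", "u", "v")
    v1 <- constraint_violation(
      constraint("en1", fol_exists_n(1, c("u", "v"), body), g), a)
    ve <- constraint_violation(
      constraint("ex", fol_exists(c("u", "v"), body), g), a)
    expect_equal(v1, ve)
    vS <- constraint_violation(
      constraint("enS", fol_exists_n(nrow(df), c("u", "v"), body), g), a)
    vf <- constraint_violation(
      constraint("fa", fol_forall(c("u", "v"), body), g), a)
    expect_equal(vS, vf)
  }
})

test_that("top-level exists_n violation is nondecreasing in n", {
  h <- hierarchy(parent_pd = stats::setNames(rep(c("p1", "p2"), each = 3),
                                             paste0("d", 1:6)))
  df <- expand.grid(u = paste0("d", 1:3), v = paste0("d", 4:6),
                    stringsAsFactors = FALSE)
  g <- list("u,v" = grounding_table(df, c("u", "v")))
  body <- fol_atom("boundd", "u", "v")
  set.seed(23)
  for (rep in 1:20) {
    keys <- pair_key(df$u, df$v)
    a <- truth_assignment(h, boundd = stats::setNames(runif(length(keys)),
                                                      keys))
    vs <- vapply(1:9, function(n) constraint_violation(
      constraint("en", fol_exists_n(n, c("u", "v"), body), g), a),
      numeric(1))
    expect_true(all(diff(vs) >= -1e-12))
  }
})

test_that("nested exists_n value equals the n-th largest body value", {
  h <- hierarchy(parent_pd = c(d1 = "p1", d2 = "p2"),
                 parent_dr = stats::setNames(rep(c("d1", "d2"), each = 3),
                                             paste0("r", 1:6)))
  df <- expand.grid(u = paste0("r", 1:3), v = paste0("r", 4:6),
                    stringsAsFactors = FALSE)
  g <- list("u,v" = grounding_table(df, c("u", "v")))
  body <- fol_atom("boundr", "u", "v")
  set.seed(24)
  keys <- pair_key(df$u, df$v)
  vals <- stats::setNames(runif(length(keys)), keys)
  a <- truth_assignment(h, boundr = vals)
  for (n in c(1, 3, 9)) {
    got <- formula_value(fol_exists_n(n, c("u", "v"), body), a, g)
    expect_equal(got, sort(unname(vals[keys]), decreasing = TRUE)[n])
  }
  expect_equal(formula_value(fol_exists_n(10, c("u", "v"), body), a, g), 0)
})

test_that("boolean oracle implements classical semantics", {
  h <- tiny_hierarchy()
  a1 <- crisp_assignment(h, list(protein = "p1|p2"))
  f <- fol_implies(fol_atom("boundp", "x", "y"),
                   fol_atom("boundd", "u", "v"))
  env <- list(x = "p1", y = "p2", u = "d1", v = "d2")
  expect_false(boolean_oracle(f, a1, env = env))     # A true, B false
  a2 <- crisp_assignment(h, list(protein = "p1|p2", domain = "d1|d2"))
  expect_true(boolean_oracle(f, a2, env = env))
  g <- list("u,v" = grounding_table(data.frame(u = "d1", v = "d2"),
                                    c("u", "v")))
  expect_true(boolean_oracle(fol_forall(c("u", "v"),
                                        fol_atom("boundd", "u", "v")),
                             a2, g))
  expect_false(boolean_oracle(fol_exists_n(2, c("u", "v"),
                                           fol_atom("boundd", "u", "v")),
                              a2, g))
  expect_error(boolean_oracle(f, random_fuzzy(h), env = env), "non-crisp")
})

test_that("compiled evaluation matches scalar recursion per grounding", {
  set.seed(25)
  for (rep in 1:10) {
    h <- random_hierarchy(4L)
    pairs <- all_level_pairs(h)
    if (!nrow(pairs$protein)) next
    a <- random_fuzzy(h)
    for (nm in c("P->D", "D->P", "D->R", "R->D")) {
      cst <- build_rule(nm, h, pairs, use_exists_n = (nm == "D->R"), n = 2)
      outer <- cst$groundings[["a,b"]]
      per <- vapply(seq_len(nrow(outer)), function(i)
        1 - formula_value(cst$formula$body, a, cst$groundings,
                          env = list(a = outer$a[i], b = outer$b[i])),
        numeric(1))
      expect_equal(constraint_violation(cst, a), sum(per), tolerance = 1e-12)
    }
  }
})

test_that("implication monotonicity: raising the consequent never increases
          violation, raising the antecedent never decreases it", {
  set.seed(26)
  h <- tiny_hierarchy()
  pairs <- all_level_pairs(h)
  cst <- build_rule("P->D", h, pairs)
  for (rep in 1:50) {
    bp <- runif(1); bd <- runif(1)
    mk <- function(p, d) truth_assignment(
      h, boundp = c("p1|p2" = p), boundd = c("d1|d2" = d))
    v <- constraint_violation(cst, mk(bp, bd))
    up_d <- min(1, bd + runif(1, 0, 1 - bd))
    expect_lte(constraint_violation(cst, mk(bp, up_d)), v + 1e-12)
    up_p <- min(1, bp + runif(1, 0, 1 - bp))
    expect_gte(constraint_violation(cst, mk(up_p, bd)), v - 1e-12)
  }
})

test_that("violation subgradients match finite differences off kinks", {
  set.seed(27)
  h <- tiny_hierarchy()
  pairs <- all_level_pairs(h)
  eps <- 1e-6
  checked <- 0
  while (checked < 100) {
    nm <- sample(c("P->D", "D->P", "D->R", "R->D", "P->R", "R->P"), 1)
    cst <- build_rule(nm, h, pairs, use_exists_n = nm %in% c("D->R", "P->R"),
                      n = 2)
    a <- random_fuzzy(h)
    # keep clear of residuum/selection kinks: require all pairwise value
    # gaps above a margin
    allv <- unlist(a$values)
    if (min(dist(allv)) < 1e-3) next
    g <- violation_subgradient(cst, a)
    v0 <- constraint_violation(cst, a)
    for (p in names(a$values)) {
      keys <- names(a$values[[p]])
      for (k in keys) {
        a2 <- a
        a2$values[[p]][k] <- a$values[[p]][k] + eps
        fd <- (constraint_violation(cst, a2) - v0) / eps
        an <- if (!is.null(g[[p]]) && k %in% names(g[[p]])) g[[p]][[k]] else 0
        expect_equal(fd, an, tolerance = 1e-5)
        checked <- checked + 1
      }
    }
  }
})

test_that("crisp correspondence: zero violation iff classically satisfied", {
  set.seed(28)
  tried <- 0
  while (tried < 60) {
    h <- random_hierarchy(4L)
    pairs <- all_level_pairs(h)
    if (!nrow(pairs$protein)) next
    a <- random_crisp(h)
    for (nm in c("P->D", "D->P", "D->R", "R->D", "P->R", "R->P")) {
      cst <- build_rule(nm, h, pairs, use_exists_n = nm %in% c("D->R"),
                        n = 2)
      outer <- cst$groundings[["a,b"]]
      sat <- all(vapply(seq_len(nrow(outer)), function(i)
        boolean_oracle(cst$formula$body, a, cst$groundings,
                       env = list(a = outer$a[i], b = outer$b[i])),
        logical(1)))
      v <- constraint_violation(cst, a)
      expect_identical(v < 1e-12, sat)
    }
    tried <- tried + 1
  }
})

test_that("the rule text parser reproduces builder formulas", {
  txt <- paste("forall (a,b) implies(and(hasdom(a), hasdom(b)),",
               "implies(boundp(a,b), exists (c,e) and(boundd(c,e),",
               "parentpd(a,c), parentpd(b,e))))")
  f <- parse_rule(txt)
  h <- tiny_hierarchy()
  built <- build_rule("P->D", h, all_level_pairs(h))
  expect_equal(unclass(f), unclass(built$formula), ignore_attr = TRUE)
  f2 <- parse_rule("exists_n 5 (r,s) boundr(r,s)")
  expect_identical(f2$kind, "exists_n")
  expect_identical(f2$n, 5L)
  expect_error(parse_rule("forall (a,b)"), "unexpected end")
  expect_error(parse_rule("and(boundp(a,b))"), "at least two")
})
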