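# Shared fixtures: tiny hierarchies, random hierarchies and crisp
# assignments for property tests, and an independent reference solver for
# the stage-1 convex problem.

# two proteins, one domain each, a few residues: the smallest hierarchy on
# which every rule has a nontrivial grounding
tiny_hierarchy <- function() {
  hierarchy(parent_pd = c(d1 = "p1", d2 = "p2"),
            parent_dr = c(r1 = "d1", r2 = "d1", r3 = "d2", r4 = "d2"))
}

all_level_pairs <- function(h) {
  ap <- function(ids) {
    if (length(ids) < 2L)
      return(data.frame(id_a = character(), id_b = character(),
                        stringsAsFactors = FALSE))
    canonical_pairs(as.data.frame(t(utils::combn(ids, 2L)),
                                  stringsAsFactors = FALSE))
  }
  list(protein = ap(h$proteins), domain = ap(h$domains),
       residue = ap(h$residues))
}

# random hierarchy with <= max_p proteins (for exhaustive crisp tests)
random_hierarchy <- function(max_p = 4L) {
  np <- sample(2:max_p, 1L)
  proteins <- paste0("p", seq_len(np))
  ndom <- sample(0:2, np, replace = TRUE)
  if (sum(ndom) < 2L) ndom[1:2] <- 1L
  domains <- paste0("d", seq_len(sum(ndom)))
  parent_pd <- stats::setNames(rep(proteins, ndom), domains)
  nres <- sample(0:3, length(domains), replace = TRUE)
  residues <- if (sum(nres)) paste0("r", seq_len(sum(nres))) else character()
  parent_dr <- stats::setNames(rep(domains, nres), residues)
  hierarchy(parent_pd, parent_dr, proteins = proteins)
}

# random crisp assignment over all pairs of a hierarchy
random_crisp <- function(h, p = 0.4) {
  pairs <- all_level_pairs(h)
  pick <- function(df) {
    if (!nrow(df)) return(character())
    keys <- pair_key(df$id_a, df$id_b)
    keys[stats::runif(length(keys)) < p]
  }
  crisp_assignment(h, positives = list(protein = pick(pairs$protein),
                                       domain = pick(pairs$domain),
                                       residue = pick(pairs$residue)))
}

# random fuzzy assignment over all pairs (values in (0,1), away from the
# residuum/selection kinks when jitter = TRUE)
random_fuzzy <- function(h, away_from_kinks = FALSE) {
  pairs <- all_level_pairs(h)
  vals <- function(df) {
    if (!nrow(df)) return(NULL)
    keys <- pair_key(df$id_a, df$id_b)
    stats::setNames(stats::runif(length(keys), 0.02, 0.98), keys)
  }
  truth_assignment(h, boundp = vals(pairs$protein),
                   boundd = vals(pairs$domain),
                   boundr = vals(pairs$residue))
}

# small random PSD gram over n objects
random_gram <- function(n, ids = paste0("x", seq_len(n)), rank = n) {
  A <- matrix(stats::rnorm(n * rank), n, rank)
  g <- tcrossprod(A)
  dimnames(g) <- list(ids, ids)
  g
}

# independent reference solver for the stage-1 problem:
# min lambda_r w'Kw + sum hinge(y, (Kw)_labeled), solved through its dual
# box-constrained QP with kernlab's interior-point solver ipop()
reference_stage1 <- function(K, labeled, y, lambda_r) {
  Kl <- K[labeled, labeled, drop = FALSE]
  Ct <- 1                                # dual box: 0 <= alpha <= 1
  H <- (y %o% y) * Kl / (2 * lambda_r)
  n <- length(y)
  # the equality row is a dummy (0 <= sum alpha <= n*C is never binding);
  # ipop needs a full-rank A
  sol <- kernlab::ipop(c = rep(-1, n), H = H + diag(1e-8, n),
                       A = matrix(1, 1, n), b = 0, r = n * Ct,
                       l = rep(0, n), u = rep(Ct, n),
                       sigf = 9, maxiter = 400)
  alpha <- kernlab::primal(sol)
  w <- numeric(nrow(K))
  w[labeled] <- y * alpha / (2 * lambda_r)
  w
}
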