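# Generator of hierarchically consistent multi-level interaction datasets:
# a random protein-domain-residue hierarchy, planted interactions that
# satisfy every consistency rule (top-down planting, upward closure by
# construction), and per-object features whose pair similarity reflects the
# planted interactions up to a tunable noise level.

#' Parameters of the synthetic dataset generator
#'
#' @param n_proteins number of proteins.
#' @param domains_per_protein integer range `c(min, max)` of domains per
#'   protein.
#' @param residues_per_domain integer range of residues per domain; the
#'   minimum must be at least `interface_size` so every bound domain pair
#'   can host a full interface.
#' @param protein_interaction_rate target probability that a protein pair
#'   is bound. Binding is mediated by domain-family compatibility, so the
#'   realized rate is approximate: the number of compatible family combos
#'   is the integer closest to the target (at least one), and dense
#'   domain complements can realize a higher rate than requested.
#' @param interface_size number of bound residue cross-pairs planted under
#'   each bound domain pair (default 5, a typical interface size).
#' @param feature_dim dimensionality of the object features.
#' @param noise_sigma standard deviation of the isotropic feature noise;
#'   either a scalar or a named vector with entries `protein`, `domain`,
#'   `residue` (distinct levels of measurement noise per layer).
#' @param n_types number of latent object types per level; objects of the
#'   same type share a feature direction and binding is decided by type
#'   compatibility, which is what makes interaction learnable from pair
#'   similarity.
#' @param balanced_negatives sample exactly as many negative pairs as there
#'   are positives at each level (the usual balanced gold standard). On
#'   degenerate instances whose candidate space is smaller than the
#'   request, all candidates are used with a warning.
#' @param negative_ratio negatives-per-positive ratio used when
#'   `balanced_negatives` is `FALSE`.
#' @param dropout probability of deleting each domain/residue-level
#'   positive from the gold standard; a scalar or a named vector with
#'   entries `domain`, `residue`. Real interaction data is heavily
#'   under-characterized below the protein level (solved complexes are
#'   scarce), so lower-level gold standards carry far fewer labeled pairs
#'   than planted interactions; `dropout` emulates that missingness. The
#'   planted truth stays complete and consistent, only the labels are
#'   thinned. Default 0.
#' @param seed integer seed; generation is deterministic given the seed.
#' @return list of class `mlpip_synth_params`.
#' @export
synth_params <- function(n_proteins, domains_per_protein = c(1L, 2L),
                         residues_per_domain = c(5L, 8L),
                         protein_interaction_rate = 0.3,
                         interface_size = 5L, feature_dim = 16L,
                         noise_sigma = 0.5, n_types = 4L,
                         balanced_negatives = TRUE, negative_ratio = 2,
                         dropout = 0, seed = 0L) {
  if (n_proteins < 2) stop("infeasible params: need at least two proteins")
  if (interface_size < 1L) stop("interface_size must be >= 1")
  if (min(residues_per_domain) < interface_size)
    stop("residues_per_domain minimum must be >= interface_size")
  if (protein_interaction_rate < 0 || protein_interaction_rate > 1)
    stop("protein_interaction_rate must be a probability")
  ns <- c(protein = NA_real_, domain = NA_real_, residue = NA_real_)
  if (length(noise_sigma) == 1L && is.null(names(noise_sigma)))
    ns[] <- noise_sigma
  else {
    if (!all(names(noise_sigma) %in% names(ns)))
      stop("noise_sigma names must be protein/domain/residue")
    ns[names(noise_sigma)] <- noise_sigma
    ns[is.na(ns)] <- 0
  }
  if (any(ns < 0)) stop("noise_sigma must be nonnegative")
  dr <- c(domain = 0, residue = 0)
  if (length(dropout) == 1L && is.null(names(dropout)))
    dr[] <- dropout
  else {
    if (!all(names(dropout) %in% names(dr)))
      stop("dropout names must be domain/residue")
    dr[names(dropout)] <- dropout
  }
  if (any(dr < 0 | dr >= 1)) stop("dropout must be in [0, 1)")
  structure(list(n_proteins = as.integer(n_proteins),
                 domains_per_protein = as.integer(domains_per_protein),
                 residues_per_domain = as.integer(residues_per_domain),
                 protein_interaction_rate = protein_interaction_rate,
                 interface_size = as.integer(interface_size),
                 feature_dim = as.integer(feature_dim),
                 noise_sigma = ns, n_types = as.integer(n_types),
                 balanced_negatives = isTRUE(balanced_negatives),
                 negative_ratio = negative_ratio,
                 dropout = dr, seed = as.integer(seed)),
            class = "mlpip_synth_params")
}

sample_range <- function(n, range) {
  if (range[1L] == range[2L]) rep(range[1L], n)
  else sample(seq(range[1L], range[2L]), n, replace = TRUE)
}

# uniform sample of `count` negative (non-positive, distinct-parent) pairs;
# rejection sampling for large universes, exhaustive enumeration when the
# candidate space is small enough to hold in memory
sample_negatives <- function(ids, parent_of, pos_keys, count) {
  out <- character()
  if (length(ids) < 2L || count == 0L) return(out)
  n_all <- length(ids) * (length(ids) - 1) / 2
  if (n_all <= 2e5) {
    m <- t(utils::combn(ids, 2L))
    keep <- rep(TRUE, nrow(m))
    if (!is.null(parent_of))
      keep <- parent_of[m[, 1L]] != parent_of[m[, 2L]]
    k <- setdiff(pair_key(m[keep, 1L], m[keep, 2L]), pos_keys)
    if (length(k) < count) {
      warning("only ", length(k), " negative candidates for ", count,
              " requested; using all of them", call. = FALSE)
      count <- length(k)
    }
    return(sort(sample(k, count)))
  }
  guard <- 0L
  while (length(out) < count) {
    guard <- guard + 1L
    if (guard > 200L) stop("unable to sample enough negative pairs")
    need <- max(2L * (count - length(out)), 16L)
    a <- sample(ids, need, replace = TRUE)
    b <- sample(ids, need, replace = TRUE)
    keep <- a != b
    if (!is.null(parent_of)) keep <- keep & parent_of[a] != parent_of[b]
    k <- unique(pair_key(a[keep], b[keep]))
    k <- setdiff(k, c(pos_keys, out))
    out <- c(out, k)
  }
  sort(out[seq_len(count)])
}

key_to_pairs <- function(keys, label = NULL) {
  if (!length(keys))
    return(data.frame(id_a = character(), id_b = character(),
                      stringsAsFactors = FALSE))
  parts <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  out <- data.frame(id_a = parts[, 1L], id_b = parts[, 2L],
                    stringsAsFactors = FALSE)
  if (!is.null(label)) out$label <- label
  out
}

#' Generate a synthetic multi-level interaction dataset
#'
#' Sampling proceeds top-down: (1) a random hierarchy; (2) every object
#' draws a latent type, and protein pairs with a compatible type
#' combination (compatibility density = `protein_interaction_rate`) are
#' bound; (3) under each bound protein pair, the domain cross-pair with the
#' most compatible domain families is bound; (4) under each bound domain
#' pair, the `interface_size` most compatible residue cross-pairs form the
#' bound interface. Planted this way the truth satisfies every consistency
#' rule (including the n-existential at `n = interface_size`) by
#' construction, and bound pairs at every level share latent structure, so
#' interaction is learnable from pair similarity. Features are the object's
#' type direction plus isotropic Gaussian noise of standard deviation
#' `noise_sigma` (the knob that degrades attainable accuracy). Gold labels
#' are the planted positives (optionally thinned by `dropout` at the lower
#' levels) plus uniformly sampled negative pairs with distinct parent
#' proteins.
#'
#' @param params [synth_params()].
#' @return list of class `mlpip_synth` with elements `hierarchy`,
#'   `features` (list of matrices per level), `gold` (list of
#'   [labeled_pairs()] per level), `planted` (list of positive-pair
#'   data.frames per level: the full crisp truth), `params`.
#' @export
generate <- function(params) {
  stopifnot(inherits(params, "mlpip_synth_params"))
  with_seed(params$seed, {
    np <- params$n_proteins
    proteins <- sprintf("p%03d", seq_len(np))
    ndom <- sample_range(np, params$domains_per_protein)
    domains <- sprintf("d%04d", seq_len(sum(ndom)))
    parent_pd <- stats::setNames(rep(proteins, ndom), domains)
    nres <- sample_range(length(domains), params$residues_per_domain)
    residues <- sprintf("r%05d", seq_len(sum(nres)))
    parent_dr <- stats::setNames(rep(domains, nres), residues)
    h <- hierarchy(parent_pd, parent_dr, proteins = proteins)
    dom_of <- children_map(h, "protein")
    res_of <- children_map(h, "domain")

    # latent types: every domain draws a family, every residue a type, each
    # with its own feature direction. Binding is decided at the domain
    # level by a global family-compatibility relation (interactions are
    # mediated by domain family pairs); protein binding is the upward
    # closure, so the planted truth is hierarchically consistent by
    # construction and bound pairs at every level share latent structure.
    m <- params$n_types
    fam_of <- stats::setNames(sample(m, length(domains), replace = TRUE),
                              domains)
    rtype_of <- stats::setNames(sample(m, length(residues), replace = TRUE),
                                residues)
    # number of compatible family combos calibrated so the expected
    # protein-pair binding density approximates protein_interaction_rate
    dbar <- mean(params$domains_per_protein)
    n_compat <- max(1L, round(params$protein_interaction_rate * m^2 /
                                (2 * dbar^2)))
    combos <- which(upper.tri(matrix(0, m, m), diag = TRUE))
    compat_d <- matrix(FALSE, m, m)
    compat_d[sample(combos, min(n_compat, length(combos)))] <- TRUE
    compat_d <- compat_d | t(compat_d)
    score_r <- matrix(stats::rnorm(m * m), m, m)
    score_r <- (score_r + t(score_r)) / 2

    # plant: compatible-family domain cross pairs are bound; their parent
    # protein pairs are bound; each bound domain pair hosts an interface of
    # the interface_size most residue-type-compatible cross pairs
    pp <- t(utils::combn(proteins, 2L))
    plant_domains <- function(compat) {
      bp <- matrix(character(), 0L, 2L)
      bd <- matrix(character(), 0L, 2L)
      for (i in seq_len(nrow(pp))) {
        da <- dom_of[[pp[i, 1L]]]
        db <- dom_of[[pp[i, 2L]]]
        cross <- expand.grid(a = da, b = db, stringsAsFactors = FALSE)
        ok <- compat[cbind(fam_of[cross$a], fam_of[cross$b])]
        if (any(ok)) {
          bp <- rbind(bp, pp[i, , drop = FALSE])
          bd <- rbind(bd, as.matrix(cross[ok, , drop = FALSE]))
        }
      }
      list(bp = bp, bd = bd)
    }
    planted_pairs <- plant_domains(compat_d)
    if (nrow(planted_pairs$bp) == 0L) {
      # the sampled compatible combos matched no realized family cross
      # pair; declare the modal observed combo compatible so the dataset
      # is never interaction-free
      obs <- character()
      for (i in seq_len(nrow(pp))) {
        da <- dom_of[[pp[i, 1L]]]
        db <- dom_of[[pp[i, 2L]]]
        cross <- expand.grid(a = da, b = db, stringsAsFactors = FALSE)
        obs <- c(obs, paste(pmin(fam_of[cross$a], fam_of[cross$b]),
                            pmax(fam_of[cross$a], fam_of[cross$b])))
      }
      modal <- as.integer(strsplit(names(which.max(table(obs))), " ")[[1L]])
      compat_d[modal[1L], modal[2L]] <- TRUE
      compat_d[modal[2L], modal[1L]] <- TRUE
      planted_pairs <- plant_domains(compat_d)
    }
    bound_p <- planted_pairs$bp
    bound_d <- planted_pairs$bd
    bound_r <- matrix(character(), 0L, 2L)
    for (i in seq_len(nrow(bound_d))) {
      ra <- res_of[[bound_d[i, 1L]]]
      rb <- res_of[[bound_d[i, 2L]]]
      cross <- expand.grid(a = ra, b = rb, stringsAsFactors = FALSE)
      sc <- score_r[cbind(rtype_of[cross$a], rtype_of[cross$b])]
      take <- order(-sc)[seq_len(params$interface_size)]
      bound_r <- rbind(bound_r, as.matrix(cross[take, ]))
    }
    planted <- list(
      protein = canonical_pairs(as.data.frame(bound_p,
                                              stringsAsFactors = FALSE)),
      domain = canonical_pairs(as.data.frame(bound_d,
                                             stringsAsFactors = FALSE)),
      residue = canonical_pairs(as.data.frame(bound_r,
                                              stringsAsFactors = FALSE)))

    # features: domains carry their family direction, residues their type
    # direction, proteins the sum of their domains' family directions
    # (protein content = its domains); plus isotropic noise
    dim <- params$feature_dim
    ids_of <- list(protein = proteins, domain = domains, residue = residues)
    fam_dirs <- matrix(stats::rnorm(m * dim), m, dim)
    rty_dirs <- matrix(stats::rnorm(m * dim), m, dim)
    base <- list(
      domain = fam_dirs[fam_of, , drop = FALSE],
      residue = rty_dirs[rtype_of, , drop = FALSE],
      protein = t(vapply(proteins, function(p) {
        ch <- dom_of[[p]]
        if (!length(ch)) return(numeric(dim))
        colSums(fam_dirs[fam_of[ch], , drop = FALSE])
      }, numeric(dim))))
    features <- list()
    for (lv in levels3) {
      ids <- ids_of[[lv]]
      z <- base[[lv]] + params$noise_sigma[[lv]] *
        matrix(stats::rnorm(length(ids) * dim), length(ids), dim)
      rownames(z) <- ids
      features[[lv]] <- z / sqrt(dim)
    }

    # gold labels: planted positives (after dropout) + sampled negatives
    parent_at <- list(protein = NULL, domain = h$parent_pd,
                      residue = h$parent_pr)
    gold <- list()
    for (lv in levels3) {
      pos <- planted[[lv]]
      if (lv != "protein" && params$dropout[[lv]] > 0 && nrow(pos))
        pos <- pos[stats::runif(nrow(pos)) >= params$dropout[[lv]], ,
                   drop = FALSE]
      pos_keys <- pair_key(pos$id_a, pos$id_b)
      n_neg <- if (params$balanced_negatives) length(pos_keys)
               else round(params$negative_ratio * length(pos_keys))
      neg_keys <- sample_negatives(ids_of[[lv]], parent_at[[lv]], pos_keys,
                                   n_neg)
      gold[[lv]] <- labeled_pairs(
        rbind(key_to_pairs(pos_keys, 1L), key_to_pairs(neg_keys, -1L)),
        lv, h)
    }
    structure(list(hierarchy = h, features = features, gold = gold,
                   planted = planted, params = params),
              class = "mlpip_synth")
  })
}

#' @export
print.mlpip_synth <- function(x, ...) {
  cat("<mlpip_synth> ", length(x$hierarchy$proteins), "p/",
      length(x$hierarchy$domains), "d/", length(x$hierarchy$residues),
      "r; positives ", paste(vapply(x$planted, nrow, integer(1)),
                             collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Check that the planted truth satisfies every consistency rule
#'
#' Evaluates all six rules (with the n-existential at
#' `n = interface_size` for the residue-directed downward rules) on the
#' planted crisp truth, grounding the universals over every object pair.
#' Returns `TRUE` iff the total violation is zero.
#'
#' @param d a [generate()] result.
#' @param verbose print per-rule violations.
#' @return logical scalar.
#' @export
verify_consistency <- function(d, verbose = FALSE) {
  h <- d$hierarchy
  all_pairs <- function(ids) {
    if (length(ids) < 2L)
      return(data.frame(id_a = character(), id_b = character(),
                        stringsAsFactors = FALSE))
    m <- t(utils::combn(ids, 2L))
    canonical_pairs(as.data.frame(m, stringsAsFactors = FALSE))
  }
  pairs <- list(protein = all_pairs(h$proteins),
                domain = all_pairs(h$domains),
                residue = all_pairs(h$residues))
  a <- crisp_assignment(h, positives = d$planted)
  ok <- TRUE
  for (nm in rule_names) {
    cst <- build_rule(nm, h, pairs, use_exists_n = TRUE,
                      n = d$params$interface_size)
    v <- constraint_violation(cst, a)
    if (verbose) cat(sprintf("%-5s violation %g\n", nm, v))
    if (v > 1e-12) ok <- FALSE
  }
  ok
}

#' Write a synthetic dataset to a directory of plain-text files
#'
#' Writes `hierarchy.tsv`, `features_<level>.tsv`, `labels.tsv`,
#' `planted.tsv` and a JSON `manifest.json` of the generator parameters.
#' Feature values are written with full double precision so a round-trip
#' reproduces the dataset exactly.
#'
#' @param d a [generate()] result.
#' @param dir output directory (created if missing).
#' @export
write_dataset <- function(d, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_hierarchy(d$hierarchy, file.path(dir, "hierarchy.tsv"))
  for (lv in names(d$features)) {
    f <- d$features[[lv]]
    rows <- vapply(seq_len(nrow(f)), function(i)
      paste(c(rownames(f)[i], sprintf("%.17g", f[i, ])), collapse = "\t"),
      character(1))
    writeLines(rows, file.path(dir, paste0("features_", lv, ".tsv")))
  }
  write_labels(d$gold, file.path(dir, "labels.tsv"))
  planted_lp <- lapply(levels3, function(lv) {
    p <- d$planted[[lv]]
    p$label <- rep(1L, nrow(p))
    labeled_pairs(p, lv, d$hierarchy)
  })
  write_labels(planted_lp, file.path(dir, "planted.tsv"))
  pl <- unclass(d$params)
  pl$noise_sigma <- as.list(pl$noise_sigma)
  pl$dropout <- as.list(pl$dropout)
  jsonlite::write_json(pl, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a synthetic dataset written by [write_dataset()]
#' @param dir dataset directory.
#' @return an `mlpip_synth` object.
#' @export
load_dataset <- function(dir) {
  h <- load_hierarchy(file.path(dir, "hierarchy.tsv"))
  features <- list()
  for (lv in levels3) {
    p <- file.path(dir, paste0("features_", lv, ".tsv"))
    if (file.exists(p)) features[[lv]] <- load_features(p)
  }
  gold <- lapply(stats::setNames(nm = levels3), function(lv)
    load_labels(file.path(dir, "labels.tsv"), lv, h))
  planted <- lapply(stats::setNames(nm = levels3), function(lv) {
    lp <- load_labels(file.path(dir, "planted.tsv"), lv, h)
    sel <- lp$label == 1L
    data.frame(id_a = lp$id_a[sel], id_b = lp$id_b[sel],
               stringsAsFactors = FALSE)
  })
  pl <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  params <- synth_params(
    n_proteins = pl$n_proteins,
    domains_per_protein = pl$domains_per_protein,
    residues_per_domain = pl$residues_per_domain,
    protein_interaction_rate = pl$protein_interaction_rate,
    interface_size = pl$interface_size, feature_dim = pl$feature_dim,
    noise_sigma = unlist(pl$noise_sigma), n_types = pl$n_types,
    balanced_negatives = pl$balanced_negatives,
    negative_ratio = pl$negative_ratio, dropout = unlist(pl$dropout),
    seed = pl$seed)
  structure(list(hierarchy = h, features = features, gold = gold,
                 planted = planted, params = params),
            class = "mlpip_synth")
}
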