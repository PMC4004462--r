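# Kernel-expansion predictors, the regularized hinge-loss objective with
# constraint penalties, and the two-stage training procedure: a convex
# independent fit per level, then joint subgradient descent on the penalized
# objective with transductive enforcement on unlabeled pairs.

#' Training configuration
#'
#' @param lambda_r weight of the squared-norm regularizer (one per level,
#'   shared), default 0.1.
#' @param lambda_c weight of the constraint penalty term, default 1.
#' @param learning_rate initial step size for the stage-2 line search.
#' @param max_iters maximum stage-2 iterations.
#' @param tolerance relative objective-change convergence threshold.
#' @param seed integer seed (recorded; training itself is deterministic).
#' @param n_exist default count for the n-existential quantifier.
#' @return list of class `mlpip_config`.
#' @export
train_config <- function(lambda_r = 0.1, lambda_c = 1, learning_rate = 0.5,
                         max_iters = 500L, tolerance = 1e-5, seed = 0L,
                         n_exist = 5L) {
  stopifnot(lambda_r >= 0, lambda_c >= 0, learning_rate > 0,
            max_iters >= 1, tolerance > 0, n_exist >= 1)
  structure(list(lambda_r = lambda_r, lambda_c = lambda_c,
                 learning_rate = learning_rate,
                 max_iters = as.integer(max_iters), tolerance = tolerance,
                 seed = as.integer(seed), n_exist = as.integer(n_exist)),
            class = "mlpip_config")
}

#' Margin-to-truth bridge
#'
#' Maps a kernel-machine margin to a `[0,1]` truth value with the linear
#' clamp `(margin + 1) / 2`: margin -1 maps to false, 0 to the decision
#' boundary 0.5, +1 to true. Piecewise linear, so the penalty subgradients
#' stay simple.
#'
#' @param margin numeric vector.
#' @return values in `[0,1]`.
#' @export
squash <- function(margin) pmin(pmax((margin + 1) / 2, 0), 1)

# subgradient of squash; 1/2 on the closed interval [-1, 1] so a value
# sitting exactly on a clamp corner can still move off it
squash_grad <- function(margin) 0.5 * (margin >= -1 & margin <= 1)

#' Hinge loss
#' @param y label in `{-1, +1}`.
#' @param margin predicted margin.
#' @return `max(0, 1 - y * margin)` (vectorized).
#' @export
hinge_loss <- function(y, margin) {
  if (!all(y %in% c(-1, 1))) stop("labels must be -1 or +1")
  pmax(0, 1 - y * margin)
}

#' Threshold a margin into a binding decision
#'
#' Positive margins (squashed value above 0.5) are predicted interactions;
#' an exact zero margin is classified negative.
#'
#' @param margin numeric vector.
#' @return integer vector in `{-1, +1}`.
#' @export
classify <- function(margin) ifelse(margin > 0, 1L, -1L)

# ---- predictor model --------------------------------------------------------

new_predictor <- function(level, basis, K, gram, w = numeric(nrow(basis))) {
  keys <- pair_key(basis$id_a, basis$id_b)
  structure(list(level = level, basis = basis, keys = keys, K = K,
                 gram = gram, w = w),
            class = "mlpip_predictor")
}

#' @export
print.mlpip_predictor <- function(x, ...) {
  cat("<mlpip_predictor> level ", x$level, ", ", length(x$w),
      " basis pairs\n", sep = "")
  invisible(x)
}

#' Margins of a kernel-expansion predictor
#'
#' Representer-form evaluation: the margin of a query pair is the weighted
#' sum of pairwise-kernel similarities to the basis pairs. Symmetric in the
#' order of the two members of any pair.
#'
#' @param m predictor model.
#' @param pairs data.frame `id_a`, `id_b`; defaults to the basis itself.
#' @return numeric vector named by canonical pair key.
#' @export
predict_margins <- function(m, pairs = NULL) {
  if (is.null(pairs)) {
    out <- drop(m$K %*% m$w)
    names(out) <- m$keys
    return(out)
  }
  Kq <- pairwise_gram(m$gram, rows = pairs, cols = m$basis)
  out <- drop(Kq %*% m$w)
  names(out) <- pair_key(pairs$id_a, pairs$id_b)
  out
}

# ---- stage 1: independent convex fits ---------------------------------------

#' Stage-1 fit: independent regularized hinge-loss machine for one level
#'
#' Minimizes `lambda_r * w' K w + sum_j hinge(y_j, (K w)_j)` over the
#' expansion weights. The problem is convex; it is solved exactly in its
#' dual by cyclic coordinate ascent (the standard box-constrained SVM dual
#' without offset), iterated to a small duality gap, so the result does not
#' depend on initialization. Weights of unlabeled basis pairs stay zero.
#'
#' @param K pairwise Gram matrix over the basis pairs (labeled and
#'   unlabeled).
#' @param labeled integer indices of the labeled basis pairs.
#' @param y labels in `{-1, +1}` aligned with `labeled`.
#' @param cfg [train_config()]; only `lambda_r` is used.
#' @param gap_tol relative duality-gap tolerance.
#' @param max_passes cap on coordinate sweeps.
#' @return weight vector over all basis pairs.
#' @export
stage1_fit <- function(K, labeled, y, cfg = train_config(),
                       gap_tol = 1e-9, max_passes = 5000L) {
  nl <- length(labeled)
  if (nl == 0L)
    stop("no labeled data for this level: supply labels or skip the level")
  if (!all(y %in% c(-1, 1))) stop("labels must be -1 or +1")
  lambda_r <- cfg$lambda_r
  if (lambda_r <= 0) stop("stage1_fit requires lambda_r > 0")
  # dual of min lambda_r w'Kw + sum hinge(y, (Kw)_labeled):
  #   max sum(alpha) - 1/2 (Y alpha)' Kt (Y alpha),  0 <= alpha <= 1,
  # with Kt = K/(2 lambda_r) and w = Y alpha / (2 lambda_r)
  Ct <- 1
  Kt <- K[labeled, labeled, drop = FALSE] / (2 * lambda_r)
  alpha <- numeric(nl)
  marg <- numeric(nl)                       # primal margins on labeled pairs
  diagK <- diag(Kt)
  for (pass in seq_len(max_passes)) {
    delta_max <- 0
    for (i in seq_len(nl)) {
      viol <- 1 - y[i] * marg[i]
      newa <- if (diagK[i] > 0)
        min(max(alpha[i] + viol / diagK[i], 0), Ct)
      else if (viol > 0) Ct else 0
      da <- newa - alpha[i]
      if (da != 0) {
        marg <- marg + da * y[i] * Kt[, i]
        alpha[i] <- newa
        delta_max <- max(delta_max, abs(da))
      }
    }
    ya <- y * alpha
    primal <- sum(ya * marg) / 2 + sum(pmax(0, 1 - y * marg))
    dual <- sum(alpha) - sum(ya * marg) / 2
    if (primal - dual <= gap_tol * max(1, abs(primal))) break
    if (delta_max == 0) break
  }
  w <- numeric(nrow(K))
  w[labeled] <- y * alpha / (2 * lambda_r)
  w
}

# ---- objective --------------------------------------------------------------

# labels_idx: list per level of list(idx = basis indices, y = labels)
make_values <- function(models, margins, clamped = NULL) {
  vals <- list()
  for (lv in names(models)) {
    pred <- names(pred_level)[pred_level == lv]
    v <- stats::setNames(squash(margins[[lv]]), models[[lv]]$keys)
    cl <- clamped[[lv]]
    if (!is.null(cl)) {
      miss <- setdiff(names(cl), names(v))
      if (length(miss)) v <- c(v, stats::setNames(rep(0, length(miss)), miss))
      v[names(cl)] <- cl
    }
    vals[[pred]] <- v
  }
  # levels held entirely by clamps (no predictor) still provide values
  for (lv in setdiff(names(clamped %||% list()), names(models))) {
    pred <- names(pred_level)[pred_level == lv]
    vals[[pred]] <- clamped[[lv]]
  }
  vals
}

eval_objective <- function(models, margins, labels_idx, compiled, cfg,
                           clamped = NULL, grad = FALSE) {
  reg <- 0; loss <- 0
  grads <- list()
  vals <- make_values(models, margins, clamped)
  h <- models[[1L]]$h_ref
  a <- structure(list(h = h$h, guards = h$guards, values = vals,
                      default = NA_real_, crisp = FALSE),
                 class = "mlpip_assignment")
  penalty <- 0
  pen_g <- list()
  for (cst in compiled) {
    r <- eval_compiled(cst, a, grad = grad)
    penalty <- penalty + cst$weight * r$violation
    if (grad) {
      for (p in names(r$grad)) {
        g0 <- pen_g[[p]] %||% numeric()
        add <- cst$weight * r$grad[[p]]
        common <- intersect(names(g0), names(add))
        if (length(common)) g0[common] <- g0[common] + add[common]
        new <- setdiff(names(add), names(g0))
        pen_g[[p]] <- c(g0, add[new])
      }
    }
  }
  for (lv in names(models)) {
    m <- margins[[lv]]
    w <- models[[lv]]$w
    reg <- reg + cfg$lambda_r * sum(w * m)        # w' K w with m = K w
    li <- labels_idx[[lv]]
    hl <- NULL
    if (!is.null(li) && length(li$idx)) {
      hl <- 1 - li$y * m[li$idx]
      loss <- loss + sum(pmax(0, hl))
    }
    if (grad) {
      gm <- numeric(length(m))
      pred <- names(pred_level)[pred_level == lv]
      pg <- pen_g[[pred]]
      if (!is.null(pg) && length(pg)) {
        if (!is.null(clamped[[lv]]))
          pg <- pg[!(names(pg) %in% names(clamped[[lv]]))]
        idx <- match(names(pg), models[[lv]]$keys)
        ok <- !is.na(idx)
        gm[idx[ok]] <- gm[idx[ok]] + unname(pg[ok]) * squash_grad(m[idx[ok]])
      }
      gl <- numeric(length(m))
      if (!is.null(hl)) {
        kink_eps <- 1e-4
        act <- hl > kink_eps
        gl[li$idx[act]] <- -li$y[act]
        # minimal-norm subgradient at the hinge kink: pick the hinge
        # coefficient in [0, 1] that best cancels the penalty push, so
        # blocked label-penalty conflicts drop out of the descent
        # direction instead of poisoning it
        kink <- abs(hl) <= kink_eps
        if (any(kink)) {
          q <- cfg$lambda_c * gm[li$idx[kink]]
          cstar <- pmin(pmax(li$y[kink] * q, 0), 1)
          gl[li$idx[kink]] <- -li$y[kink] * cstar
        }
      }
      # d(total)/dw = K (2 lambda_r w + g_loss + lambda_c g_penalty),
      # using m = K w for the regularizer term
      gw <- 2 * cfg$lambda_r * m +
        drop(models[[lv]]$K %*% (gl + cfg$lambda_c * gm))
      grads[[lv]] <- gw
    }
  }
  list(regularizer = reg, loss = loss, penalty = penalty,
       total = reg + loss + cfg$lambda_c * penalty, grads = grads)
}

#' Objective breakdown of a task set
#'
#' Evaluates the training objective at the task set's current weights:
#' `regularizer + loss + lambda_c * penalty`, with
#' `regularizer = lambda_r * sum_k w_k' K_k w_k`, `loss` the hinge loss over
#' labeled pairs, and `penalty` the weighted sum of constraint violations on
#' the squashed margins.
#'
#' @param t task set from [fit()] / [stage2_fit()].
#' @param cfg optional config override (defaults to the one stored in `t`).
#' @return list with `regularizer`, `loss`, `penalty`, `total`.
#' @export
objective <- function(t, cfg = NULL) {
  cfg <- cfg %||% t$cfg
  margins <- lapply(t$models, function(m) drop(m$K %*% m$w))
  r <- eval_objective(t$models, margins, t$labels_idx, t$compiled, cfg,
                      clamped = t$clamped, grad = FALSE)
  r[c("regularizer", "loss", "penalty", "total")]
}

# ---- stage 2: joint constrained descent -------------------------------------

#' Stage-2 fit: joint subgradient descent on the penalized objective
#'
#' Starting from the stage-1 solution, performs full-batch subgradient
#' descent on the complete objective (regularizer + hinge loss +
#' `lambda_c` times the constraint penalty) with a backtracking line search
#' that only accepts steps decreasing the objective, so the objective is
#' non-increasing across accepted iterations. Constraint selections
#' (max / top-n / residuum branches) are recomputed at every step. With
#' `lambda_c = 0` or no constraints the stage is a no-op.
#'
#' @param t task set (from [fit()]'s stage-1 phase).
#' @param cfg [train_config()].
#' @return updated task set with final weights, margins and an
#'   `optim_trace` of accepted objective values.
#' @export
stage2_fit <- function(t, cfg = NULL) {
  cfg <- cfg %||% t$cfg
  if (cfg$lambda_c == 0 || length(t$compiled) == 0L ||
      length(t$models) == 0L) return(t)
  models <- t$models
  ws <- lapply(models, `[[`, "w")
  margins <- lapply(names(models), function(lv)
    drop(models[[lv]]$K %*% ws[[lv]]))
  names(margins) <- names(models)
  cur <- eval_objective(models, margins, t$labels_idx, t$compiled, cfg,
                        clamped = t$clamped, grad = TRUE)
  if (!is.finite(cur$total))
    stop("objective diverged; use a smaller learning_rate")
  step <- cfg$learning_rate
  trace <- cur$total
  best <- list(ws = ws, margins = margins, total = cur$total)
  explore <- 0L
  t$stopped <- "max_iters"
  for (iter in seq_len(cfg$max_iters)) {
    accepted <- FALSE
    for (ls in seq_len(40L)) {
      ws2 <- lapply(names(models), function(lv)
        ws[[lv]] - step * cur$grads[[lv]])
      names(ws2) <- names(models)
      margins2 <- lapply(names(models), function(lv)
        drop(models[[lv]]$K %*% ws2[[lv]]))
      names(margins2) <- names(models)
      for (lv in names(models)) models[[lv]]$w <- ws2[[lv]]
      cand <- eval_objective(models, margins2, t$labels_idx, t$compiled, cfg,
                             clamped = t$clamped, grad = FALSE)
      if (!is.finite(cand$total))
        stop("objective diverged; use a smaller learning_rate")
      if (cand$total < cur$total) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (accepted) {
      rel <- (cur$total - cand$total) / max(1, abs(cur$total))
      explore <- 0L
    } else {
      # at a kink the chosen subgradient need not be a descent direction at
      # any step size; take a small bounded non-monotone step to move off
      # the kink, keeping the best iterate seen so far
      explore <- explore + 1L
      if (explore > 8L) {
        t$stopped <- "kink"
        break
      }
      step_e <- cfg$learning_rate * 0.1^explore
      ws2 <- lapply(names(models), function(lv)
        ws[[lv]] - step_e * cur$grads[[lv]])
      names(ws2) <- names(models)
      margins2 <- lapply(names(models), function(lv)
        drop(models[[lv]]$K %*% ws2[[lv]]))
      names(margins2) <- names(models)
      step <- cfg$learning_rate
      rel <- Inf
    }
    ws <- ws2; margins <- margins2
    for (lv in names(models)) models[[lv]]$w <- ws[[lv]]
    cur <- eval_objective(models, margins, t$labels_idx, t$compiled, cfg,
                          clamped = t$clamped, grad = TRUE)
    if (cur$total < best$total)
      best <- list(ws = ws, margins = margins, total = cur$total)
    if (accepted) {
      trace <- c(trace, cur$total)
      step <- step * 1.5
      if (rel < cfg$tolerance) {
        t$stopped <- "tolerance"
        break
      }
    }
  }
  for (lv in names(models)) models[[lv]]$w <- best$ws[[lv]]
  t$models <- models
  t$margins <- stats::setNames(
    lapply(names(models), function(lv)
      stats::setNames(best$margins[[lv]], models[[lv]]$keys)),
    names(models))
  t$optim_trace <- trace
  t
}

# ---- orchestration ----------------------------------------------------------

#' Fit the multi-level interaction model
#'
#' Orchestrates the full pipeline: builds the per-level query pair sets
#' (labeled pairs plus the candidate closure of their ancestors, plus any
#' extra unlabeled pairs), lifts the object kernels to pairwise Gram
#' matrices, grounds the consistency rules over the query sets, runs the
#' independent stage-1 fits and the joint stage-2 descent. Unlabeled query
#' pairs enter the objective only through the constraint penalty
#' (transductive, semi-supervised enforcement).
#'
#' @param h hierarchy.
#' @param grams named list of object-level Gram matrices
#'   (`protein`, `domain`, `residue`); levels absent from the list are not
#'   modelled.
#' @param labels named list of [labeled_pairs()] per level (possibly
#'   missing some levels; a level without labels gets zero stage-1
#'   weights and is driven by the constraints alone).
#' @param rules either a character vector of rule names
#'   (see [build_rule()]), an experiment setting name (see
#'   [build_experiment()]), or a prebuilt list of [constraint()] objects.
#' @param cfg [train_config()].
#' @param extra_pairs named list of additional unlabeled query pairs per
#'   level (data.frames `id_a`, `id_b`), e.g. held-out pairs to score
#'   transductively.
#' @param clamped named list per level of named numeric vectors (canonical
#'   pair key -> fixed truth value in `[0,1]`): these pairs' truth values
#'   are held fixed during constraint evaluation.
#' @param use_exists_n use the n-existential in the residue-directed rules.
#' @return object of class `mlpip_taskset`: models, margins, query sets,
#'   objective breakdown.
#' @export
fit <- function(h, grams, labels = list(), rules = character(),
                cfg = train_config(), extra_pairs = list(),
                clamped = NULL, use_exists_n = FALSE) {
  guards <- compute_guards(h)
  lv_all <- intersect(levels3, names(grams))
  if (!length(lv_all)) stop("no gram matrices supplied")
  pair_union <- function(...) {
    parts <- Filter(function(x) !is.null(x) && nrow(x) > 0, list(...))
    if (!length(parts))
      return(data.frame(id_a = character(), id_b = character(),
                        stringsAsFactors = FALSE))
    canonical_pairs(do.call(rbind, lapply(parts, function(p)
      data.frame(id_a = as.character(p$id_a), id_b = as.character(p$id_b),
                 stringsAsFactors = FALSE))))
  }
  query <- list()
  query$protein <- pair_union(labels$protein, extra_pairs$protein)
  query$domain <- pair_union(labels$domain, extra_pairs$domain,
    if (nrow(query$protein)) child_pairs(h, query$protein, "protein"))
  query$residue <- pair_union(labels$residue, extra_pairs$residue,
    if ("residue" %in% lv_all) child_pairs(h, query$domain, "domain"))

  h_ref <- list(h = h, guards = guards)
  models <- list()
  labels_idx <- list()
  for (lv in lv_all) {
    q <- query[[lv]]
    if (nrow(q) == 0L) next
    K <- pairwise_gram(grams[[lv]], q)
    mdl <- new_predictor(lv, q, K, grams[[lv]])
    mdl$h_ref <- h_ref
    lab <- labels[[lv]]
    if (!is.null(lab) && nrow(lab) > 0) {
      idx <- match(pair_key(lab$id_a, lab$id_b), mdl$keys)
      stopifnot(!anyNA(idx))
      labels_idx[[lv]] <- list(idx = idx, y = lab$label)
      mdl$w <- stage1_fit(K, idx, lab$label, cfg)
    }
    models[[lv]] <- mdl
  }

  constraints <- if (is.character(rules)) {
    build_rules_auto(rules, h, guards, query,
                     use_exists_n = use_exists_n, n = cfg$n_exist)
  } else rules
  compiled <- lapply(constraints, function(cst)
    if (is.null(cst$compiled)) compile_constraint(cst, h, guards) else cst)

  t <- structure(list(models = models, query = query,
                      labels_idx = labels_idx, compiled = compiled,
                      cfg = cfg, clamped = clamped, h = h, guards = guards),
                 class = "mlpip_taskset")
  t <- stage2_fit(t, cfg)
  if (is.null(t$margins))
    t$margins <- stats::setNames(
      lapply(names(models), function(lv) predict_margins(t$models[[lv]])),
      names(models))
  t$objective <- objective(t, cfg)
  t
}

#' @export
print.mlpip_taskset <- function(x, ...) {
  cat("<mlpip_taskset> levels:", paste(names(x$models), collapse = ", "),
      "\n  query pairs:",
      paste(vapply(x$query, nrow, integer(1)), collapse = " / "),
      "\n  objective:", format(x$objective$total, digits = 6), "\n")
  invisible(x)
}

# ---- model checkpoints ------------------------------------------------------

#' Save / load a fitted model checkpoint
#'
#' Plain-text JSON checkpoint holding, per level, the basis pair list and
#' weight vector, plus the training configuration; schema version field
#' `"mlpip-checkpoint-1"`. Kernels are not stored: reloading requires the
#' same object Gram matrices used for fitting.
#'
#' @param t task set.
#' @param path file path.
#' @export
write_model <- function(t, path) {
  obj <- list(schema = "mlpip-checkpoint-1",
              cfg = unclass(t$cfg),
              levels = lapply(t$models, function(m)
                list(level = m$level, id_a = m$basis$id_a,
                     id_b = m$basis$id_b, w = m$w)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @param grams named list of object Gram matrices to re-attach.
#' @return for `read_model`, a task set usable with [predict_margins()].
#' @export
read_model <- function(path, grams) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "mlpip-checkpoint-1"))
    stop("unrecognized checkpoint schema")
  models <- lapply(obj$levels, function(l) {
    basis <- data.frame(id_a = l$id_a, id_b = l$id_b,
                        stringsAsFactors = FALSE)
    K <- pairwise_gram(grams[[l$level]], basis)
    m <- new_predictor(l$level, basis, K, grams[[l$level]], w = l$w)
    m
  })
  names(models) <- vapply(obj$levels, `[[`, "", "level")
  cfg <- do.call(train_config, obj$cfg[c("lambda_r", "lambda_c",
                                         "learning_rate", "max_iters",
                                         "tolerance", "seed", "n_exist")])
  structure(list(models = models, cfg = cfg,
                 margins = lapply(models, predict_margins)),
            class = "mlpip_taskset")
}
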