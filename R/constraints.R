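# Compilation of universally/existentially quantified rules into continuous
# penalty functionals. The grounding structure of a rule is fixed by the
# hierarchy and the query pair sets, so it is resolved once ("compiled");
# evaluation then reduces to vectorized arithmetic over the groundings, and
# a reverse sweep yields a subgradient with respect to every target
# predicate value.

#' Construct a constraint specification
#'
#' A constraint is a quantified formula (outermost quantifier `forall`,
#' `exists` or `exists_n`), its grounding sets, and a nonnegative weight.
#'
#' @param name short label.
#' @param formula quantified [fol_forall()] / [fol_exists()] /
#'   [fol_exists_n()] formula.
#' @param groundings named list of grounding entries (see
#'   [grounding_table()]); names are the quantifiers' variable tuples.
#' @param weight nonnegative multiplier applied by the training objective.
#' @return object of class `mlpip_constraint`.
#' @export
constraint <- function(name, formula, groundings, weight = 1) {
  if (!formula$kind %in% c("forall", "exists", "exists_n"))
    stop("outermost node must be a quantifier")
  if (weight < 0) stop("weight must be nonnegative")
  structure(list(name = name, formula = formula, groundings = groundings,
                 weight = weight, compiled = NULL),
            class = "mlpip_constraint")
}

#' @export
print.mlpip_constraint <- function(x, ...) {
  cat("<mlpip_constraint> ", x$name, " (weight ", x$weight, ")\n  ",
      deparse_formula(x$formula), "\n", sep = "")
  invisible(x)
}

# ---- compilation ------------------------------------------------------------

# Walk the formula, resolving every grounding against the (fixed) hierarchy
# and precomputing the values of crisp given-predicate atoms. Target atoms
# keep their canonical key vectors for lookup at evaluation time.
compile_node <- function(node, frame, g, h, guards) {
  a_given <- truth_assignment(h, guards = guards)
  switch(node$kind,
    atom = {
      args <- lapply(node$vars, function(v) {
        if (is.null(frame[[v]])) stop("unbound variable: ", v)
        frame[[v]]
      })
      if (node$pred %in% target_predicates) {
        list(kind = "atom", pred = node$pred,
             keys = pair_key(args[[1L]], args[[2L]]))
      } else {
        list(kind = "given", value = ta_get(a_given, node$pred, args))
      }
    },
    not = list(kind = "not", a = compile_node(node$a, frame, g, h, guards)),
    and = ,
    or = ,
    implies = list(kind = node$kind,
                   a = compile_node(node$a, frame, g, h, guards),
                   b = compile_node(node$b, frame, g, h, guards)),
    {
      gr <- resolve_grounding(g, node, frame)
      frame2 <- cbind(frame[gr$group, , drop = FALSE], gr$frame)
      rownames(frame2) <- NULL
      list(kind = node$kind, n = node$n, group = gr$group,
           n_groups = nrow(frame), m = nrow(frame2),
           body = compile_node(node$body, frame2, g, h, guards))
    })
}

#' Compile a constraint's groundings against a hierarchy
#'
#' @param c constraint.
#' @param h hierarchy (fixes the given predicates).
#' @param guards optional precomputed guard table.
#' @return the constraint with a `compiled` field attached.
#' @export
compile_constraint <- function(c, h, guards = NULL) {
  guards <- guards %||% compute_guards(h)
  top <- c$formula
  pf0 <- data.frame(row.names = 1L)
  gr <- resolve_grounding(c$groundings, top, pf0)
  frame <- gr$frame
  rownames(frame) <- NULL
  c$compiled <- list(top_kind = top$kind, top_n = top$n,
                     n_outer = nrow(frame),
                     body = compile_node(top$body, frame, c$groundings, h,
                                         guards))
  c
}

# ---- evaluation -------------------------------------------------------------

# Per-group aggregation with argument tracking. u: expanded values, group:
# parent index per expanded row (grouped & in canonical order within group).
# Returns value per group and the selected global index (NA if none).
agg_groups <- function(u, group, n_groups, kind, n = NULL) {
  value <- numeric(n_groups)
  sel <- rep(NA_integer_, n_groups)
  value[] <- switch(kind, exists = 0, exists_n = 0, forall = 1)
  if (length(u)) {
    idx <- split(seq_along(u), factor(group, levels = seq_len(n_groups)))
    for (i in seq_len(n_groups)) {
      ix <- idx[[i]]
      k <- length(ix)
      if (k == 0L) next
      ui <- u[ix]
      if (kind == "exists") {
        j <- which.max(ui)            # first max: canonical tie-break
        value[i] <- ui[j]; sel[i] <- ix[j]
      } else if (kind == "forall") {
        j <- which.min(ui)
        value[i] <- ui[j]; sel[i] <- ix[j]
      } else {                        # exists_n: n-th largest body value
        if (k < n) next               # value stays 0, nothing selected
        ord <- order(-ui, seq_len(k)) # stable: canonical tie-break
        j <- ord[n]
        value[i] <- ui[j]; sel[i] <- ix[j]
      }
    }
  }
  list(value = value, sel = sel)
}

# Forward sweep: numeric value vector per node over the current frame rows.
fwd_node <- function(node, a) {
  switch(node$kind,
    given = list(node = node, value = node$value),
    atom = list(node = node, value = ta_target(a, node$pred, node$keys)),
    not = {
      ra <- fwd_node(node$a, a)
      list(node = node, value = 1 - ra$value, a = ra)
    },
    and = {
      ra <- fwd_node(node$a, a); rb <- fwd_node(node$b, a)
      list(node = node, value = ra$value * rb$value, a = ra, b = rb)
    },
    or = {
      ra <- fwd_node(node$a, a); rb <- fwd_node(node$b, a)
      list(node = node, value = ra$value + rb$value - ra$value * rb$value,
           a = ra, b = rb)
    },
    implies = {
      ra <- fwd_node(node$a, a); rb <- fwd_node(node$b, a)
      list(node = node,
           value = ifelse(ra$value <= rb$value, 1, rb$value), a = ra, b = rb)
    },
    {
      rb <- fwd_node(node$body, a)
      ag <- agg_groups(rb$value, node$group, node$n_groups, node$kind, node$n)
      list(node = node, value = ag$value, sel = ag$sel, body = rb)
    })
}

# Backward sweep: accumulate d(violation)/d(target value) into `acc`, an
# environment with lists `keys[[pred]]`, `sens[[pred]]`.
bwd_node <- function(rec, sens, acc) {
  node <- rec$node
  switch(node$kind,
    given = invisible(NULL),
    atom = {
      nz <- sens != 0
      if (any(nz)) {
        acc$keys[[node$pred]] <- c(acc$keys[[node$pred]], node$keys[nz])
        acc$sens[[node$pred]] <- c(acc$sens[[node$pred]], sens[nz])
      }
    },
    not = bwd_node(rec$a, -sens, acc),
    and = {
      bwd_node(rec$a, sens * rec$b$value, acc)
      bwd_node(rec$b, sens * rec$a$value, acc)
    },
    or = {
      bwd_node(rec$a, sens * (1 - rec$b$value), acc)
      bwd_node(rec$b, sens * (1 - rec$a$value), acc)
    },
    implies = {
      # residuum: value = b on the violated branch (a > b), constant 1
      # otherwise; subgradient w.r.t. the antecedent is 0 everywhere.
      mask <- as.numeric(rec$a$value > rec$b$value)
      bwd_node(rec$b, sens * mask, acc)
    },
    {
      s2 <- numeric(node$m)
      ok <- which(!is.na(rec$sel) & sens != 0)
      if (length(ok)) s2[rec$sel[ok]] <- sens[ok]
      bwd_node(rec$body, s2, acc)
    })
  invisible(NULL)
}

# Evaluate a compiled constraint: violation plus (optionally) subgradient.
eval_compiled <- function(c, a, grad = FALSE, literal_exists_n = FALSE) {
  cc <- c$compiled
  if (is.null(cc)) stop("constraint not compiled")
  n <- cc$n_outer
  if (n == 0L) {
    # vacuous universal is satisfied; an empty existential cannot be
    empty_v <- switch(cc$top_kind, forall = 0,
                      exists = 1, exists_n = cc$top_n)
    return(list(violation = empty_v, grad = list()))
  }
  rec <- fwd_node(cc$body, a)
  v <- rec$value
  sens <- numeric(n)
  if (cc$top_kind == "forall") {
    violation <- sum(1 - v)
    sens[] <- -1
  } else if (cc$top_kind == "exists") {
    j <- which.max(v)
    violation <- 1 - v[j]
    sens[j] <- -1
  } else {
    nn <- cc$top_n
    if (literal_exists_n) {
      # paper-literal reading: sum the n largest violations
      ord <- order(v, seq_len(n))
      take <- ord[seq_len(min(nn, n))]
    } else {
      # sum the n smallest violations (groundings with largest body value);
      # reduces to the existential at n = 1 and the universal at n = |S|
      ord <- order(-v, seq_len(n))
      take <- ord[seq_len(min(nn, n))]
    }
    violation <- sum(1 - v[take]) + max(0L, nn - n)
    sens[take] <- -1
  }
  out <- list(violation = violation, grad = list())
  if (grad) {
    acc <- new.env(parent = emptyenv())
    acc$keys <- list(); acc$sens <- list()
    bwd_node(rec, sens, acc)
    out$grad <- lapply(stats::setNames(nm = names(acc$keys)), function(p) {
      r <- rowsum(acc$sens[[p]], acc$keys[[p]])
      stats::setNames(r[, 1L], rownames(r))
    })
  }
  out
}

#' Degree of violation of a constraint
#'
#' A universally quantified rule contributes the sum over its groundings of
#' one minus the body's t-norm value (0 over an empty grounding set:
#' vacuous truth). A top-level existential contributes the smallest
#' per-grounding violation; a top-level n-existential the sum of the `n`
#' smallest per-grounding violations (each missing grounding counting as a
#' full violation when fewer than `n` exist).
#'
#' @param c constraint (compiled or not; uncompiled constraints are
#'   compiled on the fly against the assignment's hierarchy).
#' @param a truth assignment.
#' @param literal_exists_n use the literal reading of the n-existential
#'   relaxation (sum of the `n` largest violations) instead of the default
#'   reading that reduces to the existential at `n = 1`.
#' @return nonnegative scalar.
#' @export
constraint_violation <- function(c, a, literal_exists_n = FALSE) {
  if (is.null(c$compiled)) c <- compile_constraint(c, a$h, a$guards)
  eval_compiled(c, a, grad = FALSE, literal_exists_n = literal_exists_n)$violation
}

#' Subgradient of a constraint violation
#'
#' @inheritParams constraint_violation
#' @return named list per target predicate: named numeric vector (canonical
#'   pair key -> partial derivative). Entries are zero (absent) for
#'   groundings not selected by the max / top-n / residuum branches.
#' @export
violation_subgradient <- function(c, a, literal_exists_n = FALSE) {
  if (is.null(c$compiled)) c <- compile_constraint(c, a$h, a$guards)
  eval_compiled(c, a, grad = TRUE, literal_exists_n = literal_exists_n)$grad
}
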