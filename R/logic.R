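# First-order logic over the interaction predicates, and its relaxation to
# continuous [0,1] truth values via the product t-norm and the minimum
# t-norm residuum. Formulas are built programmatically, grounded against a
# hierarchy, and either evaluated classically (boolean oracle) or compiled
# into continuous penalty functionals with subgradients (see constraints.R).

target_predicates <- c("boundp", "boundd", "boundr")
given_predicates <- c("parentpd", "parentdr", "parentpr",
                      "hasdom", "hasres", "hasres_p")
pred_level <- c(boundp = "protein", boundd = "domain", boundr = "residue")

check_unit <- function(x, what) {
  if (any(x < -1e-12 | x > 1 + 1e-12, na.rm = TRUE))
    stop("out-of-range input to ", what, ": values must lie in [0,1]")
  pmin(pmax(x, 0), 1)
}

#' Product t-norm (fuzzy AND)
#'
#' @param a,b numeric in `[0,1]` (vectorized).
#' @return `a * b`.
#' @export
t_and <- function(a, b) {
  check_unit(a, "t_and") * check_unit(b, "t_and")
}

#' Product t-conorm (fuzzy OR)
#' @param a,b numeric in `[0,1]`.
#' @return `a + b - a*b`.
#' @export
t_or <- function(a, b) {
  a <- check_unit(a, "t_or"); b <- check_unit(b, "t_or")
  a + b - a * b
}

#' Fuzzy negation
#' @param a numeric in `[0,1]`.
#' @return `1 - a`.
#' @export
t_not <- function(a) 1 - check_unit(a, "t_not")

#' Minimum t-norm residuum (fuzzy implication)
#'
#' The implication is fully satisfied (value 1) whenever the consequent is
#' at least as true as the antecedent, and takes the consequent's value
#' otherwise. This makes the penalty act one-directionally: a violated
#' implication pulls its consequent up, never its antecedent down.
#'
#' @param a,b numeric in `[0,1]`: antecedent and consequent.
#' @return elementwise `ifelse(a <= b, 1, b)`.
#' @export
t_implies <- function(a, b) {
  a <- check_unit(a, "t_implies"); b <- check_unit(b, "t_implies")
  ifelse(a <= b, 1, b)
}

# ---- formula constructors ---------------------------------------------------

new_formula <- function(x) structure(x, class = "mlpip_formula")

#' Build first-order formulas over the interaction predicates
#'
#' `fol_atom` creates a predicate application; the binary connectives fold
#' left, so `fol_and(a, b, c)` is `and(and(a, b), c)`. Quantifiers bind a
#' tuple of variables; `fol_exists_n` is the n-existential, true (in the
#' classical reading) iff at least `n` groundings satisfy the body.
#'
#' @param pred predicate name: one of `boundp`, `boundd`, `boundr`,
#'   `parentpd`, `parentdr`, `parentpr`, `hasdom`, `hasres`, `hasres_p`.
#' @param ... variable names (character) for `fol_atom`; subformulas for the
#'   connectives.
#' @param a,b subformulas.
#' @param vars character vector of bound variable names.
#' @param body subformula.
#' @param n positive integer count for the n-existential.
#' @return an object of class `mlpip_formula`.
#' @examples
#' f <- fol_forall(c("p", "q"),
#'   fol_implies(fol_atom("boundp", "p", "q"),
#'     fol_exists(c("d", "e"), fol_atom("boundd", "d", "e"))))
#' @export
fol_atom <- function(pred, ...) {
  vars <- c(...)
  if (!pred %in% c(target_predicates, given_predicates))
    stop("unknown predicate: ", pred)
  arity <- if (pred %in% c("hasdom", "hasres", "hasres_p")) 1L else 2L
  if (length(vars) != arity)
    stop("predicate ", pred, " takes ", arity, " argument(s)")
  new_formula(list(kind = "atom", pred = pred, vars = as.character(vars)))
}

#' @rdname fol_atom
#' @export
fol_not <- function(a) new_formula(list(kind = "not", a = a))

fold_binary <- function(kind, xs) {
  if (length(xs) < 2L) stop(kind, " needs at least two subformulas")
  out <- xs[[1L]]
  for (i in 2:length(xs)) out <- new_formula(list(kind = kind, a = out, b = xs[[i]]))
  out
}

#' @rdname fol_atom
#' @export
fol_and <- function(...) fold_binary("and", list(...))

#' @rdname fol_atom
#' @export
fol_or <- function(...) fold_binary("or", list(...))

#' @rdname fol_atom
#' @export
fol_implies <- function(a, b) new_formula(list(kind = "implies", a = a, b = b))

quantifier <- function(kind, vars, body, n = NULL) {
  vars <- as.character(vars)
  if (!length(vars)) stop("quantifier must bind at least one variable")
  new_formula(list(kind = kind, vars = vars, n = n, body = body,
                   gid = paste(vars, collapse = ",")))
}

#' @rdname fol_atom
#' @export
fol_forall <- function(vars, body) quantifier("forall", vars, body)

#' @rdname fol_atom
#' @export
fol_exists <- function(vars, body) quantifier("exists", vars, body)

#' @rdname fol_atom
#' @export
fol_exists_n <- function(n, vars, body) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("exists_n requires n >= 1")
  quantifier("exists_n", vars, body, n = n)
}

#' @export
print.mlpip_formula <- function(x, ...) {
  cat(deparse_formula(x), "\n")
  invisible(x)
}

deparse_formula <- function(f) {
  switch(f$kind,
    atom = paste0(f$pred, "(", paste(f$vars, collapse = ","), ")"),
    not = paste0("not(", deparse_formula(f$a), ")"),
    and = paste0("and(", deparse_formula(f$a), ", ", deparse_formula(f$b), ")"),
    or = paste0("or(", deparse_formula(f$a), ", ", deparse_formula(f$b), ")"),
    implies = paste0("implies(", deparse_formula(f$a), ", ",
                     deparse_formula(f$b), ")"),
    forall = paste0("forall (", f$gid, ") ", deparse_formula(f$body)),
    exists = paste0("exists (", f$gid, ") ", deparse_formula(f$body)),
    exists_n = paste0("exists_", f$n, " (", f$gid, ") ",
                      deparse_formula(f$body)))
}

# ---- truth assignments ------------------------------------------------------

#' Truth assignment over given and target predicates
#'
#' Bundles a hierarchy (which fixes the crisp given predicates: parent maps
#' and guards) with `[0,1]` values for the target interaction predicates,
#' stored as named numeric vectors keyed by canonical pair key
#' (see [pair_key()]).
#'
#' @param h hierarchy.
#' @param boundp,boundd,boundr named numeric vectors in `[0,1]` keyed by
#'   canonical pair key, or `NULL`.
#' @param default value returned for pairs absent from the vectors
#'   (`NA` = error on missing key).
#' @param guards optional precomputed [compute_guards()] table.
#' @return object of class `mlpip_assignment`.
#' @export
truth_assignment <- function(h, boundp = NULL, boundd = NULL, boundr = NULL,
                             default = NA_real_, guards = NULL) {
  vals <- list(boundp = boundp, boundd = boundd, boundr = boundr)
  for (p in names(vals)) {
    if (!is.null(vals[[p]])) {
      if (is.null(names(vals[[p]]))) stop(p, " values must be named by pair key")
      check_unit(vals[[p]], p)
    }
  }
  structure(list(h = h, guards = guards %||% compute_guards(h),
                 values = vals, default = default, crisp = FALSE),
            class = "mlpip_assignment")
}

#' Crisp truth assignment from positive pair sets
#'
#' Every listed pair gets value 1, every other pair value 0 — the natural
#' closed-world reading of a gold standard.
#'
#' @param h hierarchy.
#' @param positives list with (optional) elements `protein`, `domain`,
#'   `residue`: each either a character vector of canonical pair keys or a
#'   data.frame with `id_a`, `id_b`.
#' @return `mlpip_assignment` whose target lookups are crisp 0/1.
#' @export
crisp_assignment <- function(h, positives = list()) {
  keyset <- function(x) {
    if (is.null(x)) return(character())
    if (is.data.frame(x)) pair_key(x$id_a, x$id_b) else as.character(x)
  }
  a <- truth_assignment(h)
  a$crisp <- TRUE
  a$pos <- list(boundp = keyset(positives$protein),
                boundd = keyset(positives$domain),
                boundr = keyset(positives$residue))
  a
}

# Vectorized lookup of target-predicate values by canonical key.
ta_target <- function(a, pred, keys) {
  if (length(keys) == 0L) return(numeric())
  if (isTRUE(a$crisp)) return(as.numeric(keys %in% a$pos[[pred]]))
  v <- a$values[[pred]]
  if (is.null(v)) stop("no values for target predicate ", pred)
  out <- unname(v[keys])
  if (anyNA(out)) {
    if (is.na(a$default))
      stop("missing value(s) for ", pred, ": ",
           paste(utils::head(keys[is.na(out)], 3L), collapse = ", "))
    out[is.na(out)] <- a$default
  }
  out
}

# Vectorized predicate lookup; args is a list of id vectors (1 or 2).
ta_get <- function(a, pred, args) {
  h <- a$h
  as0 <- function(x) { x[is.na(x)] <- FALSE; as.numeric(x) }
  switch(pred,
    boundp = ,
    boundd = ,
    boundr = ta_target(a, pred, pair_key(args[[1L]], args[[2L]])),
    parentpd = as0(unname(h$parent_pd[args[[2L]]]) == args[[1L]]),
    parentdr = as0(unname(h$parent_dr[args[[2L]]]) == args[[1L]]),
    parentpr = as0(unname(h$parent_pr[args[[2L]]]) == args[[1L]]),
    hasdom = as0(unname(a$guards$hasdom[args[[1L]]])),
    hasres = as0(unname(a$guards$hasres_d[args[[1L]]])),
    hasres_p = as0(unname(a$guards$hasres_p[args[[1L]]])),
    stop("unknown predicate: ", pred))
}

# ---- grounding sets ---------------------------------------------------------

#' Grounding sets for quantified variables
#'
#' A grounding set maps each quantifier (identified by its bound-variable
#' tuple, e.g. `"d,e"`) to the admissible assignments of those variables.
#' `grounding_table` fixes a static table of assignments;
#' `grounding_children` yields, for each enclosing assignment of a parent
#' pair of objects, the cross-pairs of their children — the only groundings
#' not annihilated by the crisp parent predicates in the rule bodies.
#'
#' @param pairs data.frame whose rows are assignments; columns are renamed
#'   to `vars`.
#' @param vars character vector of variable names (order matches columns).
#' @return a grounding entry usable in the named list passed as `groundings`.
#' @export
grounding_table <- function(pairs, vars) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (ncol(pairs) < length(vars)) stop("not enough columns for vars")
  pairs <- pairs[, seq_along(vars), drop = FALSE]
  names(pairs) <- vars
  for (j in seq_along(pairs)) pairs[[j]] <- as.character(pairs[[j]])
  pairs
}

#' @rdname grounding_table
#' @param h hierarchy.
#' @param level level of the parent objects (`"protein"` or `"domain"`).
#' @param to child level.
#' @param parent_vars names of the two enclosing variables holding the
#'   parent objects.
#' @param child_vars names of the two variables being grounded.
#' @param restrict optional character vector of canonical pair keys: only
#'   child cross-pairs in this candidate universe are kept.
#' @export
grounding_children <- function(h, level, parent_vars, child_vars, to = NULL,
                               restrict = NULL) {
  cm <- children_map(h, level, to)
  force(restrict)
  function(parent_frame) {
    pa <- parent_frame[[parent_vars[1L]]]
    pb <- parent_frame[[parent_vars[2L]]]
    n <- length(pa)
    frames <- vector("list", n)
    counts <- integer(n)
    for (i in seq_len(n)) {
      ca <- cm[[pa[i]]]; cb <- cm[[pb[i]]]
      if (is.null(ca) || is.null(cb))
        stop("unknown parent id: ", pa[i], " / ", pb[i])
      if (!length(ca) || !length(cb)) next
      g <- expand.grid(a = ca, b = cb, stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
      if (!is.null(restrict))
        g <- g[pair_key(g$a, g$b) %in% restrict, , drop = FALSE]
      counts[i] <- nrow(g)
      frames[[i]] <- g
    }
    frame <- do.call(rbind, frames[counts > 0]) %||%
      data.frame(a = character(), b = character(), stringsAsFactors = FALSE)
    names(frame) <- child_vars
    rownames(frame) <- NULL
    list(frame = frame, group = rep(seq_len(n), times = counts))
  }
}

resolve_grounding <- function(g, node, parent_frame) {
  entry <- g[[node$gid]]
  if (is.null(entry))
    stop("no grounding set for quantifier over (", node$gid, ")")
  n <- nrow(parent_frame)
  if (is.function(entry)) {
    out <- entry(parent_frame)
    stopifnot(is.list(out), nrow(out$frame) == length(out$group))
    return(out)
  }
  k <- nrow(entry)
  list(frame = entry[rep(seq_len(k), times = n), , drop = FALSE],
       group = rep(seq_len(n), each = k))
}

# ---- scalar evaluation ------------------------------------------------------

#' Continuous (t-norm) value of a formula under a truth assignment
#'
#' Recursive evaluation: atoms look up predicate values; conjunction,
#' disjunction, negation and implication use the product t-norm, its
#' co-norm, `1 - a`, and the minimum t-norm residuum; an existential is the
#' maximum of its groundings' body values, the n-existential the n-th
#' largest body value (0 when there are fewer than `n` groundings), and a
#' universal the minimum (1 over an empty set). A formula evaluates to 1
#' exactly when the crisp limit of its inputs satisfies it classically.
#'
#' @param f formula.
#' @param a truth assignment.
#' @param g grounding set (named list; see [grounding_table()]).
#' @param env named list binding free variables to object ids.
#' @return scalar in `[0,1]`.
#' @export
formula_value <- function(f, a, g = list(), env = list()) {
  val <- function(node, env) {
    switch(node$kind,
      atom = {
        args <- lapply(node$vars, function(v) {
          if (is.null(env[[v]])) stop("unbound variable: ", v)
          env[[v]]
        })
        ta_get(a, node$pred, args)
      },
      not = 1 - val(node$a, env),
      and = val(node$a, env) * val(node$b, env),
      or = { x <- val(node$a, env); y <- val(node$b, env); x + y - x * y },
      implies = { x <- val(node$a, env); y <- val(node$b, env)
                  if (x <= y) 1 else y },
      {
        pf <- if (length(env))
          as.data.frame(as.list(env), stringsAsFactors = FALSE)
        else data.frame(row.names = 1L)
        gr <- resolve_grounding(g, node, pf)
        vals <- if (nrow(gr$frame) == 0L) numeric() else
          vapply(seq_len(nrow(gr$frame)), function(i) {
            env2 <- env
            for (v in names(gr$frame)) env2[[v]] <- gr$frame[[v]][i]
            val(node$body, env2)
          }, numeric(1))
        switch(node$kind,
          exists = if (length(vals)) max(vals) else 0,
          exists_n = if (length(vals) >= node$n)
            sort(vals, decreasing = TRUE)[node$n] else 0,
          forall = if (length(vals)) min(vals) else 1)
      })
  }
  val(f, env)
}

#' Classical Boolean evaluation of a formula (test oracle)
#'
#' Exhaustive classical first-order evaluation over the grounding sets. All
#' predicate values must be crisp (0 or 1). `exists_n` is true iff at least
#' `n` groundings satisfy the body.
#'
#' @inheritParams formula_value
#' @return logical scalar.
#' @export
boolean_oracle <- function(f, a, g = list(), env = list()) {
  ev <- function(node, env) {
    switch(node$kind,
      atom = {
        args <- lapply(node$vars, function(v) env[[v]])
        v <- ta_get(a, node$pred, args)
        if (!v %in% c(0, 1)) stop("non-crisp input to boolean_oracle")
        v == 1
      },
      not = !ev(node$a, env),
      and = ev(node$a, env) && ev(node$b, env),
      or = ev(node$a, env) || ev(node$b, env),
      implies = !ev(node$a, env) || ev(node$b, env),
      {
        pf <- if (length(env))
          as.data.frame(as.list(env), stringsAsFactors = FALSE)
        else data.frame(row.names = 1L)
        gr <- resolve_grounding(g, node, pf)
        sat <- if (nrow(gr$frame) == 0L) logical() else
          vapply(seq_len(nrow(gr$frame)), function(i) {
            env2 <- env
            for (v in names(gr$frame)) env2[[v]] <- gr$frame[[v]][i]
            ev(node$body, env2)
          }, logical(1))
        switch(node$kind,
          exists = any(sat),
          exists_n = sum(sat) >= node$n,
          forall = all(sat))
      })
  }
  ev(f, env)
}
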