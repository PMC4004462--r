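# The inter-level consistency rule set and the experimental configurations:
# downward rules propagate bound pairs to their children (with an inner
# existential, or n-existential for residue interfaces), upward rules
# propagate bound children to their parents.

rule_names <- c("P->D", "D->P", "D->R", "R->D", "P->R", "R->P")
experiment_settings <- c("independent", "P->D", "D->R", "P->R",
                         "P<->D", "D<->R", "P<->R", "full")

#' Build one inter-level consistency rule
#'
#' The six rules over the bound predicates, grounded over the supplied
#' query pair sets:
#' \describe{
#' \item{`P->D`}{for all protein pairs with domains on both sides, if the
#'   proteins are bound then at least one pair of their child domains is
#'   bound.}
#' \item{`D->P`}{for all protein pairs, if some pair of their child domains
#'   is bound then the proteins are bound.}
#' \item{`D->R` / `R->D`}{the same between domains and residues; the
#'   downward rule optionally uses the n-existential (at least `n` bound
#'   residue cross-pairs, the typical size of an interaction interface).}
#' \item{`P->R` / `R->P`}{the same between proteins and residues directly,
#'   via the derived protein-residue parent map and the protein-level
#'   residue guard.}
#' }
#' Downward rules are guarded so that objects without children leave the
#' rule vacuously satisfied.
#'
#' @param name rule name, e.g. `"P->D"`.
#' @param h hierarchy.
#' @param pairs named list of query pair data.frames per level; the rule's
#'   upper level must be present.
#' @param use_exists_n use the n-existential for residue-directed downward
#'   rules (`D->R`, `P->R`); `P->D` always uses the plain existential.
#' @param n count for the n-existential (default 5: typical interface
#'   size).
#' @param restrict optional named list per level of canonical pair keys the
#'   inner child groundings are intersected with.
#' @param weight constraint weight.
#' @return a [constraint()].
#' @export
build_rule <- function(name, h, pairs, use_exists_n = FALSE, n = 5L,
                       restrict = NULL, weight = 1) {
  if (!name %in% rule_names) stop("unknown rule name: ", name)
  down <- function(upper_level, child_level, bound_up, bound_down, parent,
                   guard, exn) {
    inner_body <- fol_and(fol_atom(bound_down, "c", "e"),
                          fol_atom(parent, "a", "c"),
                          fol_atom(parent, "b", "e"))
    inner <- if (exn) fol_exists_n(n, c("c", "e"), inner_body)
             else fol_exists(c("c", "e"), inner_body)
    f <- fol_forall(c("a", "b"),
      fol_implies(fol_and(fol_atom(guard, "a"), fol_atom(guard, "b")),
        fol_implies(fol_atom(bound_up, "a", "b"), inner)))
    g <- list()
    g[["a,b"]] <- grounding_table(pairs[[upper_level]], c("a", "b"))
    g[["c,e"]] <- grounding_children(h, upper_level, c("a", "b"),
                                     c("c", "e"), to = child_level,
                                     restrict = restrict[[child_level]])
    constraint(name, f, g, weight)
  }
  up <- function(upper_level, child_level, bound_up, bound_down, parent) {
    f <- fol_forall(c("a", "b"),
      fol_implies(
        fol_exists(c("c", "e"),
          fol_and(fol_atom(bound_down, "c", "e"),
                  fol_atom(parent, "a", "c"),
                  fol_atom(parent, "b", "e"))),
        fol_atom(bound_up, "a", "b")))
    g <- list()
    g[["a,b"]] <- grounding_table(pairs[[upper_level]], c("a", "b"))
    g[["c,e"]] <- grounding_children(h, upper_level, c("a", "b"),
                                     c("c", "e"), to = child_level,
                                     restrict = restrict[[child_level]])
    constraint(name, f, g, weight)
  }
  switch(name,
    "P->D" = down("protein", "domain", "boundp", "boundd", "parentpd",
                  "hasdom", exn = FALSE),
    "D->P" = up("protein", "domain", "boundp", "boundd", "parentpd"),
    "D->R" = down("domain", "residue", "boundd", "boundr", "parentdr",
                  "hasres", exn = use_exists_n),
    "R->D" = up("domain", "residue", "boundd", "boundr", "parentdr"),
    "P->R" = down("protein", "residue", "boundp", "boundr", "parentpr",
                  "hasres_p", exn = use_exists_n),
    "R->P" = up("protein", "residue", "boundp", "boundr", "parentpr"))
}

#' Rule lists for the experimental settings
#'
#' `"independent"` uses no rules; the unidirectional settings one downward
#' rule; the bidirectional settings a downward/upward pair; `"full"`
#' activates `P->D`, `D->P`, `D->R` and `R->D` (the direct protein-residue
#' rules are omitted: protein-residue consistency is implied by the
#' protein-domain and domain-residue rules).
#'
#' @param setting one of `"independent"`, `"P->D"`, `"D->R"`, `"P->R"`,
#'   `"P<->D"`, `"D<->R"`, `"P<->R"`, `"full"`.
#' @param h,pairs,use_exists_n,n,restrict passed to [build_rule()].
#' @return list of [constraint()] objects (possibly empty).
#' @export
build_experiment <- function(setting, h, pairs, use_exists_n = FALSE,
                             n = 5L, restrict = NULL) {
  setting <- match.arg(setting, experiment_settings)
  names_for <- switch(setting,
    independent = character(),
    "P->D" = "P->D",
    "D->R" = "D->R",
    "P->R" = "P->R",
    "P<->D" = c("P->D", "D->P"),
    "D<->R" = c("D->R", "R->D"),
    "P<->R" = c("P->R", "R->P"),
    full = c("P->D", "D->P", "D->R", "R->D"))
  lapply(names_for, build_rule, h = h, pairs = pairs,
         use_exists_n = use_exists_n, n = n, restrict = restrict)
}

# rules argument of fit(): a setting name or a vector of rule names
build_rules_auto <- function(rules, h, guards, pairs, use_exists_n, n) {
  if (length(rules) == 0L) return(list())
  if (length(rules) == 1L && rules %in% experiment_settings)
    return(build_experiment(rules, h, pairs, use_exists_n = use_exists_n,
                            n = n))
  lapply(rules, build_rule, h = h, pairs = pairs,
         use_exists_n = use_exists_n, n = n)
}

#' Run one experimental configuration end to end
#'
#' Builds the setting's rule list, fits the multi-level model, and returns
#' per-level margins and thresholded classifications for every query pair.
#'
#' @param dataset a [generate()] result or a list with `hierarchy` and
#'   `gold` (labeled pairs per level).
#' @param grams named list of object-level Gram matrices.
#' @param setting experiment setting (see [build_experiment()]).
#' @param cfg [train_config()].
#' @param use_exists_n use the n-existential for residue-directed rules.
#' @param extra_pairs extra unlabeled query pairs per level.
#' @return list with the fitted `taskset`, per-level `margins` and
#'   `predictions` (named +1/-1 vectors).
#' @export
run_experiment <- function(dataset, grams, setting = "full",
                           cfg = train_config(), use_exists_n = FALSE,
                           extra_pairs = list()) {
  t <- fit(dataset$hierarchy, grams, labels = dataset$gold,
           rules = setting, cfg = cfg, extra_pairs = extra_pairs,
           use_exists_n = use_exists_n)
  preds <- lapply(t$margins, classify)
  list(taskset = t, margins = t$margins, predictions = preds)
}

# ---- textual rule notation --------------------------------------------------

#' Parse the textual rule notation
#'
#' A small prefix notation for configuration files, e.g.
#' `"forall (a,b) implies(and(hasdom(a), hasdom(b)),
#'   implies(boundp(a,b), exists (c,e) and(boundd(c,e), parentpd(a,c),
#'   parentpd(b,e))))"`.
#' Grammar: `formula := quant | conn | atom`;
#' `quant := ("forall"|"exists"|"exists_n" INT) "(" vars ")" formula`;
#' `conn := ("and"|"or"|"not"|"implies") "(" formula {"," formula} ")"`;
#' `atom := PRED "(" vars ")"`. Whitespace is insignificant.
#'
#' @param text the rule string.
#' @return an `mlpip_formula`.
#' @export
parse_rule <- function(text) {
  tokens <- regmatches(text, gregexpr("[A-Za-z_][A-Za-z_0-9]*|[0-9]+|[(),]",
                                      text))[[1L]]
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[pos] else ""
  take <- function(expect = NULL) {
    if (pos > length(tokens)) stop("unexpected end of rule text")
    tk <- tokens[pos]; pos <<- pos + 1L
    if (!is.null(expect) && tk != expect)
      stop("expected '", expect, "' but found '", tk, "'")
    tk
  }
  vars <- function() {
    take("(")
    out <- character()
    repeat {
      out <- c(out, take())
      if (peek() == ",") take() else break
    }
    take(")")
    out
  }
  formula <- function() {
    tk <- take()
    if (tk %in% c("forall", "exists", "exists_n")) {
      nn <- if (tk == "exists_n") as.integer(take()) else NULL
      vs <- vars()
      body <- formula()
      return(switch(tk, forall = fol_forall(vs, body),
                    exists = fol_exists(vs, body),
                    exists_n = fol_exists_n(nn, vs, body)))
    }
    if (tk %in% c("and", "or", "not", "implies")) {
      take("(")
      args <- list(formula())
      while (peek() == ",") { take(); args <- c(args, list(formula())) }
      take(")")
      return(switch(tk,
        "not" = { if (length(args) != 1L) stop("not() takes one argument")
                  fol_not(args[[1L]]) },
        "and" = do.call(fol_and, args),
        "or" = do.call(fol_or, args),
        "implies" = { if (length(args) != 2L)
                        stop("implies() takes two arguments")
                      fol_implies(args[[1L]], args[[2L]]) }))
    }
    # atom
    fol_atom(tk, vars())
  }
  out <- formula()
  if (pos <= length(tokens))
    stop("trailing tokens in rule text: ", paste(tokens[pos:length(tokens)],
                                                 collapse = " "))
  out
}
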