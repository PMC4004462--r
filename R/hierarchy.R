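# Data model and I/O for the protein / domain / residue hierarchy, the crisp
# parent predicates and the labeled interaction pairs.

#' Construct a protein-domain-residue hierarchy
#'
#' A hierarchy is the set of objects at the three levels plus the crisp
#' parent maps: every domain belongs to exactly one protein and every residue
#' to exactly one domain; the residue-to-protein map is derived by
#' composition. Identifier sets at the three levels must be pairwise
#' disjoint.
#'
#' @param parent_pd named character vector: names are domain ids, values the
#'   owning protein id.
#' @param parent_dr named character vector: names are residue ids, values the
#'   owning domain id.
#' @param proteins optional character vector of protein ids; defaults to the
#'   proteins referenced by `parent_pd`. Proteins without domains are allowed
#'   and must be listed explicitly.
#' @return an object of class `mlpip_hierarchy` with fields `proteins`,
#'   `domains`, `residues`, `parent_pd`, `parent_dr`, `parent_pr`.
#' @examples
#' h <- hierarchy(parent_pd = c(d1 = "p1", d2 = "p2"),
#'                parent_dr = c(r1 = "d1"))
#' h$parent_pr[["r1"]]  # "p1"
#' @export
hierarchy <- function(parent_pd = character(), parent_dr = character(),
                      proteins = NULL) {
  parent_pd <- vapply(parent_pd, as.character, character(1))
  parent_dr <- vapply(parent_dr, as.character, character(1))
  domains <- names(parent_pd) %||% character()
  residues <- names(parent_dr) %||% character()
  if (length(parent_pd) && (is.null(domains) || anyNA(domains) || any(domains == "")))
    stop("parent_pd must be a named vector (domain -> protein)")
  if (length(parent_dr) && (is.null(residues) || anyNA(residues) || any(residues == "")))
    stop("parent_dr must be a named vector (residue -> domain)")
  if (anyDuplicated(domains))
    stop("integrity error: domain with two parent proteins: ",
         paste(unique(domains[duplicated(domains)]), collapse = ", "))
  if (anyDuplicated(residues))
    stop("integrity error: residue with two parent domains: ",
         paste(unique(residues[duplicated(residues)]), collapse = ", "))
  proteins <- sort(unique(c(as.character(proteins), unname(parent_pd))))
  domains <- sort(domains)
  residues <- sort(residues)
  parent_pd <- parent_pd[domains]
  parent_dr <- parent_dr[residues]
  dangling <- setdiff(unname(parent_dr), domains)
  if (length(dangling))
    stop("integrity error: residue parent domain not declared: ",
         paste(dangling, collapse = ", "))
  ids <- c(proteins, domains, residues)
  if (anyDuplicated(ids))
    stop("integrity error: identifier used at more than one level: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  parent_pr <- parent_pd[parent_dr]
  names(parent_pr) <- residues
  structure(list(proteins = proteins, domains = domains, residues = residues,
                 parent_pd = parent_pd, parent_dr = parent_dr,
                 parent_pr = parent_pr),
            class = "mlpip_hierarchy")
}

#' @export
print.mlpip_hierarchy <- function(x, ...) {
  cat("<mlpip_hierarchy> ", length(x$proteins), " proteins, ",
      length(x$domains), " domains, ", length(x$residues), " residues\n",
      sep = "")
  invisible(x)
}

#' Read a hierarchy from a tab-separated edge file
#'
#' The dialect is one row per parent-child edge, three columns:
#' record type (`D` = domain-of-protein, `R` = residue-of-domain), child id,
#' parent id. `#` starts a comment; blank lines are ignored. An optional
#' `P <id>` record declares a protein without domains.
#'
#' @param path file path.
#' @return an [hierarchy()] object.
#' @export
load_hierarchy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  keep <- which(trimws(lines) != "")
  parent_pd <- character(); pd_names <- character()
  parent_dr <- character(); dr_names <- character()
  proteins <- character()
  for (i in keep) {
    fields <- strsplit(trimws(lines[i]), "[ \t]+")[[1L]]
    type <- fields[1L]
    if (type == "P") {
      if (length(fields) != 2L)
        stop("parse error at line ", i, ": P record needs one id")
      proteins <- c(proteins, fields[2L])
      next
    }
    if (length(fields) != 3L)
      stop("parse error at line ", i, ": expected 3 columns, got ",
           length(fields))
    if (type == "D") {
      if (fields[2L] %in% pd_names)
        stop("integrity error at line ", i, ": domain ", fields[2L],
             " already has a parent")
      parent_pd <- c(parent_pd, fields[3L]); pd_names <- c(pd_names, fields[2L])
    } else if (type == "R") {
      if (fields[2L] %in% dr_names)
        stop("integrity error at line ", i, ": residue ", fields[2L],
             " already has a parent")
      parent_dr <- c(parent_dr, fields[3L]); dr_names <- c(dr_names, fields[2L])
    } else {
      stop("parse error at line ", i, ": unknown record type '", type, "'")
    }
  }
  names(parent_pd) <- pd_names
  names(parent_dr) <- dr_names
  hierarchy(parent_pd, parent_dr, proteins = proteins)
}

#' Write a hierarchy in the canonical TSV edge format
#'
#' Inverse of [load_hierarchy()]: rows are sorted (protein declarations,
#' then domain edges, then residue edges, each lexicographically) so the
#' output is a canonical form.
#'
#' @param h hierarchy.
#' @param path output file path.
#' @export
write_hierarchy <- function(h, path) {
  stopifnot(inherits(h, "mlpip_hierarchy"))
  orphan <- setdiff(h$proteins, unique(unname(h$parent_pd)))
  rows <- c(
    if (length(orphan)) paste("P", sort(orphan), sep = "\t"),
    if (length(h$parent_pd))
      paste("D", names(h$parent_pd), unname(h$parent_pd), sep = "\t"),
    if (length(h$parent_dr))
      paste("R", names(h$parent_dr), unname(h$parent_dr), sep = "\t"))
  writeLines(rows %||% character(), path, useBytes = TRUE)
  invisible(path)
}

#' Level of each identifier
#' @param h hierarchy.
#' @param ids character vector.
#' @return character vector in `c("protein","domain","residue")`; errors on
#'   unknown ids.
#' @keywords internal
id_level <- function(h, ids) {
  out <- rep(NA_character_, length(ids))
  out[ids %in% h$proteins] <- "protein"
  out[ids %in% h$domains] <- "domain"
  out[ids %in% h$residues] <- "residue"
  if (anyNA(out))
    stop("unknown identifier(s): ", paste(ids[is.na(out)], collapse = ", "))
  out
}

level_ids <- function(h, level) {
  switch(check_level(level), protein = h$proteins, domain = h$domains,
         residue = h$residues)
}

#' Children of objects one level down
#'
#' @param h hierarchy.
#' @param level level of the parents, `"protein"` or `"domain"`; proteins
#'   with `to = "residue"` use the derived protein-to-residue map.
#' @param to level of the children.
#' @return named list mapping each parent id to a character vector of child
#'   ids (possibly empty).
#' @export
children_map <- function(h, level = c("protein", "domain"),
                         to = NULL) {
  level <- match.arg(level)
  if (is.null(to)) to <- if (level == "protein") "domain" else "residue"
  map <- if (level == "protein" && to == "domain") h$parent_pd
         else if (level == "domain" && to == "residue") h$parent_dr
         else if (level == "protein" && to == "residue") h$parent_pr
         else stop("unsupported child relation ", level, " -> ", to)
  parents <- level_ids(h, level)
  nm <- names(map) %||% character()
  out <- split(nm, factor(unname(map) %||% character(), levels = parents))
  lapply(out, as.character)
}

#' Precompute the crisp guard predicates
#'
#' `hasdom(p)` is true iff protein `p` has at least one domain; `hasres_d(d)`
#' iff domain `d` has at least one residue; `hasres_p(p)` iff protein `p` has
#' at least one residue (the protein-level analogue used by the
#' protein-to-residue rule). Guards are computed once from the parent maps
#' and looked up at constraint-evaluation time.
#'
#' @param h hierarchy.
#' @return list of named logical vectors `hasdom`, `hasres_d`, `hasres_p`.
#' @export
compute_guards <- function(h) {
  stopifnot(inherits(h, "mlpip_hierarchy"))
  hasdom <- table(factor(unname(h$parent_pd), levels = h$proteins)) > 0
  hasres_d <- table(factor(unname(h$parent_dr), levels = h$domains)) > 0
  hasres_p <- table(factor(unname(h$parent_pr), levels = h$proteins)) > 0
  list(hasdom = stats::setNames(as.logical(hasdom), h$proteins),
       hasres_d = stats::setNames(as.logical(hasres_d), h$domains),
       hasres_p = stats::setNames(as.logical(hasres_p), h$proteins))
}

#' Construct a labeled pair set
#'
#' Pairs are canonicalized (`id_a < id_b`); self-pairs, duplicates and
#' conflicting labels for the same unordered pair are integrity errors, since
#' the bound predicates are symmetric.
#'
#' @param pairs data.frame with columns `id_a`, `id_b`, `label`
#'   (+1 / -1).
#' @param level `"protein"`, `"domain"` or `"residue"`.
#' @param h optional hierarchy; when given, all ids must exist at `level`.
#' @return data.frame of class `mlpip_labels` with attribute `level`.
#' @export
labeled_pairs <- function(pairs, level, h = NULL) {
  level <- check_level(level)
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (nrow(pairs) == 0L) {
    out <- data.frame(id_a = character(), id_b = character(),
                      label = integer(), stringsAsFactors = FALSE)
  } else {
    label <- as.integer(pairs[[if ("label" %in% names(pairs)) "label" else 3L]])
    if (!all(label %in% c(-1L, 1L)))
      stop("labels must be +1 or -1")
    a <- as.character(pairs$id_a %||% pairs[[1L]])
    b <- as.character(pairs$id_b %||% pairs[[2L]])
    if (any(a == b))
      stop("integrity error: self-pair ", a[which(a == b)[1L]])
    out <- canonical_pairs(data.frame(id_a = a, id_b = b, label = label,
                                      stringsAsFactors = FALSE),
                           dedup = FALSE)
    key <- pair_key(out$id_a, out$id_b)
    agg <- tapply(out$label, key, function(l) length(unique(l)))
    if (any(agg > 1L))
      stop("integrity error: conflicting labels for pair(s) ",
           paste(names(agg)[agg > 1L], collapse = ", "))
    out <- out[!duplicated(key), , drop = FALSE]
    rownames(out) <- NULL
  }
  if (!is.null(h)) {
    ids <- unique(c(out$id_a, out$id_b))
    bad <- setdiff(ids, level_ids(h, level))
    if (length(bad))
      stop("integrity error: id(s) not at level '", level, "': ",
           paste(bad, collapse = ", "))
  }
  attr(out, "level") <- level
  class(out) <- c("mlpip_labels", "data.frame")
  out
}

#' Read labeled pairs from a TSV file
#'
#' Four tab-separated columns: level (`P`|`D`|`R`), id_a, id_b, label
#' (`+1`|`-1`); `#` comments allowed. Only rows matching `level` are kept.
#'
#' @param path file path.
#' @param level level name to extract.
#' @param h optional hierarchy for id validation.
#' @return [labeled_pairs()] object.
#' @export
load_labels <- function(path, level, h = NULL) {
  level <- check_level(level)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- sub("#.*$", "", readLines(path, encoding = "UTF-8"))
  keep <- which(trimws(lines) != "")
  code <- c(protein = "P", domain = "D", residue = "R")[[level]]
  recs <- lapply(keep, function(i) {
    fields <- strsplit(trimws(lines[i]), "[ \t]+")[[1L]]
    if (length(fields) != 4L)
      stop("parse error at line ", i, ": expected 4 columns")
    fields
  })
  if (length(recs) == 0L)
    return(labeled_pairs(data.frame(), level, h))
  m <- do.call(rbind, recs)
  m <- m[m[, 1L] == code, , drop = FALSE]
  if (nrow(m) == 0L) return(labeled_pairs(data.frame(), level, h))
  lab <- suppressWarnings(as.integer(m[, 4L]))
  if (anyNA(lab)) stop("parse error: label must be +1 or -1")
  labeled_pairs(data.frame(id_a = m[, 2L], id_b = m[, 3L], label = lab,
                           stringsAsFactors = FALSE), level, h)
}

#' Write labeled pairs in the labels TSV dialect
#' @param labels one [labeled_pairs()] object or a list of them.
#' @param path output path.
#' @export
write_labels <- function(labels, path) {
  if (inherits(labels, "mlpip_labels")) labels <- list(labels)
  rows <- unlist(lapply(labels, function(l) {
    if (nrow(l) == 0L) return(character())
    code <- c(protein = "P", domain = "D", residue = "R")[[attr(l, "level")]]
    paste(code, l$id_a, l$id_b, sprintf("%+d", l$label), sep = "\t")
  }))
  writeLines(rows, path, useBytes = TRUE)
  invisible(path)
}

#' All child cross-pairs of a set of object pairs
#'
#' For each pair `(a, b)` of objects at `level`, emits every pair `(c, d)`
#' with `c` a child of `a` and `d` a child of `b`. These are exactly the
#' groundings over which the inner quantifiers of the consistency rules
#' range: the conjunction with the crisp parent predicates makes any other
#' child assignment identically false. Pairs are canonicalized and
#' de-duplicated.
#'
#' @param h hierarchy.
#' @param pairs data.frame with columns `id_a`, `id_b`.
#' @param level level of the input pairs.
#' @param to child level (defaults one level down; `"residue"` from
#'   `"protein"` uses the derived map).
#' @return data.frame `id_a`, `id_b` of canonical child pairs.
#' @export
child_pairs <- function(h, pairs, level = c("protein", "domain"), to = NULL) {
  level <- match.arg(level)
  if (is.null(to)) to <- if (level == "protein") "domain" else "residue"
  cm <- children_map(h, level, to)
  pairs <- canonical_pairs(pairs[, c("id_a", "id_b")])
  if (nrow(pairs) == 0L)
    return(data.frame(id_a = character(), id_b = character(),
                      stringsAsFactors = FALSE))
  out <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    ca <- cm[[pairs$id_a[i]]]
    cb <- cm[[pairs$id_b[i]]]
    if (is.null(ca) || is.null(cb))
      stop("unknown id in pair: ", pairs$id_a[i], ", ", pairs$id_b[i])
    if (length(ca) == 0L || length(cb) == 0L) next
    g <- expand.grid(a = ca, b = cb, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
    out[[i]] <- g
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L)
    return(data.frame(id_a = character(), id_b = character(),
                      stringsAsFactors = FALSE))
  canonical_pairs(do.call(rbind, out))
}

#' Candidate closure of a protein-pair set
#'
#' Expands a set of protein pairs into the domain cross-pairs of their
#' children and, from those, the residue cross-pairs. These candidate sets
#' are the unlabeled pair universes used for transductive constraint
#' enforcement.
#'
#' @param h hierarchy.
#' @param protein_pairs data.frame `id_a`, `id_b` of protein pairs.
#' @return list with elements `domain_pairs` and `residue_pairs`.
#' @export
candidate_closure <- function(h, protein_pairs) {
  dp <- child_pairs(h, protein_pairs, "protein")
  rp <- child_pairs(h, dp, "domain")
  list(domain_pairs = dp, residue_pairs = rp)
}
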