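#' @title Boolean gene-reaction rules
#' @description
#' Gene-reaction rules (GPRs) are positive Boolean formulas over gene
#' identifiers with `and`/`or` operators and parentheses. They encode which
#' gene complements enable a reaction: `or` joins isoenzymes (any one gene
#' suffices), `and` joins subunits of a complex (all genes required). The
#' rules here are monotone by construction -- there is no negation -- which is
#' what makes orthology-based substitution sound.
#'
#' A rule is represented as a tree of lists. Leaves are
#' `list(op = "gene", gene = <id>)`; internal nodes are
#' `list(op = "and"|"or", args = <list of subtrees>)`; the literal
#' `list(op = "false")` arises when substitution finds no ortholog. A reaction
#' *without* a rule is represented by `NULL` everywhere in the package and is
#' distinct from any gene-bearing rule and from the false literal.
#' @name gpr
NULL

gpr_gene <- function(id) structure(list(op = "gene", gene = id), class = "gpr")
gpr_false <- function() structure(list(op = "false"), class = "gpr")

gpr_node <- function(op, args) {
  stopifnot(op %in% c("and", "or"), length(args) >= 1L)
  if (length(args) == 1L) return(args[[1L]])
  structure(list(op = op, args = args), class = "gpr")
}

#' Parse a gene-reaction rule
#'
#' Parses rule text in the conventional GPR dialect: gene identifiers joined
#' by `and` / `or` (case-insensitive), with parentheses for grouping. `and`
#' binds tighter than `or`, so `"g1 and g2 or g3"` parses as
#' `(g1 and g2) or g3`. Empty or whitespace-only text yields `NULL` (no rule).
#'
#' @param text character scalar; the rule text. `NA` or `""` give `NULL`.
#' @return an object of class `gpr`, or `NULL` for an empty rule.
#' @examples
#' r <- parse_gpr("gA and (gB or gC)")
#' gpr_genes(r)
#' eval_gpr(r, c("gA", "gB"))
#' @export
parse_gpr <- function(text) {
  if (is.null(text) || length(text) == 0L) return(NULL)
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) return(NULL)

  toks <- gpr_tokenize(text)
  state <- new.env(parent = emptyenv())
  state$toks <- toks
  state$pos <- 1L
  rule <- gpr_parse_or(state, text)
  if (state$pos <= nrow(state$toks)) {
    tk <- state$toks[state$pos, ]
    stop(sprintf("GPR parse error at position %d: unexpected '%s' in rule '%s'",
                 tk$start, tk$value, text), call. = FALSE)
  }
  rule
}

gpr_tokenize <- function(text) {
  pat <- "\\(|\\)|[^()\\s]+"
  m <- gregexpr(pat, text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) {
    return(data.frame(type = character(), value = character(),
                      start = integer(), stringsAsFactors = FALSE))
  }
  vals <- regmatches(text, list(m))[[1L]]
  starts <- as.integer(m)
  type <- vapply(vals, function(v) {
    lv <- tolower(v)
    if (v == "(") "lpar"
    else if (v == ")") "rpar"
    else if (lv == "and") "and"
    else if (lv == "or") "or"
    else "gene"
  }, character(1L), USE.NAMES = FALSE)
  data.frame(type = type, value = vals, start = starts, stringsAsFactors = FALSE)
}

gpr_peek <- function(state) {
  if (state$pos > nrow(state$toks)) NULL else state$toks[state$pos, ]
}

gpr_parse_or <- function(state, text) {
  args <- list(gpr_parse_and(state, text))
  repeat {
    tk <- gpr_peek(state)
    if (is.null(tk) || tk$type != "or") break
    state$pos <- state$pos + 1L
    args <- c(args, list(gpr_parse_and(state, text)))
  }
  gpr_node("or", args)
}

gpr_parse_and <- function(state, text) {
  args <- list(gpr_parse_atom(state, text))
  repeat {
    tk <- gpr_peek(state)
    if (is.null(tk) || tk$type != "and") break
    state$pos <- state$pos + 1L
    args <- c(args, list(gpr_parse_atom(state, text)))
  }
  gpr_node("and", args)
}

gpr_parse_atom <- function(state, text) {
  tk <- gpr_peek(state)
  if (is.null(tk)) {
    stop(sprintf("GPR parse error: dangling operator at end of rule '%s'", text),
         call. = FALSE)
  }
  state$pos <- state$pos + 1L
  if (tk$type == "gene") return(gpr_gene(tk$value))
  if (tk$type == "lpar") {
    inner <- gpr_parse_or(state, text)
    close <- gpr_peek(state)
    if (is.null(close) || close$type != "rpar") {
      stop(sprintf("GPR parse error at position %d: unbalanced '(' in rule '%s'",
                   tk$start, text), call. = FALSE)
    }
    state$pos <- state$pos + 1L
    return(inner)
  }
  stop(sprintf("GPR parse error at position %d: unexpected '%s' in rule '%s'",
               tk$start, tk$value, text), call. = FALSE)
}

#' Deparse a rule back to text
#'
#' Inverse of [parse_gpr()]: `parse_gpr(gpr_to_text(r))` is structurally
#' identical to `r`. Parentheses are emitted only where precedence requires.
#'
#' @param rule a `gpr` object or `NULL`.
#' @return character scalar (`""` for `NULL`).
#' @export
gpr_to_text <- function(rule) {
  if (is.null(rule)) return("")
  stopifnot(inherits(rule, "gpr"))
  deparse1_gpr(rule, parent = "top")
}

deparse1_gpr <- function(node, parent) {
  switch(node$op,
    gene = node$gene,
    false = "FALSE",
    or = {
      s <- paste(vapply(node$args, deparse1_gpr, character(1L), parent = "or"),
                 collapse = " or ")
      if (parent == "and") paste0("(", s, ")") else s
    },
    and = paste(vapply(node$args, deparse1_gpr, character(1L), parent = "and"),
                collapse = " and ")
  )
}

#' @export
print.gpr <- function(x, ...) {
  cat("<gpr> ", gpr_to_text(x), "\n", sep = "")
  invisible(x)
}

#' Genes referenced by a rule
#'
#' @param rule a `gpr` object or `NULL`.
#' @return character vector of distinct gene ids (empty for `NULL`/false).
#' @export
gpr_genes <- function(rule) {
  if (is.null(rule)) return(character())
  switch(rule$op,
    gene = rule$gene,
    false = character(),
    unique(unlist(lapply(rule$args, gpr_genes)))
  )
}

#' Evaluate a rule against a set of present genes
#'
#' Standard monotone Boolean semantics: a gene leaf is true iff the gene is in
#' `present_genes`; genes not listed are absent. Passing an empty rule
#' (`NULL`) is a contract violation -- "no rule" is a reaction-level state
#' ([predict_presence()] handles it) and has no truth value here.
#'
#' @param rule a `gpr` object.
#' @param present_genes character vector of gene ids counted as present.
#' @return logical scalar.
#' @export
eval_gpr <- function(rule, present_genes) {
  if (is.null(rule)) {
    stop("eval_gpr() requires a non-empty rule; reactions without a GPR are ",
         "handled at the transfer level", call. = FALSE)
  }
  stopifnot(inherits(rule, "gpr"))
  eval_gpr_rec(rule, present_genes)
}

eval_gpr_rec <- function(node, present) {
  switch(node$op,
    gene = node$gene %in% present,
    false = FALSE,
    and = all(vapply(node$args, eval_gpr_rec, logical(1L), present = present)),
    or = any(vapply(node$args, eval_gpr_rec, logical(1L), present = present))
  )
}

#' Substitute reference genes by target-genome orthologs
#'
#' Rewrites a reference-genome rule for a target genome using an orthogroup
#' table. Each reference gene is replaced by the `or` over all target-genome
#' genes in its orthogroup (the co-ortholog "OR" assumption). A reference gene
#' whose orthogroup holds no target gene becomes logical false
#' (status `absent-in-target`); a reference gene absent from the table
#' altogether becomes false with status `unmapped-no-orthogroup` and must be
#' surfaced to the user rather than silently dropped. False branches are
#' pruned (`or(FALSE, x) -> x`; `and(FALSE, x) -> FALSE`) but no further
#' simplification is applied, so the substituted rule stays traceable to the
#' original structure.
#'
#' When two or more `and`-joined reference genes fall into one orthogroup that
#' does contain target genes, the co-ortholog assumption cannot distinguish
#' the complex subunits; such rules get `and_shared_orthogroup = TRUE` in the
#' report and need manual curation.
#'
#' @param rule a `gpr` object over reference-genome gene ids.
#' @param orthotable an [orthogroup_table].
#' @param reference_genome,target_genome genome ids (columns of the table).
#' @return a list with elements `rule` (the substituted `gpr`, possibly the
#'   false literal) and `report` (data frame with one row per distinct
#'   reference gene: `gene`, `status`, `replacements`) carrying the attribute
#'   `and_shared_orthogroup`.
#' @export
substitute_gpr <- function(rule, orthotable, reference_genome, target_genome) {
  stopifnot(inherits(rule, "gpr"), inherits(orthotable, "orthogroup_table"))
  if (!target_genome %in% orthotable$genomes) {
    stop("target genome '", target_genome, "' not in orthogroup table", call. = FALSE)
  }
  if (!reference_genome %in% orthotable$genomes) {
    stop("reference genome '", reference_genome, "' not in orthogroup table", call. = FALSE)
  }
  genes <- gpr_genes(rule)
  if (any(!nzchar(genes) | is.na(genes))) {
    stop("malformed reference gene id in rule", call. = FALSE)
  }
  status <- character(length(genes))
  repl <- vector("list", length(genes))
  og_of <- character(length(genes))
  for (i in seq_along(genes)) {
    og <- og_lookup(orthotable, reference_genome, genes[[i]])
    og_of[[i]] <- if (is.na(og)) NA_character_ else og
    if (is.na(og)) {
      status[[i]] <- "unmapped-no-orthogroup"
      repl[[i]] <- character()
    } else {
      tg <- orthotable$orthogroups[[og]][[target_genome]]
      if (is.null(tg) || length(tg) == 0L) {
        status[[i]] <- "absent-in-target"
        repl[[i]] <- character()
      } else {
        status[[i]] <- "mapped"
        repl[[i]] <- tg
      }
    }
  }
  names(repl) <- genes
  sub_rule <- gpr_substitute_rec(rule, repl)

  # and-joined reference genes sharing a target-bearing orthogroup
  flag <- FALSE
  for (grp in gpr_conjunctive_groups(rule)) {
    if (length(grp) < 2L) next
    ogs <- og_of[match(grp, genes)]
    ogs <- ogs[!is.na(ogs)]
    dup <- unique(ogs[duplicated(ogs)])
    for (d in dup) {
      if (length(orthotable$orthogroups[[d]][[target_genome]])) flag <- TRUE
    }
  }
  report <- data.frame(
    gene = genes,
    status = status,
    replacements = vapply(repl, paste, character(1L), collapse = ", "),
    stringsAsFactors = FALSE
  )
  attr(report, "and_shared_orthogroup") <- flag
  list(rule = sub_rule, report = report)
}

gpr_substitute_rec <- function(node, repl) {
  switch(node$op,
    false = gpr_false(),
    gene = {
      tg <- repl[[node$gene]]
      if (length(tg) == 0L) gpr_false()
      else gpr_node("or", lapply(tg, gpr_gene))
    },
    {
      args <- lapply(node$args, gpr_substitute_rec, repl = repl)
      is_false <- vapply(args, function(a) identical(a$op, "false"), logical(1L))
      if (node$op == "and") {
        if (any(is_false)) gpr_false() else gpr_node("and", args)
      } else {
        args <- args[!is_false]
        if (length(args) == 0L) gpr_false() else gpr_node("or", args)
      }
    }
  )
}

# Maximal and-connected leaf groups: genes joined (possibly through nested
# "and" nodes) into one conjunction. Used for the shared-orthogroup check.
gpr_conjunctive_groups <- function(node) {
  switch(node$op,
    gene = list(node$gene),
    false = list(),
    or = unlist(lapply(node$args, gpr_conjunctive_groups), recursive = FALSE),
    and = {
      parts <- lapply(node$args, gpr_conjunctive_groups)
      # direct gene/and children merge into this conjunction; or-children keep
      # their own groups but their genes also participate in the conjunction
      merged <- unique(unlist(parts))
      inner <- unlist(lapply(node$args, function(a) {
        if (a$op == "or") gpr_conjunctive_groups(a) else list()
      }), recursive = FALSE)
      c(list(merged), inner)
    }
  )
}

#' Is a rule the false literal?
#' @param rule a `gpr` object or `NULL`.
#' @return logical scalar; `FALSE` for `NULL` (no rule is not false).
#' @export
gpr_is_false <- function(rule) {
  !is.null(rule) && identical(rule$op, "false")
}
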