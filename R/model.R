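#' Construct a genome-scale metabolic model
#'
#' The central container of the package. A `gem` holds compartments,
#' metabolites (with elemental formulas and charges), reactions (stoichiometry
#' as named coefficient vectors, flux bounds in mmol gCDW^-1 h^-1, parsed
#' gene-reaction rules, EC numbers), the gene set, and the objective (biomass)
#' reaction. Validation enforces the structural invariants: unique ids,
#' declared compartments, metabolites referenced by reactions exist, GPR genes
#' are in the gene set, bounds are ordered, and exchange reactions touch
#' exactly one metabolite.
#'
#' @param id model identifier.
#' @param compartments character vector of compartment ids.
#' @param metabolites data frame with columns `id`, `name`, `formula`,
#'   `charge`, `compartment`. `formula` may be `NA` (explicitly absent).
#' @param reactions data frame with columns `id`, `name`, `lower_bound`,
#'   `upper_bound` and list-columns `stoich` (named numeric: metabolite id ->
#'   signed coefficient), `gpr` (parsed rule or `NULL`), `ec` (character
#'   vector of EC numbers); optional `is_exchange` (logical; default: reaction
#'   touches exactly one metabolite) and `notes` (character).
#' @param genes character vector of gene ids (defaults to genes in GPRs).
#' @param objective id of the biomass reaction, or `NA` for none.
#' @return object of class `gem`.
#' @seealso [read_gem()], [summary.gem()], [solve_fba()]
#' @export
gem <- function(id, compartments, metabolites, reactions, genes = NULL,
                objective = NA_character_) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (nrow(metabolites) && anyDuplicated(metabolites$id)) {
    stop("duplicate metabolite id: ",
         metabolites$id[duplicated(metabolites$id)][1L], call. = FALSE)
  }
  if (nrow(reactions) && anyDuplicated(reactions$id)) {
    stop("duplicate reaction id: ",
         reactions$id[duplicated(reactions$id)][1L], call. = FALSE)
  }
  if (is.null(metabolites$charge)) metabolites$charge <- NA_integer_
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$formula)) metabolites$formula <- NA_character_
  if (is.null(reactions$name)) reactions$name <- reactions$id
  if (is.null(reactions$notes)) reactions$notes <- ""
  if (is.null(reactions$ec)) reactions$ec <- replicate(nrow(reactions), character())
  if (is.null(reactions$gpr)) reactions$gpr <- replicate(nrow(reactions), NULL)
  if (is.null(reactions$is_exchange)) {
    reactions$is_exchange <- vapply(reactions$stoich, function(s) length(s) == 1L,
                                    logical(1L))
  }
  rule_genes <- unique(unlist(lapply(reactions$gpr, gpr_genes)))
  if (is.null(genes)) genes <- rule_genes
  genes <- unique(as.character(genes))

  m <- structure(list(
    id = id,
    compartments = unique(as.character(compartments)),
    metabolites = metabolites,
    reactions = reactions,
    genes = genes,
    objective = objective
  ), class = "gem")
  validate_gem(m)
  m
}

validate_gem <- function(m) {
  met_ids <- m$metabolites$id
  bad_comp <- setdiff(unique(m$metabolites$compartment), m$compartments)
  if (length(bad_comp)) {
    stop("metabolite compartment(s) not declared: ",
         paste(bad_comp, collapse = ", "), call. = FALSE)
  }
  for (i in seq_len(nrow(m$reactions))) {
    r <- m$reactions[i, ]
    s <- r$stoich[[1L]]
    if (length(s) == 0L && !isTRUE(r$is_exchange)) {
      stop("reaction '", r$id, "' has empty stoichiometry", call. = FALSE)
    }
    missing_met <- setdiff(names(s), met_ids)
    if (length(missing_met)) {
      stop("reaction '", r$id, "' references unknown metabolite(s): ",
           paste(missing_met, collapse = ", "), call. = FALSE)
    }
    if (r$lower_bound > r$upper_bound) {
      stop("reaction '", r$id, "' has lower_bound > upper_bound", call. = FALSE)
    }
    if (isTRUE(r$is_exchange) && length(s) != 1L) {
      stop("exchange reaction '", r$id, "' must touch exactly one metabolite",
           call. = FALSE)
    }
  }
  rule_genes <- unique(unlist(lapply(m$reactions$gpr, gpr_genes)))
  missing_genes <- setdiff(rule_genes, m$genes)
  if (length(missing_genes)) {
    stop("GPR gene(s) not in the model gene set: ",
         paste(missing_genes, collapse = ", "), call. = FALSE)
  }
  if (!is.na(m$objective) && !m$objective %in% m$reactions$id) {
    stop("objective reaction '", m$objective, "' not in the model", call. = FALSE)
  }
  invisible(m)
}

#' @export
print.gem <- function(x, ...) {
  cat("<gem> ", x$id, "\n", sep = "")
  cat("  compartments: ", paste(x$compartments, collapse = ", "), "\n", sep = "")
  cat("  metabolites:  ", nrow(x$metabolites), "\n", sep = "")
  cat("  reactions:    ", nrow(x$reactions),
      " (", sum(x$reactions$is_exchange), " exchange)\n", sep = "")
  cat("  genes:        ", length(x$genes), "\n", sep = "")
  cat("  objective:    ", x$objective, "\n", sep = "")
  invisible(x)
}

#' Stoichiometric matrix of a model
#'
#' @param model a `gem`.
#' @return dense numeric matrix, metabolites x reactions, with dimnames.
#' @export
gem_smatrix <- function(model) {
  S <- matrix(0, nrow(model$metabolites), nrow(model$reactions),
              dimnames = list(model$metabolites$id, model$reactions$id))
  for (j in seq_len(nrow(model$reactions))) {
    s <- model$reactions$stoich[[j]]
    S[names(s), j] <- s
  }
  S
}

#' Summarize model composition
#'
#' Counts the entities reported in GEM composition tables: compartments,
#' genes, reactions, exchange reactions, irreversible reactions (lower bound
#' >= 0 or upper bound <= 0), orphan reactions (non-exchange reactions without
#' a GPR), metabolites, and dead-end metabolites (see
#' [find_dead_end_metabolites()]).
#'
#' @param object a `gem`.
#' @param ... unused.
#' @return a one-row data frame of class `gem_summary`.
#' @export
summary.gem <- function(object, ...) {
  rx <- object$reactions
  irreversible <- rx$lower_bound >= 0 | rx$upper_bound <= 0
  orphan <- !rx$is_exchange & vapply(rx$gpr, is.null, logical(1L))
  out <- data.frame(
    compartments = length(object$compartments),
    genes = length(object$genes),
    reactions = nrow(rx),
    exchange_reactions = sum(rx$is_exchange),
    irreversible_reactions = sum(irreversible),
    orphan_reactions = sum(orphan),
    metabolites = nrow(object$metabolites),
    dead_end_metabolites = length(find_dead_end_metabolites(object))
  )
  class(out) <- c("gem_summary", "data.frame")
  out
}

#' @export
print.gem_summary <- function(x, ...) {
  y <- as.data.frame(t(as.matrix(x)))
  colnames(y) <- "count"
  print(y)
  invisible(x)
}

#' Find dead-end metabolites
#'
#' A metabolite is dead-end when its producing channels or its consuming
#' channels are empty, resolving directions by reaction reversibility: a
#' reaction with `upper_bound > 0` can run forward (produces its products,
#' consumes its substrates) and one with `lower_bound < 0` can run backward.
#' A reversible reaction therefore both produces and consumes all its
#' participants, so a metabolite appearing in a single reversible reaction is
#' still dead-end (its production and consumption channels coincide in one
#' reaction). Exchange reactions count as ordinary producers/consumers of
#' their metabolite.
#'
#' @param model a `gem`.
#' @return character vector of dead-end metabolite ids.
#' @export
find_dead_end_metabolites <- function(model) {
  if (nrow(model$metabolites) == 0L) return(character())
  S <- gem_smatrix(model)
  fwd <- model$reactions$upper_bound > 0
  bwd <- model$reactions$lower_bound < 0
  # production channels: coef>0 in a forward-capable rxn, or coef<0 backward
  produced <- (S > 0) %*% diag(as.numeric(fwd), ncol(S)) +
              (S < 0) %*% diag(as.numeric(bwd), ncol(S))
  consumed <- (S < 0) %*% diag(as.numeric(fwd), ncol(S)) +
              (S > 0) %*% diag(as.numeric(bwd), ncol(S))
  # a metabolite touching exactly one reaction is dead-end even when that
  # reaction is reversible: its production and consumption channels coincide,
  # so no steady-state flux can pass through it
  dead <- rowSums(produced) == 0 | rowSums(consumed) == 0 |
    rowSums(S != 0) == 1
  rownames(S)[dead]
}

#' Parse an elemental formula
#'
#' @param formula formula text such as `"C6H12O6"`. Element symbols are one
#'   upper-case letter optionally followed by one lower-case letter, each with
#'   an optional integer count.
#' @return named integer vector element -> count.
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  if (is.na(formula)) stop("formula is absent (NA)", call. = FALSE)
  pat <- "([A-Z][a-z]?)([0-9]*)"
  m <- gregexpr(pat, formula, perl = TRUE)[[1L]]
  toks <- regmatches(formula, list(m))[[1L]]
  if (paste(toks, collapse = "") != formula) {
    covered <- strsplit(paste(toks, collapse = ""), "")[[1L]]
    raw <- strsplit(formula, "")[[1L]]
    bad <- setdiff(raw, covered)
    stop("unparsable formula '", formula, "': bad token(s) ",
         paste(unique(bad), collapse = " "), call. = FALSE)
  }
  el <- sub(pat, "\\1", toks, perl = TRUE)
  ct <- sub(pat, "\\2", toks, perl = TRUE)
  ct <- ifelse(ct == "", 1L, as.integer(ct))
  out <- tapply(ct, el, sum)
  storage.mode(out) <- "integer"
  out[order(names(out))]
}

#' Carbon atoms per molecule
#'
#' Number of carbon atoms in an elemental formula; used to express uptake
#' fluxes in c-mmol (millimoles of carbon) for the total-carbon cap.
#'
#' @param formula formula text, e.g. `"C6H12O6"` -> 6, `"H2O"` -> 0.
#' @return integer scalar.
#' @export
carbon_count <- function(formula) {
  f <- parse_formula(formula)
  if ("C" %in% names(f)) unname(f[["C"]]) else 0L
}

#' Check elemental mass balance of reactions
#'
#' Sums `coefficient x element-count` over each reaction's participants and
#' reports any nonzero element delta. Exchange reactions are excluded by
#' contract (they are boundary pseudo-reactions), as are reactions named in
#' `exempt` -- biomass and macromolecular lumped reactions, which are not
#' elementally balanced by construction. Reactions touching a metabolite
#' without a formula cannot be checked and are reported separately, never
#' treated as balanced.
#'
#' @param model a `gem`.
#' @param exempt character vector of reaction ids exempt from the check
#'   (defaults to the objective reaction).
#' @return data frame with columns `reaction_id`, `element`, `delta` (one row
#'   per imbalanced element), with attribute `unchecked`: ids of reactions
#'   with formula-less participants.
#' @export
check_mass_balance <- function(model, exempt = model$objective) {
  exempt <- exempt[!is.na(exempt)]
  forms <- stats::setNames(model$metabolites$formula, model$metabolites$id)
  rows <- list()
  unchecked <- character()
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    if (isTRUE(r$is_exchange) || r$id %in% exempt) next
    s <- r$stoich[[1L]]
    fs <- forms[names(s)]
    if (anyNA(fs)) {
      unchecked <- c(unchecked, r$id)
      next
    }
    bal <- numeric()
    for (k in seq_along(s)) {
      f <- parse_formula(fs[[k]])
      for (el in names(f)) {
        bal[el] <- (if (el %in% names(bal)) bal[[el]] else 0) + s[[k]] * f[[el]]
      }
    }
    bad <- bal[abs(bal) > 1e-9]
    if (length(bad)) {
      rows[[length(rows) + 1L]] <- data.frame(
        reaction_id = r$id, element = names(bad), delta = unname(bad),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(reaction_id = character(), element = character(),
               delta = numeric(), stringsAsFactors = FALSE)
  attr(out, "unchecked") <- unique(unchecked)
  out
}

# internal helpers -----------------------------------------------------------

gem_reaction <- function(model, id) {
  i <- match(id, model$reactions$id)
  if (is.na(i)) stop("no reaction '", id, "' in model '", model$id, "'", call. = FALSE)
  model$reactions[i, ]
}

# Subset a model to a reaction set, pruning metabolites and genes; keep_mets
# are retained even when orphaned (biomass precursors during transfer).
gem_subset <- function(model, reaction_ids, keep_mets = character(),
                       id = model$id) {
  rx <- model$reactions[model$reactions$id %in% reaction_ids, , drop = FALSE]
  used <- unique(c(unlist(lapply(rx$stoich, names)), keep_mets))
  mets <- model$metabolites[model$metabolites$id %in% used, , drop = FALSE]
  genes <- unique(unlist(lapply(rx$gpr, gpr_genes)))
  obj <- if (!is.na(model$objective) && model$objective %in% rx$id)
    model$objective else NA_character_
  gem(id = id, compartments = model$compartments, metabolites = mets,
      reactions = rx, genes = genes, objective = obj)
}
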