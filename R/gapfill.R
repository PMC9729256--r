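#' Read an annotation-evidence table
#'
#' Flat TSV with columns `genome`, `gene`, `ec` (semicolon- or comma-separated
#' EC numbers, may be empty), `annotation` (free-text product description) and
#' `source` (annotation pipeline label). These tables stand in for the
#' per-genome functional annotation stores the reconstruction method draws
#' its curation evidence from.
#'
#' @param path TSV path.
#' @return data frame of class `evidence_table` with a list-column `ec_list`.
#' @export
read_evidence <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("genome", "gene", "ec", "annotation", "source")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("evidence table '", path, "' lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(df$source))) {
    stop("evidence rows without a source tag in '", path, "'", call. = FALSE)
  }
  evidence_table(df)
}

#' Construct an evidence table from a data frame
#'
#' @param df data frame with columns `genome`, `gene`, `ec`, `annotation`,
#'   `source`.
#' @return the data frame with class `evidence_table` and parsed `ec_list`.
#' @export
evidence_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$ec_list <- lapply(df$ec, function(e) {
    ids <- trimws(strsplit(e, "[;,]")[[1L]])
    ids[nzchar(ids)]
  })
  class(df) <- c("evidence_table", "data.frame")
  df
}

#' Genes of a genome supporting an EC number
#'
#' @param evidence an `evidence_table`.
#' @param genome genome id.
#' @param ec EC number text.
#' @return character vector of gene ids (possibly empty).
#' @export
evidence_genes_for_ec <- function(evidence, genome, ec) {
  rows <- evidence$genome == genome &
    vapply(evidence$ec_list, function(e) ec %in% e, logical(1L))
  unique(evidence$gene[rows])
}

#' Minimal-set gap filling from a template model
#'
#' Finds a minimum-cardinality set of template reactions whose addition to a
#' non-growing draft restores growth on the given medium. The candidate pool
#' is the template reactions absent from the draft, excluding exchange
#' reactions unless the medium names them. The search is exact and
#' deterministic:
#'
#' 1. If even the full candidate pool gives no growth, the draft is
#'    unfillable and the blocked biomass precursors are reported.
#' 2. Leave-one-out over the full pool identifies *forced* candidates --
#'    reactions whose removal (with all others present) kills growth. Because
#'    adding reactions can only enlarge the feasible flux space, every forced
#'    candidate belongs to every growth-restoring subset.
#' 3. If the forced set alone restores growth it is the certified unique
#'    minimum. Otherwise the residual pool is searched in order of increasing
#'    cardinality, lexicographic within a cardinality (the deterministic
#'    tie-break); the result is certified minimal when the residual pool size
#'    is at most `candidate_cap`, else a greedy irreducible set is returned
#'    with `minimal = FALSE`.
#'
#' If the draft lacks an objective reaction (biomass did not transfer), the
#' template's objective is used as the growth target.
#'
#' @param draft a [gem] failing [growth_test()].
#' @param template a [gem] providing candidate reactions (and their
#'   metabolites).
#' @param medium a [medium_spec].
#' @param threshold growth threshold (h^-1).
#' @param candidate_cap residual-pool size up to which exhaustive search is
#'   used (certified minimality).
#' @return object of class `gapfill_solution`: `added_reactions` (sorted ids),
#'   `achieved_growth`, `minimal` (certification flag), `verdicts` (filled by
#'   [curate_gapfill()]), `unfillable`, `blocked_precursors`.
#' @export
gap_fill <- function(draft, template, medium = medium_spec(),
                     threshold = 1e-6, candidate_cap = 12L) {
  stopifnot(inherits(draft, "gem"), inherits(template, "gem"))
  candidates <- setdiff(template$reactions$id, draft$reactions$id)
  tpl_rx <- template$reactions[match(candidates, template$reactions$id), ,
                               drop = FALSE]
  is_ex <- tpl_rx$is_exchange
  medium_ids <- c(names(medium$uptake), medium$always_open)
  candidates <- candidates[!is_ex | candidates %in% medium_ids]
  candidates <- sort(candidates)

  if (growth_test(draft, medium, threshold)) {
    return(new_gapfill_solution(character(), achieved = solve_fba(draft, medium)$objective,
                                minimal = TRUE))
  }

  grows_with <- function(ids) {
    m <- merge_reactions(draft, template, ids)
    growth_test(m, medium, threshold)
  }
  if (!grows_with(candidates)) {
    full <- merge_reactions(draft, template, candidates)
    blocked <- intersect(find_dead_end_metabolites(full),
                         biomass_precursors(template))
    sol <- new_gapfill_solution(character(), achieved = 0, minimal = FALSE)
    sol$unfillable <- TRUE
    sol$blocked_precursors <- blocked
    return(sol)
  }

  forced <- candidates[!vapply(seq_along(candidates), function(i)
    grows_with(candidates[-i]), logical(1L))]

  if (grows_with(forced)) {
    added <- forced
    minimal <- TRUE
  } else {
    rest <- setdiff(candidates, forced)
    if (length(rest) <= candidate_cap) {
      added <- NULL
      for (k in seq_along(rest)) {
        combos <- utils::combn(rest, k, simplify = FALSE)  # lexicographic order
        for (cmb in combos) {
          if (grows_with(c(forced, cmb))) { added <- c(forced, cmb); break }
        }
        if (!is.null(added)) break
      }
      minimal <- TRUE
    } else {
      # greedy pruning: irreducible but not certified minimum
      added <- candidates
      for (id in rev(setdiff(candidates, forced))) {
        trial <- setdiff(added, id)
        if (grows_with(trial)) added <- trial
      }
      minimal <- FALSE
    }
  }
  achieved <- solve_fba(merge_reactions(draft, template, added), medium)$objective
  new_gapfill_solution(sort(added), achieved = achieved, minimal = minimal)
}

new_gapfill_solution <- function(added, achieved, minimal) {
  structure(list(
    added_reactions = added,
    achieved_growth = achieved,
    minimal = minimal,
    verdicts = data.frame(reaction_id = added,
                          verdict = rep(NA_character_, length(added)),
                          matched_genes = rep("", length(added)),
                          stringsAsFactors = FALSE),
    unfillable = FALSE,
    blocked_precursors = character()
  ), class = "gapfill_solution")
}

#' @export
print.gapfill_solution <- function(x, ...) {
  cat("<gapfill_solution>\n")
  if (x$unfillable) {
    cat("  UNFILLABLE; blocked biomass precursors: ",
        paste(x$blocked_precursors, collapse = ", "), "\n", sep = "")
    return(invisible(x))
  }
  cat("  added reactions (", length(x$added_reactions), "): ",
      paste(x$added_reactions, collapse = ", "), "\n", sep = "")
  cat("  achieved growth: ", format(x$achieved_growth, digits = 6), " h^-1\n",
      sep = "")
  cat("  certified minimal: ", x$minimal, "\n", sep = "")
  if (!all(is.na(x$verdicts$verdict))) {
    tb <- table(x$verdicts$verdict)
    cat("  verdicts: ", paste(names(tb), tb, sep = "=", collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

biomass_precursors <- function(model) {
  if (is.na(model$objective)) return(character())
  s <- model$reactions$stoich[[match(model$objective, model$reactions$id)]]
  names(s)[s < 0]
}

# Draft + a template reaction subset (metabolites and objective carried over
# as needed). Used for gap-fill feasibility probing.
merge_reactions <- function(draft, template, ids) {
  if (!length(ids)) add <- NULL
  else add <- template$reactions[match(ids, template$reactions$id), , drop = FALSE]
  rx <- if (is.null(add)) draft$reactions else rbind(draft$reactions, add)
  used <- unique(unlist(lapply(rx$stoich, names)))
  mets <- template$metabolites[template$metabolites$id %in% used, , drop = FALSE]
  extra <- draft$metabolites[!draft$metabolites$id %in% mets$id &
                             draft$metabolites$id %in% used, , drop = FALSE]
  mets <- rbind(mets, extra)
  obj <- draft$objective
  if (is.na(obj) && !is.na(template$objective) &&
      template$objective %in% rx$id) {
    obj <- template$objective
  }
  gem(id = draft$id, compartments = union(draft$compartments, template$compartments),
      metabolites = mets, reactions = rx,
      genes = union(draft$genes, unique(unlist(lapply(rx$gpr, gpr_genes)))),
      objective = obj)
}

#' Curate a gap-fill solution against annotation evidence
#'
#' Assigns a verdict to each added reaction: `evidence-found` when the
#' reaction's EC numbers intersect the genome's annotated ECs (matched genes
#' recorded) or, failing that, when the reaction name matches an annotation
#' text exactly after normalization; `no-evidence` otherwise;
#' `forced-by-user` for reactions in `force_include`. Only `evidence-found`
#' and `forced-by-user` reactions survive into [apply_gapfill()] -- the
#' curation step of the method keeps in-silico growth honest against the
#' genome. `force_exclude` overrides any evidence.
#'
#' @param solution a `gapfill_solution`.
#' @param evidence an `evidence_table`.
#' @param template the template [gem] (source of EC numbers and names).
#' @param target_genome genome id whose evidence rows apply.
#' @param force_include,force_exclude character vectors of reaction ids.
#' @return the solution with `verdicts` filled and `accepted` attribute set.
#' @export
curate_gapfill <- function(solution, evidence, template, target_genome,
                           force_include = character(),
                           force_exclude = character()) {
  stopifnot(inherits(solution, "gapfill_solution"),
            inherits(evidence, "evidence_table"))
  ann_norm <- tolower(trimws(evidence$annotation[evidence$genome == target_genome]))
  verdict <- character(length(solution$added_reactions))
  matched <- character(length(solution$added_reactions))
  for (i in seq_along(solution$added_reactions)) {
    id <- solution$added_reactions[[i]]
    if (id %in% force_exclude) { verdict[i] <- "no-evidence"; next }
    if (id %in% force_include) { verdict[i] <- "forced-by-user"; next }
    r <- gem_reaction(template, id)
    ecs <- r$ec[[1L]]
    genes <- unique(unlist(lapply(ecs, function(e)
      evidence_genes_for_ec(evidence, target_genome, e))))
    if (length(genes)) {
      verdict[i] <- "evidence-found"
      matched[i] <- paste(genes, collapse = ", ")
    } else if (tolower(trimws(r$name)) %in% ann_norm) {
      verdict[i] <- "evidence-found"
      rows <- evidence$genome == target_genome &
        tolower(trimws(evidence$annotation)) == tolower(trimws(r$name))
      matched[i] <- paste(unique(evidence$gene[rows]), collapse = ", ")
    } else {
      verdict[i] <- "no-evidence"
    }
  }
  solution$verdicts <- data.frame(reaction_id = solution$added_reactions,
                                  verdict = verdict, matched_genes = matched,
                                  stringsAsFactors = FALSE)
  attr(solution, "accepted") <-
    solution$added_reactions[verdict %in% c("evidence-found", "forced-by-user")]
  solution
}

#' Apply a curated gap-fill solution to a draft model
#'
#' Copies the accepted reactions (verdict `evidence-found` or
#' `forced-by-user`) from the template into the draft, together with any new
#' metabolites. When an orthogroup table is supplied, the copied reactions'
#' rules are re-substituted for the target genome; otherwise the template
#' rules are carried with a provenance note. Re-applying never removes
#' reactions, so composition counts are monotone. Restores the template's
#' objective if the draft lost it during transfer.
#'
#' @param draft a [gem].
#' @param solution a curated `gapfill_solution`.
#' @param template the template [gem].
#' @param orthotable optional [orthogroup_table] for rule re-substitution.
#' @param reference_genome,target_genome genome ids (required with
#'   `orthotable`).
#' @return the filled [gem].
#' @export
apply_gapfill <- function(draft, solution, template, orthotable = NULL,
                          reference_genome = NULL, target_genome = NULL) {
  stopifnot(inherits(solution, "gapfill_solution"))
  accepted <- attr(solution, "accepted")
  if (is.null(accepted)) {
    accepted <- solution$verdicts$reaction_id[
      solution$verdicts$verdict %in% c("evidence-found", "forced-by-user")]
  }
  if (!length(accepted)) return(draft)
  clash <- intersect(accepted, draft$reactions$id)
  if (length(clash)) {
    stop("reaction id collision(s) applying gap fill: ",
         paste(clash, collapse = ", "), call. = FALSE)
  }
  add <- template$reactions[match(accepted, template$reactions$id), , drop = FALSE]
  for (i in seq_len(nrow(add))) {
    rule <- add$gpr[[i]]
    if (!is.null(rule) && !is.null(orthotable)) {
      sub <- substitute_gpr(rule, orthotable, reference_genome, target_genome)
      add$gpr[i] <- list(if (gpr_is_false(sub$rule)) NULL else sub$rule)
      note <- "gap-filled (rule re-substituted)"
    } else {
      note <- "gap-filled (template rule carried over)"
    }
    add$notes[[i]] <- paste0(add$notes[[i]],
                             if (nzchar(add$notes[[i]])) " | " else "", note)
  }
  rx <- rbind(draft$reactions, add)
  used <- unique(unlist(lapply(rx$stoich, names)))
  new_mets <- template$metabolites[
    template$metabolites$id %in% setdiff(used, draft$metabolites$id), ,
    drop = FALSE]
  obj <- draft$objective
  if (is.na(obj) && !is.na(template$objective) && template$objective %in% rx$id) {
    obj <- template$objective
  }
  gem(id = draft$id,
      compartments = union(draft$compartments, template$compartments),
      metabolites = rbind(draft$metabolites, new_mets),
      reactions = rx,
      genes = union(draft$genes, unique(unlist(lapply(add$gpr, gpr_genes)))),
      objective = obj)
}

#' Export a gap-fill report as TSV
#'
#' @param solution a `gapfill_solution`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gapfill_report <- function(solution, path) {
  utils::write.table(solution$verdicts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
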