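#' Predict reaction presence in a target genome
#'
#' Applies the orthology-guided transfer rule to every reaction of a reference
#' model. Reactions without a gene-reaction rule -- spontaneous reactions,
#' lumped macromolecular biosynthesis, and the biomass reaction -- are
#' transferred as such (`no-gpr-transferred`, always present). For
#' GPR-bearing reactions the rule is rewritten with [substitute_gpr()] and
#' evaluated over the target genome's full gene complement: present iff the
#' substituted rule is satisfiable, i.e. did not collapse to logical false.
#' Reactions whose rule references reference genes that occur in no
#' orthogroup at all are flagged (`unmapped-gene-flagged`) so that the
#' manual-curation step the method requires can be applied; they are never
#' silently dropped or added.
#'
#' @param reference a [gem] whose GPR leaves are `reference_genome` gene ids.
#' @param table an [orthogroup_table] containing both genomes.
#' @param target_genome target genome id (a column of `table`).
#' @param reference_genome reference genome id (a column of `table`).
#' @return data frame of presence calls: `reaction_id`, `genome`, `call`
#'   (`"present"`/`"absent"`), `status` (`"gpr-evaluated"`,
#'   `"no-gpr-transferred"`, `"unmapped-gene-flagged"`), `rule` (substituted
#'   rule text), `unmapped` (comma-joined unmapped reference genes),
#'   `and_shared_orthogroup` (curation flag).
#' @export
predict_presence <- function(reference, table, target_genome, reference_genome) {
  stopifnot(inherits(reference, "gem"), inherits(table, "orthogroup_table"))
  if (!target_genome %in% table$genomes) {
    stop("target genome '", target_genome, "' not in orthogroup table",
         call. = FALSE)
  }
  rx <- reference$reactions
  n <- nrow(rx)
  call <- character(n); status <- character(n); rule_txt <- character(n)
  unmapped <- character(n); flag <- logical(n)
  target_genes <- unlist(lapply(table$orthogroups, `[[`, target_genome),
                         use.names = FALSE)
  for (i in seq_len(n)) {
    rule <- rx$gpr[[i]]
    if (is.null(rule)) {
      call[i] <- "present"; status[i] <- "no-gpr-transferred"
      rule_txt[i] <- ""; unmapped[i] <- ""
      next
    }
    sub <- substitute_gpr(rule, table, reference_genome, target_genome)
    unmapped_genes <- sub$report$gene[sub$report$status == "unmapped-no-orthogroup"]
    present <- !gpr_is_false(sub$rule) && eval_gpr(sub$rule, target_genes)
    call[i] <- if (present) "present" else "absent"
    status[i] <- if (length(unmapped_genes)) "unmapped-gene-flagged"
                 else "gpr-evaluated"
    rule_txt[i] <- gpr_to_text(sub$rule)
    unmapped[i] <- paste(unmapped_genes, collapse = ", ")
    flag[i] <- isTRUE(attr(sub$report, "and_shared_orthogroup"))
  }
  data.frame(reaction_id = rx$id, genome = target_genome, call = call,
             status = status, rule = rule_txt, unmapped = unmapped,
             and_shared_orthogroup = flag, stringsAsFactors = FALSE)
}

#' Build a reaction presence/absence matrix across genomes
#'
#' Runs [predict_presence()] for each genome and collects the calls into a
#' reactions x genomes grid -- the pan-reactome view used to compare strains.
#'
#' @param reference a [gem].
#' @param table an [orthogroup_table].
#' @param genomes character vector of target genome ids (e.g. the user's
#'   high-quality genome list).
#' @param reference_genome reference genome id.
#' @return object of class `presence_matrix`: list with `presence` (logical
#'   matrix), `status` (character matrix), `calls` (named list of per-genome
#'   call data frames), `reference_genome`.
#' @export
build_presence_matrix <- function(reference, table, genomes, reference_genome) {
  calls <- lapply(stats::setNames(genomes, genomes), function(g)
    predict_presence(reference, table, g, reference_genome))
  rids <- reference$reactions$id
  presence <- vapply(calls, function(df) df$call[match(rids, df$reaction_id)] == "present",
                     logical(length(rids)))
  status <- vapply(calls, function(df) df$status[match(rids, df$reaction_id)],
                   character(length(rids)))
  presence <- matrix(presence, nrow = length(rids),
                     dimnames = list(rids, genomes))
  status <- matrix(status, nrow = length(rids), dimnames = list(rids, genomes))
  structure(list(presence = presence, status = status, calls = calls,
                 reference_genome = reference_genome),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat("<presence_matrix> ", nrow(x$presence), " reactions x ",
      ncol(x$presence), " genomes\n", sep = "")
  cat("  present calls: ", sum(x$presence), " / ", length(x$presence), "\n",
      sep = "")
  invisible(x)
}

#' Rank reactions by how often they are missing
#'
#' @param object a `presence_matrix`.
#' @param ... unused.
#' @return data frame `reaction_id`, `n_missing`, `missing_genomes`, sorted by
#'   decreasing `n_missing` then reaction id; all-present rows are omitted.
#' @export
summary.presence_matrix <- function(object, ...) {
  miss <- rowSums(!object$presence)
  keep <- miss > 0
  df <- data.frame(
    reaction_id = rownames(object$presence)[keep],
    n_missing = unname(miss[keep]),
    missing_genomes = vapply(which(keep), function(i)
      paste(colnames(object$presence)[!object$presence[i, ]], collapse = ", "),
      character(1L)),
    stringsAsFactors = FALSE)
  df[order(-df$n_missing, df$reaction_id), , drop = FALSE]
}

#' Export a presence matrix as TSV
#'
#' @param matrix a `presence_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_presence_matrix <- function(matrix, path) {
  df <- data.frame(reaction_id = rownames(matrix$presence),
                   matrix$presence, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble a draft model from presence calls
#'
#' Builds the target-genome draft: exactly the present-called reactions, with
#' reference rules replaced by their substituted target-gene rules; the gene
#' set is the set of genes appearing in the new rules; metabolites are pruned
#' to those used, except biomass precursors which are kept even when
#' temporarily orphaned (they are the gap-filling targets). The objective is
#' carried over; if the biomass reaction itself is absent from the draft a
#' warning is raised (gap filling will address it), not an error.
#'
#' Reactions flagged for unmapped reference genes are listed in the
#' `manual_report` attribute -- the side report for manual checking -- and are
#' only added through `allowlist`, mirroring the manual re-addition step of
#' the method (e.g. reactions whose reference gene ids predate the genome
#' annotation version behind the orthogroup table).
#'
#' @param reference a [gem].
#' @param calls data frame from [predict_presence()] covering all reference
#'   reactions.
#' @param target_genome genome id (becomes part of the draft id).
#' @param allowlist optional data frame `reaction_id`, `rule` (rule text in
#'   target-genome gene ids) of flagged reactions to re-add manually.
#' @return a [gem]; attributes `manual_report` (data frame of flagged calls)
#'   and `substituted_rules` (named list of `gpr` objects).
#' @export
build_draft_model <- function(reference, calls, target_genome,
                              allowlist = NULL) {
  stopifnot(inherits(reference, "gem"))
  missing_calls <- setdiff(reference$reactions$id, calls$reaction_id)
  if (length(missing_calls)) {
    stop("presence calls incomplete; missing: ",
         paste(utils::head(missing_calls, 5L), collapse = ", "), call. = FALSE)
  }
  keep <- calls$reaction_id[calls$call == "present"]
  manual <- calls[calls$status == "unmapped-gene-flagged", , drop = FALSE]

  if (!is.null(allowlist) && nrow(allowlist)) {
    bad <- setdiff(allowlist$reaction_id, reference$reactions$id)
    if (length(bad)) {
      stop("allowlist reaction(s) not in reference: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    keep <- union(keep, allowlist$reaction_id)
  }

  rx <- reference$reactions[reference$reactions$id %in% keep, , drop = FALSE]
  rules <- stats::setNames(lapply(calls$rule, parse_gpr), calls$reaction_id)
  for (i in seq_len(nrow(rx))) {
    id <- rx$id[[i]]
    if (!is.null(allowlist) && id %in% allowlist$reaction_id) {
      rx$gpr[i] <- list(parse_gpr(allowlist$rule[match(id, allowlist$reaction_id)]))
      rx$notes[[i]] <- paste0(rx$notes[[i]],
        if (nzchar(rx$notes[[i]])) " | " else "", "manually re-added (allowlist)")
    } else {
      rx$gpr[i] <- list(rules[[id]])
    }
  }

  keep_mets <- character()
  if (!is.na(reference$objective) &&
      reference$objective %in% reference$reactions$id) {
    obj_s <- reference$reactions$stoich[[
      match(reference$objective, reference$reactions$id)]]
    keep_mets <- names(obj_s)
  }
  used <- unique(c(unlist(lapply(rx$stoich, names)), keep_mets))
  mets <- reference$metabolites[reference$metabolites$id %in% used, , drop = FALSE]
  genes <- unique(unlist(lapply(rx$gpr, gpr_genes)))
  obj <- reference$objective
  if (!is.na(obj) && !obj %in% rx$id) {
    warning("objective reaction '", obj, "' absent from draft of '",
            target_genome, "'; gap filling required", call. = FALSE)
    obj <- NA_character_
  }
  draft <- gem(id = paste0(reference$id, "_", target_genome),
               compartments = reference$compartments,
               metabolites = mets, reactions = rx, genes = genes,
               objective = obj)
  attr(draft, "manual_report") <- manual
  attr(draft, "substituted_rules") <- rules[rx$id]
  draft
}
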