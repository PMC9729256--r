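#' @title Synthetic reconstruction scenarios
#' @description
#' Seeded generators for reference models, simulated genome families,
#' orthogroup tables, evidence tables and gap-fill scenarios with recorded
#' ground truth. They let every pipeline stage be exercised end-to-end
#' without external genome or model downloads, and the recorded truth makes
#' recovery exactly checkable.
#' @name synthetic
NULL

# run code under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic reference model
#'
#' Builds a mass-balanced toy metabolism with a guaranteed-feasible biomass
#' route: per carbon source an exchange, a transporter and an entry reaction
#' feed a linear backbone of C6 intermediates; precursor taps drain backbone
#' nodes into biomass precursors; the biomass reaction consumes one unit of
#' each precursor. Extra reactions (isomerizations within the C6 pool,
#' C6 <-> 2x C3 splits/joins, and a C3 byproduct secretion route) pad the
#' network to `n_reactions`. Every non-exchange, non-biomass reaction gets a
#' synthetic EC number and a gene-reaction rule drawn from `gpr_mix`
#' (`no_gpr`, `single`, `or` = two isoenzymes, `and` = two subunits,
#' `nested` = `gA and (gB or gC)`). Feasibility under the default medium
#' (first carbon source open at 10 mmol gCDW^-1 h^-1) is verified by FBA at
#' build time; an infeasible draw triggers a rebuild with an incremented
#' sub-seed.
#'
#' @param n_reactions total reaction count (>= 10).
#' @param gpr_mix named proportions over
#'   `c("no_gpr", "single", "or", "and", "nested")`.
#' @param n_carbon_sources number of carbon-source exchange routes (>= 1).
#' @param n_precursors number of biomass precursors.
#' @param seed integer seed; same seed, same model.
#' @return a [gem] with attributes `truth` (composition counts recorded at
#'   build time) and `default_medium` (a [medium_spec]).
#' @export
make_reference_model <- function(n_reactions = 30L,
                                 gpr_mix = c(no_gpr = 0.15, single = 0.40,
                                             or = 0.20, and = 0.15,
                                             nested = 0.10),
                                 n_carbon_sources = 2L, n_precursors = 3L,
                                 seed = 1L) {
  stopifnot(n_reactions >= 10L, n_carbon_sources >= 1L, n_precursors >= 1L)
  gpr_mix <- gpr_mix / sum(gpr_mix)
  for (attempt in 0:9) {
    model <- with_seed(seed + 1000L * attempt,
                       build_reference_model(n_reactions, gpr_mix,
                                             n_carbon_sources, n_precursors))
    sol <- solve_fba(model, attr(model, "default_medium"))
    if (sol$status == "optimal" && sol$objective > 1e-6) return(model)
  }
  stop("could not draw a feasible reference model in 10 attempts", call. = FALSE)
}

build_reference_model <- function(n_reactions, gpr_mix, n_cs, n_prec) {
  C6 <- "C6H12O6"; C3 <- "C3H6O3"
  mets <- list(); rxns <- list()
  add_met <- function(id, formula, comp, name = id) {
    mets[[length(mets) + 1L]] <<- data.frame(
      id = id, name = name, formula = formula, charge = 0L, compartment = comp,
      stringsAsFactors = FALSE)
  }
  ec_counter <- 0L
  next_ec <- function() {
    ec_counter <<- ec_counter + 1L
    sprintf("9.9.%d.%d", (ec_counter - 1L) %/% 100L + 1L, (ec_counter - 1L) %% 100L + 1L)
  }
  add_rxn <- function(id, stoich, lb, ub, name = id, ec = character(),
                      exchange = FALSE) {
    rxns[[length(rxns) + 1L]] <<- list(id = id, name = name, lower_bound = lb,
                                       upper_bound = ub, stoich = stoich,
                                       ec = ec, is_exchange = exchange)
  }

  # fixed backbone: exchanges, transporters, entries, chain, taps, biomass
  n_backbone_extra <- 2L * n_cs + n_cs + n_prec + 1L + 3L  # non-chain reactions
  n_chain <- max(3L, n_reactions - n_backbone_extra - max(2L, n_reactions %/% 5L))
  for (i in seq_len(n_cs)) {
    cs_e <- sprintf("cs%d_e", i); cs_c <- sprintf("cs%d_c", i)
    add_met(cs_e, C6, "e", sprintf("carbon source %d (extracellular)", i))
    add_met(cs_c, C6, "c", sprintf("carbon source %d (cytosolic)", i))
    add_rxn(sprintf("EX_cs%d", i), stats::setNames(-1, cs_e), -1000, 1000,
            sprintf("carbon source %d exchange", i), exchange = TRUE)
    add_rxn(sprintf("T_cs%d", i), stats::setNames(c(-1, 1), c(cs_e, cs_c)),
            0, 1000, sprintf("carbon source %d transporter", i), ec = next_ec())
  }
  for (k in seq_len(n_chain)) add_met(sprintf("N%02d", k), C6, "c")
  for (i in seq_len(n_cs)) {
    add_rxn(sprintf("ENTRY_cs%d", i),
            stats::setNames(c(-1, 1), c(sprintf("cs%d_c", i), "N01")),
            0, 1000, sprintf("carbon source %d assimilation", i), ec = next_ec())
  }
  for (k in seq_len(n_chain - 1L)) {
    add_rxn(sprintf("CHAIN%02d", k),
            stats::setNames(c(-1, 1), sprintf("N%02d", c(k, k + 1L))),
            0, 1000, sprintf("backbone step %d", k), ec = next_ec())
  }
  # precursor taps off evenly spaced backbone nodes
  tap_nodes <- unique(pmax(1L, round(seq(1L, n_chain, length.out = n_prec))))
  while (length(tap_nodes) < n_prec) tap_nodes <- c(tap_nodes, n_chain)
  for (p in seq_len(n_prec)) {
    add_met(sprintf("P%d", p), C6, "c", sprintf("biomass precursor %d", p))
    add_rxn(sprintf("PREC%d", p),
            stats::setNames(c(-1, 1), c(sprintf("N%02d", tap_nodes[[p]]),
                                        sprintf("P%d", p))),
            0, 1000, sprintf("precursor %d synthesis", p), ec = next_ec())
  }
  add_rxn("BIOMASS", stats::setNames(rep(-1, n_prec), sprintf("P%d", seq_len(n_prec))),
          0, 1000, "biomass assembly")
  # byproduct secretion route through the C3 pool
  add_met("B1", C3, "c", "byproduct (cytosolic)")
  add_met("B1_e", C3, "e", "byproduct (extracellular)")
  add_rxn("SPLIT_B", stats::setNames(c(-1, 2), c("N01", "B1")), 0, 1000,
          "hexose cleavage", ec = next_ec())
  add_rxn("T_B1", stats::setNames(c(-1, 1), c("B1", "B1_e")), 0, 1000,
          "byproduct export", ec = next_ec())
  add_rxn("EX_B1", stats::setNames(-1, "B1_e"), 0, 1000,
          "byproduct exchange", exchange = TRUE)

  # random extras: isomerizations and C6 <-> 2 C3 conversions
  extra_id <- 0L
  while (length(rxns) < n_reactions) {
    extra_id <- extra_id + 1L
    kind <- sample(c("iso", "split"), 1L, prob = c(0.7, 0.3))
    if (kind == "iso" && n_chain >= 2L) {
      ab <- sample(n_chain, 2L)
      rev <- stats::runif(1) < 0.5
      add_rxn(sprintf("XTRA%02d", extra_id),
              stats::setNames(c(-1, 1), sprintf("N%02d", ab)),
              if (rev) -1000 else 0, 1000,
              sprintf("isomerization %d", extra_id), ec = next_ec())
    } else {
      a <- sample(n_chain, 1L)
      add_rxn(sprintf("XTRA%02d", extra_id),
              stats::setNames(c(-1, 2), c(sprintf("N%02d", a), "B1")),
              0, 1000, sprintf("cleavage %d", extra_id), ec = next_ec())
    }
  }

  # assemble reaction frame, then draw rules
  rx <- data.frame(
    id = vapply(rxns, `[[`, character(1L), "id"),
    name = vapply(rxns, `[[`, character(1L), "name"),
    lower_bound = vapply(rxns, `[[`, numeric(1L), "lower_bound"),
    upper_bound = vapply(rxns, `[[`, numeric(1L), "upper_bound"),
    notes = "", stringsAsFactors = FALSE)
  rx$stoich <- lapply(rxns, `[[`, "stoich")
  rx$ec <- lapply(rxns, `[[`, "ec")
  rx$is_exchange <- vapply(rxns, `[[`, logical(1L), "is_exchange")

  gene_counter <- 0L
  new_gene <- function() {
    gene_counter <<- gene_counter + 1L
    sprintf("g%04d", gene_counter)
  }
  rx$gpr <- vector("list", nrow(rx))
  kinds <- names(gpr_mix)
  for (i in seq_len(nrow(rx))) {
    if (rx$is_exchange[[i]] || rx$id[[i]] == "BIOMASS") next
    kind <- sample(kinds, 1L, prob = gpr_mix)
    rx$gpr[i] <- list(switch(kind,
      no_gpr = NULL,
      single = gpr_gene(new_gene()),
      or = gpr_node("or", list(gpr_gene(new_gene()), gpr_gene(new_gene()))),
      and = gpr_node("and", list(gpr_gene(new_gene()), gpr_gene(new_gene()))),
      nested = gpr_node("and", list(
        gpr_gene(new_gene()),
        gpr_node("or", list(gpr_gene(new_gene()), gpr_gene(new_gene())))))))
  }

  met_df <- do.call(rbind, mets)
  model <- gem(id = sprintf("synthetic_ref_%d", n_reactions),
               compartments = c("c", "e"), metabolites = met_df,
               reactions = rx, objective = "BIOMASS")
  medium <- medium_spec(uptake = stats::setNames(10, "EX_cs1"))
  attr(model, "default_medium") <- medium
  attr(model, "truth") <- list(
    n_reactions = nrow(rx),
    n_metabolites = nrow(met_df),
    n_exchange = sum(rx$is_exchange),
    n_orphan = sum(!rx$is_exchange & vapply(rx$gpr, is.null, logical(1L))),
    n_genes = gene_counter)
  model
}

#' Simulate a genome family from a reference model
#'
#' Derives `n_genomes` target genomes from the reference gene set by
#' independent gene loss (probability `gene_loss_rate` per gene per genome)
#' and co-ortholog duplication (probability `duplication_rate` per retained
#' gene). The induced orthogroup table has one orthogroup per reference gene
#' holding its surviving target copies (no fusion events). The recorded
#' ground-truth reactome of each genome evaluates the *original* reference
#' rules under that genome's retained reference genes -- the quantity the
#' transfer pipeline is supposed to recover. Evidence tables list every
#' retained target gene with the EC numbers of the reactions its reference
#' ortholog participates in.
#'
#' @param reference a [make_reference_model()] result (any [gem] with EC
#'   annotations works).
#' @param n_genomes number of target genomes.
#' @param gene_loss_rate,duplication_rate per-gene probabilities in `[0, 1)`.
#' @param seed integer seed.
#' @param reference_genome genome id used for the reference column.
#' @return object of class `gem_scenario`: `reference`, `genomes` (named
#'   list of target gene id vectors), `retained` (named list of retained
#'   reference gene vectors), `orthotable`, `truth_reactomes`, `evidence`,
#'   `seed`, `params`.
#' @export
simulate_genome_family <- function(reference, n_genomes = 20L,
                                   gene_loss_rate = 0.1,
                                   duplication_rate = 0.05, seed = 1L,
                                   reference_genome = "REF") {
  stopifnot(inherits(reference, "gem"),
            gene_loss_rate >= 0, gene_loss_rate < 1,
            duplication_rate >= 0, duplication_rate < 1)
  with_seed(seed, {
    genome_ids <- sprintf("G%02d", seq_len(n_genomes))
    ref_genes <- reference$genes
    retained <- list(); genomes <- list()
    for (g in genome_ids) {
      keep <- ref_genes[stats::runif(length(ref_genes)) >= gene_loss_rate]
      copies <- lapply(keep, function(gene) {
        ids <- paste0(g, "_", gene)
        if (stats::runif(1) < duplication_rate) {
          ids <- c(ids, paste0(g, "_", gene, "_d2"))
        }
        ids
      })
      retained[[g]] <- keep
      genomes[[g]] <- unlist(copies)
    }
    ogs <- list()
    for (k in seq_along(ref_genes)) {
      gene <- ref_genes[[k]]
      row <- stats::setNames(vector("list", n_genomes + 1L),
                             c(reference_genome, genome_ids))
      row[[reference_genome]] <- gene
      for (g in genome_ids) {
        row[[g]] <- grep(paste0("^", g, "_", gene, "(_d2)?$"),
                         genomes[[g]], value = TRUE)
      }
      ogs[[sprintf("OG%04d", k)]] <- row
    }
    orthotable <- orthogroup_table(ogs, c(reference_genome, genome_ids))

    rx <- reference$reactions
    truth <- lapply(retained, function(keep) {
      has <- vapply(seq_len(nrow(rx)), function(i) {
        rule <- rx$gpr[[i]]
        is.null(rule) || eval_gpr(rule, keep)
      }, logical(1L))
      rx$id[has]
    })

    # evidence: each retained target gene annotated with the ECs of the
    # reactions its reference ortholog supports
    gene2ec <- list()
    gene2name <- list()
    for (i in seq_len(nrow(rx))) {
      for (gene in gpr_genes(rx$gpr[[i]])) {
        gene2ec[[gene]] <- unique(c(gene2ec[[gene]], rx$ec[[i]]))
        gene2name[[gene]] <- unique(c(gene2name[[gene]], rx$name[[i]]))
      }
    }
    ev_rows <- list()
    for (g in genome_ids) {
      for (gene in retained[[g]]) {
        for (tid in grep(paste0("^", g, "_", gene, "(_d2)?$"),
                         genomes[[g]], value = TRUE)) {
          ev_rows[[length(ev_rows) + 1L]] <- data.frame(
            genome = g, gene = tid,
            ec = paste(gene2ec[[gene]], collapse = ";"),
            annotation = paste(gene2name[[gene]], collapse = "; "),
            source = "synthetic-annotation", stringsAsFactors = FALSE)
        }
      }
    }
    evidence <- evidence_table(do.call(rbind, ev_rows))

    structure(list(reference = reference, reference_genome = reference_genome,
                   genomes = genomes, retained = retained,
                   orthotable = orthotable, truth_reactomes = truth,
                   evidence = evidence, removed_for_gapfill = list(),
                   seed = seed,
                   params = list(n_genomes = n_genomes,
                                 gene_loss_rate = gene_loss_rate,
                                 duplication_rate = duplication_rate)),
              class = "gem_scenario")
  })
}

#' @export
print.gem_scenario <- function(x, ...) {
  cat("<gem_scenario> seed ", x$seed, "\n", sep = "")
  cat("  reference: ", x$reference$id, " (", nrow(x$reference$reactions),
      " reactions, ", length(x$reference$genes), " genes)\n", sep = "")
  cat("  genomes:   ", length(x$genomes), " (loss rate ",
      x$params$gene_loss_rate, ", duplication rate ",
      x$params$duplication_rate, ")\n", sep = "")
  if (!is.null(x$gapfill)) {
    cat("  gap-fill scenario on ", x$gapfill$genome, ": ",
        length(x$gapfill$expected_added), " removed, ",
        length(x$gapfill$expected_no_evidence), " without evidence\n", sep = "")
  }
  invisible(x)
}

#' Derive a gap-fill scenario from a genome family
#'
#' Takes one genome of a family whose transferred draft grows on the default
#' medium, removes `n_removed_essential` essential reactions (essentiality
#' verified by blocking each candidate in an FBA run), pads the template with
#' `n_decoys` decoy reactions that cannot contribute to growth, and strips
#' the annotation evidence for `n_no_evidence` of the removed reactions. The
#' expected gap-fill answer is recorded: because each removed reaction is
#' essential, the removed set is the unique minimum-cardinality fill, and the
#' curation verdicts are known exactly.
#'
#' @param scenario a `gem_scenario` from [simulate_genome_family()].
#' @param genome genome id within the scenario.
#' @param n_removed_essential number of essential reactions to remove.
#' @param n_decoys number of decoy template reactions to add.
#' @param n_no_evidence how many removed reactions lose their evidence.
#' @param seed integer seed.
#' @return the scenario with a `gapfill` element: `genome`, `draft` (gapped),
#'   `template`, `medium`, `evidence` (stripped), `expected_added`,
#'   `expected_no_evidence`.
#' @export
make_gapfill_scenario <- function(scenario, genome, n_removed_essential = 2L,
                                  n_decoys = 5L, n_no_evidence = 0L,
                                  seed = 1L) {
  stopifnot(inherits(scenario, "gem_scenario"),
            genome %in% names(scenario$genomes),
            n_no_evidence <= n_removed_essential)
  reference <- scenario$reference
  medium <- attr(reference, "default_medium")
  calls <- predict_presence(reference, scenario$orthotable, genome,
                            scenario$reference_genome)
  draft <- build_draft_model(reference, calls, genome)
  if (!growth_test(draft, medium)) {
    stop("draft for genome '", genome, "' does not grow; pick another genome ",
         "or lower the loss rate", call. = FALSE)
  }
  with_seed(seed, {
    # essentiality judged in the draft merged with every template reaction:
    # a reaction essential there stays required in every candidate fill, so
    # the removed set is the unique minimum-cardinality answer
    full <- merge_reactions(draft, reference,
                            setdiff(reference$reactions$id,
                                    draft$reactions$id))
    # only GPR-bearing, EC-annotated reactions are removed: curation
    # evidence is gene-based, so orphan reactions could never be re-accepted
    candidates <- draft$reactions$id[
      !draft$reactions$is_exchange & draft$reactions$id != draft$objective &
      !vapply(draft$reactions$gpr, is.null, logical(1L)) &
      lengths(draft$reactions$ec) > 0L]
    essential <- candidates[vapply(candidates, function(id) {
      !growth_test(full, medium, block = id)
    }, logical(1L))]
    if (length(essential) < n_removed_essential) {
      stop("only ", length(essential), " essential reactions available",
           call. = FALSE)
    }
    removed <- sort(sample(essential, n_removed_essential))
    gapped <- gem_subset(draft, setdiff(draft$reactions$id, removed),
                         keep_mets = biomass_precursors(draft), id = draft$id)

    template <- reference
    if (n_decoys > 0L) {
      dm <- do.call(rbind, lapply(seq_len(n_decoys), function(i) {
        data.frame(id = sprintf("decoyM%d_%s", c(2L * i - 1L, 2L * i), genome),
                   name = "decoy metabolite", formula = "C6H12O6",
                   charge = 0L, compartment = "c", stringsAsFactors = FALSE)
      }))
      dr <- data.frame(
        id = sprintf("DECOY%02d", seq_len(n_decoys)),
        name = sprintf("decoy reaction %d", seq_len(n_decoys)),
        lower_bound = 0, upper_bound = 1000, notes = "decoy",
        stringsAsFactors = FALSE)
      dr$stoich <- lapply(seq_len(n_decoys), function(i)
        stats::setNames(c(-1, 1), sprintf("decoyM%d_%s",
                                          c(2L * i - 1L, 2L * i), genome)))
      dr$gpr <- replicate(n_decoys, NULL)
      dr$ec <- replicate(n_decoys, character(), simplify = FALSE)
      dr$is_exchange <- FALSE
      template <- gem(id = paste0(reference$id, "_template"),
                      compartments = reference$compartments,
                      metabolites = rbind(reference$metabolites, dm),
                      reactions = rbind(reference$reactions, dr),
                      genes = reference$genes, objective = reference$objective)
      attr(template, "default_medium") <- medium
    }

    no_evidence <- sort(sample(removed, n_no_evidence))
    strip_ecs <- unique(unlist(
      reference$reactions$ec[match(no_evidence, reference$reactions$id)]))
    ev <- scenario$evidence
    if (length(strip_ecs)) {
      keep_row <- !(ev$genome == genome &
        vapply(ev$ec_list, function(e) any(e %in% strip_ecs), logical(1L)))
      ev <- evidence_table(as.data.frame(ev)[keep_row,
        c("genome", "gene", "ec", "annotation", "source"), drop = FALSE])
    }
    scenario$removed_for_gapfill[[genome]] <- removed
    scenario$gapfill <- list(genome = genome, draft = gapped,
                             template = template, medium = medium,
                             evidence = ev, expected_added = removed,
                             expected_no_evidence = no_evidence)
    scenario
  })
}

#' Write a scenario bundle to a directory
#'
#' Serializes a scenario as plain text: reference model (JSON and SBML),
#' `Orthogroups.tsv`, evidence TSV, per-genome truth reactome TSV, and a JSON
#' manifest with the seed and parameters. Identical seeds reproduce
#' byte-identical bundles.
#'
#' @param scenario a `gem_scenario`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gem(scenario$reference, file.path(dir, "reference.json"))
  write_gem(scenario$reference, file.path(dir, "reference.xml"))
  write_orthogroups(scenario$orthotable, file.path(dir, "Orthogroups.tsv"))
  ev <- as.data.frame(scenario$evidence)
  utils::write.table(ev[, c("genome", "gene", "ec", "annotation", "source")],
                     file.path(dir, "evidence.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- do.call(rbind, lapply(names(scenario$truth_reactomes), function(g)
    data.frame(genome = g, reaction_id = scenario$truth_reactomes[[g]],
               stringsAsFactors = FALSE)))
  utils::write.table(truth, file.path(dir, "truth_reactomes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(seed = scenario$seed, params = scenario$params,
                            reference = scenario$reference$id,
                            genomes = names(scenario$genomes)),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(dir)
}
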