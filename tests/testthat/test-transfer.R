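test_that("a single-gene knockout removes exactly that reaction", {
  ref <- make_reference_model(n_reactions = 20,
                              gpr_mix = c(no_gpr = 0, single = 1, or = 0,
                                          and = 0, nested = 0), seed = 2)
  # target genome = reference minus the genes of one single-gene reaction
  victim <- ref$reactions$id[!ref$reactions$is_exchange &
                             ref$reactions$id != "BIOMASS"][1]
  lost <- gpr_genes(ref$reactions$gpr[[match(victim, ref$reactions$id)]])
  target_map <- lapply(stats::setNames(ref$genes, ref$genes),
                       function(g) paste0("t_", g))
  target_map[lost] <- NULL
  tab <- simple_orthotable(ref$genes, target_map)
  calls <- predict_presence(ref, tab, "TGT", "REF")
  absent <- calls$reaction_id[calls$call == "absent"]
  expect_equal(absent, victim)
})

test_that("reactions without rules transfer to every genome", {
  ref <- make_reference_model(n_reactions = 20, seed = 2)
  tab <- simple_orthotable(ref$genes, list())  # target retains nothing
  calls <- predict_presence(ref, tab, "TGT", "REF")
  no_gpr <- calls$status == "no-gpr-transferred"
  expect_true(all(calls$call[no_gpr] == "present"))
  expect_true("BIOMASS" %in% calls$reaction_id[no_gpr])
  # and with genes all lost, every GPR-bearing reaction is absent
  expect_true(all(calls$call[!no_gpr] == "absent"))
})

test_that("self-transfer reproduces the reference reaction set exactly", {
  ref <- make_reference_model(n_reactions = 30, seed = 4)
  # identity orthotable: reference genome on both sides
  ogs <- lapply(stats::setNames(ref$genes, paste0("OG_", ref$genes)),
                function(g) list(REF = g, SELF = g))
  tab <- orthogroup_table(ogs, c("REF", "SELF"))
  calls <- predict_presence(ref, tab, "SELF", "REF")
  expect_true(all(calls$call == "present"))
  draft <- build_draft_model(ref, calls, "SELF")
  expect_setequal(draft$reactions$id, ref$reactions$id)
})

test_that("transfer is monotone: extra target genes never remove reactions", {
  ref <- make_reference_model(n_reactions = 25, seed = 6)
  set.seed(31)
  keep_small <- sample(ref$genes, round(0.6 * length(ref$genes)))
  keep_big <- union(keep_small, sample(ref$genes, 10))
  tab_for <- function(keep) {
    simple_orthotable(ref$genes,
      lapply(stats::setNames(keep, keep), function(g) paste0("t_", g)))
  }
  p_small <- predict_presence(ref, tab_for(keep_small), "TGT", "REF")
  p_big <- predict_presence(ref, tab_for(keep_big), "TGT", "REF")
  small_present <- p_small$reaction_id[p_small$call == "present"]
  big_present <- p_big$reaction_id[p_big$call == "present"]
  expect_true(all(small_present %in% big_present))
})

test_that("presence matrix is complete and its missing ranking matches a recount", {
  ref <- make_reference_model(n_reactions = 25, seed = 9)
  sc <- simulate_genome_family(ref, n_genomes = 6, gene_loss_rate = 0.12,
                               seed = 13)
  mat <- build_presence_matrix(ref, sc$orthotable, names(sc$genomes), "REF")
  expect_equal(dim(mat$presence), c(25L, 6L))
  expect_false(anyNA(mat$presence))

  # identical genomes give identical columns
  g1 <- names(sc$genomes)[1]
  mat2 <- build_presence_matrix(ref, sc$orthotable, c(g1, g1), "REF")
  expect_identical(mat2$presence[, 1], mat2$presence[, 2])

  # hand recount of the most-frequently-missing ranking
  rank <- summary(mat)
  for (i in seq_len(nrow(rank))) {
    expect_equal(rank$n_missing[i],
                 sum(!mat$presence[rank$reaction_id[i], ]))
  }
  expect_true(all(diff(rank$n_missing) <= 0))

  # a core-orthogroup-only reaction is present everywhere
  core <- core_orthogroups(sc$orthotable)
  core_genes <- vapply(core, function(og)
    sc$orthotable$orthogroups[[og]]$REF[1], character(1))
  for (i in seq_len(nrow(ref$reactions))) {
    genes <- gpr_genes(ref$reactions$gpr[[i]])
    if (length(genes) && all(genes %in% core_genes)) {
      expect_true(all(mat$presence[ref$reactions$id[i], ]))
    }
  }
})

test_that("draft models honour calls, prune metabolites and keep precursors", {
  ref <- make_reference_model(n_reactions = 25, seed = 10)
  sc <- simulate_genome_family(ref, n_genomes = 4, gene_loss_rate = 0.15,
                               seed = 17)
  for (g in names(sc$genomes)) {
    calls <- predict_presence(ref, sc$orthotable, g, "REF")
    draft <- build_draft_model(ref, calls, g)
    # draft is a subset of the reference
    expect_true(all(draft$reactions$id %in% ref$reactions$id))
    # every draft rule evaluates true on the target genes, or is absent
    for (i in seq_len(nrow(draft$reactions))) {
      rule <- draft$reactions$gpr[[i]]
      if (!is.null(rule)) expect_true(eval_gpr(rule, sc$genomes[[g]]))
    }
    # biomass precursors retained even if orphaned
    prec <- names(ref$reactions$stoich[[match("BIOMASS", ref$reactions$id)]])
    expect_true(all(prec %in% draft$metabolites$id))
    # ground-truth reactome recovered for unflagged reactions
    unflagged <- calls$reaction_id[calls$status != "unmapped-gene-flagged"]
    expect_setequal(intersect(draft$reactions$id, unflagged),
                    intersect(sc$truth_reactomes[[g]], unflagged))
  }
})

test_that("flagged reactions are reported and re-added only via the allowlist", {
  ref <- make_reference_model(n_reactions = 20,
                              gpr_mix = c(no_gpr = 0, single = 1, or = 0,
                                          and = 0, nested = 0), seed = 12)
  # drop one gene from the orthotable entirely: unmapped, not just absent
  victim <- ref$reactions$id[!ref$reactions$is_exchange &
                             ref$reactions$id != "BIOMASS"][2]
  ghost <- gpr_genes(ref$reactions$gpr[[match(victim, ref$reactions$id)]])
  mapped <- setdiff(ref$genes, ghost)
  tab <- simple_orthotable(mapped,
    lapply(stats::setNames(mapped, mapped), function(g) paste0("t_", g)))
  calls <- predict_presence(ref, tab, "TGT", "REF")
  expect_equal(calls$status[calls$reaction_id == victim],
               "unmapped-gene-flagged")
  expect_equal(calls$unmapped[calls$reaction_id == victim], ghost)

  draft <- build_draft_model(ref, calls, "TGT")
  expect_false(victim %in% draft$reactions$id)
  expect_true(victim %in% attr(draft, "manual_report")$reaction_id)

  allow <- data.frame(reaction_id = victim, rule = "t_manual",
                      stringsAsFactors = FALSE)
  draft2 <- build_draft_model(ref, calls, "TGT", allowlist = allow)
  expect_true(victim %in% draft2$reactions$id)
  expect_equal(gpr_to_text(draft2$reactions$gpr[[
    match(victim, draft2$reactions$id)]]), "t_manual")
  expect_true("t_manual" %in% draft2$genes)
})
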