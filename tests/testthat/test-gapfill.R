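gap_scenario <- function(seed = 19, n_removed = 2, n_decoys = 5,
                         n_no_evidence = 0, loss = 0.05) {
  ref <- make_reference_model(n_reactions = 22, seed = seed)
  sc <- simulate_genome_family(ref, n_genomes = 6, gene_loss_rate = loss,
                               seed = seed + 1)
  med <- attr(ref, "default_medium")
  for (g in names(sc$genomes)) {
    calls <- predict_presence(ref, sc$orthotable, g, "REF")
    d <- tryCatch(suppressWarnings(build_draft_model(ref, calls, g)),
                  error = function(e) NULL)
    if (!is.null(d) && !is.na(d$objective) && growth_test(d, med)) {
      return(make_gapfill_scenario(sc, g, n_removed_essential = n_removed,
                                   n_decoys = n_decoys,
                                   n_no_evidence = n_no_evidence,
                                   seed = seed + 2))
    }
  }
  stop("no growing draft in family")
}

test_that("a single missing essential reaction is recovered exactly", {
  sc <- gap_scenario(seed = 19, n_removed = 1)
  gf <- sc$gapfill
  sol <- gap_fill(gf$draft, gf$template, gf$medium)
  expect_equal(sol$added_reactions, gf$expected_added)
  expect_true(sol$minimal)
  expect_gt(sol$achieved_growth, 1e-6)
})

test_that("certified-minimal sets match the exhaustive subset oracle", {
  for (cfg in list(c(seed = 19, k = 2), c(seed = 33, k = 2),
                   c(seed = 47, k = 3))) {
    sc <- gap_scenario(seed = cfg[["seed"]], n_removed = cfg[["k"]],
                       n_decoys = 6)
    gf <- sc$gapfill
    sol <- gap_fill(gf$draft, gf$template, gf$medium)
    oracle <- gapfill_oracle(gf$draft, gf$template, gf$medium)
    expect_true(sol$minimal)
    expect_equal(sol$added_reactions, oracle)
    expect_equal(length(sol$added_reactions), cfg[["k"]])
    # decoys never enter the solution
    expect_false(any(grepl("^DECOY", sol$added_reactions)))
  }
})

test_that("gap filling is deterministic for identical inputs", {
  sc <- gap_scenario(seed = 61, n_removed = 2)
  gf <- sc$gapfill
  s1 <- gap_fill(gf$draft, gf$template, gf$medium)
  s2 <- gap_fill(gf$draft, gf$template, gf$medium)
  expect_identical(s1$added_reactions, s2$added_reactions)
})

test_that("an unfillable draft is reported with blocked precursors", {
  ref <- make_reference_model(n_reactions = 20, seed = 71)
  med <- attr(ref, "default_medium")
  # remove the biomass-precursor taps from both draft and template
  taps <- grep("^PREC", ref$reactions$id, value = TRUE)
  draft <- orthogem:::gem_subset(ref, setdiff(ref$reactions$id, taps),
                                 keep_mets = orthogem:::biomass_precursors(ref))
  template <- orthogem:::gem_subset(ref, setdiff(ref$reactions$id, taps[1]),
                                    keep_mets = orthogem:::biomass_precursors(ref))
  sol <- gap_fill(draft, template, med)
  expect_true(sol$unfillable)
  expect_true(length(sol$blocked_precursors) >= 1)
})

test_that("curation excludes exactly the planted no-evidence reactions", {
  sc <- gap_scenario(seed = 83, n_removed = 3, n_no_evidence = 2)
  gf <- sc$gapfill
  sol <- gap_fill(gf$draft, gf$template, gf$medium)
  expect_equal(sol$added_reactions, gf$expected_added)
  cur <- curate_gapfill(sol, gf$evidence, gf$template, gf$genome)
  no_ev <- cur$verdicts$reaction_id[cur$verdicts$verdict == "no-evidence"]
  expect_setequal(no_ev, gf$expected_no_evidence)
  found <- cur$verdicts$reaction_id[cur$verdicts$verdict == "evidence-found"]
  expect_setequal(found, setdiff(gf$expected_added, gf$expected_no_evidence))
  expect_true(all(nzchar(cur$verdicts$matched_genes[
    cur$verdicts$verdict == "evidence-found"])))

  # user overrides
  cur2 <- curate_gapfill(sol, gf$evidence, gf$template, gf$genome,
                         force_include = gf$expected_no_evidence)
  expect_true(all(cur2$verdicts$verdict[
    cur2$verdicts$reaction_id %in% gf$expected_no_evidence] == "forced-by-user"))
})

test_that("applying an accepted fill restores growth and reduces dead ends", {
  sc <- gap_scenario(seed = 97, n_removed = 2, n_no_evidence = 0)
  gf <- sc$gapfill
  sol <- gap_fill(gf$draft, gf$template, gf$medium)
  cur <- curate_gapfill(sol, gf$evidence, gf$template, gf$genome)
  filled <- apply_gapfill(gf$draft, cur, gf$template, sc$orthotable,
                          "REF", gf$genome)
  expect_true(growth_test(filled, gf$medium))
  expect_lt(length(find_dead_end_metabolites(filled)),
            length(find_dead_end_metabolites(gf$draft)))
  # monotone composition: reactions/genes/metabolites never shrink
  s0 <- summary(gf$draft); s1 <- summary(filled)
  expect_gte(s1$reactions, s0$reactions)
  expect_gte(s1$metabolites, s0$metabolites)
  expect_gte(s1$genes, s0$genes)

  # empty accepted set leaves the draft unchanged
  none <- sol
  none$verdicts$verdict <- "no-evidence"
  attr(none, "accepted") <- character()
  expect_identical(apply_gapfill(gf$draft, none, gf$template)$reactions$id,
                   gf$draft$reactions$id)

  # id collisions are errors
  clash <- sol
  attr(clash, "accepted") <- gf$draft$reactions$id[1]
  expect_error(apply_gapfill(gf$draft, clash, orthogem:::merge_reactions(
    gf$draft, gf$template, character())), "collision")
})
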