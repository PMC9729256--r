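test_that("the reference generator is seeded, feasible and mass balanced", {
  m1 <- make_reference_model(n_reactions = 26, seed = 14)
  m2 <- make_reference_model(n_reactions = 26, seed = 14)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_gem(m1, p1); write_gem(m2, p2)
  expect_identical(readLines(p1), readLines(p2))  # byte-identical serialization

  expect_true(growth_test(m1, attr(m1, "default_medium")))
  expect_equal(nrow(m1$reactions), 26)
  expect_equal(nrow(check_mass_balance(m1)), 0)

  truth <- attr(m1, "truth")
  s <- summary(m1)
  expect_equal(s$reactions, truth$n_reactions)
  expect_equal(s$metabolites, truth$n_metabolites)
  expect_equal(s$exchange_reactions, truth$n_exchange)
  expect_equal(s$orphan_reactions, truth$n_orphan)  # biomass counts as orphan
  expect_equal(s$genes, truth$n_genes)
})

test_that("an all-single-gene draw and an all-orphan draw behave as declared", {
  m <- make_reference_model(n_reactions = 20,
                            gpr_mix = c(no_gpr = 0, single = 1, or = 0,
                                        and = 0, nested = 0), seed = 15)
  non_ex <- !m$reactions$is_exchange & m$reactions$id != "BIOMASS"
  expect_true(all(vapply(m$reactions$gpr[non_ex],
                         function(r) !is.null(r) && r$op == "gene",
                         logical(1))))
  expect_true(growth_test(m, attr(m, "default_medium")))

  m0 <- make_reference_model(n_reactions = 20,
                             gpr_mix = c(no_gpr = 1, single = 0, or = 0,
                                         and = 0, nested = 0), seed = 15)
  tab <- simple_orthotable("ghost", list())   # no genes anywhere
  calls <- predict_presence(m0, tab, "TGT", "REF")
  expect_true(all(calls$call == "present"))   # orphan rules transfer as such
})

test_that("a loss-free family is identical to the reference everywhere", {
  ref <- make_reference_model(n_reactions = 22, seed = 16)
  sc <- simulate_genome_family(ref, n_genomes = 5, gene_loss_rate = 0,
                               duplication_rate = 0, seed = 17)
  mat <- build_presence_matrix(ref, sc$orthotable, names(sc$genomes), "REF")
  expect_true(all(mat$presence))
  for (g in names(sc$genomes)) {
    expect_setequal(sc$truth_reactomes[[g]], ref$reactions$id)
  }
})

test_that("duplication-only families gain OR branches without changing calls", {
  ref <- make_reference_model(n_reactions = 22, seed = 18)
  sc <- simulate_genome_family(ref, n_genomes = 5, gene_loss_rate = 0,
                               duplication_rate = 0.5, seed = 19)
  mat <- build_presence_matrix(ref, sc$orthotable, names(sc$genomes), "REF")
  expect_true(all(mat$presence))
  # at least one substituted rule carries a duplicated co-ortholog branch
  some_dup <- any(vapply(names(sc$genomes), function(g)
    any(grepl("_d2", mat$calls[[g]]$rule)), logical(1)))
  expect_true(some_dup)
})

test_that("transfer recovers the recorded truth reactome of every genome", {
  ref <- make_reference_model(n_reactions = 30, seed = 20)
  sc <- simulate_genome_family(ref, n_genomes = 20, gene_loss_rate = 0.1,
                               seed = 21)
  mat <- build_presence_matrix(ref, sc$orthotable, names(sc$genomes), "REF")
  for (g in names(sc$genomes)) {
    calls <- mat$calls[[g]]
    unflagged <- calls$status != "unmapped-gene-flagged"
    expect_setequal(
      calls$reaction_id[unflagged & calls$call == "present"],
      intersect(sc$truth_reactomes[[g]], calls$reaction_id[unflagged]))
  }
})

test_that("scenario bundles serialize deterministically and re-read exactly", {
  ref <- make_reference_model(n_reactions = 20, seed = 22)
  sc <- simulate_genome_family(ref, n_genomes = 4, gene_loss_rate = 0.1,
                               seed = 23)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_scenario(sc, d1)
  write_scenario(simulate_genome_family(ref, n_genomes = 4,
                                        gene_loss_rate = 0.1, seed = 23), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  tab <- read_orthogroups(file.path(d1, "Orthogroups.tsv"))
  expect_equal(tab$orthogroups, sc$orthotable$orthogroups)
  ref2 <- read_gem(file.path(d1, "reference.json"))
  expect_equal(ref2$reactions$stoich, ref$reactions$stoich)
})

test_that("gap-fill scenarios record a verifiable expected answer", {
  ref <- make_reference_model(n_reactions = 22, seed = 24)
  sc <- simulate_genome_family(ref, n_genomes = 6, gene_loss_rate = 0.05,
                               seed = 25)
  med <- attr(ref, "default_medium")
  g <- NULL
  for (cand in names(sc$genomes)) {
    calls <- predict_presence(ref, sc$orthotable, cand, "REF")
    d <- tryCatch(suppressWarnings(build_draft_model(ref, calls, cand)),
                  error = function(e) NULL)
    if (!is.null(d) && !is.na(d$objective) && growth_test(d, med)) {
      g <- cand; break
    }
  }
  sc2 <- make_gapfill_scenario(sc, g, n_removed_essential = 2, n_decoys = 4,
                               n_no_evidence = 1, seed = 26)
  gf <- sc2$gapfill
  # the gapped draft no longer grows; adding the recorded set restores growth
  expect_false(growth_test(gf$draft, gf$medium))
  merged <- orthogem:::merge_reactions(gf$draft, gf$template, gf$expected_added)
  expect_true(growth_test(merged, gf$medium))
  # stripped evidence really is gone
  for (rid in gf$expected_no_evidence) {
    ecs <- unlist(ref$reactions$ec[match(rid, ref$reactions$id)])
    for (e in ecs) {
      expect_length(evidence_genes_for_ec(gf$evidence, g, e), 0)
    }
  }
  expect_identical(sc2$removed_for_gapfill[[g]], gf$expected_added)
})
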