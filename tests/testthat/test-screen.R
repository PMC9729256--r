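mini_evidence <- function(rows) {
  evidence_table(do.call(rbind, lapply(rows, function(r)
    data.frame(genome = r[[1]], gene = r[[2]], ec = r[[3]],
               annotation = r[[4]], source = "test", stringsAsFactors = FALSE))))
}

test_that("EC-evidence screening fills the grid and applies decision rules", {
  ev <- mini_evidence(list(
    list("gnmA", "a1", "4.1.3.1", "isocitrate lyase"),
    list("gnmA", "a2", "2.3.3.9", "malate synthase"),
    list("gnmB", "b1", "4.1.3.1", "isocitrate lyase"),
    list("gnmC", "c1", "1.1.1.1", "something else")))
  res <- screen_genomes(default_screens()$glyoxylate_cycle, ev)
  g <- res$glyoxylate_cycle
  expect_equal(g$grid["gnmA", ], c(isocitrate_lyase = "yes",
                                   malate_synthase = "yes"))
  expect_equal(unname(g$verdict["gnmA"]), "yes")   # both enzymes: cycle present
  expect_equal(unname(g$verdict["gnmB"]), "no")    # lyase alone is not enough
  expect_equal(unname(g$verdict["gnmC"]), "no")

  # genome with no evidence rows at all is unknown, never coerced
  res2 <- screen_genomes(default_screens()$glyoxylate_cycle, ev,
                         genomes = c("gnmA", "gnmZ"))
  expect_true(all(res2$glyoxylate_cycle$grid["gnmZ", ] == "unknown"))
  expect_equal(unname(res2$glyoxylate_cycle$verdict["gnmZ"]), "unknown")
})

test_that("presence-matrix screening resolves members to reference reactions", {
  ref <- make_reference_model(n_reactions = 20, seed = 41)
  sc <- simulate_genome_family(ref, n_genomes = 4, gene_loss_rate = 0.2,
                               seed = 42)
  mat <- build_presence_matrix(ref, sc$orthotable, names(sc$genomes), "REF")
  rid <- ref$reactions$id[5]
  def <- screen_definition("probe", members = stats::setNames(
    list(list(reaction = rid)), rid), rule = "any-member")
  res <- screen_genomes(def, mat)
  for (g in names(sc$genomes)) {
    expect_equal(res$probe$grid[g, rid] == "yes", mat$presence[rid, g])
  }
  bad <- screen_definition("bad", members = list(x = list(reaction = "NOPE")),
                           rule = "any-member")
  expect_error(screen_genomes(bad, mat), "NOPE")
})

test_that("planted pathway losses are recovered from synthetic evidence", {
  ref <- make_reference_model(n_reactions = 25, seed = 43)
  sc <- simulate_genome_family(ref, n_genomes = 10, gene_loss_rate = 0.25,
                               seed = 44)
  # probe two synthetic enzymes by their generator-assigned EC numbers
  probe_rxns <- ref$reactions$id[!ref$reactions$is_exchange][2:3]
  idx <- match(probe_rxns, ref$reactions$id)
  def <- screen_definition("probe", members = list(
    m1 = list(ec = ref$reactions$ec[[idx[1]]]),
    m2 = list(ec = ref$reactions$ec[[idx[2]]])), rule = "all-members")
  res <- screen_genomes(def, sc$evidence, genomes = names(sc$genomes))
  for (g in names(sc$genomes)) {
    for (k in 1:2) {
      genes <- gpr_genes(ref$reactions$gpr[[idx[k]]])
      planted <- length(genes) > 0 && any(genes %in% sc$retained[[g]])
      expect_equal(res$probe$grid[g, k] == "yes", planted)
    }
  }
})

test_that("mutual exclusivity classification matches a brute-force tally", {
  tab <- transhydrogenase_calls_table()
  res <- screen_result_from_table(tab, c("membrane_transhydrogenase",
                                         "soluble_transhydrogenase"),
                                  "transhydrogenases", rule = "member-wise")
  rep <- mutual_exclusivity_report(res, "transhydrogenases",
                                   c("membrane_transhydrogenase",
                                     "soluble_transhydrogenase"))
  # brute-force recount
  n_both <- sum(tab$membrane_transhydrogenase == "Yes" &
                tab$soluble_transhydrogenase == "Yes")
  expect_equal(attr(rep, "n_both"), n_both)
  expect_equal(attr(rep, "n_both"), 1)  # single both-present exception
  expect_equal(rep$class[rep$genome == "A. aceti TMW2.1153"], "both")
  expect_true(all(rep$class[rep$genome != "A. aceti TMW2.1153"] %in%
                  c("first-only", "second-only")))

  # all-absent genomes classify as neither
  tab0 <- tab
  tab0$membrane_transhydrogenase <- "No"
  tab0$soluble_transhydrogenase <- "No"
  res0 <- screen_result_from_table(tab0, names(tab0)[2:3],
                                   "transhydrogenases", rule = "member-wise")
  rep0 <- mutual_exclusivity_report(res0, "transhydrogenases", names(tab0)[2:3])
  expect_true(all(rep0$class == "neither"))

  # random planted patterns match the tally
  set.seed(5)
  for (i in 1:20) {
    tabr <- tab
    tabr$membrane_transhydrogenase <- sample(c("Yes", "No"), nrow(tab), TRUE)
    tabr$soluble_transhydrogenase <- sample(c("Yes", "No"), nrow(tab), TRUE)
    resr <- screen_result_from_table(tabr, names(tabr)[2:3], "t", "member-wise")
    repr <- mutual_exclusivity_report(resr, "t", names(tabr)[2:3])
    expect_equal(attr(repr, "n_both"),
                 sum(tabr[[2]] == "Yes" & tabr[[3]] == "Yes"))
  }
})

test_that("phenotype concordance flags the growth-positive, pathway-absent species", {
  tab <- glyoxylate_screen_table()
  res <- screen_result_from_table(tab, c("isocitrate_lyase", "malate_synthase"),
                                  "glyoxylate_cycle", rule = "all-members")
  phen <- stats::setNames(tab$growth, tab$species)
  conc <- concordance_with_phenotype(res, "glyoxylate_cycle", phen,
                                     weak_as = "+")
  disc <- attr(conc, "discordant")
  # the three growth-positive species without the cycle
  expect_setequal(disc, c("A. fabarum", "A. cibinongensis", "A. senegalensis"))
  expect_true("A. senegalensis" %in% disc)
  # species with the cycle that grow are concordant
  expect_true(conc$concordant[conc$genome == "A. aceti"])
  expect_true(conc$concordant[conc$genome == "A. nitrogenifigens"])
  # unsequenced species (unknown calls) never enter the tally
  expect_false(any(c("A. lovaniensis", "A. estunensis") %in% conc$genome))

  # excluding weak growth drops one discordant species
  conc2 <- concordance_with_phenotype(res, "glyoxylate_cycle", phen,
                                      weak_as = "w")
  expect_setequal(attr(conc2, "discordant"),
                  c("A. fabarum", "A. senegalensis"))

  # a fully concordant family yields an empty discordance list
  tabc <- tab[tab$isocitrate_lyase != "?", ]
  tabc$growth <- ifelse(tabc$isocitrate_lyase == "Yes", "+", "-")
  resc <- screen_result_from_table(tabc, c("isocitrate_lyase",
                                           "malate_synthase"),
                                   "glyoxylate_cycle", rule = "all-members")
  concc <- concordance_with_phenotype(
    resc, "glyoxylate_cycle", stats::setNames(tabc$growth, tabc$species))
  expect_length(attr(concc, "discordant"), 0)
})

test_that("evidence- and matrix-based screening agree when annotations are complete", {
  ref <- make_reference_model(n_reactions = 25, seed = 45)
  sc <- simulate_genome_family(ref, n_genomes = 6, gene_loss_rate = 0.2,
                               seed = 46)
  mat <- build_presence_matrix(ref, sc$orthotable, names(sc$genomes), "REF")
  # single-gene reactions: evidence ECs and matrix calls must coincide
  idx <- which(vapply(ref$reactions$gpr, function(r)
    !is.null(r) && r$op == "gene", logical(1)))[1:3]
  for (i in idx) {
    rid <- ref$reactions$id[[i]]
    def_ec <- screen_definition("x", members = list(
      m = list(ec = ref$reactions$ec[[i]], reaction = rid)), rule = "any-member")
    r_ev <- screen_genomes(def_ec, sc$evidence, genomes = names(sc$genomes))
    r_mx <- screen_genomes(def_ec, mat)
    expect_equal(r_ev$x$grid[names(sc$genomes), "m"],
                 r_mx$x$grid[names(sc$genomes), "m"])
  }
})
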