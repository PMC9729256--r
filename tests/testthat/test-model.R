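# Brute-force dead-end oracle: enumerate, per metabolite, the producing and
# consuming (reaction, direction) channels by explicit loops.
dead_end_oracle <- function(model) {
  out <- character()
  for (m in model$metabolites$id) {
    producers <- 0L; consumers <- 0L; touching <- 0L
    for (i in seq_len(nrow(model$reactions))) {
      s <- model$reactions$stoich[[i]]
      if (!m %in% names(s)) next
      touching <- touching + 1L
      coef <- s[[m]]
      if (model$reactions$upper_bound[[i]] > 0) {   # forward direction
        if (coef > 0) producers <- producers + 1L else consumers <- consumers + 1L
      }
      if (model$reactions$lower_bound[[i]] < 0) {   # backward direction
        if (coef > 0) consumers <- consumers + 1L else producers <- producers + 1L
      }
    }
    if (producers == 0L || consumers == 0L || touching == 1L) out <- c(out, m)
  }
  out
}

test_that("model validation enforces the structural invariants", {
  m <- toy_chain()
  expect_s3_class(m, "gem")
  bad_rx <- m$reactions
  bad_rx$lower_bound[2] <- 2000
  expect_error(gem(m$id, m$compartments, m$metabolites, bad_rx,
                   objective = "BIO"), "lower_bound > upper_bound")
  expect_error(gem(m$id, "c", m$metabolites, m$reactions, objective = "BIO"),
               "compartment")
  expect_error(gem(m$id, m$compartments, m$metabolites, m$reactions,
                   objective = "NOPE"), "objective")
  expect_error(gem(m$id, m$compartments, m$metabolites[-1, ], m$reactions,
                   objective = "BIO"), "unknown metabolite")
})

test_that("composition summary counts follow the stated definitions", {
  m <- toy_chain()
  s <- summary(m)
  expect_equal(s$reactions, 3)
  expect_equal(s$exchange_reactions, 1)
  expect_equal(s$irreversible_reactions, 3)  # EX_glc has ub = 0
  expect_equal(s$orphan_reactions, 1)        # BIO: non-exchange, no rule
  expect_equal(s$genes, 1)
  expect_equal(s$metabolites, 2)

  empty <- gem("empty", "c",
               data.frame(id = character(), name = character(),
                          formula = character(), charge = integer(),
                          compartment = character()),
               orthogem:::empty_reactions())
  se <- summary(empty)
  expect_true(all(as.numeric(se[1, ]) == c(1, 0, 0, 0, 0, 0, 0, 0)))
})

test_that("dead-end detection agrees with the brute-force oracle", {
  # metabolite only produced by one irreversible reaction -> dead end
  mets <- data.frame(id = c("A", "B"), name = c("A", "B"), formula = "C6H12O6",
                     charge = 0L, compartment = "c", stringsAsFactors = FALSE)
  rx <- data.frame(id = "R1", name = "R1", lower_bound = 0, upper_bound = 10,
                   stringsAsFactors = FALSE)
  rx$stoich <- list(c(A = -1, B = 1))
  rx$gpr <- list(NULL); rx$ec <- list(character()); rx$is_exchange <- FALSE
  m <- gem("d1", "c", mets, rx)
  expect_setequal(find_dead_end_metabolites(m), c("A", "B"))

  # single reversible reaction: channels coincide, still dead-end
  rx$lower_bound <- -10
  m2 <- gem("d2", "c", mets, rx)
  expect_setequal(find_dead_end_metabolites(m2), c("A", "B"))

  # random models up to 50 reactions
  set.seed(7)
  for (rep in 1:25) {
    n_met <- sample(3:12, 1); n_rx <- sample(2:50, 1)
    mets <- data.frame(id = sprintf("m%02d", 1:n_met), name = "m",
                       formula = "C6H12O6", charge = 0L, compartment = "c",
                       stringsAsFactors = FALSE)
    rx <- data.frame(id = sprintf("r%02d", 1:n_rx), name = "r",
                     lower_bound = ifelse(runif(n_rx) < 0.4, -10, 0),
                     upper_bound = ifelse(runif(n_rx) < 0.1, 0, 10),
                     stringsAsFactors = FALSE)
    rx$lower_bound <- pmin(rx$lower_bound, rx$upper_bound)
    rx$stoich <- lapply(1:n_rx, function(i) {
      k <- sample(1:3, 1)
      ids <- sample(mets$id, k)
      stats::setNames(sample(c(-2, -1, 1, 2), k, replace = TRUE), ids)
    })
    rx$gpr <- replicate(n_rx, NULL)
    rx$ec <- replicate(n_rx, character(), simplify = FALSE)
    rx$is_exchange <- vapply(rx$stoich, function(s) length(s) == 1L, logical(1))
    m <- gem("rand", "c", mets, rx)
    expect_setequal(find_dead_end_metabolites(m), dead_end_oracle(m))
  }
})

test_that("carbon counting reads elemental formulas", {
  expect_equal(carbon_count("C6H12O6"), 6)
  expect_equal(carbon_count("H2O"), 0)
  expect_equal(carbon_count("C6H5O7"), 6)
  expect_equal(carbon_count("CO2"), 1)
  expect_equal(parse_formula("C10H12N5O13P3")[["P"]], 3)
  expect_error(carbon_count("C6H12?"), "bad token")
})

test_that("mass-balance checking flags injected imbalances only", {
  m <- toy_chain()
  mb <- check_mass_balance(m)
  expect_equal(nrow(mb), 0)          # exchanges and biomass excluded

  # corrupt one coefficient: transporter now creates carbon
  m$reactions$stoich[[2]] <- c(glc_e = -1, A = 2)
  mb2 <- check_mass_balance(m, exempt = "BIO")
  expect_true("TR" %in% mb2$reaction_id)
  expect_equal(mb2$delta[mb2$reaction_id == "TR" & mb2$element == "C"], 6)

  # formula-less participant: reported as unchecked, not balanced
  m3 <- toy_chain()
  m3$metabolites$formula[2] <- NA
  mb3 <- check_mass_balance(m3)
  expect_true("TR" %in% attr(mb3, "unchecked"))
})
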