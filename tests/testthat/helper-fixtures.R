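# Shared fixtures, built in code at test time.

# Linear toy: EX_glc (uptake <= 10) -> transporter -> biomass, yield 1.
# Hand-solved optimum: biomass flux 10.
toy_chain <- function() {
  mets <- data.frame(
    id = c("glc_e", "A"), name = c("glucose (extracellular)", "precursor A"),
    formula = c("C6H12O6", "C6H12O6"), charge = 0L,
    compartment = c("e", "c"), stringsAsFactors = FALSE)
  rx <- data.frame(
    id = c("EX_glc", "TR", "BIO"),
    name = c("glucose exchange", "glucose transport", "biomass"),
    lower_bound = c(-10, 0, 0), upper_bound = c(0, 1000, 1000),
    stringsAsFactors = FALSE)
  rx$stoich <- list(c(glc_e = -1), c(glc_e = -1, A = 1), c(A = -1))
  rx$gpr <- list(NULL, parse_gpr("gT"), NULL)
  rx$ec <- list(character(), "1.1.1.1", character())
  rx$is_exchange <- c(TRUE, FALSE, FALSE)
  gem("toy_chain", c("c", "e"), mets, rx, objective = "BIO")
}

# Two independent substrate branches into one precursor.
# Hand-solved optimum: 10 + 5 = 15.
toy_branch <- function() {
  mets <- data.frame(
    id = c("s1_e", "s2_e", "A"), name = c("substrate 1", "substrate 2", "A"),
    formula = c("C6H12O6", "C3H6O3", "C6H12O6"), charge = 0L,
    compartment = c("e", "e", "c"), stringsAsFactors = FALSE)
  rx <- data.frame(
    id = c("EX_s1", "EX_s2", "T1", "T2", "BIO"),
    name = c("s1 exchange", "s2 exchange", "s1 uptake", "s2 uptake", "biomass"),
    lower_bound = c(-10, -5, 0, 0, 0), upper_bound = c(0, 0, 1000, 1000, 1000),
    stringsAsFactors = FALSE)
  rx$stoich <- list(c(s1_e = -1), c(s2_e = -1),
                    c(s1_e = -1, A = 1), c(s2_e = -1, A = 1), c(A = -1))
  rx$gpr <- replicate(5, NULL)
  rx$ec <- replicate(5, character(), simplify = FALSE)
  rx$is_exchange <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  gem("toy_branch", c("c", "e"), mets, rx, objective = "BIO")
}

# Chain plus a two-reaction futile cycle between internal metabolites.
# FBA biomass optimum 10; the cycle carries arbitrary flux at the FBA
# optimum but parsimony must drive it to zero.
toy_cycle <- function() {
  mets <- data.frame(
    id = c("glc_e", "A", "B"), name = c("glucose", "A", "B"),
    formula = "C6H12O6", charge = 0L,
    compartment = c("e", "c", "c"), stringsAsFactors = FALSE)
  rx <- data.frame(
    id = c("EX_glc", "TR", "AB", "BA", "BIO"),
    name = c("glucose exchange", "transport", "A to B", "B to A", "biomass"),
    lower_bound = c(-10, 0, 0, 0, 0),
    upper_bound = c(0, 1000, 1000, 1000, 1000),
    stringsAsFactors = FALSE)
  rx$stoich <- list(c(glc_e = -1), c(glc_e = -1, A = 1),
                    c(A = -1, B = 1), c(B = -1, A = 1), c(A = -1))
  rx$gpr <- replicate(5, NULL)
  rx$ec <- replicate(5, character(), simplify = FALSE)
  rx$is_exchange <- c(TRUE, FALSE, FALSE, FALSE, FALSE)
  gem("toy_cycle", c("c", "e"), mets, rx, objective = "BIO")
}

toy_medium <- function(...) medium_spec(...)

# Random positive Boolean rule over a gene pool (for property tests).
# Trees are canonicalized (nested same-operator nodes flattened), matching
# the n-ary form the parser produces, so print -> parse round trips are
# structurally exact.
random_rule <- function(n_genes, depth = 3L) {
  pool <- sprintf("x%02d", seq_len(n_genes))
  build <- function(d, avail) {
    if (d == 0L || length(avail) == 1L || stats::runif(1) < 0.3) {
      return(gpr_gene(sample(avail, 1L)))
    }
    k <- sample(2:min(3L, length(avail)), 1L)
    op <- sample(c("and", "or"), 1L)
    args <- lapply(seq_len(k), function(i) build(d - 1L, avail))
    gpr_node(op, args)
  }
  flatten <- function(node) {
    if (node$op %in% c("gene", "false")) return(node)
    args <- lapply(node$args, flatten)
    spliced <- list()
    for (a in args) {
      if (identical(a$op, node$op)) spliced <- c(spliced, a$args)
      else spliced <- c(spliced, list(a))
    }
    gpr_node(node$op, spliced)
  }
  flatten(build(depth, pool))
}

# Independent truth-table oracle: evaluate rule text with R's own boolean
# operators, genes bound as logical variables.
eval_rule_oracle <- function(rule, present) {
  genes <- gpr_genes(rule)
  txt <- gpr_to_text(rule)
  txt <- gsub("\\bor\\b", "||", txt)
  txt <- gsub("\\band\\b", "&&", txt)
  env <- new.env()
  for (g in genes) assign(g, g %in% present, envir = env)
  eval(parse(text = txt), envir = env)
}

# Orthogroup table with one orthogroup per reference gene.
simple_orthotable <- function(ref_genes, target_map,
                              reference_genome = "REF", target_genome = "TGT") {
  ogs <- list()
  for (k in seq_along(ref_genes)) {
    g <- ref_genes[[k]]
    row <- list()
    row[[reference_genome]] <- g
    row[[target_genome]] <- if (g %in% names(target_map)) target_map[[g]]
                            else character()
    ogs[[sprintf("OG%03d", k)]] <- row
  }
  orthogroup_table(ogs, c(reference_genome, target_genome))
}

# Exhaustive subset-search oracle: smallest growth-restoring candidate
# subset, ties broken lexicographically on the sorted id vector.
gapfill_oracle <- function(draft, template, medium, threshold = 1e-6) {
  candidates <- sort(setdiff(template$reactions$id, draft$reactions$id))
  is_ex <- template$reactions$is_exchange[match(candidates, template$reactions$id)]
  keep <- !is_ex | candidates %in% c(names(medium$uptake), medium$always_open)
  candidates <- candidates[keep]
  for (k in 0:length(candidates)) {
    combos <- if (k == 0) list(character()) else
      utils::combn(candidates, k, simplify = FALSE)
    for (cmb in combos) {
      m <- orthogem:::merge_reactions(draft, template, cmb)
      if (growth_test(m, medium, threshold)) return(sort(cmb))
    }
  }
  NULL
}

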