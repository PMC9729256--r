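#' Pathway screen definitions
#'
#' A screen names a pathway module and its member enzymes, each identified by
#' an EC number set (for evidence-based screening) and/or a reference
#' reaction id (for presence-matrix screening). The decision rule turns the
#' member grid into a per-genome verdict: `all-members` (the pathway needs
#' every enzyme, e.g. the glyoxylate cycle), `any-member`, or `member-wise`
#' (no verdict; members reported individually, as for the transhydrogenase
#' pair).
#'
#' @param name screen name.
#' @param members named list: member label -> list with `ec` (character
#'   vector of EC numbers, dashes allowed) and/or `reaction` (reference
#'   reaction id).
#' @param rule `"all-members"`, `"any-member"`, or `"member-wise"`.
#' @return object of class `screen_definition`.
#' @export
screen_definition <- function(name, members,
                              rule = c("all-members", "any-member",
                                       "member-wise")) {
  rule <- match.arg(rule)
  if (length(members) < 1L) stop("a screen needs at least one member", call. = FALSE)
  for (lab in names(members)) {
    ecs <- members[[lab]]$ec
    if (!is.null(ecs)) {
      ok <- grepl("^[0-9]+\\.[0-9-]+\\.[0-9-]+\\.[0-9a-zA-Z-]+$", ecs)
      if (any(!ok)) {
        stop("invalid EC number '", ecs[!ok][1L], "' in member '", lab, "'",
             call. = FALSE)
      }
    }
  }
  structure(list(name = name, members = members, rule = rule),
            class = "screen_definition")
}

#' Pre-shipped pathway screens
#'
#' The three screens of the comparative read-out: the glyoxylate cycle
#' (isocitrate lyase EC 4.1.3.1 and malate synthase EC 2.3.3.9; both required
#' for net C2 assimilation), the aerobic respiratory chain (NADH
#' dehydrogenases I and II, cytochrome bo3 and bd oxidases; all-members), and
#' the NAD(P)+ transhydrogenases (membrane proton-translocating EC 7.1.1.1
#' versus soluble EC 1.6.1.1; reported member-wise -- their joint pattern is
#' what [mutual_exclusivity_report()] examines).
#'
#' @return named list of [screen_definition] objects.
#' @export
default_screens <- function() {
  list(
    glyoxylate_cycle = screen_definition(
      "glyoxylate_cycle",
      members = list(
        isocitrate_lyase = list(ec = "4.1.3.1"),
        malate_synthase = list(ec = "2.3.3.9")),
      rule = "all-members"),
    respiratory_chain = screen_definition(
      "respiratory_chain",
      members = list(
        nadh_dehydrogenase_I = list(ec = "7.1.1.2"),
        nadh_dehydrogenase_II = list(ec = "1.6.5.9"),
        cytochrome_bo3_oxidase = list(ec = "7.1.1.3"),
        cytochrome_bd_oxidase = list(ec = "7.1.1.7")),
      rule = "all-members"),
    transhydrogenases = screen_definition(
      "transhydrogenases",
      members = list(
        membrane_transhydrogenase = list(ec = "7.1.1.1"),
        soluble_transhydrogenase = list(ec = "1.6.1.1")),
      rule = "member-wise")
  )
}

#' Screen genomes for pathway presence
#'
#' Fills a genomes x members grid of `"yes"`/`"no"`/`"unknown"` calls from
#' either an annotation [evidence_table()] (member present iff some gene of
#' the genome carries one of the member's EC numbers; a genome with no
#' evidence rows at all has no annotation coverage and is `"unknown"` across
#' the board) or a [build_presence_matrix()] result (member resolved to its
#' reference reaction row). Per-genome verdicts follow each screen's decision
#' rule; `member-wise` screens get an `NA` verdict.
#'
#' @param defs list of [screen_definition] objects.
#' @param data an `evidence_table` or `presence_matrix`.
#' @param genomes genome ids to screen (default: all in `data`).
#' @return object of class `screen_result`: list of per-screen lists with
#'   `grid` (genomes x members character matrix) and `verdict` (named
#'   character vector).
#' @export
screen_genomes <- function(defs, data, genomes = NULL) {
  if (inherits(defs, "screen_definition")) defs <- list(defs)
  use_evidence <- inherits(data, "evidence_table")
  if (!use_evidence && !inherits(data, "presence_matrix")) {
    stop("data must be an evidence_table or a presence_matrix", call. = FALSE)
  }
  if (is.null(genomes)) {
    genomes <- if (use_evidence) unique(data$genome) else colnames(data$presence)
  }
  out <- list()
  for (def in defs) {
    labs <- names(def$members)
    grid <- matrix("unknown", length(genomes), length(labs),
                   dimnames = list(genomes, labs))
    for (lab in labs) {
      mem <- def$members[[lab]]
      for (g in genomes) {
        if (use_evidence) {
          has_rows <- any(data$genome == g)
          if (!has_rows) { grid[g, lab] <- "unknown"; next }
          if (is.null(mem$ec)) {
            stop("member '", lab, "' of screen '", def$name,
                 "' has no EC set; cannot resolve against evidence", call. = FALSE)
          }
          hit <- any(vapply(mem$ec, function(e)
            length(evidence_genes_for_ec(data, g, e)) > 0L, logical(1L)))
          grid[g, lab] <- if (hit) "yes" else "no"
        } else {
          if (is.null(mem$reaction)) {
            stop("member '", lab, "' of screen '", def$name,
                 "' has no reference reaction id; cannot resolve against a ",
                 "presence matrix", call. = FALSE)
          }
          if (!mem$reaction %in% rownames(data$presence)) {
            stop("member '", lab, "' of screen '", def$name,
                 "': reaction '", mem$reaction, "' not in presence matrix",
                 call. = FALSE)
          }
          grid[g, lab] <- if (data$presence[mem$reaction, g]) "yes" else "no"
        }
      }
    }
    verdict <- switch(def$rule,
      "all-members" = apply(grid, 1L, function(row) {
        if (any(row == "no")) "no"
        else if (all(row == "yes")) "yes"
        else "unknown"
      }),
      "any-member" = apply(grid, 1L, function(row) {
        if (any(row == "yes")) "yes"
        else if (all(row == "no")) "no"
        else "unknown"
      }),
      "member-wise" = stats::setNames(rep(NA_character_, length(genomes)),
                                      genomes)
    )
    out[[def$name]] <- list(grid = grid, verdict = verdict, rule = def$rule)
  }
  structure(out, class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  for (nm in names(x)) {
    cat("<screen> ", nm, " (", x[[nm]]$rule, ")\n", sep = "")
    print(x[[nm]]$grid)
  }
  invisible(x)
}

#' Mutual-exclusivity classification of a member pair
#'
#' Classifies each genome by the joint pattern of two screen members:
#' `first-only`, `second-only`, `both`, `neither` (`unknown` if either member
#' call is unknown). Used to test whether two enzyme systems substitute for
#' one another across a genus -- e.g. the membrane versus soluble
#' transhydrogenase -- and to count the exceptions carrying both.
#'
#' @param result a `screen_result`.
#' @param screen screen name within `result`.
#' @param member_pair character vector of two member labels.
#' @return data frame `genome`, `first`, `second`, `class`, with attribute
#'   `n_both` (count of `both` exceptions).
#' @export
mutual_exclusivity_report <- function(result, screen, member_pair) {
  stopifnot(inherits(result, "screen_result"), length(member_pair) == 2L)
  grid <- result[[screen]]$grid
  missing <- setdiff(member_pair, colnames(grid))
  if (length(missing)) {
    stop("member(s) not in screen '", screen, "': ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  a <- grid[, member_pair[[1L]]]
  b <- grid[, member_pair[[2L]]]
  cls <- ifelse(a == "unknown" | b == "unknown", "unknown",
         ifelse(a == "yes" & b == "yes", "both",
         ifelse(a == "yes", "first-only",
         ifelse(b == "yes", "second-only", "neither"))))
  out <- data.frame(genome = rownames(grid), first = a, second = b,
                    class = unname(cls), stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "n_both") <- sum(cls == "both")
  out
}

#' Concordance of screen calls with growth phenotypes
#'
#' Compares a screen's per-genome verdicts with observed growth phenotypes
#' (`+`, `-`, `w` weak, `?` untested/unknown). Genomes growing although the
#' screen says the pathway is absent are candidate false-positive growth
#' records; the reverse are candidate false negatives. `?` phenotypes and
#' `unknown` screen verdicts are excluded from the tallies. Weak growth
#' defaults to counting as growth (`weak_as = "+"`) -- the convention under
#' which the phenotype tallies of the shipped glyoxylate table add up -- but
#' is configurable.
#'
#' @param result a `screen_result`.
#' @param screen screen name.
#' @param phenotype named character vector genome -> `+`, `-`, `w`, `?`.
#' @param weak_as map `w` to `"+"` or `"-"`, or keep `"w"` to exclude it.
#' @return data frame `genome`, `phenotype`, `screen_call`, `concordant`,
#'   restricted to comparable genomes; attribute `discordant` lists the
#'   discordant genomes.
#' @export
concordance_with_phenotype <- function(result, screen, phenotype,
                                       weak_as = "+") {
  verdict <- result[[screen]]$verdict
  genomes <- intersect(names(verdict), names(phenotype))
  ph <- phenotype[genomes]
  ph[ph == "w"] <- weak_as
  vd <- verdict[genomes]
  keep <- ph %in% c("+", "-") & vd %in% c("yes", "no")
  df <- data.frame(
    genome = genomes[keep],
    phenotype = unname(ph[keep]),
    screen_call = unname(vd[keep]),
    stringsAsFactors = FALSE)
  df$concordant <- (df$phenotype == "+") == (df$screen_call == "yes")
  attr(df, "discordant") <- df$genome[!df$concordant]
  df
}

#' Load the shipped glyoxylate-cycle screen table
#'
#' A packaged TSV fixture with, per species of the genus surveyed: the growth
#' phenotype on ammonium + ethanol (the classic taxonomic test), the number
#' of genomes available, and the presence calls for the two glyoxylate-cycle
#' genes. Species without a sequenced genome carry `?` presence calls.
#'
#' @return data frame with columns `species`, `n_strains_tested`, `growth`,
#'   `n_genomes`, `isocitrate_lyase`, `malate_synthase`.
#' @export
glyoxylate_screen_table <- function() {
  path <- system.file("extdata", "glyoxylate_screen_table.tsv",
                      package = "orthogem", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
}

#' Screen result from a packaged presence table
#'
#' Converts a table of per-genome yes/no/? member calls (such as
#' [glyoxylate_screen_table()] or the synthetic transhydrogenase fixture)
#' into a `screen_result`, so the reporting operations apply uniformly.
#'
#' @param df data frame; first column genome/species labels.
#' @param members character vector of member columns in `df`.
#' @param name screen name.
#' @param rule decision rule (see [screen_definition()]).
#' @return a `screen_result`.
#' @export
screen_result_from_table <- function(df, members, name,
                                     rule = c("all-members", "any-member",
                                              "member-wise")) {
  rule <- match.arg(rule)
  grid <- as.matrix(df[, members, drop = FALSE])
  grid <- matrix(ifelse(grid %in% c("Yes", "yes"), "yes",
                 ifelse(grid %in% c("No", "no"), "no", "unknown")),
                 nrow = nrow(df), dimnames = list(df[[1L]], members))
  verdict <- switch(rule,
    "all-members" = apply(grid, 1L, function(row) {
      if (any(row == "no")) "no"
      else if (all(row == "yes")) "yes" else "unknown"
    }),
    "any-member" = apply(grid, 1L, function(row) {
      if (any(row == "yes")) "yes"
      else if (all(row == "no")) "no" else "unknown"
    }),
    "member-wise" = stats::setNames(rep(NA_character_, nrow(grid)),
                                    rownames(grid)))
  structure(stats::setNames(list(list(grid = grid, verdict = verdict,
                                      rule = rule)), name),
            class = "screen_result")
}

#' Load the synthetic transhydrogenase presence fixture
#'
#' Per-genome membrane (EC 7.1.1.1) and soluble (EC 1.6.1.1) NAD(P)+
#' transhydrogenase calls for a panel of eleven complete genomes. This table
#' is a synthetic stand-in assembled from reported narrative presence/absence
#' statements, not a published data table; it encodes the pattern that the
#' two enzyme systems are mutually exclusive across the panel with a single
#' genome carrying both.
#'
#' @return data frame with columns `genome`, `membrane_transhydrogenase`,
#'   `soluble_transhydrogenase`.
#' @export
transhydrogenase_calls_table <- function() {
  path <- system.file("extdata", "transhydrogenase_calls_synthetic.tsv",
                      package = "orthogem", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
}
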