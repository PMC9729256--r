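#' Read a genome-scale metabolic model
#'
#' Reads SBML Level 3 (with the FBC version 2 package for flux bounds, gene
#' products, gene-product associations and the objective) or the package's
#' JSON model dialect (a direct serialization of the [gem] structure; the
#' canonical round-trip format of the test suite). The format is taken from
#' the file extension unless given explicitly.
#'
#' @param path file path.
#' @param format `"sbml"`, `"json"`, or `"auto"` (by extension: `.xml`/`.sbml`
#'   -> SBML, `.json` -> JSON).
#' @return a validated [gem].
#' @export
read_gem <- function(path, format = c("auto", "sbml", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, xml = "sbml", sbml = "sbml", json = "json",
                     stop("cannot infer model format from extension '.", ext,
                          "'", call. = FALSE))
  }
  switch(format, sbml = read_gem_sbml(path), json = read_gem_json(path))
}

#' Write a genome-scale metabolic model
#'
#' Inverse of [read_gem()]. JSON round-trips all structural fields
#' bit-identically; SBML round-trips everything the FBC v2 schema represents.
#'
#' @param model a [gem].
#' @param path output file path.
#' @param format `"sbml"`, `"json"`, or `"auto"` (by extension).
#' @return `path`, invisibly.
#' @export
write_gem <- function(model, path, format = c("auto", "sbml", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(model, "gem"))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, xml = "sbml", sbml = "sbml", json = "json",
                     stop("cannot infer model format from extension '.", ext,
                          "'", call. = FALSE))
  }
  switch(format, sbml = write_gem_sbml(model, path),
         json = write_gem_json(model, path))
  invisible(path)
}

# JSON dialect ---------------------------------------------------------------

read_gem_json <- function(path) {
  x <- tryCatch(jsonlite::read_json(path),
                error = function(e) stop("malformed JSON model '", path, "': ",
                                         conditionMessage(e), call. = FALSE))
  for (f in c("id", "compartments", "metabolites", "reactions")) {
    if (is.null(x[[f]])) stop("malformed JSON model: missing element '", f, "'",
                              call. = FALSE)
  }
  mets <- if (length(x$metabolites)) do.call(rbind, lapply(x$metabolites, function(m)
    data.frame(id = m$id, name = m$name %||% m$id,
               formula = m$formula %||% NA_character_,
               charge = if (is.null(m$charge)) NA_integer_ else as.integer(m$charge),
               compartment = m$compartment, stringsAsFactors = FALSE)))
  else data.frame(id = character(), name = character(), formula = character(),
                  charge = integer(), compartment = character())
  rx <- if (length(x$reactions)) {
    df <- data.frame(
      id = vapply(x$reactions, `[[`, character(1L), "id"),
      name = vapply(x$reactions, function(r) r$name %||% r$id, character(1L)),
      lower_bound = vapply(x$reactions, function(r) as.numeric(r$lower_bound), numeric(1L)),
      upper_bound = vapply(x$reactions, function(r) as.numeric(r$upper_bound), numeric(1L)),
      notes = vapply(x$reactions, function(r) r$notes %||% "", character(1L)),
      stringsAsFactors = FALSE)
    df$stoich <- lapply(x$reactions, function(r) {
      s <- unlist(r$stoichiometry)
      if (is.null(s)) stats::setNames(numeric(), character()) else s
    })
    df$gpr <- lapply(x$reactions, function(r) parse_gpr(r$gpr %||% ""))
    df$ec <- lapply(x$reactions, function(r) as.character(unlist(r$ec)))
    df$is_exchange <- vapply(x$reactions, function(r)
      isTRUE(r$is_exchange) || (is.null(r$is_exchange) && length(r$stoichiometry) == 1L),
      logical(1L))
    df
  } else NULL
  if (is.null(x$objective)) stop("JSON model '", path, "' declares no objective",
                                 call. = FALSE)
  gem(id = x$id,
      compartments = as.character(unlist(x$compartments)),
      metabolites = mets,
      reactions = if (is.null(rx)) empty_reactions() else rx,
      genes = as.character(unlist(x$genes)),
      objective = if (isTRUE(is.na(x$objective)) || identical(x$objective, ""))
        NA_character_ else x$objective)
}

empty_reactions <- function() {
  df <- data.frame(id = character(), name = character(),
                   lower_bound = numeric(), upper_bound = numeric(),
                   notes = character(), stringsAsFactors = FALSE)
  df$stoich <- list(); df$gpr <- list(); df$ec <- list()
  df$is_exchange <- logical()
  df
}

write_gem_json <- function(model, path) {
  rx <- model$reactions
  x <- list(
    id = model$id,
    compartments = as.list(model$compartments),
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i) {
      m <- model$metabolites[i, ]
      list(id = m$id, name = m$name,
           formula = if (is.na(m$formula)) NULL else m$formula,
           charge = if (is.na(m$charge)) NULL else m$charge,
           compartment = m$compartment)
    }),
    reactions = lapply(seq_len(nrow(rx)), function(i) {
      r <- rx[i, ]
      list(id = r$id, name = r$name,
           lower_bound = r$lower_bound, upper_bound = r$upper_bound,
           stoichiometry = as.list(r$stoich[[1L]]),
           gpr = gpr_to_text(r$gpr[[1L]]),
           ec = as.list(r$ec[[1L]]),
           is_exchange = r$is_exchange,
           notes = r$notes)
    }),
    genes = as.list(model$genes),
    objective = if (is.na(model$objective)) "" else model$objective
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# SBML L3V1 + FBC v2 ---------------------------------------------------------

sbml_ns <- c(
  s = "http://www.sbml.org/sbml/level3/version1/core",
  fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2"
)

# SBML ids must match SId; metabolite/reaction/gene ids with other characters
# are escaped with the standard double-underscore codepoint convention.
sbml_sid <- function(x, prefix) {
  enc <- gsub("[^A-Za-z0-9_]", "_", x)
  paste0(prefix, enc)
}

read_gem_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed SBML '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  model_node <- xml2::xml_find_first(doc, "/s:sbml/s:model", sbml_ns)
  if (inherits(model_node, "xml_missing")) {
    stop("malformed SBML '", path, "': no <model> element", call. = FALSE)
  }
  comp_nodes <- xml2::xml_find_all(model_node,
    "./s:listOfCompartments/s:compartment", sbml_ns)
  compartments <- xml2::xml_attr(comp_nodes, "id")

  # flux-bound parameters
  par_nodes <- xml2::xml_find_all(model_node, "./s:listOfParameters/s:parameter",
                                  sbml_ns)
  pars <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                          xml2::xml_attr(par_nodes, "id"))

  sp_nodes <- xml2::xml_find_all(model_node, "./s:listOfSpecies/s:species", sbml_ns)
  mets <- data.frame(
    id = xml2::xml_attr(sp_nodes, "id"),
    name = xml2::xml_attr(sp_nodes, "name"),
    formula = xml2::xml_attr(sp_nodes, "fbc:chemicalFormula", ns = sbml_ns),
    charge = suppressWarnings(as.integer(xml2::xml_attr(sp_nodes, "fbc:charge", ns = sbml_ns))),
    compartment = xml2::xml_attr(sp_nodes, "compartment"),
    stringsAsFactors = FALSE)
  mets$name[is.na(mets$name)] <- mets$id[is.na(mets$name)]

  gp_nodes <- xml2::xml_find_all(model_node,
    "./fbc:listOfGeneProducts/fbc:geneProduct", sbml_ns)
  gp_map <- stats::setNames(xml2::xml_attr(gp_nodes, "label"),
                            xml2::xml_attr(gp_nodes, "id"))

  rx_nodes <- xml2::xml_find_all(model_node, "./s:listOfReactions/s:reaction",
                                 sbml_ns)
  rx <- empty_reactions()
  if (length(rx_nodes)) {
    recs <- lapply(rx_nodes, function(rn) {
      rid <- xml2::xml_attr(rn, "id")
      lb_ref <- xml2::xml_attr(rn, "fbc:lowerFluxBound", ns = sbml_ns)
      ub_ref <- xml2::xml_attr(rn, "fbc:upperFluxBound", ns = sbml_ns)
      if (is.na(lb_ref) || is.na(ub_ref) || !lb_ref %in% names(pars) ||
          !ub_ref %in% names(pars)) {
        stop("malformed SBML: reaction '", rid,
             "' lacks resolvable fbc flux bounds", call. = FALSE)
      }
      reac <- xml2::xml_find_all(rn, "./s:listOfReactants/s:speciesReference",
                                 sbml_ns)
      prod <- xml2::xml_find_all(rn, "./s:listOfProducts/s:speciesReference",
                                 sbml_ns)
      s <- c(
        stats::setNames(-as.numeric(xml2::xml_attr(reac, "stoichiometry")),
                        xml2::xml_attr(reac, "species")),
        stats::setNames(as.numeric(xml2::xml_attr(prod, "stoichiometry")),
                        xml2::xml_attr(prod, "species")))
      # merge duplicate species references
      if (anyDuplicated(names(s))) s <- tapply(s, names(s), sum)
      ga <- xml2::xml_find_first(rn, "./fbc:geneProductAssociation", sbml_ns)
      rule <- if (inherits(ga, "xml_missing")) NULL else
        sbml_parse_association(xml2::xml_child(ga), gp_map)
      notes_n <- xml2::xml_find_first(rn, "./s:notes", sbml_ns)
      notes <- if (inherits(notes_n, "xml_missing")) "" else
        trimws(xml2::xml_text(notes_n))
      ann <- xml2::xml_attr(rn, "name")
      list(id = rid, name = if (is.na(ann)) rid else ann,
           lower_bound = unname(pars[[lb_ref]]), upper_bound = unname(pars[[ub_ref]]),
           stoich = s, gpr = rule,
           ec = sbml_extract_ec(notes),
           notes = notes)
    })
    rx <- data.frame(
      id = vapply(recs, `[[`, character(1L), "id"),
      name = vapply(recs, `[[`, character(1L), "name"),
      lower_bound = vapply(recs, `[[`, numeric(1L), "lower_bound"),
      upper_bound = vapply(recs, `[[`, numeric(1L), "upper_bound"),
      notes = vapply(recs, `[[`, character(1L), "notes"),
      stringsAsFactors = FALSE)
    rx$stoich <- lapply(recs, `[[`, "stoich")
    rx$gpr <- lapply(recs, `[[`, "gpr")
    rx$ec <- lapply(recs, `[[`, "ec")
    rx$is_exchange <- vapply(rx$stoich, function(s) length(s) == 1L, logical(1L))
  }

  obj_node <- xml2::xml_find_first(model_node,
    "./fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective",
    sbml_ns)
  if (inherits(obj_node, "xml_missing")) {
    stop("SBML model '", path, "' declares no objective (fbc:listOfObjectives)",
         call. = FALSE)
  }
  objective <- xml2::xml_attr(obj_node, "fbc:reaction", ns = sbml_ns)
  if (is.na(objective) || !nzchar(objective)) objective <- NA_character_

  gem(id = xml2::xml_attr(model_node, "id"),
      compartments = compartments,
      metabolites = mets,
      reactions = rx,
      genes = unique(unname(gp_map)),
      objective = objective)
}

sbml_parse_association <- function(node, gp_map) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    ref <- xml2::xml_attr(node, "fbc:geneProduct", ns = sbml_ns)
    label <- gp_map[[ref]]
    if (is.null(label) || is.na(label)) label <- ref
    return(gpr_gene(label))
  }
  kids <- xml2::xml_children(node)
  args <- lapply(kids, sbml_parse_association, gp_map = gp_map)
  if (nm == "and") gpr_node("and", args)
  else if (nm == "or") gpr_node("or", args)
  else stop("malformed SBML: unexpected gene association element <", nm, ">",
            call. = FALSE)
}

sbml_extract_ec <- function(notes) {
  if (!nzchar(notes)) return(character())
  m <- regmatches(notes, gregexpr("EC[: ]([0-9]+\\.[0-9-]+\\.[0-9-]+\\.[0-9a-zA-Z-]+)",
                                  notes, perl = TRUE))[[1L]]
  unique(sub("^EC[: ]", "", m))
}

write_gem_sbml <- function(model, path) {
  rx <- model$reactions
  bounds <- sort(unique(c(rx$lower_bound, rx$upper_bound)))
  par_id <- function(v) sprintf("fb_%s", gsub("[^0-9A-Za-z]", "_", sprintf("%.15g", v)))
  gp_ids <- stats::setNames(sbml_sid(model$genes, "G_"), model$genes)

  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  L <- character()
  add <- function(...) L[[length(L) + 1L]] <<- paste0(...)
  add('<?xml version="1.0" encoding="UTF-8"?>')
  add('<sbml xmlns="', sbml_ns[["s"]], '" xmlns:fbc="', sbml_ns[["fbc"]],
      '" level="3" version="1" fbc:required="false">')
  add('  <model id="', esc(model$id), '" fbc:strict="true">')
  add('    <listOfCompartments>')
  for (cmp in model$compartments) {
    add('      <compartment id="', esc(cmp), '" constant="true"/>')
  }
  add('    </listOfCompartments>')
  if (nrow(model$metabolites)) {
    add('    <listOfSpecies>')
    for (i in seq_len(nrow(model$metabolites))) {
      m <- model$metabolites[i, ]
      extra <- ""
      if (!is.na(m$formula)) extra <- paste0(extra, ' fbc:chemicalFormula="',
                                             esc(m$formula), '"')
      if (!is.na(m$charge)) extra <- paste0(extra, ' fbc:charge="', m$charge, '"')
      add('      <species id="', esc(m$id), '" name="', esc(m$name),
          '" compartment="', esc(m$compartment),
          '" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"',
          extra, '/>')
    }
    add('    </listOfSpecies>')
  }
  add('    <listOfParameters>')
  for (v in bounds) {
    add('      <parameter id="', par_id(v), '" value="',
        sprintf("%.15g", v), '" constant="true"/>')
  }
  add('    </listOfParameters>')
  if (nrow(rx)) {
    add('    <listOfReactions>')
    for (i in seq_len(nrow(rx))) {
      r <- rx[i, ]
      rev <- r$lower_bound < 0
      add('      <reaction id="', esc(r$id), '" name="', esc(r$name),
          '" reversible="', tolower(rev), '" fast="false" fbc:lowerFluxBound="',
          par_id(r$lower_bound), '" fbc:upperFluxBound="', par_id(r$upper_bound),
          '">')
      notes <- r$notes
      ecs <- r$ec[[1L]]
      if (length(ecs)) {
        ec_txt <- paste(sprintf("EC:%s", ecs), collapse = "; ")
        notes <- if (nzchar(notes)) paste0(notes, " | ", ec_txt) else ec_txt
      }
      if (nzchar(notes)) {
        add('        <notes><body xmlns="http://www.w3.org/1999/xhtml"><p>',
            esc(notes), '</p></body></notes>')
      }
      s <- r$stoich[[1L]]
      subs <- s[s < 0]; prods <- s[s > 0]
      if (length(subs)) {
        add('        <listOfReactants>')
        for (k in seq_along(subs)) {
          add('          <speciesReference species="', esc(names(subs)[k]),
              '" stoichiometry="', sprintf("%.15g", -subs[[k]]),
              '" constant="true"/>')
        }
        add('        </listOfReactants>')
      }
      if (length(prods)) {
        add('        <listOfProducts>')
        for (k in seq_along(prods)) {
          add('          <speciesReference species="', esc(names(prods)[k]),
              '" stoichiometry="', sprintf("%.15g", prods[[k]]),
              '" constant="true"/>')
        }
        add('        </listOfProducts>')
      }
      rule <- r$gpr[[1L]]
      if (!is.null(rule) && !gpr_is_false(rule)) {
        add('        <fbc:geneProductAssociation>')
        add(sbml_write_association(rule, gp_ids, indent = "          "))
        add('        </fbc:geneProductAssociation>')
      }
      add('      </reaction>')
    }
    add('    </listOfReactions>')
  }
  add('    <fbc:listOfObjectives fbc:activeObjective="obj">')
  add('      <fbc:objective fbc:id="obj" fbc:type="maximize">')
  add('        <fbc:listOfFluxObjectives>')
  if (!is.na(model$objective)) {
    add('          <fbc:fluxObjective fbc:reaction="', esc(model$objective),
        '" fbc:coefficient="1"/>')
  }
  add('        </fbc:listOfFluxObjectives>')
  add('      </fbc:objective>')
  add('    </fbc:listOfObjectives>')
  if (length(model$genes)) {
    add('    <fbc:listOfGeneProducts>')
    for (g in model$genes) {
      add('      <fbc:geneProduct fbc:id="', gp_ids[[g]], '" fbc:label="',
          esc(g), '"/>')
    }
    add('    </fbc:listOfGeneProducts>')
  }
  add('  </model>')
  add('</sbml>')
  writeLines(L, path)
  invisible(path)
}

sbml_write_association <- function(node, gp_ids, indent) {
  if (node$op == "gene") {
    return(paste0(indent, '<fbc:geneProductRef fbc:geneProduct="',
                  gp_ids[[node$gene]], '"/>'))
  }
  inner <- vapply(node$args, sbml_write_association, character(1L),
                  gp_ids = gp_ids, indent = paste0(indent, "  "))
  paste0(indent, "<fbc:", node$op, ">\n",
         paste(inner, collapse = "\n"), "\n",
         indent, "</fbc:", node$op, ">")
}

#' Export a model summary as TSV
#'
#' @param summary a `gem_summary` from [summary.gem()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary_tsv <- function(summary, path) {
  df <- data.frame(property = names(summary),
                   count = as.integer(summary[1, ]),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
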