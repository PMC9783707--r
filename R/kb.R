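# Knowledge-base data model and file format ("pip-kb/1").
#
# A knowledge base holds: the gene table (phenotype vocabulary + reference
# phenotype per gene), the drug table (clinical area, prodrug flag), the
# interaction rules (drug x gene x phenotype -> severity, AUC change,
# evidence; optionally a second gene/phenotype for intrinsic two-gene rules),
# the modifier table (which drugs inhibit/induce which genes, with an ordinal
# strength), gene-free drug-drug(-drug) interaction rules, and optionally an
# embedded phenotype prevalence table.

#' Clinical areas
#'
#' The thirteen primary clinical areas a drug can be assigned to, by its most
#' common indication.
#'
#' @return character vector of area names.
#' @export
clinical_areas <- function() {
  c("behavioral health", "cardiology", "pain management",
    "hematology and oncology", "infectious disease", "gastroenterology",
    "urology", "transplant", "reproductive and sexual health", "neurology",
    "rheumatology", "endocrinology", "miscellaneous")
}

empty_rules <- function() {
  data.frame(drug = character(), gene = character(), phenotype = character(),
             second_gene = character(), second_phenotype = character(),
             severity = character(), auc_change = character(),
             evidence = character(), stringsAsFactors = FALSE)
}

empty_modifiers <- function() {
  data.frame(drug = character(), gene = character(), action = character(),
             strength = integer(), stringsAsFactors = FALSE)
}

empty_ddi <- function() {
  data.frame(drug1 = character(), drug2 = character(), drug3 = character(),
             severity = character(), stringsAsFactors = FALSE)
}

canonical_df <- function(df, keys) {
  if (nrow(df)) df <- df[do.call(order, df[keys]), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Construct a validated knowledge base
#'
#' Builds a `pip_kb` object from its component tables, canonicalises ordering
#' (drugs, genes, rules sorted by name) and runs the full validation; any
#' diagnostic aborts construction.
#'
#' @param genes data frame with columns `gene`, `reference` (the non-variant
#'   phenotype) and `phenotypes` (a list column of the gene's phenotype
#'   vocabulary).
#' @param drugs data frame with columns `drug`, `clinical_area`, and
#'   optionally `prodrug` (logical; TRUE when interaction rules for the drug
#'   are stated for its active metabolite).
#' @param rules data frame of interaction rules: `drug`, `gene`, `phenotype`,
#'   `severity`, `auc_change`, `evidence`, and optional `second_gene` /
#'   `second_phenotype` for two-gene rules.
#' @param modifiers optional data frame of inhibition/induction effects:
#'   `drug`, `gene`, `action` (`"inhibitor"`/`"inducer"`), `strength` (1--4).
#' @param ddi optional data frame of gene-free interactions: `drug1`, `drug2`,
#'   optional `drug3`, `severity`.
#' @param prevalence optional [as_prevalence()] input embedded in the KB.
#' @return an object of class `pip_kb`.
#' @seealso [load_kb()], [save_kb()], [validate_kb()], [demo_kb()]
#' @export
pip_kb <- function(genes, drugs, rules, modifiers = NULL, ddi = NULL,
                   prevalence = NULL) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  drugs <- as.data.frame(drugs, stringsAsFactors = FALSE)
  rules <- as.data.frame(rules, stringsAsFactors = FALSE)
  if (is.null(drugs$prodrug)) drugs$prodrug <- FALSE
  drugs$drug <- tolower(drugs$drug)
  if (nrow(rules)) {
    rules$drug <- tolower(rules$drug)
    if (is.null(rules$second_gene)) rules$second_gene <- NA_character_
    if (is.null(rules$second_phenotype)) rules$second_phenotype <- NA_character_
  } else {
    rules <- empty_rules()
  }
  modifiers <- if (is.null(modifiers) || !nrow(as.data.frame(modifiers))) {
    empty_modifiers()
  } else {
    m <- as.data.frame(modifiers, stringsAsFactors = FALSE)
    m$drug <- tolower(m$drug)
    m$strength <- as.integer(m$strength)
    m
  }
  ddi <- if (is.null(ddi) || !nrow(as.data.frame(ddi))) {
    empty_ddi()
  } else {
    d <- as.data.frame(ddi, stringsAsFactors = FALSE)
    if (is.null(d$drug3)) d$drug3 <- NA_character_
    d[c("drug1", "drug2", "drug3")] <- lapply(d[c("drug1", "drug2", "drug3")], tolower)
    # canonical within-row order so {a,b} == {b,a}
    for (i in seq_len(nrow(d))) {
      dr <- sort(stats::na.omit(unlist(d[i, c("drug1", "drug2", "drug3")])))
      d$drug1[i] <- dr[1]; d$drug2[i] <- dr[2]
      d$drug3[i] <- if (length(dr) == 3) dr[3] else NA_character_
    }
    d
  }

  kb <- structure(list(
    version = "pip-kb/1",
    genes = canonical_df(genes, "gene"),
    drugs = canonical_df(drugs, "drug"),
    rules = canonical_df(rules, c("drug", "gene", "phenotype", "second_gene",
                                  "second_phenotype")),
    modifiers = canonical_df(modifiers, c("drug", "gene")),
    ddi = canonical_df(ddi, c("drug1", "drug2", "drug3")),
    prevalence = if (!is.null(prevalence)) as_prevalence(prevalence)
  ), class = "pip_kb")

  problems <- validate_kb(kb)
  if (length(problems)) {
    stopf("invalid knowledge base:\n%s", paste("-", problems, collapse = "\n"))
  }
  kb
}

#' @describeIn pip_kb gene symbols of a knowledge base.
#' @param kb a `pip_kb` object.
#' @export
kb_genes <- function(kb) kb$genes$gene

#' @describeIn pip_kb drug names of a knowledge base.
#' @export
kb_drugs <- function(kb) kb$drugs$drug

#' Validate a knowledge base
#'
#' Checks referential integrity (every rule cites an existing drug and gene,
#' every phenotype is in its gene's vocabulary), vocabulary validity of
#' severities, AUC categories, evidence sources, clinical areas and modifier
#' actions, rule-key uniqueness, and -- when a prevalence table is embedded --
#' that each gene's frequencies are non-negative and sum to one.
#'
#' @param kb a `pip_kb` object.
#' @return character vector of diagnostics; empty when the KB is valid.
#' @export
validate_kb <- function(kb) {
  p <- character()
  note <- function(fmt, ...) p <<- c(p, sprintf(fmt, ...))

  genes <- kb$genes; drugs <- kb$drugs; rules <- kb$rules
  if (anyDuplicated(genes$gene)) note("duplicated gene symbols: %s",
    paste(unique(genes$gene[duplicated(genes$gene)]), collapse = ", "))
  if (anyDuplicated(drugs$drug)) note("duplicated drug names: %s",
    paste(unique(drugs$drug[duplicated(drugs$drug)]), collapse = ", "))

  bad_area <- setdiff(unique(drugs$clinical_area), clinical_areas())
  if (length(bad_area)) note("unknown clinical area(s): %s", paste(bad_area, collapse = ", "))

  vocab <- stats::setNames(genes$phenotypes, genes$gene)
  for (i in seq_len(nrow(genes))) {
    if (!genes$reference[i] %in% genes$phenotypes[[i]]) {
      note("gene %s: reference phenotype '%s' not in its vocabulary",
           genes$gene[i], genes$reference[i])
    }
  }

  check_ref <- function(what, vals, universe) {
    miss <- setdiff(unique(stats::na.omit(vals)), universe)
    if (length(miss)) note("%s reference(s) not in knowledge base: %s",
                           what, paste(miss, collapse = ", "))
  }
  check_ref("rule drug", rules$drug, drugs$drug)
  check_ref("rule gene", c(rules$gene, rules$second_gene), genes$gene)
  check_ref("modifier drug", kb$modifiers$drug, drugs$drug)
  check_ref("modifier gene", kb$modifiers$gene, genes$gene)
  check_ref("drug-drug rule drug",
            c(kb$ddi$drug1, kb$ddi$drug2, kb$ddi$drug3), drugs$drug)

  for (i in seq_len(nrow(rules))) {
    g <- rules$gene[i]
    if (g %in% names(vocab) && !rules$phenotype[i] %in% vocab[[g]]) {
      note("rule %s/%s: phenotype '%s' not in vocabulary of %s",
           rules$drug[i], g, rules$phenotype[i], g)
    }
    g2 <- rules$second_gene[i]
    if (!is.na(g2)) {
      if (is.na(rules$second_phenotype[i])) {
        note("rule %s/%s: second_gene without second_phenotype", rules$drug[i], g)
      } else if (g2 %in% names(vocab) && !rules$second_phenotype[i] %in% vocab[[g2]]) {
        note("rule %s/%s: phenotype '%s' not in vocabulary of %s",
             rules$drug[i], g2, rules$second_phenotype[i], g2)
      }
    }
  }

  bad <- setdiff(unique(rules$severity), severity_levels())
  if (length(bad)) note("unknown rule severity label(s): %s", paste(bad, collapse = ", "))
  bad <- setdiff(unique(kb$ddi$severity), severity_levels())
  if (length(bad)) note("unknown drug-drug severity label(s): %s", paste(bad, collapse = ", "))
  bad <- setdiff(unique(rules$auc_change), auc_categories())
  if (length(bad)) note("unknown AUC category label(s): %s", paste(bad, collapse = ", "))
  bad <- setdiff(unique(rules$evidence), evidence_sources())
  if (length(bad)) note("unknown evidence source(s): %s", paste(bad, collapse = ", "))
  bad <- setdiff(unique(kb$modifiers$action), c("inhibitor", "inducer"))
  if (length(bad)) note("unknown modifier action(s): %s", paste(bad, collapse = ", "))
  if (nrow(kb$modifiers) && any(is.na(kb$modifiers$strength) |
                                kb$modifiers$strength < 1L |
                                kb$modifiers$strength > 4L)) {
    note("modifier strength out of range 1..4")
  }

  key <- with(rules, paste(drug, gene, phenotype, second_gene, second_phenotype))
  if (anyDuplicated(key)) note("duplicated rule key(s): %s",
    paste(unique(key[duplicated(key)]), collapse = "; "))

  if (!is.null(kb$prevalence)) {
    prev <- kb$prevalence
    check_ref("prevalence gene", names(prev), genes$gene)
    for (g in intersect(names(prev), genes$gene)) {
      ph <- names(prev[[g]])
      miss <- setdiff(ph, vocab[[g]])
      if (length(miss)) note("prevalence for %s cites phenotype(s) outside vocabulary: %s",
                             g, paste(miss, collapse = ", "))
      if (any(prev[[g]] < 0)) note("prevalence for %s has negative frequencies", g)
      if (abs(sum(prev[[g]]) - 1) > 1e-9) {
        note("prevalence for %s sums to %.12f, not 1", g, sum(prev[[g]]))
      }
    }
  }
  p
}

#' Phenotype prevalence table
#'
#' Per-gene probability distributions over interpreted phenotypes (population
#' prevalences). Accepts either a named list of named numeric vectors
#' (`list(CYP2D6 = c(poor = 0.06, ...))`) or a long data frame with columns
#' `gene`, `phenotype`, `frequency`. Frequencies per gene must be
#' non-negative and sum to 1 (tolerance 1e-9).
#'
#' @param x prevalence input as described above.
#' @return an object of class `pip_prevalence` (named list of named numeric
#'   vectors).
#' @export
#' @examples
#' as_prevalence(data.frame(gene = "CYP2D6",
#'                          phenotype = c("poor", "normal"),
#'                          frequency = c(0.1, 0.9)))
as_prevalence <- function(x) {
  if (inherits(x, "pip_prevalence")) return(x)
  if (is.data.frame(x)) {
    stopifnot(all(c("gene", "phenotype", "frequency") %in% names(x)))
    x <- lapply(split(x, x$gene), function(d) stats::setNames(d$frequency, d$phenotype))
  }
  if (!is.list(x) || is.null(names(x))) stopf("prevalence must be a named list or long data frame")
  for (g in names(x)) {
    v <- x[[g]]
    if (!is.numeric(v) || is.null(names(v))) stopf("prevalence for %s must be a named numeric vector", g)
    if (any(v < 0)) stopf("prevalence for %s has negative frequencies", g)
    if (abs(sum(v) - 1) > 1e-9) stopf("prevalence for %s sums to %.12f, not 1", g, sum(v))
    x[[g]] <- v
  }
  structure(x[order(names(x))], class = "pip_prevalence")
}

#' Read a knowledge base file
#'
#' Reads a `pip-kb/1` JSON document (see [save_kb()] for the layout). The
#' file is parsed, rebuilt into component tables and fully validated; a
#' malformed document raises a parse error naming the file, and dangling
#' drug/gene references raise a validation error listing every offender.
#'
#' @param path path of a knowledge-base JSON file.
#' @return a `pip_kb` object; an embedded prevalence section is available as
#'   `kb$prevalence`.
#' @export
load_kb <- function(path) {
  if (!file.exists(path)) stopf("knowledge base file not found: %s", path)
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stopf("parse error in %s: %s", path, conditionMessage(e)))
  if (!identical(doc$version, "pip-kb/1")) {
    stopf("%s: unsupported or missing schema version (want \"pip-kb/1\")", path)
  }
  fld <- function(rec, name, default = NA) rec[[name]] %||% default

  genes <- if (length(doc$genes)) {
    g <- do.call(rbind, lapply(doc$genes, function(g) {
      data.frame(gene = g$gene, reference = g$reference, stringsAsFactors = FALSE)
    }))
    g$phenotypes <- lapply(doc$genes, function(g) as.character(unlist(g$phenotypes)))
    g
  } else {
    g <- data.frame(gene = character(), reference = character(),
                    stringsAsFactors = FALSE)
    g$phenotypes <- list()
    g
  }

  drugs <- if (length(doc$drugs)) {
    do.call(rbind, lapply(doc$drugs, function(d) {
      data.frame(drug = d$drug, clinical_area = d$clinical_area,
                 prodrug = isTRUE(d$prodrug), stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(drug = character(), clinical_area = character(),
               prodrug = logical(), stringsAsFactors = FALSE)
  }

  rules <- if (length(doc$rules)) {
    do.call(rbind, lapply(doc$rules, function(r) {
      data.frame(drug = r$drug, gene = r$gene, phenotype = r$phenotype,
                 second_gene = as.character(fld(r, "second_gene")),
                 second_phenotype = as.character(fld(r, "second_phenotype")),
                 severity = r$severity, auc_change = r$auc_change,
                 evidence = r$evidence, stringsAsFactors = FALSE)
    }))
  } else empty_rules()

  modifiers <- if (length(doc$modifiers)) {
    do.call(rbind, lapply(doc$modifiers, function(m) {
      data.frame(drug = m$drug, gene = m$gene, action = m$action,
                 strength = as.integer(m$strength), stringsAsFactors = FALSE)
    }))
  } else empty_modifiers()

  ddi <- if (length(doc$ddi)) {
    do.call(rbind, lapply(doc$ddi, function(d) {
      dr <- as.character(unlist(d$drugs))
      data.frame(drug1 = dr[1], drug2 = dr[2],
                 drug3 = if (length(dr) >= 3) dr[3] else NA_character_,
                 severity = d$severity, stringsAsFactors = FALSE)
    }))
  } else empty_ddi()

  prevalence <- if (length(doc$prevalence)) {
    as_prevalence(lapply(doc$prevalence, function(v) unlist(v)))
  }

  pip_kb(genes, drugs, rules, modifiers, ddi, prevalence)
}

#' Write a knowledge base file
#'
#' Emits the canonical `pip-kb/1` JSON document: UTF-8, two-space pretty
#' printing, sections `version` / `genes` / `drugs` / `rules` / `modifiers` /
#' `ddi` / `prevalence`, each deterministically ordered (drugs, genes,
#' rules sorted by drug, gene, phenotype). Two saves of the same knowledge
#' base are byte-identical, and `load_kb(save_kb(kb))` reproduces `kb`.
#'
#' @param kb a `pip_kb` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_kb <- function(kb, path) {
  stopifnot(inherits(kb, "pip_kb"))
  drop_na <- function(x) x[!vapply(x, function(v) is.null(v) ||
                                     (length(v) == 1 && is.na(v)), logical(1))]
  doc <- list(
    version = "pip-kb/1",
    genes = lapply(seq_len(nrow(kb$genes)), function(i) list(
      gene = kb$genes$gene[i],
      reference = kb$genes$reference[i],
      phenotypes = as.list(kb$genes$phenotypes[[i]])
    )),
    drugs = lapply(seq_len(nrow(kb$drugs)), function(i) list(
      drug = kb$drugs$drug[i],
      clinical_area = kb$drugs$clinical_area[i],
      prodrug = kb$drugs$prodrug[i]
    )),
    rules = lapply(seq_len(nrow(kb$rules)), function(i) drop_na(list(
      drug = kb$rules$drug[i], gene = kb$rules$gene[i],
      phenotype = kb$rules$phenotype[i],
      second_gene = kb$rules$second_gene[i],
      second_phenotype = kb$rules$second_phenotype[i],
      severity = kb$rules$severity[i], auc_change = kb$rules$auc_change[i],
      evidence = kb$rules$evidence[i]
    ))),
    modifiers = lapply(seq_len(nrow(kb$modifiers)), function(i) list(
      drug = kb$modifiers$drug[i], gene = kb$modifiers$gene[i],
      action = kb$modifiers$action[i], strength = kb$modifiers$strength[i]
    )),
    ddi = lapply(seq_len(nrow(kb$ddi)), function(i) list(
      drugs = as.list(stats::na.omit(unlist(kb$ddi[i, c("drug1", "drug2", "drug3")],
                                            use.names = FALSE))),
      severity = kb$ddi$severity[i]
    ))
  )
  if (!is.null(kb$prevalence)) {
    doc$prevalence <- lapply(kb$prevalence, as.list)
  }
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = 2, digits = NA)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' @export
print.pip_kb <- function(x, ...) {
  cat(sprintf("<pip_kb %s>: %d genes, %d drugs, %d interaction rules, %d modifiers, %d drug-drug rules%s\n",
              x$version, nrow(x$genes), nrow(x$drugs), nrow(x$rules),
              nrow(x$modifiers), nrow(x$ddi),
              if (is.null(x$prevalence)) "" else
                sprintf(", prevalence for %d genes", length(x$prevalence))))
  invisible(x)
}
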