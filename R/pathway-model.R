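# The pathway model assigns each gene a sign per metabolite: +1 where the
# gene product is inferred beneficial to that metabolic output, -1 where it
# competes with / is detrimental to it. Genes without a sign for a
# metabolite contribute nothing to that metabolite's score. Every signed
# gene carries a cytoplasmic or mitochondrial compartment tag so scores can
# be restricted by compartment.

#' Construct a pathway model
#'
#' @param table data.frame with columns `metabolite`, `gene`, `sign`
#'   (`"+"`/`"-"` or `+1`/`-1`) and `compartment`
#'   (`"cytoplasmic"`/`"mitochondrial"`, abbreviations `cyto`/`mito`
#'   accepted).
#' @return object of class `pathway_model`: a validated data.frame with
#'   numeric `sign` in `{-1, +1}`.
#' @seealso [default_pathway_model()] for the shipped folate/one-carbon
#'   designations, [read_pathway_model()] for file input.
#' @export
pathway_model <- function(table) {
  need <- c("metabolite", "gene", "sign", "compartment")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("pathway model is missing columns: ",
                         paste(miss, collapse = ", "))
  sgn <- as.character(table$sign)
  num <- ifelse(sgn %in% c("+", "+1", "1"), 1,
         ifelse(sgn %in% c("-", "-1"), -1, NA_real_))
  if (anyNA(num))
    stop("sign tokens must be '+' or '-': offending gene(s) ",
         paste(table$gene[is.na(num)], collapse = ", "))
  comp <- c(cyto = "cytoplasmic", cytoplasmic = "cytoplasmic",
            mito = "mitochondrial", mitochondrial = "mitochondrial")[
              as.character(table$compartment)]
  if (anyNA(comp))
    stop("compartment must be 'cytoplasmic' or 'mitochondrial': offending gene(s) ",
         paste(table$gene[is.na(comp)], collapse = ", "))
  out <- data.frame(metabolite = as.character(table$metabolite),
                    gene = as.character(table$gene),
                    sign = num, compartment = unname(comp),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out[, c("metabolite", "gene")]))
    stop("duplicate (metabolite, gene) rows in pathway model")
  class(out) <- c("pathway_model", "data.frame")
  out
}

#' Default folate/one-carbon pathway designations
#'
#' The shipped model covers three metabolic outputs of the folate pathway.
#'
#' * **purine** synthesis: genes feeding mitochondrial formate production
#'   (MTHFD2, SHMT2, AMT, SARDH, DMGDH) and its cytoplasmic incorporation
#'   into 10-formyl-THF and purines (MTHFD1, ATIC, GART) are beneficial
#'   (`+`); genes competing for formate or 10-formyl-THF or for the
#'   cytoplasmic THF pool (MTFMT, ALDH1L2, ALDH1L1, SHMT1) are
#'   detrimental (`-`).
#' * **homocysteine** level: every purine-set gene with the opposite sign
#'   (reduced one-carbon flux lowers purine output but raises homocysteine),
#'   plus the methionine-cycle genes BHMT, BHMT2, MTHFR, MTR, MTRR and the
#'   trans-sulfuration genes CBS, CTH signed `-` (their activity consumes
#'   homocysteine). MAT1A/MAT2A are excluded: AdoMet synthesis has no major
#'   direct effect on homocysteine level.
#' * **thymidylate** synthesis: the nuclear dTMP module SHMT1, TYMS, DHFR
#'   signed `+`; MTHFR signed `-` (competes with TYMS for methylene-THF);
#'   MTR, MTRR, MAT1A, MAT2A signed `+` (AdoMet-mediated inhibition of
#'   MTHFR frees methylene-THF for TYMS).
#'
#' @return a [pathway_model()].
#' @export
default_pathway_model <- function() {
  rows <- rbind(
    # purine synthesis
    cbind("purine", c("MTHFD1", "ATIC", "GART"),                     "+", "cyto"),
    cbind("purine", c("MTHFD2", "SHMT2", "AMT", "SARDH", "DMGDH"),   "+", "mito"),
    cbind("purine", c("ALDH1L1", "SHMT1"),                           "-", "cyto"),
    cbind("purine", c("MTFMT", "ALDH1L2"),                           "-", "mito"),
    # homocysteine level: purine genes sign-reversed ...
    cbind("homocysteine", c("MTHFD1", "ATIC", "GART"),                   "-", "cyto"),
    cbind("homocysteine", c("MTHFD2", "SHMT2", "AMT", "SARDH", "DMGDH"), "-", "mito"),
    cbind("homocysteine", c("ALDH1L1", "SHMT1"),                         "+", "cyto"),
    cbind("homocysteine", c("MTFMT", "ALDH1L2"),                         "+", "mito"),
    # ... plus methionine-cycle and trans-sulfuration genes (MAT1A/MAT2A excluded)
    cbind("homocysteine",
          c("BHMT", "BHMT2", "MTHFR", "MTR", "MTRR", "CBS", "CTH"),      "-", "cyto"),
    # thymidylate synthesis
    cbind("thymidylate", c("SHMT1", "TYMS", "DHFR", "MTR", "MTRR",
                           "MAT1A", "MAT2A"),                            "+", "cyto"),
    cbind("thymidylate", "MTHFR",                                        "-", "cyto")
  )
  pathway_model(data.frame(metabolite = rows[, 1], gene = rows[, 2],
                           sign = rows[, 3], compartment = rows[, 4],
                           stringsAsFactors = FALSE))
}

#' Read a pathway model from YAML or TSV
#'
#' TSV columns: `metabolite`, `gene`, `sign` (`+`|`-`), `compartment`
#' (`cyto`|`mito` or full names). YAML layout:
#' ```yaml
#' purine:
#'   - {gene: MTHFD1, sign: "+", compartment: cyto}
#' ```
#'
#' @param path file path (`.yml`/`.yaml` parsed as YAML, otherwise TSV).
#' @return a [pathway_model()].
#' @export
read_pathway_model <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    y <- yaml::read_yaml(path)
    rows <- do.call(rbind, lapply(names(y), function(met) {
      do.call(rbind, lapply(y[[met]], function(e) {
        data.frame(metabolite = met, gene = e$gene, sign = as.character(e$sign),
                   compartment = e$compartment, stringsAsFactors = FALSE)
      }))
    }))
    pathway_model(rows)
  } else {
    pathway_model(utils::read.delim(path, stringsAsFactors = FALSE,
                                    colClasses = "character"))
  }
}

#' Write a pathway model as TSV
#' @param model a [pathway_model()].
#' @param path output path.
#' @export
write_pathway_model <- function(model, path) {
  tab <- as.data.frame(model)
  tab$sign <- ifelse(tab$sign > 0, "+", "-")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-gene signs for one metabolite
#'
#' @param model a [pathway_model()].
#' @param metabolite metabolite name present in the model.
#' @param compartment `"all"`, `"cytoplasmic"` or `"mitochondrial"`; genes
#'   outside the chosen compartment are dropped.
#' @return named numeric vector of signs in `{-1, +1}`.
#' @export
pathway_signs <- function(model, metabolite,
                          compartment = c("all", "cytoplasmic", "mitochondrial")) {
  compartment <- match.arg(compartment)
  if (!metabolite %in% model$metabolite)
    stop("metabolite '", metabolite, "' absent from pathway model")
  sub <- model[model$metabolite == metabolite, , drop = FALSE]
  if (compartment != "all")
    sub <- sub[sub$compartment == compartment, , drop = FALSE]
  stats::setNames(sub$sign, sub$gene)
}

#' @export
print.pathway_model <- function(x, ...) {
  cat("Pathway model:", length(unique(x$metabolite)), "metabolite(s),",
      length(unique(x$gene)), "gene(s)\n")
  for (met in unique(x$metabolite)) {
    s <- x[x$metabolite == met, ]
    cat(sprintf("  %-13s +{%s}  -{%s}\n", met,
                paste(s$gene[s$sign > 0], collapse = ","),
                paste(s$gene[s$sign < 0], collapse = ",")))
  }
  invisible(x)
}
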