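#' @include massChem.R
NULL

## Downstream annotation: hypergeometric over-representation analysis
## with BH-FDR binning, and two-source ortholog agreement accounting.

#' Read a GMT term-collection file
#'
#' Standard tab-separated GMT: term id, description, then one gene per
#' field. Duplicate gene entries within a term are collapsed; a duplicate
#' term id is an error.
#'
#' @param path GMT file.
#' @return data.frame with columns `term_id`, `term_name`, `namespace`
#'   (`NA` unless encoded as a `namespace:rest` prefix of the id) and a
#'   list-column `genes`.
#' @export
readGMT <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, integer(1)) < 3)
  if (length(short))
    stop("GMT line ", short[1], " has fewer than 3 fields")
  ids <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(ids))
    stop("duplicate term id: ", ids[duplicated(ids)][1])
  out <- data.frame(term_id = ids,
                    term_name = vapply(fields, `[[`, character(1), 2),
                    stringsAsFactors = FALSE)
  out$genes <- lapply(fields, function(f) unique(f[-(1:2)]))
  out
}

#' Hypergeometric over-representation analysis
#'
#' For every term, the probability of observing at least the seen overlap
#' between the query and the term's genes when drawing `|query|` genes
#' from the background without replacement (upper hypergeometric tail via
#' `stats::phyper`). P-values are adjusted across all tested terms by
#' Benjamini-Hochberg, and each adjusted value is binned at the three
#' conventional reporting thresholds (< 0.01, < 0.001, < 1e-4).
#'
#' @param query character vector of gene identifiers; must be non-empty
#'   and a subset of the background.
#' @param terms a term collection from [readGMT()] (data.frame with
#'   `term_id`, `term_name`, list-column `genes`).
#' @param background character vector; defaults to the union of all genes
#'   in `terms`. Term gene sets are intersected with it before testing,
#'   and terms with no background overlap are skipped with a message.
#' @return data.frame sorted by `fdr` then `term_id`: `term_id`,
#'   `term_name`, `term_size` (in background), `overlap`, `p_value`,
#'   `fdr`, `fdr_bin` (one of `"<1e-4"`, `"<0.001"`, `"<0.01"`, `"ns"`).
#' @export
enrich <- function(query, terms, background = NULL) {
  query <- unique(query)
  if (!length(query)) stop("query gene set is empty")
  if (is.null(background)) background <- unique(unlist(terms$genes))
  background <- unique(background)
  if (!all(query %in% background))
    stop("query contains gene(s) outside the background: ",
         paste(utils::head(setdiff(query, background), 3), collapse = ", "))
  N <- length(background)
  k <- length(query)
  rows <- lapply(seq_len(nrow(terms)), function(i) {
    genes <- intersect(terms$genes[[i]], background)
    if (!length(genes)) {
      message("term ", terms$term_id[i], " has no background overlap; skipped")
      return(NULL)
    }
    m <- length(genes)
    x <- length(intersect(query, genes))
    p <- stats::phyper(x - 1, m, N - m, k, lower.tail = FALSE)
    data.frame(term_id = terms$term_id[i], term_name = terms$term_name[i],
               term_size = m, overlap = x, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no term overlaps the background")
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out$fdr_bin <- fdrBin(out$fdr)
  out <- out[order(out$fdr, out$term_id), ]
  rownames(out) <- NULL
  out
}

#' Bin adjusted FDR values at the conventional reporting thresholds
#'
#' @param fdr numeric vector in `[0, 1]`.
#' @return character vector with levels `"<1e-4"`, `"<0.001"`, `"<0.01"`,
#'   `"ns"`.
#' @export
fdrBin <- function(fdr) {
  ifelse(fdr < 1e-4, "<1e-4",
         ifelse(fdr < 1e-3, "<0.001",
                ifelse(fdr < 1e-2, "<0.01", "ns")))
}

#' Read an ortholog-mapping table
#'
#' CSV with columns `worm_gene` and `human_ortholog` (empty or `NA` for
#' "no ortholog"); the source label is attached to every row so tables
#' from different databases can be combined with `rbind`.
#'
#' @param path CSV file.
#' @param source label for the mapping source (e.g. `"UniProt"`).
#' @return data.frame with columns `worm_gene`, `source`, `human_ortholog`.
#' @export
readOrthologTable <- function(path, source) {
  stopifnot(file.exists(path))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("worm_gene", "human_ortholog")
  missing <- setdiff(need, colnames(tab))
  if (length(missing))
    stop("ortholog table lacks column(s): ", paste(missing, collapse = ", "))
  ho <- as.character(tab$human_ortholog)
  ho[!is.na(ho) & !nzchar(trimws(ho))] <- NA_character_
  data.frame(worm_gene = as.character(tab$worm_gene),
             source = source, human_ortholog = ho,
             stringsAsFactors = FALSE)
}

#' Two-source ortholog agreement summary
#'
#' Given explicit per-source mapping records (absence encoded as an `NA`
#' ortholog, not a missing row), tabulates per-source ortholog counts, the
#' both-sources and neither-source counts, and the percentage of query
#' genes with an ortholog in at least one source.
#'
#' @param records data.frame with columns `worm_gene`, `source`,
#'   `human_ortholog` (`NA` = no ortholog). Every gene must appear once
#'   per source; a duplicate (gene, source) pair or a gene missing from a
#'   source is an error.
#' @return list: `nGenes`, `perSource` (named counts), `both`, `neither`,
#'   `atLeastOne`, `pctAtLeastOne` (0-100).
#' @export
orthologAgreement <- function(records) {
  stopifnot(all(c("worm_gene", "source", "human_ortholog") %in%
                colnames(records)))
  key <- paste(records$worm_gene, records$source, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (gene, source) row: ",
         sub("\r", " / ", key[duplicated(key)][1]))
  genes <- unique(records$worm_gene)
  sources <- unique(records$source)
  if (length(sources) < 1) stop("no sources in records")
  for (s in sources) {
    absent <- setdiff(genes, records$worm_gene[records$source == s])
    if (length(absent))
      stop("gene(s) missing from source ", s, ": ",
           paste(utils::head(absent, 3), collapse = ", "),
           " (encode absence of an ortholog explicitly as NA)")
  }
  mapped <- !is.na(records$human_ortholog)
  perSource <- vapply(sources, function(s)
    sum(mapped[records$source == s]), integer(1))
  names(perSource) <- sources
  byGene <- vapply(genes, function(g)
    sum(mapped[records$worm_gene == g]), integer(1))
  both <- sum(byGene == length(sources))
  neither <- sum(byGene == 0)
  atLeastOne <- sum(byGene > 0)
  list(nGenes = length(genes), perSource = perSource, both = both,
       neither = neither, atLeastOne = atLeastOne,
       pctAtLeastOne = 100 * atLeastOne / length(genes))
}
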