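#' The five gene-ranking measures
#'
#' Genes are ranked per disease by one of: 1) the number of abstracts
#' supporting the disease-gene relation, 2) the number of evidence
#' sentences, 3) the highest normalized evidence score, 4) the sum of
#' normalized scores, 5) the mean of normalized scores.
#'
#' @return character vector of the measure names.
#' @export
rankingMeasures <- function() {
  c("n_abstracts", "n_sentences", "max_score", "sum_norm", "mean_norm")
}

#' Summarize scored evidence per gene for one disease
#'
#' Aggregates scored evidence triples into one summary row per gene.
#' Abstracts are counted as distinct `doc_id`s and sentences as distinct
#' `(doc_id, sid)` pairs: several triples for the same gene in one sentence
#' (e.g. different event types) count that sentence once, scored by the
#' maximum of its triples' normalized scores.
#'
#' @param evidence data.frame of scored evidence with columns gene, disease,
#'   etype, doc_id, sid, norm_score (e.g. triples from [assembleTriples()]
#'   joined with [scoreEvidence()] output)
#' @param disease the disease id to summarize (rows for other diseases are
#'   dropped)
#' @return data.frame with columns disease, gene, n_abstracts, n_sentences,
#'   max_score, sum_norm, mean_norm.
#' @export
summarizeGeneEvidence <- function(evidence, disease) {
  evidence <- as.data.frame(evidence, stringsAsFactors = FALSE)
  evidence <- evidence[evidence$disease == disease, , drop = FALSE]
  if (nrow(evidence) == 0)
    return(data.frame(disease = character(), gene = character(),
                      n_abstracts = integer(), n_sentences = integer(),
                      max_score = numeric(), sum_norm = numeric(),
                      mean_norm = numeric(), stringsAsFactors = FALSE))
  # one row per (gene, doc, sentence): dedup triples within a sentence
  key <- interaction(evidence$gene, evidence$doc_id, evidence$sid,
                     drop = TRUE)
  perSentence <- data.frame(
    gene = tapply(evidence$gene, key, `[`, 1),
    doc_id = tapply(evidence$doc_id, key, `[`, 1),
    norm_score = as.numeric(tapply(evidence$norm_score, key, max)),
    stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(split(perSentence, perSentence$gene),
    function(g) data.frame(
      disease = disease, gene = g$gene[1],
      n_abstracts = length(unique(g$doc_id)),
      n_sentences = nrow(g),
      max_score = max(g$norm_score),
      sum_norm = sum(g$norm_score),
      mean_norm = mean(g$norm_score),
      stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Rank genes by one of the five measures
#'
#' Orders genes by the chosen measure, descending. Ties on the measure value
#' are broken by the number of evidence sentences (descending), then by gene
#' id (lexicographic); tied measure values share the minimum rank.
#'
#' @param summaries data.frame from [summarizeGeneEvidence()]
#' @param measure one of [rankingMeasures()]
#' @return `summaries` reordered, with columns `measure`, `value` and `rank`
#'   prepended after disease/gene.
#' @export
rankGenes <- function(summaries, measure = "n_sentences") {
  if (!measure %in% rankingMeasures())
    stop("unknown measure '", measure, "'; valid measures: ",
         paste(rankingMeasures(), collapse = ", "))
  stopifnot(nrow(summaries) > 0)
  value <- summaries[[measure]]
  ord <- order(-value, -summaries$n_sentences, summaries$gene)
  out <- summaries[ord, , drop = FALSE]
  v <- value[ord]
  # min-rank for ties on the measure value
  rk <- integer(length(v))
  for (i in seq_along(v)) rk[i] <- which(v == v[i])[1]
  out <- cbind(out[c("disease", "gene")],
               data.frame(rank = rk, measure = measure, value = v,
                          stringsAsFactors = FALSE),
               out[setdiff(names(out), c("disease", "gene"))])
  rownames(out) <- NULL
  out
}

#' Filter scored evidence by a normalized-score threshold
#'
#' Keeps evidence rows with `norm_score >= t`, preserving order. Because
#' normalized scores lie strictly inside (0, 1), `t = 0` is the identity and
#' `t = 1` empties the list.
#'
#' @param evidence data.frame with a `norm_score` column
#' @param t threshold in \[0, 1\]
#' @return the filtered data.frame.
#' @export
filterEvidenceByThreshold <- function(evidence, t) {
  stopifnot(t >= 0, t <= 1)
  out <- evidence[evidence$norm_score >= t, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a per-disease gene ranking as TSV
#'
#' @param ranking data.frame from [rankGenes()]
#' @param path output path
#' @return `path`, invisibly.
#' @export
writeGeneRanking <- function(ranking, path) {
  cols <- c("disease", "gene", "rank", "measure", "value", "n_abstracts",
            "n_sentences", "max_score", "sum_norm", "mean_norm")
  utils::write.table(ranking[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
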