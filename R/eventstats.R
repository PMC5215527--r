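#' Per-disease distribution of biological event types
#'
#' Counts evidence sentences by (disease, event type), deduplicating by
#' `(doc_id, sid, etype, disease)` so that one sentence supports a given
#' event type for a disease at most once, and converts counts to
#' within-disease ratios (summing to 1).
#'
#' @param triples data.frame of evidence triples with columns disease,
#'   etype, doc_id, sid (e.g. from [assembleTriples()])
#' @return data.frame with columns disease, etype, count, ratio; every
#'   disease covers all 15 [eventTypes()] (zero-count rows included).
#' @export
perDiseaseEventRatios <- function(triples) {
  stopifnot(nrow(triples) > 0)
  dedup <- unique(triples[c("disease", "etype", "doc_id", "sid")])
  tab <- table(factor(dedup$disease),
               factor(dedup$etype, levels = eventTypes()))
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("disease", "etype", "count")
  totals <- tapply(out$count, out$disease, sum)
  out$ratio <- out$count / as.numeric(totals[out$disease])
  out <- out[order(out$disease, match(out$etype, eventTypes())), ]
  rownames(out) <- NULL
  out
}

#' Classify diseases enriched for one event type (mu + 1 sigma rule)
#'
#' A disease is enriched for an event type when its ratio of evidence
#' sentences of that type exceeds the across-disease mean plus one standard
#' deviation of those ratios. Mutation-enriched and gene-expression-enriched
#' diseases are the two cases of interest.
#'
#' @param dists data.frame from [perDiseaseEventRatios()]
#' @param etype the event type to test
#' @param sampleSd use the sample (n-1) standard deviation instead of the
#'   population one
#' @return list with `labels` (data.frame disease, ratio, enriched),
#'   `mu`, `sigma`, `threshold`.
#' @export
classifyEventEnrichment <- function(dists, etype, sampleSd = FALSE) {
  stopifnot(etype %in% eventTypes())
  d <- dists[dists$etype == etype, , drop = FALSE]
  if (nrow(d) < 2)
    stop("at least 2 diseases are required for enrichment classification")
  mu <- mean(d$ratio)
  sigma <- if (sampleSd) stats::sd(d$ratio)
           else sqrt(mean((d$ratio - mu)^2))
  threshold <- mu + sigma
  labels <- data.frame(disease = d$disease, ratio = d$ratio,
                       enriched = d$ratio > threshold,
                       stringsAsFactors = FALSE)
  rownames(labels) <- NULL
  list(labels = labels, mu = mu, sigma = sigma, threshold = threshold)
}

#' Compare a gene attribute between two disease groups
#'
#' Compares a per-gene attribute between the genes of two disease groups
#' (e.g. network degree of genes of mutation-enriched vs
#' expression-enriched diseases, or a transcription-factor flag). A
#' real-valued attribute is compared with a two-sided Mann-Whitney rank test
#' and a binary flag with Fisher's exact test on the 2x2 table. Degenerate
#' input (all values tied) yields p = 1 with a warning.
#'
#' @param valuesA,valuesB attribute values for the two groups: numeric
#'   vectors, or logical vectors for a binary flag
#' @param type "numeric" (Mann-Whitney) or "binary" (Fisher exact);
#'   guessed from the input when omitted
#' @return list with `test`, `statistic`, `p_value`, and group summaries.
#' @export
compareGroupAttribute <- function(valuesA, valuesB, type = NULL) {
  stopifnot(length(valuesA) > 0, length(valuesB) > 0)
  if (is.null(type))
    type <- if (is.logical(valuesA) && is.logical(valuesB)) "binary"
            else "numeric"
  if (type == "binary") {
    tab <- rbind(A = c(sum(valuesA), sum(!valuesA)),
                 B = c(sum(valuesB), sum(!valuesB)))
    if (sum(tab[, 1]) == 0 || sum(tab[, 2]) == 0) {
      warning("degenerate binary attribute (all identical); p = 1")
      return(list(test = "fisher_exact", statistic = NA_real_, p_value = 1,
                  table = tab))
    }
    ft <- stats::fisher.test(tab)
    list(test = "fisher_exact", statistic = unname(ft$estimate),
         p_value = ft$p.value, table = tab)
  } else {
    if (length(unique(c(valuesA, valuesB))) == 1) {
      warning("degenerate attribute (all values tied); p = 1")
      return(list(test = "mann_whitney", statistic = NA_real_, p_value = 1,
                  median_A = stats::median(valuesA),
                  median_B = stats::median(valuesB)))
    }
    wt <- suppressWarnings(stats::wilcox.test(valuesA, valuesB,
                                              alternative = "two.sided"))
    list(test = "mann_whitney", statistic = unname(wt$statistic),
         p_value = wt$p.value,
         median_A = stats::median(valuesA),
         median_B = stats::median(valuesB))
  }
}

#' Write per-disease event statistics as TSV
#'
#' Joins the per-disease event distribution with mutation/expression
#' enrichment labels.
#'
#' @param dists data.frame from [perDiseaseEventRatios()]
#' @param path output path
#' @return the written data.frame, invisibly.
#' @export
writeEventStats <- function(dists, path) {
  mut <- classifyEventEnrichment(dists, "mutation")$labels
  expr <- classifyEventEnrichment(dists, "gene_expression")$labels
  out <- dists
  out$enriched_mutation <- mut$enriched[match(out$disease, mut$disease)]
  out$enriched_expression <- expr$enriched[match(out$disease, expr$disease)]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
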