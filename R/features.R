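#' @keywords internal
tokenizeWS <- function(text) {
  toks <- strsplit(text, "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

binCount <- function(n) {
  if (n >= 3) "3+" else as.character(n)
}

# tokens strictly between two character spans (0-based half-open);
# 0 when spans touch or overlap
tokenDistance <- function(text, span1, span2) {
  lo <- min(span1[2], span2[2])
  hi <- max(span1[1], span2[1])
  if (hi <= lo) return(0L)
  between <- substring(text, lo + 1L, hi)
  length(tokenizeWS(between))
}

countKeywordHits <- function(text, keywords) {
  if (length(keywords) == 0) return(0L)
  toks <- tolower(gsub("^[[:punct:]]+|[[:punct:]]+$", "", tokenizeWS(text)))
  sum(toks %in% tolower(keywords))
}

#' Default negation cue list
#' @return character vector of negation cue tokens
#' @export
negationCues <- function() {
  c("no", "not", "without", "absent", "lack", "neither", "nor")
}

#' Extract the discrete feature vector of one evidence candidate
#'
#' Features of one (sentence, triple) pair used by the naive Bayes evidence
#' classifier. The two keyword-count features follow the disease-independent
#' keyword-expansion approach (lists built by [expandKeywords()], or any
#' other source); the remainder are surface features of the sentence:
#'
#' \describe{
#'   \item{disease_keyword_count_bin}{whole-token, case-insensitive hits of
#'     the disease keyword list, binned 0/1/2/3+}
#'   \item{hallmark_keyword_count_bin}{same for the hallmark keyword list}
#'   \item{gene_event_token_distance_bin}{whitespace tokens between the
#'     nearest boundaries of the theme gene mention and the event trigger,
#'     binned 0/1/2/3+}
#'   \item{disease_event_token_distance_bin}{same for the disease mention}
#'   \item{etype}{the triple's event type (categorical over the 15 types)}
#'   \item{negation_cue}{"1" if any negation cue token occurs, else "0"}
#'   \item{gene_mention_count_bin}{number of gene mentions, binned 0/1/2/3+}
#'   \item{sentence_position_bin}{"first" (sid 0), "last" (final sentence,
#'     when `nSentences` is known), else "middle"}
#' }
#'
#' @param sentence a [Sentence-class]
#' @param triple one evidence triple (1-row data.frame or list with fields
#'   gene, disease, etype, doc_id, sid) originating from `sentence`
#' @param diseaseKeywords,hallmarkKeywords character vectors of keyword terms
#' @param nSentences total sentences in the document, if known (enables the
#'   "last" position bin)
#' @return one-row data.frame of character features.
#' @export
extractFeatures <- function(sentence, triple, diseaseKeywords = character(),
                            hallmarkKeywords = character(),
                            nSentences = NA_integer_) {
  stopifnot(is(sentence, "Sentence"))
  triple <- as.list(triple)
  if (!identical(as.character(triple$doc_id), sentence@docId) ||
      as.integer(triple$sid) != sentence@sid)
    stop("triple does not originate from the given sentence")
  ev <- sentence@events
  ev <- ev[ev$theme_gene == triple$gene & ev$etype == triple$etype, ,
           drop = FALSE]
  if (nrow(ev) == 0)
    stop("no event in the sentence matches the triple's gene and event type")
  gm <- sentence@geneMentions
  gm <- gm[gm$id == triple$gene, , drop = FALSE]
  dm <- sentence@diseaseMentions
  dm <- dm[dm$id == triple$disease, , drop = FALSE]
  if (nrow(dm) == 0)
    stop("triple's disease is not mentioned in the sentence")
  trig <- c(ev$trigger_start[1], ev$trigger_end[1])
  gdist <- min(vapply(seq_len(nrow(gm)), function(i)
    tokenDistance(sentence@text, c(gm$start[i], gm$end[i]), trig),
    integer(1)))
  ddist <- min(vapply(seq_len(nrow(dm)), function(i)
    tokenDistance(sentence@text, c(dm$start[i], dm$end[i]), trig),
    integer(1)))
  pos <- if (sentence@sid == 0L) "first"
         else if (!is.na(nSentences) && sentence@sid == nSentences - 1L) "last"
         else "middle"
  data.frame(
    disease_keyword_count_bin =
      binCount(countKeywordHits(sentence@text, diseaseKeywords)),
    hallmark_keyword_count_bin =
      binCount(countKeywordHits(sentence@text, hallmarkKeywords)),
    gene_event_token_distance_bin = binCount(gdist),
    disease_event_token_distance_bin = binCount(ddist),
    etype = as.character(triple$etype),
    negation_cue =
      as.character(as.integer(any(tolower(tokenizeWS(sentence@text)) %in%
                                    negationCues()))),
    gene_mention_count_bin = binCount(nrow(sentence@geneMentions)),
    sentence_position_bin = pos,
    stringsAsFactors = FALSE)
}
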