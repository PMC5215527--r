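#' Biological event type vocabulary
#'
#' The closed vocabulary of 15 biological event types recognised in evidence
#' sentences: the seven core BioNLP event types (gene expression,
#' transcription, regulation, binding, localization, phosphorylation,
#' protein catabolism), seven epigenetics/post-translational-modification
#' types with reverse reactions merged (hydroxylation, ubiquitination, DNA
#' methylation, glycosylation, acetylation, methylation, catalysis), and
#' mutation.
#'
#' @return Character vector of the 15 event type identifiers.
#' @export
#' @examples
#' eventTypes()
eventTypes <- function() {
  c("gene_expression", "transcription", "regulation", "binding",
    "localization", "phosphorylation", "protein_catabolism",
    "hydroxylation", "ubiquitination", "dna_methylation", "glycosylation",
    "acetylation", "methylation", "catalysis", "mutation")
}

# MeSH top-level category for animal diseases, excluded from analyses
ANIMAL_DISEASE_CATEGORY <- "C22"

emptyMentionFrame <- function() {
  data.frame(start = integer(), end = integer(), text = character(),
             id = character(), stringsAsFactors = FALSE)
}

emptyEventFrame <- function() {
  data.frame(etype = character(), trigger_start = integer(),
             trigger_end = integer(), theme_gene = character(),
             stringsAsFactors = FALSE)
}

checkMentionFrame <- function(m, text, what) {
  msgs <- character()
  need <- c("start", "end", "text", "id")
  if (!all(need %in% names(m)))
    return(sprintf("%s mentions must have columns %s", what,
                   paste(need, collapse = ", ")))
  if (nrow(m) == 0) return(character())
  if (any(m$start >= m$end))
    msgs <- c(msgs, sprintf("%s mention with start >= end", what))
  if (any(m$start < 0) || any(m$end > nchar(text)))
    msgs <- c(msgs, sprintf("%s mention offsets outside [0, %d]", what,
                            nchar(text)))
  if (any(!nzchar(m$id)))
    msgs <- c(msgs, sprintf("%s mention with empty normalized id", what))
  if (length(msgs) == 0) {
    # offsets are 0-based half-open; substr is 1-based inclusive
    surf <- substring(text, m$start + 1L, m$end)
    bad <- which(surf != m$text)
    if (length(bad))
      msgs <- c(msgs, sprintf("%s mention text '%s' does not match span '%s'",
                              what, m$text[bad[1]], surf[bad[1]]))
  }
  msgs
}

#' Sentence: one annotated sentence
#'
#' An annotated sentence as produced by upstream named-entity and event
#' recognition: the raw text plus gene mentions, disease mentions and event
#' annotations. Mention offsets are 0-based, half-open, character-based.
#' Each event carries one of the 15 [eventTypes()] and names the gene
#' mention (by normalized id) that is its theme.
#'
#' @slot docId abstract identifier (PMID-like string)
#' @slot sid 0-based sentence index within the abstract
#' @slot text raw sentence string
#' @slot geneMentions data.frame with columns start, end, text, id
#' @slot diseaseMentions data.frame with columns start, end, text, id
#' @slot events data.frame with columns etype, trigger_start, trigger_end,
#'   theme_gene
#' @export
setClass("Sentence",
  representation(docId = "character", sid = "integer", text = "character",
                 geneMentions = "data.frame", diseaseMentions = "data.frame",
                 events = "data.frame"),
  prototype(docId = NA_character_, sid = 0L, text = "",
            geneMentions = emptyMentionFrame(),
            diseaseMentions = emptyMentionFrame(),
            events = emptyEventFrame()))

setValidity("Sentence", function(object) {
  msgs <- character()
  if (length(object@docId) != 1 || is.na(object@docId))
    msgs <- c(msgs, "docId must be a single non-NA string")
  if (length(object@sid) != 1 || is.na(object@sid) || object@sid < 0)
    msgs <- c(msgs, "sid must be a single non-negative integer")
  msgs <- c(msgs,
            checkMentionFrame(object@geneMentions, object@text, "gene"),
            checkMentionFrame(object@diseaseMentions, object@text, "disease"))
  ev <- object@events
  if (!all(c("etype", "trigger_start", "trigger_end", "theme_gene") %in%
             names(ev))) {
    msgs <- c(msgs, "events must have columns etype, trigger_start, trigger_end, theme_gene")
  } else if (nrow(ev) > 0) {
    unknown <- setdiff(unique(ev$etype), eventTypes())
    if (length(unknown))
      msgs <- c(msgs, sprintf("unknown event type(s): %s",
                              paste(unknown, collapse = ", ")))
    if (any(!ev$theme_gene %in% object@geneMentions$id))
      msgs <- c(msgs, "event theme_gene not among gene mention ids")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a Sentence
#'
#' @param docId abstract identifier
#' @param sid 0-based sentence index
#' @param text sentence string
#' @param geneMentions,diseaseMentions data.frames with columns
#'   start, end, text, id (0-based half-open character offsets)
#' @param events data.frame with columns etype, trigger_start, trigger_end,
#'   theme_gene
#' @return A validated [Sentence-class] object.
#' @export
#' @examples
#' Sentence("PMID1", 0L, "TP53 is mutated in cancer",
#'   geneMentions = data.frame(start = 0L, end = 4L, text = "TP53",
#'                             id = "7157"),
#'   diseaseMentions = data.frame(start = 19L, end = 25L, text = "cancer",
#'                                id = "D009369"),
#'   events = data.frame(etype = "mutation", trigger_start = 8L,
#'                       trigger_end = 15L, theme_gene = "7157"))
Sentence <- function(docId, sid = 0L, text = "",
                     geneMentions = emptyMentionFrame(),
                     diseaseMentions = emptyMentionFrame(),
                     events = emptyEventFrame()) {
  asMentions <- function(m) {
    m <- as.data.frame(m, stringsAsFactors = FALSE)
    if (nrow(m) == 0) return(emptyMentionFrame())
    m$start <- as.integer(m$start); m$end <- as.integer(m$end)
    m$text <- as.character(m$text); m$id <- as.character(m$id)
    rownames(m) <- NULL
    m[c("start", "end", "text", "id")]
  }
  ev <- as.data.frame(events, stringsAsFactors = FALSE)
  if (nrow(ev) == 0) ev <- emptyEventFrame() else {
    ev$etype <- as.character(ev$etype)
    ev$trigger_start <- as.integer(ev$trigger_start)
    ev$trigger_end <- as.integer(ev$trigger_end)
    ev$theme_gene <- as.character(ev$theme_gene)
    rownames(ev) <- NULL
    ev <- ev[c("etype", "trigger_start", "trigger_end", "theme_gene")]
  }
  new("Sentence", docId = as.character(docId), sid = as.integer(sid),
      text = as.character(text), geneMentions = asMentions(geneMentions),
      diseaseMentions = asMentions(diseaseMentions), events = ev)
}

#' SentenceCorpus: an ordered collection of annotated sentences
#'
#' @slot sentences list of [Sentence-class] objects
#' @export
setClass("SentenceCorpus", representation(sentences = "list"))

setValidity("SentenceCorpus", function(object) {
  ok <- vapply(object@sentences, function(s) is(s, "Sentence"), logical(1))
  if (all(ok)) TRUE else "all elements must be Sentence objects"
})

#' Construct a SentenceCorpus
#'
#' @param sentences list of [Sentence-class] objects
#' @return A `SentenceCorpus`.
#' @export
SentenceCorpus <- function(sentences = list()) {
  new("SentenceCorpus", sentences = unname(sentences))
}

#' @describeIn SentenceCorpus number of sentences
#' @param x a `SentenceCorpus`
#' @export
setMethod("length", "SentenceCorpus", function(x) length(x@sentences))

#' @export
setMethod("[[", "SentenceCorpus", function(x, i) x@sentences[[i]])

#' @export
setMethod("[", "SentenceCorpus",
          function(x, i) SentenceCorpus(x@sentences[i]))

#' Extract the sentence list from a corpus
#' @param x a `SentenceCorpus`
#' @return list of [Sentence-class] objects
#' @export
sentences <- function(x) {
  stopifnot(is(x, "SentenceCorpus"))
  x@sentences
}

setMethod("show", "Sentence", function(object) {
  cat(sprintf("Sentence %s#%d: \"%s\"\n  %d gene mention(s), %d disease mention(s), %d event(s)\n",
              object@docId, object@sid,
              if (nchar(object@text) > 60)
                paste0(substr(object@text, 1, 57), "...") else object@text,
              nrow(object@geneMentions), nrow(object@diseaseMentions),
              nrow(object@events)))
})

setMethod("show", "SentenceCorpus", function(object) {
  n <- length(object)
  nev <- sum(vapply(object@sentences, function(s) nrow(s@events), integer(1)))
  cat(sprintf("SentenceCorpus with %d sentence(s), %d event annotation(s)\n",
              n, nev))
})

#' EmbeddingTable: word vectors in a dense matrix
#'
#' Word embeddings as consumed from the word2vec text format: one fixed-length
#' real vector per vocabulary word.
#'
#' @slot vectors numeric matrix, one row per word, rownames are the vocabulary
#' @export
setClass("EmbeddingTable", representation(vectors = "matrix"))

setValidity("EmbeddingTable", function(object) {
  v <- object@vectors
  msgs <- character()
  if (ncol(v) < 1) msgs <- c(msgs, "embedding dimension must be >= 1")
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
    msgs <- c(msgs, "vocabulary words must be unique rownames")
  if (length(msgs)) msgs else TRUE
})

#' Construct an EmbeddingTable
#' @param vectors numeric matrix with one row per word (rownames = vocabulary)
#' @return An `EmbeddingTable`.
#' @export
EmbeddingTable <- function(vectors) {
  new("EmbeddingTable", vectors = as.matrix(vectors))
}

#' @describeIn EmbeddingTable vocabulary accessor
#' @param x an `EmbeddingTable`
#' @export
vocabulary <- function(x) {
  stopifnot(is(x, "EmbeddingTable"))
  rownames(x@vectors)
}

#' Look up word vectors
#' @param x an `EmbeddingTable`
#' @param words character vector of words (all must be in the vocabulary)
#' @return numeric matrix of the corresponding vectors
#' @export
wordVectors <- function(x, words) {
  stopifnot(is(x, "EmbeddingTable"))
  miss <- setdiff(words, rownames(x@vectors))
  if (length(miss))
    stop("word(s) not in embedding vocabulary: ", paste(miss, collapse = ", "))
  x@vectors[words, , drop = FALSE]
}

setMethod("show", "EmbeddingTable", function(object) {
  cat(sprintf("EmbeddingTable: %d words, dimension %d\n",
              nrow(object@vectors), ncol(object@vectors)))
})

#' NaiveBayesModel: discrete naive Bayes evidence classifier
#'
#' Class priors and per-feature class-conditional category probabilities with
#' Laplace smoothing, for classifying candidate evidence sentences as true
#' (+) or false (-) support of a gene-disease relationship.
#'
#' @slot priors named numeric of length 2 (names "+" and "-"), summing to 1
#' @slot tables named list; one matrix per feature with rows "+"/"-" and one
#'   column per category observed in training (conditional probabilities)
#' @slot counts named list of raw training count matrices (same shape)
#' @slot classTotals named numeric: training instances per class
#' @slot alpha Laplace smoothing pseudo-count
#' @export
setClass("NaiveBayesModel",
  representation(priors = "numeric", tables = "list", counts = "list",
                 classTotals = "numeric", alpha = "numeric"))

setValidity("NaiveBayesModel", function(object) {
  msgs <- character()
  if (length(object@priors) != 2 ||
      !setequal(names(object@priors), c("+", "-")))
    msgs <- c(msgs, "priors must be named '+' and '-'")
  if (abs(sum(object@priors) - 1) > 1e-8)
    msgs <- c(msgs, "priors must sum to 1")
  for (f in names(object@tables)) {
    tab <- object@tables[[f]]
    if (any(abs(rowSums(tab) - 1) > 1e-8))
      msgs <- c(msgs, sprintf("conditionals for feature '%s' must sum to 1 per class", f))
  }
  if (object@alpha <= 0) msgs <- c(msgs, "alpha must be > 0")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "NaiveBayesModel", function(object) {
  cat(sprintf("NaiveBayesModel: %d feature(s), alpha = %g\n  priors: P(+) = %.3f, P(-) = %.3f\n  features: %s\n",
              length(object@tables), object@alpha, object@priors["+"],
              object@priors["-"], paste(names(object@tables), collapse = ", ")))
})
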