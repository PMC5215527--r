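#' Read an annotated sentence corpus from JSON Lines
#'
#' One JSON record per line:
#' `{"doc_id", "sid", "text", "genes": [{"start","end","text","id"}, ...],
#' "diseases": [...], "events": [{"etype","trigger_start","trigger_end",
#' "theme_gene"}, ...]}`. Offsets are 0-based half-open character positions.
#' All invariants (offsets within the sentence, mention text matching its
#' span, event types in the closed vocabulary, event themes resolving to a
#' gene mention) are validated; violations are reported with the offending
#' line number.
#'
#' @param path path to a JSONL corpus file
#' @return A [SentenceCorpus-class].
#' @export
readCorpus <- function(path) {
  if (!file.exists(path)) stop("corpus file does not exist: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                    error = function(e)
                      stop(sprintf("line %d: malformed JSON (%s)", i,
                                   conditionMessage(e)), call. = FALSE))
    out[[i]] <- tryCatch(
      sentenceFromRecord(rec),
      error = function(e)
        stop(sprintf("line %d: %s", i, conditionMessage(e)), call. = FALSE))
  }
  SentenceCorpus(out)
}

sentenceFromRecord <- function(rec) {
  mentionFrame <- function(lst) {
    if (length(lst) == 0) return(emptyMentionFrame())
    do.call(rbind, lapply(lst, function(m)
      data.frame(start = as.integer(m$start), end = as.integer(m$end),
                 text = as.character(m$text), id = as.character(m$id),
                 stringsAsFactors = FALSE)))
  }
  eventFrame <- function(lst) {
    if (length(lst) == 0) return(emptyEventFrame())
    do.call(rbind, lapply(lst, function(e)
      data.frame(etype = as.character(e$etype),
                 trigger_start = as.integer(e$trigger_start),
                 trigger_end = as.integer(e$trigger_end),
                 theme_gene = as.character(e$theme_gene),
                 stringsAsFactors = FALSE)))
  }
  Sentence(docId = rec$doc_id, sid = rec$sid, text = rec$text,
           geneMentions = mentionFrame(rec$genes),
           diseaseMentions = mentionFrame(rec$diseases),
           events = eventFrame(rec$events))
}

#' Write a corpus to JSON Lines
#'
#' Inverse of [readCorpus()]: `readCorpus(writeCorpus(x, path))` reproduces
#' the corpus exactly.
#'
#' @param corpus a [SentenceCorpus-class] (or list of [Sentence-class])
#' @param path output path
#' @return `path`, invisibly.
#' @export
writeCorpus <- function(corpus, path) {
  if (is(corpus, "SentenceCorpus")) corpus <- sentences(corpus)
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (s in corpus) {
    mentionList <- function(m) {
      if (nrow(m) == 0) return(list())
      lapply(seq_len(nrow(m)), function(i)
        list(start = m$start[i], end = m$end[i], text = m$text[i],
             id = m$id[i]))
    }
    evList <- if (nrow(s@events) == 0) list() else
      lapply(seq_len(nrow(s@events)), function(i)
        list(etype = s@events$etype[i],
             trigger_start = s@events$trigger_start[i],
             trigger_end = s@events$trigger_end[i],
             theme_gene = s@events$theme_gene[i]))
    rec <- list(doc_id = s@docId, sid = s@sid, text = s@text,
                genes = mentionList(s@geneMentions),
                diseases = mentionList(s@diseaseMentions),
                events = evList)
    line <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
    writeLines(line, con, useBytes = TRUE)
  }
  invisible(path)
}

#' Annotate a raw sentence with lexicon-based mentions
#'
#' A dictionary-matching stand-in for external named-entity recognition:
#' matches are case-insensitive, longest-match-first, and token-boundary
#' aware (a lexicon entry never matches inside a longer alphanumeric token).
#' Overlapping candidate mentions of the same kind are resolved in favour of
#' the longer match.
#'
#' @param text raw sentence string
#' @param geneLexicon named character vector: surface name -> normalized id
#' @param diseaseLexicon named character vector: surface name -> vocabulary id
#' @param docId,sid identifiers for the resulting [Sentence-class]
#' @return A [Sentence-class] with mention annotations (no events).
#' @export
#' @examples
#' annotateSentence("TP53 causes cancer", c(TP53 = "7157"),
#'                  c(cancer = "D009369"))
annotateSentence <- function(text, geneLexicon, diseaseLexicon,
                             docId = "doc", sid = 0L) {
  stopifnot(length(geneLexicon) > 0 || length(diseaseLexicon) > 0)
  matchLexicon <- function(lexicon) {
    if (length(lexicon) == 0) return(emptyMentionFrame())
    hits <- emptyMentionFrame()
    # longest surface forms first so maximal spans win
    for (name in names(lexicon)[order(-nchar(names(lexicon)))]) {
      pat <- paste0("(?<![A-Za-z0-9])", escapeRegex(name), "(?![A-Za-z0-9])")
      m <- gregexpr(pat, text, perl = TRUE, ignore.case = TRUE)[[1]]
      if (m[1] == -1) next
      starts <- as.integer(m) - 1L
      ends <- starts + attr(m, "match.length")
      for (j in seq_along(starts)) {
        overlaps <- nrow(hits) > 0 &&
          any(starts[j] < hits$end & ends[j] > hits$start)
        if (!overlaps) {
          hits <- rbind(hits, data.frame(
            start = starts[j], end = ends[j],
            text = substring(text, starts[j] + 1L, ends[j]),
            id = unname(lexicon[[name]]), stringsAsFactors = FALSE))
        }
      }
    }
    hits <- hits[order(hits$start), , drop = FALSE]
    rownames(hits) <- NULL
    hits
  }
  Sentence(docId = docId, sid = sid, text = text,
           geneMentions = matchLexicon(geneLexicon),
           diseaseMentions = matchLexicon(diseaseLexicon))
}

escapeRegex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' Assemble gene-event-disease evidence triples
#'
#' An evidence triple records that one sentence mentions a disease and a
#' gene that is the theme of a biological event. Each (event theme gene,
#' disease mention id, event type) combination yields one triple; duplicate
#' combinations within a sentence are emitted once. Sentences lacking a
#' disease mention or lacking any event yield no triples.
#'
#' @param x a [Sentence-class] or [SentenceCorpus-class]
#' @return data.frame with columns gene, disease, etype, doc_id, sid
#'   (zero rows when no triple can be formed).
#' @export
assembleTriples <- function(x) {
  if (is(x, "SentenceCorpus")) {
    parts <- lapply(sentences(x), assembleTriples)
    out <- do.call(rbind, c(parts, list(emptyTripleFrame())))
    rownames(out) <- NULL
    return(out)
  }
  stopifnot(is(x, "Sentence"))
  validObject(x)
  if (nrow(x@events) == 0 || nrow(x@diseaseMentions) == 0)
    return(emptyTripleFrame())
  diseases <- unique(x@diseaseMentions$id)
  combos <- unique(x@events[c("theme_gene", "etype")])
  out <- expand.grid(seq_len(nrow(combos)), diseases,
                     stringsAsFactors = FALSE)
  out <- data.frame(gene = combos$theme_gene[out[[1]]],
                    disease = out[[2]],
                    etype = combos$etype[out[[1]]],
                    doc_id = x@docId, sid = x@sid,
                    stringsAsFactors = FALSE)
  out <- unique(out)
  rownames(out) <- NULL
  out
}

emptyTripleFrame <- function() {
  data.frame(gene = character(), disease = character(), etype = character(),
             doc_id = character(), sid = integer(), stringsAsFactors = FALSE)
}
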