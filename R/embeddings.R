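#' Read word embeddings in word2vec text format
#'
#' The format is a header line `"V d"` (vocabulary size and dimension)
#' followed by one line per word: the word then `d` whitespace-separated
#' floats.
#'
#' @param path path to the embeddings file
#' @return An [EmbeddingTable-class].
#' @export
readEmbeddings <- function(path) {
  if (!file.exists(path)) stop("embeddings file does not exist: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (length(lines) == 0) stop("empty embeddings file")
  hdr <- scan(text = lines[1], quiet = TRUE)
  if (length(hdr) != 2) stop("malformed header; expected 'V d'")
  V <- as.integer(hdr[1]); d <- as.integer(hdr[2])
  if (length(lines) - 1 != V)
    stop(sprintf("header promises %d words but file has %d data lines",
                 V, length(lines) - 1))
  words <- character(V)
  mat <- matrix(NA_real_, nrow = V, ncol = d)
  for (i in seq_len(V)) {
    parts <- strsplit(trimws(lines[i + 1]), "[[:space:]]+")[[1]]
    if (length(parts) != d + 1)
      stop(sprintf("line %d: expected %d values after the word, found %d",
                   i + 1, d, length(parts) - 1))
    words[i] <- parts[1]
    mat[i, ] <- as.numeric(parts[-1])
  }
  dup <- words[duplicated(words)]
  if (length(dup))
    stop("duplicate word(s) in embedding file: ",
         paste(unique(dup), collapse = ", "))
  rownames(mat) <- words
  EmbeddingTable(mat)
}

#' Write an EmbeddingTable in word2vec text format
#' @param emb an [EmbeddingTable-class]
#' @param path output path
#' @return `path`, invisibly.
#' @export
writeEmbeddings <- function(emb, path) {
  stopifnot(is(emb, "EmbeddingTable"))
  v <- emb@vectors
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(v), ncol(v)), con)
  for (i in seq_len(nrow(v)))
    writeLines(paste(c(rownames(v)[i],
                       formatC(v[i, ], format = "g", digits = 17)),
                     collapse = " "), con)
  invisible(path)
}

cosineTo <- function(mat, q) {
  qn <- sqrt(sum(q^2))
  rn <- sqrt(rowSums(mat^2))
  num <- as.numeric(mat %*% q)
  denom <- rn * qn
  # zero-norm vectors score 0 by convention
  ifelse(denom == 0, 0, num / denom)
}

#' Expand disease-related keywords by embedding analogy
#'
#' Generates a disease-related keyword list from seed pairs of
#' (source disease word, related term) — e.g. ("cancer", "proliferation") —
#' by vector analogy: for each seed pair the query point is
#' `v(source) - v(related term) + v(disease word)`, and the vocabulary is
#' ranked by cosine similarity to that point. The three query words are
#' excluded, the top `k` candidates per pair are kept, candidates appearing
#' for several pairs are merged by their maximum score, and the result is
#' sorted by score, descending.
#'
#' The default query direction is the one stated above; `reverse = TRUE`
#' uses `v(related term) - v(source) + v(disease word)` instead (the
#' king/queen-style orientation).
#'
#' @param emb an [EmbeddingTable-class]
#' @param seeds data.frame with columns `source` and `related`; pairs with
#'   out-of-vocabulary words are dropped with a warning
#' @param diseaseWord the disease term to expand for (must be in-vocabulary)
#' @param k top candidates per seed pair (default 20)
#' @param reverse use the reversed analogy direction
#' @return data.frame with columns `term` and `score`, sorted by score
#'   descending.
#' @export
expandKeywords <- function(emb, seeds, diseaseWord, k = 20, reverse = FALSE) {
  stopifnot(is(emb, "EmbeddingTable"), k >= 1)
  vocab <- vocabulary(emb)
  if (!diseaseWord %in% vocab)
    stop("disease word not in embedding vocabulary: ", diseaseWord)
  seeds <- as.data.frame(seeds, stringsAsFactors = FALSE)
  stopifnot(all(c("source", "related") %in% names(seeds)))
  oov <- !(seeds$source %in% vocab & seeds$related %in% vocab)
  if (any(oov)) {
    warning(sprintf("dropping %d seed pair(s) with out-of-vocabulary words",
                    sum(oov)))
    seeds <- seeds[!oov, , drop = FALSE]
  }
  if (nrow(seeds) == 0) stop("no usable seed pairs")
  queryWords <- unique(c(seeds$source, seeds$related, diseaseWord))
  best <- numeric(0)
  for (i in seq_len(nrow(seeds))) {
    src <- seeds$source[i]; rel <- seeds$related[i]
    q <- if (reverse)
      emb@vectors[rel, ] - emb@vectors[src, ] + emb@vectors[diseaseWord, ]
    else
      emb@vectors[src, ] - emb@vectors[rel, ] + emb@vectors[diseaseWord, ]
    keep <- setdiff(vocab, queryWords)
    if (length(keep) == 0) next
    sims <- cosineTo(emb@vectors[keep, , drop = FALSE], q)
    names(sims) <- keep
    top <- sims[order(-sims, names(sims))][seq_len(min(k, length(sims)))]
    for (w in names(top))
      best[w] <- if (w %in% names(best)) max(best[w], top[w]) else top[w]
  }
  out <- data.frame(term = names(best), score = unname(best),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
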