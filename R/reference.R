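#' Read reference disease gene sets in GMT format
#'
#' One set per line: `name TAB description TAB gene1 TAB gene2 ...`.
#' Duplicate genes within a line are collapsed with a warning.
#'
#' @param path path to a GMT file
#' @return named list of character vectors (gene ids), with per-set
#'   descriptions in the `"descriptions"` attribute.
#' @export
readGMT <- function(path) {
  if (!file.exists(path)) stop("GMT file does not exist: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); desc <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop(sprintf("line %d: GMT line needs >= 3 tab-separated fields", i))
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning(sprintf("line %d (%s): duplicate genes collapsed", i,
                      fields[1]))
      genes <- unique(genes)
    }
    sets[[fields[1]]] <- genes
    desc[fields[1]] <- fields[2]
  }
  attr(sets, "descriptions") <- desc
  sets
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors
#' @param path output path
#' @param descriptions optional named character vector of descriptions
#' @return `path`, invisibly.
#' @export
writeGMT <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions))
    descriptions <- attr(sets, "descriptions")
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (nm in names(sets)) {
    d <- if (!is.null(descriptions) && nm %in% names(descriptions))
      descriptions[[nm]] else "na"
    writeLines(paste(c(nm, d, sets[[nm]]), collapse = "\t"), con)
  }
  invisible(path)
}

#' Top-K overlap ratio between ranked gene lists and reference sets
#'
#' For each disease present in both inputs, the top `min(K, length)` genes of
#' the ranked list are intersected with the reference set. The pooled ratio
#' is `sum_d |top_d ∩ ref_d| / sum_d min(K, |list_d|)`; the macro-averaged
#' variant averages the per-disease ratios instead.
#'
#' @param ranked named list of character vectors: per-disease gene lists in
#'   rank order (best first)
#' @param refs named list of character vectors: reference gene sets keyed by
#'   the same disease ids
#' @param k top-list size (e.g. 100, 200, 300)
#' @param macro if `TRUE`, macro-average across diseases instead of pooling
#' @return overlap ratio in \[0, 1\].
#' @export
topkOverlapRatio <- function(ranked, refs, k, macro = FALSE) {
  stopifnot(k >= 1)
  common <- intersect(names(ranked), names(refs))
  if (length(common) == 0)
    stop("no disease in common between ranked lists and reference sets")
  hits <- denom <- numeric(length(common))
  for (i in seq_along(common)) {
    d <- common[i]
    top <- utils::head(ranked[[d]], k)
    hits[i] <- length(intersect(top, refs[[d]]))
    denom[i] <- length(top)
  }
  if (macro) mean(hits / denom) else sum(hits) / sum(denom)
}

#' Significance of a gene-set overlap (hypergeometric upper tail)
#'
#' `P(X >= k)` for the observed overlap `k` between a found set and a
#' reference set, under random draws of `|found|` genes from a universe of
#' size `N` containing `|ref|` reference genes (one-sided Fisher test).
#'
#' @param found character vector of found genes
#' @param ref character vector of reference genes
#' @param universeSize universe size N (>= `|found ∪ ref|`)
#' @return the upper-tail probability.
#' @export
overlapPvalue <- function(found, ref, universeSize) {
  found <- unique(found); ref <- unique(ref)
  if (universeSize < length(union(found, ref)))
    stop("universe size smaller than |found ∪ ref|")
  k <- length(intersect(found, ref))
  stats::phyper(k - 1, length(ref), universeSize - length(ref),
                length(found), lower.tail = FALSE)
}

#' Per-disease reference coverage with quartile bins
#'
#' Recall of each reference set achieved by the corresponding found set,
#' assigned to quartile bins: \[0.75, 1.00\], \[0.50, 0.75), \[0.25, 0.50),
#' \[0, 0.25). The boundary 0.75 belongs to the top bin ("75-100%").
#'
#' @param found named list of per-disease found gene sets
#' @param refs named list of per-disease reference gene sets; empty reference
#'   sets are skipped with a warning
#' @param universeSize optional universe size for per-disease overlap
#'   p-values (default: size of the union of all genes in both inputs)
#' @return data.frame with columns disease, n_found, n_ref, n_overlap,
#'   recall, bin, p_value.
#' @export
coverageBins <- function(found, refs, universeSize = NULL) {
  common <- intersect(names(found), names(refs))
  if (is.null(universeSize))
    universeSize <- length(unique(c(unlist(found), unlist(refs))))
  rows <- list()
  for (d in common) {
    if (length(refs[[d]]) == 0) {
      warning("empty reference set skipped: ", d)
      next
    }
    f <- unique(found[[d]]); r <- unique(refs[[d]])
    recall <- length(intersect(f, r)) / length(r)
    bin <- if (recall >= 0.75) "1.00-0.75"
           else if (recall >= 0.50) "0.75-0.50"
           else if (recall >= 0.25) "0.50-0.25"
           else "0.25-0.00"
    rows[[d]] <- data.frame(
      disease = d, n_found = length(f), n_ref = length(r),
      n_overlap = length(intersect(f, r)), recall = recall, bin = bin,
      p_value = overlapPvalue(f, r, universeSize),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, list(data.frame(
    disease = character(), n_found = integer(), n_ref = integer(),
    n_overlap = integer(), recall = numeric(), bin = character(),
    p_value = numeric(), stringsAsFactors = FALSE))))
  rownames(out) <- NULL
  out
}
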