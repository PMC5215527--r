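#' Read a disease vocabulary table
#'
#' A MeSH-style disease vocabulary as a flat TSV with header columns
#' `disease_id`, `name`, `synonyms` (pipe-separated), `parent_id`,
#' `tree_numbers` (pipe-separated, e.g. `C04.123|C14.2`). Tree-number
#' prefixes map each disease to its most general top-level categories
#' (C01..C26).
#'
#' @param path path to the TSV file
#' @return data.frame with one row per disease and list-columns `synonyms`
#'   and `tree_numbers`.
#' @export
readDiseaseVocabulary <- function(path) {
  if (!file.exists(path)) stop("vocabulary file does not exist: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("disease_id", "name", "synonyms", "parent_id", "tree_numbers")
  if (!all(need %in% names(tab)))
    stop("vocabulary must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$disease_id))
    stop("duplicate disease_id in vocabulary")
  splitPipe <- function(x) {
    out <- strsplit(x, "|", fixed = TRUE)
    lapply(out, function(v) v[nzchar(v)])
  }
  tab$synonyms <- splitPipe(tab$synonyms)
  tab$tree_numbers <- splitPipe(tab$tree_numbers)
  tab
}

#' Map a disease to its most general MeSH categories
#'
#' Extracts the top-level category code (the prefix before the first dot)
#' from each of the disease's tree numbers. The animal-disease category
#' (C22) is excluded from analyses; a disease whose only tree numbers fall
#' under it maps to an empty set with a warning.
#'
#' @param diseaseId a disease identifier present in `vocab`
#' @param vocab a vocabulary data.frame from [readDiseaseVocabulary()]
#' @return character vector of top-level category codes (possibly empty).
#' @export
#' @examples
#' vocab <- data.frame(disease_id = "D1", name = "x", parent_id = "",
#'                     stringsAsFactors = FALSE)
#' vocab$synonyms <- list(character())
#' vocab$tree_numbers <- list(c("C04.1", "C14.2"))
#' mapToGeneralCategories("D1", vocab)
mapToGeneralCategories <- function(diseaseId, vocab) {
  i <- match(diseaseId, vocab$disease_id)
  if (is.na(i)) stop("unknown disease id: ", diseaseId)
  tn <- vocab$tree_numbers[[i]]
  cats <- unique(sub("\\..*$", "", tn))
  kept <- setdiff(cats, ANIMAL_DISEASE_CATEGORY)
  if (length(kept) == 0 && length(cats) > 0)
    warning(sprintf("disease %s maps only to the excluded animal-disease category",
                    diseaseId))
  sort(kept)
}

#' Write a disease vocabulary table
#'
#' @param vocab vocabulary data.frame (see [readDiseaseVocabulary()])
#' @param path output path
#' @return `path`, invisibly.
#' @export
writeDiseaseVocabulary <- function(vocab, path) {
  out <- vocab
  out$synonyms <- vapply(vocab$synonyms, paste, character(1), collapse = "|")
  out$tree_numbers <- vapply(vocab$tree_numbers, paste, character(1),
                             collapse = "|")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
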