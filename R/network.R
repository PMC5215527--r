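#' Read an undirected protein-interaction network
#'
#' Two-column TSV edge list (gene_a, gene_b); lines starting with `#` are
#' comments. Self-loops are dropped and duplicate edges collapsed, so the
#' result is a simple undirected graph.
#'
#' @param path path to the edge-list file
#' @return an `igraph` undirected simple graph with gene ids as vertex names.
#' @export
readNetwork <- function(path) {
  if (!file.exists(path)) stop("network file does not exist: ", path)
  tab <- utils::read.table(path, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE,
                           colClasses = "character",
                           col.names = c("gene_a", "gene_b"))
  g <- igraph::graph_from_data_frame(tab, directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Write a network as a TSV edge list
#' @param net an `igraph` graph with named vertices
#' @param path output path
#' @return `path`, invisibly.
#' @export
writeNetwork <- function(net, path) {
  el <- igraph::as_edgelist(net)
  utils::write.table(el, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Overlap coefficient of two gene sets
#'
#' `C = |A ∩ B| / min(|A|, |B|)`. `C = 1` iff one set contains the other.
#'
#' @param A,B non-empty character vectors of gene ids
#' @return C in \[0, 1\].
#' @export
overlapCoefficient <- function(A, B) {
  A <- unique(A); B <- unique(B)
  if (length(A) == 0 || length(B) == 0) stop("gene sets must be non-empty")
  length(intersect(A, B)) / min(length(A), length(B))
}

#' Jaccard index of two gene sets
#'
#' `J = |A ∩ B| / |A ∪ B|`. `J = 1` iff the sets are identical.
#'
#' @param A,B non-empty character vectors of gene ids
#' @return J in \[0, 1\].
#' @export
jaccardIndex <- function(A, B) {
  A <- unique(A); B <- unique(B)
  if (length(A) == 0 || length(B) == 0) stop("gene sets must be non-empty")
  length(intersect(A, B)) / length(union(A, B))
}

#' Classify a disease pair by gene-set relationship
#'
#' The four groups of disease pairs: `identical` (A = B),
#' `complete_subset` (strict containment either way), `complete_separation`
#' (disjoint), and `partial_overlap` otherwise.
#'
#' @param A,B non-empty character vectors of gene ids
#' @return one of the four group labels.
#' @export
classifyPair <- function(A, B) {
  A <- unique(A); B <- unique(B)
  if (length(A) == 0 || length(B) == 0) stop("gene sets must be non-empty")
  if (setequal(A, B)) return("identical")
  if (all(A %in% B) || all(B %in% A)) return("complete_subset")
  if (length(intersect(A, B)) == 0) return("complete_separation")
  "partial_overlap"
}

#' Network separation coefficient of a disease pair
#'
#' Computes `S_AB = <d_AB> - (<d_AA> + <d_BB>) / 2` on unweighted shortest
#' paths. `<d_AB>` averages, over every gene of A, its distance to the
#' nearest gene of B, and vice versa (a gene shared by A and B contributes
#' 0). `<d_AA>` averages each gene's distance to the nearest *other* gene of
#' its own set; a singleton set has within-set distance 0. Genes absent from
#' the network are dropped (and counted), and unreachable pairs are excluded
#' from the means (and counted), so the choice of convention is auditable.
#' Negative `S_AB` indicates overlapping disease neighbourhoods in the
#' interactome; positive values indicate separated modules.
#'
#' @param A,B character vectors of gene ids
#' @param net an `igraph` undirected graph with gene ids as vertex names
#' @return list with elements `d_AB`, `d_AA`, `d_BB`, `s_AB`, `n_dropped`,
#'   `n_unreachable`.
#' @export
separationCoefficient <- function(A, B, net) {
  A <- unique(A); B <- unique(B)
  nodes <- igraph::V(net)$name
  dropped <- sum(!A %in% nodes) + sum(!B %in% nodes)
  A <- intersect(A, nodes); B <- intersect(B, nodes)
  if (length(A) == 0 || length(B) == 0)
    stop("after dropping genes absent from the network, both sets must be non-empty")
  unreachable <- 0L
  dmat <- igraph::distances(net, v = union(A, B), to = union(A, B))

  nearestCross <- function(from, to) {
    vapply(from, function(g) {
      if (g %in% to) return(0)
      min(dmat[g, to])
    }, numeric(1))
  }
  cross <- c(nearestCross(A, B), nearestCross(B, A))
  finite <- is.finite(cross)
  unreachable <- unreachable + sum(!finite)
  if (!any(finite))
    stop("all cross-set distances are unreachable; separation undefined")
  d_AB <- mean(cross[finite])

  within <- function(S) {
    if (length(S) == 1) return(0)
    v <- vapply(S, function(g) min(dmat[g, setdiff(S, g)]), numeric(1))
    fin <- is.finite(v)
    unreachable <<- unreachable + sum(!fin)
    if (!any(fin)) 0 else mean(v[fin])
  }
  d_AA <- within(A)
  d_BB <- within(B)
  list(d_AB = d_AB, d_AA = d_AA, d_BB = d_BB,
       s_AB = d_AB - (d_AA + d_BB) / 2,
       n_dropped = dropped, n_unreachable = unreachable)
}

#' Read GO annotations
#'
#' Three-column TSV (gene, go_id, aspect) with aspect one of BP, CC, MF.
#' Annotations are assumed pre-propagated by the producer; no ontology
#' traversal is performed.
#'
#' @param path path to the TSV file (with header)
#' @return data.frame with columns gene, go_id, aspect.
#' @export
readGOAnnotations <- function(path) {
  if (!file.exists(path)) stop("GO annotation file does not exist: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("gene", "go_id", "aspect")
  if (!all(need %in% names(tab)))
    stop("GO table must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(tab$aspect), c("BP", "CC", "MF"))
  if (length(bad))
    stop("unknown GO aspect(s): ", paste(bad, collapse = ", "))
  unique(tab[need])
}

#' GO-based functional similarity of a gene pair
#'
#' `S_GO(a, b) = 2 / min(n_i)` over the GO terms of the given aspect shared
#' by the two genes, where `n_i` is the number of genes annotated to term
#' `i`; the shared term with the smallest `n_i` is the most specific one.
#' Genes sharing no term score 0.
#'
#' @param a,b gene ids
#' @param go annotation data.frame from [readGOAnnotations()]
#' @param aspect one of "BP", "CC", "MF"
#' @return similarity >= 0 (1 when the most specific shared term annotates
#'   exactly the two genes).
#' @export
goPairSimilarity <- function(a, b, go, aspect = "BP") {
  go <- go[go$aspect == aspect, , drop = FALSE]
  shared <- intersect(go$go_id[go$gene == a], go$go_id[go$gene == b])
  if (length(shared) == 0) return(0)
  sizes <- vapply(shared, function(term)
    length(unique(go$gene[go$go_id == term])), integer(1))
  2 / min(sizes)
}

#' GO-based functional similarity of a disease pair
#'
#' The mean of [goPairSimilarity()] over all cross pairs (a in A, b in B):
#' `|A| * |B|` pairs.
#'
#' @param A,B non-empty character vectors of gene ids
#' @param go annotation data.frame from [readGOAnnotations()]
#' @param aspect one of "BP", "CC", "MF"
#' @return mean similarity >= 0.
#' @export
diseaseGOSimilarity <- function(A, B, go, aspect = "BP") {
  A <- unique(A); B <- unique(B)
  if (length(A) == 0 || length(B) == 0) stop("gene sets must be non-empty")
  goA <- go[go$aspect == aspect, , drop = FALSE]
  termSize <- tapply(goA$gene, goA$go_id, function(g) length(unique(g)))
  geneTerms <- split(goA$go_id, goA$gene)
  sims <- outer(A, B, Vectorize(function(a, b) {
    shared <- intersect(geneTerms[[a]], geneTerms[[b]])
    if (length(shared) == 0) 0 else 2 / min(termSize[shared])
  }))
  mean(sims)
}

#' Full disease-pair relationship table
#'
#' Computes, for every pair of diseases, the overlap coefficient C, the
#' Jaccard index J, the pair group, the separation coefficient components
#' and the GO similarity per aspect.
#'
#' @param diseaseGenes named list of per-disease gene sets
#' @param net an `igraph` interaction network
#' @param go GO annotation data.frame (optional; GO columns are NA when
#'   missing)
#' @return data.frame with one row per unordered disease pair.
#' @export
diseasePairTable <- function(diseaseGenes, net, go = NULL) {
  ids <- names(diseaseGenes)
  stopifnot(length(ids) >= 2)
  pairs <- utils::combn(ids, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    A <- diseaseGenes[[a]]; B <- diseaseGenes[[b]]
    sep <- tryCatch(separationCoefficient(A, B, net),
                    error = function(e) NULL)
    goSim <- function(asp) {
      if (is.null(go)) NA_real_ else diseaseGOSimilarity(A, B, go, asp)
    }
    data.frame(
      disease_a = a, disease_b = b,
      C = overlapCoefficient(A, B), J = jaccardIndex(A, B),
      group = classifyPair(A, B),
      d_AB = if (is.null(sep)) NA_real_ else sep$d_AB,
      d_AA = if (is.null(sep)) NA_real_ else sep$d_AA,
      d_BB = if (is.null(sep)) NA_real_ else sep$d_BB,
      S_AB = if (is.null(sep)) NA_real_ else sep$s_AB,
      S_GO_BP = goSim("BP"), S_GO_CC = goSim("CC"), S_GO_MF = goSim("MF"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
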