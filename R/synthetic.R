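# run expr under a fixed RNG seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

eventTriggerWords <- function() {
  c(gene_expression = "expressed", transcription = "transcribed",
    regulation = "regulated", binding = "bound", localization = "localized",
    phosphorylation = "phosphorylated", protein_catabolism = "degraded",
    hydroxylation = "hydroxylated", ubiquitination = "ubiquitinated",
    dna_methylation = "methylated-at-DNA", glycosylation = "glycosylated",
    acetylation = "acetylated", methylation = "methylated",
    catalysis = "catalyzed", mutation = "mutated")
}

#' Configuration for the synthetic-data generators
#'
#' Bundles every knob of the seeded generators. The defaults are the
#' standing study conditions for the package's tests: a 60-gene, 6-disease
#' universe of 150 abstracts with 12 planted gene-disease associations whose
#' intensities form a strict gradient (12 down to 1 sentences), plus decoy
#' sentences that can never form a triple, and a small background of random
#' one-off associations.
#'
#' @param seed integer seed fixing every downstream draw
#' @param nGenes,nDiseases,nDocuments universe sizes
#' @param planted data.frame(gene, disease, etype, intensity) of planted
#'   associations; `NULL` uses the default gradient design
#' @param nGeneOnly,nDiseaseOnly,nNoEvent decoy sentence counts (gene+event
#'   but no disease; disease but no gene; gene+disease but no event)
#' @param nBackground random one-sentence (gene, disease, etype)
#'   associations acting as ranking noise
#' @return a list of class `generatorConfig`.
#' @export
generatorConfig <- function(seed = 1L, nGenes = 60L, nDiseases = 6L,
                            nDocuments = 150L, planted = NULL,
                            nGeneOnly = 30L, nDiseaseOnly = 30L,
                            nNoEvent = 30L, nBackground = 25L) {
  genes <- sprintf("G%03d", seq_len(nGenes))
  diseases <- sprintf("D%03d", seq_len(nDiseases))
  if (is.null(planted)) {
    k <- 12L
    planted <- data.frame(
      gene = genes[seq_len(k)],
      disease = rep(diseases, length.out = k),
      etype = rep(eventTypes(), length.out = k),
      intensity = seq(k, 1L),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(planted$intensity >= 1))
  structure(list(seed = as.integer(seed), nGenes = as.integer(nGenes),
                 nDiseases = as.integer(nDiseases),
                 nDocuments = as.integer(nDocuments), genes = genes,
                 diseases = diseases, planted = planted,
                 nGeneOnly = as.integer(nGeneOnly),
                 nDiseaseOnly = as.integer(nDiseaseOnly),
                 nNoEvent = as.integer(nNoEvent),
                 nBackground = as.integer(nBackground)),
            class = "generatorConfig")
}

buildEvidenceSentence <- function(gene, disease, etype, withDisease = TRUE,
                                  withEvent = TRUE) {
  trig <- unname(eventTriggerWords()[etype])
  if (withEvent && withDisease) {
    text <- sprintf("%s is %s in %s", gene, trig, disease)
  } else if (withEvent) {
    text <- sprintf("%s is %s in cultured cells", gene, trig)
  } else {
    text <- sprintf("%s and %s were mentioned together", gene, disease)
  }
  gm <- data.frame(start = 0L, end = nchar(gene), text = gene, id = gene,
                   stringsAsFactors = FALSE)
  dm <- if (withDisease) {
    ds <- regexpr(disease, text, fixed = TRUE)
    data.frame(start = as.integer(ds) - 1L,
               end = as.integer(ds) - 1L + nchar(disease),
               text = disease, id = disease, stringsAsFactors = FALSE)
  } else emptyMentionFrame()
  ev <- if (withEvent) {
    ts <- regexpr(trig, text, fixed = TRUE)
    data.frame(etype = etype, trigger_start = as.integer(ts) - 1L,
               trigger_end = as.integer(ts) - 1L + nchar(trig),
               theme_gene = gene, stringsAsFactors = FALSE)
  } else emptyEventFrame()
  list(text = text, genes = gm, diseases = dm, events = ev)
}

#' Generate a synthetic annotated corpus with planted associations
#'
#' Emits a corpus whose sentences embed the planted (gene, disease, event
#' type) associations with exactly `intensity` evidence sentences each,
#' plus decoy sentences that can never yield a triple (gene+event without a
#' disease, disease without a gene, gene+disease without an event) and a
#' background of random one-off associations. Sentences are distributed
#' over `nDocuments` abstracts at random. The same configuration always
#' produces an identical corpus.
#'
#' @param cfg a [generatorConfig()]
#' @return list with `corpus` (a [SentenceCorpus-class]) and `truth`
#'   (data.frame gene, disease, etype, n_sentences of the planted
#'   associations).
#' @export
simulateCorpus <- function(cfg) {
  stopifnot(inherits(cfg, "generatorConfig"))
  if (cfg$nDocuments < 1) stop("at least one document is required")
  withSeed(cfg$seed, {
    specs <- list()
    for (i in seq_len(nrow(cfg$planted))) {
      p <- cfg$planted[i, ]
      for (j in seq_len(p$intensity))
        specs[[length(specs) + 1L]] <-
          buildEvidenceSentence(p$gene, p$disease, p$etype)
    }
    for (i in seq_len(cfg$nBackground)) {
      specs[[length(specs) + 1L]] <- buildEvidenceSentence(
        sample(cfg$genes, 1), sample(cfg$diseases, 1),
        sample(eventTypes(), 1))
    }
    for (i in seq_len(cfg$nGeneOnly))
      specs[[length(specs) + 1L]] <- buildEvidenceSentence(
        sample(cfg$genes, 1), NA, sample(eventTypes(), 1),
        withDisease = FALSE)
    for (i in seq_len(cfg$nDiseaseOnly)) {
      d <- sample(cfg$diseases, 1)
      text <- sprintf("patients with %s were examined", d)
      ds <- regexpr(d, text, fixed = TRUE)
      specs[[length(specs) + 1L]] <- list(
        text = text, genes = emptyMentionFrame(),
        diseases = data.frame(start = as.integer(ds) - 1L,
                              end = as.integer(ds) - 1L + nchar(d),
                              text = d, id = d, stringsAsFactors = FALSE),
        events = emptyEventFrame())
    }
    for (i in seq_len(cfg$nNoEvent))
      specs[[length(specs) + 1L]] <- buildEvidenceSentence(
        sample(cfg$genes, 1), sample(cfg$diseases, 1),
        sample(eventTypes(), 1), withEvent = FALSE)

    docs <- sample(cfg$nDocuments, length(specs), replace = TRUE)
    ord <- order(docs, seq_along(specs))
    sents <- vector("list", length(specs))
    sid <- integer(cfg$nDocuments)
    for (k in seq_along(ord)) {
      i <- ord[k]
      d <- docs[i]
      sp <- specs[[i]]
      sents[[k]] <- Sentence(docId = sprintf("PMID%04d", d), sid = sid[d],
                             text = sp$text, geneMentions = sp$genes,
                             diseaseMentions = sp$diseases,
                             events = sp$events)
      sid[d] <- sid[d] + 1L
    }
    truth <- cfg$planted
    names(truth)[names(truth) == "intensity"] <- "n_sentences"
    list(corpus = SentenceCorpus(sents), truth = truth)
  })
}

#' Generate labeled feature vectors for classifier evaluation
#'
#' Draws discrete feature vectors from stated per-class categorical
#' distributions, with configurable class balance. By default three binary
#' features with per-class Bernoulli probabilities `posProbs` / `negProbs`
#' are used; alternatively `posDist` / `negDist` give full categorical
#' distributions per feature (named lists of named probability vectors, as
#' from [evidenceFeatureDistributions()]). Identical class distributions
#' make the classes indistinguishable (AUC converges to 0.5);
#' well-separated ones give an easy problem (AUC above 0.9).
#'
#' @param n number of instances
#' @param seed RNG seed
#' @param posProbs,negProbs per-feature probabilities of category "1" in
#'   the positive / negative class (binary-feature shortcut)
#' @param balance fraction of positive instances
#' @param posDist,negDist named lists of per-feature category probability
#'   vectors; when given they replace the binary shortcut
#' @return list with `features` (data.frame of character columns) and
#'   `labels` (character vector of "+"/"-").
#' @export
simulateLabeledFeatures <- function(n, seed = 1L,
                                    posProbs = c(0.8, 0.75, 0.7),
                                    negProbs = c(0.2, 0.25, 0.3),
                                    balance = 0.5,
                                    posDist = NULL, negDist = NULL) {
  stopifnot(n >= 0)
  if (is.null(posDist)) {
    stopifnot(length(posProbs) == length(negProbs))
    mk <- function(p) lapply(p, function(q) c("0" = 1 - q, "1" = q))
    posDist <- mk(posProbs); negDist <- mk(negProbs)
    names(posDist) <- names(negDist) <- sprintf("f%d", seq_along(posProbs))
  }
  stopifnot(identical(names(posDist), names(negDist)))
  withSeed(seed, {
    nPos <- round(n * balance)
    labels <- c(rep("+", nPos), rep("-", n - nPos))
    cols <- lapply(names(posDist), function(f) {
      out <- character(n)
      if (nPos > 0)
        out[labels == "+"] <- sample(names(posDist[[f]]), nPos,
                                     replace = TRUE, prob = posDist[[f]])
      if (n - nPos > 0)
        out[labels == "-"] <- sample(names(negDist[[f]]), n - nPos,
                                     replace = TRUE, prob = negDist[[f]])
      out
    })
    names(cols) <- names(posDist)
    features <- as.data.frame(cols, stringsAsFactors = FALSE)
    if (n == 0)
      features <- features[0, , drop = FALSE]
    list(features = features, labels = labels)
  })
}

#' Class-conditional distributions over the evidence feature space
#'
#' Categorical distributions, per class, over the features produced by
#' [extractFeatures()]: true evidence sentences tend to mention disease and
#' hallmark keywords, place the gene and disease close to the event
#' trigger, and avoid negation cues; false candidates show the opposite
#' tendencies. Event type is uninformative by construction. Used to
#' generate training data for the evidence classifier when no manually
#' labeled corpus is available.
#'
#' @param separated if `FALSE`, the negative class copies the positive
#'   distributions (indistinguishable classes)
#' @return list with elements `pos` and `neg`, each a named list of named
#'   probability vectors.
#' @export
evidenceFeatureDistributions <- function(separated = TRUE) {
  bins <- c("0", "1", "2", "3+")
  pos <- list(
    disease_keyword_count_bin = stats::setNames(c(.15, .35, .3, .2), bins),
    hallmark_keyword_count_bin = stats::setNames(c(.2, .4, .25, .15), bins),
    gene_event_token_distance_bin = stats::setNames(c(.45, .3, .15, .1), bins),
    disease_event_token_distance_bin = stats::setNames(c(.3, .3, .2, .2), bins),
    etype = stats::setNames(rep(1 / 15, 15), eventTypes()),
    negation_cue = c("0" = .92, "1" = .08),
    gene_mention_count_bin = stats::setNames(c(.0, .6, .25, .15), bins),
    sentence_position_bin = c(first = .2, middle = .6, last = .2))
  neg <- list(
    disease_keyword_count_bin = stats::setNames(c(.6, .25, .1, .05), bins),
    hallmark_keyword_count_bin = stats::setNames(c(.65, .2, .1, .05), bins),
    gene_event_token_distance_bin = stats::setNames(c(.1, .15, .25, .5), bins),
    disease_event_token_distance_bin = stats::setNames(c(.1, .2, .25, .45), bins),
    etype = stats::setNames(rep(1 / 15, 15), eventTypes()),
    negation_cue = c("0" = .6, "1" = .4),
    gene_mention_count_bin = stats::setNames(c(.0, .3, .35, .35), bins),
    sentence_position_bin = c(first = .25, middle = .55, last = .2))
  if (!separated) neg <- pos
  list(pos = pos, neg = neg)
}

#' Generate a random interaction network
#'
#' Erdős–Rényi (`model = "erdos_renyi"`, edge probability `p`) or
#' Barabási–Albert preferential attachment (`model = "barabasi_albert"`,
#' `m` edges per new node) topologies; always a simple undirected graph
#' with vertices named `g1..gn`.
#'
#' @param nNodes number of nodes (>= 2)
#' @param model "erdos_renyi" or "barabasi_albert"
#' @param p edge probability (Erdős–Rényi)
#' @param m attachment count (Barabási–Albert)
#' @param seed RNG seed
#' @return an `igraph` graph.
#' @export
simulateNetwork <- function(nNodes, model = c("erdos_renyi",
                                              "barabasi_albert"),
                            p = 0.1, m = 2, seed = 1L) {
  model <- match.arg(model)
  stopifnot(nNodes >= 2)
  if (model == "erdos_renyi" && (p < 0 || p > 1))
    stop("edge probability must be in [0, 1]")
  withSeed(seed, {
    g <- if (model == "erdos_renyi")
      igraph::sample_gnp(nNodes, p, directed = FALSE)
    else
      igraph::sample_pa(nNodes, m = m, directed = FALSE)
    g <- igraph::simplify(g)
    igraph::V(g)$name <- sprintf("g%d", seq_len(nNodes))
    g
  })
}

#' Generate random GO annotations
#'
#' Assigns genes to GO terms per aspect with sizes drawn uniformly from
#' `sizeRange`.
#'
#' @param genes character vector of gene ids
#' @param nTerms terms per aspect
#' @param sizeRange integer range of genes per term
#' @param aspects aspects to generate
#' @param seed RNG seed
#' @return data.frame (gene, go_id, aspect).
#' @export
simulateGOAnnotations <- function(genes, nTerms = 10,
                                  sizeRange = c(2, 8),
                                  aspects = c("BP", "CC", "MF"),
                                  seed = 1L) {
  stopifnot(sizeRange[1] >= 1)
  withSeed(seed, {
    rows <- list()
    for (asp in aspects) {
      for (t in seq_len(nTerms)) {
        size <- sample(seq(sizeRange[1], min(sizeRange[2], length(genes))), 1)
        members <- sample(genes, size)
        rows[[length(rows) + 1L]] <- data.frame(
          gene = members, go_id = sprintf("GO:%s:%04d", asp, t),
          aspect = asp, stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Generate reference gene sets with controlled overlap
#'
#' For each disease, builds an OMIM/GWAS-style reference set of `setSize`
#' genes of which `round(overlapFraction * setSize)` are drawn from the
#' disease's own gene set and the rest from the remaining universe.
#'
#' @param diseaseGenes named list of per-disease gene sets
#' @param universe character vector of all gene ids
#' @param setSize reference set size
#' @param overlapFraction fraction of the reference drawn from the
#'   disease's genes
#' @param seed RNG seed
#' @return named list of reference gene sets.
#' @export
simulateReferenceSets <- function(diseaseGenes, universe, setSize = 10,
                                  overlapFraction = 0.5, seed = 1L) {
  withSeed(seed, {
    out <- lapply(diseaseGenes, function(g) {
      g <- unique(g)
      nShared <- min(round(overlapFraction * setSize), length(g))
      shared <- sample(g, nShared)
      pool <- setdiff(universe, g)
      other <- sample(pool, min(setSize - nShared, length(pool)))
      c(shared, other)
    })
    names(out) <- names(diseaseGenes)
    out
  })
}

#' Generate a module-structured disease-network study
#'
#' Builds a stochastic-block-model interaction network of `nModules` dense
#' modules, plants two overlapping disease gene sets inside each module
#' (high-overlap pairs) and pairs diseases across modules (disjoint pairs),
#' and annotates each module's genes with one module-specific GO term per
#' aspect plus one broad background term. Under this construction
#' high-overlap pairs have low (negative) separation coefficients and high
#' GO similarity, while cross-module pairs are separated and functionally
#' dissimilar — the qualitative structure expected of real disease modules
#' in an interactome.
#'
#' @param seed RNG seed
#' @param nModules number of network modules
#' @param moduleSize genes per module
#' @param pWithin,pBetween within- and between-module edge probabilities
#' @param genesPerDisease genes per planted disease set
#' @param sharedFraction fraction of genes shared within a module's disease
#'   pair
#' @return list with `network`, `diseases` (named list of gene sets), `go`
#'   (annotation data.frame), `highPairs` and `lowPairs` (data.frames with
#'   columns a, b).
#' @export
simulateDiseaseModules <- function(seed = 1L, nModules = 6, moduleSize = 12,
                                   pWithin = 0.4, pBetween = 0.02,
                                   genesPerDisease = 8,
                                   sharedFraction = 0.75) {
  stopifnot(genesPerDisease <= moduleSize)
  withSeed(seed, {
    n <- nModules * moduleSize
    pref <- matrix(pBetween, nModules, nModules)
    diag(pref) <- pWithin
    g <- igraph::sample_sbm(n, pref.matrix = pref,
                            block.sizes = rep(moduleSize, nModules))
    g <- igraph::simplify(g)
    igraph::V(g)$name <- sprintf("g%d", seq_len(n))
    moduleGenes <- split(igraph::V(g)$name,
                         rep(seq_len(nModules), each = moduleSize))
    diseases <- list()
    rowsGO <- list()
    for (m in seq_len(nModules)) {
      genes <- moduleGenes[[m]]
      a <- sample(genes, genesPerDisease)
      nShared <- round(sharedFraction * genesPerDisease)
      b <- c(sample(a, nShared),
             sample(setdiff(genes, a),
                    min(genesPerDisease - nShared,
                        length(setdiff(genes, a)))))
      diseases[[sprintf("M%02da", m)]] <- a
      diseases[[sprintf("M%02db", m)]] <- b
      for (asp in c("BP", "CC", "MF"))
        rowsGO[[length(rowsGO) + 1L]] <- data.frame(
          gene = genes, go_id = sprintf("GO:%s:MOD%02d", asp, m),
          aspect = asp, stringsAsFactors = FALSE)
    }
    allGenes <- igraph::V(g)$name
    for (asp in c("BP", "CC", "MF"))
      rowsGO[[length(rowsGO) + 1L]] <- data.frame(
        gene = allGenes, go_id = sprintf("GO:%s:ROOT", asp),
        aspect = asp, stringsAsFactors = FALSE)
    go <- do.call(rbind, rowsGO)
    rownames(go) <- NULL
    highPairs <- data.frame(a = sprintf("M%02da", seq_len(nModules)),
                            b = sprintf("M%02db", seq_len(nModules)),
                            stringsAsFactors = FALSE)
    cross <- utils::combn(seq_len(nModules), 2)
    lowPairs <- data.frame(a = sprintf("M%02da", cross[1, ]),
                           b = sprintf("M%02da", cross[2, ]),
                           stringsAsFactors = FALSE)
    list(network = g, diseases = diseases, go = go,
         highPairs = highPairs, lowPairs = lowPairs)
  })
}

#' Generate a synthetic embedding table with planted analogies
#'
#' Random unit-scale vectors for a vocabulary, with optional planted
#' analogy structure: for each planted row, the vector of `term` is placed
#' exactly at `v(source) - v(related) + v(disease)`, so the analogy query
#' of [expandKeywords()] recovers it with cosine similarity 1.
#'
#' @param words vocabulary
#' @param d embedding dimension
#' @param planted optional data.frame(source, related, disease, term)
#' @param seed RNG seed
#' @return an [EmbeddingTable-class].
#' @export
simulateEmbeddings <- function(words, d = 10, planted = NULL, seed = 1L) {
  withSeed(seed, {
    mat <- matrix(stats::rnorm(length(words) * d), nrow = length(words),
                  dimnames = list(words, NULL))
    if (!is.null(planted)) {
      for (i in seq_len(nrow(planted))) {
        p <- planted[i, ]
        mat[p$term, ] <- mat[p$source, ] - mat[p$related, ] + mat[p$disease, ]
      }
    }
    EmbeddingTable(mat)
  })
}
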