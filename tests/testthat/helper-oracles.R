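# Independent oracles used by property and acceptance tests.
# All are deliberately naive (enumeration / BFS in plain R) and share no
# code with the implementation they check.

# all-pairs shortest paths by breadth-first search on an edge-list matrix
oracleDistances <- function(nodes, edges) {
  adj <- setNames(vector("list", length(nodes)), nodes)
  if (nrow(edges) > 0) {
    for (i in seq_len(nrow(edges))) {
      a <- edges[i, 1]; b <- edges[i, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  d <- matrix(Inf, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (s in nodes) {
    d[s, s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (d[s, w] > d[s, v] + 1) {
          d[s, w] <- d[s, v] + 1
          queue <- c(queue, w)
        }
      }
    }
  }
  d
}

# separation coefficient recomputed from an oracle distance matrix,
# following the nearest-neighbor convention
oracleSeparation <- function(A, B, dmat) {
  nearest <- function(from, to, excludeSelf = FALSE) {
    vapply(from, function(g) {
      cand <- if (excludeSelf) setdiff(to, g) else to
      if (!excludeSelf && g %in% to) return(0)
      if (length(cand) == 0) return(0)
      min(dmat[g, cand])
    }, numeric(1))
  }
  meanFinite <- function(v) {
    v <- v[is.finite(v)]
    if (length(v) == 0) 0 else mean(v)
  }
  dAB <- c(nearest(A, B), nearest(B, A))
  dAB <- mean(dAB[is.finite(dAB)])
  dAA <- meanFinite(nearest(A, A, excludeSelf = TRUE))
  dBB <- meanFinite(nearest(B, B, excludeSelf = TRUE))
  dAB - (dAA + dBB) / 2
}

# upper-tail overlap probability by exhaustive enumeration of all draws
oracleOverlapPvalue <- function(nFound, nRef, k, N) {
  draws <- combn(N, nFound)
  ref <- seq_len(nRef)
  hits <- apply(draws, 2, function(s) sum(s %in% ref))
  mean(hits >= k)
}

# two-sided Mann-Whitney p by full enumeration of group labelings
oracleMannWhitneyP <- function(x, y) {
  all <- c(x, y)
  n1 <- length(x)
  uStat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  obs <- uStat(x, y)
  labelings <- combn(length(all), n1)
  us <- apply(labelings, 2, function(idx) uStat(all[idx], all[-idx]))
  pLow <- mean(us <= obs)
  pHigh <- mean(us >= obs)
  min(1, 2 * min(pLow, pHigh))
}

# naive-Bayes posterior by explicit joint-table construction: smoothed
# conditionals recomputed by direct counting, full joint enumerated, then
# normalized
oracleNaiveBayesPosterior <- function(train, labels, query, alpha = 1) {
  classes <- c("+", "-")
  nC <- table(factor(labels, levels = classes))
  prior <- nC / sum(nC)
  condP <- function(f, val, cl) {
    cats <- sort(unique(train[[f]]))
    cnt <- sum(train[[f]] == val & labels == cl)
    if (!val %in% cats) cnt <- 0
    K <- length(cats)
    (cnt + alpha) / (nC[[cl]] + alpha * K)
  }
  joint <- sapply(classes, function(cl) {
    p <- prior[[cl]]
    for (f in names(train)) p <- p * condP(f, query[[f]], cl)
    p
  })
  joint["+"] / sum(joint)
}

# a fully hand-built sentence shared by several tests
toySentence <- function() {
  Sentence("PMID1", 0L, "TP53 is mutated in breast cancer",
    geneMentions = data.frame(start = 0L, end = 4L, text = "TP53",
                              id = "7157", stringsAsFactors = FALSE),
    diseaseMentions = data.frame(start = 19L, end = 32L,
                                 text = "breast cancer", id = "D001943",
                                 stringsAsFactors = FALSE),
    events = data.frame(etype = "mutation", trigger_start = 8L,
                        trigger_end = 15L, theme_gene = "7157",
                        stringsAsFactors = FALSE))
}

# directly parameterized model (no training) for closed-form score checks
directModel <- function(pPos, pNeg, priors = c("+" = 0.5, "-" = 0.5),
                        nFeatures = 1) {
  tables <- lapply(seq_len(nFeatures), function(i)
    matrix(c(1 - pPos, pPos, 1 - pNeg, pNeg), nrow = 2, byrow = TRUE,
           dimnames = list(c("+", "-"), c("0", "1"))))
  names(tables) <- sprintf("f%d", seq_len(nFeatures))
  counts <- lapply(tables, function(t) t * 0)
  new("NaiveBayesModel", priors = priors, tables = tables,
      counts = counts, classTotals = c("+" = 10, "-" = 10), alpha = 1)
}
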