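pathGraph <- function() igraph::make_graph(~ a - b, b - c)

test_that("set similarity coefficients match hand counts", {
  A <- c("g1", "g2", "g3"); B <- c("g2", "g3", "g4", "g5")
  expect_equal(overlapCoefficient(A, A), 1)
  expect_equal(overlapCoefficient(A, c("x", "y")), 0)
  expect_equal(overlapCoefficient(A, B), 2 / 3)
  expect_equal(jaccardIndex(A, A), 1)
  expect_equal(jaccardIndex(A, c("x", "y")), 0)
  expect_equal(jaccardIndex(A, B), 2 / 5)
  expect_error(overlapCoefficient(A, character()), "non-empty")

  expect_equal(classifyPair(A, A), "identical")
  expect_equal(classifyPair("a", c("a", "b")), "complete_subset")
  expect_equal(classifyPair(c("a", "b"), c("b", "c")), "partial_overlap")
  expect_equal(classifyPair(c("a", "b"), c("x", "y")),
               "complete_separation")
})

test_that("C >= J always; C = 1 iff containment, J = 1 iff identity", {
  withr::local_seed(41)
  for (rep in 1:50) {
    A <- sample(letters, sample(1:10, 1))
    B <- sample(letters, sample(1:10, 1))
    C <- overlapCoefficient(A, B); J <- jaccardIndex(A, B)
    expect_gte(C, J)
    expect_equal(C == 1, all(A %in% B) || all(B %in% A))
    expect_equal(J == 1, setequal(A, B))
  }
})

test_that("separation coefficient reproduces the path-graph cases", {
  g <- pathGraph()
  s1 <- separationCoefficient("a", "c", g)
  expect_equal(s1$d_AB, 2)
  expect_equal(s1$d_AA, 0)   # singleton within-set distance
  expect_equal(s1$s_AB, 2)

  expect_equal(separationCoefficient("a", "a", g)$s_AB, 0)

  s3 <- separationCoefficient(c("a", "c"), c("a", "c"), g)
  expect_equal(s3$d_AB, 0)   # shared genes contribute zero
  expect_equal(s3$d_AA, 2)
  expect_equal(s3$s_AB, -2)

  # symmetry, and dropped-gene accounting
  s4 <- separationCoefficient(c("a", "ghost"), "c", g)
  expect_equal(s4$n_dropped, 1)
  sAB <- separationCoefficient("a", "c", g)$s_AB
  sBA <- separationCoefficient("c", "a", g)$s_AB
  expect_equal(sAB, sBA)

  disc <- igraph::make_graph(~ a - b, c - d)
  expect_error(separationCoefficient("a", "c", disc), "unreachable")
  expect_error(separationCoefficient("ghost1", "a", g), "non-empty")
})

test_that("separation matches the brute-force BFS oracle on random graphs", {
  withr::local_seed(52)
  for (rep in 1:60) {
    n <- sample(5:30, 1)
    net <- simulateNetwork(n, p = runif(1, 0.1, 0.5), seed = rep)
    nodes <- igraph::V(net)$name
    el <- igraph::as_edgelist(net)
    dmat <- oracleDistances(nodes, el)
    A <- sample(nodes, sample(1:4, 1))
    B <- sample(nodes, sample(1:4, 1))
    res <- tryCatch(separationCoefficient(A, B, net),
                    error = function(e) NULL)
    if (is.null(res)) next
    expect_equal(res$s_AB, oracleSeparation(A, B, dmat), tolerance = 1e-12)
  }
})

test_that("GO pair similarity is 2 / (size of most specific shared term)", {
  go <- data.frame(
    gene = c("a", "b", "a", "b", "c", "d", "a", "b"),
    go_id = c("T2", "T2", "T4", "T4", "T4", "T4", "M1", "M1"),
    aspect = c("BP", "BP", "BP", "BP", "BP", "BP", "MF", "MF"),
    stringsAsFactors = FALSE)
  expect_equal(goPairSimilarity("a", "b", go, "BP"), 1)     # 2-gene term
  expect_equal(goPairSimilarity("a", "c", go, "BP"), 0.5)   # n_i = 4
  expect_equal(goPairSimilarity("a", "d", go, "MF"), 0)     # nothing shared

  # disease-level similarity is the mean over all cross pairs
  expect_equal(diseaseGOSimilarity("a", c("b", "c"), go, "BP"),
               mean(c(1, 0.5)))
  expect_equal(diseaseGOSimilarity(c("a", "b"), c("a", "b"), go, "BP"), 1)
  expect_equal(diseaseGOSimilarity("a", "d", go, "BP"), 0.5)

  tf <- withr::local_tempfile()
  write.table(go, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(readGOAnnotations(tf), go)
  write.table(transform(go, aspect = "XX"), tf, sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(readGOAnnotations(tf), "aspect")
})

test_that("network edge lists round-trip through TSV with comments", {
  net <- simulateNetwork(10, p = 0.4, seed = 3)
  tf <- withr::local_tempfile()
  writeNetwork(net, tf)
  lines <- readLines(tf)
  writeLines(c("# protein interactions", lines), tf)
  back <- readNetwork(tf)
  expect_equal(igraph::ecount(back), igraph::ecount(net))
  expect_setequal(igraph::V(back)$name,
                  igraph::V(net)$name[igraph::degree(net) > 0])
})

test_that("disease pair table combines all statistics", {
  st <- simulateDiseaseModules(seed = 4, nModules = 3)
  tab <- diseasePairTable(st$diseases[1:4], st$network, st$go)
  expect_equal(nrow(tab), choose(4, 2))
  expect_true(all(tab$C >= tab$J))
  expect_true(all(tab$group %in% c("complete_separation", "partial_overlap",
                                   "complete_subset", "identical")))
  expect_true(all(is.finite(tab$S_GO_BP)))
})
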