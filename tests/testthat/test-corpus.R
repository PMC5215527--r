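test_that("corpus reading validates records and reports line numbers", {
  tf <- withr::local_tempfile()
  writeLines(character(), tf)
  expect_equal(length(readCorpus(tf)), 0)

  writeCorpus(SentenceCorpus(list(toySentence())), tf)
  corpus <- readCorpus(tf)
  expect_equal(length(corpus), 1)
  expect_equal(nrow(corpus[[1]]@events), 1)

  writeLines("{not json", tf)
  expect_error(readCorpus(tf), "line 1.*malformed JSON")

  # mention end beyond sentence length violates the offset invariant
  bad <- '{"doc_id":"d","sid":0,"text":"short","genes":[{"start":0,"end":99,"text":"short","id":"g"}],"diseases":[],"events":[]}'
  writeLines(bad, tf)
  expect_error(readCorpus(tf), "line 1.*offsets")

  # unknown event type is named in the error
  bad2 <- '{"doc_id":"d","sid":0,"text":"G here","genes":[{"start":0,"end":1,"text":"G","id":"g"}],"diseases":[],"events":[{"etype":"teleportation","trigger_start":2,"trigger_end":6,"theme_gene":"g"}]}'
  writeLines(bad2, tf)
  expect_error(readCorpus(tf), "teleportation")
})

test_that("write/read round-trips corpora exactly, including unicode", {
  s <- toySentence()
  uni <- Sentence("PMID9", 1L, "HBA1 (α-globin) in anæmia",
    geneMentions = data.frame(start = 0L, end = 4L, text = "HBA1",
                              id = "HBAα", stringsAsFactors = FALSE),
    diseaseMentions = data.frame(start = 19L, end = 25L, text = "anæmia",
                                 id = "D000740", stringsAsFactors = FALSE))
  corpus <- SentenceCorpus(list(s, uni))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  writeCorpus(corpus, f1)
  back <- readCorpus(f1)
  writeCorpus(back, f2)
  expect_identical(readLines(f1, encoding = "UTF-8"),
                   readLines(f2, encoding = "UTF-8"))
  expect_equal(back[[2]]@geneMentions$id, "HBAα")
  # empty corpus round trip
  writeCorpus(SentenceCorpus(), f1)
  expect_equal(length(readCorpus(f1)), 0)
})

test_that("lexicon annotation is boundary-aware and longest-match-first", {
  s <- annotateSentence("TP53 causes cancer", c(TP53 = "7157"),
                        c(cancer = "D009369"))
  expect_equal(nrow(s@geneMentions), 1)
  expect_equal(nrow(s@diseaseMentions), 1)
  expect_equal(s@geneMentions$id, "7157")

  # token-boundary rule: "protein kinase" never matches inside "protein"
  s2 <- annotateSentence("protein level", c(`protein kinase` = "g1"),
                         c(cancer = "d"))
  expect_equal(nrow(s2@geneMentions), 0)

  # longest match wins over a contained shorter entry
  s3 <- annotateSentence("breast cancer studied", c(TP53 = "x"),
                         c(cancer = "D009369", `breast cancer` = "D001943"))
  expect_equal(nrow(s3@diseaseMentions), 1)
  expect_equal(s3@diseaseMentions$id, "D001943")
  expect_equal(s3@diseaseMentions$text, "breast cancer")

  # matching is case-insensitive and offsets satisfy the Sentence invariant
  s4 <- annotateSentence("tp53 and Cancer", c(TP53 = "7157"),
                         c(cancer = "D009369"))
  expect_equal(s4@geneMentions$text, "tp53")
  expect_true(validObject(s4))
})

test_that("triple assembly pairs theme genes with every disease, once", {
  expect_equal(nrow(assembleTriples(toySentence())), 1)

  two <- Sentence("d", 0L, "AKT1 is expressed in cancer and diabetes",
    geneMentions = data.frame(start = 0L, end = 4L, text = "AKT1",
                              id = "207", stringsAsFactors = FALSE),
    diseaseMentions = data.frame(start = c(21L, 32L), end = c(27L, 40L),
                                 text = c("cancer", "diabetes"),
                                 id = c("D009369", "D003920"),
                                 stringsAsFactors = FALSE),
    events = data.frame(etype = "gene_expression", trigger_start = 8L,
                        trigger_end = 17L, theme_gene = "207",
                        stringsAsFactors = FALSE))
  tr <- assembleTriples(two)
  expect_equal(nrow(tr), 2)
  expect_setequal(tr$disease, c("D009369", "D003920"))

  # gene that is no event's theme yields nothing
  noTheme <- Sentence("d", 0L, "AKT1 in cancer",
    geneMentions = data.frame(start = 0L, end = 4L, text = "AKT1",
                              id = "207", stringsAsFactors = FALSE),
    diseaseMentions = data.frame(start = 8L, end = 14L, text = "cancer",
                                 id = "D009369", stringsAsFactors = FALSE))
  expect_equal(nrow(assembleTriples(noTheme)), 0)

  # duplicate events of the same etype collapse to one triple
  dup <- two
  dup@diseaseMentions <- dup@diseaseMentions[1, , drop = FALSE]
  dup@events <- rbind(dup@events, dup@events)
  expect_equal(nrow(assembleTriples(dup)), 1)
})

test_that("no sentence without a disease mention ever yields a triple", {
  sim <- simulateCorpus(generatorConfig(seed = 42))
  for (s in sentences(sim$corpus)) {
    tr <- assembleTriples(s)
    if (nrow(s@diseaseMentions) == 0 || nrow(s@events) == 0) {
      expect_equal(nrow(tr), 0)
    } else {
      expect_lte(nrow(tr),
                 nrow(unique(s@events[c("theme_gene", "etype")])) *
                   length(unique(s@diseaseMentions$id)))
    }
  }
})

test_that("disease vocabulary maps tree numbers to general categories", {
  vocab <- data.frame(disease_id = c("D1", "D2", "D3"),
                      name = c("one", "two", "animal-only"),
                      parent_id = c("", "", ""),
                      stringsAsFactors = FALSE)
  vocab$synonyms <- list("alpha", c("beta", "b2"), character())
  vocab$tree_numbers <- list("C04.123", c("C04.1", "C14.2"), "C22.5")

  expect_equal(mapToGeneralCategories("D1", vocab), "C04")
  expect_equal(mapToGeneralCategories("D2", vocab), c("C04", "C14"))
  expect_warning(res <- mapToGeneralCategories("D3", vocab), "animal")
  expect_equal(res, character())
  expect_error(mapToGeneralCategories("nope", vocab), "unknown disease")

  tf <- withr::local_tempfile()
  writeDiseaseVocabulary(vocab, tf)
  back <- readDiseaseVocabulary(tf)
  expect_equal(back$tree_numbers, vocab$tree_numbers)
  expect_equal(back$synonyms[[2]], c("beta", "b2"))
})
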