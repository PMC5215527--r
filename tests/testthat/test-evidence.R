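test_that("feature extraction matches the worked sentence", {
  s <- toySentence()  # "TP53 is mutated in breast cancer"
  triple <- data.frame(gene = "7157", disease = "D001943",
                       etype = "mutation", doc_id = "PMID1", sid = 0L,
                       stringsAsFactors = FALSE)
  fv <- extractFeatures(s, triple,
                        diseaseKeywords = c("breast", "cancer"),
                        hallmarkKeywords = character())
  expect_equal(fv$disease_keyword_count_bin, "2")
  expect_equal(fv$hallmark_keyword_count_bin, "0")
  # "TP53 is mutated": one token ("is") between gene and trigger
  expect_equal(fv$gene_event_token_distance_bin, "1")
  # "mutated in breast": one token between trigger and disease
  expect_equal(fv$disease_event_token_distance_bin, "1")
  expect_equal(fv$etype, "mutation")
  expect_equal(fv$negation_cue, "0")
  expect_equal(fv$sentence_position_bin, "first")

  # five keyword hits cap at the "3+" bin
  fv2 <- extractFeatures(s, triple,
                         diseaseKeywords = c("tp53", "is", "mutated", "in",
                                             "breast"))
  expect_equal(fv2$disease_keyword_count_bin, "3+")

  # adjacent gene and trigger: zero intervening tokens
  adj <- Sentence("d", 0L, "BRCA1 mutated in cancer",
    geneMentions = data.frame(start = 0L, end = 5L, text = "BRCA1",
                              id = "672", stringsAsFactors = FALSE),
    diseaseMentions = data.frame(start = 17L, end = 23L, text = "cancer",
                                 id = "D009369", stringsAsFactors = FALSE),
    events = data.frame(etype = "mutation", trigger_start = 6L,
                        trigger_end = 13L, theme_gene = "672",
                        stringsAsFactors = FALSE))
  fvAdj <- extractFeatures(adj, data.frame(gene = "672",
                                           disease = "D009369",
                                           etype = "mutation",
                                           doc_id = "d", sid = 0L))
  expect_equal(fvAdj$gene_event_token_distance_bin, "0")

  # mismatched triple is a consistency error
  badTriple <- triple; badTriple$doc_id <- "OTHER"
  expect_error(extractFeatures(s, badTriple), "does not originate")
})

test_that("model fitting follows closed-form count arithmetic", {
  # one positive and one negative with identical features: symmetric model
  feats <- data.frame(f = c("a", "a"), stringsAsFactors = FALSE)
  m <- fitEvidenceModel(feats, c("+", "-"), alpha = 1)
  expect_equal(unname(m@priors), c(0.5, 0.5))
  sc <- scoreEvidence(m, data.frame(f = "a"))
  expect_equal(sc$raw_score, 0)
  expect_equal(sc$norm_score, 0.5)

  # alpha -> 0 limit approaches hard 1/0 conditionals
  sep <- data.frame(f = c("1", "1", "0", "0"), stringsAsFactors = FALSE)
  mSep <- fitEvidenceModel(sep, c("+", "+", "-", "-"), alpha = 1e-9)
  expect_equal(mSep@tables$f["+", "1"], 1, tolerance = 1e-6)
  expect_equal(mSep@tables$f["-", "1"], 0, tolerance = 1e-6)

  # category unseen for one class gets (0 + alpha) / (n + |categories|)
  un <- data.frame(f = c("a", "b", "a"), stringsAsFactors = FALSE)
  mUn <- fitEvidenceModel(un, c("+", "-", "-"), alpha = 1)
  expect_equal(mUn@tables$f["+", "b"], (0 + 1) / (1 + 2))

  expect_error(fitEvidenceModel(feats, c("+", "+")), "both classes")
  expect_error(fitEvidenceModel(feats, c("+", "-"), alpha = 0))
})

test_that("scores follow the log-posterior-odds closed forms", {
  # equal priors, single binary feature with P(1|+) = .8, P(1|-) = .2
  m1 <- directModel(0.8, 0.2)
  sc <- scoreEvidence(m1, data.frame(f1 = "1"))
  expect_equal(sc$raw_score, log(4))
  expect_equal(sc$norm_score, 0.8)

  # two independent copies of the same feature multiply the odds
  m2 <- directModel(0.8, 0.2, nFeatures = 2)
  sc2 <- scoreEvidence(m2, data.frame(f1 = "1", f2 = "1"))
  expect_equal(sc2$raw_score, 2 * log(4))
  expect_equal(sc2$norm_score, 16 / 17)

  # unknown category at score time is smoothed, never an error
  train <- data.frame(f = c("a", "b"), stringsAsFactors = FALSE)
  m3 <- fitEvidenceModel(train, c("+", "-"))
  expect_silent(sc3 <- scoreEvidence(m3, data.frame(f = "zzz")))
  expect_true(is.finite(sc3$raw_score))
})

test_that("normalized score is a sigmoid that preserves the ranking", {
  sim <- simulateLabeledFeatures(300, seed = 21)
  m <- fitEvidenceModel(sim$features, sim$labels)
  sc <- scoreEvidence(m, sim$features)
  expect_true(all(sc$norm_score > 0 & sc$norm_score < 1))
  expect_equal(sc$norm_score, plogis(sc$raw_score))
  expect_equal(order(sc$raw_score), order(sc$norm_score))
})

test_that("naive Bayes posterior equals exhaustive joint-table computation", {
  withr::local_seed(31)
  for (rep in 1:20) {
    nf <- sample(1:3, 1)
    n <- sample(6:20, 1)
    train <- as.data.frame(lapply(seq_len(nf), function(i)
      as.character(rbinom(n, 1, 0.5))), col.names = sprintf("f%d", 1:nf),
      stringsAsFactors = FALSE)
    labels <- c("+", "-", sample(c("+", "-"), n - 2, replace = TRUE))
    model <- fitEvidenceModel(train, labels, alpha = 1)
    query <- as.data.frame(lapply(seq_len(nf), function(i)
      as.character(rbinom(1, 1, 0.5))), col.names = sprintf("f%d", 1:nf),
      stringsAsFactors = FALSE)
    expect_equal(scoreEvidence(model, query)$norm_score,
                 unname(oracleNaiveBayesPosterior(train, labels, query)),
                 tolerance = 1e-12)
  }
})

test_that("ranking evaluation matches pairwise enumeration", {
  expect_equal(evaluateRanking(c(0.9, 0.8, 0.3), c("+", "+", "-"))$auc, 1)
  # pos {.9,.4} vs neg {.6,.1}: 3 of 4 pairs concordant
  expect_equal(evaluateRanking(c(0.9, 0.4, 0.6, 0.1),
                               c("+", "+", "-", "-"))$auc, 0.75)
  expect_equal(evaluateRanking(rep(0.5, 6),
                               c("+", "+", "+", "-", "-", "-"))$auc, 0.5)
  expect_error(evaluateRanking(c(1, 2), c("+", "+")), "both classes")

  ev <- evaluateRanking(c(0.9, 0.6, 0.4, 0.1), c("+", "-", "+", "-"))
  expect_equal(ev$precision, 0.5)  # predicted positive: {.9, .6}
  expect_equal(ev$recall, 0.5)
  expect_equal(ev$f, 0.5)
})

test_that("model JSON serialization round-trips scores exactly", {
  sim <- simulateLabeledFeatures(200, seed = 12)
  m <- fitEvidenceModel(sim$features, sim$labels, alpha = 0.5)
  tf <- withr::local_tempfile()
  writeEvidenceModel(m, tf)
  back <- readEvidenceModel(tf)
  q <- simulateLabeledFeatures(50, seed = 13)$features
  expect_equal(scoreEvidence(back, q), scoreEvidence(m, q))
  expect_equal(back@alpha, 0.5)
})
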