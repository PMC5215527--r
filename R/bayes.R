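#' Fit the naive Bayes evidence classifier
#'
#' Fits class priors by maximum likelihood and, independently per feature, a
#' class-conditional categorical distribution with Laplace smoothing:
#' `P(f = c | y) = (n_{y,c} + alpha) / (n_y + alpha * K)` where `K` is the
#' number of categories observed for that feature in training.
#'
#' @param features data.frame of discrete (character) features, one row per
#'   training instance — e.g. rows from [extractFeatures()]
#' @param labels vector of class labels, "+" / "-" (or a logical vector,
#'   `TRUE` = positive); both classes must be present
#' @param alpha Laplace smoothing pseudo-count (> 0)
#' @return A [NaiveBayesModel-class].
#' @export
fitEvidenceModel <- function(features, labels, alpha = 1) {
  stopifnot(alpha > 0)
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  if (is.logical(labels)) labels <- ifelse(labels, "+", "-")
  labels <- as.character(labels)
  if (!all(labels %in% c("+", "-")))
    stop("labels must be '+' or '-'")
  if (length(unique(labels)) < 2)
    stop("both classes must be present in the training set")
  if (nrow(features) != length(labels))
    stop("features and labels disagree in length")
  n <- length(labels)
  classTotals <- c("+" = sum(labels == "+"), "-" = sum(labels == "-"))
  priors <- classTotals / n
  counts <- list(); tables <- list()
  for (f in names(features)) {
    vals <- as.character(features[[f]])
    cats <- sort(unique(vals))
    cnt <- matrix(0, nrow = 2, ncol = length(cats),
                  dimnames = list(c("+", "-"), cats))
    for (cl in c("+", "-")) {
      t <- table(factor(vals[labels == cl], levels = cats))
      cnt[cl, ] <- as.numeric(t)
    }
    tab <- (cnt + alpha) / (classTotals + alpha * length(cats))
    counts[[f]] <- cnt
    tables[[f]] <- tab
  }
  new("NaiveBayesModel", priors = priors, tables = tables, counts = counts,
      classTotals = classTotals, alpha = alpha)
}

#' Score evidence candidates with a fitted model
#'
#' The raw score is the log posterior odds
#' `log P(+) + sum_f log P(f|+) - log P(-) - sum_f log P(f|-)`; the
#' normalized score is its sigmoid transform, `1 / (1 + exp(-raw))`, which
#' lies strictly inside (0, 1) and preserves the ranking. A feature category
#' unseen at training time is treated as smoothed-unseen
#' (`alpha / (n_y + alpha * K)`), never an error.
#'
#' @param model a [NaiveBayesModel-class]
#' @param features data.frame of discrete features (columns must include the
#'   model's features; extra columns are ignored)
#' @return data.frame with columns `raw_score` and `norm_score`, one row per
#'   input row.
#' @export
scoreEvidence <- function(model, features) {
  stopifnot(is(model, "NaiveBayesModel"))
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  miss <- setdiff(names(model@tables), names(features))
  if (length(miss))
    stop("missing feature column(s): ", paste(miss, collapse = ", "))
  n <- nrow(features)
  raw <- rep(log(model@priors["+"]) - log(model@priors["-"]), n)
  for (f in names(model@tables)) {
    tab <- model@tables[[f]]
    K <- ncol(tab)
    unseen <- model@alpha / (model@classTotals + model@alpha * K)
    vals <- as.character(features[[f]])
    idx <- match(vals, colnames(tab))
    pPos <- ifelse(is.na(idx), unseen["+"], tab["+", ][pmax(idx, 1L)])
    pNeg <- ifelse(is.na(idx), unseen["-"], tab["-", ][pmax(idx, 1L)])
    raw <- raw + log(pPos) - log(pNeg)
  }
  data.frame(raw_score = unname(raw),
             norm_score = stats::plogis(unname(raw)))
}

#' Evaluate a ranking of scored evidence against labels
#'
#' AUC is the probability that a positive outranks a negative (ties counted
#' 0.5, equivalent to the Mann-Whitney statistic). Precision, recall and F
#' are computed at a fixed decision threshold on the normalized score
#' (predicted positive iff `score >= threshold`).
#'
#' @param scores numeric scores (normalized scores when `threshold` is used
#'   on the (0,1) scale)
#' @param labels vector of "+" / "-" (or logical); both classes required
#' @param threshold decision threshold for the F score (default 0.5)
#' @return list with elements `auc`, `f`, `precision`, `recall`.
#' @export
evaluateRanking <- function(scores, labels, threshold = 0.5) {
  if (is.logical(labels)) labels <- ifelse(labels, "+", "-")
  labels <- as.character(labels)
  if (length(unique(labels)) < 2)
    stop("both classes must be present to evaluate a ranking")
  stopifnot(length(scores) == length(labels))
  pos <- labels == "+"
  nPos <- sum(pos); nNeg <- sum(!pos)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[pos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
  pred <- scores >= threshold
  tp <- sum(pred & pos)
  precision <- if (sum(pred) == 0) 0 else tp / sum(pred)
  recall <- tp / nPos
  f <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(auc = auc, f = f, precision = precision, recall = recall)
}

#' Serialize a fitted model to JSON
#'
#' @param model a [NaiveBayesModel-class]
#' @param path output path
#' @return `path`, invisibly.
#' @export
writeEvidenceModel <- function(model, path) {
  stopifnot(is(model, "NaiveBayesModel"))
  obj <- list(
    priors = as.list(model@priors),
    alpha = model@alpha,
    class_totals = as.list(model@classTotals),
    features = lapply(model@counts, function(cnt)
      list(categories = colnames(cnt),
           counts = list(`+` = unname(cnt["+", ]), `-` = unname(cnt["-", ])))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a serialized model back from JSON
#'
#' @param path path written by [writeEvidenceModel()]
#' @return A [NaiveBayesModel-class].
#' @export
readEvidenceModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  alpha <- obj$alpha
  classTotals <- c("+" = obj$class_totals[["+"]], "-" = obj$class_totals[["-"]])
  priors <- c("+" = obj$priors[["+"]], "-" = obj$priors[["-"]])
  counts <- list(); tables <- list()
  for (f in names(obj$features)) {
    ft <- obj$features[[f]]
    cats <- ft$categories
    cnt <- rbind("+" = as.numeric(ft$counts[["+"]]),
                 "-" = as.numeric(ft$counts[["-"]]))
    colnames(cnt) <- cats
    counts[[f]] <- cnt
    tables[[f]] <- (cnt + alpha) / (classTotals + alpha * length(cats))
  }
  new("NaiveBayesModel", priors = priors, tables = tables, counts = counts,
      classTotals = classTotals, alpha = alpha)
}
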