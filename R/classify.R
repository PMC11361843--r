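# MSI status classification from unstable-locus counts.

#' Encode per-sample unstable-locus counts as model features
#'
#' The default feature is the scalar number of unstable loci in the
#' model's region stratum.  With \code{cfg$stratifyFeatures}, one count
#' per repeat class within the region plus the region total is used.
#'
#' @param summaries Named list of per-sample summary data.frames (the
#'   \code{\link{instabilitySummary}} of each sample's
#'   \code{\linkS4class{InstabilityResult}}), or a list of
#'   \code{InstabilityResult} objects.
#' @param cfg A \code{\link{trainingConfig}} naming the region stratum.
#' @return A numeric matrix (samples x features) with sample ids as row
#'   names.
#' @export
encodeFeatures <- function(summaries, cfg = trainingConfig()) {
  if (length(summaries) && methods::is(summaries[[1]], "InstabilityResult")) {
    names(summaries) <- vapply(summaries, sampleId, character(1))
    summaries <- lapply(summaries, instabilitySummary)
  }
  if (is.null(names(summaries)) || any(!nzchar(names(summaries))))
    stop("summaries must be named by sample id", call. = FALSE)
  reg <- cfg$region
  rows <- lapply(names(summaries), function(sid) {
    s <- summaries[[sid]]
    tot <- s[s$region == reg & s$class == "ALL", ]
    if (!nrow(tot) || tot$n_tested == 0L)
      stop("sample ", sid, " has no tested loci in region stratum ", reg,
           call. = FALSE)
    if (cfg$stratifyFeatures) {
      per <- vapply(c("mono", "di", "tri", "tetra"), function(k)
        s$n_unstable[s$region == reg & s$class == k], numeric(1))
      c(per, total = tot$n_unstable)
    } else {
      c(n_unstable = tot$n_unstable)
    }
  })
  x <- do.call(rbind, rows)
  rownames(x) <- names(summaries)
  x
}

#' Balanced train/test split
#'
#' Draws \code{floor(trainFraction * n_MSI-H)} MSI-H samples and an equal
#' number of MSS samples, without replacement, as the training set; all
#' remaining samples form the test set.
#'
#' @param labels Factor or character vector of \code{"MSI-H"} /
#'   \code{"MSS"} labels, named by sample id.
#' @param cfg A \code{\link{trainingConfig}}.
#' @param seed Overrides \code{cfg$seed} (used by
#'   \code{\link{crossValidate}} for per-repeat seeds).
#' @return A list with \code{train} and \code{test} (character vectors of
#'   sample ids).
#' @examples
#' labs <- setNames(rep(c("MSI-H", "MSS"), c(10, 50)), paste0("s", 1:60))
#' sp <- balancedSplit(labs, trainingConfig(seed = 1))
#' table(labs[sp$train])  # 8 + 8
#' @export
balancedSplit <- function(labels, cfg = trainingConfig(), seed = NULL) {
  if (is.null(names(labels)) || any(!nzchar(names(labels))))
    stop("labels must be named by sample id", call. = FALSE)
  ids <- names(labels)
  labels <- setNames(as.character(labels), ids)
  if (!all(labels %in% c("MSI-H", "MSS")))
    stop("labels must be 'MSI-H' or 'MSS'", call. = FALSE)
  hi <- ids[labels == "MSI-H"]
  ss <- ids[labels == "MSS"]
  if (length(hi) < 2L || length(ss) < 2L)
    stop("need at least 2 samples per class", call. = FALSE)
  nTrain <- floor(cfg$trainFraction * length(hi))
  if (nTrain < 1L)
    stop("trainFraction too small for ", length(hi), " MSI-H samples",
         call. = FALSE)
  if (length(ss) < nTrain)
    stop("fewer MSS samples (", length(ss), ") than the ", nTrain,
         " required for a balanced training set", call. = FALSE)
  set.seed(seed %||% cfg$seed)
  train <- c(sample(hi, nTrain), sample(ss, nTrain))
  list(train = train, test = setdiff(ids, train))
}

.LABEL_LEVELS <- c("MSS", "MSI-H")

#' Train an MSI status classifier
#'
#' Fits a tree ensemble -- random forest
#' (\code{\link[randomForest]{randomForest}}) or gradient-boosted trees
#' (\code{\link[xgboost]{xgboost}}) -- of \code{cfg$nTrees} trees on
#' unstable-count features.
#'
#' @param x Feature matrix from \code{\link{encodeFeatures}} (training
#'   rows).
#' @param labels \code{"MSI-H"} / \code{"MSS"} labels aligned with the
#'   rows of \code{x}.
#' @param cfg A \code{\link{trainingConfig}}.
#' @param seed Overrides \code{cfg$seed}.
#' @return An \code{\linkS4class{MSIModel}}.
#' @export
trainClassifier <- function(x, labels, cfg = trainingConfig(), seed = NULL) {
  x <- as.matrix(x)
  labels <- factor(as.character(labels), levels = .LABEL_LEVELS)
  if (any(is.na(labels))) stop("labels must be 'MSI-H' or 'MSS'",
                               call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("training data must contain both classes", call. = FALSE)
  stopifnot(nrow(x) == length(labels))
  set.seed(seed %||% cfg$seed)
  if (all(apply(x, 2, function(col) length(unique(col)) == 1L))) {
    # zero-variance design: no tree can split, every tree votes the
    # training prior (0.5 on a balanced training set)
    fit <- structure(list(prior = mean(labels == "MSI-H")),
                     class = "msirnaConstantFit")
    return(methods::new("MSIModel", modelType = cfg$modelType,
                        region = cfg$region, fit = fit,
                        featureNames = colnames(x),
                        config = unclass(cfg)))
  }
  fit <- switch(cfg$modelType,
    random_forest = randomForest::randomForest(
      x = as.data.frame(x), y = labels, ntree = cfg$nTrees),
    gradient_boosted = xgboost::xgboost(
      x, labels, nrounds = cfg$nTrees, max_depth = 3,
      learning_rate = 0.3, nthread = 1, verbosity = 0))
  methods::new("MSIModel", modelType = cfg$modelType, region = cfg$region,
               fit = fit, featureNames = colnames(x),
               config = unclass(cfg))
}

#' Predict MSI-H probabilities
#'
#' For a random forest the probability is the fraction of trees voting
#' MSI-H; for gradient-boosted trees it is the logistic ensemble score.
#' Labels use a 0.5 probability cut by default.
#'
#' @param model An \code{\linkS4class{MSIModel}}.
#' @param x Feature matrix with the model's feature columns.
#' @param cutoff Probability threshold for the MSI-H label (default 0.5).
#' @return A data.frame with \code{sample_id}, \code{probability},
#'   \code{label}.
#' @export
predictProbability <- function(model, x, cutoff = 0.5) {
  stopifnot(methods::is(model, "MSIModel"))
  x <- as.matrix(x)
  if (!identical(colnames(x), model@featureNames))
    stop("feature columns do not match the model: expected ",
         paste(model@featureNames, collapse = ", "), call. = FALSE)
  prob <- if (inherits(model@fit, "msirnaConstantFit")) {
    rep(model@fit$prior, nrow(x))
  } else switch(model@modelType,
    random_forest = stats::predict(model@fit, as.data.frame(x),
                                   type = "prob")[, "MSI-H"],
    gradient_boosted = stats::predict(model@fit, x, type = "response"))
  data.frame(sample_id = rownames(x) %||% as.character(seq_len(nrow(x))),
             probability = as.numeric(prob),
             label = ifelse(prob >= cutoff, "MSI-H", "MSS"),
             row.names = NULL)
}

#' Area under the ROC curve
#'
#' \eqn{AUC = P(s_+ > s_-) + \frac12 P(s_+ = s_-)} over all
#' positive/negative pairs, computed by the rank formula (ties get half
#' weight).
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels: \code{"MSI-H"}/\code{"MSS"}, logical, or
#'   0/1 (positive = MSI-H / TRUE / 1).
#' @return AUC in [0, 1].
#' @examples
#' computeAuc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))  # 1
#' @export
computeAuc <- function(scores, labels) {
  pos <- if (is.character(labels) || is.factor(labels))
    as.character(labels) == "MSI-H" else as.logical(labels)
  if (any(is.na(pos))) stop("unrecognized labels", call. = FALSE)
  nP <- sum(pos); nN <- sum(!pos)
  if (nP == 0L || nN == 0L)
    stop("both classes must be present to compute an AUC", call. = FALSE)
  r <- rank(scores)  # average ranks handle ties as half-concordant
  (sum(r[pos]) - nP * (nP + 1) / 2) / (nP * nN)
}

#' Repeated balanced-resampling cross-validation
#'
#' Runs \code{cfg$nRepeats} independent cycles of
#' \code{\link{balancedSplit}} -> \code{\link{trainClassifier}} ->
#' evaluate on the held-out samples, with per-repeat seeds derived from
#' \code{cfg$seed}.
#'
#' @param x Feature matrix (all samples).
#' @param labels Labels aligned with (and named like) the rows of
#'   \code{x}.
#' @param cfg A \code{\link{trainingConfig}}.
#' @return A list with \code{aucs} (per-repeat test AUCs), \code{mean},
#'   and \code{sd} (\code{NA} when \code{nRepeats = 1}).
#' @export
crossValidate <- function(x, labels, cfg = trainingConfig()) {
  x <- as.matrix(x)
  labels <- setNames(as.character(labels), rownames(x))
  aucs <- vapply(seq_len(cfg$nRepeats), function(i) {
    s <- deriveSeed(cfg$seed, i)
    sp <- balancedSplit(labels, cfg, seed = s)
    model <- trainClassifier(x[sp$train, , drop = FALSE], labels[sp$train],
                             cfg, seed = deriveSeed(s, 1L))
    pred <- predictProbability(model, x[sp$test, , drop = FALSE])
    computeAuc(pred$probability, labels[sp$test])
  }, numeric(1))
  list(aucs = aucs, mean = mean(aucs),
       sd = if (cfg$nRepeats > 1L) stats::sd(aucs) else NA_real_)
}
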