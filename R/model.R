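# Random-forest efficacy classifier on one-hot-encoded 50-mer target
# windows, with trichotomous labels, stratified 85/15 splitting, balanced
# K-fold cross-validation, repeated segmentation and evaluation by the
# prevalence-adjusted area under the precision-recall curve (AUCPR_adj).

#' One-hot encode a 50-nt target window
#'
#' Per position, `A = [1,0,0,0]`, `U = [0,1,0,0]`, `C = [0,0,1,0]`,
#' `G = [0,0,0,1]`; a `?` (isoform-discordant position) contributes a
#' zero block, preserving the fixed 200-dimensional feature space.
#'
#' @param window character string of length `width` over `A,C,G,U,?`.
#' @param width expected window width.
#' @return numeric vector of length `4 * width`.
#' @export
encodeWindow <- function(window, width = 50) {
  ch <- strsplit(window, "")[[1]]
  if (length(ch) != width)
    stop("window must have length ", width)
  bad <- which(!ch %in% c("A", "C", "G", "U", "?"))
  if (length(bad))
    stop("invalid character '", ch[bad[1]], "' at window position ",
         bad[1])
  enc <- matrix(0, nrow = 4, ncol = width)
  ord <- c(A = 1L, U = 2L, C = 3L, G = 4L)
  for (i in seq_len(width))
    if (ch[i] != "?") enc[ord[[ch[i]]], i] <- 1
  as.vector(enc)
}

#' Decode a one-hot feature vector back to a window
#'
#' Inverse of [encodeWindow()]; zero blocks decode to `?`.
#' @param v numeric vector of length `4 * width`.
#' @param width window width.
#' @return character window.
#' @export
decodeWindow <- function(v, width = 50) {
  enc <- matrix(v, nrow = 4)
  bases <- c("A", "U", "C", "G")
  paste(apply(enc, 2, function(col) {
    k <- which(col == 1)
    if (length(k) == 1) bases[k] else "?"
  }), collapse = "")
}

#' Encode many windows into a feature matrix
#' @param windows character vector of windows.
#' @param width window width.
#' @return numeric matrix, one row per window, `4 * width` columns.
#' @export
encodeWindows <- function(windows, width = 50) {
  t(vapply(windows, encodeWindow, numeric(4 * width), width = width,
           USE.NAMES = FALSE))
}

#' Label examples from mean expression values
#'
#' Delegates to [classifyHit()]; undefined examples are retained in the
#' output but are excluded from model fitting and PR evaluation by the
#' downstream functions.
#'
#' @param examples data.frame with a `mean` column (percent expression).
#' @param h1,h2 effective / ineffective cutoffs.
#' @return the data.frame with a `label` column added.
#' @export
labelExamples <- function(examples, h1 = 35, h2 = 55) {
  examples$label <- classifyHit(examples$mean,
                                labelThresholds(h1 = h1, h2 = h2))
  examples
}

#' Random-forest model parameters
#'
#' Defaults: 200 trees of maximum depth 3 (enforced as at most
#' `2^max_depth` terminal nodes) with at least one sample per leaf.
#'
#' @param n_trees number of trees.
#' @param max_depth maximum tree depth.
#' @param min_samples_leaf minimum samples per leaf.
#' @return validated parameter list.
#' @export
modelParams <- function(n_trees = 200, max_depth = 3,
                        min_samples_leaf = 1) {
  stopifnot(n_trees >= 1, max_depth >= 1, min_samples_leaf >= 1)
  list(n_trees = as.integer(n_trees), max_depth = as.integer(max_depth),
       min_samples_leaf = as.integer(min_samples_leaf))
}

#' Split scheme for repeated segmentation
#'
#' @param holdout_fraction holdout proportion (0.15: an 85/15 split).
#' @param K cross-validation folds.
#' @param n_repeats segmentation repeats.
#' @return validated scheme list.
#' @export
splitScheme <- function(holdout_fraction = 0.15, K = 10,
                        n_repeats = 1000) {
  stopifnot(holdout_fraction > 0, holdout_fraction < 1, K >= 2,
            n_repeats >= 1)
  list(holdout_fraction = holdout_fraction, K = as.integer(K),
       n_repeats = as.integer(n_repeats))
}

#' Stratified train/holdout split
#'
#' Samples the holdout within each class so class proportions match
#' between train and holdout to within one example.
#'
#' @param labels character vector over `effective` / `ineffective`.
#' @param holdout_fraction holdout proportion.
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `holdout`
#'   (a partition of `seq_along(labels)`).
#' @export
splitBalanced <- function(labels, holdout_fraction = 0.15, seed = 1) {
  classes <- unique(labels)
  if (any(table(labels) < 2)) stop("each class needs at least 2 examples")
  withSeed(seed, {
    hold <- integer(0)
    for (cl in classes) {
      idx <- which(labels == cl)
      n_h <- max(1L, round(length(idx) * holdout_fraction))
      hold <- c(hold, sample(idx, n_h))
    }
    list(train = setdiff(seq_along(labels), hold), holdout = sort(hold))
  })
}

#' Stratified K-fold assignment
#'
#' @param labels class labels.
#' @param K number of folds (at most the smaller class size).
#' @param seed integer seed.
#' @return integer fold id per example; per class, fold sizes differ by
#'   at most one.
#' @export
kfoldAssign <- function(labels, K = 10, seed = 1) {
  if (K > min(table(labels)))
    stop("K exceeds the smaller class size")
  withSeed(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(K), length(idx))
    }
    fold
  })
}

#' Train the random-forest efficacy classifier
#'
#' An ensemble of depth-limited classification trees; the example score
#' is the fraction of trees voting `effective`.
#'
#' @param X feature matrix ([encodeWindows()]).
#' @param labels `effective` / `ineffective` per row.
#' @param params [modelParams()].
#' @param seed integer seed.
#' @return fitted [randomForest::randomForest] object.
#' @export
trainForest <- function(X, labels, params = modelParams(), seed = 1) {
  y <- factor(labels, levels = c("ineffective", "effective"))
  if (length(unique(labels)) < 2) stop("training set has a single class")
  withSeed(seed, {
    randomForest::randomForest(
      x = X, y = y, ntree = params$n_trees,
      maxnodes = 2L^params$max_depth,
      nodesize = params$min_samples_leaf)
  })
}

#' Continuous efficacy scores from a fitted forest
#' @param model fitted forest.
#' @param X feature matrix.
#' @return numeric scores in `[0, 1]` (probability of `effective`).
#' @export
predictScores <- function(model, X) {
  unname(stats::predict(model, X, type = "prob")[, "effective"])
}

#' Precision-recall evaluation with prevalence adjustment
#'
#' The PR curve is traced over decreasing score thresholds with tied
#' scores treated as one threshold group; the area is accumulated
#' stepwise, `AUCPR = sum (R_i - R_(i-1)) * P_i`. The adjusted metric
#' subtracts the area defined by precision at maximum recall -- the
#' positive-class prevalence -- so models trained on datasets with
#' different hit proportions are comparable:
#' `AUCPR_adj = AUCPR - prevalence`. A perfect ranking gives
#' `AUCPR_adj = 1 - prevalence`; constant scores give 0.
#'
#' @param scores numeric scores (higher = more likely effective).
#' @param labels `effective` / `ineffective` per score (both classes
#'   present).
#' @return list with `curve` (data.frame `recall`, `precision`),
#'   `aucpr`, `prevalence`, `aucpr_adj`.
#' @export
prEvaluate <- function(scores, labels) {
  pos <- labels == "effective"
  P <- sum(pos); N <- sum(!pos)
  if (P == 0 || N == 0) stop("PR evaluation needs both classes")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- pos[ord]
  grp_end <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(y)[grp_end]
  n_pred <- grp_end
  recall <- tp / P
  precision <- tp / n_pred
  dR <- diff(c(0, recall))
  aucpr <- sum(dR * precision)
  prevalence <- P / (P + N)
  list(curve = data.frame(recall = recall, precision = precision),
       aucpr = aucpr, prevalence = prevalence,
       aucpr_adj = aucpr - prevalence)
}

#' Undersample positives to a target prevalence
#'
#' Randomly removes `effective` examples until their prevalence matches
#' the target to within one example; negatives are untouched.
#'
#' @param labels class labels.
#' @param target_prevalence desired positive fraction (below the current
#'   one).
#' @param seed integer seed.
#' @return integer indices of the retained examples.
#' @export
undersamplePositives <- function(labels, target_prevalence, seed = 1) {
  pos <- which(labels == "effective")
  neg <- which(labels != "effective")
  cur <- length(pos) / length(labels)
  if (target_prevalence >= cur)
    stop("target prevalence must be below the current prevalence")
  n_keep <- round(target_prevalence * length(neg) /
                  (1 - target_prevalence))
  withSeed(seed, sort(c(neg, sample(pos, n_keep))))
}

#' Repeated segmentation pipeline
#'
#' For each repeat: a stratified 85/15 split, optional stratified K-fold
#' cross-validation on the training set, a final model fit on the full
#' training set, and holdout evaluation by AUCPR_adj. All randomness
#' derives from the master seed.
#'
#' @param windows character windows (or a prebuilt feature matrix in
#'   `X`).
#' @param labels `effective` / `ineffective` per example; `undefined`
#'   examples are dropped before splitting.
#' @param scheme [splitScheme()].
#' @param params [modelParams()].
#' @param seed master integer seed.
#' @param do_cv run the K-fold cross-validation (skim it off for speed
#'   when only holdout performance is needed).
#' @param shuffle_labels permute labels independently per repeat (null
#'   calibration).
#' @param X optional feature matrix overriding `windows`.
#' @return list with `holdout_aucpr_adj` (length `n_repeats`),
#'   `cv_aucpr_adj` (mean over folds per repeat, `NA` when `do_cv` is
#'   off), `mean`, `sd`.
#' @export
repeatPipeline <- function(windows, labels, scheme = splitScheme(),
                           params = modelParams(), seed = 1,
                           do_cv = TRUE, shuffle_labels = FALSE,
                           X = NULL) {
  keep <- labels %in% c("effective", "ineffective")
  labels <- labels[keep]
  if (is.null(X)) X <- encodeWindows(windows[keep]) else X <- X[keep, ]
  hold_res <- cv_res <- rep(NA_real_, scheme$n_repeats)
  for (r in seq_len(scheme$n_repeats)) {
    lab <- labels
    if (shuffle_labels)
      lab <- withSeed(childSeed(seed, 10000 + r), sample(labels))
    sp <- splitBalanced(lab, scheme$holdout_fraction,
                        seed = childSeed(seed, 2 * r))
    if (do_cv) {
      fold <- kfoldAssign(lab[sp$train], scheme$K,
                          seed = childSeed(seed, 2 * r + 1))
      aucs <- vapply(seq_len(scheme$K), function(k) {
        tr <- sp$train[fold != k]; te <- sp$train[fold == k]
        if (length(unique(lab[te])) < 2 || length(unique(lab[tr])) < 2)
          return(NA_real_)
        m <- trainForest(X[tr, , drop = FALSE], lab[tr], params,
                         seed = childSeed(seed, 100000 + r * 100 + k))
        prEvaluate(predictScores(m, X[te, , drop = FALSE]),
                   lab[te])$aucpr_adj
      }, 0)
      cv_res[r] <- mean(aucs, na.rm = TRUE)
    }
    m <- trainForest(X[sp$train, , drop = FALSE], lab[sp$train], params,
                     seed = childSeed(seed, 3 * r + 2))
    hold_res[r] <- prEvaluate(
      predictScores(m, X[sp$holdout, , drop = FALSE]),
      lab[sp$holdout])$aucpr_adj
  }
  list(holdout_aucpr_adj = hold_res, cv_aucpr_adj = cv_res,
       mean = mean(hold_res), sd = stats::sd(hold_res))
}
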