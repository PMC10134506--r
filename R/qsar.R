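## Combinatorial QSAR engine: 5 algorithms (ADA, BNB, KNN, RF, SVM) x 3
## fingerprints (MACCS, ECFP, FCFP) = 15 member models per assay, each
## emitting calibrated probabilities in [0, 1]; consensus = arithmetic mean.

.ALGORITHMS <- c("ADA", "BNB", "KNN", "RF", "SVM")

#' Model specification
#'
#' @param algorithm one of `"ADA"` (AdaBoost over decision stumps),
#'   `"BNB"` (Bernoulli naive Bayes), `"KNN"` (Tanimoto k-nearest
#'   neighbors), `"RF"` (random forest), `"SVM"` (RBF support vector
#'   machine with Platt-calibrated probabilities).
#' @param fingerprint_kind one of `"MACCS"`, `"ECFP"`, `"FCFP"`.
#' @param grid named list of hyperparameter candidate vectors; an empty
#'   grid uses the documented defaults without tuning (see
#'   [default_grid()]).
#' @param seed integer seed controlling all randomness of training.
#' @return a `model_spec` object.
#' @export
model_spec <- function(algorithm, fingerprint_kind, grid = list(), seed = 1L) {
  algorithm <- match.arg(algorithm, .ALGORITHMS)
  fingerprint_kind <- match.arg(fingerprint_kind, .FP_KINDS)
  structure(list(algorithm = algorithm, fingerprint_kind = fingerprint_kind,
                 grid = grid, seed = as.integer(seed)),
            class = "model_spec")
}

#' Declared hyperparameter grids
#'
#' The candidate grids searched when tuning is requested, and (first value
#' of each entry) the defaults used when a spec carries an empty grid:
#' RF: 100/500 trees, mtry sqrt/log2 of the bit count; SVM: RBF kernel with
#' cost 1/0.1/10 and gamma 1/nbits; KNN: k = 5/1/3/7; ADA: 50/100 stumps
#' with learning rate 1/0.1; BNB: Laplace smoothing alpha 1/0.1.
#'
#' @param algorithm algorithm code; see [model_spec()].
#' @return named list of candidate vectors.
#' @export
default_grid <- function(algorithm) {
  algorithm <- match.arg(algorithm, .ALGORITHMS)
  switch(algorithm,
    RF = list(num_trees = c(100, 500), mtry_rule = c("sqrt", "log2")),
    SVM = list(cost = c(1, 0.1, 10)),
    KNN = list(k = c(5, 1, 3, 7)),
    ADA = list(n_estimators = c(50, 100), learning_rate = c(1, 0.1)),
    BNB = list(alpha = c(1, 0.1))
  )
}

.grid_combos <- function(algorithm, grid) {
  if (length(grid) == 0) {
    grid <- lapply(default_grid(algorithm), `[`, 1)
  }
  combos <- expand.grid(grid, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(combos)), function(i) as.list(combos[i, , drop = FALSE]))
}

.mtry_from_rule <- function(rule, p) {
  max(1L, switch(rule, sqrt = floor(sqrt(p)), log2 = floor(log2(p)),
                 as.integer(rule)))
}

## -- per-algorithm fit / predict -------------------------------------------

.fit_one <- function(algorithm, X, y, params, seed) {
  switch(algorithm,
    RF = {
      fit <- ranger::ranger(
        x = X, y = factor(y, levels = c(0, 1)), probability = TRUE,
        num.trees = params$num_trees,
        mtry = .mtry_from_rule(params$mtry_rule, ncol(X)),
        seed = seed, num.threads = 1
      )
      list(fit = fit)
    },
    SVM = {
      # variance-scaled RBF width: gamma = 1 / (p * Var(X)), which keeps
      # kernel distances informative for sparse binary bit vectors
      p_bit <- colMeans(X)
      v <- mean(p_bit * (1 - p_bit))
      gamma <- if (v > 0) 1 / (ncol(X) * v) else 1 / ncol(X)
      fit <- local_seed(seed, e1071::svm(
        x = X, y = factor(y, levels = c(0, 1)), kernel = "radial",
        cost = params$cost, gamma = gamma,
        probability = TRUE, scale = FALSE
      ))
      list(fit = fit)
    },
    KNN = list(X = X, y = y, k = params$k),
    BNB = {
      a <- params$alpha
      n1 <- sum(y == 1); n0 <- sum(y == 0)
      theta1 <- (colSums(X[y == 1, , drop = FALSE]) + a) / (n1 + 2 * a)
      theta0 <- (colSums(X[y == 0, , drop = FALSE]) + a) / (n0 + 2 * a)
      list(theta1 = theta1, theta0 = theta0,
           logprior = log(c(n0, n1) / (n0 + n1)))
    },
    ADA = .fit_adaboost(X, y, params$n_estimators, params$learning_rate)
  )
}

# Discrete AdaBoost over one-bit decision stumps. All features are binary,
# so the best weighted stump per round reduces to vectorized weighted
# counts; ties go to the lowest feature index. The staged score is squashed
# to a probability by the logistic (sigmoid) link.
.fit_adaboost <- function(X, y, n_estimators, learning_rate) {
  n <- nrow(X)
  yy <- ifelse(y == 1, 1, -1)
  w <- rep(1 / n, n)
  feats <- integer(0); pols <- integer(0); alphas <- numeric(0)
  for (m in seq_len(n_estimators)) {
    wy1 <- w * (y == 1); wy0 <- w * (y == 0)
    a1 <- as.numeric(crossprod(X, wy1))   # weight of x=1, y=1
    a0 <- as.numeric(crossprod(X, wy0))   # weight of x=1, y=0
    tot1 <- sum(wy1)
    # stump "active iff bit set": errors are (x=1, y=0) + (x=0, y=1)
    err_pos <- a0 + (tot1 - a1)
    err <- pmin(err_pos, 1 - err_pos)
    j <- which.min(err)
    pol <- if (err_pos[j] <= 1 - err_pos[j]) 1L else -1L
    e <- min(max(err[j], 1e-10), 1 - 1e-10)
    if (e >= 0.5) break
    alpha <- learning_rate * 0.5 * log((1 - e) / e)
    h <- pol * ifelse(X[, j] == 1, 1, -1)
    w <- w * exp(-alpha * h * yy)
    w <- w / sum(w)
    feats <- c(feats, j); pols <- c(pols, pol); alphas <- c(alphas, alpha)
  }
  if (length(feats) == 0) {
    # no stump beats chance; fall back to the class prior
    return(list(feats = integer(0), pols = integer(0), alphas = numeric(0),
                prior = mean(y)))
  }
  list(feats = feats, pols = pols, alphas = alphas, prior = mean(y))
}

.predict_one <- function(algorithm, fitted, X) {
  p <- switch(algorithm,
    RF = {
      pr <- stats::predict(fitted$fit, data = X, num.threads = 1)$predictions
      pr[, "1"]
    },
    SVM = {
      pr <- attr(stats::predict(fitted$fit, X, probability = TRUE),
                 "probabilities")
      pr[, "1"]
    },
    KNN = {
      sims <- tanimoto_similarity(X, fitted$X)
      apply(sims, 1, function(s) {
        nn <- order(-s)[seq_len(min(fitted$k, length(s)))]
        mean(fitted$y[nn])
      })
    },
    BNB = {
      ll1 <- as.numeric(X %*% log(fitted$theta1) +
                          (1 - X) %*% log(1 - fitted$theta1)) +
        fitted$logprior[2]
      ll0 <- as.numeric(X %*% log(fitted$theta0) +
                          (1 - X) %*% log(1 - fitted$theta0)) +
        fitted$logprior[1]
      1 / (1 + exp(ll0 - ll1))
    },
    ADA = {
      if (length(fitted$feats) == 0) {
        rep(fitted$prior, nrow(X))
      } else {
        H <- ifelse(X[, fitted$feats, drop = FALSE] == 1, 1, -1)
        H <- sweep(H, 2, fitted$pols, "*")
        score <- as.numeric(H %*% fitted$alphas)
        1 / (1 + exp(-2 * score))
      }
    }
  )
  pmin(1, pmax(0, as.numeric(p)))
}

## -- folds, training, cross-validation -------------------------------------

# Stratified fold assignment: within each class, a seeded permutation is
# dealt round-robin; the minority class continues the cycle where the
# majority left off so overall fold sizes differ by at most one.
.stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  offset <- 0L
  for (cls in sort(unique(y), decreasing = TRUE)) {
    idx <- which(y == cls)
    perm <- local_seed(derive_seed(seed, "folds", cls), sample(idx))
    fold[perm] <- ((offset + seq_along(perm) - 1L) %% k) + 1L
    offset <- offset + length(perm)
  }
  fold
}

.metrics_at_threshold <- function(prob, y, threshold = 0.5) {
  pred <- as.integer(prob >= threshold)  # ties classified active
  classification_metrics(tp = sum(pred == 1 & y == 1),
                         fn = sum(pred == 0 & y == 1),
                         tn = sum(pred == 0 & y == 0),
                         fp = sum(pred == 1 & y == 0))
}

#' Train one QSAR model
#'
#' If the spec carries a hyperparameter grid with more than one candidate,
#' candidates are compared by internal stratified 5-fold cross-validated
#' CCR (first-best wins ties) and the winner is refit on all data; an empty
#' grid trains directly with the documented defaults. All randomness is
#' derived from `spec$seed`.
#'
#' @param spec a [model_spec()].
#' @param X integer 0/1 fingerprint matrix.
#' @param y binary labels (0/1), one per row of `X`.
#' @return a `trained_model` whose predictions are probabilities in
#'   \[0, 1\].
#' @export
train <- function(spec, X, y) {
  stopifnot(inherits(spec, "model_spec"), nrow(X) == length(y))
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("training requires both classes present")
  combos <- .grid_combos(spec$algorithm, spec$grid)
  best <- combos[[1]]
  if (length(combos) > 1) {
    fold <- .stratified_folds(y, 5, derive_seed(spec$seed, "tune"))
    score <- vapply(combos, function(params) {
      prob <- numeric(length(y))
      for (f in 1:5) {
        hold <- fold == f
        fit <- .fit_one(spec$algorithm, X[!hold, , drop = FALSE], y[!hold],
                        params, derive_seed(spec$seed, "tune", f))
        prob[hold] <- .predict_one(spec$algorithm, fit, X[hold, , drop = FALSE])
      }
      .metrics_at_threshold(prob, y)[["ccr"]]
    }, 0)
    best <- combos[[which.max(score)]]
  }
  fitted <- .fit_one(spec$algorithm, X, y, best, spec$seed)
  structure(list(spec = spec, params = best, fitted = fitted,
                 n_features = ncol(X)),
            class = "trained_model")
}

#' Predict active-class probabilities
#'
#' @param model a `trained_model`.
#' @param X fingerprint matrix with the same column count used in training.
#' @return numeric vector of probabilities in \[0, 1\].
#' @export
predict_probability <- function(model, X) {
  stopifnot(inherits(model, "trained_model"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != model$n_features) {
    stop("feature dimension mismatch: model expects ", model$n_features,
         ", got ", ncol(X))
  }
  .predict_one(model$spec$algorithm, model$fitted, X)
}

#' @export
predict.trained_model <- function(object, newdata, ...) {
  predict_probability(object, newdata)
}

# CV on an already-featurized matrix.
.cv_matrix <- function(spec, X, y, seed) {
  n <- length(y)
  if (n < 10) stop("cross-validation requires n >= 10")
  fold <- .stratified_folds(y, 5, seed)
  prob <- numeric(n)
  for (f in 1:5) {
    hold <- fold == f
    fit_spec <- spec
    fit_spec$seed <- derive_seed(spec$seed, "cv", f)
    m <- train(fit_spec, X[!hold, , drop = FALSE], y[!hold])
    prob[hold] <- predict_probability(m, X[hold, , drop = FALSE])
  }
  structure(list(spec = spec, prob = prob, fold = fold, y = y,
                 metrics = .metrics_at_threshold(prob, y)),
            class = "cv_result")
}

#' Five-fold cross-validation of one model spec
#'
#' The dataset is split into five stratified folds (sizes differing by at
#' most one); each compound is predicted exactly once while held out, and
#' the out-of-fold probabilities are scored at the 0.5 threshold (ties
#' classified active).
#'
#' @param spec a [model_spec()].
#' @param dataset balanced data.frame with `canonical_smiles` (or `smiles`)
#'   and `y`; typically the output of [undersample_balance()].
#' @param seed integer seed for the fold split.
#' @param nbits,radius fingerprint parameters; see [fingerprint()].
#' @return a `cv_result`: out-of-fold `prob`, `fold` assignment, `y`, and
#'   `metrics` (sensitivity, specificity, CCR, PPV).
#' @export
cross_validate_5fold <- function(spec, dataset, seed, nbits = 1024, radius = 3) {
  feat <- featurize_dataset(dataset, spec$fingerprint_kind,
                            nbits = nbits, radius = radius)
  .cv_matrix(spec, feat$X, as.integer(feat$y), seed)
}

## -- consensus --------------------------------------------------------------

#' The 15 member specifications of a consensus model
#'
#' @param seed base seed; each member derives its own seed from it.
#' @param grids optional named list (by algorithm) of hyperparameter grids;
#'   defaults to empty grids (documented default parameters, no tuning).
#' @return list of 15 [model_spec()] objects (5 algorithms x 3
#'   fingerprints).
#' @export
consensus_specs <- function(seed = 1L, grids = NULL) {
  out <- list()
  for (alg in .ALGORITHMS) {
    for (fpk in .FP_KINDS) {
      g <- if (!is.null(grids) && !is.null(grids[[alg]])) grids[[alg]] else list()
      out[[paste(alg, fpk, sep = "_")]] <-
        model_spec(alg, fpk, grid = g, seed = derive_seed(seed, alg, fpk))
    }
  }
  out
}

#' Build a consensus QSAR model for one assay
#'
#' Trains every member spec on the full (balanced) dataset and evaluates
#' each by five-fold cross-validation; the consensus out-of-fold
#' probability of a compound is the arithmetic mean of the members'
#' out-of-fold probabilities. Members that fail to train are skipped with a
#' warning; at least `min_members` survivors are required.
#'
#' @param assay_id assay identifier for bookkeeping.
#' @param dataset balanced data.frame with `canonical_smiles`, `y`, `id`.
#' @param specs list of [model_spec()]s (default: [consensus_specs()]).
#' @param seed base seed for fold splits.
#' @param nbits,radius fingerprint parameters.
#' @param min_members minimum surviving members (default 8).
#' @param evaluate run five-fold cross-validation for every member and the
#'   consensus (default TRUE); with FALSE only the fitted members are
#'   returned (`member_cv` and `cv` are `NULL`), which is much faster when
#'   the model is only needed for prediction.
#' @return a `consensus_model` with elements `assay_id`, `members` (trained
#'   models), `member_cv` (per-member metrics data.frame), `cv`
#'   (consensus `cv_result`), `ids`.
#' @export
build_consensus <- function(assay_id, dataset, specs = NULL, seed = 1L,
                            nbits = 1024, radius = 3, min_members = 8,
                            evaluate = TRUE) {
  if (is.null(specs)) specs <- consensus_specs(seed)
  kinds <- unique(vapply(specs, function(s) s$fingerprint_kind, ""))
  feats <- lapply(stats::setNames(kinds, kinds), function(k)
    featurize_dataset(dataset, k, nbits = nbits, radius = radius))
  keep_ids <- Reduce(intersect, lapply(feats, `[[`, "ids"))
  if (length(keep_ids) < 10) stop("fewer than 10 fingerprintable compounds")
  feats <- lapply(feats, function(f) {
    sel <- match(keep_ids, f$ids)
    list(X = f$X[sel, , drop = FALSE], y = as.integer(f$y[sel]))
  })
  y <- feats[[1]]$y

  members <- list(); member_cv <- list(); probs <- list()
  for (nm in names(specs)) {
    spec <- specs[[nm]]
    res <- tryCatch({
      Xk <- feats[[spec$fingerprint_kind]]$X
      cv <- if (evaluate) .cv_matrix(spec, Xk, y, derive_seed(seed, "memberfold"))
      fit <- train(spec, Xk, y)
      list(fit = fit, cv = cv)
    }, error = function(e) {
      warning("consensus member ", nm, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) next
    members[[nm]] <- res$fit
    if (evaluate) {
      probs[[nm]] <- res$cv$prob
      member_cv[[nm]] <- data.frame(
        member = nm, algorithm = spec$algorithm,
        fingerprint = spec$fingerprint_kind,
        t(res$cv$metrics), stringsAsFactors = FALSE)
    }
  }
  if (length(members) < min_members) {
    stop("only ", length(members), " members trained; need >= ", min_members)
  }
  cv <- NULL; member_oof <- NULL
  if (evaluate) {
    member_oof <- do.call(cbind, probs)
    rownames(member_oof) <- keep_ids
    consensus_prob <- rowMeans(member_oof)
    cv <- structure(list(spec = NULL, prob = consensus_prob,
                         fold = NULL, y = y,
                         metrics = .metrics_at_threshold(consensus_prob, y)),
                    class = "cv_result")
  }
  structure(list(assay_id = assay_id, members = members,
                 member_cv = if (evaluate)
                   do.call(rbind, c(member_cv, make.row.names = FALSE)),
                 cv = cv, member_oof = member_oof, ids = keep_ids,
                 nbits = nbits, radius = radius),
            class = "consensus_model")
}

#' @export
print.consensus_model <- function(x, ...) {
  cat("Consensus QSAR model for assay ", x$assay_id, ": ",
      length(x$members), " members\n", sep = "")
  if (!is.null(x$cv)) {
    m <- x$cv$metrics
    cat(sprintf("  5-fold CV: CCR=%.3f, sens=%.3f, spec=%.3f, PPV=%.3f\n",
                m[["ccr"]], m[["sensitivity"]], m[["specificity"]], m[["ppv"]]))
  }
  invisible(x)
}

#' Predict consensus probabilities for new structures
#'
#' @param object a `consensus_model`.
#' @param newdata character vector of SMILES or a data.frame with a
#'   `canonical_smiles`/`smiles` column.
#' @param ... unused.
#' @return numeric vector of consensus probabilities (`NA` for structures
#'   that cannot be fingerprinted), named by compound id where available.
#' @export
predict.consensus_model <- function(object, newdata, ...) {
  if (is.character(newdata)) {
    newdata <- data.frame(id = names(newdata) %||% seq_along(newdata),
                          canonical_smiles = unname(newdata),
                          stringsAsFactors = FALSE)
  }
  kinds <- unique(vapply(object$members, function(m) m$spec$fingerprint_kind, ""))
  feats <- lapply(stats::setNames(kinds, kinds), function(k)
    featurize_dataset(newdata, k, nbits = object$nbits, radius = object$radius))
  ids <- as.character(newdata$id %||% seq_len(nrow(newdata)))
  acc <- matrix(NA_real_, nrow = nrow(newdata), ncol = length(object$members),
                dimnames = list(ids, names(object$members)))
  for (nm in names(object$members)) {
    m <- object$members[[nm]]
    f <- feats[[m$spec$fingerprint_kind]]
    if (length(f$ids) == 0) next
    acc[match(f$ids, ids), nm] <- predict_probability(m, f$X)
  }
  out <- rowMeans(acc)
  stats::setNames(out, ids)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
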