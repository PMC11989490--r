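#' tf-idf configuration
#'
#' Tokens are unicode word tokens (runs of letters/digits), lower-cased and
#' accent-folded. Inverse document frequency uses add-one smoothing on the
#' document frequencies: `idf(t) = ln((1 + N) / (1 + df(t))) + 1`, so a
#' term present in every document still receives weight 1. Document rows
#' are L2-normalized.
#'
#' @param min_document_frequency drop terms occurring in fewer documents.
#' @param max_features keep at most this many terms (highest document
#'   frequency first, ties alphabetically); `NULL` keeps all.
#' @param sublinear_tf use `1 + ln(tf)` instead of raw term frequency.
#' @return object of class `tfidf_config`.
#' @export
tfidf_config <- function(min_document_frequency = 1L, max_features = NULL,
                         sublinear_tf = FALSE) {
  stopifnot(min_document_frequency >= 1L)
  structure(list(min_document_frequency = as.integer(min_document_frequency),
                 max_features = max_features, sublinear_tf = sublinear_tf),
            class = "tfidf_config")
}

tfidf_tokens <- function(texts) {
  stringi::stri_extract_all_regex(fold_text(texts), "[\\p{L}\\p{N}]+",
                                  omit_no_match = TRUE)
}

#' Fit a tf-idf vocabulary and weighting
#'
#' @param texts character vector of documents (non-empty corpus).
#' @param config a [tfidf_config()].
#' @return object of class `tfidf_model` with `vocabulary` and `idf`.
#' @export
tfidf_fit <- function(texts, config = tfidf_config()) {
  stopifnot(length(texts) > 0L)
  toks <- tfidf_tokens(texts)
  n_docs <- length(texts)
  df_counts <- table(unlist(lapply(toks, unique)))
  df_counts <- df_counts[df_counts >= config$min_document_frequency]
  if (length(df_counts) == 0L) {
    stop("configuration error: empty vocabulary after frequency filtering",
         call. = FALSE)
  }
  # highest document frequency first, ties alphabetically
  ord <- order(-as.integer(df_counts), names(df_counts))
  df_counts <- df_counts[ord]
  if (!is.null(config$max_features) &&
      length(df_counts) > config$max_features) {
    df_counts <- df_counts[seq_len(config$max_features)]
  }
  vocab <- sort(names(df_counts))
  df_v <- as.integer(df_counts[vocab])
  idf <- log((1 + n_docs) / (1 + df_v)) + 1
  structure(list(vocabulary = vocab, idf = setNames(idf, vocab),
                 n_docs = n_docs, config = config),
            class = "tfidf_model")
}

#' Transform documents into L2-normalized tf-idf vectors
#'
#' @param model a fitted `tfidf_model`.
#' @param texts character vector of documents.
#' @return sparse `dgCMatrix` (documents x vocabulary).
#' @export
tfidf_transform <- function(model, texts) {
  toks <- tfidf_tokens(texts)
  vocab <- model$vocabulary
  ijx <- lapply(seq_along(toks), function(d) {
    tf <- table(toks[[d]])
    tf <- tf[names(tf) %in% vocab]
    if (length(tf) == 0L) return(NULL)
    w <- as.numeric(tf)
    if (model$config$sublinear_tf) w <- 1 + log(w)
    data.frame(i = d, j = match(names(tf), vocab),
               x = w * unname(model$idf[names(tf)]))
  })
  ijx <- do.call(rbind, ijx)
  if (is.null(ijx)) {
    return(Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(length(texts), length(vocab)),
                                dimnames = list(NULL, vocab)))
  }
  m <- Matrix::sparseMatrix(i = ijx$i, j = ijx$j, x = ijx$x,
                            dims = c(length(texts), length(vocab)),
                            dimnames = list(NULL, vocab))
  norms <- sqrt(Matrix::rowSums(m^2))
  norms[norms == 0] <- 1
  Matrix::Diagonal(x = 1 / norms) %*% m
}

#' @rdname tfidf_fit
#' @return `tfidf_fit_transform()` returns a list with the fitted `model`
#'   and the weight `matrix`.
#' @export
tfidf_fit_transform <- function(texts, config = tfidf_config()) {
  model <- tfidf_fit(texts, config)
  list(model = model, matrix = tfidf_transform(model, texts))
}

#' Feedforward network configuration
#'
#' A fully connected feedforward network with sigmoid output and binary
#' cross-entropy loss, trained full-batch with Adam and L2 weight decay.
#' With `early_stopping` a fraction of the training data is held aside as
#' a validation split and training stops once validation loss has not
#' improved for `patience` epochs (the best weights are restored).
#'
#' @param hidden_layers integer vector of hidden layer widths.
#' @param activation hidden nonlinearity: `"relu"` or `"tanh"`.
#' @param learning_rate Adam step size.
#' @param max_epochs maximum training epochs.
#' @param decay L2 weight decay.
#' @param early_stopping use a validation split for early stopping.
#' @param validation_fraction fraction held out for early stopping.
#' @param patience epochs without validation improvement before stopping.
#' @param seed integer seed for initialization and the validation split.
#' @return object of class `ff_config`.
#' @export
ff_config <- function(hidden_layers = 64L, activation = c("relu", "tanh"),
                      learning_rate = 0.01, max_epochs = 300L,
                      decay = 1e-4, early_stopping = TRUE,
                      validation_fraction = 0.1, patience = 25L,
                      seed = 1L) {
  stopifnot(all(hidden_layers >= 1L), learning_rate > 0, max_epochs >= 1L,
            decay >= 0)
  structure(list(hidden_layers = as.integer(hidden_layers),
                 activation = match.arg(activation),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs), decay = decay,
                 early_stopping = isTRUE(early_stopping),
                 validation_fraction = validation_fraction,
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "ff_config")
}

ff_forward <- function(weights, x, activation) {
  a <- x
  hs <- list()
  n_layers <- length(weights)
  for (l in seq_len(n_layers)) {
    z <- a %*% weights[[l]]$W +
      matrix(weights[[l]]$b, nrow(a), length(weights[[l]]$b), byrow = TRUE)
    if (l < n_layers) {
      a <- if (activation == "relu") pmax(z, 0) else tanh(z)
      hs[[l]] <- a
    } else {
      a <- 1 / (1 + exp(-z))
    }
  }
  list(prob = as.numeric(a), hidden = hs)
}

ff_loss <- function(p, y, weights, decay) {
  eps <- 1e-12
  ce <- -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
  l2 <- sum(vapply(weights, function(w) sum(w$W^2), 0))
  ce + decay * l2 / 2
}

#' Train the feedforward AF-onset classifier
#'
#' @param x numeric feature matrix (dense or sparse; coerced to dense),
#'   documents in rows.
#' @param y logical or 0/1 vector (TRUE/1 = af_onset).
#' @param config an [ff_config()].
#' @return object of class `ff_model`.
#' @export
ff_train <- function(x, y, config = ff_config()) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)), nrow(x) == length(y))
  if (length(unique(y)) < 2L) {
    stop("input error: single-class training set", call. = FALSE)
  }
  with_seed(config$seed, ff_train_impl(x, y, config))
}

ff_train_impl <- function(x, y, config) {
  dims <- c(ncol(x), config$hidden_layers, 1L)
  weights <- lapply(seq_len(length(dims) - 1L), function(l) {
    fan_in <- dims[l]
    list(W = matrix(rnorm(dims[l] * dims[l + 1L], sd = sqrt(2 / fan_in)),
                    dims[l], dims[l + 1L]),
         b = rep(0, dims[l + 1L]))
  })

  # validation split for early stopping (kept class-stratified)
  val_idx <- integer()
  if (config$early_stopping) {
    n_val <- floor(nrow(x) * config$validation_fraction)
    if (n_val >= 4L) {
      val_idx <- unlist(lapply(c(0, 1), function(cl) {
        idx <- which(y == cl)
        sample(idx, max(1L, round(length(idx) * config$validation_fraction)))
      }))
    }
  }
  if (length(val_idx)) {
    x_val <- x[val_idx, , drop = FALSE]
    y_val <- y[val_idx]
    x_tr <- x[-val_idx, , drop = FALSE]
    y_tr <- y[-val_idx]
  } else {
    x_tr <- x
    y_tr <- y
  }

  m_state <- lapply(weights, function(w)
    list(W = w$W * 0, b = w$b * 0))
  v_state <- m_state
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  best <- list(loss = Inf, weights = weights, epoch = 0L)
  wait <- 0L
  n <- nrow(x_tr)
  n_layers <- length(weights)

  for (epoch in seq_len(config$max_epochs)) {
    fwd <- ff_forward(weights, x_tr, config$activation)
    p <- fwd$prob
    # backprop
    grads <- vector("list", n_layers)
    delta <- matrix((p - y_tr) / n, n, 1)
    for (l in rev(seq_len(n_layers))) {
      a_prev <- if (l == 1L) x_tr else fwd$hidden[[l - 1L]]
      grads[[l]] <- list(
        W = crossprod(a_prev, delta) + config$decay * weights[[l]]$W,
        b = colSums(delta))
      if (l > 1L) {
        delta <- delta %*% t(weights[[l]]$W)
        h <- fwd$hidden[[l - 1L]]
        delta <- if (config$activation == "relu") {
          delta * (h > 0)
        } else {
          delta * (1 - h^2)
        }
      }
    }
    # Adam update
    for (l in seq_len(n_layers)) {
      for (part in c("W", "b")) {
        g <- grads[[l]][[part]]
        m_state[[l]][[part]] <- beta1 * m_state[[l]][[part]] +
          (1 - beta1) * g
        v_state[[l]][[part]] <- beta2 * v_state[[l]][[part]] +
          (1 - beta2) * g^2
        mhat <- m_state[[l]][[part]] / (1 - beta1^epoch)
        vhat <- v_state[[l]][[part]] / (1 - beta2^epoch)
        weights[[l]][[part]] <- weights[[l]][[part]] -
          config$learning_rate * mhat / (sqrt(vhat) + eps)
      }
    }
    if (length(val_idx)) {
      pv <- ff_forward(weights, x_val, config$activation)$prob
      vloss <- ff_loss(pv, y_val, weights, config$decay)
      if (vloss < best$loss - 1e-6) {
        best <- list(loss = vloss, weights = weights, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
  }
  final <- if (length(val_idx)) best$weights else weights
  structure(list(weights = final, config = config,
                 n_features = ncol(x)), class = "ff_model")
}

#' @export
predict.ff_model <- function(object, newdata, type = c("class", "prob"),
                             ...) {
  type <- match.arg(type)
  p <- ff_forward(object$weights, as.matrix(newdata),
                  object$config$activation)$prob
  if (type == "prob") p else as.integer(p >= 0.5)
}

#' Classification metrics from a confusion matrix
#'
#' Positive class is AF onset. Ratios with a zero denominator are reported
#' as `NA` (not applicable) and excluded from averages downstream.
#'
#' @param tp,fp,fn,tn confusion counts.
#' @return named numeric vector: accuracy, precision, recall, f1.
#' @export
confusion_metrics <- function(tp, fp, fn, tn) {
  total <- tp + fp + fn + tn
  acc <- if (total > 0) (tp + tn) / total else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0) {
    2 * prec * rec / (prec + rec)
  } else NA_real_
  c(accuracy = acc, precision = prec, recall = rec, f1 = f1)
}

confusion_counts <- function(truth, pred) {
  c(tp = sum(truth == 1 & pred == 1), fp = sum(truth == 0 & pred == 1),
    fn = sum(truth == 1 & pred == 0), tn = sum(truth == 0 & pred == 0))
}

# stratified fold assignment, seed-deterministic
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      if (length(idx) < k) {
        stop("input error: class '", cls, "' has fewer members (",
             length(idx), ") than folds (", k, ")", call. = FALSE)
      }
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

#' Stratified k-fold evaluation of the tf-idf + feedforward classifier
#'
#' The tf-idf vocabulary and idf weights are fitted on the training folds
#' only, so no test-fold information leaks into the features. The seed
#' controls both the fold assignment and the network initialization.
#'
#' @param corpus a `labeled_corpus` (or data.frame with `text`, `label`).
#' @param tfidf a [tfidf_config()].
#' @param ff an [ff_config()].
#' @param k_folds number of folds.
#' @param seed integer seed.
#' @return object of class `eval_result`: per-fold metric data.frame,
#'   fold assignments and per-fold confusion matrices.
#' @export
crossval_evaluate <- function(corpus, tfidf = tfidf_config(),
                              ff = ff_config(), k_folds = 5L, seed = 1L) {
  y <- as.integer(corpus$label == "af_onset")
  if (length(unique(y)) < 2L) {
    stop("input error: single-class corpus", call. = FALSE)
  }
  fold <- stratified_folds(y, k_folds, seed)
  per_fold <- list()
  confusions <- list()
  for (f in seq_len(k_folds)) {
    tr <- fold != f
    fitted <- tfidf_fit_transform(corpus$text[tr], tfidf)
    x_te <- tfidf_transform(fitted$model, corpus$text[!tr])
    ff_f <- ff
    ff_f$seed <- derive_seed(ff$seed, seed, f)
    model <- ff_train(fitted$matrix, y[tr], ff_f)
    pred <- predict(model, x_te)
    cm <- confusion_counts(y[!tr], pred)
    confusions[[f]] <- cm
    per_fold[[f]] <- data.frame(fold = f, t(confusion_metrics(
      cm[["tp"]], cm[["fp"]], cm[["fn"]], cm[["tn"]])))
  }
  structure(list(metrics = do.call(rbind, per_fold), folds = fold,
                 confusions = confusions, k_folds = k_folds, seed = seed),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat("<eval_result> ", x$k_folds, "-fold cross-validation\n", sep = "")
  means <- colMeans(x$metrics[, -1, drop = FALSE], na.rm = TRUE)
  print(round(means, 4))
  invisible(x)
}

#' Classic paired t-test on per-fold metric vectors
#'
#' Degenerate contracts: identical vectors give `t = 0, p = 1`; a constant
#' nonzero difference (zero variance) gives an infinite `t` and `p = 0`.
#'
#' @param scores_a,scores_b equal-length (>= 2) paired metric vectors.
#' @return list with `t`, `p` (two-sided), `df`, `mean_difference`.
#' @export
paired_ttest <- function(scores_a, scores_b) {
  stopifnot(length(scores_a) == length(scores_b), length(scores_a) >= 2L)
  d <- scores_a - scores_b
  n <- length(d)
  md <- mean(d)
  s <- sd(d)
  if (s == 0) {
    if (md == 0) {
      return(list(t = 0, p = 1, df = n - 1L, mean_difference = 0))
    }
    return(list(t = sign(md) * Inf, p = 0, df = n - 1L,
                mean_difference = md))
  }
  t_stat <- md / (s / sqrt(n))
  list(t = t_stat, p = 2 * pt(-abs(t_stat), df = n - 1L), df = n - 1L,
       mean_difference = md)
}

#' Compare intersection- and union-trained classifiers on shared held-out
#' data
#'
#' For each of `k_folds` resamples, one fold is dropped from each training
#' corpus, a tf-idf + feedforward model is trained on the remainder, and
#' both models are evaluated on the same gold-labeled held-out set; the
#' per-resample held-out error rates are compared with a paired t-test
#' (union minus intersection).
#'
#' @param corpus_a,corpus_b `labeled_corpus` objects sharing the negative
#'   pool (typically intersection and union).
#' @param heldout data.frame with `report_id`, `text`, `label`; must not
#'   overlap the training corpora.
#' @param tfidf,ff,k_folds,seed as in [crossval_evaluate()].
#' @return list with per-corpus mean held-out metrics, per-resample error
#'   vectors, and the paired test.
#' @export
compare_corpora <- function(corpus_a, corpus_b, heldout,
                            tfidf = tfidf_config(), ff = ff_config(),
                            k_folds = 5L, seed = 1L) {
  train_ids <- union(corpus_a$report_id, corpus_b$report_id)
  if (length(intersect(train_ids, heldout$report_id)) > 0L) {
    stop("input error: held-out set overlaps a training corpus",
         call. = FALSE)
  }
  y_h <- as.integer(heldout$label == "af_onset")

  eval_corpus <- function(corpus, tag) {
    y <- as.integer(corpus$label == "af_onset")
    fold <- stratified_folds(y, k_folds, derive_seed(seed, tag))
    errs <- numeric(k_folds)
    cms <- list()
    for (f in seq_len(k_folds)) {
      tr <- fold != f
      fitted <- tfidf_fit_transform(corpus$text[tr], tfidf)
      ff_f <- ff
      ff_f$seed <- derive_seed(ff$seed, seed, tag, f)
      model <- ff_train(fitted$matrix, y[tr], ff_f)
      pred <- predict(model, tfidf_transform(fitted$model, heldout$text))
      cm <- confusion_counts(y_h, pred)
      cms[[f]] <- cm
      errs[f] <- (cm[["fp"]] + cm[["fn"]]) / sum(cm)
    }
    list(errors = errs, confusions = cms)
  }

  a <- eval_corpus(corpus_a, "a")
  b <- eval_corpus(corpus_b, "b")
  mean_metrics <- function(res) {
    m <- sapply(res$confusions, function(cm) {
      confusion_metrics(cm[["tp"]], cm[["fp"]], cm[["fn"]], cm[["tn"]])
    })
    rowMeans(m, na.rm = TRUE)
  }
  list(a = list(name = attr(corpus_a, "name"), errors = a$errors,
                mean_error = mean(a$errors), metrics = mean_metrics(a)),
       b = list(name = attr(corpus_b, "name"), errors = b$errors,
                mean_error = mean(b$errors), metrics = mean_metrics(b)),
       paired = paired_ttest(b$errors, a$errors))
}
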