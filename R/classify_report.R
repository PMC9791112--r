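#' Classifier specification
#'
#' One of the four model families used for LN vs non-LN classification,
#' with its decision threshold on the held-out score. Reference
#' thresholds: 0.63 (logistic regression), 0 (decision tree), 0.23
#' (random forest), 0.2 (support-vector classifier; 0.24 when MFR
#' features are used). Hyperparameters are deliberately left at library
#' defaults apart from the stated ones (tree split criterion = entropy,
#' 30 forest trees): with so few samples, tuning would overfit.
#'
#' @param kind `"logistic"`, `"decision_tree"`, `"random_forest"` or
#'   `"svc"`.
#' @param threshold Decision threshold on the held-out score; `NULL`
#'   picks the reference default for `kind`.
#' @param params Named list of extra arguments passed to the underlying
#'   fitting function.
#' @return List of class `model_spec`.
#' @export
model_spec <- function(kind = c("logistic", "decision_tree",
                                "random_forest", "svc"),
                       threshold = NULL, params = list()) {
  kind <- match.arg(kind)
  defaults <- c(logistic = 0.63, decision_tree = 0,
                random_forest = 0.23, svc = 0.2)
  if (is.null(threshold)) threshold <- unname(defaults[kind])
  if (kind != "decision_tree" && (threshold < 0 || threshold > 1))
    stop("threshold must lie in [0, 1] for probability-output models")
  structure(list(kind = kind, threshold = threshold, params = params),
            class = "model_spec")
}

## fit on training rows, return P(case) for the held-out row(s)
fit_predict <- function(spec, x_train, y_train, x_test) {
  x_train <- as.data.frame(x_train)
  x_test <- as.data.frame(x_test)
  y <- factor(y_train, levels = c("control", "case"))
  switch(spec$kind,
    logistic = {
      ridge_feasible <- ncol(x_train) >= 2L && min(table(y)) >= 2L
      if (ncol(x_train) <= nrow(x_train) - 2L || !ridge_feasible) {
        dat <- cbind(x_train, .y = as.integer(y == "case"))
        fit <- suppressWarnings(do.call(stats::glm,
          c(list(formula = .y ~ ., family = stats::binomial(), data = dat),
            spec$params)))
        as.numeric(suppressWarnings(
          stats::predict(fit, newdata = x_test, type = "response")))
      } else {
        ## more features than samples: maximum likelihood is degenerate,
        ## so fit the L2-regularised (ridge) logistic model instead
        fit <- suppressWarnings(do.call(glmnet::glmnet,
          c(list(x = as.matrix(x_train), y = y, family = "binomial",
                 alpha = 0, lambda = 1 / nrow(x_train)),
            spec$params)))
        as.numeric(stats::predict(fit, newx = as.matrix(x_test),
                                  type = "response"))
      }
    },
    decision_tree = {
      dat <- cbind(x_train, .y = y)
      ## sklearn-like growth limits: split down to pure leaves
      ctrl <- rpart::rpart.control(minsplit = 2L, minbucket = 1L, cp = 0,
                                   xval = 0L)
      fit <- do.call(rpart::rpart,
        c(list(formula = .y ~ ., data = dat, method = "class",
               parms = list(split = "information"), control = ctrl),
          spec$params))
      as.numeric(stats::predict(fit, newdata = x_test,
                                type = "prob")[, "case"])
    },
    random_forest = {
      fit <- do.call(randomForest::randomForest,
        c(list(x = x_train, y = y, ntree = 30L), spec$params))
      as.numeric(stats::predict(fit, newdata = x_test,
                                type = "prob")[, "case"])
    },
    svc = {
      xm <- as.matrix(x_train)
      ## RBF bandwidth 1 / (n_features * overall variance), so the kernel
      ## resolves differences on the data's own scale
      gam <- 1 / (ncol(xm) * max(stats::var(as.vector(xm)), 1e-12))
      fit <- do.call(e1071::svm,
        c(list(x = xm, y = y, probability = TRUE,
               kernel = "radial", cost = 1, gamma = gam, scale = FALSE),
          spec$params))
      pr <- stats::predict(fit, newdata = as.matrix(x_test),
                           probability = TRUE)
      as.numeric(attr(pr, "probabilities")[, "case"])
    })
}

#' Leave-one-out cross-validated prediction
#'
#' For each sample, trains the specified model on the remaining samples
#' and records the held-out case probability (or class score); labels are
#' then assigned by comparing the score to the model threshold
#' (`score > threshold` -> case). Folds whose training set contains a
#' single class are flagged and not scored.
#'
#' @param features Numeric matrix or data frame, rows = samples (rownames
#'   = sample ids), columns = features; no missing values.
#' @param labels Data frame with `sample_id`, `group` (`"case"` /
#'   `"control"`), or a vector aligned with the rows.
#' @param spec A [model_spec()].
#' @param seed Integer seed (re-seeded per fold, so results are
#'   reproducible for the stochastic models).
#' @return Object of class `loocv_result`: data frame with `sample_id`,
#'   `true`, `score`, `predicted`, plus attributes `kind` and
#'   `threshold`.
#' @export
loocv_predict <- function(features, labels, spec = model_spec("logistic"),
                          seed = 1L) {
  features <- as.matrix(features)
  if (anyNA(features)) stop("features must not contain missing values")
  if (nrow(features) < 3L) stop("need at least 3 samples")
  if (is.data.frame(labels)) {
    grp <- labels$group[match(rownames(features), labels$sample_id)]
  } else grp <- as.character(labels)
  if (anyNA(grp)) stop("every sample needs a label")

  n <- nrow(features)
  score <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    y_tr <- grp[-i]
    if (length(unique(y_tr)) < 2L) next  # one-class fold: flagged, unscored
    set.seed(seed + i)
    score[i] <- fit_predict(spec, features[-i, , drop = FALSE], y_tr,
                            features[i, , drop = FALSE])
  }
  out <- data.frame(sample_id = rownames(features), true = grp,
                    score = score,
                    predicted = ifelse(is.na(score), NA_character_,
                                       ifelse(score > spec$threshold,
                                              "case", "control")),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "kind") <- spec$kind
  attr(out, "threshold") <- spec$threshold
  class(out) <- c("loocv_result", "data.frame")
  out
}

#' Agreement of binary predictions across models
#'
#' @param ... Two or more `loocv_result` objects (or a single list of
#'   them) over the same samples.
#' @return List with `per_sample` (sample_id, one predicted-label column
#'   per model, `agree` flag) and `concordance` (fraction of samples on
#'   which all models agree).
#' @export
concordance <- function(...) {
  results <- list(...)
  if (length(results) == 1L && !inherits(results[[1L]], "loocv_result"))
    results <- results[[1L]]
  if (length(results) < 2L) stop("need at least 2 model results")
  ids <- results[[1L]]$sample_id
  kinds <- vapply(seq_along(results), function(i) {
    k <- attr(results[[i]], "kind")
    if (is.null(k)) sprintf("model%d", i) else k
  }, character(1L))
  kinds <- make.unique(kinds)
  per <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  for (i in seq_along(results)) {
    r <- results[[i]]
    if (!identical(sort(r$sample_id), sort(ids)))
      stop("all results must cover the same samples")
    per[[kinds[i]]] <- r$predicted[match(ids, r$sample_id)]
  }
  pred <- as.matrix(per[, kinds, drop = FALSE])
  per$agree <- apply(pred, 1L, function(z) length(unique(z)) == 1L)
  list(per_sample = per, concordance = mean(per$agree))
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Orchestrates simulation -> fragmentomics -> region metrics -> feature
#' selection -> methylation scores -> exact group tests -> LOOCV
#' classification, and returns (optionally writes) a machine-readable
#' results list plus a short human-readable report. Any stage failure is
#' rethrown with a stage label.
#'
#' @param config Nested list (or path to a YAML file) with optional
#'   blocks: `sim` (arguments of [sim_config()]), `fragmentomics`
#'   (`motif`, `min_mapq`, `loess_span`), `scoring` (`metric`, `alpha`,
#'   `side`), `classify` (`models` = kinds vector, `seed`).
#' @param out_dir If non-`NULL`, writes `results.json`, `report.md` and
#'   the intermediate tables there.
#' @return List of class `pipeline_report` with elements `samples`,
#'   `fragmentomics`, `features`, `scores`, `tests`, `loocv`,
#'   `concordance`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  sim_args <- config$sim %||% list()
  frg <- config$fragmentomics %||% list()
  sco <- config$scoring %||% list()
  cls <- config$classify %||% list()

  cohort <- stage("simulate", generate_cohort(do.call(sim_config, sim_args)))
  labels <- cohort$labels

  fr <- stage("fragmentomics", {
    per_sample <- lapply(labels$sample_id, function(sid) {
      f <- cohort$fragments[cohort$fragments$sample_id == sid, ]
      pk <- cohort$peaks[cohort$peaks$sample_id == sid, ]
      d <- suppressWarnings(suppressMessages(
        delfi_score(f, cohort$regions,
                    loess_span = frg$loess_span %||% 0.75,
                    min_mapq = frg$min_mapq %||% 20L)))
      data.frame(sample_id = sid,
                 fragmentation_index = fragmentation_index(pk),
                 motif_score = end_motif_frequency(
                   f, frg$motif %||% "CCCA"),
                 delfi = d$score, stringsAsFactors = FALSE)
    })
    do.call(rbind, per_sample)
  })

  metrics <- stage("metrics", region_metrics(
    cohort$methcalls, region_ids = cohort$regions$name,
    sample_ids = labels$sample_id))

  alpha <- sco$alpha %||% 0.05
  feats <- stage("feature_selection", suppressMessages(select_features(
    metrics, labels, metric = sco$metric %||% "mfr", alpha = alpha)))

  scores <- NULL
  if (length(feats) > 0L)
    scores <- stage("scoring", suppressWarnings(score_cohort(
      metrics, labels, feats, value = sco$metric %||% "mfr",
      side = sco$side %||% "upper")))

  tests <- stage("group_tests", {
    is_case <- labels$group == "case"
    gtest <- function(v) exact_rank_sum(v[is_case], v[!is_case])$p_two_sided
    out <- list(delfi_p = gtest(fr$delfi),
                motif_p = gtest(fr$motif_score),
                fragmentation_index_p = gtest(fr$fragmentation_index))
    if (!is.null(scores)) out$methylation_score_p <- gtest(scores$score)
    out
  })

  loocv <- NULL; conc <- NULL
  if (length(feats) > 1L) {
    loocv <- stage("classification", {
      fm <- t(metrics_matrix(metrics, sco$metric %||% "mfr")[feats, , drop = FALSE])
      fm <- fm[labels$sample_id, , drop = FALSE]
      kinds <- cls$models %||% c("logistic", "decision_tree",
                                 "random_forest", "svc")
      res <- lapply(kinds, function(k)
        loocv_predict(fm, labels, model_spec(k),
                      seed = cls$seed %||% 1L))
      names(res) <- kinds
      res
    })
    if (length(loocv) >= 2L) conc <- concordance(loocv)
  }

  report <- structure(list(
    samples = labels, fragmentomics = fr,
    features = feats, n_features = length(feats), alpha = alpha,
    scores = scores, tests = tests, loocv = loocv,
    concordance = conc), class = "pipeline_report")

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_cohort(cohort, out_dir)
    write_tsv(fr, file.path(out_dir, "fragmentomics.tsv"))
    write_tsv(metrics, file.path(out_dir, "metrics.tsv"))
    if (!is.null(scores))
      write_tsv(scores, file.path(out_dir, "scores.tsv"))
    jsonlite::write_json(list(
      n_features = length(feats), features = as.vector(feats),
      tests = tests,
      concordance = if (is.null(conc)) NULL else conc$concordance,
      mean_scores = if (is.null(scores)) NULL else
        tapply(scores$score, scores$group, mean)),
      file.path(out_dir, "results.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    writeLines(format_report(report), file.path(out_dir, "report.md"))
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

format_report <- function(x) {
  ln <- c("# Synthetic cfDNA cohort report", "",
          sprintf("Samples: %d case / %d control",
                  sum(x$samples$group == "case"),
                  sum(x$samples$group == "control")),
          sprintf("Selected features (p < %g): %d", x$alpha, x$n_features),
          "",
          sprintf("- DELFI group p: %.4f", x$tests$delfi_p),
          sprintf("- Motif-score group p: %.4f", x$tests$motif_p),
          sprintf("- Fragmentation-index group p: %.4f",
                  x$tests$fragmentation_index_p))
  if (!is.null(x$tests$methylation_score_p))
    ln <- c(ln, sprintf("- Methylation-score group p: %.4f",
                        x$tests$methylation_score_p))
  if (x$n_features == 0L)
    ln <- c(ln, "", "No feature passed selection (null-like cohort).")
  if (!is.null(x$concordance))
    ln <- c(ln, "", sprintf("Model concordance: %.3f",
                            x$concordance$concordance))
  ln
}

#' @export
print.pipeline_report <- function(x, ...) {
  writeLines(format_report(x))
  invisible(x)
}
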