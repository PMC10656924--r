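#' Label samples as early- or late-stage
#'
#' Recolonization samples at 2 and 7 dpr are `early`; 14 and 28 dpr are
#' `late`. Inoculum samples are excluded.
#'
#' @param meta sample metadata (see [community_table()]).
#' @return named character vector (`sample_id` -> `"early"`/`"late"`).
#' @export
label_stages <- function(meta) {
  tp <- as.character(meta$timepoint)
  bad <- setdiff(tp, .TIMEPOINTS)
  .assert(length(bad) == 0, "unknown timepoint(s): %s",
          paste(unique(bad), collapse = ", "))
  keep <- tp %in% .RECOL_TIMEPOINTS
  setNames(ifelse(tp[keep] %in% c("2", "7"), "early", "late"),
           meta$sample_id[keep])
}

.rf_importance <- function(x, y, n_trees, seed) {
  df <- data.frame(x, check.names = FALSE)
  df$.class <- factor(y)
  fit <- ranger::ranger(dependent.variable.name = ".class", data = df,
                        num.trees = n_trees, importance = "permutation",
                        scale.permutation.importance = TRUE,
                        seed = seed, num.threads = 1,
                        respect.unordered.factors = TRUE)
  fit$variable.importance
}

#' Shadow-feature random-forest selection (Boruta-style), one repeat
#'
#' Implements the all-relevant selection wrapper: every original feature
#' is duplicated as a value-permuted "shadow" (the shadow pool keeps its
#' full width even after features are rejected), a random forest with
#' z-score-scaled permutation importance is fitted on the still-active
#' real features plus all shadows, and a
#' feature scores a *hit* when its importance exceeds the maximum shadow
#' importance. After each iteration two-sided binomial tests (hit
#' probability 0.5) at level `alpha`, Bonferroni-adjusted across features,
#' confirm features with significantly many hits and reject features with
#' significantly few, until all are decided or `max_iter` is reached.
#'
#' @param pa a [project_pathways()] result, or a features x samples matrix.
#' @param labels named `"early"`/`"late"` labels from [label_stages()];
#'   only samples present in both are used.
#' @param n_trees random forest size per iteration.
#' @param max_iter maximum Boruta iterations.
#' @param alpha two-sided binomial test level.
#' @param seed integer seed for shadows and forests.
#' @return list with `decision` (named: `confirmed`/`rejected`/
#'   `tentative`), `importance` (mean raw permutation importance of each
#'   feature over the iterations in which it was in play), `n_iter` and
#'   `seed`.
#' @references Kursa, M.B. & Rudnicki, W.R. (2010) Feature selection with
#'   the Boruta package. Journal of Statistical Software 36(11).
#' @export
boruta_select <- function(pa, labels, n_trees = 500, max_iter = 100,
                          alpha = 0.01, seed = 1) {
  x <- if (inherits(pa, "pathway_abundance")) t(pa$A) else t(as.matrix(pa))
  common <- intersect(rownames(x), names(labels))
  .assert(length(common) > 0, "no overlap between samples and labels")
  x <- x[common, , drop = FALSE]
  y <- labels[common]
  .assert(ncol(x) >= 2, "need at least two features")
  cls <- table(y)
  .assert(length(cls) == 2 && all(cls >= 4),
          "each class needs at least 4 samples")

  feats <- colnames(x)
  decision <- setNames(rep("tentative", length(feats)), feats)
  hits <- setNames(rep(0L, length(feats)), feats)
  imp_sum <- setNames(rep(0, length(feats)), feats)
  imp_n <- setNames(rep(0L, length(feats)), feats)
  iter <- 0L
  with_seed(seed, {
    while (any(decision == "tentative") && iter < max_iter) {
      iter <- iter + 1L
      active <- feats[decision != "rejected"]
      # the shadow pool keeps the full original width (rejected features
      # continue to serve as noise probes), so the max-shadow bar does not
      # drop as features are rejected
      shadows <- apply(x, 2, sample)
      colnames(shadows) <- paste0(".shadow_", feats)
      xi <- cbind(x[, active, drop = FALSE], shadows)
      imp <- .rf_importance(xi, y, n_trees,
                            seed = sample.int(.Machine$integer.max, 1))
      shadow_max <- max(imp[colnames(shadows)])
      real_imp <- imp[active]
      imp_sum[active] <- imp_sum[active] + real_imp
      imp_n[active] <- imp_n[active] + 1L
      und <- feats[decision == "tentative"]
      hits[und] <- hits[und] + as.integer(real_imp[und] > shadow_max)
      # two-sided binomial decision at level alpha, Bonferroni-adjusted
      # across features (multiplicity control over the repeated looks)
      adj <- length(feats)
      p_hi <- pmin(1, adj * pbinom(hits[und] - 1L, iter, 0.5,
                                   lower.tail = FALSE))
      p_lo <- pmin(1, adj * pbinom(hits[und], iter, 0.5))
      decision[und[p_hi < alpha / 2]] <- "confirmed"
      decision[und[p_lo < alpha / 2]] <- "rejected"
    }
  })
  importance <- ifelse(imp_n > 0, imp_sum / pmax(imp_n, 1L), 0)
  list(decision = decision, importance = setNames(importance, feats),
       n_iter = iter, seed = seed)
}

#' Repeated shadow-feature selection
#'
#' Runs [boruta_select()] `n_repeats` times with consecutive seeds. The
#' `consistent_set` is the intersection of the confirmed sets over all
#' repeats; the reported importance is the mean of the per-repeat
#' importances after scaling each repeat so its maximum is 1 (negative raw
#' importances are clipped at 0). That normalization gives the subsystem
#' score threshold of 0.5 a defined scale.
#'
#' @inheritParams boruta_select
#' @param n_repeats number of repeats (>= 1).
#' @return object of class `selection_result`: list with `importance`
#'   (named, in `[0, 1]`), `decision` (from majority over repeats),
#'   `consistent_set`, `n_repeats`, `seed` and `per_repeat` decisions.
#' @export
repeated_selection <- function(pa, labels, n_repeats = 10, n_trees = 500,
                               max_iter = 100, alpha = 0.01, seed = 1) {
  .assert(n_repeats >= 1, "n_repeats must be >= 1")
  reps <- lapply(seq_len(n_repeats), function(i)
    boruta_select(pa, labels, n_trees, max_iter, alpha, seed + i - 1L))
  feats <- names(reps[[1]]$decision)
  confirmed_sets <- lapply(reps, function(r)
    names(r$decision)[r$decision == "confirmed"])
  consistent <- Reduce(intersect, confirmed_sets)
  norm_imp <- vapply(reps, function(r) {
    v <- pmax(r$importance, 0)
    if (max(v) > 0) v / max(v) else v
  }, numeric(length(feats)))
  if (!is.matrix(norm_imp)) norm_imp <- matrix(norm_imp, length(feats))
  importance <- setNames(rowMeans(norm_imp), feats)
  n_conf <- rowSums(vapply(reps, function(r) r$decision == "confirmed",
                           logical(length(feats))))
  n_rej <- rowSums(vapply(reps, function(r) r$decision == "rejected",
                          logical(length(feats))))
  decision <- setNames(ifelse(n_conf > n_repeats / 2, "confirmed",
                       ifelse(n_rej > n_repeats / 2, "rejected",
                              "tentative")), feats)
  structure(list(importance = importance, decision = decision,
                 consistent_set = consistent, n_repeats = n_repeats,
                 seed = seed,
                 per_repeat = lapply(reps, `[[`, "decision")),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result: %d features, %d consistently confirmed over %d repeats\n",
              length(x$importance), length(x$consistent_set), x$n_repeats))
  invisible(x)
}

#' Stratified k-fold cross-validated classification accuracy
#'
#' Random-forest classification of samples into early/late stages from the
#' selected pathway abundances; folds are stratified by class and accuracy
#' is pooled over folds.
#'
#' @param pa a [project_pathways()] result or features x samples matrix
#'   (typically restricted to a `consistent_set`).
#' @param labels named stage labels (see [label_stages()]).
#' @param k number of folds.
#' @param n_trees forest size per fold.
#' @param seed integer seed for fold assignment and forests.
#' @return pooled accuracy in `[0, 1]`.
#' @export
cv_accuracy <- function(pa, labels, k = 5, n_trees = 500, seed = 1) {
  x <- if (inherits(pa, "pathway_abundance")) t(pa$A) else t(as.matrix(pa))
  common <- intersect(rownames(x), names(labels))
  x <- x[common, , drop = FALSE]
  y <- factor(labels[common])
  .assert(ncol(x) >= 1, "feature set is empty")
  .assert(all(table(y) >= k), "k exceeds the size of a class")
  with_seed(seed, {
    fold <- integer(length(y))
    for (cl in levels(y)) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    correct <- 0L
    for (f in seq_len(k)) {
      tr <- fold != f
      df <- data.frame(x[tr, , drop = FALSE], check.names = FALSE)
      df$.class <- y[tr]
      fit <- ranger::ranger(dependent.variable.name = ".class", data = df,
                            num.trees = n_trees, num.threads = 1,
                            seed = sample.int(.Machine$integer.max, 1))
      pred <- predict(fit, data.frame(x[!tr, , drop = FALSE],
                                      check.names = FALSE))$predictions
      correct <- correct + sum(pred == y[!tr])
    }
    correct / length(y)
  })
}

#' Sum confirmed-pathway importances into subsystem scores
#'
#' `score(subsystem) = sum of importance over confirmed pathways mapped to
#' it`; subsystems at or above `threshold` are retained.
#'
#' @param sel a [repeated_selection()] result (or a named importance
#'   vector, in which case `decision` must be given).
#' @param subsystem_of named pathway -> subsystem mapping (e.g.
#'   `pathway_presence$subsystem_of`).
#' @param threshold minimum retained score.
#' @param decision optional named decision vector overriding `sel$decision`.
#' @return data.frame `subsystem`, `score`, sorted decreasing, with only
#'   scores `>= threshold`; the full score table is attached as attribute
#'   `"all_scores"`.
#' @export
subsystem_scores <- function(sel, subsystem_of, threshold = 0.5,
                             decision = NULL) {
  if (inherits(sel, "selection_result")) {
    importance <- sel$importance
    if (is.null(decision)) decision <- sel$decision
  } else {
    importance <- sel
    .assert(!is.null(decision), "decision vector required")
  }
  conf <- names(decision)[decision == "confirmed"]
  subs <- unique(unname(subsystem_of))
  score <- setNames(numeric(length(subs)), subs)
  for (p in conf) {
    s <- subsystem_of[[p]] %||% "unassigned"
    score[s] <- score[s] + importance[[p]]
  }
  all_scores <- data.frame(subsystem = names(score), score = unname(score))
  all_scores <- all_scores[order(-all_scores$score), , drop = FALSE]
  out <- all_scores[all_scores$score >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all_scores") <- all_scores
  out
}

#' Early/late log2 fold change of mean pathway abundances
#'
#' `lfc(p) = log2((mean_late + pseudocount) / (mean_early + pseudocount))`,
#' so pathways enriched in the early stage carry negative values. The
#' direction is stated in the result's `"direction"` attribute.
#'
#' @param pa a [project_pathways()] result or features x samples matrix.
#' @param labels named stage labels.
#' @param pseudocount stabilizer for zero means.
#' @return named numeric vector of signed log2 fold changes.
#' @export
early_late_lfc <- function(pa, labels, pseudocount = 1e-6) {
  a <- if (inherits(pa, "pathway_abundance")) pa$A else as.matrix(pa)
  common <- intersect(colnames(a), names(labels))
  a <- a[, common, drop = FALSE]
  y <- labels[common]
  .assert(all(c("early", "late") %in% y), "both stages must be populated")
  m_early <- rowMeans(a[, y == "early", drop = FALSE])
  m_late <- rowMeans(a[, y == "late", drop = FALSE])
  out <- log2((m_late + pseudocount) / (m_early + pseudocount))
  attr(out, "direction") <- "late_over_early"
  out
}
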