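# Dosage matrix -> model data.frame for the forest (per-SNP mean imputation
# of missing calls; forests cannot split on NA).
rf_features <- function(g) {
  M <- g$dosage
  storage.mode(M) <- "double"
  if (anyNA(M)) {
    mu <- colMeans(M, na.rm = TRUE)
    mu[is.na(mu)] <- 0
    for (j in which(colSums(is.na(M)) > 0)) {
      M[is.na(M[, j]), j] <- mu[j]
    }
  }
  M
}

#' Single class-balanced random forest scan
#'
#' Grows one classification forest on the dosage features with
#' inverse-class-frequency weights (even weighting of the prediction error
#' between disease statuses) and permutation variable importance. VIM% is
#' the raw permutation importance (mean decrease in accuracy over
#' out-of-bag samples) expressed in percent. Out-of-bag error is reported
#' overall and per phenotype class. Fixed seed and single-threaded growth
#' make the result bitwise reproducible.
#'
#' @param g_train training [genotype_matrix()].
#' @param status_train named 0/1 vector covering the training animals.
#' @param n_trees trees per forest (default 75).
#' @param seed integer seed.
#' @param mtry features tried per split (default `sqrt(m)`).
#' @return list with `vim_pct` (named per-SNP vector), `oob_overall`,
#'   `oob_per_class` (named by class "0"/"1"), `model` (the ranger fit).
#' @export
run_forest <- function(g_train, status_train, n_trees = 75, seed = 1,
                       mtry = NULL) {
  ids <- animal_ids(g_train)
  y <- factor(as.integer(status_train[ids]), levels = c(0L, 1L))
  if (anyNA(y)) stop("training animals without phenotype")
  if (length(unique(y)) < 2L) {
    stop("cohort error: training set has a single phenotype class")
  }
  M <- rf_features(g_train)
  # even weighting between disease statuses: inverse-class-frequency case
  # weights balance the bootstrap draw of every tree (so terminal votes and
  # the per-class prediction errors are not dominated by the majority
  # class), and matching class weights enter the split criterion
  tab <- table(y)
  cw <- as.numeric(1 / tab)
  cw <- cw / sum(cw)
  case_w <- cw[as.integer(y)]
  fit <- ranger::ranger(
    x = M, y = y,
    num.trees = n_trees,
    mtry = if (is.null(mtry)) floor(sqrt(ncol(M))) else mtry,
    importance = "permutation",
    scale.permutation.importance = FALSE,
    class.weights = cw,
    case.weights = case_w,
    seed = seed,
    num.threads = 1
  )
  vim <- fit$variable.importance * 100
  pred <- fit$predictions
  ok <- !is.na(pred)
  oob_overall <- mean(pred[ok] != y[ok])
  oob_cls <- vapply(levels(y), function(l) {
    sel <- ok & y == l
    if (!any(sel)) NA_real_ else mean(pred[sel] != y[sel])
  }, 0)
  list(vim_pct = vim, oob_overall = oob_overall, oob_per_class = oob_cls,
       model = fit)
}

#' Replicated-forest consensus scan
#'
#' Replicates [run_forest()] `n_forests` times with per-forest seeds
#' `base_seed + forest index`. SNPs with a strictly positive VIM% in a
#' forest count as "non-zero" there (negative permutation importances are
#' noise and count as zero); SNPs non-zero in at least two forests are
#' retained, with their forest frequency and the mean VIM% over the
#' non-zero occurrences, sorted by frequency then mean VIM%.
#'
#' @param g_train,status_train as in [run_forest()].
#' @param n_forests number of replicate forests (default 100; >= 2).
#' @param n_trees trees per forest (default 75).
#' @param base_seed base seed.
#' @param keep_models keep the fitted forests (needed for
#'   [evaluate_prediction()]).
#' @return object of class `rf_consensus`: list with `records`
#'   (data.frame `snp_id`, `forest_frequency`, `mean_vim_pct`,
#'   `region_of_interest` placeholder FALSE), `oob` (per-forest overall and
#'   per-class OOB errors), `forests` (list of ranger fits or NULL),
#'   `n_forests`, `n_trees`.
#' @export
replicate_forests <- function(g_train, status_train, n_forests = 100,
                              n_trees = 75, base_seed = 1,
                              keep_models = TRUE) {
  if (n_forests < 2L) stop("n_forests must be >= 2")
  vims <- matrix(0, ncol(g_train$dosage), n_forests,
                 dimnames = list(g_train$map$snp_id, NULL))
  oob <- matrix(NA_real_, n_forests, 3,
                dimnames = list(NULL, c("overall", "class0", "class1")))
  models <- if (keep_models) vector("list", n_forests) else NULL
  for (f in seq_len(n_forests)) {
    res <- run_forest(g_train, status_train, n_trees = n_trees,
                      seed = base_seed + f)
    vims[, f] <- res$vim_pct
    oob[f, ] <- c(res$oob_overall, res$oob_per_class)
    if (keep_models) models[[f]] <- res$model
  }
  nz <- vims > 0
  freq <- rowSums(nz)
  keep <- freq >= 2L
  mean_vim <- vapply(which(keep), function(i) mean(vims[i, nz[i, ]]), 0)
  records <- data.frame(
    snp_id = rownames(vims)[keep],
    forest_frequency = freq[keep],
    mean_vim_pct = mean_vim,
    region_of_interest = FALSE,
    stringsAsFactors = FALSE
  )
  records <- records[order(-records$forest_frequency,
                           -records$mean_vim_pct), ]
  rownames(records) <- NULL
  structure(list(records = records, oob = oob, forests = models,
                 n_forests = n_forests, n_trees = n_trees),
            class = "rf_consensus")
}

#' @export
print.rf_consensus <- function(x, ...) {
  cat("rf_consensus:", x$n_forests, "forests x", x$n_trees, "trees;",
      nrow(x$records), "SNPs retained (non-zero VIM% in >= 2 forests)\n")
  cat(sprintf("  mean OOB error: %.3f (class 0: %.3f, class 1: %.3f)\n",
              mean(x$oob[, "overall"]), mean(x$oob[, "class0"]),
              mean(x$oob[, "class1"])))
  invisible(x)
}

#' Flag top-frequency consensus SNPs as regions of interest
#'
#' Flags retained SNPs whose forest frequency is at or above the given
#' quantile of retained frequencies (default the median: "top 50%"); ties
#' at the threshold are included.
#'
#' @param consensus an `rf_consensus` or its `records` data.frame.
#' @param quantile probability cut (default 0.5).
#' @return the records data.frame with `region_of_interest` set.
#' @export
top_frequency_regions <- function(consensus, quantile = 0.5) {
  rec <- if (inherits(consensus, "rf_consensus")) consensus$records
         else consensus
  if (!nrow(rec)) stop("empty consensus")
  thr <- stats::quantile(rec$forest_frequency, probs = quantile, type = 1)
  rec$region_of_interest <- rec$forest_frequency >= thr
  rec
}

#' Estimation (OOB) and prediction (test-set) error of a forest ensemble
#'
#' Aggregates the training-cohort out-of-bag error across the replicate
#' forests (the estimation error) and predicts the held-out test cohort
#' with each forest, reporting the mean held-out misclassification (the
#' prediction error), each overall and per phenotype class.
#'
#' @param consensus an `rf_consensus` fitted with `keep_models = TRUE`.
#' @param g_test test-cohort [genotype_matrix()] (same SNPs as training;
#'   ids must be disjoint from training if you want honest prediction
#'   error).
#' @param status_test named 0/1 vector over the test animals.
#' @return data.frame with rows `estimation` (OOB) and `prediction`
#'   (test set) and columns `overall`, `class0`, `class1`.
#' @export
evaluate_prediction <- function(consensus, g_test, status_test) {
  stopifnot(inherits(consensus, "rf_consensus"))
  if (is.null(consensus$forests)) {
    stop("consensus was built with keep_models = FALSE")
  }
  ids <- animal_ids(g_test)
  if (!length(ids)) stop("empty test set")
  y <- factor(as.integer(status_test[ids]), levels = c(0L, 1L))
  if (anyNA(y)) stop("test animals without phenotype")
  feat_train <- consensus$forests[[1]]$forest$independent.variable.names
  if (!identical(feat_train, g_test$map$snp_id)) {
    stop("alignment error: test SNP set differs from the training features")
  }
  M <- rf_features(g_test)
  err <- matrix(NA_real_, length(consensus$forests), 3)
  for (f in seq_along(consensus$forests)) {
    pred <- predict(consensus$forests[[f]], data = M,
                    num.threads = 1)$predictions
    err[f, 1] <- mean(pred != y)
    err[f, 2] <- if (any(y == "0")) mean(pred[y == "0"] != "0") else NA
    err[f, 3] <- if (any(y == "1")) mean(pred[y == "1"] != "1") else NA
  }
  out <- rbind(
    estimation = colMeans(consensus$oob, na.rm = TRUE),
    prediction = colMeans(err, na.rm = TRUE)
  )
  colnames(out) <- c("overall", "class0", "class1")
  as.data.frame(out)
}

#' Intersect the forest consensus with the GQLS hits
#'
#' Inner join on SNP id of the consensus records with the association
#' records significant at chromosome-wise pFDR <= `q_max`, carrying the
#' association q-value/tier/MAF and the consensus frequency and VIM%
#' (plus polarity when present in `assoc`).
#'
#' @param consensus an `rf_consensus` or its records.
#' @param assoc a q-annotated `gqls_scan` (optionally with a `polarity`
#'   column merged in).
#' @param q_max pFDR cutoff applied to `assoc` (default 0.10).
#' @return data.frame of common SNPs sorted by chromosome and position.
#' @export
intersect_with_gqls <- function(consensus, assoc, q_max = 0.10) {
  rec <- if (inherits(consensus, "rf_consensus")) consensus$records
         else consensus
  stopifnot("q_value" %in% names(assoc))
  sig <- assoc[!is.na(assoc$q_value) & assoc$q_value <= q_max, , drop = FALSE]
  keep_cols <- intersect(
    c("snp_id", "chromosome", "position_bp", "p_value", "q_value",
      "pfdr_tier", "maf", "polarity"),
    names(sig)
  )
  out <- merge(sig[, keep_cols, drop = FALSE],
               rec[, c("snp_id", "forest_frequency", "mean_vim_pct")],
               by = "snp_id")
  ord <- if (all(c("chromosome", "position_bp") %in% names(out))) {
    order(out$chromosome, out$position_bp)
  } else order(out$snp_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
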