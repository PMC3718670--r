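#' Read a ground-truth genotype table
#'
#' Tab-separated `chrom  pos  label`, where `label` is either a genotype
#' state (`aa`/`ab`/`bb`) or a binary SNV flag (`0`/`1`). ab and bb are
#' SNVs.
#'
#' @param path Path to the truth TSV (a header line is optional).
#' @return Data frame with `chrom`, `pos`, `truth_state` (may be `NA` for
#'   binary input) and logical `is_snv`.
#' @export
read_truth_tsv <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("chrom", "pos", "label"),
                          colClasses = c("character", "character", "character"))
  if (nrow(df) && df$pos[1] == "pos") df <- df[-1L, , drop = FALSE]
  df$pos <- as.integer(df$pos)
  if (anyNA(df$pos)) stop("non-numeric position in truth file ", path)
  lab <- tolower(df$label)
  if (!all(lab %in% c("aa", "ab", "bb", "0", "1")))
    stop("truth labels must be aa/ab/bb or 0/1")
  data.frame(chrom = df$chrom, pos = df$pos,
             truth_state = ifelse(lab %in% c("aa", "ab", "bb"), lab, NA),
             is_snv = lab %in% c("ab", "bb", "1"),
             stringsAsFactors = FALSE)
}

#' Confusion counts of SNV calls against ground truth
#'
#' Every truth position is evaluated: a truth position absent from the
#' calls is counted as a negative prediction (no SNV reported there) and a
#' message records how many were missing. Calls at positions without truth
#' are ignored.
#'
#' @param calls A call data frame from [call_sites()] (needs `chrom`,
#'   `pos`, `is_snv`).
#' @param truth A data frame with `chrom`, `pos` and logical `is_snv`
#'   (see [read_truth_tsv()]).
#' @return A `confusion_table`: list with integer `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(calls, truth) {
  key_t <- paste(truth$chrom, truth$pos)
  if (anyDuplicated(key_t)) stop("duplicate positions in truth set")
  key_c <- paste(calls$chrom, calls$pos)
  m <- match(key_t, key_c)
  if (anyNA(m))
    message(sum(is.na(m)),
            " truth position(s) absent from calls; counted as negative predictions")
  pred <- ifelse(is.na(m), FALSE, calls$is_snv[m])
  structure(list(TP = sum(pred & truth$is_snv),
                 FP = sum(pred & !truth$is_snv),
                 TN = sum(!pred & !truth$is_snv),
                 FN = sum(!pred & truth$is_snv)),
            class = "confusion_table")
}

#' Benchmarking metrics from a confusion table
#'
#' `sensitivity = TP/(TP+FN)` (= recall), `specificity = TN/(TN+FP)`,
#' `accuracy = (TP+TN)/total`, `precision = TP/(TP+FP)` and
#' `F = 2 * precision * recall / (precision + recall)`. A metric whose
#' denominator is zero is returned as `NA` with a warning, except the
#' F-score, which is 0 by convention when precision and recall are both
#' defined and sum to zero. All values are fractions in `[0, 1]`; multiply
#' by 100 for the percentage scale used in reports.
#'
#' @param ct A `confusion_table` (or list with `TP`, `FP`, `TN`, `FN`).
#' @return A `metrics_report`: list of `sensitivity`, `specificity`,
#'   `accuracy`, `precision`, `recall`, `f_score`.
#' @export
compute_metrics <- function(ct) {
  TP <- ct$TP; FP <- ct$FP; TN <- ct$TN; FN <- ct$FN
  total <- TP + FP + TN + FN
  if (total == 0L) stop("empty confusion table")
  frac <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined: zero denominator")
      NA_real_
    } else num / den
  }
  sens <- frac(TP, TP + FN, "sensitivity")
  spec <- frac(TN, TN + FP, "specificity")
  prec <- frac(TP, TP + FP, "precision")
  f <- if (is.na(prec) || is.na(sens)) NA_real_
  else if (prec + sens == 0) 0
  else 2 * prec * sens / (prec + sens)
  structure(list(sensitivity = sens, specificity = spec,
                 accuracy = (TP + TN) / total,
                 precision = prec, recall = sens, f_score = f),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "NA" else sprintf("%.2f%%", 100 * v)
  cat(sprintf("sensitivity %s  specificity %s  accuracy %s  F-score %s\n",
              pct(x$sensitivity), pct(x$specificity), pct(x$accuracy),
              if (is.na(x$f_score)) "NA" else sprintf("%.4f", x$f_score)))
  invisible(x)
}

#' Sweep MQ/BQ/MVC settings over the full train-and-call pipeline
#'
#' For each grid row the pileup is re-read with the row's thresholds, the
#' HMM is trained on the data itself from the priors, the path is decoded,
#' calls are gated by the row's MVC, and metrics against the truth set are
#' recorded. Deterministic for a fixed seed.
#'
#' @param pileup_path Pileup file evaluated at every grid point.
#' @param truth Truth data frame ([read_truth_tsv()]).
#' @param grid Data frame with columns `mq`, `bq`, `mvc`.
#' @param hyper A [prior_hyperparameters()].
#' @param config A [train_config()]; its `seed` is reused at every grid
#'   point so runs differ only by thresholds.
#' @param dialect,default_mq,qual_offset Passed to [read_pileup()].
#' @return A data frame: the grid columns plus `TP`, `FP`, `TN`, `FN`,
#'   `sensitivity`, `specificity`, `accuracy`, `precision`, `f_score`
#'   (fractions) and `fpr` (= 1 - specificity, for ROC-style plotting).
#' @export
threshold_sweep <- function(pileup_path, truth, grid,
                            hyper = prior_hyperparameters(),
                            config = train_config(),
                            dialect = "samtools", default_mq = 30L,
                            qual_offset = 33L) {
  stopifnot(all(c("mq", "bq", "mvc") %in% names(grid)), nrow(grid) >= 1L)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    filt <- filter_config(grid$mq[k], grid$bq[k], grid$mvc[k])
    obs <- read_pileup(pileup_path, filt, dialect, default_mq, qual_offset)
    fit <- baum_welch_train(obs, hyper = hyper, config = config)
    dec <- viterbi_decode(obs, fit$params)
    cache <- forward_backward(obs, fit$params)
    calls <- call_sites(obs, dec$path, cache, filt)
    ct <- confusion_counts(calls, truth)
    met <- compute_metrics(ct)
    data.frame(mq = grid$mq[k], bq = grid$bq[k], mvc = grid$mvc[k],
               TP = ct$TP, FP = ct$FP, TN = ct$TN, FN = ct$FN,
               sensitivity = met$sensitivity, specificity = met$specificity,
               accuracy = met$accuracy, precision = met$precision,
               f_score = met$f_score, fpr = 1 - met$specificity)
  })
  do.call(rbind, rows)
}

#' Write a metrics table as TSV
#'
#' @param tab Data frame (e.g. from [threshold_sweep()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_metrics_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
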