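#' Construct ordinal confidence counts
#'
#' @param malignant,benign length-4 nonnegative integer counts of lesions
#'   per confidence score 1..4 (definitely benign .. definitely malignant).
#' @export
ordinalCounts <- function(malignant, benign) {
  new("OrdinalCounts", malignant = as.integer(malignant),
      benign = as.integer(benign))
}

setMethod("show", "OrdinalCounts", function(object) {
  cat("OrdinalCounts (four-point confidence scale)\n")
  m <- rbind(malignant = object@malignant, benign = object@benign)
  colnames(m) <- c("def.benign", "pos.benign", "pos.malignant",
                   "def.malignant")
  print(m)
})

# integer-percent rounding, half away from zero (matches printed tables)
.pctRound <- function(x) floor(100 * x + 0.5)

#' Confusion metrics at the test-positive cutoff
#'
#' A malignant lesion scored at or above \code{cutoff} (default 3,
#' "possibly malignant") counts as true positive; a benign lesion scored
#' below it as true negative. Sensitivity, specificity, PPV and NPV are
#' returned both as exact fractions and as half-up rounded integer
#' percentages. A zero denominator yields \code{NaN} for that metric rather
#' than an error.
#'
#' @param c an \code{\linkS4class{OrdinalCounts}}.
#' @param cutoff lowest score counted test-positive.
#' @return list with \code{percent} (named, rounded), \code{fraction}
#'   (named, exact) and the \code{counts} (TP, FP, TN, FN).
#' @export
confusionMetrics <- function(c, cutoff = 3) {
  stopifnot(is(c, "OrdinalCounts"), cutoff >= 1, cutoff <= 4)
  pos <- seq(cutoff, 4)
  neg <- seq_len(cutoff - 1)
  TP <- sum(c@malignant[pos]); FN <- sum(c@malignant[neg])
  TN <- sum(c@benign[neg]); FP <- sum(c@benign[pos])
  frac <- c(sensitivity = TP / (TP + FN), specificity = TN / (TN + FP),
            ppv = TP / (TP + FP), npv = TN / (TN + FN))
  list(percent = .pctRound(frac), fraction = frac,
       counts = c(TP = TP, FP = FP, TN = TN, FN = FN))
}

#' Empirical AUC of an ordinal confidence rating
#'
#' Tie-corrected two-sample rank statistic over the four-point scores:
#' \deqn{AUC = [\sum_{i>j} m_i b_j + \frac12 \sum_i m_i b_i] / (M B),}
#' the probability that a random malignant lesion outscores a random benign
#' one, counting ties one half. Equals the trapezoidal area under the
#' 5-point empirical ROC through the per-cutoff operating points, which are
#' returned alongside.
#'
#' @param c an \code{\linkS4class{OrdinalCounts}} with both classes
#'   nonempty.
#' @return list with \code{auc} and \code{roc}, a data.frame of operating
#'   points (fpr, tpr) for cutoffs "score >= k", k = 5..1.
#' @export
empiricalAuc <- function(c) {
  stopifnot(is(c, "OrdinalCounts"))
  m <- as.numeric(c@malignant); b <- as.numeric(c@benign)
  M <- sum(m); B <- sum(b)
  if (M == 0 || B == 0)
    stop("empirical AUC is undefined with an empty class")
  gt <- sum(vapply(2:4, function(i) m[i] * sum(b[seq_len(i - 1)]),
                   numeric(1)))
  auc <- (gt + 0.5 * sum(m * b)) / (M * B)
  # operating points for thresholds "positive if score >= k", k = 5..1
  tpr <- c(0, cumsum(rev(m)) / M)
  fpr <- c(0, cumsum(rev(b)) / B)
  roc <- data.frame(cutoff = c(5, 4, 3, 2, 1), fpr = fpr, tpr = tpr)
  list(auc = auc, roc = roc)
}

#' Equivocal judgments (scores 2 and 3)
#'
#' @param c an \code{\linkS4class{OrdinalCounts}}.
#' @return list with \code{count} of equivocal judgments across both
#'   classes and \code{percent} of all lesions (half-up integer).
#' @export
equivocalSummary <- function(c) {
  stopifnot(is(c, "OrdinalCounts"))
  n <- sum(c@malignant) + sum(c@benign)
  cnt <- sum(c@malignant[2:3]) + sum(c@benign[2:3])
  list(count = cnt, percent = if (n > 0) .pctRound(cnt / n) else NaN)
}

#' Interpretation band of a kappa value
#'
#' The conventional agreement bands: 0 poor; (0, 0.20] slight; (0.21, 0.40]
#' fair; (0.41, 0.60] moderate; (0.61, 0.80] substantial; (0.81, 1.00]
#' almost perfect.
#'
#' @param kappa a kappa value.
#' @export
kappaAgreementBand <- function(kappa) {
  if (is.na(kappa)) return(NA_character_)
  if (kappa <= 0) return("poor agreement")
  if (kappa <= 0.20) return("slight agreement")
  if (kappa <= 0.40) return("fair agreement")
  if (kappa <= 0.60) return("moderate agreement")
  if (kappa <= 0.80) return("substantial agreement")
  "almost perfect agreement"
}

#' Weighted kappa between two readers on the four-point scale
#'
#' \deqn{\kappa_w = 1 - \sum w_{ij} O_{ij} / \sum w_{ij} E_{ij}} with
#' disagreement weights \code{w_ij = |i-j|/3} (linear, the default) or its
#' square (quadratic), observed proportions O and margin-product expected
#' proportions E.
#'
#' @param crossTab 4x4 matrix of joint counts, reader 1 in rows, reader 2
#'   in columns.
#' @param weights \code{"linear"} or \code{"quadratic"}.
#' @return list with \code{kappa}, the \code{weights} used and the
#'   agreement \code{band}; kappa is \code{NaN} when a reader used a single
#'   category (degenerate margins).
#' @export
weightedKappa <- function(crossTab, weights = c("linear", "quadratic")) {
  weights <- match.arg(weights)
  stopifnot(is.matrix(crossTab), all(dim(crossTab) == c(4, 4)),
            all(crossTab >= 0), sum(crossTab) >= 1)
  n <- sum(crossTab)
  O <- crossTab / n
  E <- outer(rowSums(O), colSums(O))
  W <- abs(outer(1:4, 1:4, "-")) / 3
  if (weights == "quadratic") W <- W^2
  denom <- sum(W * E)
  kappa <- if (denom == 0) NaN else 1 - sum(W * O) / denom
  list(kappa = kappa, weights = weights, band = kappaAgreementBand(kappa))
}

#' Paired Student t test with Bonferroni adjustment
#'
#' @param a,b equal-length paired samples.
#' @param nComparisons number of comparisons in the family; the adjusted p
#'   is \code{min(1, p * nComparisons)}.
#' @return list with t, df, the raw two-sided p and the adjusted p; all
#'   NaN (flagged degenerate) when the paired differences have zero
#'   variance.
#' @export
pairedTBonferroni <- function(a, b, nComparisons = 1) {
  stopifnot(length(a) == length(b), length(a) >= 2, nComparisons >= 1)
  d <- a - b
  if (stats::var(d) == 0) {
    if (all(d == 0))
      return(list(t = 0, df = length(d) - 1, p = 1, pAdjusted = 1,
                  degenerate = TRUE))
    return(list(t = NaN, df = length(d) - 1, p = NaN, pAdjusted = NaN,
                degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, pAdjusted = min(1, tt$p.value * nComparisons),
       degenerate = FALSE)
}

# DeLong-style placement variance of the empirical AUC from ordinal counts
.aucVariance <- function(c) {
  m <- as.numeric(c@malignant); b <- as.numeric(c@benign)
  M <- sum(m); B <- sum(b)
  # placement of a malignant lesion with score i among benign scores
  cumB <- cumsum(b); cumM <- cumsum(m)
  v10 <- vapply(1:4, function(i)
    (ifelse(i > 1, cumB[i - 1], 0) + 0.5 * b[i]) / B, numeric(1))
  v01 <- vapply(1:4, function(j)
    ((M - cumM[j]) + 0.5 * m[j]) / M, numeric(1))
  auc <- sum(m * v10) / M
  s10 <- sum(m * (v10 - auc)^2) / (M - 1)
  s01 <- sum(b * (v01 - auc)^2) / (B - 1)
  s10 / M + s01 / B
}

#' Compare two AUCs
#'
#' Unpaired case (\code{paired = FALSE}): two-sided normal test on the AUC
#' difference with tie-corrected placement (DeLong-type) variances computed
#' from the ordinal counts, treating the two ratings as independent
#' samples. Paired case: \code{c1}, \code{c2} must be per-lesion score
#' data.frames over the same lesions (columns truth and score); the null
#' distribution of the AUC difference is built by a seeded bootstrap over
#' lesions.
#'
#' @param c1,c2 \code{OrdinalCounts} (unpaired) or per-lesion score
#'   data.frames (paired).
#' @param paired logical.
#' @param nBoot bootstrap replicates for the paired test.
#' @param seed bootstrap seed.
#' @return list with \code{p}, the AUC estimates and the \code{method}
#'   used.
#' @export
compareAuc <- function(c1, c2, paired = FALSE, nBoot = 2000, seed = 1L) {
  if (!paired) {
    if (!is(c1, "OrdinalCounts") || !is(c2, "OrdinalCounts"))
      stop("unpaired comparison requires OrdinalCounts input")
    a1 <- empiricalAuc(c1)$auc; a2 <- empiricalAuc(c2)$auc
    v <- .aucVariance(c1) + .aucVariance(c2)
    z <- (a1 - a2) / sqrt(v)
    list(p = 2 * stats::pnorm(-abs(z)), auc1 = a1, auc2 = a2, z = z,
         method = "normal test, tie-corrected placement variance")
  } else {
    if (!is.data.frame(c1) || !is.data.frame(c2))
      stop("paired comparison requires per-lesion scores, not counts")
    stopifnot(nrow(c1) == nrow(c2),
              all(c(c1$truth, c2$truth) %in% c("malignant", "benign")))
    aucOf <- function(s1, s2, truth, idx) {
      cls <- truth[idx] == "malignant"
      if (!any(cls) || all(cls)) return(c(NA, NA))
      cnt <- function(s) ordinalCounts(tabulate(s[idx][cls], 4),
                                       tabulate(s[idx][!cls], 4))
      c(empiricalAuc(cnt(s1))$auc, empiricalAuc(cnt(s2))$auc)
    }
    n <- nrow(c1)
    obs <- aucOf(c1$score, c2$score, c1$truth, seq_len(n))
    d0 <- obs[1] - obs[2]
    set.seed(seed)
    dd <- replicate(nBoot, {
      idx <- sample.int(n, n, replace = TRUE)
      a <- aucOf(c1$score, c2$score, c1$truth, idx)
      a[1] - a[2]
    })
    dd <- dd[!is.na(dd)]
    # centre the bootstrap distribution at 0 to emulate the null, then
    # two-sided p = P(|D| >= |observed difference|)
    p <- mean(abs(dd - d0) >= abs(d0))
    list(p = p, auc1 = obs[1], auc2 = obs[2],
         method = sprintf("lesion bootstrap (%d replicates)", nBoot))
  }
}

#' Read a per-lesion scores CSV
#'
#' Expected columns: lesion_id, truth (malignant/benign), reader, modality,
#' score (1-4). Malformed rows are reported by number.
#'
#' @param path CSV path.
#' @export
readScores <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("lesion_id", "truth", "reader", "modality", "score")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("scores CSV lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(df) == 0) stop("scores CSV is empty: ", path)
  bad <- which(!(df$score %in% 1:4))
  if (length(bad))
    stop("score outside 1-4 at row ", bad[1])
  bad <- which(!df$truth %in% c("malignant", "benign"))
  if (length(bad))
    stop("truth must be 'malignant' or 'benign' at row ", bad[1])
  df
}

#' Collapse per-lesion scores to ordinal counts
#'
#' @param scores data.frame as returned by \code{\link{readScores}}.
#' @param reader,modality optional filters.
#' @return an \code{\linkS4class{OrdinalCounts}}.
#' @export
scoresToCounts <- function(scores, reader = NULL, modality = NULL) {
  if (!is.null(reader)) scores <- scores[scores$reader == reader, ]
  if (!is.null(modality)) scores <- scores[scores$modality == modality, ]
  if (nrow(scores) == 0) stop("no scores left after filtering")
  mal <- scores$truth == "malignant"
  ordinalCounts(tabulate(scores$score[mal], 4),
                tabulate(scores$score[!mal], 4))
}

#' Cross-tabulate two readers' scores over the same lesions
#'
#' @param scores per-lesion scores data.frame.
#' @param modality modality to tabulate.
#' @param readers length-2 vector of reader ids (default the first two).
#' @return 4x4 joint count matrix (reader 1 rows, reader 2 columns).
#' @export
readerCrossTab <- function(scores, modality, readers = NULL) {
  s <- scores[scores$modality == modality, ]
  if (is.null(readers)) readers <- sort(unique(s$reader))[1:2]
  s1 <- s[s$reader == readers[1], ]
  s2 <- s[s$reader == readers[2], ]
  m <- merge(s1[, c("lesion_id", "score")], s2[, c("lesion_id", "score")],
             by = "lesion_id")
  tab <- table(factor(m$score.x, 1:4), factor(m$score.y, 1:4))
  matrix(as.integer(tab), 4, 4)
}

#' The published four-point confidence counts of the clinical reader study
#'
#' Per-modality counts for reader 1 over 744 metastatic and 1002 benign
#' hypermetabolic lesions, shipped as the packaged CSV
#' \code{extdata/reader1_confidence_counts.csv}. These are the inputs from
#' which the study's accuracy table, equivocal rates and ROC areas are
#' recomputed.
#'
#' @return named list of \code{OrdinalCounts}: \code{wb_spect},
#'   \code{spectct_2d}, \code{spectct_3d}.
#' @export
reader1ConfidenceCounts <- function() {
  path <- system.file("extdata", "reader1_confidence_counts.csv",
                      package = "bonefuse", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(split(df, df$modality), function(g) {
    g <- g[order(g$score), ]
    ordinalCounts(g$malignant, g$benign)
  })
  out[c("wb_spect", "spectct_2d", "spectct_3d")]
}
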