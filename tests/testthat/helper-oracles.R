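# Independent oracles used by the unit and property tests. Each is a direct,
# naive implementation kept deliberately separate from the package code paths
# it checks.

# AUC by brute-force enumeration of all malignant x benign score pairs.
bruteForceAuc <- function(cnt) {
  sm <- rep(1:4, cnt@malignant)
  sb <- rep(1:4, cnt@benign)
  cmp <- outer(sm, sb, ">") + 0.5 * outer(sm, sb, "==")
  mean(cmp)
}

# Hole filling as the complement of a vectorised 6-neighbour flood fill of
# the background from the volume border.
floodFillOracle <- function(mask) {
  d <- dim(mask)
  outside <- array(FALSE, d)
  outside[c(1, d[1]), , ] <- TRUE
  outside[, c(1, d[2]), ] <- TRUE
  outside[, , c(1, d[3])] <- TRUE
  outside <- outside & !mask
  repeat {
    grown <- outside
    grown[-1, , ] <- grown[-1, , ] | outside[-d[1], , ]
    grown[-d[1], , ] <- grown[-d[1], , ] | outside[-1, , ]
    grown[, -1, ] <- grown[, -1, ] | outside[, -d[2], ]
    grown[, -d[2], ] <- grown[, -d[2], ] | outside[, -1, ]
    grown[, , -1] <- grown[, , -1] | outside[, , -d[3]]
    grown[, , -d[3]] <- grown[, , -d[3]] | outside[, , -1]
    grown <- grown & !mask
    if (identical(grown, outside)) break
    outside <- grown
  }
  mask | !outside
}

# Weighted kappa by direct double summation of the defining formula.
doubleSumKappa <- function(tab, quadratic = FALSE) {
  n <- sum(tab)
  rs <- rowSums(tab) / n
  cs <- colSums(tab) / n
  num <- 0
  den <- 0
  for (i in 1:4) {
    for (j in 1:4) {
      w <- abs(i - j) / 3
      if (quadratic) w <- w^2
      num <- num + w * tab[i, j] / n
      den <- den + w * rs[i] * cs[j]
    }
  }
  1 - num / den
}

# random ordinal count table with both classes nonempty
randomCountTable <- function() {
  repeat {
    m <- rpois(4, 2)
    b <- rpois(4, 2)
    if (sum(m) > 0 && sum(b) > 0) return(ordinalCounts(m, b))
  }
}

# a truth list for simulateReaders with the given class sizes
syntheticTruth <- function(nMalignant, nBenign) {
  list(lesions = c(
    lapply(seq_len(nMalignant), function(i) list(malignant = TRUE)),
    lapply(seq_len(nBenign), function(i) list(malignant = FALSE))))
}
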