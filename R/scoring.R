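## Three sequence-based scoring methods over 11-mer pY windows, and the
## top-fraction consensus that intersects their rankings.

## Accept either a peptide_windows data frame or a bare character vector.
as_peptides <- function(x) {
  p <- if (is.data.frame(x)) x$peptide else as.character(x)
  if (length(p) == 0L) stop("no peptides supplied")
  if (any(nchar(p) != WINDOW_WIDTH)) {
    stop("all peptides must be ", WINDOW_WIDTH, "-mers")
  }
  if (any(substr(p, CENTER_OFFSET, CENTER_OFFSET) != "Y")) {
    stop("all peptides must have Y at the centre position")
  }
  p
}

#' Build a sequence-logo height matrix from positive windows
#'
#' Computes, for each flank position j (-5..-1, +1..+5), the residue
#' frequencies f(i,j) of the positive alignment and the column information
#' content R_j = log2(20) - (H_j + e_n), where H_j is the Shannon entropy of
#' the column in bits and e_n = 19 / (2 ln(2) n) is the small-sample
#' correction for n aligned sequences (0 when \code{correction = FALSE};
#' R_j is clamped at 0).  The logo height of residue i at position j is
#' f(i,j) * R_j.  Blank symbols (\code{-}, beyond-terminus padding) do not
#' enter the frequencies and always score 0.
#'
#' @param positives Positive-class windows (\code{peptide_windows} or
#'   character vector of 11-mers with central Y).
#' @param correction Apply the small-sample correction (default TRUE).
#' @return A 20 x 10 matrix of class \code{logo_matrix} (rows: amino acids;
#'   columns: positions \code{-5..-1, +1..+5}) with attributes
#'   \code{n_sequences} and \code{correction}.
#' @export
build_logo <- function(positives, correction = TRUE) {
  peps <- as_peptides(positives)
  fl <- flank_matrix(peps)
  n <- length(peps)
  freqs <- apply(fl, 2, function(col) {
    col <- col[col != "-"]
    tab <- table(factor(col, levels = AA20))
    if (sum(tab) == 0L) rep(0, length(AA20)) else as.numeric(tab) / sum(tab)
  })
  rownames(freqs) <- AA20
  colnames(freqs) <- as.character(FLANK_POSITIONS)
  e_n <- if (correction) 19 / (2 * log(2) * n) else 0
  heights <- freqs
  for (j in seq_len(ncol(freqs))) {
    f <- freqs[, j]
    h <- -sum(ifelse(f > 0, f * log2(f), 0))
    r <- max(0, log2(20) - (h + e_n))
    heights[, j] <- f * r
  }
  structure(heights, n_sequences = n, correction = correction,
            class = c("logo_matrix", "matrix"))
}

#' Score windows by summed sequence-logo heights (method 1)
#'
#' The score of a window is the sum over the 10 flank positions of the logo
#' height of its residue at that position; \code{-} contributes 0.
#'
#' @param windows Windows to score (\code{peptide_windows} or character).
#' @param logo A \code{logo_matrix} from [build_logo()].
#' @return Numeric vector of scores, one per window.
#' @export
score_logo <- function(windows, logo) {
  peps <- as_peptides(windows)
  fl <- flank_matrix(peps)
  vapply(seq_len(nrow(fl)), function(k) {
    s <- 0
    for (j in seq_len(ncol(fl))) {
      a <- fl[k, j]
      if (a != "-") s <- s + logo[a, j]
    }
    s
  }, numeric(1))
}

## Column-wise relative frequencies over the 21-symbol alphabet.
freq_matrix21 <- function(peptides) {
  fl <- flank_matrix(peptides)
  freqs <- apply(fl, 2, function(col) {
    tab <- table(factor(col, levels = AA21))
    as.numeric(tab) / length(col)
  })
  rownames(freqs) <- AA21
  colnames(freqs) <- as.character(FLANK_POSITIONS)
  freqs
}

#' Build positive, negative and total frequency matrices (method 2)
#'
#' Each matrix has 21 rows (20 amino acids plus blank) and 10 columns
#' (flank positions); every column sums to 1.  The total matrix is the
#' frequency matrix of the pooled positive + negative alignments, i.e. the
#' sample-size-weighted mixture of the two class matrices.
#'
#' @param positives,negatives Class alignments (\code{peptide_windows} or
#'   character vectors of 11-mers).
#' @return An object of class \code{pssm}: a list with elements
#'   \code{positive}, \code{negative}, \code{total} and counts
#'   \code{n_pos}, \code{n_neg}.
#' @export
build_pssm <- function(positives, negatives) {
  pos <- as_peptides(positives)
  neg <- as_peptides(negatives)
  n_pos <- length(pos)
  n_neg <- length(neg)
  fp <- freq_matrix21(pos)
  fn <- freq_matrix21(neg)
  ft <- (n_pos * fp + n_neg * fn) / (n_pos + n_neg)
  structure(list(positive = fp, negative = fn, total = ft,
                 n_pos = n_pos, n_neg = n_neg),
            class = "pssm")
}

#' Score windows with the position-specific scoring matrices (method 2)
#'
#' The default combining formula is a pseudocount log-odds: for each flank
#' position j with residue a, the contribution is
#' \code{log2((f_pos(a,j) + alpha f_tot(a,j)) / (f_neg(a,j) + alpha
#' f_tot(a,j)))}, and the window score is the sum over the 10 positions.
#' A symbol absent from both classes (f_tot = 0) contributes 0.  The
#' formula identifier is attached to the result so downstream tables can
#' record how scores were combined.
#'
#' @param windows Windows to score.
#' @param pssm A \code{pssm} from [build_pssm()].
#' @param alpha Pseudocount weight on the total matrix; must be > 0.
#'   Default 0.05.
#' @return Numeric vector of scores with attribute \code{formula}.
#' @export
score_pssm <- function(windows, pssm, alpha = 0.05) {
  stopifnot(inherits(pssm, "pssm"))
  if (!is.numeric(alpha) || alpha <= 0) stop("alpha must be > 0")
  peps <- as_peptides(windows)
  fl <- flank_matrix(peps)
  scores <- vapply(seq_len(nrow(fl)), function(k) {
    s <- 0
    for (j in seq_len(ncol(fl))) {
      a <- fl[k, j]
      ft <- pssm$total[a, j]
      if (ft == 0) next
      s <- s + log2((pssm$positive[a, j] + alpha * ft) /
                    (pssm$negative[a, j] + alpha * ft))
    }
    s
  }, numeric(1))
  attr(scores, "formula") <- "logodds_total_pseudocount"
  attr(scores, "alpha") <- alpha
  scores
}

## One-hot flank encoding (21 symbols x 10 positions) plus amino-acid
## composition over the flanks: the feature map of the site classifier.
encode_windows <- function(peptides) {
  fl <- flank_matrix(peptides)
  n <- nrow(fl)
  onehot <- matrix(0, n, length(AA21) * ncol(fl))
  colnames(onehot) <- paste0(rep(colnames(fl), each = length(AA21)), ":",
                             rep(AA21, ncol(fl)))
  for (j in seq_len(ncol(fl))) {
    idx <- (j - 1L) * length(AA21) + match(fl[, j], AA21)
    onehot[cbind(seq_len(n), idx)] <- 1
  }
  comp <- t(vapply(seq_len(n), function(k) {
    tab <- table(factor(fl[k, ], levels = AA20))
    as.numeric(tab) / ncol(fl)
  }, numeric(length(AA20))))
  colnames(comp) <- paste0("comp:", AA20)
  cbind(onehot, comp)
}

## Smallest observed-score threshold t with mean(scores >= t) <= 1 - spec;
## if the most stringent observed score still lets too many pass (massive
## ties at the top), step just above the maximum.
calibrate_threshold <- function(scores, target_specificity) {
  cand <- sort(unique(scores))
  for (t in cand) {
    if (mean(scores >= t) <= 1 - target_specificity) return(t)
  }
  max(scores) + 1e-8
}

#' Train a specificity-calibrated phosphosite classifier (method 3)
#'
#' A linear model under logistic loss (ridge-regularised, fitted with
#' \pkg{glmnet}) over a one-hot window encoding plus flank amino-acid
#' composition.  Half of the negatives, sampled with the given seed, are
#' held out from fitting and used to calibrate the decision threshold so
#' that at most \code{1 - target_specificity} of held-out negatives score
#' at or above it.
#'
#' @param positives,negatives Class windows; each class needs at least 20.
#' @param target_specificity Desired specificity on negatives, in (0,1).
#'   Default 0.95.
#' @param seed Integer seed controlling the calibration split (required).
#' @param lambda Ridge penalty passed to \pkg{glmnet}; default 0.01.
#' @return An object of class \code{site_classifier} holding the fitted
#'   coefficients, the threshold, the calibration scores and the split.
#' @export
train_site_classifier <- function(positives, negatives,
                                  target_specificity = 0.95, seed,
                                  lambda = 0.01) {
  pos <- as_peptides(positives)
  neg <- as_peptides(negatives)
  if (length(pos) < 20L || length(neg) < 20L) {
    stop("each class needs at least 20 windows (got ",
         length(pos), " positive, ", length(neg), " negative)")
  }
  if (!is.numeric(target_specificity) || target_specificity <= 0 ||
      target_specificity >= 1) {
    stop("target_specificity must be in (0, 1)")
  }
  if (missing(seed)) stop("seed is required")
  set.seed(as.integer(seed))

  cal_idx <- sort(sample(length(neg), floor(length(neg) / 2)))
  neg_cal <- neg[cal_idx]
  neg_fit <- neg[-cal_idx]

  x <- encode_windows(c(pos, neg_fit))
  y <- c(rep(1L, length(pos)), rep(0L, length(neg_fit)))
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                        lambda = lambda, standardize = FALSE)
  beta <- as.numeric(fit$beta[, 1L])
  a0 <- as.numeric(fit$a0[1L])

  clf <- structure(list(beta = beta, a0 = a0,
                        feature_names = colnames(x),
                        target_specificity = target_specificity,
                        lambda = lambda, seed = as.integer(seed),
                        n_pos = length(pos), n_neg_fit = length(neg_fit),
                        n_neg_cal = length(neg_cal)),
                   class = "site_classifier")
  cal_scores <- score_classifier(neg_cal, clf)
  clf$threshold <- calibrate_threshold(cal_scores, target_specificity)
  clf$calibration_scores <- cal_scores
  clf
}

#' Score windows with a trained site classifier (method 3)
#'
#' Returns the continuous linear-predictor score; windows at or above the
#' calibrated threshold are classified as dephosphorylation sites (see
#' [classify_sites()]).
#'
#' @param windows Windows to score.
#' @param clf A \code{site_classifier} from [train_site_classifier()].
#' @return Numeric vector of scores.
#' @export
score_classifier <- function(windows, clf) {
  stopifnot(inherits(clf, "site_classifier"))
  x <- encode_windows(as_peptides(windows))
  as.numeric(x %*% clf$beta + clf$a0)
}

#' Classify windows at the calibrated specificity threshold
#'
#' @inheritParams score_classifier
#' @return Logical vector: score >= threshold.
#' @export
classify_sites <- function(windows, clf) {
  score_classifier(windows, clf) >= clf$threshold
}

#' Read externally produced site scores
#'
#' Adapter for score files produced outside the package (e.g. by a
#' standalone site predictor), so an external method can stand in for the
#' built-in classifier.  Expects a TSV with columns \code{peptide} and
#' \code{score}.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns \code{peptide}, \code{score}.
#' @export
read_external_scores <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("peptide", "score") %in% names(tab))) {
    stop("external score table must have columns peptide, score")
  }
  tab$peptide <- as_peptides(tab$peptide)
  tab[, c("peptide", "score")]
}

## Competition-free ranking: descending score, ties broken by lexicographic
## peptide order; returns a permutation of 1..N.
rank_descending <- function(score, peptide) {
  ord <- order(-score, peptide)
  r <- integer(length(score))
  r[ord] <- seq_along(score)
  r
}

#' Assemble a candidate table from three method scores
#'
#' @param windows A \code{peptide_windows} data frame (or character vector).
#' @param score1,score2,score3 Numeric scores from the three methods, one
#'   per window.
#' @return A data frame of class \code{candidate_records}: peptide, the
#'   three scores, the three ranks (1 = best; descending score, peptide
#'   lexicographic tie-break), and an \code{in_consensus} column
#'   initialised to NA until [consensus()] is applied.
#' @export
candidate_table <- function(windows, score1, score2, score3) {
  peps <- as_peptides(windows)
  n <- length(peps)
  for (s in list(score1, score2, score3)) {
    if (length(s) != n || anyNA(s)) {
      stop("each score vector must be complete and match the window count")
    }
  }
  out <- data.frame(
    peptide = peps,
    score1 = as.numeric(score1), score2 = as.numeric(score2),
    score3 = as.numeric(score3),
    rank1 = rank_descending(score1, peps),
    rank2 = rank_descending(score2, peps),
    rank3 = rank_descending(score3, peps),
    in_consensus = NA,
    stringsAsFactors = FALSE
  )
  if (is.data.frame(windows) && "sources" %in% names(windows)) {
    out$sources <- windows$sources
  }
  class(out) <- c("candidate_records", "data.frame")
  out
}

#' Mark the top-fraction consensus across the three methods
#'
#' A record is in the consensus when its rank is within the top
#' \code{ceiling(q * N)} under all three methods simultaneously.
#'
#' @param records A \code{candidate_records} data frame.
#' @param q Top fraction in (0, 1]; the protocol default is 0.1.
#' @return \code{records} with \code{in_consensus} set.
#' @export
consensus <- function(records, q = 0.1) {
  stopifnot(inherits(records, "candidate_records"))
  if (!is.numeric(q) || q <= 0 || q > 1) stop("q must be in (0, 1]")
  if (anyNA(records$score1) || anyNA(records$score2) || anyNA(records$score3)) {
    stop("all three scores must be populated before taking the consensus")
  }
  cut <- ceiling(q * nrow(records))
  records$in_consensus <- records$rank1 <= cut & records$rank2 <= cut &
    records$rank3 <= cut
  attr(records, "q") <- q
  records
}

#' Write a scoring matrix with a JSON sidecar
#'
#' Serialises a \code{logo_matrix} or \code{pssm} as TSV (symbols x
#' positions) next to a \code{.json} sidecar recording sample sizes and
#' settings, so score tables remain traceable to the model that produced
#' them.
#'
#' @param model A \code{logo_matrix} or \code{pssm}.
#' @param basepath Output path without extension; a \code{pssm} writes
#'   \code{<basepath>.positive.tsv} etc.
#' @return The sidecar path, invisibly.
#' @export
write_scoring_model <- function(model, basepath) {
  write_mat <- function(m, path) {
    utils::write.table(data.frame(symbol = rownames(m), m,
                                  check.names = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (inherits(model, "logo_matrix")) {
    write_mat(unclass(model), paste0(basepath, ".tsv"))
    meta <- list(kind = "logo_matrix",
                 n_sequences = attr(model, "n_sequences"),
                 correction = attr(model, "correction"))
  } else if (inherits(model, "pssm")) {
    for (part in c("positive", "negative", "total")) {
      write_mat(model[[part]], paste0(basepath, ".", part, ".tsv"))
    }
    meta <- list(kind = "pssm", n_pos = model$n_pos, n_neg = model$n_neg,
                 formula = "logodds_total_pseudocount")
  } else {
    stop("model must be a logo_matrix or pssm")
  }
  sidecar <- paste0(basepath, ".json")
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, pretty = TRUE)
  invisible(sidecar)
}
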