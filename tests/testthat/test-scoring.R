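test_that("logo heights follow the information-content formula", {
  # every flank column uniform over the 20 AA -> zero information, zero heights
  uniform <- vapply(seq_along(AA20), function(k) {
    paste0(strrep(AA20[k], 5), "Y", strrep(AA20[k], 5))
  }, character(1))
  logo <- build_logo(uniform, correction = FALSE)
  expect_true(all(abs(logo) < 1e-12))
  expect_equal(score_logo("DPSDNYAEPID", logo), 0)

  # a single-sequence column is pure: height = log2(20)
  logo1 <- build_logo("EEEEEYEEEEE", correction = FALSE)
  expect_equal(unname(logo1["E", "-5"]), log2(20), tolerance = 1e-12)
  expect_equal(score_logo("EEEEEYEEEEE", logo1), 10 * log2(20),
               tolerance = 1e-9)

  # small-sample correction at n = 10: height = log2(20) - 19/(20 ln 2)
  logo10 <- build_logo(rep("EEEEEYEEEEE", 10), correction = TRUE)
  expect_equal(unname(logo10["E", "3"]), log2(20) - 19 / (20 * log(2)),
               tolerance = 1e-12)
})

test_that("logo is invariant to duplicating the alignment (correction off)", {
  pos <- motif_windows(30, seed = 5)
  l1 <- build_logo(pos, correction = FALSE)
  l3 <- build_logo(rep(pos, 3), correction = FALSE)
  expect_equal(unclass(l1), unclass(l3), ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("method-1 scores equal brute-force height summation", {
  logo <- build_logo(motif_windows(50, seed = 1))
  queries <- rand_windows(100, seed = 2)
  expected <- vapply(queries, brute_logo_score, numeric(1), logo = logo)
  expect_equal(score_logo(queries, logo), unname(expected),
               tolerance = 1e-9)
  # blank symbols contribute zero
  padded <- "----AYCCCCC"
  expect_equal(score_logo(padded, logo), brute_logo_score(padded, logo),
               tolerance = 1e-12)
})

test_that("frequency matrices are column-normalised with a pooled total", {
  pos <- rand_windows(3, seed = 3)
  neg <- rand_windows(7, seed = 4)
  m <- build_pssm(pos, neg)
  for (part in c("positive", "negative", "total")) {
    expect_equal(unname(colSums(m[[part]])), rep(1, 10), tolerance = 1e-9)
  }
  # total is the 0.3/0.7 mixture of the class matrices
  expect_equal(m$total, 0.3 * m$positive + 0.7 * m$negative,
               tolerance = 1e-12)

  same <- build_pssm(pos, pos)
  expect_equal(same$positive, same$negative)
  expect_equal(same$positive, same$total)

  single <- build_pssm("AAAAAYAAAAA", neg)
  expect_equal(unname(single$positive["A", ]), rep(1, 10))
})

test_that("PSSM scores match the log-odds formula and its symmetries", {
  pos <- rand_windows(20, seed = 6)
  neg <- rand_windows(30, seed = 7)
  m <- build_pssm(pos, neg)
  queries <- rand_windows(100, seed = 8)
  got <- score_pssm(queries, m, alpha = 0.05)
  expected <- vapply(queries, brute_pssm_score, numeric(1), pssm = m,
                     alpha = 0.05)
  expect_equal(as.numeric(got), unname(expected), tolerance = 1e-9)
  expect_equal(attr(got, "formula"), "logodds_total_pseudocount")

  # identical classes give zero odds everywhere
  null <- build_pssm(pos, pos)
  expect_true(all(abs(score_pssm(queries, null)) < 1e-12))

  # swapping the classes negates the score
  swapped <- build_pssm(neg, pos)
  expect_equal(as.numeric(score_pssm(queries, swapped, alpha = 0.05)),
               -as.numeric(got), tolerance = 1e-9)

  # a residue seen only in positives scores positive
  mm <- build_pssm("WWWWWYWWWWW", "AAAAAYAAAAA")
  expect_gt(as.numeric(score_pssm("WWWWWYWWWWW", mm, alpha = 0.01)), 0)

  expect_error(score_pssm(queries, m, alpha = 0), "alpha")
})

test_that("threshold calibration sits just above the specificity quantile", {
  thr <- ptpscreen:::calibrate_threshold(1:100, 0.95)
  expect_equal(thr, 96)                  # 5 of 100 scores pass, none more
  expect_lte(mean(1:100 >= thr), 0.05)
  # heavy top ties force the threshold above the maximum
  thr2 <- ptpscreen:::calibrate_threshold(rep(7, 50), 0.95)
  expect_gt(thr2, 7)
})

test_that("classifier separates planted motif classes at calibrated specificity", {
  pos <- motif_windows(120, strength = 0.9, seed = 9)
  neg <- rand_windows(400, seed = 10)
  clf <- train_site_classifier(pos, neg, target_specificity = 0.95,
                               seed = 99)
  # deterministic given the seed
  clf2 <- train_site_classifier(pos, neg, target_specificity = 0.95,
                                seed = 99)
  expect_identical(clf$beta, clf2$beta)
  expect_identical(clf$threshold, clf2$threshold)

  # held-out positives: sensitivity at 95% specificity
  fresh_pos <- motif_windows(200, strength = 0.9, seed = 11)
  expect_gte(mean(classify_sites(fresh_pos, clf)), 0.95)
  # fresh negatives: specificity near target (single-seed binomial check,
  # so allow the usual 3-sigma band)
  fresh_neg <- rand_windows(400, seed = 12)
  expect_lte(mean(classify_sites(fresh_neg, clf)),
             0.05 + 3 * sqrt(0.05 * 0.95 / 400))

  # batch scoring equals per-item scoring
  some <- fresh_pos[1:5]
  expect_equal(score_classifier(some, clf),
               vapply(some, function(p) score_classifier(p, clf),
                      numeric(1), USE.NAMES = FALSE))
  # windows containing blanks are still scored
  expect_true(is.finite(score_classifier("----AYCCCCC", clf)))

  expect_error(train_site_classifier(pos[1:5], neg, seed = 1),
               "at least 20")
})

test_that("no-signal classes yield chance-level sensitivity", {
  pos <- rand_windows(150, seed = 13)
  neg <- rand_windows(300, seed = 14)
  clf <- train_site_classifier(pos, neg, target_specificity = 0.95,
                               seed = 15)
  fresh <- rand_windows(400, seed = 16)
  # same distribution as negatives: pass rate ~ 1 - specificity
  expect_lte(mean(classify_sites(fresh, clf)),
             0.05 + 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("consensus equals the intersection of the three top-q sets", {
  set.seed(17)
  n <- 100
  w <- rand_windows(n)
  s1 <- rnorm(n); s2 <- rnorm(n); s3 <- rnorm(n)
  rec <- candidate_table(w, s1, s2, s3)
  expect_equal(sort(rec$rank1), 1:n)     # ranks are a permutation

  out <- consensus(rec, q = 0.1)
  cut <- ceiling(0.1 * n)
  top <- function(s) w[order(-s, w)][1:cut]
  brute <- Reduce(intersect, list(top(s1), top(s2), top(s3)))
  expect_setequal(out$peptide[out$in_consensus], brute)

  # subset of each method's top set, and monotone in q
  expect_true(all(out$rank1[out$in_consensus] <= cut))
  out2 <- consensus(rec, q = 0.2)
  expect_true(all(out$peptide[out$in_consensus] %in%
                  out2$peptide[out2$in_consensus]))
  expect_true(all(consensus(rec, q = 1)$in_consensus))
})

test_that("rank ties break deterministically by peptide order", {
  w <- c("AAAAAYAAAAA", "CCCCCYCCCCC", "DDDDDYDDDDD")
  rec <- candidate_table(w, c(1, 1, 0), c(1, 1, 0), c(1, 1, 0))
  expect_equal(rec$rank1, c(1L, 2L, 3L))
  out <- consensus(rec, q = 1 / 3)
  expect_equal(out$peptide[out$in_consensus], "AAAAAYAAAAA")
})

test_that("consensus refuses incomplete scores and bad q", {
  rec <- candidate_table(rand_windows(10, seed = 18), 1:10, 1:10, 1:10)
  expect_error(consensus(rec, q = 0), "q must be")
  rec$score2[1] <- NA
  expect_error(consensus(rec, q = 0.5), "populated")
})

test_that("scoring models serialise with JSON sidecars", {
  dir <- withr::local_tempdir()
  logo <- build_logo(motif_windows(20, seed = 19))
  side <- write_scoring_model(logo, file.path(dir, "logo"))
  meta <- jsonlite::read_json(side)
  expect_equal(meta$n_sequences, 20)
  m <- build_pssm(motif_windows(20, seed = 20), rand_windows(20, seed = 21))
  write_scoring_model(m, file.path(dir, "pssm"))
  expect_true(file.exists(file.path(dir, "pssm.positive.tsv")))
  tab <- read.delim(file.path(dir, "pssm.total.tsv"), check.names = FALSE)
  expect_equal(tab$symbol, ptpscreen:::AA21)
})
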