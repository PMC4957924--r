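test_that("FASTA reading uppercases, validates and collapses duplicate sequences", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">P1 GN=GENEA", "aaaaayaaaaa",
               ">P2 GN=GENEB", "AAAAAYAAAAA",
               ">P3", "CCCCCYCCCCC"), f)
  prot <- read_fasta(f)
  expect_s3_class(prot, "protein_set")
  expect_equal(nrow(prot), 2L)
  dup <- prot[prot$sequence == "AAAAAYAAAAA", ]
  expect_equal(dup$id, "P1;P2")
  expect_equal(dup$gene, "GENEA;GENEB")

  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(), empty)
  expect_equal(nrow(read_fasta(empty)), 0L)

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">P1", "AAAB1AA"), bad)
  expect_error(read_fasta(bad), "non-amino-acid")
})

test_that("FASTA round-trips through write_fasta", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">P1 GN=GENEA", "DPSDNYAEPIDKL", ">P3", "CCCCCYCCCCC"), f)
  prot <- read_fasta(f)
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(prot, f2)
  expect_equal(read_fasta(f2), prot)
})

make_proteins <- function(...) {
  seqs <- c(...)
  ptpscreen:::as_protein_set(names(seqs), rep(NA_character_, length(seqs)),
                             unname(seqs))
}

test_that("site annotations are validated with explicit rejection reasons", {
  prot <- make_proteins(P1 = "AAAAAYAAAAA")
  tab <- data.frame(protein_id = c("P1", "P1", "P1", "PX"),
                    position = c(6L, 6L, 3L, 2L),
                    residue = c("Y", "Y", "Y", "Y"))
  expect_warning(sites <- read_site_annotations(tab, prot), "rejected")
  expect_equal(nrow(sites), 1L)          # duplicates collapse to one site
  expect_equal(sites$position, 6L)
  rej <- attr(sites, "rejected")
  expect_equal(nrow(rej), 2L)
  expect_true(any(grepl("not Y", rej$reason)))
  expect_true(any(grepl("not found", rej$reason)))

  out_of_range <- data.frame(protein_id = "P1", position = 99L, residue = "Y")
  expect_error(read_site_annotations(out_of_range, prot),
               "out of range.*P1:99")
})

test_that("window extraction pads termini, deduplicates and merges sources", {
  prot <- make_proteins(P1 = "DPSDNYAEPID", P2 = "AYCCCCC",
                        P3 = "KKDPSDNYAEPIDKK")
  sites <- data.frame(protein_id = c("P1", "P2", "P3"),
                      position = c(6L, 2L, 8L), residue = "Y")
  w <- extract_windows(sites, prot)
  expect_setequal(w$peptide, c("DPSDNYAEPID", "----AYCCCCC"))
  shared <- w[w$peptide == "DPSDNYAEPID", ]
  expect_equal(shared$n_sources, 2L)     # same 11-mer from two proteins
  expect_equal(shared$sources, "P1:6;P3:8")
  expect_equal(w$peptide[w$sources == "P2:2"], "----AYCCCCC")
})

test_that("every window is reconstructible from each of its sources", {
  set.seed(42)
  seqs <- vapply(1:20, function(i) {
    paste(sample(AA20, 60, replace = TRUE), collapse = "")
  }, character(1))
  prot <- make_proteins(stats::setNames(seqs, sprintf("Q%02d", 1:20)))
  sites <- do.call(rbind, lapply(seq_len(nrow(prot)), function(k) {
    pos <- which(strsplit(prot$sequence[k], "")[[1]] == "Y")
    if (length(pos) == 0) return(NULL)
    data.frame(protein_id = prot$id[k], position = pos, residue = "Y")
  }))
  w <- extract_windows(sites, prot)
  expect_lte(nrow(w), nrow(sites))       # dedup can only shrink
  idx <- ptpscreen:::protein_id_index(prot)
  for (k in seq_len(nrow(w))) {
    for (s in strsplit(w$sources[k], ";")[[1]]) {
      pid <- sub(":\\d+$", "", s)
      pos <- as.integer(sub("^.*:", "", s))
      expect_equal(ptpscreen:::window_at(prot$sequence[idx[pid]], pos),
                   w$peptide[k])
    }
  }
  # idempotent / order-independent
  w2 <- extract_windows(sites[sample(nrow(sites)), ], prot)
  expect_equal(w, w2)
})

test_that("windows containing X are dropped with a warning", {
  prot <- make_proteins(P1 = "AAXAAYAAAAA", P2 = "CCCCCYCCCCC")
  sites <- data.frame(protein_id = c("P1", "P2"), position = 6L,
                      residue = "Y")
  expect_warning(w <- extract_windows(sites, prot), "containing X")
  expect_equal(w$peptide, "CCCCCYCCCCC")
})

test_that("background enumeration excludes whole annotated proteins by default", {
  prot <- make_proteins(P1 = "AAYAAAAYAAAAAYAA",   # 3 Y, unannotated
                        P2 = "CCCCCYCCCCC",        # annotated
                        P3 = "AAAAAAAAAA")         # no Y
  ann <- data.frame(protein_id = "P2", position = 6L, residue = "Y")
  bg <- enumerate_background_windows(prot, ann)
  srcs <- unlist(strsplit(bg$sources, ";"))
  expect_equal(sum(lengths(strsplit(bg$sources, ";"))), 3L)
  expect_true(all(startsWith(srcs, "P1:")))

  # site-level exclusion keeps unannotated tyrosines on annotated proteins
  prot2 <- make_proteins(P2 = "CCCCCYCCCCCYCCCCC")
  ann2 <- data.frame(protein_id = "P2", position = 6L, residue = "Y")
  expect_equal(nrow(enumerate_background_windows(prot2, ann2, "protein")), 0L)
  bg2 <- enumerate_background_windows(prot2, ann2, "site")
  expect_equal(bg2$sources, "P2:12")
})
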