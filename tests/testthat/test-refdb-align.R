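make_entries <- function(seqs) {
  lapply(seq_along(seqs), function(i)
    reference_entry(paste0("e", i), seqs[[i]],
                    rep(0L, nchar(seqs[[i]]))))
}

test_that("database construction filters exact matches and rejects duplicates", {
  set.seed(11)
  seqs <- replicate(5, random_aa_string(40))
  db <- build_reference_db(make_entries(seqs), exclude_exact_of = seqs[3])
  expect_identical(length(db), 4L)
  expect_false("e3" %in% names(db$entries))

  expect_identical(length(build_reference_db(make_entries(seqs))), 5L)

  dup <- make_entries(seqs[1:2])
  dup[[2]]$id <- "e1"
  expect_error(build_reference_db(dup), "duplicate")
})

test_that("a self-match ranks first with full-coverage pairs", {
  set.seed(12)
  seqs <- replicate(6, random_aa_string(100))
  db <- build_reference_db(make_entries(seqs))
  hits <- local_align_search(seqs[1], db, search_params())
  expect_gt(length(hits), 0)
  expect_identical(hits[[1]]$subject_id, "e1")
  expect_identical(hits[[1]]$pairs[, 1], 1:100)
  expect_identical(hits[[1]]$pairs[, 2], 1:100)
})

test_that("hit lists respect e-value ceiling, ordering, and top_s truncation", {
  set.seed(13)
  base <- random_aa_string(120)
  # 15 mutated copies all qualify; top_s = 10 must truncate
  copies <- vapply(1:15, function(i) {
    ch <- strsplit(base, "")[[1]]
    idx <- sample(120, 12)
    ch[idx] <- sample(c("A","G","S","T","V"), 12, replace = TRUE)
    paste(ch, collapse = "")
  }, "")
  db <- build_reference_db(make_entries(copies))
  hits <- local_align_search(base, db, search_params(top_s = 10))
  expect_length(hits, 10)
  ev <- vapply(hits, `[[`, 0, "evalue")
  expect_true(all(diff(ev) >= 0))
  expect_true(all(ev <= 0.1))
  expect_true(all(ev > 0))

  # aligned pairs are strictly increasing in both coordinates
  for (h in hits) {
    expect_true(all(diff(h$pairs[, 1]) > 0))
    expect_true(all(diff(h$pairs[, 2]) > 0))
  }
})

test_that("an unrelated query returns no hits at a strict ceiling", {
  set.seed(14)
  db_seqs <- replicate(4, random_aa_string(60))
  db <- build_reference_db(make_entries(db_seqs))
  query <- random_aa_string(50)
  # oracle: no brute-force SW score reaches e <= 1e-6
  data("BLOSUM62", package = "Biostrings", envir = environment())
  max_score <- max(vapply(db_seqs, function(s)
    sw_score_oracle(query, s, BLOSUM62), 0))
  lambda <- hingecrf:::KA_LAMBDA; K <- hingecrf:::KA_K
  expect_gt(K * 50 * db$total_residues * exp(-lambda * max_score), 1e-6)
  expect_length(local_align_search(query, db, search_params(e_max = 1e-6)), 0)
})

test_that("built-in local alignment matches a brute-force Gotoh DP on short sequences", {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  set.seed(15)
  for (i in 1:20) {
    a <- random_aa_string(sample(8:12, 1))
    b <- random_aa_string(sample(8:12, 1))
    ours <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(b), a, type = "local",
      substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
      scoreOnly = TRUE)
    expect_equal(ours, sw_score_oracle(a, b, BLOSUM62), tolerance = 1e-9)
  }
})

test_that("search validates inputs", {
  db <- build_reference_db(make_entries(list(random_aa_string(30))))
  expect_error(local_align_search("ACDB1", db), "non-amino-acid")
  expect_identical(local_align_search("ACDEFGHIK",
                                      build_reference_db(list())), list())
})

test_that("tabular hit import filters, sorts, and checks referential integrity", {
  set.seed(16)
  seqs <- replicate(3, random_aa_string(30))
  db <- build_reference_db(make_entries(seqs))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("query_id\tsubject_id\tevalue\tbits\tblocks",
               "q1\te1\t0.5\t20\t1-10/5-14",        # above e_max: dropped
               "q1\te2\t0.05\t30\t1-10/2-11",
               "q1\te3\t0.01\t40\t2-9/3-10",
               "q1\te1\t0.03\t35\t1-8/1-8"), path)
  hits <- import_tabular_hits(path, db, search_params())$q1
  expect_identical(vapply(hits, `[[`, "", "subject_id"), c("e3", "e1", "e2"))
  expect_identical(hits[[1]]$pairs[, 1], 2:9)
  expect_identical(hits[[1]]$pairs[, 2], 3:10)

  writeLines(c("query_id\tsubject_id\tevalue\tbits\tblocks",
               "q1\tnope\t0.01\t40\t1-5/1-5"), path)
  expect_error(import_tabular_hits(path, db), "nope")
})

test_that("hit tables round-trip through write and import", {
  set.seed(17)
  seqs <- replicate(6, random_aa_string(80))
  db <- build_reference_db(make_entries(seqs))
  hits <- local_align_search(seqs[2], db)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tabular_hits(list(q = hits), path)
  back <- import_tabular_hits(path, db)$q
  expect_identical(length(back), length(hits))
  for (i in seq_along(hits)) {
    expect_identical(back[[i]]$subject_id, hits[[i]]$subject_id)
    expect_identical(back[[i]]$pairs, hits[[i]]$pairs)
  }
})

test_that("reference databases round-trip through FASTA plus label files", {
  fx <- fixture_small()
  fa <- withr::local_tempfile(fileext = ".fasta")
  lb <- withr::local_tempfile(fileext = ".tsv")
  write_reference_db(fx$db, fa, lb)
  back <- read_reference_db(fa, lb)
  expect_identical(length(back), length(fx$db))
  id <- names(fx$db$entries)[5]
  expect_identical(back$entries[[id]]$sequence, fx$db$entries[[id]]$sequence)
  expect_identical(back$entries[[id]]$labels3, fx$db$entries[[id]]$labels3)
})
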