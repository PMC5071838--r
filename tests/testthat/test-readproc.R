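adapter <- "TGGAATTCTCGGGTGCCAAGG"

test_that("trim_adapter returns the insert 5' of the left-most match", {
  insert <- "TGAGGTAGTAGGTTGTATAGTT"
  r <- trim_adapter(paste0(insert, adapter), adapter3 = adapter)
  expect_false(r$removed)
  expect_identical(r$seq, insert)

  # qualities are trimmed alongside
  q <- strrep("I", nchar(insert) + nchar(adapter))
  r <- trim_adapter(paste0(insert, adapter), q, adapter3 = adapter)
  expect_identical(nchar(r$qual), nchar(insert))

  # no adapter anywhere -> removed with reason 3ADT
  r <- trim_adapter(strrep("ACGT", 9), adapter3 = adapter)
  expect_true(r$removed)
  expect_identical(r$reason, "3ADT")

  # read that is pure adapter -> empty insert (length filter removes later)
  r <- trim_adapter(adapter, adapter3 = adapter)
  expect_false(r$removed)
  expect_identical(r$seq, "")
  expect_false(filter_length(r$seq))

  # one mismatch in the matched region is tolerated, two are not
  mut1 <- sub("TGGAATT", "TGCAATT", adapter)
  expect_false(trim_adapter(paste0(insert, mut1), adapter3 = adapter)$removed)
  mut2 <- sub("TGGAATTCTC", "TGCAATTCTG", adapter)
  expect_true(trim_adapter(paste0(insert, mut2), adapter3 = adapter)$removed)

  # partial adapter at the 3' end counts if the overlap is >= min_overlap
  r <- trim_adapter(paste0(insert, substr(adapter, 1, 7)), adapter3 = adapter)
  expect_identical(r$seq, insert)
  r <- trim_adapter(paste0(insert, substr(adapter, 1, 4)), adapter3 = adapter)
  expect_true(r$removed)

  expect_error(trim_adapter("ACGT", adapter3 = ""), "empty adapter")
  expect_error(trim_adapter("ACGT", adapter3 = adapter, min_overlap = 3),
               "min_overlap")
})

test_that("length filter keeps 15-30 nt inclusive", {
  expect_identical(filter_length(strrep("A", 14)), FALSE)
  expect_identical(filter_length(strrep("A", 15)), TRUE)
  expect_identical(filter_length(strrep("A", 22)), TRUE)
  expect_identical(filter_length(strrep("A", 30)), TRUE)
  expect_identical(filter_length(strrep("A", 31)), FALSE)
})

test_that("quality filter thresholds the mean Phred, boundary inclusive", {
  q30 <- strrep(rawToChar(as.raw(30 + 33)), 20)
  q10 <- strrep(rawToChar(as.raw(10 + 33)), 20)
  expect_true(filter_quality(q30))
  expect_false(filter_quality(q10))
  # mean exactly 20.0 -> keep (removal is for < 20)
  q_mix <- paste0(strrep(rawToChar(as.raw(10 + 33)), 10),
                  strrep(rawToChar(as.raw(30 + 33)), 10))
  expect_true(filter_quality(q_mix))
  expect_false(filter_quality(q_mix, threshold = 20.5))
})

test_that("composition filter fires the documented rules with reasons", {
  cases <- list(
    list(strrep("AC", 10), "dimer"),
    list(paste0("GGGGGGA", strrep("ACT", 5)), "polyG"),
    list("ANCGTNACGTACGTACG", "N"),
    list(paste0("CGT", strrep("A", 7), "CGTCGTCGAT"), "polyA"),
    list(paste0("GAT", strrep("C", 8), "GTAGTAGAT"), "polyC"),
    list(paste0("GAC", strrep("T", 7), "GACGACGAC"), "polyT"),
    list(paste0(strrep("ACT", 6), "GA"), "trimer"),
    list(strrep("ACGT", 5), "tetramer")
  )
  for (cs in cases) {
    got <- filter_composition(cs[[1]])
    expect_false(got$keep)
    expect_identical(got$reason, cs[[2]])
  }
  # clean miRNA-like sequences pass
  expect_true(filter_composition("TGAGGTAGTAGGTTGTATAGTT")$keep)
  # boundary: runs one short of the threshold pass
  expect_true(filter_composition(paste0("CGT", strrep("A", 6), "CGTCGTCG"))$keep)
  expect_true(filter_composition(paste0(strrep("AC", 9), "GTT"))$keep)
  expect_error(filter_composition("ACGTXACGT"), "non-nucleotide")
})

test_that("collapse produces one tag per distinct sequence and conserves counts", {
  r <- collapse_tags(list(A = c("ACGTACGTACGTACG", "ACGTACGTACGTACG",
                                "ACGTACGTACGTACG"),
                          B = character()))
  expect_identical(nrow(r), 1L)
  expect_identical(r$A, 3L)
  expect_identical(r$B, 0L)

  expect_identical(nrow(collapse_tags(list(A = character()))), 0L)

  set.seed(42)
  seqs <- replicate(50, rand_dna(20))
  libA <- sample(seqs, 400, replace = TRUE)
  libB <- sample(seqs, 300, replace = TRUE)
  tags <- collapse_tags(list(A = libA, B = libB))
  expect_identical(nrow(tags), length(unique(c(libA, libB))))
  expect_identical(sum(tags$A), 400L)
  expect_identical(sum(tags$B), 300L)
  # round trip: expanding tags by their counts recovers the multiset
  expect_identical(sort(rep(tags$seq, tags$A)), sort(libA))
})

test_that("summaries recount exactly", {
  tags <- collapse_tags(list(A = c(rep("TAGCTAGCTAGCTAGCTAGCTT", 3),
                                   rep("TTTTACGTACGTACGTACGTAC", 2))))
  s <- summarize_library(tags)
  expect_identical(as.integer(s$length_histogram[["22"]]), 2L)
  expect_identical(unname(s$first_base_freq["T"]), 1)
  expect_equal(colSums(s$per_position_freq), rep(1, 22))
  expect_identical(as.integer(s$read_count_frequency[["3"]]), 1L)

  set.seed(7)
  tags <- collapse_tags(list(A = replicate(80, rand_dna(sample(15:25, 1)))))
  s <- summarize_library(tags)
  expect_equal(unname(colSums(s$per_position_freq)),
               rep(1, ncol(s$per_position_freq)))
  expect_equal(sum(s$first_base_freq), 1)
  expect_equal(sum(s$last_base_freq), 1)
})

test_that("clean_reads ledger conserves reads exactly and is idempotent on survivors", {
  set.seed(31)
  good <- character(0)   # random inserts vetted to pass every pure filter
  while (length(good) < 40) {
    cand <- rand_dna(22)
    if (filter_composition(cand)$keep &&
        !grepl(substr(adapter, 1, 6), cand, fixed = TRUE))
      good <- c(good, cand)
  }
  reads <- c(paste0(good, adapter),                  # clean
             strrep("ACGT", 9),                      # no adapter
             paste0(strrep("A", 10), adapter),       # too short after trim
             paste0(strrep("AC", 10), adapter))      # dimer composition
  fq <- write_tiny_fastq(reads, tempfile(fileext = ".fastq"))
  cl <- clean_reads(c(lib = fq), adapter3 = adapter)
  expect_identical(sum(cl$ledger[, "lib"]), cl$n_raw[["lib"]])
  expect_identical(cl$ledger["3ADT", "lib"], 1L)
  expect_identical(cl$ledger["length", "lib"], 1L)
  expect_identical(cl$ledger["composition", "lib"], 1L)
  expect_identical(sum(cl$tags$lib), 40L)

  # survivors pass every pure filter again (idempotence)
  expect_true(all(filter_length(cl$tags$seq)))
  expect_true(all(filter_composition(cl$tags$seq)$keep))
})
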