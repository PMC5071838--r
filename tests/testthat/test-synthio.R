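test_that("make_reference validates inputs and is deterministic", {
  expect_error(make_reference(seed = 1, n_mirnas = 0), "n_mirnas")
  expect_error(make_reference(seed = 1, n_mirnas = 50, genome_length = 500),
               "genome too small")
  r1 <- make_reference(seed = 7, n_mirnas = 20, genome_length = 50000)
  r2 <- make_reference(seed = 7, n_mirnas = 20, genome_length = 50000)
  expect_identical(r1, r2)
  r3 <- make_reference(seed = 8, n_mirnas = 20, genome_length = 50000)
  expect_false(identical(r1$genome, r3$genome))
})

test_that("reference bundle satisfies its structural invariants", {
  ref <- make_reference(seed = 7, n_mirnas = 20, genome_length = 50000)
  # every mature occurs verbatim in its precursor
  for (i in seq_len(nrow(ref$mature_info))) {
    pre <- ref$precursors[[ref$mature_info$precursor_id[i]]]
    expect_true(grepl(ref$mature_info$seq[i], pre, fixed = TRUE))
    # and at the recorded coordinates
    expect_identical(
      substr(pre, ref$mature_info$mature_start[i], ref$mature_info$mature_end[i]),
      ref$mature_info$seq[i])
  }
  # every precursor occurs verbatim in the genome at its recorded start
  for (i in seq_len(nrow(ref$mature_info))) {
    pre <- ref$precursors[[ref$mature_info$precursor_id[i]]]
    s <- ref$mature_info$genome_start[i]
    expect_identical(unname(substr(ref$genome, s, s + nchar(pre) - 1L)), pre)
  }
  # decoys share no 18 nt substring with any mature
  mers <- unlist(lapply(ref$matures, function(m) {
    substring(m, 1:(nchar(m) - 17), 18:nchar(m))
  }))
  for (d in c(ref$ncrna_decoys, ref$repeat_decoys))
    expect_false(any(vapply(mers, grepl, NA, d, fixed = TRUE)))
  # truth weights form a distribution
  expect_equal(sum(ref$truth$base_weight), 1)
})

test_that("embed_hairpin builds a valid, deterministic precursor", {
  m <- "TGAGGTAGTAGGTTGTATAGTT"
  p1 <- embed_hairpin(m, seed = 3)
  p2 <- embed_hairpin(m, seed = 3)
  expect_identical(p1, p2)
  expect_true(grepl(m, p1, fixed = TRUE))
  # the opposite arm carries the full reverse complement
  expect_true(grepl(revcomp(m), p1, fixed = TRUE))
  # accepted by the package's own fold + validation oracle
  f <- fold_hairpin(as.character(p1))
  v <- validate_hairpin(f, c(attr(p1, "mature_start"), attr(p1, "mature_end")))
  expect_true(v$pass)
  # U input is equivalent to T input
  expect_identical(as.character(embed_hairpin("UGAGGUAGUAGGUUGUAUAGUU", 3)),
                   as.character(embed_hairpin(m, 3)))

  expect_error(embed_hairpin("ACGTACGTAC", seed = 1), "length")
  expect_error(embed_hairpin("ACGTACGTACGTACGTACXT", seed = 1),
               "non-nucleotide")
})

test_that("library_spec rejects degenerate settings", {
  expect_error(library_spec(adapter3 = "ACGTA"), "6 nt")
  expect_error(library_spec(contamination_fraction = 0.9,
                            degenerate_fraction = 0.2), "sum")
  expect_error(library_spec(depth = -1), "depth")
})

test_that("simulated libraries have exactly depth records and a consistent truth table", {
  ref <- make_reference(seed = 11, n_mirnas = 15, genome_length = 30000)
  spec <- library_spec(seed = 4, depth = 4000)
  out <- tempfile("sim")
  sim <- simulate_libraries(ref, spec, NULL, out)

  for (fq in sim$fastq)
    expect_identical(nrow(read_fastq(fq)), 4000L)

  # truth totals: depth x (1 - contamination - degenerate) within
  # multinomial error (3 sd of the binomial for the real-read class)
  expectn <- 4000 * (1 - spec$contamination_fraction - spec$degenerate_fraction)
  sdn <- sqrt(4000 * 0.88 * 0.12)
  expect_lt(abs(sum(sim$truth_df$cond1_count) - expectn), 3 * sdn)
  expect_lt(abs(sum(sim$truth_df$cond2_count) - expectn), 3 * sdn)

  # determinism: identical inputs give byte-identical outputs
  sim2 <- simulate_libraries(ref, spec, NULL, tempfile("sim"))
  expect_identical(unname(tools::md5sum(sim$fastq)),
                   unname(tools::md5sum(sim2$fastq)))
  expect_identical(sim$truth_df, sim2$truth_df)
})

test_that("null fold changes give equal counts within binomial error", {
  ref <- make_reference(seed = 12, n_mirnas = 10, genome_length = 20000)
  spec <- library_spec(seed = 5, depth = 20000,
                       contamination_fraction = 0, degenerate_fraction = 0)
  sim <- simulate_libraries(ref, spec, NULL, tempfile("sim"))
  t <- sim$truth_df
  # conditional on the pair total T, c1 ~ Binomial(T, 1/2), so
  # sd(c1 - c2) = sqrt(T); allow 3 sd per mature
  diffs <- abs(t$cond1_count - t$cond2_count)
  bound <- 3 * sqrt(t$cond1_count + t$cond2_count)
  expect_true(all(diffs <= pmax(bound, 10)))
})

test_that("depth zero yields empty libraries", {
  ref <- make_reference(seed = 13, n_mirnas = 5, genome_length = 20000)
  sim <- simulate_libraries(ref, library_spec(seed = 1, depth = 0),
                            NULL, tempfile("sim"))
  expect_identical(nrow(read_fastq(sim$fastq[[1]])), 0L)
  expect_true(all(sim$truth_df$cond1_count == 0))
})

test_that("fc_map validation and spiked fold changes are realized", {
  ref <- make_reference(seed = 21, n_mirnas = 40, genome_length = 60000)
  spec <- library_spec(seed = 9, depth = 50000)
  expect_error(simulate_libraries(ref, spec, c("sav-miR-1" = -2), tempfile()),
               "> 0")
  expect_error(simulate_libraries(ref, spec, c(nosuch = 2), tempfile()),
               "mirna ids")

  # spike a mid-weight mature at fc 8.38: realized ratio within sampling
  # tolerance of the compositional expectation fc / (1 + w (fc - 1))
  w <- ref$truth$base_weight
  pick <- ref$truth$mirna_id[order(abs(w - 0.01))[1]]
  wp <- w[ref$truth$mirna_id == pick]
  sim <- simulate_libraries(ref, spec, setNames(8.38, pick), tempfile("sim"))
  row <- sim$truth_df[sim$truth_df$mirna_id == pick, ]
  ratio <- row$cond2_count / row$cond1_count
  expect_gt(row$cond1_count, 100)
  expect_lt(abs(ratio / (8.38 / (1 + wp * 7.38)) - 1), 0.25)
})

test_that("degenerate inserts violate their intended composition rule first", {
  set.seed(99)
  rules <- c("N", "polyA", "polyC", "polyG", "polyT",
             "dimer", "trimer", "tetramer")
  for (r in rules) {
    s <- savmir:::degenerate_insert(r)
    got <- filter_composition(s)
    expect_false(got$keep)
    expect_identical(got$reason, r)
  }
})
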