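test_that("match_le1 agrees with a brute-force Hamming oracle", {
  set.seed(101)
  for (i in 1:40) {
    subj <- rand_dna(300)
    tag <- if (i %% 2 == 0) rand_dna(sample(15:25, 1))
           else {
             # plant the tag (possibly mutated) so hits actually occur
             s <- sample(280, 1)
             t0 <- substr(subj, s, s + 19)
             if (i %% 3 == 0) {
               pos <- sample(20, 1)
               base <- setdiff(c("A", "C", "G", "T"), substr(t0, pos, pos))[1]
               substr(t0, pos, pos) <- base
             }
             t0
           }
    idx <- reference_index(c(r1 = subj), "precursor")
    got <- match_le1(tag, idx)
    exp <- oracle_hamming_scan(tag, subj, 1L)
    expect_identical(got$start, exp$start)
    expect_identical(got$mismatches, exp$mismatches)
  }
})

test_that("genome matching scans both strands with reverse-complement symmetry", {
  set.seed(102)
  g <- rand_dna(2000)
  tag <- substr(g, 500, 520)
  gidx <- reference_index(c(chr1 = g), "genome")
  plus <- match_le1(tag, gidx)
  expect_true(any(plus$strand == "+" & plus$start == 499))
  # hits of the reverse complement on - strand mirror + strand hits
  rc <- match_le1(revcomp(tag), gidx)
  expect_identical(plus[plus$strand == "+", c("start", "mismatches")],
                   rc[rc$strand == "-", c("start", "mismatches")])

  # two substitutions kill the only hit
  t2 <- tag
  substr(t2, 3, 3) <- if (substr(t2, 3, 3) == "A") "C" else "A"
  substr(t2, 10, 10) <- if (substr(t2, 10, 10) == "G") "T" else "G"
  idx1 <- reference_index(c(r = substr(g, 490, 530)), "precursor")
  expect_identical(nrow(match_le1(t2, idx1)), 0L)

  expect_error(match_le1("ACGTACGTACGT", gidx), ">= 15")
  expect_error(reference_index(character(), "genome"), "non-empty")
})

test_that("subtract_tags removes decoy-matching tags exhaustively and disjointly", {
  set.seed(103)
  decoy <- rand_dna(120)
  idx <- reference_index(c(tRNA_1 = decoy), "ncrna")
  inside <- substr(decoy, 20, 40)          # verbatim decoy substring
  near <- inside
  substr(near, 5, 5) <- if (substr(near, 5, 5) == "A") "G" else "A"
  free <- rand_dna(21)
  tags <- collapse_tags(list(L = c(inside, near, free)))
  r <- subtract_tags(tags, idx)
  expect_setequal(r$removed$seq, c(inside, near))
  expect_identical(r$kept$seq, free)
  expect_identical(nrow(r$kept) + nrow(r$removed), nrow(tags))
  expect_error(subtract_tags(tags, reference_index(c(g = decoy), "genome")),
               "ncrna or repeat")
})

test_that("classification follows the joint mapping rule", {
  set.seed(104)
  mat <- "TGAGGTAGTAGGTTGTATAGTT"
  pre <- as.character(embed_hairpin(mat, seed = 5))
  genome <- c(chr1 = paste0(rand_dna(200), pre, rand_dna(200)))
  gidx <- reference_index(genome, "genome")
  midx <- reference_index(c(`mir-known` = pre), "precursor")

  # in miRBase stand-in AND genome -> conserved
  expect_identical(classify_tag(mat, midx, gidx)$class, "conserved")

  # in miRBase only -> semi-conserved
  lone <- rand_dna(22)
  midx2 <- reference_index(c(`mir-lone` = lone), "mature")
  expect_identical(classify_tag(lone, midx2, gidx)$class, "semi-conserved")

  # genome only with a valid flanking hairpin -> novel
  mat2 <- "ACGGTTACGGATCCAGTCAAGT"
  pre2 <- as.character(embed_hairpin(mat2, seed = 6))
  genome2 <- c(chr1 = paste0(rand_dna(150), pre2, rand_dna(150)))
  gidx2 <- reference_index(genome2, "genome")
  expect_identical(classify_tag(mat2, midx2, gidx2)$class, "novel")

  # genome only, no hairpin context -> not novel
  bare <- substr(genome2[[1]], 30, 51)
  expect_identical(classify_tag(bare, midx2, gidx2)$class, "semi-conserved")

  # mapping nowhere -> unclassified
  expect_identical(classify_tag(rand_dna(22), midx2, gidx2)$class,
                   "unclassified")
})

test_that("novel detection works for matures on the 3p arm and - strand", {
  set.seed(105)
  mat <- "TTGACTGGATCCGTAACCGTAG"
  pre <- as.character(embed_hairpin(mat, seed = 9, arm = "3p"))
  genome <- c(chr1 = paste0(rand_dna(100), pre, rand_dna(100)))
  midx <- reference_index(c(x = rand_dna(60)), "mature")
  gidx <- reference_index(genome, "genome")
  expect_identical(classify_tag(mat, midx, gidx)$class, "novel")

  # same locus, read off the - strand
  genome_rc <- c(chr1 = revcomp(genome[[1]]))
  gidx_rc <- reference_index(genome_rc, "genome")
  expect_identical(classify_tag(mat, midx, gidx_rc)$class, "novel")
})

test_that("extract_seed slices positions 2-8", {
  expect_identical(extract_seed("TGAGGTAGTAGGTTGTATAGTT"), "GAGGTAG")
  expect_identical(extract_seed("ACGTACGT"), "CGTACGT")
  expect_error(extract_seed("ACGTACG"), "at least 8")
})

test_that("families group by identical seed with deterministic naming", {
  ann <- data.frame(
    id = c("mir-b", "mir-a", "mir-c"),
    family_seed = c("GAGGTAG", "GAGGTAG", "CCCTGAG"),
    stringsAsFactors = FALSE
  )
  fam <- assign_families(ann)
  expect_identical(nrow(fam), 2L)
  expect_identical(fam$family[fam$seed == "GAGGTAG"], "mir-a")
  expect_identical(fam$size[fam$seed == "GAGGTAG"], 2L)

  expect_identical(nrow(assign_families(ann[0, ])), 0L)

  set.seed(106)
  seeds <- replicate(12, rand_dna(7))
  ann2 <- data.frame(id = sprintf("m%02d", 1:24),
                     family_seed = rep(seeds, 2), stringsAsFactors = FALSE)
  expect_identical(nrow(assign_families(ann2)), length(unique(seeds)))
})

test_that("annotate_tags recovers planted classes on synthetic references", {
  ref <- make_reference(seed = 31, n_mirnas = 12, genome_length = 30000)
  tags <- collapse_tags(list(L = rep(unname(ref$matures), 2)))
  midx <- reference_index(
    c(ref$precursors[ref$mature_info$conserved],
      ref$matures[ref$mature_info$conserved]), "precursor")
  gidx <- reference_index(ref$genome, "genome")
  ann <- annotate_tags(tags, midx, gidx)
  got <- ann$class[match(ref$mature_info$seq, ann$seq)]
  expect_identical(got, ifelse(ref$mature_info$conserved, "conserved", "novel"))
  # family seed column matches positions 2-8
  expect_identical(ann$family_seed, substr(ann$seq, 2, 8))
})
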