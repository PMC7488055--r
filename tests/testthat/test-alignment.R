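test_that("FASTA parsing yields validated alignments and reports ragged rows", {
  p <- write_fasta_tmp(list(a = "ACGT", b = "ACGA"))
  a <- read_alignment(p, "fasta")
  expect_equal(length(a$taxa), 2L)
  expect_equal(n_sites(a), 4L)
  expect_equal(unname(a$mat[2, 4]), "A")

  ragged <- write_fasta_tmp(list(a = "ACGT", b = "ACGTA"))
  expect_error(read_alignment(ragged, "fasta"), "ragged")
  expect_error(dna_alignment(list(a = c("A", "C"), a = c("A", "C"))))
})

test_that("NEXUS sequential and interleaved data blocks parse", {
  nex <- tempfile(fileext = ".nex")
  writeLines(c(
    "#NEXUS", "BEGIN DATA;", "DIMENSIONS NTAX=2 NCHAR=8;",
    "FORMAT DATATYPE=DNA MISSING=? GAP=- INTERLEAVE=YES;", "MATRIX",
    "a ACGT", "b ACGA", "", "a TTTT", "b TTT-", ";", "END;"), nex)
  a <- read_alignment(nex, "nexus")
  expect_equal(n_sites(a), 8L)
  expect_equal(paste(a$mat["b", ], collapse = ""), "ACGATTT-")
})

test_that("relaxed PHYLIP round trips through write and read", {
  a <- toy_alignment(list(longtaxonname_one = "ACGTAC", t2 = "AC-TNC"))
  p <- tempfile(fileext = ".phy")
  write_alignment(a, p, "phylip-relaxed")
  b <- read_alignment(p, "phylip-relaxed")
  expect_equal(b$taxa, a$taxa)
  expect_equal(b$mat, a$mat, ignore_attr = TRUE)
})

test_that("concatenation is additive, pads missing taxa, and records a partition map", {
  a1 <- toy_alignment(list(x = "AC", y = "GT"), "l1")
  a2 <- toy_alignment(list(x = "AAA", y = "CCC"), "l2")
  cc <- concatenate_alignments(list(a1, a2))
  expect_equal(n_sites(cc), 5L)
  expect_equal(attr(cc, "partition")$end, c(2L, 5L))

  a3 <- toy_alignment(list(z = "GGG"), "l2b")
  cc2 <- concatenate_alignments(list(a1, a3))
  expect_equal(sort(cc2$taxa), c("x", "y", "z"))
  expect_equal(paste(cc2$mat["z", ], collapse = ""), "--GGG")
  expect_equal(paste(cc2$mat["x", 3:5], collapse = ""), "---")
  expect_error(concatenate_alignments(list()), "no alignments")
})

test_that("concatenation reproduces the four-locus study dimensions", {
  # per-locus widths 825 / 624 / 621 / 1962 over partially overlapping taxon
  # sets whose union has 63 terminals
  set.seed(1)
  taxa <- paste0("t", 1:63)
  widths <- c(825, 624, 621, 1962)
  present <- list(taxa[1:63], taxa[1:46], taxa[10:42], taxa[17:63])
  alns <- lapply(1:4, function(l) {
    m <- matrix(sample(c("A", "C", "G", "T"), length(present[[l]]) * widths[l],
                       replace = TRUE),
                nrow = length(present[[l]]),
                dimnames = list(present[[l]], NULL))
    dna_alignment(m, locus = paste0("locus", l))
  })
  cc <- concatenate_alignments(alns)
  expect_equal(n_sites(cc), 4032L)
  expect_equal(length(cc$taxa), 63L)
})

test_that("concatenated width is associative over random alignments", {
  set.seed(2)
  for (i in 1:10) {
    alns <- lapply(1:3, function(j) random_alignment(sample(2:6, 1), sample(1:30, 1)))
    cc <- concatenate_alignments(alns)
    expect_equal(n_sites(cc), sum(vapply(alns, n_sites, integer(1))))
  }
})

test_that("parsimony-informative counting follows the two-states-twice rule", {
  expect_equal(count_parsimony_informative(
    toy_alignment(list(a = "A", b = "A", c = "T", d = "T"))), 1L)
  expect_equal(count_parsimony_informative(
    toy_alignment(list(a = "A", b = "A", c = "A", d = "T"))), 0L)
  # columns (A,A,T,T), (A,A,A,T), (C,C,-,G): only the first is informative
  aln <- toy_alignment(list(a = "AAC", b = "AAC", c = "TA-", d = "TTG"))
  expect_equal(count_parsimony_informative(aln), 1L)
})

test_that("parsimony-informative counts match a brute-force per-column oracle", {
  set.seed(3)
  for (i in 1:20) {
    a <- random_alignment(sample(2:20, 1), sample(1:50, 1), gap_p = 0.2)
    expect_equal(count_parsimony_informative(a), pis_oracle(a))
  }
})

test_that("UPGMA clock trees match hand-computed distances", {
  a0 <- toy_alignment(list(a = "ACGT", b = "ACGT"))
  expect_equal(max(upgma_clock_tree(a0, "raw")$age), 0)

  s <- paste(rep("A", 100), collapse = "")
  s2 <- paste(c(rep("A", 97), "C", "C", "C"), collapse = "")
  a <- toy_alignment(list(a = s, b = s2))
  expect_equal(max(upgma_clock_tree(a, "raw")$age), 0.015)
  # JC69 at p = 0.03: d = -(3/4) log(1 - 4p/3), root age d/2
  d <- -0.75 * log(1 - 4 * 0.03 / 3)
  expect_equal(max(upgma_clock_tree(a, "jc69")$age), d / 2, tolerance = 1e-12)

  sat <- toy_alignment(list(a = paste(rep("A", 20), collapse = ""),
                            b = paste(rep("C", 20), collapse = "")))
  expect_error(upgma_clock_tree(sat, "jc69"), "0.75")
})

test_that("UPGMA output is always a valid ultrametric tree", {
  set.seed(4)
  for (i in 1:8) {
    st <- simulate_species_tree(4, tau_root = 0.2)
    gg <- simulate_gene_trees(st, rep(0.02, 7), n_per_species = 2)
    aln <- simulate_alignment(gg$gene_trees[[1]], 300)
    tr <- upgma_clock_tree(aln, "jc69")
    expect_silent(clock_tree(tr$phylo, tolerance = 1e-9))
  }
})

test_that("taxon-map and trait tables read, validate, and reject conflicts", {
  tm <- tempfile(); tt <- tempfile()
  writeLines(c("individual\tspecies", "i1\tspA", "i2\tspA", "i3\tspB"), tm)
  writeLines(c("individual\tmorphotype", "i1\tclusters", "i2\tlong chains",
               "i3\tNA"), tt)
  res <- read_mappings(tm, tt, trait_levels = list(
    morphotype = c("clusters", "short chains", "long chains")))
  expect_s3_class(res$taxon_map, "taxon_map")
  expect_equal(nrow(res$taxon_map), 3L)
  expect_equal(length(unique(res$taxon_map$species)), 2L)
  expect_true(is.na(res$traits["i3", "morphotype"]))
  expect_equal(as.character(res$traits["i2", "morphotype"]), "long chains")

  writeLines(c("individual\tspecies", "i1\tspA", "i1\tspB"), tm)
  expect_error(read_mappings(tm), "more than one species")

  writeLines(c("individual\tmorphotype", "i1\tfilaments"), tt)
  writeLines(c("individual\tspecies", "i1\tspA"), tm)
  expect_error(read_mappings(tm, tt, trait_levels = list(
    morphotype = c("clusters", "short chains", "long chains"))), "unknown level")
})
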