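test_that("IUPAC expansion enumerates all concrete oligos", {
  expect_equal(expand_iupac("ACGT"), "ACGT")
  expect_setequal(expand_iupac("RY"), c("AC", "AT", "GC", "GT"))
  expect_equal(primer_degeneracy("RY"), 4)
  expect_error(expand_iupac("ACXT"), "position 3")
  expect_error(expand_iupac(""), "non-empty")
})

test_that("degeneracy equals the per-position product, checked by expansion", {
  set.seed(11)
  for (i in 1:25) {
    p <- random_iupac(sample(3:12, 1))
    expect_equal(length(expand_iupac(p)), primer_degeneracy(p), info = p)
  }
})

test_that("mix degeneracy deduplicates the oligo union", {
  expect_equal(mix_degeneracy(list("ACGT")), 1)
  expect_equal(mix_degeneracy(list("AY", "AC")), 2)
  # nested members add nothing
  expect_equal(mix_degeneracy(list("NN", "AY")), 16)
  expect_error(mix_degeneracy(list()), "non-empty")
})

test_that("mismatch counting treats primer ambiguity as permissive", {
  expect_equal(count_mismatches("ACGT", "ACGT"), 0)
  expect_equal(count_mismatches("Y", "C"), 0)
  expect_equal(count_mismatches("Y", "G"), 1)
  expect_equal(count_mismatches("NNNN", "ACGT"), 0)
  expect_error(count_mismatches("ACG", "AC"), "equal length")
})

test_that("mismatch count is symmetric under joint reverse-complement", {
  set.seed(7)
  for (i in 1:50) {
    n <- sample(5:20, 1)
    p <- random_iupac(n)
    w <- random_dna(n)
    expect_equal(count_mismatches(p, w),
                 count_mismatches(reverse_complement(p), oracle_revcomp(w)))
  }
})

test_that("binding-site search matches the exhaustive all-window oracle", {
  set.seed(23)
  for (i in 1:100) {
    tlen <- sample(30:300, 1)
    plen <- sample(8:25, 1)
    tmpl <- template_seq("t", random_dna(tlen))
    orientation <- sample(c("forward", "reverse"), 1)
    # bias some primers toward the template so hits actually occur
    pseq <- if (i %% 3 == 0) {
      s <- sample(tlen - plen + 1, 1)
      core <- substr(tmpl$sequence, s, s + plen - 1)
      if (orientation == "reverse") core <- oracle_revcomp(core)
      core
    } else {
      random_iupac(plen)
    }
    max_mm <- sample(0:2, 1)
    prim <- degenerate_primer("p", pseq, orientation)
    got <- find_binding_sites(tmpl, prim, max_mm)
    want <- oracle_binding_sites(tmpl$sequence, pseq, orientation, max_mm)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$mismatches, want$mismatches)
  }
})

test_that("binding-site search agrees with Biostrings matchPattern", {
  set.seed(31)
  for (i in 1:10) {
    tmpl <- template_seq("t", random_dna(200))
    s <- sample(180, 1)
    pseq <- substr(tmpl$sequence, s, s + 17)
    prim <- degenerate_primer("p", pseq, "forward")
    for (k in 0:1) {
      got <- find_binding_sites(tmpl, prim, k)
      ref <- Biostrings::matchPattern(pseq, Biostrings::DNAString(tmpl$sequence),
                                      max.mismatch = k)
      expect_setequal(got$start, BiocGenerics::start(ref) - 1L)
    }
  }
})

test_that("raising the mismatch tolerance only adds hits", {
  set.seed(41)
  tmpl <- template_seq("t", random_dna(250))
  prim <- degenerate_primer("p", random_iupac(15), "forward")
  prev <- find_binding_sites(tmpl, prim, 0)
  for (k in 1:3) {
    cur <- find_binding_sites(tmpl, prim, k)
    expect_true(all(prev$start %in% cur$start))
    prev <- cur
  }
})

test_that("short templates yield empty hit lists, not errors", {
  tmpl <- template_seq("t", "ACGT")
  prim <- degenerate_primer("p", "ACGTACGTAC", "forward")
  expect_equal(nrow(find_binding_sites(tmpl, prim, 1)), 0)
})

test_that("amplification requires a convergent forward/reverse pair", {
  fwd <- degenerate_primer("f", "ACGTACGTAC", "forward")
  rev <- degenerate_primer("r", "GGGTTTCCCA", "reverse")
  ps <- primer_set("ps", list(fwd), list(rev))
  backbone <- paste(rep("A", 60), collapse = "")
  # forward site only
  t1 <- template_seq("t1", paste0("ACGTACGTAC", backbone))
  expect_false(is_amplifiable(t1, ps)$amplifiable)
  # convergent pair: forward site upstream of the reverse-complement site
  t2 <- template_seq("t2", paste0("ACGTACGTAC", backbone,
                                  oracle_revcomp("GGGTTTCCCA")))
  res <- is_amplifiable(t2, ps)
  expect_true(res$amplifiable)
  expect_equal(res$forward_mm, 0L)
  expect_equal(res$reverse_mm, 0L)
  expect_equal(res$amplicon_length, nchar(t2$sequence))
  # reversed order (divergent) is not amplifiable
  t3 <- template_seq("t3", paste0(oracle_revcomp("GGGTTTCCCA"), backbone,
                                  "ACGTACGTAC"))
  expect_false(is_amplifiable(t3, ps)$amplifiable)
})

test_that("amplifiability matrix equals element-wise is_amplifiable", {
  ref <- dsrb_reference()
  amat <- ref$amplifiability
  for (id in sample(names(ref$templates), 4)) {
    for (ps in ref$primer_sets) {
      expect_identical(unname(amat$matrix[id, ps$name]),
                       is_amplifiable(ref$templates[[id]], ps)$amplifiable)
    }
  }
})

test_that("panel classification reproduces the designed coverage structure", {
  ref <- dsrb_reference()
  amat <- ref$amplifiability
  expect_equal(unname(colSums(amat$matrix)[c(
    "DSRp2060F/DSR4R", "DSR1728Fmix/DSR4Rmix", "DSR1762Fmix/DSR2107Rmix")]),
    c(7, 8, 9))
  expect_equal(unname(table(amat$groups)[c("common", "less common", "rare")]),
               c(4L, 4L, 4L), ignore_attr = TRUE)
  # a template amplifiable by all sets is labelled common
  expect_equal(unname(amat$groups["gBlock4"]), "common")
  # the designed single-mismatch binders are classified as amplifiable
  tab <- amat$table
  g3 <- tab[tab$template_id == "gBlock3" &
              tab$set == "DSR1762Fmix/DSR2107Rmix", ]
  expect_true(g3$amplifiable)
  expect_equal(max(g3$forward_mm, g3$reverse_mm), 1L)
  # templates hit by no set are flagged
  lonely <- template_seq("x", random_dna(100))
  expect_warning(amplifiability_matrix(list(lonely),
                                       ref$primer_sets[1]), "no primer set")
})
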