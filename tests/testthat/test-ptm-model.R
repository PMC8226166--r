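test_that("annotation parsing handles the study peptides and caps", {
  s <- parse_annotation("ART[ph]K[me3]QTAR[me2]KSTG-NME")
  expect_length(s$residues, 12)
  expect_equal(s$n_cap, "free_amine")
  expect_equal(s$c_cap, "NMe")
  modified <- which(vapply(s$residues, function(r) r$ptm != "none", logical(1)))
  expect_equal(modified, c(3L, 4L, 8L))
  expect_equal(s$residues[[3]]$ptm, "ph")
  expect_equal(s$residues[[4]]$ptm, "me3")
  expect_equal(s$residues[[8]]$ptm, "me2")

  s2 <- parse_annotation("ACE-R[me2]T[ph]K[me3]QTAR[me2]K[me3]S[ph]TG-NME")
  expect_length(s2$residues, 11)
  expect_equal(s2$n_cap, "ACE")
  expect_equal(sum(vapply(s2$residues, function(r) r$ptm != "none",
                          logical(1))), 6)

  s3 <- parse_annotation("G")
  expect_length(s3$residues, 1)
  expect_equal(s3$n_cap, "free_amine")
  expect_equal(s3$c_cap, "free_acid")
})

test_that("malformed annotations raise distinct, position-naming errors", {
  expect_error(parse_annotation("A[ph]RT"), "not admissible.*position 1")
  expect_error(parse_annotation("AR[foo]T"), "unknown PTM tag.*position 2")
  expect_error(parse_annotation("ARB"), "unexpected character 'B'.*position 3")
  expect_error(parse_annotation("AR[me2"), "unterminated.*position 2")
  expect_error(parse_annotation(""), "empty sequence")
  expect_error(parse_annotation("ACE--NME"), "empty sequence")
  expect_error(parse_annotation("AK[ph]"), "not admissible.*position 2")
})

test_that("formal charges of the four study peptides are +5, +4, +3, 0", {
  ps <- builtin_peptides()
  expect_named(ps, c("P0M0_ala", "P0M0_ace", "P1M2", "P2M4"))
  expect_equal(vapply(ps, compute_formal_charge, integer(1)),
               c(P0M0_ala = 5L, P0M0_ace = 4L, P1M2 = 3L, P2M4 = 0L))
})

test_that("charge model covers caps, acidic residues and acetyl-lysine", {
  # capped polyglycine has no ionizable group at all
  expect_equal(compute_formal_charge(parse_annotation("ACE-GGGG-NME")), 0L)
  # free termini cancel
  expect_equal(compute_formal_charge(parse_annotation("GGGG")), 0L)
  expect_equal(compute_formal_charge(parse_annotation("ACE-DE-NME")), -2L)
  expect_equal(compute_formal_charge(parse_annotation("ACE-K[ac]-NME")), 0L)
  expect_equal(compute_formal_charge(parse_annotation("ACE-H-NME")), 0L)
  expect_equal(compute_formal_charge(parse_annotation("ACE-Y[ph]-NME")), -2L)
})

test_that("charge is additive over capped-neutral fragments", {
  set.seed(42)
  for (i in 1:20) {
    f1 <- random_peptide_spec()
    f2 <- random_peptide_spec()
    # re-cap both fragments neutrally, then concatenate
    cap <- function(s) peptide_spec(s$residues, n_cap = "ACE", c_cap = "NMe")
    joined <- peptide_spec(c(cap(f1)$residues, cap(f2)$residues),
                           n_cap = "ACE", c_cap = "NMe")
    expect_identical(compute_formal_charge(joined),
                     compute_formal_charge(cap(f1)) +
                       compute_formal_charge(cap(f2)))
  }
})

test_that("phosphorylation lowers charge by 2; methylation never changes it", {
  set.seed(7)
  for (i in 1:30) {
    s <- random_peptide_spec(10)
    bases <- vapply(s$residues, `[[`, character(1), "base")
    ptms <- vapply(s$residues, `[[`, character(1), "ptm")
    ref <- compute_formal_charge(s)
    target <- which(bases %in% c("S", "T", "Y") & ptms == "none")
    if (length(target)) {
      k <- target[1]
      res2 <- s$residues
      res2[[k]] <- list(base = bases[k], ptm = "ph")
      s2 <- peptide_spec(res2, n_cap = s$n_cap, c_cap = s$c_cap)
      expect_identical(compute_formal_charge(s2), ref - 2L)
    }
    target <- which(bases %in% c("K", "R") & ptms == "none")
    if (length(target)) {
      k <- target[1]
      res2 <- s$residues
      res2[[k]] <- list(base = bases[k], ptm = "me2")
      s2 <- peptide_spec(res2, n_cap = s$n_cap, c_cap = s$c_cap)
      expect_identical(compute_formal_charge(s2), ref)
    }
  }
})

test_that("annotations round-trip through format and parse", {
  ps <- builtin_peptides()
  for (p in ps) {
    expect_identical(format_annotation(parse_annotation(format_annotation(p))),
                     format_annotation(p))
  }
  set.seed(99)
  for (i in 1:40) {
    s <- random_peptide_spec()
    s2 <- parse_annotation(format_annotation(s))
    expect_identical(format_annotation(s2), format_annotation(s))
    expect_identical(lapply(s2$residues, `[`, c("base", "ptm")),
                     lapply(s$residues, `[`, c("base", "ptm")))
    expect_identical(s2$n_cap, s$n_cap)
    expect_identical(s2$c_cap, s$c_cap)
  }
})

test_that("the bundled peptide table matches the built-in definitions", {
  path <- system.file("extdata", "h3_peptides.tsv", package = "ptmdimer")
  expect_true(nzchar(path))
  tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  expect_equal(nrow(tab), 4)
  ps <- builtin_peptides()
  for (k in seq_len(nrow(tab))) {
    expect_identical(tab$annotation[k],
                     format_annotation(ps[[tab$label[k]]]))
    expect_identical(compute_formal_charge(parse_annotation(tab$annotation[k])),
                     tab$charge[k])
  }
})
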