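make_cands <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(sequence = r$seq, missed_cleavages = r$mc,
               length = nchar(r$seq), stringsAsFactors = FALSE)
  }))
  df$phospho <- lapply(rows, function(r) r$ph)
  df
}

ev_table <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(modified_sequence = r[[1]], count = as.integer(r[[2]]),
               routes = r[[3]], stringsAsFactors = FALSE)
  }))
}

test_that("observed missed-cleaved form rescues a too-short tryptic peptide", {
  cands <- make_cands(list(seq = "DSLQK", mc = 0, ph = 2L),
                      list(seq = "RDSLQKPGLEAPPR", mc = 2, ph = 3L))
  ev <- ev_table(list("RD(pS)LQKPGLEAPPR", 12, "IMAC"))
  sel <- select_peptide(cands, ev)
  expect_identical(sel$status, "selected")
  expect_identical(sel$sequence, "RDSLQKPGLEAPPR")
  expect_identical(sel$modified_sequence, "RD(pS)LQKPGLEAPPR")
})

test_that("length limits reject with the right reasons", {
  long45 <- strrep("AGSLT", 9)
  sel <- select_peptide(make_cands(list(seq = long45, mc = 0, ph = 3L)))
  expect_identical(sel$status, "rejected")
  expect_identical(sel$rejection_reason, "too_long")

  sel2 <- select_peptide(make_cands(list(seq = "DSLQK", mc = 0, ph = 2L)))
  expect_identical(sel2$rejection_reason, "too_short_no_rescue")
  expect_error(select_peptide(make_cands(list(seq = "DSLQK", mc = 0,
                                              ph = 2L))[0, ]), "empty")
})

test_that("highest observation count wins; ties prefer fewer missed cleavages then shorter", {
  cands <- make_cands(list(seq = "ADSVEGTLK", mc = 0, ph = 3L),
                      list(seq = "KADSVEGTLK", mc = 1, ph = 4L))
  ev <- ev_table(list("AD(pS)VEGTLK", 5, "IMAC"),
                 list("KAD(pS)VEGTLK", 9, "IMAC"))
  expect_identical(select_peptide(cands, ev)$sequence, "KADSVEGTLK")
  # equal counts: fully cleaved (fewer missed cleavages) wins
  ev_tie <- ev_table(list("AD(pS)VEGTLK", 9, "IMAC"),
                     list("KAD(pS)VEGTLK", 9, "IMAC"))
  expect_identical(select_peptide(cands, ev_tie)$sequence, "ADSVEGTLK")
})

test_that("unobserved nominated sites reject unless explicitly included", {
  cands <- make_cands(list(seq = "ADSVEGTLK", mc = 0, ph = 3L))
  sel <- select_peptide(cands, NULL, source = "nominated")
  expect_identical(sel$rejection_reason, "not_observed")
  sel2 <- select_peptide(cands, NULL, source = "nominated",
                         include_unobserved = TRUE)
  expect_identical(sel2$status, "selected")
  # discovery-derived sites carry their own observation by construction
  sel3 <- select_peptide(cands, NULL, source = "discovery")
  expect_identical(sel3$status, "selected")
})

test_that("doubly phosphorylated form needs a 3-fold excess to displace singly", {
  cands <- make_cands(list(seq = "FLTEYVATR", mc = 0, ph = 3L),
                      list(seq = "FLTEYVATR", mc = 0, ph = c(3L, 5L)))
  ev_a <- ev_table(list("FL(pT)EYVATR", 10, "IMAC"),
                   list("FL(pT)E(pY)VATR", 50, "IMAC"))
  expect_identical(lengths(select_peptide(cands, ev_a)$phospho), 2L)
  ev_b <- ev_table(list("FL(pT)EYVATR", 10, "IMAC"),
                   list("FL(pT)E(pY)VATR", 20, "IMAC"))
  expect_identical(lengths(select_peptide(cands, ev_b)$phospho), 1L)
})

test_that("selection is deterministic on identical inputs", {
  cands <- make_cands(list(seq = "ADSVEGTLK", mc = 0, ph = 3L),
                      list(seq = "KADSVEGTLK", mc = 1, ph = 4L))
  ev <- ev_table(list("AD(pS)VEGTLK", 9, "IMAC"),
                 list("KAD(pS)VEGTLK", 9, "IMAC"))
  expect_identical(select_peptide(cands, ev), select_peptide(cands, ev))
})

test_that("shared peptides report every containing gene; uniqueness matches brute force", {
  proteome <- data.frame(
    gene_symbol = c("MOB1A", "MOB1B", "OTHER"),
    sequence = c("AAAKETIQTWFKGGG", "CCCKETIQTWFKDDD", "WWWWLLLLK"),
    stringsAsFactors = FALSE)
  expect_setequal(annotate_uniqueness("ETIQTWFK", proteome),
                  c("MOB1A", "MOB1B"))
  expect_identical(annotate_uniqueness("WWWWLLLLK", proteome), "OTHER")
  # brute-force check over random peptides
  set.seed(3)
  prots <- data.frame(
    gene_symbol = sprintf("G%02d", 1:10),
    sequence = vapply(1:10, function(i)
      paste(sample(c("A", "G", "S", "T", "L", "K"), 40, replace = TRUE),
            collapse = ""), character(1)), stringsAsFactors = FALSE)
  for (rep in 1:20) {
    src <- sample(10, 1)
    at <- sample(1:35, 1)
    pep <- substr(prots$sequence[src], at, at + 5)
    brute <- prots$gene_symbol[vapply(prots$sequence, function(s)
      grepl(pep, s, fixed = TRUE), logical(1))]
    expect_setequal(annotate_uniqueness(pep, prots), brute)
  }
})

test_that("conservation check is an exact substring test", {
  mouse <- data.frame(gene_symbol = "m1", sequence = "AAADSVEGTLKAAA",
                      stringsAsFactors = FALSE)
  expect_true(check_conservation("ADSVEGTLK", mouse))
  expect_false(check_conservation("ADSVEGTLR", mouse))
})

test_that("enrichment routes follow phospho residue and prior evidence", {
  expect_identical(assign_route("AD(pS)VEGTLK", "IMAC"), "IMAC")
  expect_identical(assign_route("GD(pY)ENVGSR", c("IMAC", "pY")), "IMACpY")
  expect_identical(assign_route("GD(pY)ENVGSR", character(0)), "pY")
})

test_that("heavy label sits on the C-terminal K/R, with C-terminal-peptide fallbacks", {
  expect_identical(choose_heavy_label("ADSVEGTLK"),
                   list(position = 9L, residue = "K"))
  expect_identical(choose_heavy_label("KADSVEGTLG", is_protein_cterm = TRUE),
                   list(position = 1L, residue = "K"))
  expect_identical(choose_heavy_label("ADSVEGTLG", is_protein_cterm = TRUE),
                   list(position = 8L, residue = "L"))
  expect_error(choose_heavy_label("ADSVEGTMG", is_protein_cterm = TRUE),
               "no labelable")
})

test_that("every selected panel entry satisfies the length and phospho invariants", {
  syn <- make_proteome(simulation_design(seed = 42))
  panel <- design_panel(syn$proteome, syn$sites, syn$evidence)
  sel <- panel[panel$status == "selected", ]
  expect_gt(nrow(sel), 0)
  expect_true(all(sel$length >= 6 & sel$length <= 40))
  n_p <- lengths(strsplit(sel$phospho_offsets, ","))
  expect_true(all(n_p >= 1 & n_p <= 2))
  expect_true(all(sel$enrichment_route %in% c("IMAC", "pY", "IMACpY")))
})

test_that("QC bookkeeping reproduces the panel-development funnel", {
  qc <- panel_qc_summary(352, 24, 30)
  expect_identical(qc$n_surviving, 298)
  expect_identical(qc$success_rate_pct, 85)
  expect_identical(quantification_rate(74, 96)$rate_pct, 77)
  expect_identical(assay_unique_sites(140, 58, 28), 54)
  expect_error(panel_qc_summary(10, 8, 5), "exceed")
})
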