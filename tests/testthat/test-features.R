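# feature-table construction, filtering, subsetting and summaries

mini_seqs <- function(ids, anns, seqs) {
  data.frame(protein_id = ids, annotation = anns, sequence = seqs,
             length = nchar(seqs), flagged = grepl("X", seqs),
             stringsAsFactors = FALSE)
}

test_that("build_feature_table counts, normalizes by FASTA length, and
           handles missing partners", {
  seqs <- mini_seqs(c("P1", "P2", "P3"),
                    c("helix protein", "other", "no model"),
                    c(strrep("A", 10), strrep("K", 20), "ACD"))
  models <- list(P1 = make_ideal_helix(10, protein_id = "P1"),
                 P2 = make_ideal_helix(24, protein_id = "P2"))
  qm <- data.frame(protein_id = c("P1", "P2"), qmean = c(-1, -2))
  expect_warning(tab <- build_feature_table(seqs, models, qm),
                 "without a model")
  expect_equal(nrow(tab), 2)
  p1 <- tab[tab$protein_id == "P1", ]
  expect_equal(p1$n_hbonds, 6)                # helix oracle: n - 4
  expect_equal(p1$hbonds_per_aa, 0.6)         # denominator = FASTA length
  expect_equal(p1$aa_A, 10)
  expect_equal(sum(p1[paste0("aa_", strsplit("ACDEFGHIKLMNPQRSTVWY",
                                             "")[[1]])]), p1$length)
  # rate can exceed 1 when the model has more residues than the sequence
  p2 <- tab[tab$protein_id == "P2", ]
  expect_equal(p2$n_hbonds / 20, p2$hbonds_per_aa)

  expect_error(build_feature_table(mini_seqs("P9", "x", "AAA"), models, qm),
               "without a matching sequence")
  expect_error(build_feature_table(seqs, models,
                                   data.frame(protein_id = "P1",
                                              qmean = -1)),
               "QMEAN")
})

test_that("zero detected features keeps the record with rate 0", {
  seqs <- mini_seqs("P1", "flat", strrep("G", 8))
  flat <- structure_model(data.frame(
    name = c("N", "O"), resname = "GLY", chain = "A", resseq = c(1, 20),
    x = c(0, 50), y = 0, z = 0), protein_id = "P1")
  tab <- build_feature_table(seqs, list(P1 = flat),
                             c(P1 = 0))
  expect_equal(tab$n_hbonds, 0)
  expect_equal(tab$hbonds_per_aa, 0)
})

filter_fixture <- function() {
  hb <- c(1, 2, 3, 4, 5, 6)
  tab <- ft_from_rates(hb, label = "flt")
  tab$annotation <- c("Cytochrome C oxidase 1", "cytochrome  c oxidase 1",
                      "Cytochrome C oxidase 1", "Uncharacterized protein",
                      "malate dehydrogenase", "isocitrate dehydrogenase")
  tab$qmean <- c(-2, -1, -3, 0, -5.0, -5.1)
  tab
}

test_that("quality filters: QMEAN boundary, dedup by highest QMEAN,
           uncharacterized removal", {
  out <- apply_quality_filters(filter_fixture())
  # dedup keeps the -1 duplicate (case/whitespace-folded annotations match)
  expect_true("P0002" %in% out$protein_id)
  expect_false(any(c("P0001", "P0003") %in% out$protein_id))
  # QMEAN -5.0 kept, -5.1 dropped
  expect_true("P0005" %in% out$protein_id)
  expect_false("P0006" %in% out$protein_id)
  # uncharacterized dropped
  expect_false("P0004" %in% out$protein_id)
  expect_equal(nrow(out), 2)
  log <- attr(out, "filter_log")
  expect_equal(log$n[log$stage == "input"], 6)
  expect_equal(log$n[log$stage == "unique_annotation"], 4)
})

test_that("boundary QMEAN set {-4.9, -5.0, -5.1} leaves two survivors and
           filtering is idempotent", {
  tab <- ft_from_rates(c(1, 2, 3), label = "q")
  tab$qmean <- c(-4.9, -5.0, -5.1)
  out <- apply_quality_filters(tab)
  expect_equal(sort(out$qmean), c(-5.0, -4.9))
  again <- apply_quality_filters(out)
  expect_equal(strip_ft(again), strip_ft(out))
})

test_that("ortholog pairing by normalized annotation", {
  a <- ft_from_rates(c(1, 2, 3), ids = c("A1", "A2", "A3"), label = "a")
  a$annotation <- c("MDH", "IDH", "actin")
  b <- ft_from_rates(c(4, 5), ids = c("B1", "B2"), label = "b")
  b$annotation <- c("idh", "tubulin")
  pairs <- pair_orthologs(a, b)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$protein_id_a, "A2")
  expect_equal(pairs$protein_id_b, "B1")

  b2 <- ft_from_rates(c(1, 2), ids = c("B1", "B2"), label = "b")
  b2$annotation <- c("x", "y")
  expect_equal(nrow(pair_orthologs(a, b2)), 0)
  expect_equal(nrow(pair_orthologs(a, a)), nrow(a))
})

test_that("upper_fraction sizes use ceiling and deterministic tie-breaks", {
  # paper-scale arithmetic: 482 -> 121/241, 58 -> 15/29
  t482 <- ft_from_rates(seq_len(482) / 100, label = "g")
  t58 <- ft_from_rates(seq_len(58) / 100, label = "t")
  expect_equal(nrow(upper_fraction(t482, "hbonds_per_aa", 0.25)), 121)
  expect_equal(nrow(upper_fraction(t482, "hbonds_per_aa", 0.5)), 241)
  expect_equal(nrow(upper_fraction(t58, "hbonds_per_aa", 0.25)), 15)
  expect_equal(nrow(upper_fraction(t58, "hbonds_per_aa", 0.5)), 29)
  t4 <- ft_from_rates(c(1, 2, 3, 4), label = "s")
  expect_equal(nrow(upper_fraction(t4, "hbonds_per_aa", 0.5)), 2)
  # ties broken by ascending protein_id
  tie <- ft_from_rates(c(1, 1, 1), ids = c("Z", "A", "M"), label = "tie")
  expect_equal(upper_fraction(tie, "hbonds_per_aa", 1 / 3)$protein_id, "A")
  expect_error(upper_fraction(t4, "hbonds_per_aa", 0), "fraction")
  expect_error(upper_fraction(t4, "hbonds_per_aa", 1.5), "fraction")
})

test_that("upper_fraction properties: full table at 1.0, monotone nesting", {
  set.seed(9)
  tab <- ft_from_rates(runif(57), label = "p")
  expect_equal(sort(upper_fraction(tab, "hbonds_per_aa", 1)$protein_id),
               sort(tab$protein_id))
  q25 <- upper_fraction(tab, "hbonds_per_aa", 0.25)$protein_id
  q50 <- upper_fraction(tab, "hbonds_per_aa", 0.5)$protein_id
  expect_true(all(q25 %in% q50))
})

test_that("threshold percentages use strict comparison, 1-decimal percent", {
  t482 <- ft_from_rates(c(rep(5, 26), rep(1, 456)), label = "g")
  r <- threshold_percentages(t482, "hbonds_per_aa", 4.0)
  expect_equal(r$count, 26)
  expect_equal(r$percent, 5.4)
  t482b <- ft_from_rates(c(rep(5, 32), rep(1, 450)), label = "g")
  expect_equal(threshold_percentages(t482b, "hbonds_per_aa", 4)$percent,
               6.6)
  t58 <- ft_from_rates(c(rep(0.2, 2), rep(0.1, 56)), label = "t")
  expect_equal(threshold_percentages(t58, "saltbridges_per_aa",
                                     0.14)$count, 0)
  expect_equal(threshold_percentages(t58, "hbonds_per_aa", 0.14)$percent,
               3.4)
  # strictly greater: a value at the threshold does not count
  at <- ft_from_rates(c(4, 4, 5), label = "s")
  expect_equal(threshold_percentages(at, "hbonds_per_aa", 4)$count, 1)
  expect_equal(threshold_percentages(at, "hbonds_per_aa", 99)$percent, 0)
})

test_that("histograms use half-open bins and percents sum to 100", {
  tab <- ft_from_rates(c(0.1, 0.15, 0.3), label = "h")
  h <- feature_histogram(tab, "hbonds_per_aa", 0.2)
  expect_equal(h$count, c(2, 1))
  expect_equal(h$percent, c(66.7, 33.3))
  expect_equal(h$bin_low, c(0, 0.2))
  set.seed(4)
  tab2 <- ft_from_rates(runif(200, 0, 4), label = "h2")
  h2 <- feature_histogram(tab2, "hbonds_per_aa", 0.25)
  expect_equal(sum(h2$count), 200)
  expect_lt(abs(sum(h2$percent) - 100), 0.5)
  empty <- ft_from_rates(1, label = "e")[0, ]
  empty <- feature_table(as.data.frame(empty), "e")
  expect_equal(nrow(feature_histogram(empty, "hbonds_per_aa", 0.25)), 0)
})

test_that("overlap percentages", {
  a <- ft_from_rates(rep(1, 241), ids = sprintf("P%03d", 1:241))
  b <- ft_from_rates(rep(1, 241), ids = sprintf("P%03d", 42:282))
  ov <- overlap_stats(a, b)
  expect_equal(ov$n_overlap, 200)
  expect_equal(ov$percent_of_union, 71)     # 200 of 282
  expect_equal(overlap_stats(a, a)$percent_of_union, 100)
  c2 <- ft_from_rates(rep(1, 10), ids = sprintf("Q%03d", 1:10))
  expect_equal(overlap_stats(a, c2)$percent_of_union, 0)
})
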