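# Codon tables, back-translation, translation, and motif scanning.

tab <- default_codon_table()

test_that("the bundled codon table satisfies its invariants", {
  df <- tab$table
  expect_identical(sum(df$aa != "*"), 61L)
  sums <- tapply(df$rel_freq, df$aa, sum)
  expect_true(all(abs(sums - 1) < 1e-6))
  expect_true(all(df$rel_freq >= 0))
})

test_that("malformed codon tables are rejected", {
  df <- tab$table
  expect_error(codon_table(df[df$codon != "ATG", ]),
               class = "consenzyme_format_error")
  bad <- df; bad$rel_freq[bad$aa == "A"] <- bad$rel_freq[bad$aa == "A"] * 2
  expect_error(codon_table(bad), class = "consenzyme_format_error")
})

test_that("single-residue protein back-translates to start codon plus stop", {
  gene <- back_translate(protein_sequence("m", "M"), tab)
  expect_identical(nchar(gene$cds), 6L)
  expect_identical(substr(gene$cds, 1, 3), "ATG")
  expect_identical(translate_cds(gene$cds)$residues, "M")
})

test_that("a 502-residue protein yields a 1509-nt CDS including stop", {
  set.seed(3)
  p <- protein_sequence("p502", random_protein(502))
  gene <- back_translate(p, tab)
  expect_identical(nchar(gene$cds), 1509L)
  expect_identical(translate_cds(gene$cds)$residues, p$residues)
})

test_that("translation handles stops and bad input", {
  expect_identical(translate_cds("ATGTAA")$residues, "M")
  err <- tryCatch(translate_cds("ATGTGATAA"), condition = identity)
  expect_s3_class(err, "consenzyme_premature_stop_error")
  expect_match(conditionMessage(err), "codon index 2")
  expect_error(translate_cds("ATGTA"), class = "consenzyme_input_error")
  expect_error(translate_cds("ATGTAN"), class = "consenzyme_input_error")
  expect_error(back_translate(protein_sequence("x", "MXK"), tab),
               class = "consenzyme_input_error")
})

test_that("motif scanning reports both strands with forward coordinates", {
  hits <- scan_motifs("AAGGATCCTT", "GGATCC")
  # GGATCC is palindromic: one hit per strand at the same span
  expect_identical(nrow(hits), 2L)
  expect_setequal(hits$strand, c("+", "-"))
  expect_true(all(hits$start == 3L))
  expect_identical(nrow(scan_motifs("AAAAAA", "GGATCC")), 0L)
  # non-palindromic motif found on the reverse strand only
  h2 <- scan_motifs("TTTCCAGTT", "ACTGGA")  # revcomp(ACTGGA) = TCCAGT
  expect_identical(h2$strand, "-")
  expect_identical(h2$start, 3L)
})

test_that("forbidden motifs are avoided by synonymous swaps", {
  # G + S can combine as GGA|TCC = a BamHI site; force that pairing
  df <- tab$table
  df$rel_freq[df$aa == "G"] <- ifelse(df$codon[df$aa == "G"] == "GGA", 0.97,
                                      0.01)
  df$rel_freq[df$aa == "S"] <- ifelse(df$codon[df$aa == "S"] == "TCC", 0.95,
                                      0.01)
  forced <- codon_table(df)
  fg <- forced$table[forced$table$aa == "G", ]
  fs <- forced$table[forced$table$aa == "S", ]
  expect_identical(fg$codon[which.max(fg$rel_freq)], "GGA")
  expect_identical(fs$codon[which.max(fs$rel_freq)], "TCC")
  gene <- back_translate(protein_sequence("gs", "GS"), forced,
                         mode = "max-frequency")
  expect_identical(translate_cds(gene$cds)$residues, "GS")
  expect_identical(nrow(scan_motifs(gene$cds, c("GGATCC", "GAATTC"))), 0L)
})

test_that("round trip holds over random proteins in both modes", {
  set.seed(7)
  for (rep in 1:40) {
    p <- protein_sequence("p", random_protein(sample(1:120, 1)))
    for (mode in c("max-frequency", "weighted-sampled")) {
      gene <- back_translate(p, tab, mode = mode, seed = rep)
      expect_identical(translate_cds(gene$cds)$residues, p$residues)
      expect_identical(nrow(scan_motifs(gene$cds, gene$forbidden_motifs)),
                       0L)
    }
  }
})

test_that("weighted sampling is seed-reproducible and seed-sensitive", {
  p <- protein_sequence("p", random_protein(80))
  g1 <- back_translate(p, tab, mode = "weighted-sampled", seed = 5)
  g2 <- back_translate(p, tab, mode = "weighted-sampled", seed = 5)
  g3 <- back_translate(p, tab, mode = "weighted-sampled", seed = 6)
  expect_identical(g1$cds, g2$cds)
  expect_false(identical(g1$cds, g3$cds))
})

test_that("weighted-sampled codon proportions match table frequencies", {
  set.seed(9)
  p <- protein_sequence("p", paste0(rep("L", 3000), collapse = ""))
  gene <- back_translate(p, tab, mode = "weighted-sampled", seed = 12)
  codons <- substring(gene$cds, seq(1, nchar(gene$cds) - 3, 3),
                      seq(3, nchar(gene$cds) - 1, 3))
  obs <- table(codons) / length(codons)
  lt <- tab$table[tab$table$aa == "L", ]
  for (k in seq_len(nrow(lt))) {
    o <- if (lt$codon[k] %in% names(obs)) obs[[lt$codon[k]]] else 0
    se <- sqrt(lt$rel_freq[k] * (1 - lt$rel_freq[k]) / 3000)
    expect_lt(abs(o - lt$rel_freq[k]), 4 * se + 1e-9)
  }
})

test_that("requested flanks appear exactly once at the construct termini", {
  p <- protein_sequence("p", "MKTAYIAK")
  gene <- back_translate(p, tab,
                         flanks = c(five = "GGATCC", three = "GAATTC"))
  expect_true(startsWith(gene$construct, "GGATCC"))
  expect_true(endsWith(gene$construct, "GAATTC"))
  inner <- substr(gene$construct, 7, nchar(gene$construct) - 6)
  expect_identical(nrow(scan_motifs(inner, c("GGATCC", "GAATTC"))), 0L)
})
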