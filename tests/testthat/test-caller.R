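test_that("heterozygous read sets cluster into two supported alleles", {
  tg <- demo_target()
  rd <- simulate_amplicon_reads(diploid_amplicon_spec(
    tg, list(demo_edits()$del2, NULL), depth = 100, error_rate = 0, seed = 5))
  sc <- call_site(rd, tg)
  expect_equal(sc$status, "called")
  supports <- sort(vapply(sc$alleles, `[[`, integer(1), "support"))
  expect_equal(sum(supports), 100)
  expect_equal(supports, sort(as.integer(table(rd$allele))))
  expect_equal(sc$dosage, 1)  # frameshift / wildtype
})

test_that("homozygous wildtype reads give dosage 0 with two identical alleles", {
  tg <- demo_target()
  rd <- simulate_amplicon_reads(diploid_amplicon_spec(
    tg, list(NULL, NULL), depth = 100, error_rate = 0, seed = 6))
  sc <- call_site(rd, tg)
  expect_equal(sc$status, "called")
  expect_length(sc$alleles, 2)
  expect_equal(sc$alleles[[1]]$haplotype, sc$alleles[[2]]$haplotype)
  expect_equal(sc$dosage, 0)
})

test_that("three well-supported haplotypes are ambiguous; thin data is low support", {
  tg <- demo_target()
  ed <- demo_edits()
  h1 <- tg$reference
  h2 <- beatcall:::apply_variants(tg$reference, ed$del2)
  h3 <- beatcall:::apply_variants(tg$reference, ed$syn)
  reads <- data.frame(read_id = sprintf("r%d", 1:100),
                      sequence = c(rep(h1, 40), rep(h2, 35), rep(h3, 25)),
                      stringsAsFactors = FALSE)
  sc <- call_site(reads, tg)
  expect_equal(sc$status, "missing")
  expect_equal(sc$reason, "ambiguous")
  expect_true(is.na(sc$dosage))

  few <- data.frame(read_id = sprintf("r%d", 1:4),
                    sequence = rep(h1, 4), stringsAsFactors = FALSE)
  sc2 <- call_site(few, tg)
  expect_equal(sc2$status, "missing")
  expect_equal(sc2$reason, "low support")
})

test_that("variant calling respects the cut-site window boundary", {
  tg <- demo_target()
  cut1 <- tg$cut_site + 1  # 91
  flip_base <- function(pos) {
    b <- substr(tg$reference, pos, pos)
    data.frame(pos = pos, ref = b, alt = setdiff(c("A", "C", "G", "T"), b)[1])
  }
  mk_call <- function(v) {
    rd <- simulate_amplicon_reads(diploid_amplicon_spec(tg, list(v, NULL),
                                                        depth = 60, seed = 8))
    call_site(rd, tg)
  }
  at30 <- mk_call(flip_base(cut1 + 30))
  expect_equal(at30$status, "called")
  expect_equal(at30$dosage > 0, TRUE)
  n30 <- sum(vapply(at30$alleles, function(a) nrow(a$variants), integer(1)))
  expect_equal(n30, 1)

  at31 <- mk_call(flip_base(cut1 + 31))
  n31 <- sum(vapply(at31$alleles, function(a) nrow(a$variants), integer(1)))
  expect_equal(n31, 0)
  expect_equal(at31$dosage, 0)
})

test_that("blacklisted natural variants are excluded from calls", {
  base <- demo_target()
  snv <- demo_edits()$snv
  tg <- amplicon_target(base$name, base$reference, base$cut_site,
                        base$cds_frame_offset, base$strand,
                        blacklist = snv[, c("pos", "ref", "alt")])
  rd <- simulate_amplicon_reads(diploid_amplicon_spec(tg, list(snv, NULL),
                                                      depth = 60, seed = 9))
  sc <- call_site(rd, tg)
  expect_equal(sc$status, "called")
  expect_equal(sc$dosage, 0)
})

test_that("consequence annotation follows the genetic code and reading frame", {
  tg <- demo_target()
  ann <- function(v) annotate_consequence(
    list(pos = v$pos, ref = v$ref, alt = v$alt,
         kind = if (nchar(v$ref) > 1) "deletion" else
           if (nchar(v$alt) > 1) "insertion" else "snv"), tg)
  ed <- demo_edits()
  expect_equal(ann(ed$del2)[c("category", "impact", "weight")],
               list(category = "frameshift", impact = "HIGH", weight = 1))
  expect_equal(ann(ed$del3)[c("category", "impact", "weight")],
               list(category = "inframe_indel", impact = "MODERATE", weight = 0.66))
  expect_equal(ann(ed$syn)$category, "synonymous")
  expect_equal(ann(ed$syn)$weight, 0.33)
  expect_equal(ann(ed$mis)$category, "missense")
  expect_equal(ann(ed$mis)$weight, 0.66)

  # engineer a stop: codon 94-96 GAA -> TAA via SNV at 94
  stopv <- list(pos = 94, ref = "G", alt = "T", kind = "snv")
  expect_equal(annotate_consequence(stopv, tg)$category, "stop_gained")
  expect_equal(annotate_consequence(stopv, tg)$weight, 1)
})

test_that("no length-multiple-of-3 indel is ever a frameshift, and vice versa", {
  tg <- demo_target()
  for (len in 1:6) {
    del <- list(pos = 89, ref = substr(tg$reference, 89, 89 + len), alt = "C",
                kind = "deletion")
    cq <- annotate_consequence(del, tg)
    if (len %% 3 == 0) expect_equal(cq$category, "inframe_indel")
    else expect_equal(cq$category, "frameshift")
  }
})

test_that("minus-strand SNVs are annotated on the reverse complement", {
  base <- demo_target()
  tg <- amplicon_target("rc", base$reference, base$cut_site,
                        cds_frame_offset = 0L, strand = "-")
  # independent oracle: translate the affected codon of the revcomp directly
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(base$reference)))
  pos <- 96L
  b <- substr(base$reference, pos, pos)
  alt <- setdiff(c("A", "C", "G", "T"), b)[1]
  pos_rc <- nchar(rc) - pos + 1
  alt_rc <- chartr("ACGT", "TGCA", alt)
  cstart <- pos_rc - ((pos_rc - 1) %% 3)
  codon_ref <- substr(rc, cstart, cstart + 2)
  codon_alt <- codon_ref
  substr(codon_alt, pos_rc - cstart + 1, pos_rc - cstart + 1) <- alt_rc
  gc <- Biostrings::GENETIC_CODE
  expected <- if (gc[codon_alt] == gc[codon_ref]) "synonymous"
    else if (gc[codon_alt] == "*") "stop_gained" else "missense"
  got <- annotate_consequence(list(pos = pos, ref = b, alt = alt, kind = "snv"), tg)
  expect_equal(got$category, expected)
})

test_that("called variants reconstruct the simulated haplotypes exactly", {
  tg <- demo_target()
  ed <- demo_edits()
  combos <- list(list(ed$del2, NULL), list(ed$syn, ed$del3),
                 list(ed$ins2, ed$mis), list(NULL, NULL))
  for (av in combos) {
    rd <- simulate_amplicon_reads(diploid_amplicon_spec(tg, av, depth = 60,
                                                        seed = 12))
    sc <- call_site(rd, tg)
    expect_equal(sc$status, "called")
    truth <- sort(vapply(av, function(v)
      beatcall:::apply_variants(tg$reference, v), ""))
    called <- sort(vapply(sc$alleles, function(a)
      beatcall:::apply_variants(tg$reference, a$variants[, c("pos", "ref", "alt")]),
      ""))
    expect_equal(called, truth)
  }
})

test_that("dosage is bounded and monotone in variant impact", {
  tg <- demo_target()
  ed <- demo_edits()
  dosage_of <- function(a1, a2) {
    rd <- simulate_amplicon_reads(diploid_amplicon_spec(tg, list(a1, a2),
                                                        depth = 60, seed = 14))
    call_site(rd, tg)$dosage
  }
  d_syn <- dosage_of(ed$syn, NULL)      # LOW / wildtype
  d_mis <- dosage_of(ed$mis, NULL)      # MODERATE / wildtype
  d_fs <- dosage_of(ed$del2, NULL)      # HIGH / wildtype
  d_2fs <- dosage_of(ed$del2, ed$del2)  # HIGH / HIGH
  expect_equal(d_syn, 0.33)
  expect_equal(d_mis, 0.66)
  expect_equal(d_fs, 1)
  expect_equal(d_2fs, 2)
  expect_true(d_syn <= d_mis && d_mis <= d_fs && d_fs <= d_2fs)
  for (d in c(d_syn, d_mis, d_fs, d_2fs)) expect_true(d >= 0 && d <= 2)
})

test_that("diploid genotypes are recovered from noisy reads", {
  tg <- demo_target()
  ed <- demo_edits()
  pool <- list(NULL, ed$syn, ed$del2, ed$ins2, ed$snv)
  set.seed(99)
  ok <- 0
  n <- 40
  for (i in seq_len(n)) {
    a1 <- pool[[sample(5, 1)]]; a2 <- pool[[sample(5, 1)]]
    rd <- simulate_amplicon_reads(diploid_amplicon_spec(
      tg, list(a1, a2), depth = 50, error_rate = 0.01, seed = 2000 + i))
    sc <- call_site(rd, tg)
    truth <- sort(c(variant_key(a1), variant_key(a2)))
    if (identical(called_genotype(sc), truth)) ok <- ok + 1
  }
  expect_gte(ok, n - 1)
})
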