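test_that("zygosity thresholds follow the read-fraction rule exactly", {
  expect_equal(classify_zygosity(0.80), "homozygous")   # boundary inclusive
  expect_equal(classify_zygosity(0.25), "heterozygous") # boundary inclusive
  expect_equal(classify_zygosity(0.10), "not_called")
  expect_equal(classify_zygosity(0.7999), "heterozygous")
  expect_error(classify_zygosity(1.2), "\\[0, 1\\]")
  expect_error(classify_zygosity(-0.1), "\\[0, 1\\]")

  # the three classes partition [0, 1]
  fr <- seq(0, 1, by = 0.001)
  cls <- classify_zygosity(fr)
  expect_true(all(cls %in% c("homozygous", "heterozygous", "not_called")))
  expect_equal(sum(cls == "homozygous"), sum(fr >= 0.80))
  expect_equal(sum(cls == "heterozygous"), sum(fr >= 0.25 & fr < 0.80))
})

test_that("substitution classes and Ti/Tv follow the textbook definition", {
  expect_equal(classify_substitution("A", "G"), "transition")
  expect_equal(classify_substitution("C", "A"), "transversion")
  expect_equal(classify_substitution("T", "C"), "transition")
  expect_error(classify_substitution("A", "N"), "unambiguous")
  expect_error(classify_substitution("A", "A"), "differ")

  # 5 transitions, 4 transversions -> 1.25
  ref <- c("A", "G", "C", "T", "A", "A", "C", "G", "T")
  alt <- c("G", "A", "T", "C", "G", "C", "A", "T", "G")
  expect_equal(ti_tv_ratio(ref, alt), 1.25)

  # uniform random substitutions: 1 of 3 alternatives is a transition,
  # so Ti/Tv converges to 0.5; delta-method SE on the ratio
  set.seed(31)
  n <- 1e5
  ref <- sample(c("A", "C", "G", "T"), n, TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                character(1))
  se_ratio <- (1 / (1 - 1 / 3)^2) * sqrt((1 / 3) * (2 / 3) / n)
  expect_lt(abs(ti_tv_ratio(ref, alt) - 0.5), 3 * se_ratio)
})

test_that("InDel kind and length classes use the stated bins", {
  expect_equal(classify_indel("AT", "A"),
               list(kind = "deletion", length = 1L, length_class = "1 bp"))
  expect_equal(classify_indel("A", "ACGTC"),
               list(kind = "insertion", length = 4L, length_class = "2-9 bp"))
  expect_equal(classify_indel(strrep("A", 12), "A")$length_class, "10-99 bp")
  expect_error(classify_indel("AC", "GT"), "equal length")
  expect_error(classify_indel(paste0("A", strrep("C", 100)), "A"), "100 bp")
})

test_that("junction context detects homopolymers and tandem repeats", {
  # deletion of one A inside a run of four
  expect_equal(junction_context("GTCGATCGCC", "A", "AAAGGCTTAG"),
               "homopolymer")
  # deletion of AT inside an AT x3 tract
  expect_equal(junction_context("CGTAGCTGAT", "AT", "ATCGGCATCA"),
               "polynucleotide_repeat")
  # homopolymer takes precedence over a dinucleotide reading
  expect_equal(junction_context("CGTAGCTGAA", "AA", "AGCGGCATCA"),
               "homopolymer")
  # deletion of G inside ACTGCA: no qualifying run or repeat; confirmed by
  # an exhaustive scan over every unit length and phase below
  lf <- "TCACGTGACT"; rf <- "CATGACTGCA"
  expect_equal(junction_context(lf, "G", rf), "none")
  ctx <- paste0(lf, "G", rf)
  found <- FALSE
  for (k in 1:6) {
    for (s in 1:(nchar(ctx) - 2 * k + 1)) {
      unit <- substr(ctx, s, s + k - 1)
      cp <- 1
      while (substr(ctx, s + cp * k, s + (cp + 1) * k - 1) == unit) cp <- cp + 1
      t_hi <- s + cp * k - 1
      # does any run/repeat of >= 2 copies (>= 3 bases for k = 1) contain
      # the deleted base (position 11) and touch a flank?
      need <- if (k == 1) 3 else 2 * k
      if (cp * k >= need && s <= 11 && t_hi >= 11 && (s < 11 || t_hi > 11)) {
        found <- TRUE
      }
    }
  }
  expect_false(found)

  expect_error(junction_context("ACGT", "A", "ACGTACGTAC"), "flank window")
})

test_that("region classification uses the any-overlap rule", {
  genes <- list(gene_model("g1", "chr1", "+", 101, 160),
                gene_model("g2", "chr1", "-", 301, 360))
  expect_equal(region_class("chr1", 120, "A", "G", genes), "CDS")
  expect_equal(region_class("chr1", 200, "A", "G", genes), "non-coding")
  # anchored deletion spanning the CDS boundary
  expect_equal(region_class("chr1", 98, paste0("A", strrep("C", 6)), "A",
                            genes), "CDS")
  # anchored deletion entirely upstream
  expect_equal(region_class("chr1", 95, "ACC", "A", genes), "non-coding")
  expect_error(region_class("chr9", 10, "A", "G", genes), "unknown chromosome")
})

test_that("consequence calls match a full-translation oracle", {
  cfg <- generator_config(genome_length = 30000, n_genes = 12,
                          cds_codons_range = c(60, 120))
  gg <- gen_genome_and_genes(cfg, seed = 21)
  set.seed(22)
  checked <- 0
  for (rep in 1:120) {
    gene <- gg$genes[[sample(length(gg$genes), 1)]]
    glen <- gene$ends - gene$starts + 1
    kind <- sample(c("sbs", "del", "ins"), 1, prob = c(0.6, 0.25, 0.15))
    if (kind == "sbs") {
      pos <- sample(gene$starts:gene$ends, 1)
      ref <- substr(gg$genome[[1]], pos, pos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    } else if (kind == "del") {
      len <- sample(1:6, 1)
      pos <- sample(gene$starts:(gene$ends - len - 1), 1)
      ref <- substr(gg$genome[[1]], pos, pos + len)
      alt <- substr(ref, 1, 1)
    } else {
      len <- sample(1:6, 1)
      pos <- sample((gene$starts + 1):(gene$ends - 1), 1)
      ref <- substr(gg$genome[[1]], pos, pos)
      alt <- paste0(ref, paste(sample(c("A", "C", "G", "T"), len, TRUE),
                               collapse = ""))
    }
    got <- consequence("chr1", pos, ref, alt, gene, gg$genome)
    want <- oracle_consequence("chr1", pos, ref, alt, gene, gg$genome)
    expect_equal(got, want,
                 info = sprintf("%s %s>%s at %d in %s (%s strand)",
                                kind, ref, alt, pos, gene$gene_id,
                                gene$strand))
    checked <- checked + 1
  }
  expect_equal(checked, 120)

  # canonical examples
  genes <- list(gene_model("t1", "chr1", "+", 11, 22))
  genome <- c(chr1 = paste0("AAAAAAAAAA", "ATGGGACTTTAA", "AAAAAAAAAA"))
  expect_equal(consequence("chr1", 16, "A", "G", genes[[1]], genome),
               "silent")                       # GGA -> GGG, both Gly
  expect_equal(consequence("chr1", 14, "GGGA", "G", genes[[1]], genome),
               "in-frame_deletion")            # 3-bp deletion in frame
  expect_equal(consequence("chr1", 14, "GG", "G", genes[[1]], genome),
               "frameshift")                   # 1-bp deletion
  expect_error(consequence("chr1", 2, "A", "G", genes[[1]], genome),
               "does not overlap")
})

test_that("spectrum summaries are consistent and permutation-invariant", {
  v <- data.frame(chrom = "chr1", pos = seq(10, by = 200, length.out = 37),
                  ref = "A", alt = "G", stringsAsFactors = FALSE)
  # 29 deletions and 8 insertions: printed ratio 3.63
  v$ref[1:29] <- "AT"; v$alt[1:29] <- "A"
  v$ref[30:37] <- "A"; v$alt[30:37] <- "AC"
  s <- summarize_spectrum(v, genome_length = 1e6, n_individuals = 1)
  expect_equal(unname(s$indel_kind["deletion"]), 29)
  expect_equal(s$del_ins_ratio, 29 / 8)
  expect_equal(s$del_ins_ratio_printed, 3.63)

  # 6 SBSs on a 1 Mb genome, one individual -> 6e-6 per bp
  v2 <- data.frame(chrom = "chr1", pos = 1:6 * 100, ref = "A", alt = "G",
                   stringsAsFactors = FALSE)
  s2 <- summarize_spectrum(v2, genome_length = 1e6, n_individuals = 1)
  expect_equal(s2$sbs_freq_per_bp, 6e-6)

  # counts are conserved and invariant under record permutation
  cfg <- generator_config(genome_length = 60000, n_variants = 120)
  gg <- gen_genome_and_genes(cfg, seed = 5)
  vt <- gen_variant_table(cfg, gg$genome, seed = 6)
  s3 <- summarize_spectrum(vt$variants, 60000, 1, genes = gg$genes,
                           genome = gg$genome)
  expect_equal(sum(s3$type), s3$n_records)
  expect_equal(sum(s3$zygosity), s3$n_records)
  expect_equal(sum(s3$region), s3$n_records)
  expect_equal(sum(s3$substitution) + sum(s3$indel_kind), s3$n_records)
  set.seed(8)
  perm <- sample(nrow(vt$variants))
  s4 <- summarize_spectrum(vt$variants[perm, ], 60000, 1, genes = gg$genes,
                           genome = gg$genome)
  expect_equal(s4$type, s3$type)
  expect_equal(s4$zygosity, s3$zygosity)
  expect_equal(s4$indel_length_class, s3$indel_length_class)
  expect_equal(s4$junction_context, s3$junction_context)

  expect_error(summarize_spectrum(v2, 0, 1), "genome length")
  expect_error(summarize_spectrum(v2[0, ], 1e6, 1), "empty")
})
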