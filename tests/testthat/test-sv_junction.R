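test_that("a clean inversion with no shared sequence is class A / cNHEJ", {
  ref <- make_mh_reference("", flank = 60, mid_len = 90, seed = 3)
  prod <- build_inversion_product(ref$R, ref$b1, ref$b2)
  rep <- analyze_junction(junction_case(ref$R, prod, ref$b1, ref$b2,
                                        id = "clean"))
  expect_equal(rep$mh_length, 0L)
  expect_equal(rep$del_on_overlap, 0L)
  expect_equal(rep$del_adjacent_left, 0L)
  expect_equal(rep$del_adjacent_right, 0L)
  expect_equal(rep$insertion_len, 0L)
  expect_equal(rep$archetype, "A")
  expect_equal(rep$mechanism, "cNHEJ")
})

test_that("an engineered CATG tract is reported as 4 bp microhomology", {
  # CATG present at the segment start and (reverse-complemented) at the
  # segment end: every breakpoint shift produces the identical product
  ref <- make_mh_reference("CATG", flank = 60, mid_len = 90, seed = 5)
  prod <- build_inversion_product(ref$R, ref$b1, ref$b2)
  # shifting both breakpoints across the tract leaves the product unchanged
  for (k in 0:4) {
    shifted <- build_inversion_product(ref$R, ref$b1 + k, ref$b2 - k)
    expect_identical(shifted, prod)
  }
  rep <- analyze_junction(junction_case(ref$R, prod, ref$b1, ref$b2,
                                        id = "catg"))
  expect_equal(rep$mh_length, 4L)
  expect_equal(rep$mh_seq, "CATG")
  expect_equal(rep$del_on_overlap, 0L)
  expect_equal(rep$archetype, "B")
  expect_equal(rep$mechanism, "cNHEJ-MH")
})

test_that("junction deletions are measured and classified", {
  # 2 bp trimmed from the overlap: microhomology sequence shortened,
  # deletion on overlap = 2 -> class C; joining still used the tract, so
  # the mechanism stays microhomology-guided cNHEJ
  cs <- make_processed_case("GCATGC", trim_seg_top = 2, seed = 9)
  rep <- analyze_junction(junction_case(cs$R, cs$product, cs$b1, cs$b2))
  expect_equal(rep$mh_length, 6L)
  expect_equal(rep$del_on_overlap, 2L)
  expect_equal(rep$mh_retained, 4L)
  expect_equal(nchar(rep$mh_seq), 4L)
  expect_equal(rep$archetype, "C")
  expect_equal(rep$mechanism, "cNHEJ-MH")

  # 25 bp resected beyond the tract -> class D, the MMEJ signature
  cs2 <- make_processed_case("GCATGC", trim_prefix = 25, seed = 10)
  rep2 <- analyze_junction(junction_case(cs2$R, cs2$product, cs2$b1, cs2$b2))
  expect_equal(rep2$mh_length, 6L)
  expect_equal(rep2$del_adjacent_left, 25L)
  expect_equal(rep2$archetype, "D")
  expect_equal(rep2$mechanism, "MMEJ-candidate")

  # adjacent deletions across the reported range are recovered exactly
  for (d in c(1L, 11L, 38L, 61L)) {
    cs3 <- make_processed_case("GCATGC", trim_suffix = d, seed = 20 + d)
    r <- analyze_junction(junction_case(cs3$R, cs3$product, cs3$b1, cs3$b2))
    expect_equal(r$del_adjacent_right, d)
    expect_equal(r$mh_length, 6L)
  }
})

test_that("planted microhomology lengths 2-23 bp round-trip exactly", {
  set.seed(17)
  for (L in 2:23) {
    M <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
    ref <- make_mh_reference(M, flank = 60, mid_len = 80,
                             seed = 1000 + L)
    prod <- build_inversion_product(ref$R, ref$b1, ref$b2)
    rep <- analyze_junction(junction_case(ref$R, prod, ref$b1, ref$b2))
    expect_equal(rep$mh_length, ref$L)
    expect_equal(rep$del_on_overlap, 0L)
    expect_equal(rep$del_adjacent_left + rep$del_adjacent_right, 0L)
  }
})

test_that("untemplated junction insertions are recovered", {
  cs <- make_processed_case("TTAGCC", trim_seg_top = 3, ins_left = "GGATC",
                            seed = 13)
  rep <- analyze_junction(junction_case(cs$R, cs$product, cs$b1, cs$b2))
  expect_equal(rep$insertion_len, 5L)
  expect_equal(rep$insertion_seq, "GGATC")
  expect_equal(rep$insertion_site, "on_overlap")
  expect_equal(rep$del_on_overlap, 3L)
})

test_that("reports are invariant to the declared genomic offset", {
  cs <- make_processed_case("ACGTT", trim_seg_bottom = 2, seed = 23)
  r0 <- analyze_junction(junction_case(cs$R, cs$product, cs$b1, cs$b2,
                                       offset = 0))
  r1 <- analyze_junction(junction_case(cs$R, cs$product, cs$b1, cs$b2,
                                       offset = 123456))
  expect_equal(r1$b1 - r0$b1, 123456L)
  expect_equal(r1$b2 - r0$b2, 123456L)
  for (f in c("mh_length", "mh_seq", "del_on_overlap", "del_adjacent_left",
              "del_adjacent_right", "insertion_len", "archetype",
              "mechanism")) {
    expect_equal(r1[[f]], r0[[f]])
  }
})

test_that("reverse-complementing reference and product mirrors the report", {
  cs <- make_processed_case("GGTACA", trim_prefix = 15, seed = 29)
  r_fwd <- analyze_junction(junction_case(cs$R, cs$product, cs$b1, cs$b2))
  n <- nchar(cs$R)
  r_rev <- analyze_junction(junction_case(revcomp(cs$R), revcomp(cs$product),
                                          n - cs$b2 + 1, n - cs$b1 + 1))
  expect_equal(r_rev$mh_length, r_fwd$mh_length)
  expect_equal(r_rev$del_on_overlap, r_fwd$del_on_overlap)
  expect_equal(r_rev$del_adjacent_left, r_fwd$del_adjacent_right)
  expect_equal(r_rev$del_adjacent_right, r_fwd$del_adjacent_left)
  expect_equal(r_rev$archetype, r_fwd$archetype)
  expect_equal(r_rev$mechanism, r_fwd$mechanism)
})

test_that("inconsistent or ambiguous products are rejected with diagnostics", {
  ref <- make_mh_reference("CATG", flank = 60, mid_len = 90, seed = 31)
  prod <- build_inversion_product(ref$R, ref$b1, ref$b2)
  # unrelated product: anchors cannot be found
  set.seed(1)
  noise <- paste(sample(c("A", "C", "G", "T"), nchar(prod), TRUE),
                 collapse = "")
  expect_error(analyze_junction(junction_case(ref$R, noise, ref$b1, ref$b2)),
               "inconsistent")
  # un-rearranged product: no inverted block between the anchors
  expect_error(analyze_junction(junction_case(ref$R, ref$R, ref$b1, ref$b2)),
               "inconsistent")
  expect_error(junction_case(ref$R, prod, ref$b2, ref$b1), "ordered")
  expect_error(junction_case(ref$R, prod, 5, ref$b2), "30 bp")
})

test_that("deletion-type junctions are analyzed with the same machinery", {
  flank <- 80
  M <- "TGCAT"
  # tract M at the start of the deleted segment and again right after it;
  # flanks re-drawn until no chance match blurs any junction boundary
  for (s in 1:100) {
    set.seed(40 + s)
    A <- paste(sample(c("A", "C", "G", "T"), flank, TRUE), collapse = "")
    mid <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
    B <- paste(sample(c("A", "C", "G", "T"), flank, TRUE), collapse = "")
    ok <- substr(mid, 1, 1) != substr(B, 1, 1) &&          # tract maximal fwd
      substr(A, flank, flank) != substr(mid, 100, 100) &&  # tract maximal bwd
      substr(A, flank, flank) != substr(M, 2, 2) &&        # trim-2 lcs stop
      substr(A, flank - 30, flank - 30) != substr(mid, 100, 100) &&
      substr(A, flank - 29, flank - 29) != substr(M, 1, 1) # trim-30 lcp stop
    if (ok) break
  }
  R <- paste0(A, M, mid, M, B)
  b1 <- flank + 1L
  b2 <- flank + nchar(M) + 100L
  prod <- build_deletion_product(R, b1, b2)
  rep <- analyze_junction(junction_case(R, prod, b1, b2, type = "deletion"))
  expect_equal(rep$mh_length, 5L)
  expect_equal(rep$del_on_overlap, 0L)
  expect_equal(rep$archetype, "B")

  # eating 2 bp into the retained copy
  prod2 <- build_deletion_product(R, b1, b2, trim_suffix = 2)
  rep2 <- analyze_junction(junction_case(R, prod2, b1, b2,
                                         type = "deletion"))
  expect_equal(rep2$mh_length, 5L)
  expect_equal(rep2$del_on_overlap, 2L)
  expect_equal(rep2$archetype, "C")

  # resection far beyond the tract
  prod3 <- build_deletion_product(R, b1, b2, trim_prefix = 30)
  rep3 <- analyze_junction(junction_case(R, prod3, b1, b2,
                                         type = "deletion"))
  expect_equal(rep3$del_adjacent_left, 30L)
  expect_equal(rep3$mechanism, "MMEJ-candidate")
})

test_that("archetype classification and mechanism rules cover the archetypes", {
  mk <- function(mh, don, dal, dar, ins = 0L) {
    list(mh_length = mh, del_on_overlap = don, del_adjacent_left = dal,
         del_adjacent_right = dar, insertion_len = ins)
  }
  expect_equal(classify_junction_archetype(mk(0L, 0L, 0L, 0L)), "A")
  expect_equal(classify_junction_archetype(mk(5L, 1L, 0L, 0L)), "C")
  expect_equal(classify_junction_archetype(mk(3L, 0L, 0L, 61L)), "D")
  expect_equal(classify_junction_archetype(mk(4L, 0L, 0L, 0L)), "B")
  expect_equal(classify_junction_archetype(mk(4L, 0L, 10L, 0L)), "C")  # boundary: <= 10

  expect_equal(infer_mechanism(mk(4L, 0L, 0L, 0L)), "cNHEJ-MH")
  expect_equal(infer_mechanism(mk(3L, 0L, 0L, 61L)), "MMEJ-candidate")
  expect_equal(infer_mechanism(mk(0L, 0L, 0L, 0L)), "cNHEJ")
  expect_equal(infer_mechanism(mk(5L, 2L, 3L, 0L)), "cNHEJ")
  # deletions confined to the tract itself still imply joining via the
  # microhomology (no resection beyond it)
  expect_equal(infer_mechanism(mk(5L, 2L, 0L, 0L)), "cNHEJ-MH")
})

test_that("junction tabulation matches hand counts and printed shapes", {
  cfg <- generator_config()
  jc <- gen_junction_cases(cfg, n = 11, seed = 53,
                           classes = c("A", rep("B", 4), rep("C", 4),
                                       rep("D", 2)))
  reps <- lapply(jc$cases, analyze_junction)
  tab <- tabulate_junctions(reps, group = rep("G1", 11))
  expect_equal(tab$n_total, 11)
  expect_equal(tab$overlap, 10)
  expect_equal(tab$overlap_pct, 91)          # 10/11 -> 91%
  expect_equal(tab$del_on_overlap, sum(jc$truth$del_on_overlap > 0))

  # 8 of 9 with overlap formats as "8 (89%)"; 2 of 2 as "2 (100%)"
  mk <- function(mh) list(id = "x", type = "inversion", mh_length = mh,
                          mh_seq = "", mh_retained = mh,
                          del_on_overlap = 0L, del_adjacent_left = 0L,
                          del_adjacent_right = 0L, insertion_len = 0L,
                          insertion_site = "none", b1 = 1L, b2 = 2L,
                          archetype = if (mh >= 2) "B" else "A",
                          mechanism = "cNHEJ")
  nine <- lapply(c(rep(4L, 8), 0L), mk)
  two <- lapply(rep(3L, 2), mk)
  t2 <- tabulate_junctions(c(nine, two),
                           group = c(rep("P787", 9), rep("P493", 2)))
  expect_equal(t2$overlap_label[t2$group == "P787"], "8 (89%)")
  expect_equal(t2$overlap_label[t2$group == "P493"], "2 (100%)")
  expect_equal(t2$del_on_overlap_label, c("0", "0"))

  expect_error(tabulate_junctions(two, group = "P493"),
               "one group per report")
})
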