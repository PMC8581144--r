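# shared builders and independent oracles

# deterministic reference with a planted inverted-repeat tract M:
#   A | M | mid | revcomp(M) | B,  b1 = |A|+1, b2 = |A|+L+|mid|+L
make_mh_reference <- function(M, flank = 60, mid_len = 80, seed = 11) {
  set.seed(seed)
  repeat {
    A <- paste(sample(c("A", "C", "G", "T"), flank, TRUE), collapse = "")
    B <- paste(sample(c("A", "C", "G", "T"), flank, TRUE), collapse = "")
    mid <- paste(sample(c("A", "C", "G", "T"), mid_len, TRUE), collapse = "")
    L <- nchar(M)
    R <- paste0(A, M, mid, if (L > 0) revcomp(M) else "", B)
    b1 <- flank + 1L
    b2 <- flank + L + mid_len + L
    # reject chance tract extensions so the planted tract is maximal
    comp1 <- chartr("ACGT", "TGCA", substr(R, b2 + 1, b2 + 1))
    comp2 <- chartr("ACGT", "TGCA", substr(R, b2 - L, b2 - L))
    ok <- substr(R, b1 - 1, b1 - 1) != comp1 &&
      (L == 0 || substr(R, b1 + L, b1 + L) != comp2)
    if (ok) return(list(R = R, b1 = b1, b2 = b2, L = L))
  }
}

# reference plus processed inversion product, re-drawn until the flanks are
# free of chance matches at every junction boundary (same screening contract
# as the package generator), so planted quantities are exactly recoverable
make_processed_case <- function(M, trim_prefix = 0, trim_seg_top = 0,
                                trim_seg_bottom = 0, trim_suffix = 0,
                                ins_left = "", ins_right = "",
                                flank = 100, mid_len = 90, seed = 1) {
  plan <- list(L = nchar(M), t_pre = trim_prefix, t_top = trim_seg_top,
               t_bot = trim_seg_bottom, t_suf = trim_suffix,
               ins_left = ins_left, ins_right = ins_right)
  for (k in 0:200) {
    ref <- make_mh_reference(M, flank = flank, mid_len = mid_len,
                             seed = seed + 1000 * k)
    prod <- build_inversion_product(ref$R, ref$b1, ref$b2,
                                    trim_prefix = trim_prefix,
                                    trim_seg_top = trim_seg_top,
                                    trim_seg_bottom = trim_seg_bottom,
                                    trim_suffix = trim_suffix,
                                    ins_left = ins_left,
                                    ins_right = ins_right)
    if (radmut:::junction_case_screens(ref$R, prod, plan, ref$b1, ref$b2)) {
      return(list(R = ref$R, product = prod, b1 = ref$b1, b2 = ref$b2,
                  L = ref$L))
    }
  }
  stop("could not build a screened junction case")
}

# translation-based consequence oracle: applies the edit to the CDS string
# and classifies by comparing the translated proteins (valid for variants
# wholly inside a single CDS interval)
oracle_consequence <- function(chrom, pos, ref, alt, gene, genome) {
  g <- if (inherits(genome, "DNAStringSet")) as.character(genome) else genome
  seq <- g[[gene$chrom]]
  cds_old <- substr(seq, gene$starts[1], gene$ends[1])
  rel <- pos - gene$starts[1] + 1L
  cds_new <- paste0(substr(cds_old, 1, rel - 1), alt,
                    substr(cds_old, rel + nchar(ref), nchar(cds_old)))
  if (gene$strand == "-") {
    cds_old <- radmut::revcomp(cds_old)
    cds_new <- radmut::revcomp(cds_new)
  }
  if (nchar(cds_new) %% 3 != 0) return("frameshift")
  tr <- function(s) {
    as.character(Biostrings::translate(Biostrings::DNAString(s)))
  }
  p_old <- tr(cds_old); p_new <- tr(cds_new)
  if (p_old == p_new) return("silent")
  if (nchar(cds_new) < nchar(cds_old)) return("in-frame_deletion")
  if (nchar(cds_new) > nchar(cds_old)) return("in-frame_insertion")
  if (substr(p_new, 1, 1) != "M") return("start_loss")
  diff_at <- which(strsplit(p_old, "")[[1]] != strsplit(p_new, "")[[1]])[1]
  if (substr(p_new, diff_at, diff_at) == "*") return("premature_stop")
  "missense"
}
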