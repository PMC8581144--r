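# Reconstruction and classification of structural-variant junctions.
#
# An inversion of reference segment [b1, b2] yields
#   product = R[1..b1-1] | revcomp(R[b1..b2]) | R[b2+1..n].
# When a tract M of length L satisfies R[b1..b1+L-1] == revcomp(R[b2-L+1..b2])
# (the same short sequence sits at both breakpoints, one copy in reverse
# orientation), every breakpoint shift (b1+k, b2-k), k = 0..L, produces the
# *identical* product: the junctions are ambiguous over L bases. That L is
# the event's microhomology. End-processing before ligation can delete bases
# of the tract ("on overlap") or beyond it ("adjacent") and insert
# untemplated bases.
#
# The analyzer aligns product to reference by maximal exact extension from
# the outer anchors plus a seeded match of the inverted (or joined) middle
# block, then finds the breakpoint pair carrying a microhomologous tract
# consistent with the observed block bounds (nearest the nominal
# breakpoints when deletions leave the placement underdetermined), and
# reads off the deletion/insertion anatomy.

#' Construct a structural-variant junction case
#'
#' Bundles the reference segment, the rearranged product (the amplicon
#' analog a validation PCR would recover), and the approximate breakpoints.
#'
#' @param reference Reference DNA sequence (character).
#' @param product Rearranged product sequence.
#' @param bp1,bp2 Nominal 1-based breakpoints within the reference
#'   (ordered, at least 30 bp from either end).
#' @param type Rearrangement hypothesis: `"inversion"` or `"deletion"`.
#'   Duplication and translocation junctions are handled with the same
#'   two-anchor machinery by supplying each junction as a `"deletion"`-type
#'   case whose reference is the concatenation of the donor and acceptor
#'   flanks.
#' @param id Case identifier.
#' @param offset Genomic offset of the reference segment (added to reported
#'   breakpoints; coordinates only, no effect on classification).
#' @return An object of class `junction_case`.
#' @export
junction_case <- function(reference, product, bp1, bp2,
                          type = c("inversion", "deletion"),
                          id = "case", offset = 0L) {
  type <- match.arg(type)
  reference <- toupper(reference); product <- toupper(product)
  n <- nchar(reference)
  if (!(bp1 < bp2)) stop("breakpoints must be ordered: bp1 < bp2", call. = FALSE)
  if (bp1 < 31L || bp2 > n - 30L) {
    stop("breakpoints must lie >= 30 bp from the reference segment ends",
         call. = FALSE)
  }
  structure(list(reference = reference, product = product,
                 bp1 = as.integer(bp1), bp2 = as.integer(bp2),
                 type = type, id = id, offset = as.integer(offset)),
            class = "junction_case")
}

#' Forward model of an inversion product
#'
#' Builds `prefix | revcomp(segment) | suffix` with optional end-processing:
#' trimming at the four new junction edges and untemplated insertions at
#' either junction. With a microhomologous tract planted at the breakpoints,
#' `trim_seg_top` removes tract bases seen at the left junction and
#' `trim_seg_bottom` tract bases seen at the right junction (the inversion
#' flips the segment, so its high end surfaces at the left junction).
#'
#' @param reference Reference DNA sequence.
#' @param bp1,bp2 Breakpoints; the inverted segment is
#'   `reference[bp1..bp2]` inclusive.
#' @param trim_prefix Bases removed from the end of the prefix
#'   (adjacent deletion, left junction).
#' @param trim_seg_top Bases removed from the segment's high (`bp2`) end
#'   (surfaces as on-overlap deletion at the left junction).
#' @param trim_seg_bottom Bases removed from the segment's low (`bp1`) end
#'   (on-overlap deletion at the right junction).
#' @param trim_suffix Bases removed from the start of the suffix
#'   (adjacent deletion, right junction).
#' @param ins_left,ins_right Untemplated sequence inserted at each junction.
#' @return The product sequence (character). Deterministic.
#' @export
build_inversion_product <- function(reference, bp1, bp2,
                                    trim_prefix = 0, trim_seg_top = 0,
                                    trim_seg_bottom = 0, trim_suffix = 0,
                                    ins_left = "", ins_right = "") {
  reference <- toupper(reference)
  n <- nchar(reference)
  stopifnot(bp1 >= 1, bp2 <= n, bp1 < bp2)
  trims <- c(trim_prefix, trim_seg_top, trim_seg_bottom, trim_suffix)
  if (any(trims < 0)) stop("trims must be non-negative", call. = FALSE)
  if (trim_prefix >= bp1) {
    stop("trim_prefix exceeds the available prefix", call. = FALSE)
  }
  if (trim_suffix > n - bp2) {
    stop("trim_suffix exceeds the available suffix", call. = FALSE)
  }
  if (trim_seg_bottom + trim_seg_top >= bp2 - bp1 + 1) {
    stop("segment trims exceed the inverted segment", call. = FALSE)
  }
  paste0(substr(reference, 1, bp1 - 1 - trim_prefix),
         toupper(ins_left),
         revcomp(substr(reference, bp1 + trim_seg_bottom, bp2 - trim_seg_top)),
         toupper(ins_right),
         substr(reference, bp2 + 1 + trim_suffix, n))
}

#' Forward model of a deletion product
#'
#' Removes `reference[bp1..bp2]` and applies optional end-processing:
#' `trim_prefix` bases off the prefix end (adjacent deletion, left side)
#' and `trim_suffix` bases off the suffix start (eats into the retained
#' microhomology copy first, then adjacent sequence), plus an untemplated
#' insertion at the junction.
#'
#' @inheritParams build_inversion_product
#' @param trim_suffix Bases removed from the start of the retained suffix.
#' @param ins Untemplated sequence inserted at the junction.
#' @return The product sequence (character).
#' @export
build_deletion_product <- function(reference, bp1, bp2,
                                   trim_prefix = 0, trim_suffix = 0,
                                   ins = "") {
  reference <- toupper(reference)
  n <- nchar(reference)
  stopifnot(bp1 >= 1, bp2 <= n, bp1 <= bp2)
  if (trim_prefix >= bp1) stop("trim_prefix exceeds the prefix", call. = FALSE)
  if (bp2 + trim_suffix >= n) stop("trim_suffix exceeds the suffix",
                                   call. = FALSE)
  paste0(substr(reference, 1, bp1 - 1 - trim_prefix), toupper(ins),
         substr(reference, bp2 + 1 + trim_suffix, n))
}

# Choose among feasible microhomology placements. When end-processing has
# deleted the junction ambiguity, the sequence alone cannot place the tract
# within the deleted window, so placements nearest the nominal breakpoints
# are preferred; remaining ties go to the longest tract, then the smallest
# total deletion. Equally good placements on distinct anti-diagonals
# (b1 + b2 differs, i.e. genuinely different tracts) are an error.
select_tract_candidate <- function(cands) {
  if (!length(cands)) return(NULL)
  dist <- vapply(cands, `[[`, integer(1), "dist")
  ls <- vapply(cands, `[[`, integer(1), "l")
  ds <- vapply(cands, `[[`, integer(1), "dels")
  top <- which(dist == min(dist))
  top <- top[ls[top] == max(ls[top])]
  top <- top[ds[top] == min(ds[top])]
  diags <- unique(vapply(cands[top], function(c) c$b1 + c$b2, integer(1)))
  if (length(diags) > 1L) {
    pos <- vapply(cands[top], function(c) paste0(c$b1, "/", c$b2),
                  character(1))
    stop("ambiguous junction: multiple equally long microhomology ",
         "placements (candidates: ", paste(pos, collapse = ", "), ")",
         call. = FALSE)
  }
  cands[[top[1]]]
}

# maximal inverted-tract length at (b1, b2): largest l <= lmax with
# R[b1+i] == comp(R[b2-i]), i = 0..l-1
inv_tract_length <- function(Rr, Cr, b1, b2, lmax) {
  k <- min(lmax, b2 - b1 + 1L)
  if (k < 1L) return(0L)
  v <- Rr[b1 + 0:(k - 1L)] == Cr[b2 - 0:(k - 1L)]
  d <- which(!v)
  if (length(d)) d[1] - 1L else k
}

# maximal forward-tract length at (b1, b2): largest l <= lmax with
# R[b1+i] == R[b2+1+i]
fwd_tract_length <- function(Rr, b1, b2, lmax, n) {
  k <- min(lmax, b2 - b1 + 1L, n - b2)
  if (k < 1L) return(0L)
  v <- Rr[b1 + 0:(k - 1L)] == Rr[b2 + 1L + 0:(k - 1L)]
  d <- which(!v)
  if (length(d)) d[1] - 1L else k
}

#' Analyze a structural-variant junction case
#'
#' Aligns the product to the reference by maximal exact extension from both
#' outer anchors (which must match exactly for at least `anchor_min` bases;
#' otherwise the product is inconsistent with the hypothesis), locates the
#' rearranged middle block through a unique seed match, then searches for
#' a breakpoint pair carrying a microhomologous tract consistent with the
#' observed block bounds. Clean junctions pin the placement uniquely; when
#' end-processing has deleted the junction ambiguity, placements nearest
#' the nominal breakpoints are preferred (the sequence alone cannot
#' resolve positions inside a deleted window), and equally good genuinely
#' distinct placements raise an `"ambiguous junction"` error listing the
#' candidates. Reported quantities:
#'
#' * `mh_length` --- length of the microhomologous tract at the
#'   breakpoints of the *original* molecule (0 when below `mh_min`);
#' * `mh_seq` / `mh_retained` --- the portion of the tract still present at
#'   the most heavily processed junction;
#' * `del_on_overlap` --- tract bases deleted across both junctions;
#' * `del_adjacent_left` / `del_adjacent_right` --- non-tract reference
#'   bases missing at each junction (left/right in product orientation);
#' * `insertion_len` / `insertion_seq` / `insertion_site` --- untemplated
#'   junction insertion, located on the overlap when it accompanies an
#'   on-overlap deletion at a microhomologous junction, otherwise adjacent;
#' * `archetype` and `mechanism` (see [classify_junction_archetype()],
#'   [infer_mechanism()]).
#'
#' @param case A [junction_case()].
#' @param anchor_min Minimum exact outer anchor length (default 20 bp).
#' @param mh_min Minimum reportable microhomology (default 2 bp; a single
#'   shared base is uninformative).
#' @param mh_max Longest tract searched for (default 30 bp).
#' @param search_window Breakpoint search window around the aligned block
#'   bounds, which caps the detectable adjacent deletion (default 100 bp).
#' @return An object of class `junction_report`.
#' @export
analyze_junction <- function(case, anchor_min = 20L, mh_min = 2L,
                             mh_max = 30L, search_window = 100L) {
  stopifnot(inherits(case, "junction_case"))
  R <- case$reference; P <- case$product
  n <- nchar(R); nP <- nchar(P)

  x <- lcp_length(P, R)
  y <- lcs_length(P, R)
  if (x < anchor_min || y < anchor_min) {
    stop("product inconsistent with hypothesis: exact flank anchors ",
         "shorter than ", anchor_min, " bp (got ", x, " / ", y, ")",
         call. = FALSE)
  }
  r_s <- n - y + 1L   # reference start of the maximal suffix anchor

  if (case$type == "inversion") {
    rep <- analyze_inversion(case, R, P, n, nP, x, y, r_s,
                             anchor_min, mh_min, mh_max, search_window)
  } else {
    rep <- analyze_forward_join(case, R, P, n, nP, x, y, r_s,
                                mh_min, mh_max, search_window)
  }
  rep$id <- case$id
  rep$type <- case$type
  rep$archetype <- classify_junction_archetype(rep)
  rep$mechanism <- infer_mechanism(rep)
  class(rep) <- "junction_report"
  rep
}

analyze_inversion <- function(case, R, P, n, nP, x, y, r_s,
                              anchor_min, mh_min, mh_max, search_window) {
  rcR <- revcomp(R)

  # seed the inverted block from the centre of the unexplained middle
  mid_lo <- x + 1L; mid_hi <- nP - y
  if (mid_hi - mid_lo + 1L < anchor_min) {
    stop("product inconsistent with hypothesis: no inverted block between ",
         "the anchors", call. = FALSE)
  }
  seed_len <- anchor_min
  centre <- (mid_lo + mid_hi) %/% 2L
  starts <- unique(pmax(mid_lo, pmin(mid_hi - seed_len + 1L,
                                     centre - seed_len %/% 2L + c(0L, -40L, 40L, -80L, 80L))))
  hit <- NULL; seed_at <- NA_integer_
  for (s in starts) {
    seed <- substr(P, s, s + seed_len - 1L)
    h <- find_all_fixed(seed, rcR)
    if (length(h) > 1L) {
      stop("ambiguous junction: inverted-block seed matches the reference ",
           "at ", length(h), " sites", call. = FALSE)
    }
    if (length(h) == 1L) { hit <- h; seed_at <- s; break }
  }
  if (is.null(hit)) {
    stop("product inconsistent with hypothesis: inverted block not found ",
         "in the reverse-complemented reference", call. = FALSE)
  }

  # maximal extension of the block on both sides
  left_ext <- lcs_length(substr(P, 1, seed_at - 1L),
                         substr(rcR, 1, hit - 1L))
  right_ext <- lcp_length(substr(P, seed_at + seed_len, nP),
                          substr(rcR, hit + seed_len, n))
  p_lo <- seed_at - left_ext
  p_hi <- seed_at + seed_len - 1L + right_ext
  q_lo <- hit - left_ext
  q_hi <- hit + seed_len - 1L + right_ext
  r_lo <- n - q_hi + 1L   # block covers R[r_lo..r_hi], read in reverse
  r_hi <- n - q_lo + 1L

  ins_left_seq <- if (p_lo > x + 1L) substr(P, x + 1L, p_lo - 1L) else ""
  ins_right_seq <- if (nP - y > p_hi) substr(P, p_hi + 1L, nP - y) else ""

  # search for the breakpoint pair with the longest inverted tract
  # consistent with the observed alignment
  Rr <- charToRaw(R)
  Cr <- charToRaw(chartr("ACGT", "TGCA", R))
  b1_rng <- seq.int(max(2L, x + 1L - mh_max),
                    min(r_lo, x + 1L + search_window))
  b2_rng <- seq.int(max(r_hi, r_s - 1L - search_window),
                    min(n - 1L, r_s - 1L + mh_max))
  cands <- list()
  for (b1 in b1_rng) {
    for (b2 in b2_rng) {
      if (b2 <= b1) next
      l <- inv_tract_length(Rr, Cr, b1, b2, mh_max)
      if (l < max(2L, mh_min)) next
      # each junction is either clean (anchor extends through the full
      # tract and the block bound sits exactly on the breakpoint) or
      # trimmed (anchor stops at or before the breakpoint)
      left_ok <- if (x == b1 - 1L + l) {
        r_hi == b2 && x - p_lo + 1L == l
      } else {
        x <= b1 - 1L
      }
      right_ok <- if (r_s == b2 + 1L - l) {
        r_lo == b1 && p_hi - (nP - y + 1L) + 1L == l
      } else {
        r_s >= b2 + 1L
      }
      if (!left_ok || !right_ok) next
      if (r_lo < b1 || r_hi > b2) next
      dels <- max(0L, b1 - 1L - x) + (b2 - r_hi) + (r_lo - b1) +
        max(0L, r_s - 1L - b2)
      cands[[length(cands) + 1L]] <- list(
        b1 = b1, b2 = b2, l = l, dels = dels,
        dist = abs(b1 - case$bp1) + abs(b2 - case$bp2))
    }
  }
  best <- select_tract_candidate(cands)

  if (is.null(best)) {
    # no microhomologous tract: clean blunt junctions, possibly with a
    # sub-threshold (< mh_min) chance overlap
    ov_l <- x - p_lo + 1L
    ov_r <- p_hi - (nP - y + 1L) + 1L
    mh_len <- max(0L, min(ov_l, ov_r))
    b1 <- r_lo
    b2 <- r_hi
    del_adj_l <- max(0L, case$bp1 - 1L - x) + max(0L, case$bp2 - r_hi)
    del_adj_r <- max(0L, r_lo - case$bp1) + max(0L, r_s - 1L - case$bp2)
    if (ov_l >= 0L && ov_r >= 0L) { del_adj_l <- 0L; del_adj_r <- 0L }
    report <- list(mh_length = mh_len, mh_seq = "",
                   mh_retained = 0L,
                   del_on_overlap = 0L,
                   del_adjacent_left = del_adj_l,
                   del_adjacent_right = del_adj_r,
                   b1 = b1 + case$offset, b2 = b2 + case$offset)
  } else {
    b1 <- best$b1; b2 <- best$b2; l <- best$l
    don_l <- min(l, b2 - r_hi)
    don_r <- min(l, r_lo - b1)
    del_adj_l <- max(0L, b1 - 1L - x) + max(0L, (b2 - l) - r_hi)
    del_adj_r <- max(0L, r_s - 1L - b2) + max(0L, r_lo - (b1 + l))
    don_max <- max(don_l, don_r)
    mh_seq <- if (don_max < l) substr(R, b1 + don_max, b1 + l - 1L) else ""
    report <- list(mh_length = l, mh_seq = mh_seq,
                   mh_retained = l - don_max,
                   del_on_overlap = don_l + don_r,
                   del_adjacent_left = del_adj_l,
                   del_adjacent_right = del_adj_r,
                   b1 = b1 + case$offset, b2 = b2 + case$offset)
  }

  finish_report(report, ins_left_seq, ins_right_seq, mh_min)
}

analyze_forward_join <- function(case, R, P, n, nP, x, y, r_s,
                                 mh_min, mh_max, search_window) {
  ps <- nP - y + 1L              # product start of the suffix anchor
  ins_seq <- if (ps > x + 1L) substr(P, x + 1L, ps - 1L) else ""

  Rr <- charToRaw(R)
  b1_rng <- seq.int(max(2L, x + 1L - mh_max),
                    min(n - 1L, x + 1L + search_window))
  b2_rng <- seq.int(max(1L, r_s - 1L - mh_max - search_window),
                    min(n - 1L, r_s - 1L))
  cands <- list()
  for (b1 in b1_rng) {
    for (b2 in b2_rng) {
      if (b2 < b1) next
      l <- fwd_tract_length(Rr, b1, b2, mh_max, n)
      if (l < max(2L, mh_min)) next
      s_trim <- r_s - b2 - 1L
      left_ok <- if (x == b1 - 1L + l) {
        s_trim == 0L && x - ps + 1L == l
      } else {
        x <= b1 - 1L
      }
      if (!left_ok || s_trim < 0L) next
      dels <- max(0L, b1 - 1L - x) + s_trim
      cands[[length(cands) + 1L]] <- list(
        b1 = b1, b2 = b2, l = l, dels = dels,
        dist = abs(b1 - case$bp1) + abs(b2 - case$bp2))
    }
  }
  best <- select_tract_candidate(cands)

  if (is.null(best)) {
    ov <- x - ps + 1L
    mh_len <- max(0L, ov)
    del_adj_l <- max(0L, case$bp1 - 1L - x)
    del_adj_r <- max(0L, r_s - 1L - case$bp2)
    if (ov >= 0L) { del_adj_l <- 0L; del_adj_r <- 0L }
    report <- list(mh_length = mh_len,
                   mh_seq = if (mh_len > 0) substr(P, ps, x) else "",
                   mh_retained = mh_len, del_on_overlap = 0L,
                   del_adjacent_left = del_adj_l,
                   del_adjacent_right = del_adj_r,
                   b1 = (x + 1L) + case$offset,
                   b2 = (r_s - 1L) + case$offset)
  } else {
    b1 <- best$b1; b2 <- best$b2; l <- best$l
    s_trim <- r_s - b2 - 1L
    don <- if (x >= b1 - 1L + l) 0L else min(l, s_trim)
    del_adj_l <- max(0L, b1 - 1L - x)
    del_adj_r <- max(0L, s_trim - l)
    mh_seq <- if (don < l) substr(R, b1 + don, b1 + l - 1L) else ""
    report <- list(mh_length = l, mh_seq = mh_seq, mh_retained = l - don,
                   del_on_overlap = don,
                   del_adjacent_left = del_adj_l,
                   del_adjacent_right = del_adj_r,
                   b1 = b1 + case$offset, b2 = b2 + case$offset)
  }
  finish_report(report, ins_seq, "", mh_min)
}

finish_report <- function(report, ins_left_seq, ins_right_seq, mh_min) {
  ins_seq <- paste0(ins_left_seq, ins_right_seq)
  report$insertion_len <- nchar(ins_seq)
  report$insertion_seq <- ins_seq
  report$insertion_site <- if (report$insertion_len == 0L) {
    "none"
  } else if (report$mh_length >= mh_min && report$del_on_overlap > 0L) {
    "on_overlap"
  } else {
    "adjacent"
  }
  if (report$mh_length < mh_min) {
    report$mh_length <- 0L
    report$mh_seq <- ""
    report$mh_retained <- 0L
  }
  report
}

#' Classify a junction report into the four inversion archetypes
#'
#' * `A` --- no microhomology at the junctions (blunt joining);
#' * `B` --- microhomologous tract (>= 2 bp) with no deletion at all;
#' * `C` --- microhomology with deletions confined to a few nucleotides on
#'   or near the tract (every adjacent deletion <= `small_max` bp);
#' * `D` --- microhomology with an adjacent deletion longer than
#'   `small_max` bp (tens of nucleotides resected beyond the tract).
#'
#' @param report A `junction_report` (or list with the same fields).
#' @param small_max Largest deletion still called "a few nucleotides"
#'   (default 10 bp).
#' @return `"A"`, `"B"`, `"C"` or `"D"`.
#' @export
classify_junction_archetype <- function(report, small_max = 10L) {
  adj <- max(report$del_adjacent_left, report$del_adjacent_right)
  total_del <- report$del_on_overlap + report$del_adjacent_left +
    report$del_adjacent_right
  if (report$mh_length < 2L) return("A")
  if (adj > small_max) return("D")
  if (total_del > 0L) return("C")
  "B"
}

#' Infer the end-joining mechanism behind a junction
#'
#' Microhomology with zero adjacent deletion implies breaks on or at the
#' ends of the tract, i.e. classical NHEJ guided by the microhomology
#' (`cNHEJ-MH`) --- resection-dependent MMEJ is excluded. Adjacent
#' deletions longer than `mmej_min` bp next to a microhomologous tract are
#' the MMEJ signature (`MMEJ-candidate`). Everything else (no
#' microhomology, or only small deletions) is compatible with plain
#' classical NHEJ (`cNHEJ`).
#'
#' @inheritParams classify_junction_archetype
#' @param mmej_min Adjacent-deletion length above which MMEJ is invoked
#'   (default 10 bp).
#' @return `"cNHEJ"`, `"cNHEJ-MH"` or `"MMEJ-candidate"`.
#' @export
infer_mechanism <- function(report, mmej_min = 10L) {
  adj <- max(report$del_adjacent_left, report$del_adjacent_right)
  if (report$mh_length >= 2L && adj > mmej_min) return("MMEJ-candidate")
  if (report$mh_length >= 2L && adj == 0L) return("cNHEJ-MH")
  "cNHEJ"
}

#' Collect junction reports into a data frame
#'
#' @param reports List of `junction_report` objects.
#' @return A `data.frame`, one row per report.
#' @export
junction_report_table <- function(reports) {
  do.call(rbind, lapply(reports, function(r) {
    data.frame(id = r$id, type = r$type, mh_length = r$mh_length,
               mh_seq = r$mh_seq, mh_retained = r$mh_retained,
               del_on_overlap = r$del_on_overlap,
               del_adjacent_left = r$del_adjacent_left,
               del_adjacent_right = r$del_adjacent_right,
               insertion_len = r$insertion_len,
               insertion_site = r$insertion_site,
               b1 = r$b1, b2 = r$b2,
               archetype = r$archetype, mechanism = r$mechanism,
               stringsAsFactors = FALSE)
  }))
}

#' Tabulate junction reports per irradiation group
#'
#' Produces the per-group accounting of inversion junction characteristics:
#' events with an overlapped (microhomologous) sequence, deletions and
#' insertions on the overlap, deletions and insertions at the adjacent
#' area, and totals. Percentages are of the group's total events, rounded
#' half-up to integers.
#'
#' @param reports List of `junction_report` objects (or the data frame from
#'   [junction_report_table()]).
#' @param group Character vector assigning each report to a group.
#' @return A `data.frame`, one row per group, with `<count>` and
#'   `<count>_pct` columns plus formatted `"<count> (<pct>%)"` labels.
#' @export
tabulate_junctions <- function(reports, group) {
  tab <- if (is.data.frame(reports)) reports else junction_report_table(reports)
  if (length(group) != nrow(tab)) {
    stop("`group` must assign one group per report", call. = FALSE)
  }
  groups <- unique(group)
  rows <- lapply(groups, function(g) {
    d <- tab[group == g, , drop = FALSE]
    if (nrow(d) == 0L) {
      warning("group ", g, " has no reports; omitted", call. = FALSE)
      return(NULL)
    }
    n <- nrow(d)
    cnt <- c(overlap = sum(d$mh_length >= 2),
             del_on_overlap = sum(d$del_on_overlap > 0),
             ins_on_overlap = sum(d$insertion_site == "on_overlap"),
             del_adjacent = sum(d$del_adjacent_left > 0 |
                                  d$del_adjacent_right > 0),
             ins_adjacent = sum(d$insertion_site == "adjacent"))
    pct <- round_half_up(100 * cnt / n)
    out <- data.frame(group = g, n_total = n, t(cnt), t(`names<-`(pct, paste0(names(pct), "_pct"))),
                      stringsAsFactors = FALSE)
    for (nm in names(cnt)) {
      out[[paste0(nm, "_label")]] <-
        if (cnt[[nm]] > 0) sprintf("%d (%d%%)", cnt[[nm]], pct[[nm]]) else "0"
    }
    out
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' @export
print.junction_report <- function(x, ...) {
  cat("Junction report [", x$id, ", ", x$type, "]\n", sep = "")
  cat(sprintf("  microhomology: %d bp%s\n", x$mh_length,
              if (x$mh_length > 0 && nzchar(x$mh_seq)) {
                paste0(" (retained '", x$mh_seq, "')")
              } else ""))
  cat(sprintf("  deletions: %d on overlap, %d/%d adjacent (left/right)\n",
              x$del_on_overlap, x$del_adjacent_left, x$del_adjacent_right))
  if (x$insertion_len > 0) {
    cat(sprintf("  insertion: %d bp (%s)\n", x$insertion_len,
                x$insertion_site))
  }
  cat(sprintf("  class %s, mechanism %s\n", x$archetype, x$mechanism))
  invisible(x)
}
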