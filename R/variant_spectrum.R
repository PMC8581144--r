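# Classification of small mutations (SBSs and InDels < 100 bp) by zygosity,
# substitution type, length class, junction sequence context, genomic region
# and coding consequence, plus group-level spectrum summaries.

ZYGOSITY_HOM <- 0.80
ZYGOSITY_HET <- 0.25

#' Classify zygosity from the mutant-read fraction
#'
#' A mutation site is called homozygous when the proportion of mutant reads
#' is at least 0.80, heterozygous when it is in \[0.25, 0.80), and left
#' uncalled below 0.25.
#'
#' @param fraction Mutant-read fraction(s) in \[0, 1\].
#' @return Character vector: `"homozygous"`, `"heterozygous"` or
#'   `"not_called"`.
#' @export
classify_zygosity <- function(fraction) {
  if (any(!is.finite(fraction)) || any(fraction < 0) || any(fraction > 1)) {
    stop("mutant-read fraction must lie in [0, 1]", call. = FALSE)
  }
  ifelse(fraction >= ZYGOSITY_HOM, "homozygous",
         ifelse(fraction >= ZYGOSITY_HET, "heterozygous", "not_called"))
}

#' Classify a base substitution as transition or transversion
#'
#' Purine-purine (A<->G) and pyrimidine-pyrimidine (C<->T) changes are
#' transitions; all others are transversions.
#'
#' @param ref,alt Single bases in `A/C/G/T` (vectorised, `ref != alt`).
#' @return Character vector: `"transition"` or `"transversion"`.
#' @export
classify_substitution <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  ok <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (!all(ok)) {
    stop("ref and alt must be single unambiguous bases (A/C/G/T)",
         call. = FALSE)
  }
  if (any(ref == alt)) stop("ref and alt must differ", call. = FALSE)
  purine <- c("A", "G")
  same_class <- (ref %in% purine) == (alt %in% purine)
  ifelse(same_class, "transition", "transversion")
}

#' Transition/transversion ratio
#'
#' @param ref,alt Vectors of single bases for each substitution.
#' @return `Ti/Tv`, the ratio of transition to transversion counts.
#' @export
ti_tv_ratio <- function(ref, alt) {
  cls <- classify_substitution(ref, alt)
  sum(cls == "transition") / sum(cls == "transversion")
}

# ref/alt may be VCF-anchored ("AT" -> "A") or plain; the InDel length is
# the absolute allele-length difference either way.
indel_length <- function(ref, alt) abs(nchar(ref) - nchar(alt))

#' Classify an InDel by kind and length class
#'
#' Length bins follow the usual small-InDel reporting: 1 bp, 2-9 bp and
#' 10-99 bp; 100 bp and larger are structural variants and rejected here.
#'
#' @param ref,alt Allele strings (VCF-anchored representation accepted).
#' @return A list with `kind` (`"insertion"`/`"deletion"`), `length` (bp)
#'   and `length_class` (`"1 bp"`, `"2-9 bp"`, `"10-99 bp"`).
#' @export
classify_indel <- function(ref, alt) {
  len <- indel_length(ref, alt)
  if (length(len) != 1L) stop("classify_indel takes one variant", call. = FALSE)
  if (len == 0L) stop("not an InDel: alleles have equal length", call. = FALSE)
  if (len >= 100L) {
    stop("InDel length >= 100 bp: route to structural-variant handling",
         call. = FALSE)
  }
  kind <- if (nchar(alt) > nchar(ref)) "insertion" else "deletion"
  cls <- if (len == 1L) "1 bp" else if (len <= 9L) "2-9 bp" else "10-99 bp"
  list(kind = kind, length = len, length_class = cls)
}

#' Sequence context at an InDel junction
#'
#' Reports whether the InDel sits in a homopolymer run or a polynucleotide
#' tandem repeat. The allele counts as homopolymeric context when it is a
#' single-base string and, together with adjacent flank bases, forms a run
#' of at least `min_run` (default 3) identical bases. Otherwise a tandem
#' repeat with unit length `unit_min`-`unit_max` (default 2-6) and at least
#' `min_copies` (default 2) full copies that contains the allele and
#' extends into at least one flank qualifies as repeat context.
#' Homopolymer takes precedence.
#'
#' @param left_flank,right_flank Reference sequence on each side of the
#'   InDel (>= 10 bp each).
#' @param allele The deleted or inserted sequence.
#' @param min_run Minimum homopolymer run length.
#' @param unit_min,unit_max Tandem repeat unit length bounds.
#' @param min_copies Minimum number of full unit copies.
#' @return `"homopolymer"`, `"polynucleotide_repeat"` or `"none"`.
#' @export
junction_context <- function(left_flank, allele, right_flank,
                             min_run = 3, unit_min = 2, unit_max = 6,
                             min_copies = 2) {
  left_flank <- toupper(left_flank); right_flank <- toupper(right_flank)
  allele <- toupper(allele)
  if (nchar(left_flank) < 10 || nchar(right_flank) < 10) {
    stop("flank window shorter than the InDel context requires ",
         "(need >= 10 bp each side)", call. = FALSE)
  }
  if (nchar(allele) < 1) stop("empty allele", call. = FALSE)

  bases <- strsplit(allele, "")[[1]]
  if (length(unique(bases)) == 1L) {
    b <- bases[1]
    run <- nchar(allele)
    lf <- strsplit(left_flank, "")[[1]]
    rf <- strsplit(right_flank, "")[[1]]
    i <- length(lf)
    while (i >= 1 && lf[i] == b) { run <- run + 1; i <- i - 1 }
    j <- 1
    while (j <= length(rf) && rf[j] == b) { run <- run + 1; j <- j + 1 }
    if (run >= min_run) return("homopolymer")
  }

  context <- paste0(left_flank, allele, right_flank)
  a_lo <- nchar(left_flank) + 1L
  a_hi <- nchar(left_flank) + nchar(allele)
  n <- nchar(context)
  for (k in unit_min:unit_max) {
    for (s in seq_len(n - 2 * k + 1)) {
      if (s > a_lo) break  # tract starting after the allele cannot contain it
      unit <- substr(context, s, s + k - 1)
      copies <- 1L
      while (s + (copies + 1) * k - 1 <= n &&
             substr(context, s + copies * k, s + (copies + 1) * k - 1) == unit) {
        copies <- copies + 1L
      }
      t_hi <- s + copies * k - 1L
      if (copies >= min_copies && s <= a_lo && t_hi >= a_hi &&
          (s < a_lo || t_hi > a_hi)) {
        return("polynucleotide_repeat")
      }
    }
  }
  "none"
}

# ---- gene models -----------------------------------------------------------

#' Single-transcript gene model
#'
#' Ordered, non-overlapping CDS intervals (1-based, inclusive) on one
#' strand. The concatenated CDS must be a whole number of codons and start
#' with ATG on the coding strand (checked when a genome is supplied).
#'
#' @param gene_id Identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param starts,ends Parallel integer vectors of CDS interval bounds.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, starts, ends) {
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'", call. = FALSE)
  if (length(starts) != length(ends) || length(starts) < 1L) {
    stop("starts/ends must be parallel non-empty vectors", call. = FALSE)
  }
  o <- order(starts)
  starts <- as.integer(starts[o]); ends <- as.integer(ends[o])
  if (any(ends < starts)) stop("interval end before start", call. = FALSE)
  if (length(starts) > 1L && any(starts[-1] <= ends[-length(ends)])) {
    stop("CDS intervals overlap", call. = FALSE)
  }
  if (sum(ends - starts + 1L) %% 3L != 0L) {
    stop("total CDS length must be divisible by 3", call. = FALSE)
  }
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 starts = starts, ends = ends),
            class = "gene_model")
}

# genome: named character vector of chromosome sequences (or DNAStringSet)
as_genome <- function(genome) {
  g <- if (inherits(genome, "DNAStringSet")) as.character(genome) else genome
  if (is.null(names(g)) || any(!nzchar(names(g)))) {
    stop("genome sequences must be named by chromosome", call. = FALSE)
  }
  toupper(g)
}

cds_sequence <- function(gene, genome) {
  g <- as_genome(genome)
  if (!gene$chrom %in% names(g)) {
    stop("unknown chromosome: ", gene$chrom, call. = FALSE)
  }
  seqs <- mapply(function(s, e) substr(g[[gene$chrom]], s, e),
                 gene$starts, gene$ends)
  cds <- paste(seqs, collapse = "")
  if (gene$strand == "-") cds <- revcomp(cds)
  cds
}

#' Validate a gene model against a genome
#'
#' Checks the ATG start and terminal stop codon of the concatenated CDS.
#'
#' @param gene A [gene_model()].
#' @param genome Named character vector (or `DNAStringSet`) of chromosomes.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_gene_model <- function(gene, genome) {
  cds <- cds_sequence(gene, genome)
  if (substr(cds, 1, 3) != "ATG") {
    stop(gene$gene_id, ": CDS does not begin with ATG", call. = FALSE)
  }
  last <- substr(cds, nchar(cds) - 2, nchar(cds))
  if (!last %in% c("TAA", "TAG", "TGA")) {
    stop(gene$gene_id, ": CDS does not end with a stop codon", call. = FALSE)
  }
  invisible(TRUE)
}

# 1-based reference span a variant affects. VCF-anchored InDels share their
# first base; the affected span excludes the anchor for deletions and is the
# two bases flanking the insertion point for insertions.
affected_span <- function(pos, ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  if (nr == na) {
    c(pos, pos + nr - 1L)                      # substitution
  } else if (nr > na) {
    anchored <- substr(ref, 1, na) == alt
    if (anchored) c(pos + na, pos + nr - 1L) else c(pos, pos + nr - 1L)
  } else {
    c(pos, min(pos + nr, pos + 1L))            # insertion: flanking bases
  }
}

#' Classify a variant as CDS or non-coding
#'
#' A variant is coding iff any affected reference base overlaps a CDS
#' interval of any gene.
#'
#' @param chrom Chromosome of the variant.
#' @param pos 1-based position (VCF-style anchor for InDels).
#' @param ref,alt Allele strings.
#' @param genes List of [gene_model()] objects.
#' @return `"CDS"` or `"non-coding"`.
#' @export
region_class <- function(chrom, pos, ref, alt, genes) {
  known <- vapply(genes, function(g) g$chrom, character(1))
  if (!chrom %in% known) {
    stop("unknown chromosome: ", chrom, call. = FALSE)
  }
  span <- affected_span(pos, ref, alt)
  for (g in genes) {
    if (g$chrom != chrom) next
    if (any(span[1] <= g$ends & span[2] >= g$starts)) return("CDS")
  }
  "non-coding"
}

# genomic position -> 1-based CDS coordinate (coding-strand orientation)
genomic_to_cds <- function(gene, pos) {
  offs <- 0L
  cds_pos <- NA_integer_
  for (i in seq_along(gene$starts)) {
    s <- gene$starts[i]; e <- gene$ends[i]
    if (pos >= s && pos <= e) { cds_pos <- offs + (pos - s + 1L); break }
    offs <- offs + (e - s + 1L)
  }
  if (is.na(cds_pos)) return(NA_integer_)
  if (gene$strand == "-") {
    total <- sum(gene$ends - gene$starts + 1L)
    cds_pos <- total - cds_pos + 1L
  }
  cds_pos
}

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) stop("cannot translate codon ", codon, call. = FALSE)
  aa
}

#' Coding consequence of a variant overlapping a CDS
#'
#' SBSs are classified by translating the affected codon before and after
#' the change: `silent`, `missense`, `premature_stop`, or `start_loss` when
#' the change falls in codon 1 and destroys the ATG. InDels are
#' `frameshift` when the number of CDS bases gained or lost is not a
#' multiple of 3, otherwise `in-frame_insertion` / `in-frame_deletion`.
#'
#' @inheritParams region_class
#' @param gene The [gene_model()] the variant overlaps.
#' @param genome Named character vector (or `DNAStringSet`) of chromosomes.
#' @return One of `"silent"`, `"missense"`, `"premature_stop"`,
#'   `"start_loss"`, `"in-frame_insertion"`, `"in-frame_deletion"`,
#'   `"frameshift"`.
#' @export
consequence <- function(chrom, pos, ref, alt, gene, genome) {
  g <- as_genome(genome)
  if (chrom != gene$chrom) stop("variant is on a different chromosome than ",
                                gene$gene_id, call. = FALSE)
  span <- affected_span(pos, ref, alt)
  in_cds <- any(span[1] <= gene$ends & span[2] >= gene$starts)
  if (!in_cds) {
    stop("variant does not overlap the CDS of ", gene$gene_id,
         " (classify region first)", call. = FALSE)
  }
  nr <- nchar(ref); na <- nchar(alt)

  if (nr == 1L && na == 1L) {
    cds <- cds_sequence(gene, genome)
    cpos <- genomic_to_cds(gene, pos)
    base_new <- if (gene$strand == "-") revcomp(alt) else alt
    base_old <- if (gene$strand == "-") revcomp(ref) else ref
    if (substr(cds, cpos, cpos) != base_old) {
      stop("reference allele does not match the genome at ", chrom, ":", pos,
           call. = FALSE)
    }
    codon_i <- (cpos - 1L) %/% 3L + 1L
    lo <- (codon_i - 1L) * 3L + 1L
    codon_old <- substr(cds, lo, lo + 2L)
    codon_new <- codon_old
    substr(codon_new, cpos - lo + 1L, cpos - lo + 1L) <- base_new
    aa_old <- translate_codon(codon_old)
    aa_new <- translate_codon(codon_new)
    if (aa_new == aa_old) return("silent")
    if (codon_i == 1L && codon_new != "ATG") return("start_loss")
    if (aa_new == "*") return("premature_stop")
    return("missense")
  }

  # InDel: count CDS bases inserted or removed
  if (nr > na) {
    del_lo <- span[1]; del_hi <- span[2]
    cds_removed <- 0L
    for (i in seq_along(gene$starts)) {
      cds_removed <- cds_removed +
        max(0L, min(del_hi, gene$ends[i]) - max(del_lo, gene$starts[i]) + 1L)
    }
    if (cds_removed %% 3L != 0L) return("frameshift")
    return("in-frame_deletion")
  }
  inserted <- na - nr
  if (inserted %% 3L != 0L) return("frameshift")
  "in-frame_insertion"
}

# ---- spectrum summary ------------------------------------------------------

#' Summarise a small-mutation spectrum
#'
#' Aggregates a variant table into the group-level spectrum: zygosity
#' counts, SBS/InDel counts, Ti/Tv ratio, InDel kind and length-class
#' counts, the deletion/insertion ratio, per-bp mutation frequencies
#' (count / (genome length x number of individuals)), and --- when gene
#' models / genome are supplied --- CDS vs non-coding counts and junction
#' context counts.
#'
#' @param variants `data.frame` with columns `chrom`, `pos`, `ref`, `alt`
#'   and optionally `fraction` (mutant-read fraction) and `sample`.
#' @param genome_length Total genome length in bp (> 0).
#' @param n_individuals Number of sequenced individuals the records came
#'   from (> 0).
#' @param genes Optional list of [gene_model()] objects for region counts.
#' @param genome Optional named chromosome sequences for junction context.
#' @param flank Flank width used for junction context (default 10 bp).
#' @return An object of class `spectrum_summary` (a list of tables).
#' @export
summarize_spectrum <- function(variants, genome_length, n_individuals,
                               genes = NULL, genome = NULL, flank = 10) {
  if (nrow(variants) == 0L) stop("empty variant table", call. = FALSE)
  if (genome_length <= 0) stop("genome length must be positive", call. = FALSE)
  if (n_individuals <= 0) stop("need a positive number of individuals",
                               call. = FALSE)

  nr <- nchar(variants$ref); na <- nchar(variants$alt)
  if (any(nr == na & nr != 1L)) {
    stop("multi-base substitutions are not supported", call. = FALSE)
  }
  is_sbs <- nr == 1L & na == 1L
  lens <- abs(nr - na)
  if (any(lens >= 100L)) {
    stop("records with allele-length difference >= 100 bp belong to ",
         "structural-variant handling", call. = FALSE)
  }

  out <- list(n_records = nrow(variants))

  if (!is.null(variants$fraction)) {
    zyg <- classify_zygosity(variants$fraction)
    out$zygosity <- table(factor(zyg, levels = c("homozygous", "heterozygous",
                                                 "not_called")))
  }

  out$type <- c(SBS = sum(is_sbs), InDel = sum(!is_sbs))
  if (sum(is_sbs) > 0) {
    cls <- classify_substitution(variants$ref[is_sbs], variants$alt[is_sbs])
    out$substitution <- table(factor(cls, levels = c("transition",
                                                     "transversion")))
    out$ti_tv <- unname(out$substitution["transition"] /
                          out$substitution["transversion"])
  }

  if (sum(!is_sbs) > 0) {
    ind <- which(!is_sbs)
    kinds <- ifelse(na[ind] > nr[ind], "insertion", "deletion")
    lcls <- ifelse(lens[ind] == 1L, "1 bp",
                   ifelse(lens[ind] <= 9L, "2-9 bp", "10-99 bp"))
    out$indel_kind <- table(factor(kinds, levels = c("deletion", "insertion")))
    out$indel_length_class <- table(factor(lcls, levels = c("1 bp", "2-9 bp",
                                                            "10-99 bp")))
    n_del <- sum(kinds == "deletion"); n_ins <- sum(kinds == "insertion")
    out$del_ins_ratio <- if (n_ins > 0) n_del / n_ins else NA_real_
    out$del_ins_ratio_printed <- if (n_ins > 0) {
      round_half_up(n_del / n_ins, 2)
    } else NA_real_

    if (!is.null(genome)) {
      g <- as_genome(genome)
      ctx <- vapply(ind, function(i) {
        p <- variants$pos[i]; r <- variants$ref[i]; a <- variants$alt[i]
        chrom_seq <- g[[variants$chrom[i]]]
        if (nchar(r) > nchar(a)) {
          allele <- substr(r, nchar(a) + 1L, nchar(r))
          lo <- p + nchar(a); hi <- p + nchar(r) - 1L
        } else {
          allele <- substr(a, nchar(r) + 1L, nchar(a))
          lo <- p + 1L; hi <- p
        }
        lf <- substr(chrom_seq, max(1L, lo - flank), lo - 1L)
        rf <- substr(chrom_seq, hi + 1L, min(nchar(chrom_seq), hi + flank))
        if (nchar(lf) < flank || nchar(rf) < flank) return(NA_character_)
        junction_context(lf, allele, rf)
      }, character(1))
      out$junction_context <- table(factor(ctx, levels = c("homopolymer",
                                                           "polynucleotide_repeat",
                                                           "none")))
    }
  }

  if (!is.null(genes)) {
    reg <- vapply(seq_len(nrow(variants)), function(i) {
      region_class(variants$chrom[i], variants$pos[i], variants$ref[i],
                   variants$alt[i], genes)
    }, character(1))
    out$region <- table(factor(reg, levels = c("CDS", "non-coding")))
  }

  denom <- genome_length * n_individuals
  out$sbs_freq_per_bp <- sum(is_sbs) / denom
  out$indel_freq_per_bp <- sum(!is_sbs) / denom
  out$total_freq_per_bp <- nrow(variants) / denom
  class(out) <- "spectrum_summary"
  out
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat("Small-mutation spectrum:", x$n_records, "records\n")
  cat("  SBS:", x$type["SBS"], " InDel:", x$type["InDel"], "\n")
  if (!is.null(x$ti_tv)) cat(sprintf("  Ti/Tv = %.3f\n", x$ti_tv))
  if (!is.null(x$del_ins_ratio)) {
    cat(sprintf("  deletion/insertion = %.2f\n", x$del_ins_ratio))
  }
  cat(sprintf("  per-bp frequency (per individual): SBS %.3g, InDel %.3g\n",
              x$sbs_freq_per_bp, x$indel_freq_per_bp))
  invisible(x)
}
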