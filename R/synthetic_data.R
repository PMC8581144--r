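# Generators for every input the analysis consumes, with known ground
# truth: random genomes with embedded single-transcript genes, dose-survival
# assays under the multitarget model, called-variant tables with planted
# zygosity and read-depth noise, and structural-variant junction cases with
# planted microhomology, junction deletions and insertions.
#
# Defaults mirror the study conditions: a 100 MeV proton-beam survival
# curve (D0/m consistent with shoulder dose 754 Gy and LD50 1051 Gy,
# assayed as 4 replicates x 50 seeds on the 113.7-1188.4 Gy dose grid),
# ~46x short-read depth rounded to 40x for read-fraction sampling, a
# mutation mix of ~68% SBS with deletions ~4x more frequent than
# insertions, microhomology lengths 2-23 bp and adjacent junction
# deletions 1-61 bp.

#' Generator configuration
#'
#' @param genome_length Genome size in bp.
#' @param gc GC fraction of the random genome.
#' @param n_genes Number of embedded genes.
#' @param cds_codons_range Range the per-gene codon count is drawn from
#'   (start and stop codons included).
#' @param D0,m Multitarget survival parameters of the simulated assay
#'   (defaults solved from shoulder dose 754 Gy and LD50 1051 Gy).
#' @param doses Dose grid in Gy.
#' @param n_replicates,seeds_per_replicate Survival assay layout.
#' @param n_variants Number of small mutations per variant table.
#' @param p_sbs Proportion of variants that are SBSs.
#' @param p_hom Proportion of planted homozygous variants (rest
#'   heterozygous).
#' @param p_deletion Proportion of InDels that are deletions.
#' @param depth Sequencing depth used for read-fraction sampling.
#' @param mh_range Microhomology lengths planted at junction cases (bp).
#' @param adj_del_range Adjacent-deletion lengths for class D cases (bp;
#'   the class C portion uses the sub-11 bp part).
#' @param class_mix Named numeric vector of relative weights for junction
#'   classes A-D.
#' @param flank_len,mid_len Junction-case geometry: outer flank length and
#'   inverted-core length (bp).
#' @param ins_prob Probability of an untemplated junction insertion (1-5 bp).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(genome_length = 100000, gc = 0.36,
                             n_genes = 40, cds_codons_range = c(80, 300),
                             D0 = 632.16, m = 3.2961, doses = c(113.7, 190.3,
                               280.6, 393.4, 493.4, 574.0, 682.1, 786.9,
                               994.9, 1188.4),
                             n_replicates = 4, seeds_per_replicate = 50,
                             n_variants = 200, p_sbs = 0.68, p_hom = 0.5,
                             p_deletion = 0.8, depth = 40,
                             mh_range = c(2, 23), adj_del_range = c(1, 61),
                             class_mix = c(A = 3, B = 12, C = 6, D = 4),
                             flank_len = 150, mid_len = 150,
                             ins_prob = 0.08) {
  cfg <- as.list(environment())
  stopifnot(genome_length > 0, gc > 0, gc < 1, n_genes >= 0,
            D0 > 0, m >= 1, depth >= 1, n_variants >= 0,
            p_sbs >= 0, p_sbs <= 1, p_hom >= 0, p_hom <= 1,
            p_deletion >= 0, p_deletion <= 1)
  if (mh_range[1] < 2 || mh_range[2] > 23) {
    stop("mh_range must lie within [2, 23]", call. = FALSE)
  }
  if (any(class_mix < 0)) stop("class_mix weights must be >= 0", call. = FALSE)
  class(cfg) <- "generator_config"
  cfg
}

#' Generate a random genome with embedded gene models
#'
#' A single random chromosome at the configured GC content with
#' `n_genes` non-overlapping single-transcript genes written into it:
#' ATG start, stop-free random codons, terminal stop codon; half the genes
#' sit on the minus strand (the reverse complement is embedded).
#'
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @return A list with `genome` (named character vector, one chromosome
#'   `"chr1"`) and `genes` (list of [gene_model()]).
#' @export
gen_genome_and_genes <- function(config, seed = 1) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(seed)
  n <- config$genome_length
  genome <- random_dna(n, config$gc)

  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste, collapse = "")
  sense_codons <- setdiff(codons, c("TAA", "TAG", "TGA", "ATG"))

  genes <- list()
  if (config$n_genes > 0) {
    n_codons <- sample(seq(config$cds_codons_range[1],
                           config$cds_codons_range[2]), config$n_genes,
                       replace = TRUE)
    lens <- n_codons * 3L
    if (sum(lens) + 2L * config$n_genes > n) {
      stop("infeasible packing: total CDS demand exceeds the genome length",
           call. = FALSE)
    }
    # lay genes left to right with random gaps
    slack <- n - sum(lens)
    gaps <- stats::rmultinom(1, slack, rep(1, config$n_genes + 1))[, 1]
    pos <- 1L
    for (i in seq_len(config$n_genes)) {
      pos <- pos + gaps[i]
      start <- pos
      end <- start + lens[i] - 1L
      cds <- paste0("ATG",
                    paste(sample(sense_codons, n_codons[i] - 2L,
                                 replace = TRUE), collapse = ""),
                    sample(c("TAA", "TAG", "TGA"), 1))
      strand <- sample(c("+", "-"), 1)
      embedded <- if (strand == "-") revcomp(cds) else cds
      substr(genome, start, end) <- embedded
      genes[[i]] <- gene_model(gene_id = sprintf("gene%03d", i),
                               chrom = "chr1", strand = strand,
                               starts = start, ends = end)
      pos <- end + 1L
    }
  }
  list(genome = c(chr1 = genome), genes = genes)
}

#' Simulate a dose-survival assay
#'
#' With `noise = TRUE`, survived counts are Binomial(total, S(D)) per
#' replicate; with `noise = FALSE` a `fraction` column carries the exact
#' model value (one row per dose).
#'
#' @param config A [generator_config()].
#' @param seed Integer seed (used only when `noise = TRUE`).
#' @param noise Sample binomial counts, or return exact fractions.
#' @return A `data.frame` suitable for [fit_multitarget()].
#' @export
gen_survival_dataset <- function(config, seed = 1, noise = TRUE) {
  stopifnot(inherits(config, "generator_config"))
  if (config$seeds_per_replicate <= 0) {
    stop("seeds_per_replicate must be positive", call. = FALSE)
  }
  s <- survival_fraction(config$doses, config$D0, config$m)
  if (!noise) {
    return(data.frame(dose_gy = config$doses, fraction = s))
  }
  set.seed(seed)
  d <- expand.grid(replicate = seq_len(config$n_replicates),
                   dose_gy = config$doses)
  d$total <- config$seeds_per_replicate
  p <- survival_fraction(d$dose_gy, config$D0, config$m)
  d$survived <- stats::rbinom(nrow(d), d$total, p)
  d[, c("dose_gy", "replicate", "survived", "total")]
}

#' Generate a called-variant table with planted truth
#'
#' Plants SBSs and small InDels at distinct genome positions with known
#' zygosity; the observed mutant-read fraction is
#' `Binomial(depth, p) / depth` with `p = 1` for homozygous and `p = 0.5`
#' for heterozygous sites, emulating read sampling at fixed depth.
#'
#' @param config A [generator_config()].
#' @param genome Named chromosome sequences from [gen_genome_and_genes()].
#' @param seed Integer seed.
#' @return A list with `variants` (`chrom`, `pos`, `ref`, `alt`,
#'   `fraction`, `sample`) and `truth` (`zygosity`, `kind`, `length`).
#' @export
gen_variant_table <- function(config, genome, seed = 1) {
  stopifnot(inherits(config, "generator_config"))
  g <- as_genome(genome)
  chrom <- names(g)[1]
  chrom_seq <- g[[1]]
  n <- nchar(chrom_seq)
  n_var <- config$n_variants
  if (n_var == 0) {
    empty <- data.frame(chrom = character(), pos = integer(),
                        ref = character(), alt = character(),
                        fraction = numeric(), sample = character())
    return(list(variants = empty,
                truth = data.frame(zygosity = character(),
                                   kind = character(), length = integer())))
  }
  if (n_var * 120L > n) {
    stop("variant count exceeds genome capacity: use a longer genome",
         call. = FALSE)
  }
  set.seed(seed)
  # spaced positions so alleles never collide
  pos <- sort(sample.int(n %/% 120L - 1L, n_var)) * 120L
  is_sbs <- stats::runif(n_var) < config$p_sbs
  is_hom <- stats::runif(n_var) < config$p_hom
  is_del <- stats::runif(n_var) < config$p_deletion
  # InDel lengths: mostly 1 bp, then 2-9, occasionally 10-99
  ilen_choice <- stats::runif(n_var)
  ilen <- ifelse(ilen_choice < 0.5, 1L,
                 ifelse(ilen_choice < 0.85, sample(2:9, n_var, TRUE),
                        sample(10:99, n_var, TRUE)))

  ref <- character(n_var); alt <- character(n_var)
  for (i in seq_len(n_var)) {
    base <- substr(chrom_seq, pos[i], pos[i])
    if (is_sbs[i]) {
      ref[i] <- base
      alt[i] <- sample(setdiff(c("A", "C", "G", "T"), base), 1)
    } else if (is_del[i]) {
      ref[i] <- substr(chrom_seq, pos[i], pos[i] + ilen[i])
      alt[i] <- base
    } else {
      ref[i] <- base
      alt[i] <- paste0(base, random_dna(ilen[i], config$gc))
    }
  }
  p_alt <- ifelse(is_hom, 1.0, 0.5)
  frac <- stats::rbinom(n_var, config$depth, p_alt) / config$depth
  variants <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                         fraction = frac, sample = "sim1",
                         stringsAsFactors = FALSE)
  truth <- data.frame(zygosity = ifelse(is_hom, "homozygous", "heterozygous"),
                      kind = ifelse(is_sbs, "SBS",
                                    ifelse(is_del, "deletion", "insertion")),
                      length = ifelse(is_sbs, 0L, ilen),
                      stringsAsFactors = FALSE)
  list(variants = variants, truth = truth)
}

# draw planted parameters for one junction case of a given class
plan_junction_case <- function(config, cls) {
  L <- if (cls == "A") 0L else
    sample(seq(config$mh_range[1], config$mh_range[2]), 1)
  t_pre <- t_top <- t_bot <- t_suf <- 0L
  if (cls == "C") {
    if (sample(c(TRUE, FALSE), 1)) {
      t_top <- sample(seq_len(min(10L, L)), 1)
    } else {
      t_bot <- sample(seq_len(min(10L, L)), 1)
    }
    if (stats::runif(1) < 0.4) {   # small adjacent nibble stays class C
      if (sample(c(TRUE, FALSE), 1)) t_pre <- sample(1:10, 1)
      else t_suf <- sample(1:10, 1)
    }
  } else if (cls == "D") {
    big <- sample(seq(max(11L, config$adj_del_range[1]),
                      config$adj_del_range[2]), 1)
    if (sample(c(TRUE, FALSE), 1)) t_pre <- big else t_suf <- big
    if (stats::runif(1) < 0.5) t_top <- sample(seq_len(min(10L, L)), 1)
  }
  ins_left <- ins_right <- ""
  if (cls != "A" && stats::runif(1) < config$ins_prob) {
    ins <- random_dna(sample(1:5, 1), 0.5)
    if (t_top > 0) ins_left <- ins else ins_right <- ins
  }
  list(cls = cls, L = L, t_pre = t_pre, t_top = t_top, t_bot = t_bot,
       t_suf = t_suf, ins_left = ins_left, ins_right = ins_right)
}

# expected alignment primitives for a planted inversion case; used to
# screen candidate references for chance matches that would blur recovery
junction_case_screens <- function(R, P, plan, b1, b2) {
  n <- nchar(R); nP <- nchar(P)
  L <- plan$L
  clean_left <- plan$t_pre == 0L && plan$t_top == 0L && plan$ins_left == ""
  clean_right <- plan$t_suf == 0L && plan$t_bot == 0L && plan$ins_right == ""
  x_exp <- if (clean_left) b1 - 1L + L else b1 - 1L - plan$t_pre
  r_s_exp <- if (clean_right) b2 + 1L - L else b2 + 1L + plan$t_suf
  y_exp <- n - r_s_exp + 1L
  if (lcp_length(P, R) != x_exp) return(FALSE)
  if (lcs_length(P, R) != y_exp) return(FALSE)

  r_lo <- b1 + plan$t_bot; r_hi <- b2 - plan$t_top
  p_lo <- (b1 - 1L - plan$t_pre) + nchar(plan$ins_left) + 1L
  p_hi <- p_lo + (r_hi - r_lo)
  q_lo <- n - r_hi + 1L; q_hi <- n - r_lo + 1L
  rcR <- revcomp(R)
  # the block must not extend past its planted bounds by chance
  if (p_lo > 1L && q_lo > 1L &&
      substr(P, p_lo - 1L, p_lo - 1L) == substr(rcR, q_lo - 1L, q_lo - 1L)) {
    return(FALSE)
  }
  if (p_hi < nP && q_hi < n &&
      substr(P, p_hi + 1L, p_hi + 1L) == substr(rcR, q_hi + 1L, q_hi + 1L)) {
    return(FALSE)
  }
  # planted tract must be maximal (or absent, for class A)
  Rr <- charToRaw(R); Cr <- charToRaw(chartr("ACGT", "TGCA", R))
  if (L > 0L) {
    if (inv_tract_length(Rr, Cr, b1, b2, 30L) != L) return(FALSE)
    if (substr(R, b1 - 1L, b1 - 1L) ==
        chartr("ACGT", "TGCA", substr(R, b2 + 1L, b2 + 1L))) return(FALSE)
  } else {
    if (inv_tract_length(Rr, Cr, b1, b2, 30L) >= 2L) return(FALSE)
  }
  # unique seed for the analyzer's block search
  centre <- (p_lo + p_hi) %/% 2L
  seed20 <- substr(P, centre - 9L, centre + 10L)
  if (length(find_all_fixed(seed20, rcR)) != 1L) return(FALSE)
  TRUE
}

#' Generate structural-variant junction cases with planted truth
#'
#' Each case is an independent random reference segment carrying an
#' inversion whose junctions are engineered to a target class:
#' a microhomologous tract of planted length (classes B-D), on-overlap
#' and/or adjacent junction deletions, and occasional untemplated
#' insertions. Flanking sequence is rejection-sampled until the planted
#' structure is the only alignment the reference supports (repeat-free
#' anchors, no chance tract extensions, unique block seed), so an exact
#' analyzer must recover the planted values exactly.
#'
#' @param config A [generator_config()].
#' @param n Number of cases; class identity is drawn from
#'   `config$class_mix` unless `classes` is supplied.
#' @param seed Integer seed.
#' @param classes Optional explicit character vector of classes
#'   (`"A"`-`"D"`), recycled to length `n`.
#' @param max_attempts Rejection-sampling budget per case.
#' @return A list with `cases` (list of [junction_case()]) and `truth`
#'   (`data.frame` of planted values per case).
#' @export
gen_junction_cases <- function(config, n, seed = 1, classes = NULL,
                               max_attempts = 200) {
  stopifnot(inherits(config, "generator_config"))
  if (n == 0) {
    return(list(cases = list(),
                truth = data.frame(id = character(), class = character(),
                                   mh_length = integer(),
                                   del_on_overlap = integer(),
                                   del_adjacent_left = integer(),
                                   del_adjacent_right = integer(),
                                   insertion_len = integer())))
  }
  set.seed(seed)
  if (is.null(classes)) {
    classes <- sample(names(config$class_mix), n, replace = TRUE,
                      prob = config$class_mix)
  } else {
    classes <- rep_len(classes, n)
  }
  fl <- config$flank_len; ml <- config$mid_len
  cases <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    plan <- plan_junction_case(config, classes[i])
    ok <- FALSE
    for (attempt in seq_len(max_attempts)) {
      A <- random_dna(fl, 0.5)
      B <- random_dna(fl, 0.5)
      mid <- random_dna(ml, 0.5)
      M <- if (plan$L > 0) random_dna(plan$L, 0.5) else ""
      R <- paste0(A, M, mid, if (plan$L > 0) revcomp(M) else "", B)
      b1 <- fl + 1L
      b2 <- fl + plan$L + ml + plan$L
      P <- build_inversion_product(R, b1, b2,
                                   trim_prefix = plan$t_pre,
                                   trim_seg_top = plan$t_top,
                                   trim_seg_bottom = plan$t_bot,
                                   trim_suffix = plan$t_suf,
                                   ins_left = plan$ins_left,
                                   ins_right = plan$ins_right)
      if (junction_case_screens(R, P, plan, b1, b2)) { ok <- TRUE; break }
    }
    if (!ok) {
      stop("rejection sampling failed after ", max_attempts,
           " attempts; increase flank_len/mid_len", call. = FALSE)
    }
    id <- sprintf("case%03d", i)
    cases[[i]] <- junction_case(R, P, b1, b2, type = "inversion", id = id)
    ins_len <- nchar(plan$ins_left) + nchar(plan$ins_right)
    truth[[i]] <- data.frame(
      id = id, class = plan$cls, mh_length = plan$L,
      del_on_overlap = plan$t_top + plan$t_bot,
      del_adjacent_left = plan$t_pre,
      del_adjacent_right = plan$t_suf,
      insertion_len = ins_len,
      stringsAsFactors = FALSE)
  }
  list(cases = cases, truth = do.call(rbind, truth))
}
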