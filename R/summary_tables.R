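# Ingestion and accounting of the published summary tables: phenotypic
# mutation rates (mutant counts per M2 lines screened), structural-variant
# event/process records with breakpoints in kb, junction-characteristic
# tallies, and gene-impact summaries (means +/- standard errors).

#' Phenotypic mutation rate
#'
#' `100 * mutants / lines`, rounded half-up to two decimals, as printed in
#' phenotype screening tables.
#'
#' @param mutants Number of mutant M2 lines (0 <= mutants <= lines).
#' @param lines Number of M2 lines screened (> 0).
#' @return Mutation rate in percent, two decimals.
#' @export
mutation_rate <- function(mutants, lines) {
  if (any(lines <= 0)) stop("`lines` must be positive", call. = FALSE)
  if (any(mutants < 0 | mutants > lines)) {
    stop("need 0 <= mutants <= lines", call. = FALSE)
  }
  round_half_up(100 * mutants / lines, 2)
}

#' Read a phenotype-count table
#'
#' TSV with columns `category`, `characteristic`, `group`, `dose_gy`,
#' `count` plus rows with `category == "lines_screened"` giving the number
#' of M2 lines per group x dose.
#'
#' @param path Path to the TSV.
#' @return A `data.frame`.
#' @export
read_phenotype_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("category", "characteristic", "group", "dose_gy", "count")
  if (!all(need %in% names(d))) {
    stop("phenotype table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  d
}

#' Recompute phenotypic mutation rates from a count table
#'
#' Sums mutant counts over categories per group x dose, divides by the
#' lines screened and appends per-radiation-source totals.
#'
#' @param pheno A `data.frame` from [read_phenotype_tsv()].
#' @return A `data.frame` with `group`, `dose`, `mutants`, `lines`,
#'   `rate_pct` (dose `"total"` rows pool all doses of a group).
#' @export
phenotype_rates <- function(pheno) {
  lines <- pheno[pheno$category == "lines_screened", ]
  counts <- pheno[pheno$category != "lines_screened", ]
  rows <- lapply(seq_len(nrow(lines)), function(i) {
    g <- lines$group[i]; d <- lines$dose_gy[i]
    mut <- sum(counts$count[counts$group == g & counts$dose_gy == d])
    data.frame(group = g, dose = as.character(d), mutants = mut,
               lines = lines$count[i],
               rate_pct = mutation_rate(mut, lines$count[i]),
               stringsAsFactors = FALSE)
  })
  per_dose <- do.call(rbind, rows)
  totals <- lapply(unique(per_dose$group), function(g) {
    d <- per_dose[per_dose$group == g, ]
    data.frame(group = g, dose = "total", mutants = sum(d$mutants),
               lines = sum(d$lines),
               rate_pct = mutation_rate(sum(d$mutants), sum(d$lines)),
               stringsAsFactors = FALSE)
  })
  rbind(per_dose, do.call(rbind, totals))
}

#' Read a structural-variant event table
#'
#' TSV shaped like the published SV table: one row per rearrangement
#' event with columns `sample`, `group`, `type`, `chrom1`, `pos1_kb`,
#' `chrom2`, `pos2_kb`, `size_kb` (may be `NA` for interchromosomal
#' events), `zygosity`, `truncated_genes`, `deleted_genes`, `process_id`
#' (events footnoted as arising in one rearrangement process share an id).
#' Sizes of intrachromosomal events are checked against `|pos2 - pos1|`
#' (0.1 kb tolerance for the table's rounding) and flagged in
#' `size_consistent` rather than rejected.
#'
#' @param path Path to the TSV.
#' @return A `data.frame` of validated events.
#' @export
read_sv_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "group", "type", "chrom1", "pos1_kb", "chrom2",
            "pos2_kb", "size_kb", "zygosity", "truncated_genes",
            "deleted_genes", "process_id")
  if (!all(need %in% names(d))) {
    stop("SV table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  types <- c("inversion", "deletion", "duplication", "translocation")
  if (any(!d$type %in% types)) {
    stop("unknown SV type value(s): ",
         paste(unique(setdiff(d$type, types)), collapse = ", "), call. = FALSE)
  }
  if (any(!d$zygosity %in% c("homozygous", "heterozygous"))) {
    stop("zygosity must be homozygous or heterozygous", call. = FALSE)
  }
  computed <- fragment_size(d)
  d$size_consistent <- is.na(d$size_kb) | is.na(computed) |
    abs(computed - d$size_kb) <= 0.1 + 1e-9
  d
}

#' Fragment size of a rearrangement event
#'
#' `|pos2 - pos1|` in kb (one decimal) for intrachromosomal events; `NA`
#' for events whose breakpoints lie on different chromosomes.
#'
#' @param events `data.frame` with `chrom1`, `pos1_kb`, `chrom2`, `pos2_kb`.
#' @return Numeric vector of sizes in kb.
#' @export
fragment_size <- function(events) {
  ifelse(events$chrom1 == events$chrom2,
         round_half_up(abs(events$pos2_kb - events$pos1_kb), 1),
         NA_real_)
}

#' Count rearrangement events
#'
#' @param events SV event `data.frame` (see [read_sv_tsv()]).
#' @param by `"type"` or `"zygosity"`.
#' @return A named table of counts (all levels present, zero-filled).
#' @export
count_events <- function(events, by = c("type", "zygosity")) {
  by <- match.arg(by)
  levels <- if (by == "type") {
    c("inversion", "deletion", "duplication", "translocation")
  } else {
    c("homozygous", "heterozygous")
  }
  table(factor(events[[by]], levels = levels))
}

#' Count rearrangement processes per group
#'
#' A process groups the events marked as arising from one rearrangement
#' (shared `process_id`): paired inversions formed together count once.
#'
#' @param events SV event `data.frame`.
#' @return A table of distinct process counts per group.
#' @export
count_processes <- function(events) {
  c(tapply(events$process_id, events$group,
           function(x) length(unique(x))))
}

#' Read a junction-characteristics count table
#'
#' TSV with per-group counts of inversions with an overlapped
#' (microhomologous) sequence, deletions/insertions on the overlap,
#' deletions/insertions at the adjacent area, and the group total.
#'
#' @param path Path to the TSV.
#' @return A `data.frame` with the counts plus `<column>_pct` percentages
#'   of the group total, rounded half-up to integers.
#' @export
read_junction_counts_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("group", "overlap_n", "del_on_overlap_n", "ins_on_overlap_n",
            "del_adjacent_n", "ins_adjacent_n", "total_inversions")
  if (!all(need %in% names(d))) {
    stop("junction count table needs columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  for (col in setdiff(need, c("group", "total_inversions"))) {
    d[[paste0(col, "_pct")]] <-
      round_half_up(100 * d[[col]] / d$total_inversions)
  }
  d
}

#' Read a gene-impact table
#'
#' TSV with columns `group`, `impact` (`moderate`/`high`/`silent`),
#' `category`, `mean`, `se`, `mean_hom`, `se_hom` (homozygous-only values),
#' plus printed `total_*` rows retained for cross-checks.
#'
#' @param path Path to the TSV.
#' @return A `data.frame`.
#' @export
read_impact_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("group", "impact", "category", "mean", "se")
  if (!all(need %in% names(d))) {
    stop("impact table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  d
}

MODERATE_CATEGORIES <- c("missense", "in_frame_deletion", "in_frame_insertion")
HIGH_CATEGORIES <- c("start_loss", "premature_stop", "frameshift",
                     "truncation", "complete_deletion")
HIGH_SV_CATEGORIES <- c("truncation", "complete_deletion")

#' Gene-impact totals from per-category means
#'
#' Moderate impact totals missense + in-frame InDels; high impact totals
#' start loss + premature stop + frameshift + gene truncation + complete
#' gene deletion; the SV-exclusive high total omits the two SV-borne
#' categories (truncation, complete deletion).
#'
#' @param impact A `data.frame` with columns `group`, `category`, `mean`
#'   (printed `total_*` rows, if present, are ignored here).
#' @return A `data.frame` with one row per group and columns
#'   `moderate_total`, `high_total`, `high_total_excl_sv`.
#' @export
impact_totals <- function(impact) {
  impact <- impact[!startsWith(impact$category, "total"), ]
  groups <- unique(impact$group)
  do.call(rbind, lapply(groups, function(g) {
    d <- impact[impact$group == g, ]
    val <- function(cats) sum(d$mean[d$category %in% cats])
    data.frame(group = g,
               moderate_total = val(MODERATE_CATEGORIES),
               high_total = val(HIGH_CATEGORIES),
               high_total_excl_sv = val(setdiff(HIGH_CATEGORIES,
                                                HIGH_SV_CATEGORIES)),
               stringsAsFactors = FALSE)
  }))
}

#' Gene-impact summary from per-sample consequence counts
#'
#' Computes the mean +/- standard error of affected-gene counts per
#' category within each group, and the three derived totals of
#' [impact_totals()]. At least two samples per group are required for a
#' standard error.
#'
#' @param per_sample `data.frame` with columns `group`, `sample`, and one
#'   column per consequence category (`missense`, `in_frame_deletion`,
#'   `in_frame_insertion`, `start_loss`, `premature_stop`, `frameshift`,
#'   `truncation`, `complete_deletion`).
#' @return A list with `by_category` (group x category means and SEs) and
#'   `totals` (the [impact_totals()] table computed on the means).
#' @export
impact_summary <- function(per_sample) {
  cats <- c(MODERATE_CATEGORIES, HIGH_CATEGORIES)
  missing_cols <- setdiff(cats, names(per_sample))
  if (length(missing_cols)) {
    stop("per-sample table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  groups <- unique(per_sample$group)
  by_cat <- do.call(rbind, lapply(groups, function(g) {
    d <- per_sample[per_sample$group == g, ]
    if (nrow(d) < 2L) {
      stop("group ", g, " has fewer than 2 samples: no standard error",
           call. = FALSE)
    }
    do.call(rbind, lapply(cats, function(cc) {
      v <- d[[cc]]
      data.frame(group = g, category = cc, mean = mean(v),
                 se = stats::sd(v) / sqrt(length(v)),
                 stringsAsFactors = FALSE)
    }))
  }))
  list(by_category = by_cat, totals = impact_totals(by_cat))
}
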