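# Consensus of the two substrate-prediction approaches and the dataset-level
# summary statistics (counts and printed-precision percentages).

#' Combine the two substrate assignments per cluster
#'
#' Joins the homology-based and voting-based assignments over the universe
#' of detected clusters and computes the union / intersection / agreement
#' counts. Agreement compares substrates after normalization (case-fold and
#' trim); no glycan-synonym merging is applied.
#'
#' @param homology assignments with columns `cgc_id`, `substrate`
#'   (unassigned clusters may be absent or carry `NA`).
#' @param voting same layout for the voting approach.
#' @param universe character vector of all detected cluster ids; every
#'   assigned id must belong to it.
#' @return a list with `assignments` (tibble: `cgc_id`,
#'   `substrate_homology`, `substrate_voting`, `both`, `agree`, one row per
#'   cluster in `universe`) and `counts` (named list: `n_universe`, `n_a1`,
#'   `n_a2`, `n_union`, `n_both`, `n_agree`).
#' @export
combine_assignments <- function(homology, voting, universe) {
  pick <- function(x) {
    x <- x[!is.na(x$substrate), c("cgc_id", "substrate"), drop = FALSE]
    if (anyDuplicated(x$cgc_id)) {
      stop("multiple assignments for one cgc_id", call. = FALSE)
    }
    x
  }
  a1 <- pick(homology)
  a2 <- pick(voting)
  outside <- setdiff(c(a1$cgc_id, a2$cgc_id), universe)
  if (length(outside) > 0) {
    stop("assigned cgc_id(s) outside the universe: ",
         paste(head(outside, 3), collapse = ", "), call. = FALSE)
  }
  s1 <- a1$substrate[match(universe, a1$cgc_id)]
  s2 <- a2$substrate[match(universe, a2$cgc_id)]
  both <- !is.na(s1) & !is.na(s2)
  agree <- both & norm_substrate(s1) == norm_substrate(s2)
  assignments <- tibble::tibble(
    cgc_id = universe,
    substrate_homology = s1,
    substrate_voting = s2,
    both = both,
    agree = agree
  )
  counts <- list(
    n_universe = length(universe),
    n_a1 = sum(!is.na(s1)),
    n_a2 = sum(!is.na(s2)),
    n_union = sum(!is.na(s1) | !is.na(s2)),
    n_both = sum(both),
    n_agree = sum(agree)
  )
  list(assignments = assignments, counts = counts)
}

#' Dataset-level summary statistics
#'
#' Computes the per-dataset counts reported for microbiome CAZyme/CGC
#' catalogs: genome, protein and CAZyme totals, cluster totals, how many
#' genomes encode CAZymes/clusters, how many CAZymes sit inside clusters,
#' and per-approach assignment coverage with per-substrate cluster counts.
#'
#' @param genes classified gene tibble for the whole dataset
#'   ([classify_genes()] output).
#' @param cgc_genes cluster member genes ([find_cgcs()] output).
#' @param homology,voting assignment tibbles (`cgc_id`, `substrate`).
#' @param decimals decimal places for the percentage rows (default 2).
#' @return a list with `counts` (named list), `percentages` (named list,
#'   printed precision) and `substrate_counts` (tibble: `substrate`,
#'   `approach` in `homology`/`voting`/`union`, `cgc_count`).
#' @export
summarize_dataset <- function(genes, cgc_genes, homology, voting, decimals = 2) {
  asg <- function(x) x[!is.na(x$substrate), , drop = FALSE]
  a1 <- asg(homology)
  a2 <- asg(voting)
  genome_of_cgc <- function(cgcs) {
    unique(cgc_genes$genome_id[cgc_genes$cgc_id %in% cgcs])
  }
  caz_in_cgcs <- cgc_genes[cgc_genes$gene_class == "CAZyme", , drop = FALSE]
  counts <- list(
    n_mags = length(unique(genes$genome_id)),
    n_proteins = nrow(genes),
    n_cazymes = sum(genes$gene_class == "CAZyme"),
    n_cgcs = length(unique(cgc_genes$cgc_id)),
    n_mags_with_cazymes = length(unique(genes$genome_id[genes$gene_class == "CAZyme"])),
    n_mags_with_cgcs = length(unique(cgc_genes$genome_id)),
    n_cazymes_in_cgcs = nrow(caz_in_cgcs),
    homology = list(
      n_cgcs_assigned = nrow(a1),
      n_mags_assigned = length(genome_of_cgc(a1$cgc_id)),
      n_cazymes_assigned = sum(caz_in_cgcs$cgc_id %in% a1$cgc_id)
    ),
    voting = list(
      n_cgcs_assigned = nrow(a2),
      n_mags_assigned = length(genome_of_cgc(a2$cgc_id)),
      n_cazymes_assigned = sum(caz_in_cgcs$cgc_id %in% a2$cgc_id)
    )
  )
  pct <- function(n, d) if (d > 0) percentage(n, d, decimals) else NA_real_
  percentages <- list(
    pct_cazymes = pct(counts$n_cazymes, counts$n_proteins),
    pct_mags_with_cazymes = pct(counts$n_mags_with_cazymes, counts$n_mags),
    pct_mags_with_cgcs = pct(counts$n_mags_with_cgcs, counts$n_mags),
    pct_cazymes_in_cgcs = pct(counts$n_cazymes_in_cgcs, counts$n_cazymes),
    pct_cgcs_assigned_homology = pct(counts$homology$n_cgcs_assigned, counts$n_cgcs),
    pct_cgcs_assigned_voting = pct(counts$voting$n_cgcs_assigned, counts$n_cgcs),
    pct_mags_assigned_homology = pct(counts$homology$n_mags_assigned, counts$n_mags),
    pct_mags_assigned_voting = pct(counts$voting$n_mags_assigned, counts$n_mags)
  )
  tab <- function(x, approach) {
    if (nrow(x) == 0) {
      return(tibble::tibble(substrate = character(), approach = character(),
                            cgc_count = integer()))
    }
    t <- table(x$substrate)
    tibble::tibble(substrate = names(t), approach = approach,
                   cgc_count = as.integer(t))
  }
  union_asg <- dplyr::bind_rows(
    a1[c("cgc_id", "substrate")],
    a2[!(a2$cgc_id %in% a1$cgc_id), c("cgc_id", "substrate"), drop = FALSE]
  )
  substrate_counts <- dplyr::bind_rows(
    tab(a1, "homology"), tab(a2, "voting"), tab(union_asg, "union")
  ) |>
    dplyr::arrange(approach, dplyr::desc(cgc_count), substrate)
  list(counts = counts, percentages = percentages,
       substrate_counts = substrate_counts)
}

#' Top substrates by cluster count
#'
#' Ranks the substrates of one approach by the number of clusters assigned
#' to them (the usual "top 20 most abundant substrate groups" view).
#'
#' @param substrate_counts the `substrate_counts` tibble from
#'   [summarize_dataset()].
#' @param approach one of `"homology"`, `"voting"`, `"union"`.
#' @param n how many substrates to keep.
#' @return the top-`n` rows for that approach.
#' @export
top_substrates <- function(substrate_counts, approach = "union", n = 20) {
  x <- substrate_counts[substrate_counts$approach == approach, , drop = FALSE]
  head(x[order(-x$cgc_count, x$substrate), , drop = FALSE], n)
}
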