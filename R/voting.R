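# Substrate prediction, approach 2: each CAZyme in a cluster is annotated
# with a substrate through the subfamily -> EC -> substrate mapping table,
# and the cluster's substrate is the one backed by the most CAZymes
# (plurality; ties yield no call). CAZymes whose subfamily is absent from
# the table, or mapped but without a curated substrate, abstain.

#' Substrate of a single CAZyme subfamily
#'
#' Looks a k-mer subfamily name (e.g. `GH130_e13`) up in the mapping table
#' and returns its curated substrate, or `NA` when the subfamily is absent
#' or has no substrate (subfamilies without experimentally characterized
#' members carry no EC number and hence no substrate).
#'
#' @param ecami_subfamily subfamily name(s); vectorized.
#' @param subfam_map mapping table ([read_subfamily_map()] layout).
#' @return character vector of substrates, `NA` where unmapped.
#' @export
annotate_cazyme_substrate <- function(ecami_subfamily, subfam_map) {
  i <- match(ecami_subfamily, subfam_map$ecami_subfamily)
  out <- subfam_map$substrate[i]
  out[is.na(i)] <- NA_character_
  out
}

#' Majority vote over a cluster's CAZyme substrates
#'
#' Each CAZyme with a mapped substrate casts exactly one vote; the winner
#' is the unique substrate with the strictly highest count, provided it
#' reaches `min_votes`. A tied top count yields no winner (the tied
#' substrates are reported alphabetically); unmapped CAZymes abstain.
#' With `strict_majority = TRUE` the winner must additionally be backed by
#' more than half of the annotated CAZymes.
#'
#' @param cgc_id cluster id.
#' @param subfamilies the eCAMI subfamily of each CAZyme gene in the
#'   cluster (`NA` for CAZymes without a subfamily call).
#' @param subfam_map mapping table ([read_subfamily_map()] layout).
#' @param min_votes minimum winning vote count (default 1).
#' @param strict_majority require > 50% of annotated CAZymes (default
#'   plurality).
#' @return a one-row tibble: `cgc_id`, `substrate` (`NA` when no winner),
#'   `votes` (serialized as `A:3;B:1`, descending count then name),
#'   `n_cazymes`, `n_annotated`, `tied` (semicolon-joined, empty unless the
#'   top count is tied).
#' @export
vote_substrate <- function(cgc_id, subfamilies, subfam_map,
                           min_votes = 1, strict_majority = FALSE) {
  stopifnot(min_votes >= 1)
  subs <- annotate_cazyme_substrate(subfamilies, subfam_map)
  subs <- subs[!is.na(subs)]
  n_annotated <- length(subs)
  winner <- NA_character_
  tied <- character()
  votes <- ""
  if (n_annotated > 0) {
    tally <- sort(table(subs), decreasing = TRUE)
    nm <- names(tally)
    # stable serialization: descending count, then alphabetical
    o <- order(-as.integer(tally), nm)
    tally <- as.integer(tally)[o]
    nm <- nm[o]
    votes <- paste(sprintf("%s:%d", nm, tally), collapse = ";")
    top <- tally[1]
    at_top <- nm[tally == top]
    if (length(at_top) > 1) {
      tied <- sort(at_top)
    } else if (top >= min_votes &&
               (!strict_majority || top > n_annotated / 2)) {
      winner <- at_top
    }
  }
  tibble::tibble(
    cgc_id = cgc_id,
    substrate = winner,
    votes = votes,
    n_cazymes = length(subfamilies),
    n_annotated = n_annotated,
    tied = paste(tied, collapse = ";")
  )
}

#' Voting-based substrate assignment for all clusters
#'
#' Runs [vote_substrate()] over every detected cluster, using the eCAMI
#' subfamily recorded for each CAZyme member gene.
#'
#' @param cgc_genes cluster member genes ([find_cgcs()] output, carrying
#'   `gene_class` and `ecami_subfamily` columns).
#' @param subfam_map mapping table ([read_subfamily_map()] layout).
#' @param min_votes,strict_majority passed to [vote_substrate()].
#' @return a tibble with one row per cluster (including clusters with no
#'   winner, `substrate = NA`).
#' @export
assign_substrates_voting <- function(cgc_genes, subfam_map,
                                     min_votes = 1, strict_majority = FALSE) {
  caz <- cgc_genes[cgc_genes$gene_class == "CAZyme", , drop = FALSE]
  per_cgc <- split(caz$ecami_subfamily, caz$cgc_id)
  out <- lapply(sort(unique(cgc_genes$cgc_id)), function(cid) {
    vote_substrate(cid, per_cgc[[cid]] %||% character(), subfam_map,
                   min_votes = min_votes, strict_majority = strict_majority)
  })
  dplyr::bind_rows(out)
}
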