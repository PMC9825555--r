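# Multi-tool CAZyme consensus and per-gene signature classification.
#
# CAZymes are called by three independent tools (an HMM scan of family
# models, a pairwise-alignment search of a curated sequence database, and a
# k-mer subfamily classifier); a protein is accepted as a CAZyme only when
# at least `min_tools` DISTINCT tools report it. Each gene then receives
# exactly one signature class among CAZyme, TC (transporter), TF
# (transcription factor), STP (signal transduction protein) or Other.

#' Multi-tool CAZyme consensus
#'
#' Retains a protein as a CAZyme when the number of distinct tools
#' reporting any CAZyme family for it is at least `min_tools` (default 2 of
#' the 3 tools). The retained family set is the union of families over the
#' reporting tools; names reported by the k-mer tool in subfamily form
#' (`GH130_e13`) contribute their family prefix (`GH130`) to the family set
#' and are additionally recorded as the protein's eCAMI subfamily.
#'
#' @param hits per-tool CAZyme calls: a tibble with columns `protein_id`,
#'   `tool` (`hmm`, `alignment` or `kmer`), `family`, `score`
#'   ([read_cazyme_hits()] layout).
#' @param min_tools minimum number of distinct reporting tools (1--3).
#' @return a tibble with one row per retained protein: `protein_id`,
#'   `cazyme_families` (semicolon-joined, sorted), `ecami_subfamily`
#'   (`NA` when the k-mer tool reported no subfamily).
#' @examples
#' hits <- tibble::tibble(
#'   protein_id = c("p1", "p1", "p2"),
#'   tool = c("hmm", "kmer", "hmm"),
#'   family = c("GH5", "GH5_e7", "GH13"),
#'   score = c(1e-20, 0.9, 1e-10)
#' )
#' consensus_cazyme(hits) # p1 kept (2 tools), p2 dropped (1 tool)
#' @export
consensus_cazyme <- function(hits, min_tools = 2) {
  stopifnot(min_tools %in% 1:3)
  bad <- setdiff(unique(hits$tool), CAZYME_TOOLS)
  if (length(bad) > 0) {
    stop("unknown tool name(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (nrow(hits) == 0) {
    return(tibble::tibble(protein_id = character(),
                          cazyme_families = character(),
                          ecami_subfamily = character()))
  }
  hits |>
    dplyr::group_by(protein_id) |>
    dplyr::summarise(
      n_tools = dplyr::n_distinct(tool),
      cazyme_families = paste(
        sort(unique(ifelse(is_ecami_subfamily(family),
                           ecami_family_prefix(family), family))),
        collapse = ";"
      ),
      ecami_subfamily = {
        sub <- sort(family[tool == "kmer" & is_ecami_subfamily(family)])
        if (length(sub) > 0) sub[1] else NA_character_
      },
      .groups = "drop"
    ) |>
    dplyr::filter(n_tools >= min_tools) |>
    dplyr::select(protein_id, cazyme_families, ecami_subfamily)
}

#' Assign one signature class per gene
#'
#' Combines the CAZyme consensus map with the TC/TF/STP annotation table
#' and gives every gene exactly one class. When a protein carries several
#' calls the precedence CAZyme > TC > TF > STP applies, so a CAZyme call is
#' never masked (CAZymes anchor the cluster search); genes with no call are
#' class `Other`.
#'
#' @param genes gene tibble ([read_gff()] layout).
#' @param cazyme_map output of [consensus_cazyme()].
#' @param signature_table TC/TF/STP calls ([read_signature_labels()] layout).
#' @param precedence class precedence used to resolve multiple calls,
#'   highest first.
#' @return the gene tibble with added columns `gene_class`,
#'   `cazyme_families`, `ecami_subfamily`, `detail`.
#' @export
classify_genes <- function(genes, cazyme_map, signature_table,
                           precedence = c("CAZyme", "TC", "TF", "STP")) {
  stopifnot(setequal(precedence, SIGNATURE_CLASSES))
  out <- genes |>
    dplyr::left_join(cazyme_map, by = "protein_id") |>
    dplyr::left_join(
      signature_table |>
        dplyr::distinct(protein_id, .keep_all = TRUE) |>
        dplyr::rename(.cls = gene_class),
      by = "protein_id"
    )
  if (is.null(out$detail)) out$detail <- NA_character_
  is_caz <- !is.na(out$cazyme_families)
  other_cls <- out$.cls
  out$gene_class <- ifelse(
    is_caz & !is.na(other_cls),
    # both a CAZyme call and a TC/TF/STP call: apply precedence
    ifelse(match("CAZyme", precedence) < match(other_cls, precedence),
           "CAZyme", other_cls),
    ifelse(is_caz, "CAZyme", ifelse(is.na(other_cls), "Other", other_cls))
  )
  out$cazyme_families[out$gene_class != "CAZyme"] <- NA_character_
  out$ecami_subfamily[out$gene_class != "CAZyme"] <- NA_character_
  out$.cls <- NULL
  out
}
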