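# Substrate prediction, approach 1: homology mapping of cluster proteins
# against a database of experimentally characterized PULs with curated
# substrates. For each (CGC, PUL) pair the pairwise protein hits are
# reduced to a one-to-one matching, summed bit scores rank the candidate
# PULs, and the best eligible PUL's substrate is transferred to the CGC.
# Eligibility requires at least one matched CAZyme pair plus at least one
# matched pair of another signature class (TC, TF or STP).

#' One-to-one protein pairing between a cluster and a PUL
#'
#' Filters the hits to significant ones (`e_value <= min_evalue`), sorts by
#' descending bit score (ties by query then subject id, for determinism)
#' and greedily accepts pairs so that each query protein and each subject
#' protein appears in at most one accepted pair. The one-to-one constraint
#' stops a single promiscuous protein from inflating the summed score.
#'
#' @param hits pairwise hits ([read_hits()] layout), already restricted to
#'   (cluster member, PUL member) protein pairs.
#' @param min_evalue significance cutoff on the alignment e-value
#'   (default `1e-4`).
#' @return the accepted subset of `hits`, sorted by descending bit score.
#' @export
pair_hits <- function(hits, min_evalue = 1e-4) {
  hits <- hits[hits$e_value <= min_evalue, , drop = FALSE]
  if (nrow(hits) == 0) return(tibble::as_tibble(hits))
  hits <- hits[order(-hits$bit_score, hits$query_protein, hits$subject_protein), ,
               drop = FALSE]
  used_q <- character()
  used_s <- character()
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    q <- hits$query_protein[i]
    s <- hits$subject_protein[i]
    if (!(q %in% used_q) && !(s %in% used_s)) {
      keep[i] <- TRUE
      used_q <- c(used_q, q)
      used_s <- c(used_s, s)
    }
  }
  tibble::as_tibble(hits[keep, , drop = FALSE])
}

#' Score one candidate PUL for one cluster
#'
#' Sums the bit scores of the accepted pairs and counts the matched
#' signature pairs that decide eligibility: a CAZyme pair has a CAZyme on
#' BOTH sides; an other-signature pair shares one class in `{TC, TF, STP}`
#' on both sides. Proteins without a known class are treated as `Other`
#' (they contribute to the score but not to eligibility).
#'
#' @param cgc_id,pul_id identifiers for the scored pair.
#' @param pairs accepted pairs from [pair_hits()].
#' @param class_of named character vector mapping protein id -> gene class
#'   (query and subject proteins).
#' @return a one-row tibble: `cgc_id`, `pul_id`, `summed_bits`, `n_pairs`,
#'   `n_cazyme_pairs`, `n_other_signature_pairs`, `eligible`.
#' @export
score_pul <- function(cgc_id, pul_id, pairs, class_of) {
  cls <- function(p) {
    k <- unname(class_of[p])
    ifelse(is.na(k), "Other", k)
  }
  qc <- cls(pairs$query_protein)
  sc <- cls(pairs$subject_protein)
  n_caz <- sum(qc == "CAZyme" & sc == "CAZyme")
  n_other <- sum(qc == sc & qc %in% c("TC", "TF", "STP"))
  tibble::tibble(
    cgc_id = cgc_id,
    pul_id = pul_id,
    summed_bits = sum(pairs$bit_score),
    n_pairs = nrow(pairs),
    n_cazyme_pairs = n_caz,
    n_other_signature_pairs = n_other,
    eligible = n_caz >= 1 && n_other >= 1
  )
}

#' Best PUL hit for one cluster
#'
#' Scores every candidate PUL with hits to the cluster and returns the
#' eligible match with the highest summed bit score; ties are broken by
#' more accepted pairs, then by lexicographically smaller PUL id. Returns a
#' zero-row tibble when no PUL is eligible.
#'
#' @param cgc_id cluster id.
#' @param cgc_proteins character vector of the cluster's protein ids.
#' @param pul_proteins PUL membership table ([read_pul_proteins()] layout).
#' @param pul_substrates PUL substrate map ([read_pul_substrates()] layout);
#'   every scored PUL id must be present.
#' @param hits all pairwise hits, cluster proteins as queries and PUL
#'   proteins as subjects.
#' @param class_of named vector protein id -> gene class for both sides.
#' @param min_evalue passed to [pair_hits()].
#' @return a tibble with 0 or 1 row: `cgc_id`, `substrate`, `pul_id`,
#'   `summed_bits`, `n_pairs`, `n_cazyme_pairs`, `n_other_signature_pairs`.
#' @export
best_pul <- function(cgc_id, cgc_proteins, pul_proteins, pul_substrates,
                     hits, class_of, min_evalue = 1e-4) {
  empty <- tibble::tibble(
    cgc_id = character(), substrate = character(), pul_id = character(),
    summed_bits = double(), n_pairs = integer(),
    n_cazyme_pairs = integer(), n_other_signature_pairs = integer()
  )
  hits <- hits[hits$query_protein %in% cgc_proteins, , drop = FALSE]
  if (nrow(hits) == 0) return(empty)
  prot2pul <- split(pul_proteins$pul_id, pul_proteins$protein_id)
  cand_puls <- sort(unique(unlist(prot2pul[unique(hits$subject_protein)],
                                  use.names = FALSE)))
  scores <- lapply(cand_puls, function(pid) {
    members <- pul_proteins$protein_id[pul_proteins$pul_id == pid]
    pairs <- pair_hits(hits[hits$subject_protein %in% members, , drop = FALSE],
                       min_evalue = min_evalue)
    score_pul(cgc_id, pid, pairs, class_of)
  })
  scores <- dplyr::bind_rows(scores)
  scores <- scores[scores$eligible, , drop = FALSE]
  if (nrow(scores) == 0) return(empty)
  scores <- scores[order(-scores$summed_bits, -scores$n_pairs, scores$pul_id), ,
                   drop = FALSE]
  best <- scores[1, , drop = FALSE]
  i <- match(best$pul_id, pul_substrates$pul_id)
  if (is.na(i)) {
    stop("PUL ", best$pul_id, " has no entry in the substrate map", call. = FALSE)
  }
  tibble::tibble(
    cgc_id = best$cgc_id,
    substrate = pul_substrates$substrate[i],
    pul_id = best$pul_id,
    summed_bits = best$summed_bits,
    n_pairs = as.integer(best$n_pairs),
    n_cazyme_pairs = as.integer(best$n_cazyme_pairs),
    n_other_signature_pairs = as.integer(best$n_other_signature_pairs)
  )
}

#' Homology-based substrate assignment for all clusters
#'
#' Runs [best_pul()] for every detected cluster. The returned class map for
#' the query side comes from the cluster gene table; the subject side from
#' the PUL membership table.
#'
#' @param cgc_genes cluster member genes ([find_cgcs()] output).
#' @param pul_proteins,pul_substrates the PUL database tables.
#' @param hits pairwise hits ([read_hits()] layout).
#' @param min_evalue significance cutoff (default `1e-4`).
#' @return a tibble with one row per cluster that received an assignment.
#' @export
assign_substrates_homology <- function(cgc_genes, pul_proteins, pul_substrates,
                                       hits, min_evalue = 1e-4) {
  class_of <- c(
    setNames(cgc_genes$gene_class, cgc_genes$protein_id),
    setNames(pul_proteins$gene_class, pul_proteins$protein_id)
  )
  per_cgc <- split(cgc_genes$protein_id, cgc_genes$cgc_id)
  out <- lapply(sort(names(per_cgc)), function(cid) {
    best_pul(cid, per_cgc[[cid]], pul_proteins, pul_substrates,
             hits, class_of, min_evalue = min_evalue)
  })
  dplyr::bind_rows(out)
}
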