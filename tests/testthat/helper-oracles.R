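# Brute-force oracles and small builders shared across the suite. The
# oracles are deliberately naive (exhaustive enumeration) and independent
# of the implementation paths they check.

# build a classified gene tibble for one contig from a class vector
genes_from_classes <- function(classes, genome = "G1", contig = "c1") {
  n <- length(classes)
  tibble::tibble(
    gene_id = sprintf("%s_%s_g%03d", genome, contig, seq_len(n)),
    genome_id = genome,
    contig_id = contig,
    start = (seq_len(n) - 1L) * 1000L + 1L,
    end = (seq_len(n) - 1L) * 1000L + 900L,
    strand = "+",
    protein_id = sprintf("%s_%s_g%03d", genome, contig, seq_len(n)),
    ordinal = seq_len(n) - 1L,
    gene_class = classes,
    cazyme_families = ifelse(classes == "CAZyme", "GH5", NA_character_),
    ecami_subfamily = NA_character_,
    detail = NA_character_
  )
}

# exhaustive maximal-window enumerator for cluster detection: every
# contiguous window whose ends are signature genes and whose internal
# non-signature runs are <= max_insert is chain-valid; maximal chain-valid
# windows are then filtered by the composition rule. Returns a list of
# 1-based c(start, end) index pairs, left to right.
oracle_cgcs <- function(classes, max_insert = 2,
                        required_other = c("TC", "TF", "STP"),
                        active = c("CAZyme", "TC", "TF", "STP"),
                        require_all = FALSE) {
  n <- length(classes)
  if (n == 0) return(list())
  is_sig <- classes %in% active
  chain_valid <- function(i, j) {
    if (!is_sig[i] || !is_sig[j]) return(FALSE)
    run <- 0
    for (t in i:j) {
      if (is_sig[t]) run <- 0 else {
        run <- run + 1
        if (run > max_insert) return(FALSE)
      }
    }
    TRUE
  }
  wins <- list()
  for (i in seq_len(n)) for (j in i:n) {
    if (chain_valid(i, j)) wins[[length(wins) + 1L]] <- c(i, j)
  }
  maximal <- Filter(function(w) {
    !any(vapply(wins, function(v) {
      v[1] <= w[1] && v[2] >= w[2] && !(v[1] == w[1] && v[2] == w[2])
    }, logical(1)))
  }, wins)
  keep <- Filter(function(w) {
    cls <- classes[w[1]:w[2]]
    has_caz <- any(cls == "CAZyme")
    present <- intersect(required_other, cls)
    ok <- if (require_all) length(present) == length(required_other)
          else length(present) > 0
    has_caz && ok
  }, maximal)
  keep[order(vapply(keep, `[`, 0, 1))]
}

# cluster index spans (1-based) as produced by find_cgcs on one contig
found_spans <- function(classes, params = cgc_params()) {
  members <- find_cgcs(genes_from_classes(classes), params)
  if (nrow(members) == 0) return(list())
  lapply(split(members$ordinal, members$cgc_id)[
    unique(members$cgc_id)], function(o) c(min(o) + 1L, max(o) + 1L))
}

# exhaustive maximum-weight one-to-one matching value over a hit table
oracle_matching_value <- function(hits) {
  qs <- unique(hits$query_protein)
  best <- 0
  rec <- function(qi, used_s, acc) {
    if (qi > length(qs)) {
      best <<- max(best, acc)
      return(invisible())
    }
    rec(qi + 1L, used_s, acc)
    hq <- hits[hits$query_protein == qs[qi], , drop = FALSE]
    for (r in seq_len(nrow(hq))) {
      s <- hq$subject_protein[r]
      if (!(s %in% used_s)) rec(qi + 1L, c(used_s, s), acc + hq$bit_score[r])
    }
  }
  rec(1L, character(), 0)
  best
}

# random contig class vector, biased towards Other genes
random_classes <- function(n) {
  sample(c("CAZyme", "TC", "TF", "STP", "Other"), n, replace = TRUE,
         prob = c(0.2, 0.12, 0.08, 0.08, 0.52))
}

make_hit_tbl <- function(q, s, bits, evalue = 1e-30) {
  tibble::tibble(query_protein = q, subject_protein = s,
                 identity = 90, e_value = evalue, bit_score = bits)
}
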