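# CGC detection: scan each contig's ordered, classified gene list and chain
# signature genes into clusters, allowing a bounded number of inserted
# non-signature genes between consecutive signature genes.

#' CGC detection parameters
#'
#' @param max_insert maximum number of consecutive non-signature genes
#'   allowed between two signature genes of the same cluster (default 2,
#'   counted in genes, not base pairs).
#' @param required_other which of the non-CAZyme signature classes can
#'   satisfy the cluster composition rule. By default a cluster needs at
#'   least one CAZyme plus at least one gene of any class in
#'   `{TC, TF, STP}`.
#' @param active_signature_set classes treated as chain-extending signature
#'   genes during the scan (default all four; genes outside this set count
#'   as inserted non-signature genes).
#' @param require_all if `TRUE`, every class in `required_other` must be
#'   present (strict mode) instead of at least one.
#' @param keep_flanks if `TRUE`, clusters retain up to `max_insert`
#'   flanking non-signature genes on each side instead of being trimmed to
#'   their first and last signature gene.
#' @return a list of validated parameters.
#' @export
cgc_params <- function(max_insert = 2,
                       required_other = c("TC", "TF", "STP"),
                       active_signature_set = c("CAZyme", "TC", "TF", "STP"),
                       require_all = FALSE,
                       keep_flanks = FALSE) {
  stopifnot(
    length(max_insert) == 1, !is.na(max_insert), max_insert >= 0,
    all(required_other %in% c("TC", "TF", "STP")), length(required_other) > 0,
    all(active_signature_set %in% SIGNATURE_CLASSES),
    "CAZyme" %in% active_signature_set,
    is.logical(require_all), is.logical(keep_flanks)
  )
  list(
    max_insert = as.integer(max_insert),
    required_other = required_other,
    active_signature_set = active_signature_set,
    require_all = require_all,
    keep_flanks = keep_flanks
  )
}

# scan one contig (rows sorted by ordinal); returns integer cluster index
# per gene (NA outside clusters), numbered left to right from 1
scan_contig <- function(classes, params) {
  n <- length(classes)
  member <- rep(NA_integer_, n)
  sig <- which(classes %in% params$active_signature_set)
  if (length(sig) == 0) return(member)
  # split signature positions into chains at gaps > max_insert
  gap_too_big <- c(FALSE, diff(sig) - 1L > params$max_insert)
  chain_id <- cumsum(gap_too_big)
  next_id <- 1L
  for (cid in unique(chain_id)) {
    pos <- sig[chain_id == cid]
    lo <- pos[1]
    hi <- pos[length(pos)]
    cls <- classes[lo:hi]
    ok_caz <- any(cls == "CAZyme")
    present <- intersect(params$required_other, cls)
    ok_other <- if (params$require_all) {
      length(present) == length(params$required_other)
    } else {
      length(present) > 0
    }
    if (ok_caz && ok_other) {
      if (params$keep_flanks) {
        lo <- max(1L, lo - params$max_insert)
        hi <- min(n, hi + params$max_insert)
      }
      member[lo:hi] <- next_id
      next_id <- next_id + 1L
    }
  }
  member
}

#' Detect CAZyme gene clusters
#'
#' Scans each contig left to right and chains signature genes (classes in
#' `active_signature_set`) into one candidate cluster whenever at most
#' `max_insert` consecutive non-signature genes separate two signature
#' genes. Candidates are trimmed to their first and last signature gene and
#' kept only when they contain at least one CAZyme and at least one gene of
#' a class in `required_other`. Kept clusters never overlap and are
#' numbered left to right from 1 per contig, with ids of the form
#' `<genome>_<contig>|CGC<n>`.
#'
#' @param genes classified gene tibble ([classify_genes()] output), any
#'   number of genomes/contigs; must be sorted by ordinal within contig.
#' @param params a [cgc_params()] list.
#' @return a tibble of cluster member genes: the input columns plus
#'   `cgc_id`. Genes outside clusters are dropped.
#' @examples
#' # a CAZyme alone never forms a cluster; CAZyme + transporter does
#' @export
find_cgcs <- function(genes, params = cgc_params()) {
  stopifnot(is.data.frame(genes), "gene_class" %in% names(genes))
  if (nrow(genes) == 0) {
    out <- genes
    out$cgc_id <- character()
    return(tibble::as_tibble(out))
  }
  pieces <- split(genes, paste(genes$genome_id, genes$contig_id, sep = "\r"),
                  drop = TRUE)
  # contig scan order follows (genome, contig) sort for stable numbering
  pieces <- pieces[order(names(pieces))]
  out <- lapply(pieces, function(g) {
    if (anyDuplicated(g$ordinal)) {
      stop("gene ordinals must be unique within a contig", call. = FALSE)
    }
    if (is.unsorted(g$ordinal)) {
      stop("genes must be sorted by ordinal within each contig", call. = FALSE)
    }
    member <- scan_contig(g$gene_class, params)
    g <- g[!is.na(member), , drop = FALSE]
    idx <- member[!is.na(member)]
    g$cgc_id <- sprintf("%s_%s|CGC%d", g$genome_id, g$contig_id, idx)
    g
  })
  tibble::as_tibble(dplyr::bind_rows(out))
}

#' Summarize detected clusters
#'
#' One row per cluster with its span and per-class gene counts.
#'
#' @param cgc_genes output of [find_cgcs()].
#' @return a tibble with columns `cgc_id`, `genome_id`, `contig_id`,
#'   `start_ordinal`, `end_ordinal`, `n_genes`, one `n_<class>` count per
#'   gene class, and the semicolon-joined member `gene_ids`.
#' @export
cgc_summary <- function(cgc_genes) {
  if (nrow(cgc_genes) == 0) {
    return(tibble::tibble(
      cgc_id = character(), genome_id = character(), contig_id = character(),
      start_ordinal = integer(), end_ordinal = integer(), n_genes = integer(),
      n_cazyme = integer(), n_tc = integer(), n_tf = integer(),
      n_stp = integer(), n_other = integer(), gene_ids = character()
    ))
  }
  cgc_genes |>
    dplyr::group_by(cgc_id, genome_id, contig_id) |>
    dplyr::summarise(
      start_ordinal = min(ordinal),
      end_ordinal = max(ordinal),
      n_genes = dplyr::n(),
      n_cazyme = sum(gene_class == "CAZyme"),
      n_tc = sum(gene_class == "TC"),
      n_tf = sum(gene_class == "TF"),
      n_stp = sum(gene_class == "STP"),
      n_other = sum(gene_class == "Other"),
      gene_ids = paste(gene_id, collapse = ";"),
      .groups = "drop"
    ) |>
    dplyr::arrange(genome_id, contig_id, start_ordinal)
}
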