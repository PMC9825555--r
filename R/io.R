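# Readers and writers for the external formats consumed and produced by the
# pipeline: GFF3 gene coordinates, BLAST tabular (outfmt 6) protein hits,
# curated PUL->substrate and subfamily->EC->substrate mapping tables, and the
# per-tool annotation tables.

#' Read gene coordinates from a GFF3 file
#'
#' Parses `gene` (or, when no `gene` features are present, `CDS`) features
#' and returns one row per gene with 1-based inclusive coordinates, exactly
#' as stored in the file. Genes are sorted by contig and start coordinate
#' (ties broken by end, then gene id) and assigned a 0-based `ordinal` rank
#' along their contig; all downstream clustering operates on ordinals, never
#' on base pairs.
#'
#' @param path path to a GFF3 file whose features carry `ID` attributes.
#' @param genome_id genome label attached to every record. Defaults to the
#'   `genome` attribute when present in the file, otherwise the file's
#'   basename without extension.
#' @return a tibble with columns `gene_id`, `genome_id`, `contig_id`,
#'   `start`, `end`, `strand`, `protein_id`, `ordinal`.
#' @seealso [write_gff()] for the inverse operation.
#' @export
read_gff <- function(path, genome_id = NULL) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  body <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(body) == 0) return(empty_gene_table())

  gff <- as.data.frame(rtracklayer::readGFF(path))
  keep_type <- if (any(gff$type == "gene")) "gene" else "CDS"
  gff <- gff[gff$type == keep_type, , drop = FALSE]
  if (nrow(gff) == 0) return(empty_gene_table())

  if (is.null(gff$ID) || anyNA(gff$ID)) {
    stop("GFF3 features must carry an ID attribute: ", path, call. = FALSE)
  }
  if (any(gff$start > gff$end)) {
    bad <- gff$ID[gff$start > gff$end][1]
    stop("GFF3 record with start > end: ", bad, call. = FALSE)
  }

  inferred <- if (!is.null(gff$genome)) as.character(gff$genome) else NA_character_
  fallback <- genome_id %||% sub("\\.[^.]*$", "", basename(path))

  genes <- tibble::tibble(
    gene_id = as.character(gff$ID),
    genome_id = ifelse(is.na(inferred), fallback, inferred),
    contig_id = as.character(gff$seqid),
    start = as.integer(gff$start),
    end = as.integer(gff$end),
    strand = as.character(gff$strand),
    protein_id = if (!is.null(gff$protein_id)) {
      ifelse(is.na(gff$protein_id), as.character(gff$ID), as.character(gff$protein_id))
    } else {
      as.character(gff$ID)
    }
  )
  genes$strand[is.na(genes$strand) | genes$strand == "*"] <- "."
  if (anyDuplicated(genes[c("genome_id", "gene_id")])) {
    stop("duplicate gene ids within a genome in ", path, call. = FALSE)
  }
  assign_ordinals(genes)
}

empty_gene_table <- function() {
  tibble::tibble(
    gene_id = character(), genome_id = character(), contig_id = character(),
    start = integer(), end = integer(), strand = character(),
    protein_id = character(), ordinal = integer()
  )
}

#' Assign per-contig gene ordinals
#'
#' Sorts genes by (genome, contig, start, end, gene id) and assigns each
#' gene its 0-based rank along its contig. Deterministic for tied starts.
#'
#' @param genes a gene tibble as returned by [read_gff()] (the `ordinal`
#'   column, if present, is recomputed).
#' @return the sorted tibble with an `ordinal` column.
#' @export
assign_ordinals <- function(genes) {
  genes |>
    dplyr::arrange(genome_id, contig_id, start, end, gene_id) |>
    dplyr::group_by(genome_id, contig_id) |>
    dplyr::mutate(ordinal = dplyr::row_number() - 1L) |>
    dplyr::ungroup()
}

#' Write gene records to GFF3
#'
#' Emits one `gene` feature per record with `ID`, `protein_id` and `genome`
#' attributes, preserving 1-based inclusive coordinates so that
#' [read_gff()] round-trips the table exactly.
#'
#' @param genes gene tibble ([read_gff()] layout).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gff <- function(genes, path) {
  lines <- c(
    "##gff-version 3",
    sprintf(
      "%s\tcgckit\tgene\t%d\t%d\t.\t%s\t.\tID=%s;protein_id=%s;genome=%s",
      genes$contig_id, genes$start, genes$end, genes$strand,
      genes$gene_id, genes$protein_id, genes$genome_id
    )
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read pairwise protein hits in BLAST tabular format
#'
#' Parses 12-column tab-separated alignment output (BLAST/DIAMOND
#' `-outfmt 6`: qseqid, sseqid, pident, length, mismatch, gapopen, qstart,
#' qend, sstart, send, evalue, bitscore) into the columns the homology
#' scorer needs.
#'
#' @param path path to the tabular hits file.
#' @return a tibble with columns `query_protein`, `subject_protein`,
#'   `identity` (percent), `e_value`, `bit_score` (bits).
#' @export
read_hits <- function(path) {
  if (!file.exists(path)) stop("hits file not found: ", path, call. = FALSE)
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 1 && nzchar(first) &&
      length(strsplit(first, "\t", fixed = TRUE)[[1]]) != 12) {
    stop("expected 12 tab-separated columns (outfmt 6) in ", path, call. = FALSE)
  }
  hits <- suppressWarnings(
    readr::read_tsv(path, col_names = cols, col_types = "ccdiiiiiiidd",
                    progress = FALSE)
  )
  probs <- readr::problems(hits)
  if (nrow(probs) > 0) {
    stop("malformed hit row(s) in ", path, " (first at line ", probs$row[1], ")",
         call. = FALSE)
  }
  tibble::tibble(
    query_protein = hits$qseqid,
    subject_protein = hits$sseqid,
    identity = hits$pident,
    e_value = hits$evalue,
    bit_score = hits$bitscore
  )
}

read_tsv_strict <- function(path, required, col_types = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- readr::read_tsv(path, col_types = col_types %||% readr::cols(.default = "c"),
                       progress = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    stop("missing column(s) ", paste(missing, collapse = ", "), " in ", path,
         call. = FALSE)
  }
  x
}

#' Read the PUL-to-substrate mapping table
#'
#' The table is a curated two-column TSV (`pul_id`, `substrate`) mapping
#' each experimentally characterized polysaccharide utilization locus to
#' its literature-curated glycan substrate. An empty substrate cell is
#' read as `NA` (substrate unknown).
#'
#' @param path TSV path with header columns `pul_id` and `substrate`.
#' @return a tibble (`pul_id`, `substrate`); duplicate `pul_id` is an error.
#' @export
read_pul_substrates <- function(path) {
  x <- read_tsv_strict(path, c("pul_id", "substrate"))
  if (anyDuplicated(x$pul_id)) {
    stop("duplicate pul_id in ", path, ": ",
         x$pul_id[duplicated(x$pul_id)][1], call. = FALSE)
  }
  x$substrate[!is.na(x$substrate) & trimws(x$substrate) == ""] <- NA_character_
  tibble::as_tibble(x[c("pul_id", "substrate")])
}

#' Read the CAZyme subfamily-to-substrate mapping table
#'
#' Curated TSV mapping k-mer based CAZyme subfamilies (names like
#' `GH130_e13`) through their EC numbers to a substrate. Subfamilies with
#' no experimentally characterized member have no EC number and hence no
#' substrate; those cells are read as `NA`.
#'
#' @param path TSV path with header columns `family`, `ecami_subfamily`,
#'   `ec_numbers` (semicolon-separated, may be empty) and `substrate`.
#' @return a tibble with `ec_numbers` split into a list-column; duplicate
#'   subfamily names are an error.
#' @export
read_subfamily_map <- function(path) {
  x <- read_tsv_strict(path, c("family", "ecami_subfamily", "ec_numbers", "substrate"))
  if (anyDuplicated(x$ecami_subfamily)) {
    stop("duplicate ecami_subfamily in ", path, ": ",
         x$ecami_subfamily[duplicated(x$ecami_subfamily)][1], call. = FALSE)
  }
  x$substrate[!is.na(x$substrate) & trimws(x$substrate) == ""] <- NA_character_
  x$ec_numbers <- lapply(x$ec_numbers, function(s) {
    if (is.na(s) || trimws(s) == "") character() else strsplit(s, ";", fixed = TRUE)[[1]]
  })
  tibble::as_tibble(x[c("family", "ecami_subfamily", "ec_numbers", "substrate")])
}

#' Read both curated substrate mapping tables
#'
#' @param pul_map path to the PUL->substrate TSV ([read_pul_substrates()]).
#' @param subfam_map path to the subfamily->EC->substrate TSV
#'   ([read_subfamily_map()]).
#' @return a list with elements `pul_substrate` and `subfamily`.
#' @export
read_mapping_tables <- function(pul_map, subfam_map) {
  list(
    pul_substrate = read_pul_substrates(pul_map),
    subfamily = read_subfamily_map(subfam_map)
  )
}

#' Read per-tool CAZyme hit calls
#'
#' @param path TSV with header columns `protein_id`, `tool` (one of `hmm`,
#'   `alignment`, `kmer`), `family`, `score`.
#' @return tibble of per-tool CAZyme calls.
#' @export
read_cazyme_hits <- function(path) {
  x <- read_tsv_strict(path, c("protein_id", "tool", "family", "score"),
                       col_types = readr::cols(protein_id = "c", tool = "c",
                                               family = "c", score = "d"))
  bad <- setdiff(unique(x$tool), CAZYME_TOOLS)
  if (length(bad) > 0) {
    stop("unknown CAZyme tool(s) in ", path, ": ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(x[c("protein_id", "tool", "family", "score")])
}

#' Read TC/TF/STP signature calls
#'
#' @param path TSV with header columns `protein_id`, `gene_class` (one of
#'   `TC`, `TF`, `STP`) and optional `detail`.
#' @return tibble of non-CAZyme signature calls.
#' @export
read_signature_labels <- function(path) {
  x <- read_tsv_strict(path, c("protein_id", "gene_class"))
  bad <- setdiff(unique(x$gene_class), c("TC", "TF", "STP"))
  if (length(bad) > 0) {
    stop("gene_class must be TC, TF or STP in ", path, "; got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(x$detail)) x$detail <- NA_character_
  tibble::as_tibble(x[c("protein_id", "gene_class", "detail")])
}

#' Read PUL member proteins with their signature classes
#'
#' @param path TSV with header columns `pul_id`, `protein_id`, `gene_class`
#'   (one of the four signature classes or `Other`).
#' @return tibble of PUL membership.
#' @export
read_pul_proteins <- function(path) {
  x <- read_tsv_strict(path, c("pul_id", "protein_id", "gene_class"))
  bad <- setdiff(unique(x$gene_class), GENE_CLASSES)
  if (length(bad) > 0) {
    stop("unknown gene_class in ", path, ": ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(x[c("pul_id", "protein_id", "gene_class")])
}
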